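## Network construction: read raw connectomes, apply the streamline-count
## threshold, weight retained edges by inverse mean radial diffusivity, and
## calibrate thresholds against target cohort-mean densities.
##
## Threshold semantics: edges with FEWER than ns_thr streamlines are
## excluded, i.e. an edge is retained iff count >= ns_thr and count > 0
## (thresholds 0 and 1 are equivalent because count-0 cells were never
## edges).  The retained edge set depends only on the counts, never on RD.

#' Read a raw connectome from a counts/RD file pair
#'
#' Parses two labelled square TSV matrices (as written by [writeCohort()]
#' or any upstream tool emitting the same layout) and validates them
#' jointly: identical dimensions and label order (a permutation between the
#' two files is an error, never a silent reorder), exactly symmetric
#' integer counts with a zero diagonal, and RD finite-positive exactly
#' where the count is positive.  RD asymmetry up to 1e-12 relative is
#' tolerated (float noise from upstream writers) and resolved by averaging;
#' counts must be exactly symmetric.
#'
#' @param countsFile,rdFile file paths.
#' @param participantId recorded id; defaults to the counts-file stem.
#' @param atlasName recorded atlas label.
#' @return a validated [RawConnectome-class].
#' @export
readConnectome <- function(countsFile, rdFile,
                           participantId = sub("_counts.*$", "",
                               basename(countsFile)),
                           atlasName = "unspecified") {
    counts <- .readMatrixTSV(countsFile)
    rd <- .readMatrixTSV(rdFile)
    if (!identical(dim(counts), dim(rd)))
        stop("dimension mismatch between '", basename(countsFile),
            "' and '", basename(rdFile), "'")
    if (!identical(rownames(counts), rownames(rd)) ||
        !identical(colnames(counts), colnames(rd)))
        stop("node labels differ between counts and RD files ",
            "(permuted labels are rejected, not reordered)")
    if (any(counts < 0) || any(rd < 0))
        stop("negative entries in input matrices")
    ## RD: tolerate float asymmetry, then symmetrize by averaging
    asym <- abs(rd - t(rd))
    if (any(asym > 1e-12 * pmax(abs(rd), abs(t(rd)), 1e-300)))
        stop("RD matrix asymmetry exceeds tolerance")
    rd <- (rd + t(rd)) / 2
    RawConnectome(participantId, atlasName, counts, rd)
}

.readMatrixTSV <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
        check.names = FALSE, comment.char = "")
    m <- as.matrix(tab)
    if (nrow(m) != ncol(m))
        stop("matrix in '", basename(path), "' is not square")
    if (!identical(rownames(m), colnames(m)))
        stop("row and column labels disagree in '", basename(path), "'")
    storage.mode(m) <- "double"
    m
}

#' Threshold and weight a connectome
#'
#' Retains an edge iff its streamline count is at least \code{nsThr} (and
#' positive); the retained edge weight is the reciprocal mean radial
#' diffusivity, 1/RD in s/mm^2.  All other cells are 0.
#'
#' @param raw a [RawConnectome-class].
#' @param nsThr integer streamline-count threshold, >= 0.
#' @return a [WeightedNetwork-class].
#' @examples
#' \dontrun{buildWeighted(raw, nsThr = 6)  # keeps count >= 6}
#' @export
buildWeighted <- function(raw, nsThr) {
    stopifnot(is(raw, "RawConnectome"), nsThr >= 0)
    cn <- streamlineCounts(raw)
    keep <- cn >= nsThr & cn > 0
    w <- matrix(0, nrow(cn), ncol(cn), dimnames = dimnames(cn))
    w[keep] <- 1 / meanRD(raw)[keep]
    WeightedNetwork(w, as.integer(nsThr))
}

#' Network sparsity (connection density)
#'
#' The fraction of possible edges retained: nonzero upper-triangle weights
#' over n(n-1)/2.  (The source literature calls this quantity "sparsity";
#' values fall from 0.85 towards 0.25 as thresholding strengthens.)
#'
#' @param object a [WeightedNetwork-class] (or a symmetric weight matrix).
#' @return a fraction in [0, 1].
#' @export
#' @rdname networkSparsity
setMethod("networkSparsity", "WeightedNetwork", function(object)
    networkSparsity(edgeWeights(object)))

#' @rdname networkSparsity
setMethod("networkSparsity", "matrix", function(object) {
    n <- nrow(object)
    if (n < 2L)
        stop("sparsity needs at least 2 nodes")
    sum(object[upper.tri(object)] > 0) / (n * (n - 1L) / 2L)
})

## per-participant upper-triangle count vectors, computed once per cohort
.upperCounts <- function(cohort)
    lapply(cohort, function(rc) {
        cn <- streamlineCounts(rc)
        cn[upper.tri(cn)]
    })

.meanSparsityAt <- function(upperCounts, thr) {
    thr <- max(thr, 1L)  # count-0 cells are never edges
    mean(vapply(upperCounts, function(cnt) mean(cnt >= thr), numeric(1)))
}

#' Calibrate the streamline-count threshold to a target mean sparsity
#'
#' Returns the smallest integer threshold at which the cohort-mean network
#' sparsity (mean of per-participant densities, not the density of a
#' group-average network) is at or below \code{target}; 0 if the
#' unthresholded cohort is already at or below it.
#'
#' @param cohort list of [RawConnectome-class].
#' @param target target mean sparsity in (0, 1].
#' @return integer threshold.
#' @export
calibrateThreshold <- function(cohort, target) {
    if (!length(cohort))
        stop("empty cohort")
    if (target <= 0 || target > 1)
        stop("'target' must lie in (0, 1]")
    uc <- .upperCounts(cohort)
    .calibrate(uc, target)
}

.calibrate <- function(upperCounts, target) {
    if (.meanSparsityAt(upperCounts, 0L) <= target)
        return(0L)
    ## mean sparsity is non-increasing in thr and reaches 0 at
    ## max(count) + 1, so the minimal threshold exists; binary search
    lo <- 1L
    hi <- max(vapply(upperCounts, max, numeric(1))) + 1L
    while (lo < hi) {
        mid <- as.integer((lo + hi) %/% 2L)
        if (.meanSparsityAt(upperCounts, mid) <= target) hi <- mid
        else lo <- mid + 1L
    }
    as.integer(lo)
}

#' Plan a threshold sweep
#'
#' Calibrates one cohort-level threshold per target sparsity.  Targets
#' default to 0.85 down to 0.25 in steps of 0.05 (13 targets).
#'
#' @param cohort list of [RawConnectome-class].
#' @param targets strictly decreasing target sparsities in (0, 1].
#' @return a [SweepPlan-class].
#' @export
planSweep <- function(cohort, targets = seq(0.85, 0.25, by = -0.05)) {
    if (anyDuplicated(targets))
        stop("duplicate sweep targets")
    if (length(targets) > 1L && any(diff(targets) >= 0))
        stop("sweep targets must be strictly decreasing")
    uc <- .upperCounts(cohort)
    thr <- vapply(targets, function(tg) .calibrate(uc, tg), integer(1))
    new("SweepPlan", targetSparsities = as.numeric(targets),
        thresholds = thr)
}

#' Detect isolated nodes within a subnetwork
#'
#' Labels from \code{nodeSubset} that have no retained edge to any other
#' member of the subset.  Participants with isolated subnetwork nodes are
#' the typical source of influence-based exclusions downstream.
#'
#' @param net a [WeightedNetwork-class].
#' @param nodeSubset character vector of labels (defaults to all nodes).
#' @return character vector of isolated labels (possibly empty).
#' @export
detectIsolated <- function(net, nodeSubset = nodeLabels(net)) {
    stopifnot(is(net, "WeightedNetwork"))
    unknown <- setdiff(nodeSubset, nodeLabels(net))
    if (length(unknown))
        stop("unknown label(s): ", paste(unknown, collapse = ", "))
    sub <- edgeWeights(net)[nodeSubset, nodeSubset, drop = FALSE]
    nodeSubset[rowSums(sub > 0) == 0L]
}

#' Export the retained edge list of a thresholded connectome
#'
#' Optional per-threshold export: one row per retained upper-triangle edge
#' with the source count, RD and 1/RD weight.
#'
#' @param raw a [RawConnectome-class].
#' @param nsThr integer threshold.
#' @param path output TSV path.
#' @return the edge-list data.frame, invisibly.
#' @export
exportEdgeList <- function(raw, nsThr, path) {
    net <- buildWeighted(raw, nsThr)
    w <- edgeWeights(net)
    idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    lab <- nodeLabels(net)
    df <- data.frame(node_a = lab[idx[, 1]], node_b = lab[idx[, 2]],
        count = streamlineCounts(raw)[idx], rd = meanRD(raw)[idx],
        weight = w[idx])
    df <- df[order(df$node_a, df$node_b), , drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
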