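## Node-level and subnetwork-mean graph metrics.
##
## Three metrics, the ones computed per system network in the source
## analysis: node degree (weight-independent), nodal strength (sum of
## incident 1/RD weights), and the weighted clustering coefficient.  The
## weighted clustering variant is the Onnela geometric-mean form on
## max-normalised weights -- the Brain Connectivity Toolbox convention for
## undirected weighted graphs:
##
##   c_i = (2 / (k_i (k_i - 1))) * sum_{j<h} (w'_ij w'_ih w'_jh)^(1/3),
##   w' = w / max(w),  c_i = 0 when k_i < 2.
##
## Metrics are computed on induced subgraphs (extraction before metric
## computation), so degree counts only intra-subnetwork edges.

.asWeights <- function(object) {
    if (is(object, "WeightedNetwork")) edgeWeights(object)
    else if (is.matrix(object)) object
    else stop("expected a WeightedNetwork or a weight matrix")
}

#' Node degree
#'
#' Number of retained (nonzero-weight) edges incident to each node.
#' Independent of the edge weighting: rescaling every weight leaves it
#' unchanged.
#'
#' @param object a [WeightedNetwork-class] or symmetric weight matrix.
#' @return named integer vector over nodes.
#' @rdname nodeDegree
#' @export
setMethod("nodeDegree", "WeightedNetwork",
    function(object) nodeDegree(edgeWeights(object)))

#' @rdname nodeDegree
setMethod("nodeDegree", "matrix", function(object) {
    d <- rowSums(object > 0)
    storage.mode(d) <- "integer"
    d
})

#' Nodal strength
#'
#' Sum of the weights of the edges incident to each node (s/mm^2 under the
#' 1/RD weighting).  Reduces to the degree when all weights are 1.
#'
#' @param object a [WeightedNetwork-class] or symmetric weight matrix.
#' @return named numeric vector over nodes.
#' @rdname nodeStrength
#' @export
setMethod("nodeStrength", "WeightedNetwork",
    function(object) nodeStrength(edgeWeights(object)))

#' @rdname nodeStrength
setMethod("nodeStrength", "matrix", function(object) rowSums(object))

#' Weighted clustering coefficient
#'
#' Per-node triangle intensity in [0, 1].  The default \code{"onnela"}
#' variant takes the geometric mean of max-normalised triangle edge
#' weights, so it equals the binary clustering coefficient whenever all
#' nonzero weights are equal, and is invariant under global positive
#' rescaling of the weights.  \code{"binary"} clusters the binarised
#' support.  Nodes with degree < 2 score 0; an empty network scores all 0
#' (the max-weight normaliser is undefined).
#'
#' @param object a [WeightedNetwork-class] or symmetric weight matrix.
#' @param variant \code{"onnela"} (default) or \code{"binary"}.
#' @return named numeric vector over nodes.
#' @rdname nodeClustering
#' @export
setMethod("nodeClustering", "WeightedNetwork",
    function(object, variant = "onnela")
        nodeClustering(edgeWeights(object), variant))

#' @rdname nodeClustering
setMethod("nodeClustering", "matrix", function(object, variant = "onnela") {
    variant <- match.arg(variant, c("onnela", "binary"))
    w <- object
    k <- rowSums(w > 0)
    cc <- numeric(nrow(w))
    names(cc) <- rownames(w)
    mx <- max(w)
    if (mx == 0)
        return(cc)
    wh <- if (variant == "onnela") (w / mx)^(1 / 3) else (w > 0) * 1
    num <- diag(wh %*% wh %*% wh)  # 2 * sum over j<h of triangle terms
    ok <- k >= 2
    cc[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
    cc
})

#' Arithmetic mean of a node metric over a subnetwork
#'
#' Isolated nodes remain members and contribute their value (0 for degree,
#' strength and clustering) unless \code{dropIsolated} is set.
#'
#' @param values named numeric vector of node values.
#' @param members labels to average over (default: all).
#' @param dropIsolated if TRUE, drop zero-degree nodes before averaging;
#'   requires \code{degree}.
#' @param degree named degree vector, needed only with
#'   \code{dropIsolated = TRUE}.
#' @return the mean value.
#' @export
subnetworkMean <- function(values, members = names(values),
                           dropIsolated = FALSE, degree = NULL) {
    if (!length(members))
        stop("empty node set")
    missing <- setdiff(members, names(values))
    if (length(missing))
        stop("values missing for: ", paste(missing, collapse = ", "))
    if (dropIsolated) {
        if (is.null(degree))
            stop("'degree' required when dropIsolated = TRUE")
        members <- members[degree[members] > 0]
        if (!length(members))
            return(NaN)
    }
    mean(values[members])
}

#' Compute the cohort metric table
#'
#' For every participant, threshold and subnetwork: builds the thresholded
#' inverse-RD-weighted network, extracts the induced subnetwork, computes
#' node degree, strength and clustering, and records both the node-level
#' vectors and their arithmetic means.
#'
#' @param cohort list of [RawConnectome-class].
#' @param thresholds integer thresholds, or a [SweepPlan-class].
#' @param subnetworks named list of [SubnetworkSpec-class] (as returned by
#'   [loadSubnetworks()]).
#' @param clusteringVariant passed to [nodeClustering()].
#' @return a [MetricTable-class].
#' @export
computeMetrics <- function(cohort, thresholds, subnetworks,
                           clusteringVariant = "onnela") {
    if (is(thresholds, "SweepPlan"))
        thresholds <- unique(sweepThresholds(thresholds))
    thresholds <- as.integer(thresholds)
    memberSets <- lapply(subnetworks, function(s)
        if (is(s, "SubnetworkSpec")) members(s) else as.character(s))
    nCells <- length(cohort) * length(thresholds) * length(memberSets)
    ## accumulate flat vectors; data.frame construction once at the end
    mPid <- mSnm <- character(nCells)
    mThr <- integer(nCells)
    mDeg <- mClu <- mStr <- numeric(nCells)
    nvList <- vector("list", nCells)
    r <- 0L
    for (rc in cohort) {
        pid <- participantId(rc)
        cn <- streamlineCounts(rc)
        rdInv <- ifelse(cn > 0, 1 / meanRD(rc), 0)
        for (thr in thresholds) {
            w <- ifelse(cn >= max(thr, 1L), rdInv, 0)
            for (snm in names(memberSets)) {
                mem <- memberSets[[snm]]
                wm <- w[mem, mem, drop = FALSE]
                deg <- nodeDegree(wm)
                str <- nodeStrength(wm)
                clu <- nodeClustering(wm, clusteringVariant)
                r <- r + 1L
                mPid[r] <- pid; mSnm[r] <- snm; mThr[r] <- thr
                mDeg[r] <- mean(deg); mClu[r] <- mean(clu)
                mStr[r] <- mean(str)
                nvList[[r]] <- list(pid, snm, thr, mem,
                    as.numeric(deg), str, clu)
            }
        }
    }
    nm <- lengths(lapply(nvList, `[[`, 4L))
    nodeValues <- data.frame(
        participant = rep(vapply(nvList, `[[`, character(1), 1L), 3L * nm),
        subnetwork = rep(vapply(nvList, `[[`, character(1), 2L), 3L * nm),
        threshold = rep(vapply(nvList, `[[`, numeric(1), 3L), 3L * nm),
        metric = unlist(lapply(nm, function(k)
            rep(c("degree", "strength", "clustering"), each = k))),
        node = unlist(lapply(nvList, function(x) rep(x[[4L]], 3L))),
        value = unlist(lapply(nvList, function(x)
            c(x[[5L]], x[[6L]], x[[7L]]))))
    nodeValues$threshold <- as.integer(nodeValues$threshold)
    new("MetricTable",
        means = data.frame(participant = mPid, subnetwork = mSnm,
            threshold = mThr, mean_degree = mDeg, mean_clustering = mClu,
            mean_strength = mStr),
        nodeValues = nodeValues)
}

.METRIC_PRIORITY <- c("mean_degree", "mean_clustering", "mean_strength")

#' Collinearity screen over the mean metrics
#'
#' Per subnetwork, Pearson correlations among the three mean metrics across
#' rows of the metric table.  A metric is dropped when its absolute
#' correlation with an already-retained metric exceeds the cutoff, with a
#' fixed retention priority (degree, then clustering, then strength) so the
#' screen is deterministic.  A metric dropped in any subnetwork is dropped
#' from the analysis family altogether (the screen outcome is global, as in
#' the source analysis where mean strength fell to its > 0.85 correlation
#' with mean degree).  Zero-variance metrics are flagged and treated as
#' droppable.
#'
#' @param metricTable a [MetricTable-class] (or its means data.frame).
#' @param cutoff absolute-correlation cutoff, default 0.85.
#' @return list with elements \code{retained}, \code{dropped} (named by
#'   metric, value = reason), and \code{correlations} (per-subnetwork
#'   correlation matrices).
#' @export
collinearityScreen <- function(metricTable, cutoff = 0.85) {
    means <- if (is(metricTable, "MetricTable")) metricMeans(metricTable)
             else metricTable
    if (nrow(means) < 3L)
        stop("need at least 3 rows for a collinearity screen")
    cors <- list()
    droppedBy <- setNames(rep(NA_character_, 3L), .METRIC_PRIORITY)
    for (snm in unique(means$subnetwork)) {
        block <- means[means$subnetwork == snm, .METRIC_PRIORITY,
            drop = FALSE]
        sds <- vapply(block, stats::sd, numeric(1))
        cm <- suppressWarnings(cor(as.matrix(block)))
        cors[[snm]] <- cm
        retained <- character()
        for (mcol in .METRIC_PRIORITY) {
            if (is.na(sds[mcol]) || sds[mcol] == 0) {
                if (is.na(droppedBy[mcol]))
                    droppedBy[mcol] <- paste0("zero variance in '", snm, "'")
                next
            }
            rWith <- cm[mcol, retained]
            hit <- retained[which(abs(rWith) > cutoff)]
            if (length(hit)) {
                if (is.na(droppedBy[mcol]))
                    droppedBy[mcol] <- paste0("|r| > ", cutoff, " with ",
                        hit[1], " in '", snm, "'")
            } else retained <- c(retained, mcol)
        }
    }
    dropped <- droppedBy[!is.na(droppedBy)]
    list(retained = setdiff(.METRIC_PRIORITY, names(dropped)),
        dropped = dropped, correlations = cors)
}

#' Export a metric table
#'
#' Writes the tidy long node-level table and the wide per-row means table.
#'
#' @param metricTable a [MetricTable-class].
#' @param meansPath,nodesPath output CSV paths (NULL to skip either).
#' @return invisibly, the means data.frame.
#' @export
exportMetricTable <- function(metricTable, meansPath = NULL,
                              nodesPath = NULL) {
    stopifnot(is(metricTable, "MetricTable"))
    mm <- metricMeans(metricTable)
    mm <- mm[order(mm$subnetwork, mm$threshold, mm$participant), ,
        drop = FALSE]
    if (!is.null(meansPath))
        write.csv(mm, meansPath, row.names = FALSE, quote = FALSE)
    if (!is.null(nodesPath)) {
        nv <- nodeMetrics(metricTable)
        nv <- nv[order(nv$subnetwork, nv$metric, nv$threshold,
            nv$participant, nv$node), , drop = FALSE]
        write.csv(nv, nodesPath, row.names = FALSE, quote = FALSE)
    }
    invisible(mm)
}
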