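#' @import methods
#' @importFrom stats cor cor.test pt rnorm runif rbinom rnbinom rbeta sd
#'   setNames p.adjust plogis qlogis lm.fit
#' @importFrom utils read.table write.table read.csv write.csv head
NULL

.isSquare <- function(m) is.matrix(m) && nrow(m) == ncol(m)

.checkSymmetricZeroDiag <- function(m, what, tol = 0) {
    msg <- character()
    if (!.isSquare(m))
        return(sprintf("'%s' must be a square matrix", what))
    if (any(diag(m) != 0))
        msg <- c(msg, sprintf("'%s' must have a zero diagonal", what))
    d <- abs(m - t(m))
    if (tol == 0) {
        if (any(d > 0))
            msg <- c(msg, sprintf("'%s' must be exactly symmetric", what))
    } else if (any(d > tol * pmax(abs(m), abs(t(m)), 1e-300))) {
        msg <- c(msg, sprintf("'%s' asymmetry exceeds tolerance", what))
    }
    msg
}

#' Atlas node registry
#'
#' An \code{AtlasRegistry} holds the ordered node labels of a brain
#' parcellation atlas together with their gross compartment (cerebrum or
#' cerebellum).  Two registries ship with the package: \code{"aal"}
#' (90 cerebral areas) and \code{"desikan_killiany"} (84 areas: 82 cortical
#' and subcortical plus the two cerebellar hemispheres).  Label order is the
#' file order of the packaged registry and is never reordered by analysis
#' code.
#'
#' @slot name single character, the atlas name.
#' @slot nodeLabels character vector of unique node labels, in canonical
#'   order.
#' @slot cerebrumLabels subset of \code{nodeLabels} in the cerebrum.
#' @slot cerebellumLabels subset of \code{nodeLabels} in the cerebellum.
#'
#' @seealso [loadAtlas()], [loadSubnetworks()]
#' @export
setClass("AtlasRegistry",
    representation(name = "character", nodeLabels = "character",
        cerebrumLabels = "character", cerebellumLabels = "character"))

setValidity("AtlasRegistry", function(object) {
    msg <- character()
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    if (anyDuplicated(object@nodeLabels))
        msg <- c(msg, "node labels must be unique")
    if (!all(object@cerebrumLabels %in% object@nodeLabels))
        msg <- c(msg, "cerebrum labels must be a subset of node labels")
    if (!all(object@cerebellumLabels %in% object@nodeLabels))
        msg <- c(msg, "cerebellum labels must be a subset of node labels")
    if (length(intersect(object@cerebrumLabels, object@cerebellumLabels)))
        msg <- c(msg, "a label cannot be both cerebral and cerebellar")
    if (length(msg)) msg else TRUE
})

#' @rdname AtlasRegistry-class
#' @param name atlas name.
#' @param nodeLabels ordered node labels.
#' @param cerebrumLabels,cerebellumLabels compartment membership; by default
#'   all nodes are cerebral.
#' @return an \code{AtlasRegistry}.
#' @export
AtlasRegistry <- function(name, nodeLabels, cerebrumLabels = nodeLabels,
                          cerebellumLabels = character()) {
    new("AtlasRegistry", name = as.character(name),
        nodeLabels = as.character(nodeLabels),
        cerebrumLabels = as.character(cerebrumLabels),
        cerebellumLabels = as.character(cerebellumLabels))
}

#' Subnetwork specification
#'
#' Names a functional system (default mode, sensorimotor, visual or
#' auditory) and lists the atlas nodes belonging to it.
#'
#' @slot name subnetwork name.
#' @slot members character vector of atlas node labels, at least two.
#' @export
setClass("SubnetworkSpec",
    representation(name = "character", members = "character"))

setValidity("SubnetworkSpec", function(object) {
    msg <- character()
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    if (length(object@members) < 2L)
        msg <- c(msg, "a subnetwork needs at least 2 members")
    if (anyDuplicated(object@members))
        msg <- c(msg, "duplicate member labels")
    if (length(msg)) msg else TRUE
})

#' @rdname SubnetworkSpec-class
#' @param name,members see slots.
#' @export
SubnetworkSpec <- function(name, members)
    new("SubnetworkSpec", name = as.character(name),
        members = as.character(members))

#' Raw structural connectome for one participant
#'
#' Pairs the streamline-count matrix with the co-indexed mean radial
#' diffusivity (RD) matrix produced by tractography for a single
#' participant on one atlas.  Counts are exact integers and must be exactly
#' symmetric with a zero diagonal; RD is finite and strictly positive
#' exactly where the count is positive and zero elsewhere (an RD value
#' without a reconstructed tract is meaningless).  RD is in mm^2/s.
#'
#' @slot participantId participant identifier.
#' @slot atlasName atlas the matrices are indexed on.
#' @slot counts symmetric non-negative integer matrix of streamline counts,
#'   zero diagonal, node labels as dimnames.
#' @slot meanRD symmetric matrix of mean radial diffusivity along the
#'   connecting tracts (mm^2/s); positive where \code{counts > 0}, zero
#'   elsewhere.
#'
#' @seealso [readConnectome()], [buildWeighted()]
#' @export
setClass("RawConnectome",
    representation(participantId = "character", atlasName = "character",
        counts = "matrix", meanRD = "matrix"))

setValidity("RawConnectome", function(object) {
    msg <- .checkSymmetricZeroDiag(object@counts, "counts")
    msg <- c(msg, .checkSymmetricZeroDiag(object@meanRD, "meanRD"))
    cn <- object@counts
    rd <- object@meanRD
    if (.isSquare(cn) && .isSquare(rd)) {
        if (!identical(dim(cn), dim(rd)))
            msg <- c(msg, "counts and meanRD dimensions differ")
        else {
            if (!identical(dimnames(cn), dimnames(rd)))
                msg <- c(msg, "counts and meanRD labels differ")
            if (any(cn < 0) || any(cn != round(cn)))
                msg <- c(msg, "counts must be non-negative integers")
            pos <- cn > 0
            if (any(!is.finite(rd[pos])) || any(rd[pos] <= 0))
                msg <- c(msg,
                    "meanRD must be finite and positive wherever counts > 0")
            if (any(rd[!pos] != 0))
                msg <- c(msg, "meanRD must be zero wherever counts == 0")
        }
    }
    if (is.null(rownames(object@counts)))
        msg <- c(msg, "counts must carry node labels as dimnames")
    if (length(msg)) msg else TRUE
})

#' @rdname RawConnectome-class
#' @param participantId,atlasName,counts,meanRD see slots.
#' @export
RawConnectome <- function(participantId, atlasName, counts, meanRD)
    new("RawConnectome", participantId = as.character(participantId),
        atlasName = as.character(atlasName), counts = counts, meanRD = meanRD)

#' Thresholded, inverse-RD-weighted network
#'
#' The object every graph metric consumes.  An edge was retained if its
#' streamline count was at least \code{thresholdUsed} (and positive); its
#' weight is the reciprocal of the mean radial diffusivity of the tract
#' (units s/mm^2), so lower RD -- plausibly reflecting higher myelination or
#' axonal density -- gives a stronger edge.  A zero weight means the edge is
#' absent.
#'
#' @slot weights symmetric non-negative matrix, zero diagonal, node labels
#'   as dimnames.
#' @slot thresholdUsed the integer streamline-count threshold applied.
#' @export
setClass("WeightedNetwork",
    representation(weights = "matrix", thresholdUsed = "integer"))

setValidity("WeightedNetwork", function(object) {
    msg <- .checkSymmetricZeroDiag(object@weights, "weights")
    if (any(object@weights < 0))
        msg <- c(msg, "weights must be non-negative")
    if (length(object@thresholdUsed) != 1L || is.na(object@thresholdUsed) ||
        object@thresholdUsed < 0L)
        msg <- c(msg, "'thresholdUsed' must be a single non-negative integer")
    if (is.null(rownames(object@weights)))
        msg <- c(msg, "weights must carry node labels as dimnames")
    if (length(msg)) msg else TRUE
})

#' @rdname WeightedNetwork-class
#' @param weights,thresholdUsed see slots.
#' @export
WeightedNetwork <- function(weights, thresholdUsed = 0L)
    new("WeightedNetwork", weights = weights,
        thresholdUsed = as.integer(thresholdUsed))

#' Calibrated threshold sweep plan
#'
#' Maps each target mean network density ("sparsity" in the connectomics
#' usage adopted here: the fraction of possible edges retained, averaged
#' over participants) to the smallest integer streamline-count threshold
#' achieving it.  Thresholds are non-decreasing as the target density
#' decreases.
#'
#' @slot targetSparsities descending target densities in (0, 1].
#' @slot thresholds calibrated integer thresholds, parallel to the targets.
#' @export
setClass("SweepPlan",
    representation(targetSparsities = "numeric", thresholds = "integer"))

setValidity("SweepPlan", function(object) {
    msg <- character()
    ts <- object@targetSparsities
    if (length(ts) != length(object@thresholds))
        msg <- c(msg, "targets and thresholds must be parallel")
    if (any(ts <= 0) || any(ts > 1))
        msg <- c(msg, "targets must lie in (0, 1]")
    if (length(ts) > 1L && any(diff(ts) >= 0))
        msg <- c(msg, "targets must be strictly decreasing")
    if (length(object@thresholds) > 1L && any(diff(object@thresholds) < 0L))
        msg <- c(msg, "thresholds must be non-decreasing as targets decrease")
    if (length(msg)) msg else TRUE
})

#' Connectome-generating template
#'
#' Statistical stand-in for the tractogram-derived matrices of a cohort:
#' per-edge existence probabilities, expected streamline counts where an
#' edge exists, and the radial-diffusivity distribution.  Defaults place RD
#' at 0.6e-3 mm^2/s (sd 0.05e-3), a physiologically plausible white-matter
#' scale.
#'
#' @slot atlasName atlas the template is indexed on.
#' @slot edgeProb symmetric matrix of edge probabilities in [0, 1], zero
#'   diagonal.
#' @slot countMean symmetric positive matrix of expected streamline counts
#'   given edge existence.
#' @slot rdMean,rdSd mean and sd of edge RD (mm^2/s).
#' @slot countDispersion negative-binomial size parameter for the
#'   (overdispersed) streamline counts.
#' @export
setClass("ConnectomeTemplate",
    representation(atlasName = "character", edgeProb = "matrix",
        countMean = "matrix", rdMean = "numeric", rdSd = "numeric",
        countDispersion = "numeric"))

setValidity("ConnectomeTemplate", function(object) {
    msg <- .checkSymmetricZeroDiag(object@edgeProb, "edgeProb")
    msg <- c(msg, .checkSymmetricZeroDiag(object@countMean, "countMean"))
    if (any(object@edgeProb < 0) || any(object@edgeProb > 1))
        msg <- c(msg, "edgeProb entries must lie in [0, 1]")
    off <- row(object@countMean) != col(object@countMean)
    if (any(object@countMean[off] <= 0))
        msg <- c(msg, "countMean must be positive off the diagonal")
    if (object@rdMean <= 0 || object@rdSd <= 0 || object@countDispersion <= 0)
        msg <- c(msg, "rdMean, rdSd and countDispersion must be positive")
    if (length(msg)) msg else TRUE
})

#' Planted trait-connectivity effect
#'
#' Encodes a recoverable ground truth: on every edge incident to a target
#' node, the trait score (standardised within the cohort) shifts the edge RD
#' by \code{betaWeight} per SD (negative values lower RD and therefore raise
#' the 1/RD weight) and the edge-existence log-odds by \code{betaEdge} per
#' SD.  \code{betaWeight = betaEdge = 0} defines the global null.
#'
#' @slot targetNodes node labels carrying the effect.
#' @slot betaWeight RD shift (mm^2/s) per SD of the trait score.
#' @slot betaEdge logit shift of edge probability per SD of the trait score.
#' @export
setClass("EffectSpec",
    representation(targetNodes = "character", betaWeight = "numeric",
        betaEdge = "numeric"))

#' @rdname EffectSpec-class
#' @param targetNodes,betaWeight,betaEdge see slots.
#' @export
EffectSpec <- function(targetNodes = character(), betaWeight = 0,
                       betaEdge = 0)
    new("EffectSpec", targetNodes = as.character(targetNodes),
        betaWeight = as.numeric(betaWeight), betaEdge = as.numeric(betaEdge))

#' Synthetic cohort configuration
#'
#' Everything needed to generate a cohort reproducibly: one integer seed
#' governs all draws.  Identical configurations give identical output, down
#' to the written files.
#'
#' @slot nParticipants cohort size.
#' @slot seed integer seed for all randomness.
#' @slot ageRange ages are uniform on [min, max] years.
#' @slot femaleFraction probability that a participant is female (sex coded
#'   0 = male, 1 = female).
#' @slot subscaleResponseProb per-item endorsement probability of the trait
#'   questionnaire.
#' @slot subscales data.frame with columns \code{name} and \code{n_items};
#'   the default instrument has nine subscales whose item counts sum to 74.
#' @slot template a [ConnectomeTemplate-class].
#' @slot effect an [EffectSpec-class].
#' @export
setClass("SynthConfig",
    representation(nParticipants = "integer", seed = "integer",
        ageRange = "numeric", femaleFraction = "numeric",
        subscaleResponseProb = "numeric", subscales = "data.frame",
        template = "ConnectomeTemplate", effect = "EffectSpec"))

setValidity("SynthConfig", function(object) {
    msg <- character()
    if (object@nParticipants < 0L)
        msg <- c(msg, "'nParticipants' must be non-negative")
    if (length(object@ageRange) != 2L || diff(object@ageRange) < 0)
        msg <- c(msg, "'ageRange' must be c(min, max) with min <= max")
    if (object@femaleFraction < 0 || object@femaleFraction > 1)
        msg <- c(msg, "'femaleFraction' must lie in [0, 1]")
    if (object@subscaleResponseProb < 0 || object@subscaleResponseProb > 1)
        msg <- c(msg, "'subscaleResponseProb' must lie in [0, 1]")
    if (!all(c("name", "n_items") %in% names(object@subscales)))
        msg <- c(msg, "'subscales' needs columns 'name' and 'n_items'")
    tmpl <- object@template
    bad <- setdiff(object@effect@targetNodes, rownames(tmpl@edgeProb))
    if (length(bad))
        msg <- c(msg, paste0("effect target nodes not in template atlas: ",
            paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Per-participant subnetwork metric table
#'
#' Tidy container for graph metrics over a cohort: one mean row per
#' (participant, subnetwork, threshold) and the matching node-level values.
#' Means are exact arithmetic means of the node vectors, isolated nodes
#' included at zero.
#'
#' @slot means data.frame with columns \code{participant},
#'   \code{subnetwork}, \code{threshold}, \code{mean_degree},
#'   \code{mean_clustering}, \code{mean_strength}.
#' @slot nodeValues data.frame with columns \code{participant},
#'   \code{subnetwork}, \code{threshold}, \code{metric}, \code{node},
#'   \code{value}.
#' @export
setClass("MetricTable",
    representation(means = "data.frame", nodeValues = "data.frame"))

setValidity("MetricTable", function(object) {
    need <- c("participant", "subnetwork", "threshold", "mean_degree",
        "mean_clustering", "mean_strength")
    msg <- character()
    if (!all(need %in% names(object@means)))
        msg <- c(msg, paste("means must have columns",
            paste(need, collapse = ", ")))
    key <- object@means[c("participant", "subnetwork", "threshold")]
    if (anyDuplicated(key))
        msg <- c(msg, "duplicate (participant, subnetwork, threshold) rows")
    if (length(msg)) msg else TRUE
})
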