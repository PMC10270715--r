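#' @name accessors
#' @title Accessors for connsweep classes
#' @description Slot accessors; analysis code never touches slots directly.
#' @param object a connsweep object.
NULL

#' @rdname accessors
#' @export
setGeneric("atlasName", function(object) standardGeneric("atlasName"))
#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))
#' @rdname accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))
#' @rdname accessors
#' @export
setGeneric("streamlineCounts",
    function(object) standardGeneric("streamlineCounts"))
#' @rdname accessors
#' @export
setGeneric("meanRD", function(object) standardGeneric("meanRD"))
#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))
#' @rdname accessors
#' @export
setGeneric("thresholdUsed", function(object) standardGeneric("thresholdUsed"))
#' @rdname accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("targetSparsities",
    function(object) standardGeneric("targetSparsities"))
#' @rdname accessors
#' @export
setGeneric("sweepThresholds",
    function(object) standardGeneric("sweepThresholds"))
#' @rdname accessors
#' @export
setGeneric("metricMeans", function(object) standardGeneric("metricMeans"))
#' @rdname accessors
#' @export
setGeneric("nodeMetrics", function(object) standardGeneric("nodeMetrics"))

#' @rdname networkSparsity
#' @export
setGeneric("networkSparsity",
    function(object) standardGeneric("networkSparsity"))
#' @rdname nodeDegree
#' @export
setGeneric("nodeDegree", function(object) standardGeneric("nodeDegree"))
#' @rdname nodeStrength
#' @export
setGeneric("nodeStrength", function(object) standardGeneric("nodeStrength"))
#' @rdname nodeClustering
#' @export
setGeneric("nodeClustering", function(object, variant = "onnela")
    standardGeneric("nodeClustering"))

setMethod("atlasName", "AtlasRegistry", function(object) object@name)
setMethod("atlasName", "RawConnectome", function(object) object@atlasName)
setMethod("atlasName", "ConnectomeTemplate", function(object) object@atlasName)

setMethod("nodeLabels", "AtlasRegistry", function(object) object@nodeLabels)
setMethod("nodeLabels", "RawConnectome",
    function(object) rownames(object@counts))
setMethod("nodeLabels", "WeightedNetwork",
    function(object) rownames(object@weights))

setMethod("participantId", "RawConnectome",
    function(object) object@participantId)
setMethod("streamlineCounts", "RawConnectome", function(object) object@counts)
setMethod("meanRD", "RawConnectome", function(object) object@meanRD)
setMethod("edgeWeights", "WeightedNetwork", function(object) object@weights)
setMethod("thresholdUsed", "WeightedNetwork",
    function(object) object@thresholdUsed)
setMethod("members", "SubnetworkSpec", function(object) object@members)
setMethod("targetSparsities", "SweepPlan",
    function(object) object@targetSparsities)
setMethod("sweepThresholds", "SweepPlan", function(object) object@thresholds)
setMethod("metricMeans", "MetricTable", function(object) object@means)
setMethod("nodeMetrics", "MetricTable", function(object) object@nodeValues)

setMethod("show", "AtlasRegistry", function(object) {
    cat("AtlasRegistry '", object@name, "': ", length(object@nodeLabels),
        " nodes (", length(object@cerebrumLabels), " cerebral, ",
        length(object@cerebellumLabels), " cerebellar)\n", sep = "")
})

setMethod("show", "RawConnectome", function(object) {
    n <- nrow(object@counts)
    ne <- sum(object@counts[upper.tri(object@counts)] > 0)
    cat("RawConnectome participant '", object@participantId, "' on atlas '",
        object@atlasName, "': ", n, " nodes, ", ne, " edges\n", sep = "")
})

setMethod("show", "WeightedNetwork", function(object) {
    n <- nrow(object@weights)
    ne <- sum(object@weights[upper.tri(object@weights)] > 0)
    cat("WeightedNetwork: ", n, " nodes, ", ne,
        " edges (streamline threshold ", object@thresholdUsed, ")\n",
        sep = "")
})

setMethod("show", "SubnetworkSpec", function(object) {
    cat("SubnetworkSpec '", object@name, "': ", length(object@members),
        " members\n", sep = "")
})

setMethod("show", "SweepPlan", function(object) {
    cat("SweepPlan:", length(object@targetSparsities), "targets\n")
    print(data.frame(target_sparsity = object@targetSparsities,
        ns_thr = object@thresholds), row.names = FALSE)
})

setMethod("show", "MetricTable", function(object) {
    cat("MetricTable:", nrow(object@means),
        "(participant x subnetwork x threshold) rows\n")
    print(head(object@means), row.names = FALSE)
})
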