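## Atlas registries and subnetwork membership.
##
## The four analysed systems (default mode, sensorimotor, visual, auditory)
## are those consistently reported as altered in schizophrenia.  Published
## atlases do not fix their node memberships, so the packaged defaults are
## reconstructions: conventional resting-state assignments, guaranteed to
## contain the regions named as correlation drivers in the source analyses.
## They are fully overridable through a config file.

.SUBNETWORK_NAMES <- c("default_mode", "sensorimotor", "visual", "auditory")

.builtinAtlasFile <- function(name) {
    f <- system.file("extdata", paste0("atlas_", name, ".tsv"),
        package = "connsweep")
    if (!nzchar(f))
        stop("unknown built-in atlas: '", name, "'")
    f
}

#' Load an atlas node registry
#'
#' @param name either a built-in atlas name (\code{"aal"}, 90 cerebral
#'   areas; \code{"desikan_killiany"}, 84 areas of which 82 are cerebral and
#'   2 cerebellar) or the path to a two-column TSV with header
#'   \code{label<TAB>compartment}, compartment one of \code{cerebrum} /
#'   \code{cerebellum}.
#' @return an [AtlasRegistry-class].
#' @examples
#' length(nodeLabels(loadAtlas("aal")))              # 90
#' length(nodeLabels(loadAtlas("desikan_killiany"))) # 84
#' @export
loadAtlas <- function(name) {
    stopifnot(is.character(name), length(name) == 1L)
    path <- if (file.exists(name) && !dir.exists(name)) name
            else .builtinAtlasFile(name)
    tab <- read.table(path, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE, comment.char = "")
    if (!all(c("label", "compartment") %in% names(tab)))
        stop("atlas file must have columns 'label' and 'compartment'")
    if (anyDuplicated(tab$label))
        stop("duplicate labels in atlas file: ",
            paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
    bad <- setdiff(unique(tab$compartment), c("cerebrum", "cerebellum"))
    if (length(bad))
        stop("unknown compartment(s): ", paste(bad, collapse = ", "))
    nm <- if (file.exists(name) && !dir.exists(name))
        sub("\\.[^.]*$", "", basename(name)) else name
    AtlasRegistry(name = nm, nodeLabels = tab$label,
        cerebrumLabels = tab$label[tab$compartment == "cerebrum"],
        cerebellumLabels = tab$label[tab$compartment == "cerebellum"])
}

#' Load subnetwork membership definitions
#'
#' Returns the four analysed systems as named [SubnetworkSpec-class]
#' objects.  With \code{configPath = NULL} the packaged default
#' reconstructions for the given atlas are used; a user JSON config of the
#' shape \code{atlas -> subnetwork -> [labels]} overrides them.  Every
#' member must exist in the atlas; unknown labels are an error that names
#' the offending label, never a silent drop.
#'
#' @param atlas an [AtlasRegistry-class].
#' @param configPath optional path to a JSON membership config.
#' @return named list of \code{SubnetworkSpec}, names
#'   \code{default_mode}, \code{sensorimotor}, \code{visual},
#'   \code{auditory}.
#' @export
loadSubnetworks <- function(atlas, configPath = NULL) {
    stopifnot(is(atlas, "AtlasRegistry"))
    path <- configPath %||% system.file("extdata",
        "subnetworks_default.json", package = "connsweep")
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!atlasName(atlas) %in% names(cfg))
        stop("no subnetwork definitions for atlas '", atlasName(atlas), "'")
    defs <- cfg[[atlasName(atlas)]]
    out <- lapply(names(defs), function(nm) {
        mem <- as.character(defs[[nm]])
        if (!length(mem))
            stop("subnetwork '", nm, "' is empty")
        unknown <- setdiff(mem, nodeLabels(atlas))
        if (length(unknown))
            stop("subnetwork '", nm, "' references labels absent from ",
                "atlas '", atlasName(atlas), "': ",
                paste(unknown, collapse = ", "))
        SubnetworkSpec(nm, mem)
    })
    names(out) <- names(defs)
    out
}

#' Extract the induced subnetwork
#'
#' Restricts a weighted network to a subnetwork's member nodes.  The result
#' is the induced subgraph: exactly the edges with both endpoints in the
#' member set, weights preserved bit-exactly.
#'
#' @param net a [WeightedNetwork-class].
#' @param spec a [SubnetworkSpec-class] (or a character vector of labels).
#' @return a [WeightedNetwork-class] on the member nodes, in member order.
#' @export
extractSubnetwork <- function(net, spec) {
    stopifnot(is(net, "WeightedNetwork"))
    mem <- if (is(spec, "SubnetworkSpec")) members(spec)
           else as.character(spec)
    missing <- setdiff(mem, nodeLabels(net))
    if (length(missing))
        stop("subnetwork members absent from network: ",
            paste(missing, collapse = ", "))
    WeightedNetwork(edgeWeights(net)[mem, mem, drop = FALSE],
        thresholdUsed(net))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
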