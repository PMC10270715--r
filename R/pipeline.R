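## Pipeline orchestration: simulate (or read) -> build -> sweep ->
## associate -> report, as one configured, logged, seed-controlled run.
## All CSV outputs are sorted deterministically so identical configs give
## byte-identical result files.

#' Simulate a cohort to disk
#'
#' Generates participants and connectomes from a [SynthConfig-class] and
#' writes them (cohort table, matrix file pairs, manifest) to a directory,
#' which is created if absent.
#'
#' @param config a [SynthConfig-class].
#' @param dir output directory.
#' @return the manifest, invisibly.
#' @export
simulateCohort <- function(config, dir) {
    participants <- genParticipants(config)
    connectomes <- genConnectomes(participants, config)
    writeCohort(participants, connectomes, dir, config = config)
}

#' Read a cohort directory
#'
#' Reads \code{cohort.csv} plus each participant's counts/RD matrix pair,
#' validating every connectome on the way in.
#'
#' @param dir directory as written by [simulateCohort()] / [writeCohort()].
#' @param atlasName atlas label recorded on the connectomes.
#' @return list with \code{participants} (data.frame) and
#'   \code{connectomes} (list of [RawConnectome-class]).
#' @export
readCohort <- function(dir, atlasName = "unspecified") {
    cohortFile <- file.path(dir, "cohort.csv")
    if (!file.exists(cohortFile))
        stop("no cohort.csv in ", dir)
    participants <- read.csv(cohortFile, stringsAsFactors = FALSE)
    connectomes <- lapply(participants$id, function(id)
        readConnectome(file.path(dir, paste0(id, "_counts.tsv")),
            file.path(dir, paste0(id, "_rd.tsv")),
            participantId = id, atlasName = atlasName))
    list(participants = participants, connectomes = connectomes)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order -- cohort input (synthetic or on-disk),
#' threshold-sweep calibration, metric computation, collinearity screen,
#' per-threshold association with outlier exclusion and BH-FDR,
#' persistence classification, node-driver analysis for flagged pairs --
#' and writes result files, a stage-granularity log, and a manifest echoing
#' the full configuration.
#'
#' Node drivers are computed at the calibrated threshold whose target
#' sparsity is closest to \code{driverSparsity} (default 0.3, the density
#' at which the source analysis shows its per-node results).
#'
#' @param synth a [SynthConfig-class] to simulate from, or NULL.
#' @param cohortDir directory to read a cohort from (ignored when
#'   \code{synth} given).
#' @param atlas an [AtlasRegistry-class], a built-in atlas name, or NULL
#'   when \code{subnetworks} is supplied directly.
#' @param subnetworks named list of [SubnetworkSpec-class]; default
#'   \code{loadSubnetworks(atlas, subnetworkConfig)}.
#' @param subnetworkConfig optional membership JSON path.
#' @param targets strictly decreasing sweep targets, default 0.85..0.25 by
#'   0.05.
#' @param persistenceFraction,fdrLevel,cooksMultiplier analysis knobs
#'   (defaults 0.8, 0.05, 4).
#' @param cooksModel exclusion regression, see [excludeOutliers()].
#' @param metrics mean-metric columns to test; NULL (default) takes the
#'   collinearity screen's retained set.
#' @param driverSparsity target sparsity at which node drivers are tested.
#' @param clusteringVariant passed to [computeMetrics()].
#' @param outDir output directory, or NULL to skip writing files.
#' @param writeSimulatedCohort also write the simulated raw cohort under
#'   \code{outDir/cohort}.
#' @return list with elements \code{participants}, \code{sweepPlan},
#'   \code{metricTable}, \code{screen}, \code{associations},
#'   \code{persistence}, \code{drivers}, \code{driverThreshold},
#'   \code{manifest}; invisibly when \code{outDir} is set.
#' @export
runPipeline <- function(synth = NULL, cohortDir = NULL, atlas = NULL,
                        subnetworks = NULL, subnetworkConfig = NULL,
                        targets = seq(0.85, 0.25, by = -0.05),
                        persistenceFraction = 0.8, fdrLevel = 0.05,
                        cooksMultiplier = 4,
                        cooksModel = c("covariates", "association"),
                        metrics = NULL,
                        driverSparsity = 0.3,
                        clusteringVariant = "onnela", outDir = NULL,
                        writeSimulatedCohort = FALSE) {
    log <- character()
    say <- function(...) {
        log <<- c(log, paste0(...))
        invisible(NULL)
    }
    stage <- "input"
    res <- tryCatch({
        if (!is.null(synth)) {
            participants <- genParticipants(synth)
            connectomes <- genConnectomes(participants, synth)
            say("simulated cohort: n = ", nrow(participants), ", seed = ",
                synth@seed)
            if (writeSimulatedCohort && !is.null(outDir))
                simulateCohort(synth, file.path(outDir, "cohort"))
        } else if (!is.null(cohortDir)) {
            cr <- readCohort(cohortDir,
                atlasName = if (is.character(atlas)) atlas else "unspecified")
            participants <- cr$participants
            connectomes <- cr$connectomes
            say("read cohort from ", cohortDir, ": n = ",
                nrow(participants))
        } else stop("either 'synth' or 'cohortDir' is required")

        stage <- "subnetworks"
        if (is.null(subnetworks)) {
            if (is.null(atlas))
                stop("'atlas' or 'subnetworks' is required")
            reg <- if (is(atlas, "AtlasRegistry")) atlas else loadAtlas(atlas)
            subnetworks <- loadSubnetworks(reg, subnetworkConfig)
        }
        say("subnetworks: ", paste(names(subnetworks), collapse = ", "))

        stage <- "sweep calibration"
        plan <- planSweep(connectomes, targets)
        say("sweep: ", length(targets), " targets -> thresholds ",
            paste(sweepThresholds(plan), collapse = ","))

        stage <- "graph metrics"
        mt <- computeMetrics(connectomes, plan, subnetworks,
            clusteringVariant)
        say("metric table: ", nrow(metricMeans(mt)), " rows")

        stage <- "collinearity screen"
        screen <- collinearityScreen(mt)
        if (is.null(metrics))
            metrics <- screen$retained
        say("retained metrics: ", paste(metrics, collapse = ", "),
            if (length(screen$dropped))
                paste0(" (dropped: ",
                    paste(names(screen$dropped), collapse = ", "), ")")
            else "")

        stage <- "association"
        thrs <- unique(sweepThresholds(plan))
        assocU <- do.call(rbind, lapply(thrs, function(thr)
            runAssociation(mt, participants, thr, metrics = metrics,
                cooksMultiplier = cooksMultiplier,
                cooksModel = cooksModel)))
        ## one result block per sweep target; coincident thresholds
        ## duplicate their block so persistence is a fraction of targets
        assoc <- do.call(rbind, lapply(seq_along(targets), function(i) {
            blk <- assocU[assocU$threshold == sweepThresholds(plan)[i], ,
                drop = FALSE]
            cbind(target_sparsity = targetSparsities(plan)[i], blk)
        }))
        rownames(assoc) <- NULL
        say("associations: ", nrow(assocU), " tests over ", length(thrs),
            " distinct thresholds; excluded participants per test: ",
            paste(range(vapply(strsplit(assoc$excluded_ids, ";"),
                function(x) sum(nzchar(x)), integer(1))), collapse = "-"))

        stage <- "persistence"
        persistence <- summarizePersistence(assoc,
            persistenceFraction = persistenceFraction, alpha = fdrLevel)
        flagged <- persistence[persistence$persistence != "none", ,
            drop = FALSE]
        say("persistence: ", sum(persistence$persistence == "robust"),
            " robust, ", sum(persistence$persistence == "nominal"),
            " nominal")

        stage <- "node drivers"
        dthr <- sweepThresholds(plan)[
            which.min(abs(targetSparsities(plan) - driverSparsity))]
        drivers <- NULL
        if (nrow(flagged)) {
            drivers <- do.call(rbind, lapply(seq_len(nrow(flagged)),
                function(i) {
                    arow <- assoc[assoc$metric == flagged$metric[i] &
                        assoc$subnetwork == flagged$subnetwork[i] &
                        assoc$threshold == dthr, , drop = FALSE]
                    exIds <- if (nrow(arow))
                        strsplit(arow$excluded_ids[1], ";")[[1]]
                        else character()
                    nodeDriverAnalysis(mt, participants,
                        flagged$metric[i], flagged$subnetwork[i], dthr,
                        excludedIds = exIds[nzchar(exIds)])
                }))
            say("drivers at threshold ", dthr, ": ",
                sum(drivers$is_driver), " of ", nrow(drivers),
                " node tests")
        } else say("no flagged pairs; node-driver analysis skipped")

        manifest <- list(
            config = list(
                synthetic = !is.null(synth),
                synth = if (!is.null(synth)) .echoConfig(synth) else NULL,
                cohortDir = cohortDir,
                atlas = if (is(atlas, "AtlasRegistry")) atlasName(atlas)
                        else atlas,
                subnetworks = lapply(subnetworks, members),
                targets = targets, persistenceFraction = persistenceFraction,
                fdrLevel = fdrLevel, cooksMultiplier = cooksMultiplier,
                cooksModel = cooksModel,
                metrics = metrics, driverSparsity = driverSparsity,
                clusteringVariant = clusteringVariant),
            sweep = list(targets = targetSparsities(plan),
                thresholds = sweepThresholds(plan)),
            nParticipants = nrow(participants),
            driverThreshold = dthr)

        list(participants = participants, sweepPlan = plan,
            metricTable = mt, screen = screen, associations = assoc,
            persistence = persistence, drivers = drivers,
            driverThreshold = dthr, manifest = manifest, log = log)
    }, error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
            call. = FALSE))

    if (!is.null(outDir)) {
        .writeRunOutputs(res, outDir)
        return(invisible(res))
    }
    res
}

.writeRunOutputs <- function(res, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    plan <- res$sweepPlan
    write.csv(data.frame(target_sparsity = targetSparsities(plan),
        ns_thr = sweepThresholds(plan)),
        file.path(outDir, "sweep_plan.csv"), row.names = FALSE,
        quote = FALSE)
    exportMetricTable(res$metricTable,
        meansPath = file.path(outDir, "metrics_means.csv"),
        nodesPath = file.path(outDir, "metrics_nodes.csv"))
    assoc <- res$associations
    assoc <- assoc[order(assoc$subnetwork, assoc$metric, assoc$threshold,
        -assoc$target_sparsity), , drop = FALSE]
    write.csv(assoc, file.path(outDir, "associations.csv"),
        row.names = FALSE, quote = FALSE)
    write.csv(res$persistence, file.path(outDir, "persistence.csv"),
        row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
        list(persistence = res$persistence,
            driverThreshold = res$driverThreshold),
        file.path(outDir, "sweep_summary.json"), auto_unbox = TRUE,
        digits = NA, dataframe = "rows", pretty = TRUE)
    if (!is.null(res$drivers)) {
        dr <- res$drivers
        dr <- dr[order(dr$subnetwork, dr$metric, dr$node), , drop = FALSE]
        write.csv(dr, file.path(outDir, "node_drivers.csv"),
            row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(res$log, file.path(outDir, "log.txt"))
    invisible(NULL)
}

#' Human-readable run report
#'
#' Summarises a completed run directory: per metric x subnetwork x
#' threshold the partial r, p, q and significance tier (FDR / nominal /
#' ns), the persistence classification, and the driver list of every
#' flagged pair (or an explicit "no significant pairs" section).
#'
#' @param resultsDir directory written by [runPipeline()].
#' @param path output text file; default \code{report.txt} inside the run
#'   directory.
#' @return the report lines, invisibly.
#' @export
reportTables <- function(resultsDir, path = file.path(resultsDir,
                             "report.txt")) {
    manifestFile <- file.path(resultsDir, "manifest.json")
    if (!file.exists(manifestFile))
        stop("incomplete run: no manifest.json in ", resultsDir)
    assoc <- read.csv(file.path(resultsDir, "associations.csv"),
        stringsAsFactors = FALSE)
    pers <- read.csv(file.path(resultsDir, "persistence.csv"),
        stringsAsFactors = FALSE)
    tier <- ifelse(is.na(assoc$q), "degenerate",
        ifelse(assoc$q < 0.05, "FDR",
            ifelse(assoc$p < 0.05, "nominal", "ns")))
    lines <- c("Association results (metric x subnetwork x threshold)",
        sprintf("%-16s %-14s %9s %6s %7s %7s %7s %-9s", "metric",
            "subnetwork", "threshold", "n", "r", "p", "q", "tier"),
        sprintf("%-16s %-14s %9d %6s %7.3f %7.4f %7.4f %-9s",
            assoc$metric, assoc$subnetwork, assoc$threshold,
            ifelse(is.na(assoc$n_used), "NA", assoc$n_used),
            assoc$r, assoc$p, assoc$q, tier),
        "", "Persistence classification",
        sprintf("%-16s %-14s %12s %12s %-8s", "metric", "subnetwork",
            "frac_fdr", "frac_nominal", "class"),
        sprintf("%-16s %-14s %12.3f %12.3f %-8s", pers$metric,
            pers$subnetwork, pers$frac_fdr, pers$frac_nominal,
            pers$persistence), "")
    driversFile <- file.path(resultsDir, "node_drivers.csv")
    flagged <- pers[pers$persistence != "none", , drop = FALSE]
    if (nrow(flagged) && file.exists(driversFile)) {
        dr <- read.csv(driversFile, stringsAsFactors = FALSE)
        for (i in seq_len(nrow(flagged))) {
            blk <- dr[dr$metric == sub("^mean_", "", flagged$metric[i]) &
                dr$subnetwork == flagged$subnetwork[i], , drop = FALSE]
            hits <- blk[blk$is_driver, , drop = FALSE]
            lines <- c(lines, paste0("Drivers of ", flagged$metric[i],
                " in ", flagged$subnetwork[i], " (",
                flagged$persistence[i], "):"),
                if (nrow(hits)) sprintf("  %-24s r = %6.3f  p = %.4f",
                    hits$node, hits$r, hits$p)
                else "  (no node below p = 0.05)", "")
        }
    } else {
        lines <- c(lines, "No significant pairs: no persistent",
            "metric x subnetwork correlation was found.")
    }
    writeLines(lines, path)
    invisible(lines)
}
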