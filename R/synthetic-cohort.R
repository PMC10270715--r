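## Synthetic cohort generator.
##
## Stands in for the (undeposited) raw study data: trait questionnaire
## totals built from nine subscales bounded at 74, age and sex covariates
## independent of the score by construction, and per-participant
## streamline-count / radial-diffusivity matrix pairs in which connectivity
## of chosen target nodes shifts with the standardised trait score by a
## configurable effect size.
##
## RNG scheme: one integer seed governs everything.  Each generator stage
## seeds its own stream deterministically from the config seed plus a fixed
## stage offset (participants +0, connectomes +1), so identical configs are
## bit-identical and stages are insensitive to each other's draw counts.

.STAGE_OFFSET <- c(participants = 0L, connectomes = 1L)

#' Default trait questionnaire subscale registry
#'
#' Nine subscales whose item counts sum to 74, the structure of the
#' Schizotypal Personality Questionnaire (each item endorsed 0/1, the total
#' is the sum of the nine subscale scores, so the maximum attainable total
#' is 74).  Any nine-subscale registry summing to 74 is accepted by
#' [synthConfig()] in strict-instrument mode.
#'
#' @return data.frame with columns \code{name}, \code{n_items}.
#' @export
defaultSubscales <- function() {
    data.frame(
        name = c("ideas_of_reference", "excessive_social_anxiety",
            "odd_beliefs_magical_thinking", "unusual_perceptual_experiences",
            "odd_eccentric_behaviour", "no_close_friends", "odd_speech",
            "constricted_affect", "suspiciousness"),
        n_items = c(9L, 8L, 7L, 9L, 7L, 9L, 9L, 8L, 8L))
}

#' Generate a connectome template
#'
#' Draws a statistical template for a cohort's connectomes: symmetric
#' per-edge existence probabilities with the requested expected
#' upper-triangle density, and log-normally dispersed expected streamline
#' counts.  Edge probabilities are Beta-distributed around \code{density}
#' (concentration 10) so realised networks vary in topology; the degenerate
#' densities 0 and 1 are honoured exactly.
#'
#' @param atlasName label recorded on the template.
#' @param nNodes number of nodes (>= 3); ignored if \code{labels} given.
#' @param density expected edge density in [0, 1].
#' @param seed integer seed for the template draws.
#' @param labels optional node labels; default \code{n01, n02, ...}.
#' @param countMeanScale median expected streamline count on existing edges.
#' @param rdMean,rdSd radial-diffusivity mean and sd, mm^2/s.
#' @param countDispersion negative-binomial size for count overdispersion.
#' @return a [ConnectomeTemplate-class].
#' @export
genTemplate <- function(atlasName = "synthetic", nNodes = 20L, density = 0.5,
                        seed = 1L, labels = NULL, countMeanScale = 30,
                        rdMean = 0.6e-3, rdSd = 0.05e-3,
                        countDispersion = 5) {
    if (density < 0 || density > 1)
        stop("'density' must lie in [0, 1]")
    if (is.null(labels))
        labels <- sprintf("n%02d", seq_len(nNodes))
    n <- length(labels)
    if (n < 3L)
        stop("'nNodes' must be at least 3")
    set.seed(as.integer(seed))
    up <- upper.tri(matrix(0, n, n))
    m <- n * (n - 1L) / 2L
    p <- if (density == 0) rep(0, m)
         else if (density == 1) rep(1, m)
         else stats::rbeta(m, 10 * density, 10 * (1 - density))
    cm <- countMeanScale * exp(rnorm(m, 0, 0.4))
    edgeProb <- countMean <- matrix(0, n, n, dimnames = list(labels, labels))
    edgeProb[up] <- p
    countMean[up] <- cm
    edgeProb <- edgeProb + t(edgeProb)
    countMean <- countMean + t(countMean)
    diag(countMean) <- 0
    ## validity requires positive off-diagonal countMean even where
    ## edgeProb is 0 (the mean is conditional on existence)
    new("ConnectomeTemplate", atlasName = as.character(atlasName),
        edgeProb = edgeProb, countMean = countMean,
        rdMean = rdMean, rdSd = rdSd, countDispersion = countDispersion)
}

#' Assemble a synthetic cohort configuration
#'
#' Defaults mirror the reference cohort: 140 participants, ages uniform on
#' 19--55 years, 66\% female, per-item endorsement probability 0.17 (giving
#' a mean total near 12.6 of a 74 maximum).
#'
#' @param nParticipants cohort size.
#' @param seed integer seed governing all draws.
#' @param ageRange c(min, max) years.
#' @param femaleFraction P(sex == 1).
#' @param subscaleResponseProb per-item endorsement probability.
#' @param template a [ConnectomeTemplate-class].
#' @param effect an [EffectSpec-class]; the default is the global null.
#' @param subscales subscale registry (data.frame name, n_items).
#' @param strictInstrument if TRUE (default), require exactly nine
#'   subscales with item counts summing to 74.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(nParticipants = 140L, seed = 1L,
                        ageRange = c(19, 55), femaleFraction = 92 / 140,
                        subscaleResponseProb = 0.17,
                        template = genTemplate(seed = seed),
                        effect = EffectSpec(),
                        subscales = defaultSubscales(),
                        strictInstrument = TRUE) {
    if (strictInstrument &&
        (nrow(subscales) != 9L || sum(subscales$n_items) != 74L))
        stop("instrument error: strict mode requires nine subscales with ",
            "item counts summing to 74 (got ", nrow(subscales),
            " subscales, ", sum(subscales$n_items), " items)")
    new("SynthConfig", nParticipants = as.integer(nParticipants),
        seed = as.integer(seed), ageRange = as.numeric(ageRange),
        femaleFraction = femaleFraction,
        subscaleResponseProb = subscaleResponseProb,
        subscales = subscales, template = template, effect = effect)
}

#' Generate participants
#'
#' Subscale scores are binomial (one 0/1 endorsement per item with the
#' configured probability); the trait total is their exact sum, so it is
#' bounded by the 74-item instrument.  Age is uniform on the configured
#' range and sex Bernoulli(femaleFraction); score, age and sex are mutually
#' independent by construction.
#'
#' @param config a [SynthConfig-class].
#' @return data.frame with columns \code{id}, \code{spq_total},
#'   \code{sub1} ... \code{sub9}, \code{age}, \code{sex} (0 = male,
#'   1 = female).
#' @export
genParticipants <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    n <- config@nParticipants
    ns <- config@subscales$n_items
    k <- length(ns)
    subCols <- setNames(as.data.frame(matrix(0L, max(n, 0L), k)),
        paste0("sub", seq_len(k)))
    if (n == 0L)
        return(data.frame(id = character(), spq_total = integer(),
            subCols[0, , drop = FALSE], age = numeric(), sex = integer()))
    set.seed(config@seed + .STAGE_OFFSET[["participants"]])
    for (j in seq_len(k))
        subCols[[j]] <- rbinom(n, ns[j], config@subscaleResponseProb)
    total <- as.integer(rowSums(subCols))
    age <- runif(n, config@ageRange[1], config@ageRange[2])
    sex <- rbinom(n, 1L, config@femaleFraction)
    data.frame(id = sprintf("sub-%04d", seq_len(n)), spq_total = total,
        subCols, age = age, sex = sex)
}

## draws a truncated-normal matrix entrywise; redraws until strictly
## positive (physiological parameters make redraws vanishingly rare)
.rtruncnormPos <- function(n, mean, sd) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x <= 0))
        x[bad] <- rnorm(sum(bad), mean[bad], sd)
    x
}

#' Generate cohort connectomes
#'
#' For each participant draws a symmetric streamline-count matrix (edge
#' existence Bernoulli per the template probabilities; counts where present
#' are shifted negative-binomial, hence overdispersed and at least 1) and a
#' co-indexed radial-diffusivity matrix (truncated normal, strictly
#' positive) defined exactly where the count is positive.
#'
#' The planted effect standardises the trait total within the cohort to a
#' z-score and, on every edge incident to a target node, adds
#' \code{betaEdge * z} to the edge-existence log-odds and
#' \code{betaWeight * z} to the RD mean.  A negative \code{betaWeight}
#' therefore raises the 1/RD edge weight with the trait.
#'
#' @param participants as returned by [genParticipants()].
#' @param config the same [SynthConfig-class].
#' @return list of [RawConnectome-class], one per participant, in order.
#' @export
genConnectomes <- function(participants, config) {
    stopifnot(is(config, "SynthConfig"))
    tmpl <- config@template
    eff <- config@effect
    labels <- rownames(tmpl@edgeProb)
    n <- length(labels)
    up <- which(upper.tri(matrix(0, n, n)))
    iRow <- row(matrix(0, n, n))[up]
    jCol <- col(matrix(0, n, n))[up]
    targetIdx <- match(eff@targetNodes, labels)
    incident <- iRow %in% targetIdx | jCol %in% targetIdx
    z <- if (nrow(participants) > 1L && stats::sd(participants$spq_total) > 0)
        as.numeric(scale(participants$spq_total)) else
        rep(0, nrow(participants))
    p0 <- tmpl@edgeProb[up]
    mu0 <- tmpl@countMean[up]
    set.seed(config@seed + .STAGE_OFFSET[["connectomes"]])
    out <- vector("list", nrow(participants))
    for (i in seq_len(nrow(participants))) {
        p <- p0
        if (any(incident) && eff@betaEdge != 0)
            p[incident] <- stats::plogis(
                stats::qlogis(p0[incident]) + eff@betaEdge * z[i])
        exists <- rbinom(length(p), 1L, p) == 1L
        cnt <- integer(length(p))
        if (any(exists))
            cnt[exists] <- 1L + rnbinom(sum(exists),
                size = tmpl@countDispersion,
                mu = pmax(mu0[exists] - 1, 0.01))
        rdMean <- rep(tmpl@rdMean, length(p))
        if (any(incident) && eff@betaWeight != 0)
            rdMean[incident] <- rdMean[incident] + eff@betaWeight * z[i]
        rd <- numeric(length(p))
        if (any(exists))
            rd[exists] <- .rtruncnormPos(sum(exists), rdMean[exists],
                tmpl@rdSd)
        counts <- matrix(0L, n, n, dimnames = list(labels, labels))
        rdm <- matrix(0, n, n, dimnames = list(labels, labels))
        counts[up] <- cnt
        rdm[up] <- rd
        counts <- counts + t(counts)
        rdm <- rdm + t(rdm)
        out[[i]] <- RawConnectome(participants$id[i], tmpl@atlasName,
            counts, rdm)
    }
    out
}

#' Write a synthetic cohort to disk
#'
#' Writes the cohort table (\code{cohort.csv}, header
#' \code{id,spq_total,sub1..sub9,age,sex}), one pair of labelled square TSV
#' matrix files per participant (\code{<id>_counts.tsv},
#' \code{<id>_rd.tsv}), and a JSON manifest recording the seed, a config
#' echo, and the file list.  Output round-trips through
#' [readConnectome()]; two writes of the same config are byte-identical.
#'
#' @param participants,connectomes as generated.
#' @param dir output directory (created if absent).
#' @param config optional [SynthConfig-class], echoed into the manifest.
#' @return the manifest, invisibly.
#' @export
writeCohort <- function(participants, connectomes, dir, config = NULL) {
    if (nrow(participants) != length(connectomes))
        stop("participants and connectomes lengths differ")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(participants, file.path(dir, "cohort.csv"), row.names = FALSE,
        quote = FALSE)
    files <- c("cohort.csv")
    for (i in seq_along(connectomes)) {
        rc <- connectomes[[i]]
        id <- participantId(rc)
        if (id != participants$id[i])
            stop("participant order mismatch at row ", i)
        cf <- paste0(id, "_counts.tsv")
        rf <- paste0(id, "_rd.tsv")
        .writeMatrixTSV(streamlineCounts(rc), file.path(dir, cf))
        .writeMatrixTSV(meanRD(rc), file.path(dir, rf))
        files <- c(files, cf, rf)
    }
    manifest <- list(
        n_participants = nrow(participants),
        atlas = if (length(connectomes)) atlasName(connectomes[[1]])
                else NA_character_,
        seed = if (!is.null(config)) config@seed else NA_integer_,
        config = if (!is.null(config)) .echoConfig(config) else NULL,
        files = files)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

.writeMatrixTSV <- function(m, path) {
    con <- file(path, open = "wb")  # "wb": stable newlines across platforms
    on.exit(close(con))
    writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
    body <- apply(m, 1L, function(r)
        paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con)
}

.echoConfig <- function(config) {
    list(nParticipants = config@nParticipants, seed = config@seed,
        ageRange = config@ageRange, femaleFraction = config@femaleFraction,
        subscaleResponseProb = config@subscaleResponseProb,
        subscales = config@subscales,
        atlas = config@template@atlasName,
        nNodes = nrow(config@template@edgeProb),
        rdMean = config@template@rdMean, rdSd = config@template@rdSd,
        countDispersion = config@template@countDispersion,
        effect = list(targetNodes = config@effect@targetNodes,
            betaWeight = config@effect@betaWeight,
            betaEdge = config@effect@betaEdge))
}
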