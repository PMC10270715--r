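## Association statistics: demographic screening, partial correlation with
## age/sex correction, Cook's-distance outlier exclusion, BH-FDR over the
## per-threshold test family, persistence classification across the
## threshold sweep, and node-driver analysis.

#' Demographic screen
#'
#' Pairwise Pearson correlations (sex enters as its 0/1 code, i.e.
#' point-biserial) with two-sided p values among trait score, age and sex,
#' to verify the covariates are not correlated with the score or each
#' other.
#'
#' @param participants cohort data.frame with columns \code{spq_total},
#'   \code{age}, \code{sex}.
#' @return data.frame with columns \code{pair}, \code{r}, \code{p}.
#' @export
demographicScreen <- function(participants) {
    need <- c("spq_total", "age", "sex")
    stopifnot(all(need %in% names(participants)))
    if (nrow(participants) < 4L)
        stop("need at least 4 participants")
    for (v in need)
        if (stats::sd(participants[[v]]) == 0)
            stop("zero variance in '", v, "'")
    pairs <- list(c("spq_total", "age"), c("spq_total", "sex"),
        c("age", "sex"))
    do.call(rbind, lapply(pairs, function(pr) {
        ct <- cor.test(participants[[pr[1]]], participants[[pr[2]]],
            method = "pearson")
        data.frame(pair = paste(pr, collapse = " vs "),
            r = unname(ct$estimate), p = ct$p.value)
    }))
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of \code{x} and \code{y} after
#' least-squares projection on an intercept plus the covariates, with a
#' two-sided p value from the t transform on n - 2 - k degrees of freedom
#' (k covariates).  With no covariates this is the plain Pearson
#' correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix (n x k), or NULL for none.
#' @return list with \code{r}, \code{p}, \code{df}, \code{n}.
#' @export
partialCorr <- function(x, y, covariates = NULL) {
    n <- length(x)
    stopifnot(length(y) == n)
    k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
    if (n <= k + 3L)
        stop("need n > k + 3 observations")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        stop("zero residual variance: constant input")
    if (k > 0L) {
        z <- cbind(1, as.matrix(covariates))
        if (qr(z)$rank < ncol(z))
            stop("rank-deficient covariate matrix")
        rx <- stats::lm.fit(z, x)$residuals
        ry <- stats::lm.fit(z, y)$residuals
    } else {
        rx <- x - mean(x)
        ry <- y - mean(y)
    }
    if (sum(rx^2) == 0 || sum(ry^2) == 0)
        stop("zero residual variance")
    r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
    df <- n - 2L - k
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    list(r = r, p = 2 * pt(-abs(tstat), df), df = df, n = n)
}

#' Cook's distance
#'
#' Influence of each observation on an OLS fit:
#' D_i = e_i^2 / (p s^2) * h_ii / (1 - h_ii)^2 with hat diagonal h_ii,
#' residual e_i, p design columns and residual mean square s^2; equal to
#' the leave-one-out fitted-value displacement form.  Exact leverage points
#' (h_ii = 1) are flagged with infinite distance.
#'
#' @param response numeric response vector.
#' @param design design matrix including the intercept column.
#' @return numeric vector of distances.
#' @export
cooksDistance <- function(response, design) {
    design <- as.matrix(design)
    n <- nrow(design)
    p <- ncol(design)
    stopifnot(length(response) == n, n > p)
    qrd <- qr(design)
    if (qrd$rank < p)
        stop("rank-deficient design")
    e <- qr.resid(qrd, response)
    q <- qr.Q(qrd)
    h <- rowSums(q^2)
    s2 <- sum(e^2) / (n - p)
    d <- numeric(n)
    exact <- h >= 1 - 1e-10
    d[exact] <- Inf
    d[!exact] <- e[!exact]^2 / (p * s2) * h[!exact] / (1 - h[!exact])^2
    d
}

#' Exclude influential observations
#'
#' Removes, in a single pass, every observation whose Cook's distance
#' exceeds \code{multiplier} times the mean Cook's distance.  In connectome
#' data such points typically have isolated subnetwork nodes or are
#' degree-distribution outliers; pass \code{annotations} (named by
#' participant) to carry that context into the exclusion record.
#'
#' Two regression models are available for the distances.  The default,
#' \code{"covariates"}, regresses the metric on intercept + covariates
#' only, so exclusion flags metric-distribution anomalies and is
#' independent of the trait score under the null -- the downstream partial
#' correlation keeps its nominal type-I error.  \code{"association"}
#' includes the trait score in the regression; that variant conditions the
#' exclusion on the relation being tested and demonstrably inflates the
#' null rejection rate (roughly twofold at n = 100 in simulation), so it is
#' provided for comparison, not as the default.
#'
#' @param metric numeric metric values.
#' @param score numeric trait scores.
#' @param covariates numeric covariate matrix or NULL.
#' @param multiplier exclusion multiplier, default 4.
#' @param ids observation identifiers.
#' @param annotations optional named character vector of per-id notes.
#' @param model \code{"covariates"} (default) or \code{"association"}.
#' @return list with \code{kept} (integer index), \code{excludedIds},
#'   \code{cooks} (named by id), \code{record} (data.frame id, cooks_d,
#'   excluded, note).
#' @export
excludeOutliers <- function(metric, score, covariates = NULL, multiplier = 4,
                            ids = as.character(seq_along(metric)),
                            annotations = NULL,
                            model = c("covariates", "association")) {
    model <- match.arg(model)
    ones <- rep(1, length(metric))
    design <- if (model == "association")
        cbind(intercept = ones, score = score, covariates)
    else cbind(intercept = ones, covariates)
    d <- cooksDistance(metric, design)
    out <- is.finite(d) & d > multiplier * mean(d)
    out[is.infinite(d)] <- TRUE
    kept <- which(!out)
    k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
    if (length(kept) <= k + 3L)
        stop("outlier exclusion would leave n <= k + 3")
    note <- rep("", length(ids))
    if (!is.null(annotations)) {
        hit <- match(ids, names(annotations))
        note[!is.na(hit)] <- annotations[hit[!is.na(hit)]]
    }
    list(kept = kept, excludedIds = ids[out],
        cooks = setNames(d, ids),
        record = data.frame(id = ids, cooks_d = d, excluded = out,
            note = note))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR-adjusted q values over a test family, order-preserving and
#' capped at 1.
#'
#' @param p numeric vector of p values in (0, 1].
#' @return numeric vector of q values, same order as the input.
#' @export
fdrBH <- function(p) {
    if (!length(p))
        stop("empty p-value vector")
    if (any(!is.na(p) & (p <= 0 | p > 1)))
        stop("p values must lie in (0, 1]")
    p.adjust(p, method = "BH")
}

#' Per-threshold association analysis
#'
#' For every retained metric x subnetwork cell at one threshold: Cook's
#' distance exclusion (see [excludeOutliers()]), partial correlation of the
#' metric with the trait score correcting for the covariates on the kept
#' rows, then BH-FDR across the family of tests at this threshold (by
#' default 2 metrics x 4 subnetworks = 8 tests).  Degenerate cells (zero
#' variance and similar) are reported as NA rows with the failure message,
#' never silently dropped.
#'
#' @param metricTable a [MetricTable-class].
#' @param participants cohort data.frame (\code{id}, \code{spq_total},
#'   \code{age}, \code{sex}).
#' @param threshold the integer threshold to analyse.
#' @param metrics mean-metric columns to test (typically the
#'   \code{retained} element of [collinearityScreen()]).
#' @param covariates character vector of covariate columns, default age
#'   and sex.
#' @param cooksMultiplier exclusion multiplier, default 4.
#' @param cooksModel exclusion regression, see [excludeOutliers()].
#' @return data.frame with one row per metric x subnetwork: \code{metric},
#'   \code{subnetwork}, \code{threshold}, \code{n_used}, \code{r},
#'   \code{p}, \code{q}, \code{excluded_ids} (';'-joined), \code{note};
#'   Cook's distances attached as attribute \code{"cooks"}.
#' @export
runAssociation <- function(metricTable, participants, threshold,
                           metrics = c("mean_degree", "mean_clustering"),
                           covariates = c("age", "sex"),
                           cooksMultiplier = 4,
                           cooksModel = c("covariates", "association")) {
    cooksModel <- match.arg(cooksModel)
    means <- metricMeans(metricTable)
    means <- means[means$threshold == threshold, , drop = FALSE]
    if (!nrow(means))
        stop("no metric rows at threshold ", threshold)
    covm <- as.matrix(participants[, covariates, drop = FALSE])
    rows <- list()
    cooksAll <- list()
    i <- 0L
    for (snm in sort(unique(means$subnetwork))) {
        block <- means[means$subnetwork == snm, , drop = FALSE]
        block <- block[match(participants$id, block$participant), ,
            drop = FALSE]
        if (anyNA(block$participant))
            stop("metric table is missing participants in subnetwork '",
                snm, "'")
        for (mcol in metrics) {
            i <- i + 1L
            res <- tryCatch({
                ex <- excludeOutliers(block[[mcol]],
                    participants$spq_total, covm,
                    multiplier = cooksMultiplier, ids = participants$id,
                    model = cooksModel)
                pc <- partialCorr(block[[mcol]][ex$kept],
                    participants$spq_total[ex$kept],
                    covm[ex$kept, , drop = FALSE])
                cooksAll[[paste(mcol, snm, sep = "|")]] <- ex$cooks
                data.frame(metric = mcol, subnetwork = snm,
                    threshold = threshold, n_used = length(ex$kept),
                    r = pc$r, p = pc$p, q = NA_real_,
                    excluded_ids = paste(ex$excludedIds, collapse = ";"),
                    note = "")
            }, error = function(e)
                data.frame(metric = mcol, subnetwork = snm,
                    threshold = threshold, n_used = NA_integer_,
                    r = NA_real_, p = NA_real_, q = NA_real_,
                    excluded_ids = "",
                    note = paste("degenerate:", conditionMessage(e))))
            rows[[i]] <- res
        }
    }
    out <- do.call(rbind, rows)
    ok <- !is.na(out$p)
    out$q[ok] <- fdrBH(out$p[ok])
    out <- out[order(out$subnetwork, out$metric), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "cooks") <- cooksAll
    out
}

#' Classify persistence across the threshold sweep
#'
#' A metric x subnetwork pair is \code{robust} when FDR-significant
#' (q < alpha) at at least \code{persistenceFraction} of the swept
#' thresholds; otherwise \code{nominal} when p < alpha at at least that
#' fraction of thresholds; otherwise \code{none}.  Both fractions are
#' always reported so the classification is auditable.
#'
#' @param results rbind of [runAssociation()] outputs over >= 2 thresholds.
#' @param persistenceFraction default 0.8.
#' @param alpha significance level, default 0.05.
#' @return data.frame per pair: \code{metric}, \code{subnetwork},
#'   \code{n_thresholds}, \code{frac_fdr}, \code{frac_nominal},
#'   \code{persistence}.
#' @export
summarizePersistence <- function(results, persistenceFraction = 0.8,
                                 alpha = 0.05) {
    if (length(unique(results$threshold)) < 2L)
        stop("persistence needs results from at least 2 thresholds")
    keys <- unique(results[c("metric", "subnetwork")])
    out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
        blk <- results[results$metric == keys$metric[i] &
            results$subnetwork == keys$subnetwork[i], , drop = FALSE]
        nt <- nrow(blk)
        fFdr <- sum(!is.na(blk$q) & blk$q < alpha) / nt
        fNom <- sum(!is.na(blk$p) & blk$p < alpha) / nt
        cls <- if (fFdr >= persistenceFraction) "robust"
               else if (fNom >= persistenceFraction) "nominal"
               else "none"
        data.frame(metric = keys$metric[i],
            subnetwork = keys$subnetwork[i], n_thresholds = nt,
            frac_fdr = fFdr, frac_nominal = fNom, persistence = cls)
    }))
    out[order(out$subnetwork, out$metric), , drop = FALSE]
}

#' Node-driver analysis
#'
#' For a metric x subnetwork pair already flagged by the persistence
#' summary, correlates each member node's metric value with the trait score
#' (same covariates; the subnetwork-level exclusion set is reused, so node
#' tests run on exactly the rows the subnetwork test used).  A node drives
#' the subnetwork correlation when its uncorrected p value is below 0.05
#' -- exploratory by design, no multiplicity correction.
#'
#' @param metricTable a [MetricTable-class].
#' @param participants cohort data.frame.
#' @param metric \code{"degree"}, \code{"strength"} or \code{"clustering"}
#'   (mean-column names \code{mean_*} are also accepted).
#' @param subnetwork subnetwork name.
#' @param threshold integer threshold at which to test.
#' @param excludedIds participant ids excluded at the subnetwork level.
#' @param covariates covariate columns, default age and sex.
#' @param alpha driver threshold on the uncorrected p value, default 0.05.
#' @return data.frame per node: \code{subnetwork}, \code{metric},
#'   \code{node}, \code{r}, \code{p}, \code{is_driver}.
#' @export
nodeDriverAnalysis <- function(metricTable, participants, metric, subnetwork,
                               threshold, excludedIds = character(),
                               covariates = c("age", "sex"), alpha = 0.05) {
    metric <- sub("^mean_", "", metric)
    nv <- nodeMetrics(metricTable)
    nv <- nv[nv$subnetwork == subnetwork & nv$threshold == threshold &
        nv$metric == metric, , drop = FALSE]
    if (!nrow(nv))
        stop("no node values for ", metric, " / ", subnetwork,
            " at threshold ", threshold)
    keep <- !participants$id %in% excludedIds
    part <- participants[keep, , drop = FALSE]
    covm <- as.matrix(part[, covariates, drop = FALSE])
    out <- do.call(rbind, lapply(sort(unique(nv$node)), function(nd) {
        vals <- nv[nv$node == nd, , drop = FALSE]
        v <- vals$value[match(part$id, vals$participant)]
        if (anyNA(v))
            stop("missing node values for node '", nd, "'")
        res <- tryCatch(partialCorr(v, part$spq_total, covm),
            error = function(e) list(r = NA_real_, p = NA_real_))
        data.frame(subnetwork = subnetwork, metric = metric, node = nd,
            r = res$r, p = res$p,
            is_driver = !is.na(res$p) && res$p < alpha)
    }))
    rownames(out) <- NULL
    out
}
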