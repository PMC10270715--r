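test_that("demographic screen reports pairwise r/p and rejects degenerates", {
    set.seed(2)
    p <- data.frame(spq_total = rpois(200, 12), age = runif(200, 19, 55),
        sex = rbinom(200, 1, 0.5))
    scr <- demographicScreen(p)
    expect_identical(nrow(scr), 3L)
    expect_true(all(abs(scr$r) < 0.2))
    # age duplicated as score -> r = 1
    dup <- p
    dup$spq_total <- dup$age
    scrDup <- demographicScreen(dup)
    expect_equal(scrDup$r[scrDup$pair == "spq_total vs age"], 1)
    cst <- p
    cst$sex <- 1L
    expect_error(demographicScreen(cst), "zero variance")
    # independent variables at n = 1000: small r, p not extreme
    set.seed(3)
    big <- data.frame(spq_total = rpois(1000, 12),
        age = runif(1000, 19, 55), sex = rbinom(1000, 1, 0.66))
    expect_true(all(abs(demographicScreen(big)$r) < 0.1))
})

test_that("partialCorr equals the inverse-correlation-matrix closed form", {
    # no covariates: plain Pearson
    set.seed(4)
    x <- rnorm(50)
    y <- 0.5 * x + rnorm(50)
    pc <- partialCorr(x, y)
    ct <- cor.test(x, y)
    expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
    # y = x given a non-collinear covariate -> r = 1
    z <- rnorm(50)
    expect_equal(partialCorr(x, x, cbind(z))$r, 1, tolerance = 1e-12)
    # trivariate Gaussian fixtures against the matrix-inversion oracle
    for (s in 1:10) {
        set.seed(s)
        n <- 40 + 10 * s
        cv <- cbind(rnorm(n), rbinom(n, 1, 0.5))
        xx <- rnorm(n) + 0.3 * cv[, 1]
        yy <- 0.4 * xx + rnorm(n) - 0.2 * cv[, 2]
        expect_equal(partialCorr(xx, yy, cv)$r,
            partialCorrInv(xx, yy, cv), tolerance = 1e-10)
    }
    expect_error(partialCorr(x[1:4], y[1:4], cbind(z[1:4])), "n > k")
    expect_error(partialCorr(x, y, cbind(z, z)), "rank")
    expect_error(partialCorr(x, rep(1, 50), cbind(z)), "residual variance")
})

test_that("cooksDistance matches the leave-one-out refit definition", {
    for (s in 1:8) {
        set.seed(s)
        n <- 30
        X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
        y <- X %*% c(1, 0.5, -0.3) + rnorm(n)
        d <- cooksDistance(y, X)
        expect_equal(d, cooksLOO(y, X), tolerance = 1e-8)
        expect_equal(d, unname(stats::cooks.distance(
            stats::lm(y ~ X[, 2] + X[, 3]))), tolerance = 1e-10)
    }
    # a point adjusted to have exactly zero residual has zero distance
    set.seed(99)
    X <- cbind(1, rnorm(12))
    y0 <- rnorm(12)
    qrX <- qr(X)
    e0 <- qr.resid(qrX, y0)
    h <- rowSums(qr.Q(qrX)^2)
    y0[3] <- y0[3] - e0[3] / (1 - h[3])
    d <- cooksDistance(y0, X)
    expect_lt(d[3], 1e-20)
    # duplicated balanced design rows get equal distance within pairs
    Xd <- cbind(1, rep(c(0, 1, 2), each = 2))
    yd <- c(0.1, 0.1, 1.2, 1.2, 1.9, 1.9)
    dd <- cooksDistance(yd, Xd)
    expect_equal(dd[1], dd[2])
    expect_equal(dd[3], dd[4])
    expect_error(cooksDistance(yd, cbind(Xd, Xd[, 2])), "rank")
})

test_that("outlier exclusion removes planted gross outliers, single pass", {
    set.seed(9)
    n <- 80
    score <- rpois(n, 12)
    cv <- cbind(age = runif(n, 19, 55), sex = rbinom(n, 1, 0.5))
    metric <- 2 + 0.1 * score + rnorm(n, 0, 1)
    metric[17] <- metric[17] + 10  # ~10 SD off the line
    ex <- excludeOutliers(metric, score, cv)
    expect_true("17" %in% ex$excludedIds)
    expect_false(17L %in% ex$kept)
    expect_identical(nrow(ex$record), as.integer(n))
    # multiplier -> Inf keeps everything
    exInf <- excludeOutliers(metric, score, cv, multiplier = Inf)
    expect_identical(exInf$kept, seq_len(n))
    # balanced design with symmetric perturbations: every observation has
    # the same Cook's distance, so none can exceed 4x the mean
    sh <- rep(c(0, 1), each = 10)
    mh <- 0.5 * sh + rep(c(0.01, -0.01), 10)
    exh <- excludeOutliers(mh, sh, NULL, multiplier = 4)
    expect_length(exh$excludedIds, 0)
})

test_that("the 4x-mean rule rarely bites hard on Gaussian cohorts", {
    fracs <- vapply(1:40, function(s) {
        set.seed(s)
        n <- 100
        score <- rnorm(n)
        m <- 0.3 * score + rnorm(n)
        ex <- excludeOutliers(m, score, NULL)
        length(ex$excludedIds) / n
    }, numeric(1))
    expect_true(all(fracs <= 0.2))
})

test_that("fdrBH performs the step-up adjustment", {
    expect_equal(fdrBH(0.037), 0.037)
    expect_equal(fdrBH(rep(0.02, 5)), rep(0.02, 5))
    # hand-worked example
    expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    for (s in 1:10) {
        set.seed(s)
        p <- runif(8)^2
        q <- fdrBH(p)
        expect_equal(q, bhHand(p), tolerance = 1e-12)
        expect_true(all(q >= p))
        # permutation equivariance
        o <- sample(8)
        expect_equal(fdrBH(p[o]), q[o], tolerance = 1e-12)
        # monotone transform of p
        expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
    expect_error(fdrBH(numeric(0)), "empty")
    expect_error(fdrBH(c(0.5, 0)), "lie in")
})

test_that("runAssociation runs the 8-test family with FDR at one
           threshold", {
    cfg <- toyConfig(n = 120, seed = 77, betaEdge = 0.8)
    p <- genParticipants(cfg)
    cn <- genConnectomes(p, cfg)
    mt <- computeMetrics(cn, 0L, toySubnetworks())
    res <- runAssociation(mt, p, 0L)
    expect_identical(nrow(res), 8L)
    expect_setequal(unique(res$metric), c("mean_degree", "mean_clustering"))
    ok <- !is.na(res$p)
    expect_equal(res$q[ok], bhHand(res$p[ok]), tolerance = 1e-12)
    # a strongly planted sensorimotor edge effect shows up positive
    sm <- res[res$metric == "mean_degree" & res$subnetwork ==
        "sensorimotor", ]
    expect_gt(sm$r, 0)
    expect_lt(sm$q, 0.05)
    expect_identical(sm$n_used,
        nrow(p) - sum(nzchar(strsplit(sm$excluded_ids, ";")[[1]])))
    # a constant metric column is reported as degenerate, not dropped
    mtc <- mt
    mm <- metricMeans(mtc)
    mm$mean_clustering[mm$subnetwork == "auditory"] <- 0.5
    mtc@means <- mm
    resc <- runAssociation(mtc, p, 0L)
    bad <- resc[resc$metric == "mean_clustering" &
        resc$subnetwork == "auditory", ]
    expect_true(is.na(bad$r))
    expect_match(bad$note, "degenerate")
    expect_identical(nrow(resc), 8L)
})

test_that("persistence classification follows the stated fractions", {
    mk <- function(p, q) data.frame(metric = "mean_degree",
        subnetwork = "sensorimotor", threshold = seq_along(p),
        n_used = 100L, r = 0.3, p = p, q = q, excluded_ids = "",
        note = "")
    # q < 0.05 everywhere -> robust
    allq <- mk(rep(0.01, 13), rep(0.02, 13))
    expect_identical(summarizePersistence(allq)$persistence, "robust")
    # p >= 0.05 everywhere -> none
    none <- mk(rep(0.5, 13), rep(0.8, 13))
    expect_identical(summarizePersistence(none)$persistence, "none")
    # q < 0.05 at 10 of 13 (0.769 < 0.8), p < 0.05 at 13 of 13 -> nominal
    mixed <- mk(rep(0.01, 13), c(rep(0.01, 10), rep(0.2, 3)))
    s <- summarizePersistence(mixed)
    expect_identical(s$persistence, "nominal")
    expect_equal(s$frac_fdr, 10 / 13, tolerance = 1e-12)
    expect_equal(s$frac_nominal, 1)
    # 11 of 13 is 0.846 >= 0.8 -> robust
    mixed2 <- mk(rep(0.01, 13), c(rep(0.01, 11), rep(0.2, 2)))
    expect_identical(summarizePersistence(mixed2)$persistence, "robust")
    expect_error(summarizePersistence(mk(0.5, 0.5)), "2 thresholds")
})

test_that("node drivers use subnetwork-level exclusions and the p < 0.05
           rule", {
    cfg <- toyConfig(n = 150, seed = 88, betaEdge = 0.9)
    p <- genParticipants(cfg)
    cn <- genConnectomes(p, cfg)
    mt <- computeMetrics(cn, 0L, toySubnetworks())
    res <- runAssociation(mt, p, 0L)
    sm <- res[res$metric == "mean_degree" &
        res$subnetwork == "sensorimotor", ]
    exIds <- strsplit(sm$excluded_ids, ";")[[1]]
    dr <- nodeDriverAnalysis(mt, p, "mean_degree", "sensorimotor", 0L,
        excludedIds = exIds[nzchar(exIds)])
    expect_identical(nrow(dr), 6L)
    expect_identical(dr$is_driver, !is.na(dr$p) & dr$p < 0.05)
    # strongly planted targets are detected as drivers
    expect_true(all(dr$is_driver[dr$node %in% c("n01", "n02")]))
    # consistency: when node values within a pair-node subnetwork are
    # identical, the node result equals the subnetwork-mean result
    lab <- c("n01", "n02")
    mt2 <- computeMetrics(cn, 0L, list(pair = lab))
    nv2 <- nodeMetrics(mt2)
    nv2 <- nv2[nv2$metric == "degree", ]
    v1 <- nv2$value[nv2$node == "n01"]
    v2 <- nv2$value[nv2$node == "n02"]
    expect_identical(v1, v2)  # a 2-node graph: both ends share the edge
    mm2 <- metricMeans(mt2)
    pc <- partialCorr(mm2$mean_degree[match(p$id, mm2$participant)],
        p$spq_total, cbind(p$age, p$sex))
    dr2 <- nodeDriverAnalysis(mt2, p, "degree", "pair", 0L)
    expect_equal(dr2$r, rep(pc$r, 2), tolerance = 1e-12)
    expect_equal(dr2$p, rep(pc$p, 2), tolerance = 1e-12)
})
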