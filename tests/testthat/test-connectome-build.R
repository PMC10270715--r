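test_that("readConnectome validates jointly and rejects silent reorders", {
    raw <- randomRaw(1, n = 6)
    d <- withr::local_tempdir()
    cf <- file.path(d, "x_counts.tsv")
    rf <- file.path(d, "x_rd.tsv")
    connsweep:::.writeMatrixTSV(streamlineCounts(raw), cf)
    connsweep:::.writeMatrixTSV(meanRD(raw), rf)
    back <- readConnectome(cf, rf, atlasName = "toy")
    expect_equal(unname(streamlineCounts(back)),
        unname(streamlineCounts(raw)) * 1.0)
    expect_equal(meanRD(back), meanRD(raw), tolerance = 1e-15)
    expect_identical(participantId(back), "x")

    # count present but RD zero at that cell -> invariant violation
    rdBad <- meanRD(raw)
    pos <- which(streamlineCounts(raw) > 0, arr.ind = TRUE)[1, ]
    rdBad[pos[1], pos[2]] <- 0
    rdBad[pos[2], pos[1]] <- 0
    connsweep:::.writeMatrixTSV(rdBad, rf)
    expect_error(readConnectome(cf, rf), "positive")

    # labels permuted between the two files -> error, never reorder
    perm <- rev(nodeLabels(raw))
    connsweep:::.writeMatrixTSV(meanRD(raw)[perm, perm], rf)
    expect_error(readConnectome(cf, rf), "labels differ")

    # negative entry
    cnBad <- streamlineCounts(raw)
    cnBad[1, 2] <- cnBad[2, 1] <- -1L
    connsweep:::.writeMatrixTSV(cnBad, cf)
    connsweep:::.writeMatrixTSV(meanRD(raw), rf)
    expect_error(readConnectome(cf, rf), "egative")
})

test_that("threshold semantics: fewer than nsThr streamlines are excluded", {
    lab <- toyLabels(3)
    cn <- matrix(0L, 3, 3, dimnames = list(lab, lab))
    cn[1, 2] <- cn[2, 1] <- 5L
    cn[1, 3] <- cn[3, 1] <- 6L
    rd <- matrix(0, 3, 3, dimnames = list(lab, lab))
    rd[cn > 0] <- 0.5e-3
    raw <- RawConnectome("p", "toy", cn, rd)
    w6 <- edgeWeights(buildWeighted(raw, 6L))
    expect_identical(w6["n01", "n02"], 0)      # count 5 < 6: excluded
    expect_equal(w6["n01", "n03"], 2000, ignore_attr = TRUE)  # 1/0.5e-3
    # thresholds 0 and 1 are identical: count-0 cells are never edges
    expect_identical(edgeWeights(buildWeighted(raw, 0L)),
        edgeWeights(buildWeighted(raw, 1L)))
})

test_that("thresholded edge sets are nested and RD never affects topology", {
    for (s in 1:5) {
        raw <- randomRaw(s, n = 10, maxCount = 15)
        prev <- NULL
        spPrev <- Inf
        for (t in 0:16) {
            net <- buildWeighted(raw, t)
            w <- edgeWeights(net)
            expect_identical(w, t(w))
            expect_true(all(diag(w) == 0))
            edges <- w > 0
            expect_identical(edges,
                streamlineCounts(raw) >= max(t, 1) &
                    streamlineCounts(raw) > 0)
            if (!is.null(prev)) expect_true(all(edges <= prev))
            sp <- networkSparsity(net)
            expect_lte(sp, spPrev)
            prev <- edges
            spPrev <- sp
        }
        # scaling RD changes weights, not the retained edge set
        raw2 <- RawConnectome("p2", "toy", streamlineCounts(raw),
            meanRD(raw) * 3)
        expect_identical(edgeWeights(buildWeighted(raw2, 5L)) > 0,
            edgeWeights(buildWeighted(raw, 5L)) > 0)
    }
})

test_that("networkSparsity counts retained upper-triangle edges", {
    lab <- toyLabels(4)
    full <- matrix(1, 4, 4, dimnames = list(lab, lab))
    diag(full) <- 0
    expect_identical(networkSparsity(full), 1)
    expect_identical(networkSparsity(full * 0), 0)
    w <- randomWeights(3, n = 10)
    expect_identical(networkSparsity(w),
        sum(w[upper.tri(w)] > 0) / 45)
})

test_that("calibrateThreshold is minimal, matching a brute-force scan", {
    # worked case: all counts 10 at density 0.5, target 0.25 -> 11
    lab <- toyLabels(20)
    cn <- matrix(0L, 20, 20, dimnames = list(lab, lab))
    up <- which(upper.tri(cn))
    set.seed(5)
    cn[sample(up, length(up) / 2)] <- 10L
    cn <- cn + t(cn)
    rd <- matrix(0, 20, 20, dimnames = list(lab, lab))
    rd[cn > 0] <- 6e-4
    raw <- RawConnectome("p", "toy", cn, rd)
    expect_identical(calibrateThreshold(list(raw), 0.25), 11L)
    expect_identical(calibrateThreshold(list(raw), 0.85), 0L)

    bruteScan <- function(cohort, target) {
        maxC <- max(vapply(cohort, function(r)
            max(streamlineCounts(r)), numeric(1)))
        for (t in 0:(maxC + 1)) {
            ms <- mean(vapply(cohort, function(r)
                networkSparsity(buildWeighted(r, t)), numeric(1)))
            if (ms <= target) return(as.integer(t))
        }
        stop("unreachable")
    }
    for (s in 1:10) {
        cohort <- lapply(s * 10 + 1:4, randomRaw, n = 9, maxCount = 12)
        for (target in c(0.9, 0.6, 0.4, 0.2, 0.05)) {
            t_pkg <- calibrateThreshold(cohort, target)
            expect_identical(t_pkg, bruteScan(cohort, target))
            ms <- function(t) mean(vapply(cohort, function(r)
                networkSparsity(buildWeighted(r, t)), numeric(1)))
            expect_lte(ms(t_pkg), target)
            if (t_pkg > 0) expect_gt(ms(t_pkg - 1L), target)
        }
    }
    expect_error(calibrateThreshold(list(), 0.5), "empty")
    expect_error(calibrateThreshold(list(randomRaw(1)), 0), "target")
})

test_that("planSweep calibrates 13 monotone thresholds by default", {
    cohort <- lapply(1:6, randomRaw, n = 12, maxCount = 40)
    plan <- planSweep(cohort)
    expect_length(targetSparsities(plan), 13)
    expect_length(sweepThresholds(plan), 13)
    expect_true(all(diff(sweepThresholds(plan)) >= 0))
    # graded counts: strong thresholding needs a higher cut
    plan2 <- planSweep(cohort, targets = c(0.8, 0.3))
    expect_gt(sweepThresholds(plan2)[2], sweepThresholds(plan2)[1])
    expect_error(planSweep(cohort, targets = c(0.5, 0.5)), "duplicate")
    expect_error(planSweep(cohort, targets = c(0.3, 0.8)), "decreasing")
})

test_that("detectIsolated finds nodes with no intra-subset edges", {
    lab <- toyLabels(5)
    w <- matrix(0, 5, 5, dimnames = list(lab, lab))
    w[1, 2:5] <- w[2:5, 1] <- 1  # star centred on n01
    net <- WeightedNetwork(w, 0L)
    expect_identical(detectIsolated(net), character(0))
    expect_identical(sort(detectIsolated(net, lab[2:5])), lab[2:5])
    full <- WeightedNetwork(randomWeights(1, 5, pEdge = 1), 0L)
    expect_identical(detectIsolated(full), character(0))
    expect_error(detectIsolated(net, c("n01", "zz")), "zz")
    for (s in 1:5) {
        w <- randomWeights(s, n = 8, pEdge = 0.3)
        net <- WeightedNetwork(w, 0L)
        sub <- toyLabels(8)[1:5]
        iso <- detectIsolated(net, sub)
        oracle <- sub[rowSums(w[sub, sub] > 0) == 0]
        expect_identical(iso, oracle)
    }
})
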