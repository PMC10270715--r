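test_that("degree, strength and clustering honour their closed-form cases", {
    lab <- toyLabels(3)
    w <- matrix(2, 3, 3, dimnames = list(lab, lab))
    diag(w) <- 0
    expect_identical(unname(nodeDegree(w)), c(2L, 2L, 2L))
    # complete graph with equal weights: clustering 1 everywhere
    expect_equal(unname(nodeClustering(w)), c(1, 1, 1))
    expect_equal(unname(nodeStrength(w)), c(4, 4, 4))
    # empty graph
    w0 <- w * 0
    expect_identical(unname(nodeDegree(w0)), c(0L, 0L, 0L))
    expect_identical(unname(nodeClustering(w0)), c(0, 0, 0))
    # star graph: no triangles anywhere
    lab5 <- toyLabels(5)
    st <- matrix(0, 5, 5, dimnames = list(lab5, lab5))
    st[1, 2:5] <- st[2:5, 1] <- runif(4, 0.5, 2)
    expect_identical(unname(nodeClustering(st)), rep(0, 5))
    # single edge of weight 2000: endpoints carry it, others 0
    se <- matrix(0, 5, 5, dimnames = list(lab5, lab5))
    se[1, 2] <- se[2, 1] <- 2000
    expect_equal(unname(nodeStrength(se)), c(2000, 2000, 0, 0, 0))
    # strength reduces to degree at unit weights
    wb <- (randomWeights(8, 7) > 0) * 1
    expect_equal(unname(nodeStrength(wb)), as.numeric(nodeDegree(wb)))
})

test_that("metrics match brute-force oracles on random weighted graphs", {
    for (s in 1:25) {
        w <- randomWeights(s, n = sample(3:6, 1), pEdge = runif(1, 0.2, 1))
        expect_identical(nodeDegree(w), bruteDegree(w))
        expect_equal(nodeStrength(w), bruteStrength(w), tolerance = 1e-12)
        expect_equal(nodeClustering(w), bruteClustering(w),
            tolerance = 1e-12)
        expect_true(all(nodeClustering(w) >= 0 & nodeClustering(w) <= 1))
    }
})

test_that("scale invariance: degree and clustering ignore global rescaling,
           strength is linear", {
    for (s in 1:5) {
        w <- randomWeights(40 + s, n = 6)
        expect_identical(nodeDegree(w), nodeDegree(w * 7.3))
        expect_equal(nodeClustering(w), nodeClustering(w * 7.3),
            tolerance = 1e-12)
        expect_equal(nodeStrength(w * 7.3), 7.3 * nodeStrength(w),
            tolerance = 1e-12)
    }
    # equal nonzero weights: weighted clustering equals binary clustering
    w <- (randomWeights(77, 6, pEdge = 0.6) > 0) * 0.4
    expect_equal(nodeClustering(w, "onnela"), nodeClustering(w, "binary"),
        tolerance = 1e-12)
})

test_that("subnetwork means are exact arithmetic means with isolated nodes
           included", {
    v <- c(n01 = 2, n02 = 2, n03 = 0, n04 = 0)
    expect_identical(subnetworkMean(v), 1)
    expect_identical(subnetworkMean(c(a = 5, b = 5, c = 5)), 5)
    expect_error(subnetworkMean(v, character(0)), "empty")
    deg <- c(n01 = 2L, n02 = 2L, n03 = 0L, n04 = 0L)
    expect_identical(subnetworkMean(v, dropIsolated = TRUE, degree = deg), 2)
})

test_that("computeMetrics agrees with the one-object-at-a-time route", {
    cohort <- lapply(1:3, randomRaw, n = 20, maxCount = 15)
    subs <- toySubnetworks()
    mt <- computeMetrics(cohort, c(0L, 5L), subs)
    mm <- metricMeans(mt)
    expect_identical(nrow(mm), 3L * 2L * 4L)
    nv <- nodeMetrics(mt)
    for (i in seq_len(nrow(mm))) {
        rc <- cohort[[match(mm$participant[i],
            vapply(cohort, participantId, character(1)))]]
        sub <- extractSubnetwork(buildWeighted(rc, mm$threshold[i]),
            subs[[mm$subnetwork[i]]])
        deg <- nodeDegree(sub)
        clu <- nodeClustering(sub)
        str <- nodeStrength(sub)
        expect_identical(mm$mean_degree[i], mean(deg))
        expect_identical(mm$mean_clustering[i], mean(clu))
        expect_identical(mm$mean_strength[i], mean(str))
        blk <- nv[nv$participant == mm$participant[i] &
            nv$subnetwork == mm$subnetwork[i] &
            nv$threshold == mm$threshold[i], ]
        expect_identical(setNames(blk$value[blk$metric == "degree"],
            blk$node[blk$metric == "degree"]),
            setNames(as.numeric(deg), names(deg)))
        expect_identical(setNames(blk$value[blk$metric == "clustering"],
            blk$node[blk$metric == "clustering"]), clu)
    }
    # reported means equal means of reported node vectors to 1e-12
    agg <- aggregate(value ~ participant + subnetwork + threshold + metric,
        nv, mean)
    for (i in seq_len(nrow(mm))) {
        for (m in c("degree", "clustering", "strength")) {
            a <- agg$value[agg$participant == mm$participant[i] &
                agg$subnetwork == mm$subnetwork[i] &
                agg$threshold == mm$threshold[i] & agg$metric == m]
            expect_equal(a, mm[[paste0("mean_", m)]][i],
                tolerance = 1e-12)
        }
    }
})

test_that("collinearity screen drops by fixed priority and flags
           degenerates", {
    set.seed(1)
    n <- 60
    base <- data.frame(participant = sprintf("p%02d", 1:n),
        subnetwork = "s1", threshold = 0L,
        mean_degree = rnorm(n, 10), mean_clustering = rnorm(n, 0.5, 0.1),
        mean_strength = rnorm(n, 100, 10))
    # independent metrics: all retained
    sc <- collinearityScreen(base)
    expect_setequal(sc$retained,
        c("mean_degree", "mean_clustering", "mean_strength"))
    # strength an exact multiple of degree: dropped with r = 1
    dep <- base
    dep$mean_strength <- 3 * dep$mean_degree
    sc2 <- collinearityScreen(dep)
    expect_identical(sc2$retained, c("mean_degree", "mean_clustering"))
    expect_named(sc2$dropped, "mean_strength")
    expect_equal(sc2$correlations$s1["mean_degree", "mean_strength"], 1)
    # zero-variance metric flagged and dropped
    degen <- base
    degen$mean_clustering <- 0.5
    sc3 <- collinearityScreen(degen)
    expect_true("mean_clustering" %in% names(sc3$dropped))
    expect_match(sc3$dropped[["mean_clustering"]], "zero variance")
    expect_error(collinearityScreen(base[1:2, ]), "3 rows")
})

test_that("under the default generator, strength tracks degree above the
           0.85 screen cutoff in most subnetworks", {
    cfg <- toyConfig(n = 60, seed = 55)
    p <- genParticipants(cfg)
    cn <- genConnectomes(p, cfg)
    mt <- computeMetrics(cn, 0L, toySubnetworks())
    sc <- collinearityScreen(mt)
    rs <- vapply(sc$correlations, function(cm)
        abs(cm["mean_degree", "mean_strength"]), numeric(1))
    expect_gte(sum(rs > 0.85), 3)
    expect_true("mean_strength" %in% names(sc$dropped))
    expect_true("mean_degree" %in% sc$retained)
})
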