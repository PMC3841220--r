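test_that("topK returns ordered ids and warns when short", {
    reg <- loadMappingRegistry()
    sim <- simulateAnnotations(simConfig(nAntibodies = 40, seed = 9))
    sset <- scoreAntibodies(sim$annotations, reg)
    tab <- scoresTable(sset)

    ids <- topK(sset, "Breast", k = 10)
    expect_length(ids, 10L)
    sc <- tab$score[match(ids, tab$antibody_id)]
    expect_true(all(diff(sc) <= 1e-12))
    expect_identical(ids, tab$antibody_id[tab$mapping_id == "Breast"][1:10])

    expect_warning(all40 <- topK(sset, "Breast", k = 100), "returning all")
    expect_length(all40, 40L)
    expect_error(topK(sset, "Atlantis", k = 1), "unknown mapping")
})

test_that("one-sample t-test matches the closed-form case and errors", {
    # mean equals mu0 -> t = 0, one-sided p = 0.5
    r <- oneSampleTTest(c(1, 2, 3), 2)
    expect_equal(r$t_statistic, 0)
    expect_equal(r$p_value, 0.5)

    # sample {1,2,3} vs mu0 = 0: t = 2*sqrt(3); closed form for df = 2
    # gives P(T > t) = (1 - t / sqrt(t^2 + 2)) / 2 ~ 0.0371
    r <- oneSampleTTest(c(1, 2, 3), 0)
    expect_equal(r$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
    expect_equal(r$p_value, (1 - 2 * sqrt(3) / sqrt(14)) / 2,
                 tolerance = 1e-12)
    expect_equal(r$p_value, 0.0371, tolerance = 1e-3)

    expect_error(oneSampleTTest(1, 0), "at least 2")
    expect_error(oneSampleTTest(c(2, 2, 2), 0), "zero")
})

test_that("t statistic and p agree with integration oracle and stats::t.test", {
    set.seed(7)
    for (n in c(3L, 5L, 12L, 100L)) {
        for (rep in 1:3) {
            x <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
            mu0 <- runif(1, -1, 1)
            mine <- oneSampleTTest(x, mu0)
            # direct recomputation of the statistic
            tref <- (mean(x) - mu0) / (sd(x) / sqrt(n))
            expect_equal(mine$t_statistic, tref, tolerance = 1e-12)
            # independent numeric-integration Student-t oracle
            expect_equal(mine$p_value, tUpperTailOracle(tref, n - 1L),
                         tolerance = 1e-6)
            # and the reference implementation, both alternatives
            ref <- stats::t.test(x, mu = mu0, alternative = "greater")
            expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
            two <- oneSampleTTest(x, mu0, alternative = "two.sided")
            ref2 <- stats::t.test(x, mu = mu0)
            expect_equal(two$p_value, unname(ref2$p.value), tolerance = 1e-12)
        }
    }
})

test_that("validateTopkMeans mirrors the direct t-test on handcrafted input", {
    # single mapping, 4 antibodies, k = 2
    reg <- tinyRegistry(2L)
    EiN <- matrix(0, 4, 2, dimnames = list(paste0("A", 1:4),
                                           reg$mapping_id))
    EiC <- matrix(c(150, 100, 25, 5, 0, 5, 10, 15), 4, 2,
                  dimnames = dimnames(EiN))
    sset <- scoreAntibodies(buildEDMatrix(craftAnnotations(EiN, EiC, reg),
                                          reg))
    v <- validateTopkMeans(sset, k = 2)
    row <- v[v$mapping_id == "M01" & v$statistic == "EiC", ]
    top2 <- topK(sset, "M01", 2)
    ref <- oneSampleTTest(EiC[top2, 1], mean(EiC[, 1]))
    expect_equal(row$t, ref$t_statistic)
    expect_equal(row$p_value, ref$p_value)
    expect_equal(row$population_mean, mean(EiC[, 1]))
    # ED test equals EiC test here because EiN is identically zero
    rowED <- v[v$mapping_id == "M01" & v$statistic == "ED", ]
    expect_equal(rowED$t, row$t)
})

test_that("random scores give approximately uniform validation p-values", {
    # when top-k selection is unrelated to EiC, the one-sided p is U(0,1):
    # type-I error at 5% stays near 5%
    set.seed(123)
    p <- replicate(400, {
        pop <- rnorm(60)
        smp <- sample(pop, 10)   # selection carries no signal
        oneSampleTTest(smp, mean(pop))$p_value
    })
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
    expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})

test_that("ED heat map has the documented shape and All column semantics", {
    reg <- loadMappingRegistry()
    sim <- simulateAnnotations(
        simConfig(nAntibodies = 54, plantedMarkers = plantMarkers(54, effect = 4),
                  seed = 77))
    sset <- scoreAntibodies(sim$annotations, reg)
    H <- edHeatmap(sset, k = 10)
    expect_equal(dim(H), c(27L, 28L))
    expect_identical(colnames(H)[28], "All")
    expect_equal(unname(H[, "All"]),
                 unname(colMeans(edMatrix(sset), na.rm = TRUE)))
    # All column is independent of k
    expect_equal(H[, "All"], edHeatmap(sset, k = 3)[, "All"])
    # planted mapping-specific markers: diagonal maximal in every row
    for (i in seq_len(27)) expect_equal(which.max(H[i, 1:27]), i,
                                        ignore_attr = TRUE)
})

test_that("off-diagonal heat-map cells stay near the population mean", {
    # coverage of the 2-SE band around the All column is consistent with
    # the nominal 95% for cells whose selection mapping is unrelated to the
    # evaluation mapping
    reg <- loadMappingRegistry()
    sim <- simulateAnnotations(
        simConfig(nAntibodies = 200, plantedMarkers = plantMarkers(200),
                  seed = 88))
    sset <- scoreAntibodies(sim$annotations, reg)
    k <- 20L
    H <- edHeatmap(sset, k = k)
    ed <- edMatrix(sset)
    ct <- mappingRegistry(sset)$cancer_type
    z <- c()
    for (i in 1:27) for (j in 1:27) {
        if (i == j || ct[i] == ct[j]) next   # skip diagonal and siblings
        se <- sqrt(mean((ed[, i] - mean(ed[, i]))^2)) / sqrt(k)
        z <- c(z, (H[i, j] - H[i, "All"]) / se)
    }
    expect_gt(mean(abs(z) <= 2), 0.85)
    expect_lt(mean(abs(z)), 1.2)
})
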