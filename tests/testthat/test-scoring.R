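test_that("ordinal transforms follow the published tables", {
    expect_identical(
        intensityToNumeric(c("Negative", "Weak", "Moderate", "Strong")),
        c(0L, 1L, 2L, 3L))
    expect_identical(
        quantityToNumeric(c("Negative", "Rare", "<25%", "25-75%", ">75%")),
        c(0L, 5L, 25L, 50L, 75L))
    expect_identical(quantityToNumeric("75%-25%"), 50L)
    expect_error(intensityToNumeric("Very strong"), "unknown intensity")
    expect_error(quantityToNumeric("80%"), "unknown quantity")
})

test_that("EiN, EiC and ED reproduce the worked example", {
    expect_equal(expressionInNormal("Moderate", ">75%"), 150)
    expect_equal(expressionInNormal("Negative", ">75%"), 0)
    expect_equal(expressionInNormal("Strong", ">75%"), 225)

    ann <- readAnnotations(exampleAnnotationFile())
    canc <- ann[ann$sample_kind == "cancer", ]
    eic <- expressionInCancer(canc$intensity, canc$quantity)
    expect_equal(eic$EiC, 2025 / 12)     # = 168.75
    expect_equal(eic$n_patients, 12L)

    expect_equal(expressionInCancer("Strong", ">75%")$EiC, 225)
    expect_equal(
        expressionInCancer(c("Strong", "Negative"),
                           c(">75%", "Negative"))$EiC, 112.5)
    expect_error(expressionInCancer(character(), character()), "not tested")

    expect_equal(expressionDifference(168.75, 150), 18.75)
    expect_equal(expressionDifference(42, 42), 0)
    expect_equal(expressionDifference(0, 225), -225)
    expect_true(is.na(expressionDifference(NA, 150)))
})

test_that("ED matrix has one cell per fully tested pair", {
    reg <- loadMappingRegistry()
    ann <- readAnnotations(exampleAnnotationFile())
    sset <- buildEDMatrix(ann, reg)
    expect_s4_class(sset, "IHCScoreSet")
    expect_equal(dim(sset), c(1L, 27L))
    expect_equal(sum(!is.na(edMatrix(sset))), 1L)
    expect_equal(edMatrix(sset)["HPA034966", "Breast"], 18.75)
    expect_equal(nPatients(sset)["HPA034966", "Breast"], 12)

    # cancer records without the mapping's normal record leave the cell
    # missing, and vice versa
    ann2 <- rbind(
        annRow("AB1", "G1", "cancer", cancer = "Breast cancer",
               patient = "P1", intensity = "Strong", quantity = ">75%"),
        annRow("AB2", "G2", "normal", tissue = "breast",
               cell = "glandular cells", intensity = "Weak",
               quantity = "Rare"))
    sset2 <- buildEDMatrix(ann2, reg)
    expect_true(all(is.na(edMatrix(sset2))))

    expect_error(buildEDMatrix(ann, reg[0, ]), "empty")
})

test_that("SG and SP match brute-force z-scoring with a series-expansion CDF", {
    # column EDs {0, 10, -10, 20, -20}, target 20
    reg <- tinyRegistry(2L)
    EiN <- matrix(c(0, 0, 10, 5, 25,  0, 0, 0, 0, 0), 5, 2,
                  dimnames = list(paste0("A", 1:5), reg$mapping_id))
    EiC <- matrix(c(0, 10, 0, 25, 5,  0, 0, 0, 0, 0), 5, 2,
                  dimnames = dimnames(EiN))
    sset <- buildEDMatrix(craftAnnotations(EiN, EiC, reg), reg)
    ed <- edMatrix(sset)
    expect_equal(unname(ed[, "M01"]), c(0, 10, -10, 20, -20))

    sigma <- sqrt(mean((ed[, "M01"] - mean(ed[, "M01"]))^2))
    expect_equal(significance(sset, "A4", "M01"),
                 phiSeries(20 / sigma), tolerance = 1e-7)
    # ED equal to the column mean -> SG exactly 0.5
    expect_equal(significance(sset, "A1", "M01"), 0.5)

    # row EDs {100, 0, 0, 0}, target 100
    reg4 <- tinyRegistry(4L)
    EiN4 <- matrix(0, 2, 4, dimnames = list(c("B1", "B2"), reg4$mapping_id))
    EiC4 <- matrix(c(100, 0, 0, 0, 0, 0, 0, 0), 2, 4, byrow = TRUE,
                   dimnames = dimnames(EiN4))
    sset4 <- buildEDMatrix(craftAnnotations(EiN4, EiC4, reg4), reg4)
    mu <- 25; sigma <- sqrt(mean((c(100, 0, 0, 0) - mu)^2))
    expect_equal(specificity(sset4, "B1", "M01"),
                 phiSeries((100 - mu) / sigma), tolerance = 1e-7)
    # all row EDs identical -> degenerate dispersion -> SP 0.5
    expect_equal(specificity(sset4, "B2", "M01"), 0.5)

    expect_error(significance(sset, "A1", "nope"), "unknown mapping")
    expect_error(significance(sset, "nope", "M01"), "unknown antibody")
})

test_that("SG/SP agree with an independent reimplementation on small matrices", {
    set.seed(11)
    lv <- c(0, 5, 10, 15, 25, 50, 75, 100, 150, 225)  # attainable I*Q values
    for (rep in 1:5) {
        reg <- tinyRegistry(5L)
        EiN <- matrix(sample(lv, 25, replace = TRUE), 5, 5,
                      dimnames = list(paste0("A", 1:5), reg$mapping_id))
        EiC <- matrix(sample(lv, 25, replace = TRUE), 5, 5,
                      dimnames = dimnames(EiN))
        sset <- scoreAntibodies(buildEDMatrix(craftAnnotations(EiN, EiC, reg),
                                              reg))
        ed <- edMatrix(sset)
        for (a in rownames(ed)) for (m in colnames(ed)) {
            col <- ed[, m]; row <- ed[a, ]
            zg <- (ed[a, m] - mean(col)) / sqrt(mean((col - mean(col))^2))
            zp <- (ed[a, m] - mean(row)) / sqrt(mean((row - mean(row))^2))
            expect_equal(sgMatrix(sset)[a, m], phiSeries(zg),
                         tolerance = 1e-7)
            expect_equal(spMatrix(sset)[a, m], phiSeries(zp),
                         tolerance = 1e-7)
        }
    }
})

test_that("score law, ranking and z-normalization hold on synthetic runs", {
    reg <- loadMappingRegistry()
    sim <- simulateAnnotations(
        simConfig(nAntibodies = 80, plantedMarkers = plantMarkers(80),
                  missingRate = 0.1, seed = 202))
    sset <- scoreAntibodies(sim$annotations, reg)
    tab <- scoresTable(sset)

    expect_true(all(tab$SG > 0 & tab$SG < 1))
    expect_true(all(tab$SP > 0 & tab$SP < 1))
    expect_true(all(tab$score >= 0 & tab$score <= 225))
    expect_equal(tab$score, tab$EiC * tab$SG * tab$SP, tolerance = 1e-9)
    expect_equal(tab$ED, tab$EiC - tab$EiN, tolerance = 1e-12)

    # ranks: descending score within each mapping, starting at 1
    for (m in unique(tab$mapping_id)) {
        sub <- tab[tab$mapping_id == m, ]
        expect_identical(sub$rank, seq_len(nrow(sub)))
        expect_true(all(diff(sub$score) <= 1e-12))
    }

    # z-normalization: each column's z-scores have mean 0, population SD 1
    ed <- edMatrix(sset)
    for (m in colnames(ed)) {
        z <- stats::qnorm(sgMatrix(sset)[, m])
        z <- z[!is.na(z)]
        expect_equal(mean(z), 0, tolerance = 1e-9)
        expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-9)
    }

    # within a column SG is strictly increasing in ED
    keep <- !is.na(ed[, 1])
    o <- order(ed[keep, 1])
    sg <- sgMatrix(sset)[keep, 1][o]
    edo <- ed[keep, 1][o]
    expect_true(all(diff(sg[!duplicated(edo)]) > 0))
})

test_that("shift invariance: adding a constant to a column leaves SG unchanged", {
    set.seed(5)
    for (rep in 1:20) {
        v <- rnorm(sample(3:30, 1), sd = 50)
        shifted <- v + runif(1, -100, 100)
        expect_equal(pnorm(ihcscore:::.zVector(v)),
                     pnorm(ihcscore:::.zVector(shifted)), tolerance = 1e-9)
    }
})

test_that("degenerate and unscorable cells are handled per the rules", {
    reg <- tinyRegistry(2L)
    # two antibodies, identical EDs in column M01 -> sd 0 -> SG 0.5
    EiN <- matrix(c(0, 0, 0, 0), 2, 2,
                  dimnames = list(c("A1", "A2"), reg$mapping_id))
    EiC <- matrix(c(50, 50, 100, 0), 2, 2, dimnames = dimnames(EiN))
    sset <- scoreAntibodies(buildEDMatrix(craftAnnotations(EiN, EiC, reg),
                                          reg))
    expect_equal(unname(sgMatrix(sset)[, "M01"]), c(0.5, 0.5))

    # single tested cell: both axes have < 2 entries -> unscorable, omitted
    ann1 <- readAnnotations(exampleAnnotationFile())
    expect_message(s1 <- scoreAntibodies(buildEDMatrix(ann1,
                                                       loadMappingRegistry())),
                   "unscorable")
    expect_equal(nrow(scoresTable(s1)), 0L)
})

test_that("planted mapping-specific marker attains rank 1 in its mapping", {
    reg <- loadMappingRegistry()
    pm <- data.frame(antibody_id = "AB0007", mapping_id = "Glioma",
                     effect = 4)
    sim <- simulateAnnotations(
        simConfig(nAntibodies = 50, plantedMarkers = pm, seed = 31))
    tab <- scoresTable(scoreAntibodies(sim$annotations, reg))
    expect_identical(topK(tab, "Glioma", k = 1), "AB0007")
    expect_equal(tab$rank[tab$antibody_id == "AB0007" &
                          tab$mapping_id == "Glioma"], 1L)
})
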