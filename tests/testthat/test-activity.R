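test_that("rank aggregation sums within taxa and conserves totals", {
    m <- rbind(o1 = c(3L, 1L), o2 = c(4L, 2L), o3 = c(7L, 0L))
    colnames(m) <- c("s1_DNA", "s1_RNA")
    tax <- c(o1 = "P1;C1;O1;F1;GenusA",
             o2 = "P1;C1;O1;F1;GenusA",
             o3 = "P1;C1")   # unassigned at genus
    tab <- makeOtu(m, taxonomy = tax)
    agg <- aggregateToRank(tab, "genus")
    expect_equal(unname(agg["GenusA", ]), c(7, 3))
    expect_equal(unname(agg["unclassified", ]), c(7, 0))
    expect_equal(colSums(agg), colSums(m))
    expect_error(aggregateToRank(tab, "species"), "unknown rank")
})

test_that("RNA:DNA ratios divide proportions and reject phantom leaks", {
    expect_equal(rnaDnaRatio(0.5, 0.5), 1)
    expect_equal(rnaDnaRatio(0.5, 0.8), 1.6)
    expect_equal(rnaDnaRatio(0.5, 0.2), 0.4)
    expect_equal(rnaDnaRatio(0.3, 0), 0)
    expect_equal(rnaDnaRatio(0, 0), 0)
    expect_error(rnaDnaRatio(0, 0.1), "phantom")
})

test_that("activity bands partition the ratio axis at 0.1/1/10", {
    expect_equal(as.character(classifyBand(c(0, 0.05, 0.5, 1, 5, 10, 11760))),
                 c("zero", "lt_0.1", "0.1_to_1", "1_to_10", "1_to_10",
                   "gt_10", "gt_10"))
    expect_error(classifyBand(-1), "non-negative")
    # ratio 1 is active (inclusive boundary); every ratio gets exactly one band
    expect_true(isActive(1))
    expect_false(isActive(0.999))
    set.seed(6)
    r <- c(0, rlnorm(200, 0, 3))
    expect_false(anyNA(classifyBand(r)))
})

test_that("activity table computes per-taxon per-sample ratios on proportions", {
    m <- rbind(o1 = c(50L, 20L, 30L, 30L),
               o2 = c(50L, 80L, 70L, 70L))
    colnames(m) <- c("s1_DNA", "s1_RNA", "s2_DNA", "s2_RNA")
    tax <- c(o1 = "P1;C1;O1;F1;GA", o2 = "P1;C1;O1;F1;GB")
    act <- activityTable(makeOtu(m, taxonomy = tax), rank = "genus")
    a <- act[act$taxon == "GA" & act$sample_id == "s1", ]
    expect_equal(a$ratio, 0.2 / 0.5)
    expect_equal(as.character(a$band), "0.1_to_1")
    b <- act[act$taxon == "GB" & act$sample_id == "s1", ]
    expect_true(isActive(b$ratio))
    # taxon absent from RNA: ratio 0, band zero
    m2 <- rbind(o1 = c(10L, 5L), o2 = c(10L, 0L))
    colnames(m2) <- c("s1_DNA", "s1_RNA")
    act2 <- activityTable(makeOtu(m2, taxonomy = tax), rank = "genus")
    expect_equal(act2$ratio[act2$taxon == "GB"], 0)
    expect_equal(as.character(act2$band[act2$taxon == "GB"]), "zero")
    # unmatched samples are an error
    m3 <- matrix(1L, 1, 1, dimnames = list("o1", "s1_DNA"))
    expect_error(activityTable(makeOtu(m3), rank = "genus"), "lacks")
})

test_that("ratios are invariant to RNA depth rescaling", {
    m <- rbind(o1 = c(50L, 20L), o2 = c(50L, 80L))
    colnames(m) <- c("s1_DNA", "s1_RNA")
    tax <- c(o1 = "P;C;O;F;GA", o2 = "P;C;O;F;GB")
    a1 <- activityTable(makeOtu(m, taxonomy = tax), rank = "genus")
    m2 <- m; m2[, "s1_RNA"] <- 7L * m2[, "s1_RNA"]
    a2 <- activityTable(makeOtu(m2, taxonomy = tax), rank = "genus")
    expect_equal(a1$ratio, a2$ratio)
})

test_that("per-OTU screen flags the designated active set on synthetic truth", {
    g <- generateCommunity(syntheticConfig(
        nOtus = 60L, lognormalSigma = 1, depthDna = 2e4, depthRna = 2e4,
        activeFraction = 0.15, inactiveFraction = 0.85,
        activeMultiplierRange = c(5, 5),
        inactiveMultiplierRange = c(0.2, 0.2),
        contaminantCount = 0L, phantomCount = 0L, seed = 21L))
    tab <- runFilterChain(g$table, allowNoControls = TRUE)$table
    scr <- otuRnaDnaRatios(tab)
    called <- scr$otu_id[scr$active]
    sc <- recoveryScores(called, g$truth$active_set, scr$otu_id)
    expect_gte(sc[["recall"]], 0.9)
    expect_gte(sc[["precision"]], 0.9)
    # the designated actives sit in the expected band
    aRows <- scr[scr$otu_id %in% g$truth$active_set, ]
    expect_true(mean(aRows$band == "1_to_10") > 0.8)
})

test_that("rare taxa show inflated ratios when the generator says so", {
    g <- generateCommunity(syntheticConfig(
        nOtus = 300L, depthDna = 3e4, depthRna = 3e4,
        activeFraction = 0, inactiveFraction = 0,
        rareRatioInflation = 2, contaminantCount = 0L, phantomCount = 0L,
        seed = 31L))
    tab <- runFilterChain(g$table, allowNoControls = TRUE)$table
    act <- otuRnaDnaRatios(tab, perSample = TRUE)
    names(act)[names(act) == "otu_id"] <- "taxon"
    trend <- rareRatioTrend(act)
    expect_true(all(trend$spearman_rho < 0))
})

test_that("average-rank top-taxon selection follows ranks then abundance", {
    # three samples; taxon A is rank 1 everywhere
    m <- rbind(A = c(90L, 90L, 95L), B = c(6L, 7L, 4L), C = c(4L, 3L, 1L))
    colnames(m) <- c("s1_DNA", "s2_DNA", "s3_DNA")
    # add RNA columns so the table is well-formed for OtuExperiment use
    top <- topTaxaByAverageRank(m, n = 2)
    expect_equal(top, c("A", "B"))
    expect_equal(length(topTaxaByAverageRank(m, n = 10)), 3L)
    expect_error(topTaxaByAverageRank(m, n = 0), ">= 1")
    # tie on average rank broken by total abundance
    m2 <- rbind(X = c(50L, 10L), Y = c(30L, 30L), Z = c(20L, 60L))
    colnames(m2) <- c("s1_DNA", "s2_DNA")
    # ranks: X (1,3) avg 2; Y (2,2) avg 2; Z (3,1) avg 2 -> order by totals
    top2 <- topTaxaByAverageRank(m2, n = 3)
    # Z leads on total abundance; X and Y tie again and fall back to name
    expect_equal(top2, c("Z", "X", "Y"))
})

test_that("absent taxa are ranked last", {
    m <- rbind(A = c(5L, 0L), B = c(3L, 10L), C = c(2L, 5L))
    colnames(m) <- c("s1_DNA", "s2_DNA")
    # A: ranks (1, 4); B: (2, 1); C: (3, 2)
    expect_equal(topTaxaByAverageRank(m, n = 3), c("B", "C", "A"))
})
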