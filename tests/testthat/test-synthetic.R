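test_that("the generator is deterministic in its seed", {
    cfg <- syntheticConfig(nOtus = 50L, depthDna = 2000, depthRna = 2000,
                           seed = 17L)
    a <- generateCommunity(cfg)
    b <- generateCommunity(cfg)
    expect_identical(otuCounts(a$table), otuCounts(b$table))
    expect_identical(a$truth, b$truth)
    expect_identical(taxonomy(a$table), taxonomy(b$table))
    cfg2 <- syntheticConfig(nOtus = 50L, depthDna = 2000, depthRna = 2000,
                            seed = 18L)
    expect_false(identical(otuCounts(a$table),
                           otuCounts(generateCommunity(cfg2)$table)))
})

test_that("sample columns sum exactly to the configured depths", {
    g <- generateCommunity(syntheticConfig(nOtus = 70L, depthDna = 3100,
                                           depthRna = 1700, seed = 2L))
    sf <- sampleFractions(g$table)
    cs <- colSums(otuCounts(g$table))
    expect_true(all(cs[sf$fraction == "DNA" & !sf$is_control] == 3100))
    expect_true(all(cs[sf$fraction == "RNA"] == 1700))
})

test_that("truth sets are disjoint and sized by the config", {
    cfg <- syntheticConfig(nOtus = 100L, activeFraction = 0.2,
                           inactiveFraction = 0.3, contaminantCount = 4L,
                           phantomCount = 6L, depthDna = 2000,
                           depthRna = 2000, seed = 9L)
    tr <- generateCommunity(cfg)$truth
    expect_equal(length(tr$active_set), 20L)
    expect_equal(length(tr$inactive_set), 30L)
    expect_equal(length(tr$contaminant_set), 4L)
    expect_equal(length(tr$phantom_set), 6L)
    all_ids <- c(tr$active_set, tr$inactive_set, tr$contaminant_set,
                 tr$phantom_set)
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_true(all(tr$multipliers[tr$active_set] >= 3))
    expect_true(all(tr$multipliers[tr$inactive_set] <= 1 / 3))
})

test_that("a flat community at high depth has near-zero Gini", {
    g <- generateCommunity(syntheticConfig(
        nOtus = 100L, lognormalSigma = 0, depthDna = 1e5, depthRna = 1e5,
        activeFraction = 0, inactiveFraction = 0, contaminantCount = 0L,
        phantomCount = 0L, seed = 4L))
    cnt <- otuCounts(g$table)
    expect_lt(gini(cnt[, "cloud1_DNA"]), 0.05)
})

test_that("unevenness (Gini) increases with the lognormal sigma", {
    meanGini <- vapply(c(0.5, 1.5, 2.5), function(s) {
        mean(vapply(1:3, function(seed) {
            g <- generateCommunity(syntheticConfig(
                nOtus = 150L, lognormalSigma = s, depthDna = 2e4,
                depthRna = 2e4, contaminantCount = 0L, phantomCount = 0L,
                activeFraction = 0, inactiveFraction = 0, seed = seed))
            gini(otuCounts(g$table)[, "cloud1_DNA"])
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(meanGini) > 0))
})

test_that("designed phantoms are exactly the OTUs the phantom filter removes", {
    # deep, even community: every community OTU is DNA-detected, so the
    # phantom stage touches the designed phantoms and nothing else
    cfg <- syntheticConfig(nOtus = 50L, lognormalSigma = 1,
                           depthDna = 2e4, depthRna = 2e4,
                           activeFraction = 0, inactiveFraction = 0,
                           contaminantCount = 0L, phantomCount = 10L,
                           seed = 6L)
    g <- generateCommunity(cfg)
    res <- phantomFilter(g$table)
    expect_setequal(res$entry$otuIds, g$truth$phantom_set)
})

test_that("contaminants are present in the control column and in samples", {
    g <- generateCommunity(syntheticConfig(nOtus = 60L, depthDna = 5000,
                                           depthRna = 5000,
                                           contaminantCount = 5L, seed = 3L))
    cnt <- otuCounts(g$table)
    k <- g$truth$contaminant_set
    expect_true(all(cnt[k, "CTRL1_DNA"] > 0))
    expect_true(all(rowSums(cnt[k, colnames(cnt) != "CTRL1_DNA"]) > 0))
    # and decontamination removes exactly them from a deep enough table
    res <- decontaminate(g$table)
    expect_setequal(res$entry$otuIds, k)
})

test_that("invalid configs name the offending field", {
    expect_error(syntheticConfig(activeFraction = 1.5), "activeFraction")
    expect_error(syntheticConfig(activeMultiplierRange = c(0.5, 2)),
                 "activeMultiplierRange")
    expect_error(syntheticConfig(inactiveMultiplierRange = c(0.5, 2)),
                 "inactiveMultiplierRange")
    expect_error(syntheticConfig(depthDna = 0), "depth")
})

test_that("read generation respects counts, divergence and quality", {
    cents <- randomCentroids(3, length = 120L, seed = 1L)
    counts <- matrix(c(3L, 2L, 0L, 1L, 1L, 1L), 3,
                     dimnames = list(names(cents), c("s1_DNA", "s1_RNA")))
    gr <- generateReads(cents, counts, divergence = 0, qual = 30L, seed = 2L)
    expect_equal(length(gr$reads), sum(counts))
    expect_equal(nrow(gr$truth), sum(counts))
    # divergence 0: reads are exact centroid copies; clustering at 0.97
    # recovers the centroid partition
    cl <- greedyCluster(as.character(gr$reads), 0.97)
    part <- split(gr$truth$read, cl$centroid[match(gr$truth$read, cl$id)])
    expect_equal(length(part), 3L)
    for (ids in part)
        expect_equal(length(unique(gr$truth$otu[match(ids, gr$truth$read)])),
                     1L)
    # constant quality 20 fails a mean-25 threshold for every read
    gr20 <- generateReads(cents, counts, divergence = 0, qual = 20L, seed = 2L)
    res <- qcFilter(gr20$reads, qcConfig(minLength = 100L,
                                         minMeanQuality = 25))
    expect_equal(res$report$passed, 0L)
    expect_equal(unname(res$report$rejected_by_rule["quality"]),
                 sum(counts))
    # a divergence too close to the threshold margin warns
    expect_warning(generateReads(cents, counts, divergence = 0.05,
                                 seed = 2L, threshold = 0.97), "merge")
})

test_that("mutated families cluster back to their own centroids", {
    cents <- randomCentroids(3, length = 100L, seed = 5L)
    for (i in 1:2) for (j in (i + 1):3)
        expect_lt(pairwiseIdentity(cents[[i]], cents[[j]]), 0.9)
    counts <- matrix(5L, 3, 1, dimnames = list(names(cents), "s1_DNA"))
    gr <- generateReads(cents, counts, divergence = 0.01, seed = 8L)
    cl <- greedyCluster(as.character(gr$reads), 0.97)
    expect_equal(length(attr(cl, "centroids")), 3L)
    fam <- gr$truth$otu[match(cl$id, gr$truth$read)]
    expect_true(all(tapply(fam, cl$centroid, function(v)
        length(unique(v))) == 1L))
})
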