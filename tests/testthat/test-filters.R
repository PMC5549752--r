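test_that("minimum-read filter drops OTUs below the dataset-total threshold", {
    m <- rbind(low = c(1L, 1L), edge = c(3L, 0L), high = c(10L, 10L))
    colnames(m) <- c("s1_DNA", "s1_RNA")
    res <- minCountFilter(makeOtu(m), 3L)
    expect_setequal(rownames(res$table), c("edge", "high"))
    expect_equal(res$entry$otuIds, "low")
    expect_equal(res$entry$readsRemoved, 2)
    # minReads = 1 is the identity when no row is all-zero
    expect_equal(nrow(minCountFilter(makeOtu(m), 1L)$table), 3L)
    expect_error(minCountFilter(makeOtu(m), 0L), ">= 1")
})

test_that("decontamination is presence-based and drops control columns", {
    m <- rbind(contam = c(500L, 300L, 1L),
               clean = c(40L, 20L, 0L))
    colnames(m) <- c("s1_DNA", "s1_RNA", "CTRL1_DNA")
    res <- decontaminate(makeOtu(m))
    expect_equal(rownames(res$table), "clean")
    expect_false(any(sampleFractions(res$table)$is_control))
    # one control read condemned 800 sample reads too
    expect_equal(res$entry$readsRemoved, 801)
    # OTU absent from controls is untouched; all-zero controls = identity
    m2 <- m; m2["contam", "CTRL1_DNA"] <- 0L
    res2 <- decontaminate(makeOtu(m2))
    expect_equal(nrow(res2$table), 2L)
    expect_equal(res2$entry$otusRemoved, 0L)
    # a table without controls must be explicit about it
    m3 <- m[, 1:2]
    expect_error(decontaminate(makeOtu(m3)), "control")
    expect_equal(nrow(decontaminate(makeOtu(m3),
                                    allowNoControls = TRUE)$table), 2L)
})

test_that("phantom filter zeroes RNA-only detections per sample", {
    m <- rbind(A = c(5L, 3L, 2L, 1L),
               B = c(0L, 7L, 0L, 0L))
    colnames(m) <- c("s1_DNA", "s1_RNA", "s2_DNA", "s2_RNA")
    res <- phantomFilter(makeOtu(m))
    # B was RNA-only in s1 and absent elsewhere: zeroed, then removed
    expect_equal(rownames(res$table), "A")
    expect_equal(res$entry$readsRemoved, 7)
    # DNA-only OTUs are untouched
    m2 <- rbind(A = c(5L, 0L, 4L, 0L))
    colnames(m2) <- colnames(m)
    expect_equal(otuCounts(phantomFilter(makeOtu(m2))$table), otuCounts(makeOtu(m2)))
    # phantom in sample 1 but DNA-backed in sample 2: zeroed only in s1
    m3 <- rbind(C = c(0L, 6L, 8L, 2L))
    colnames(m3) <- colnames(m)
    res3 <- phantomFilter(makeOtu(m3))
    expect_equal(unname(otuCounts(res3$table)["C", ]), c(0L, 0L, 8L, 2L))
    # global scope removes the OTU everywhere instead
    res3g <- phantomFilter(makeOtu(m3), scope = "global")
    expect_equal(nrow(res3g$table), 0L)
    # RNA fraction without a matching DNA fraction is a contract violation
    m4 <- matrix(c(1L, 2L), 1, dimnames = list("A", c("s1_RNA", "s2_DNA")))
    expect_error(phantomFilter(makeOtu(m4)), "no DNA fraction")
})

test_that("after the phantom filter no RNA-positive cell lacks DNA backing", {
    g <- generateCommunity(syntheticConfig(nOtus = 120L, depthDna = 4000,
                                           depthRna = 4000,
                                           phantomCount = 15L, seed = 8L))
    tab <- phantomFilter(decontaminate(g$table)$table)$table
    sf <- sampleFractions(tab)
    cnt <- otuCounts(tab)
    for (s in unique(sf$sample_id)) {
        d <- which(sf$sample_id == s & sf$fraction == "DNA")
        r <- which(sf$sample_id == s & sf$fraction == "RNA")
        expect_equal(sum(cnt[, r] > 0 & cnt[, d] == 0), 0L)
    }
})

test_that("proportions normalize each column to 1 and keep zeros", {
    m <- matrix(c(1L, 3L, 5L, 0L), 2,
                dimnames = list(c("A", "B"), c("s1_DNA", "s1_RNA")))
    p <- normalizeProportions(m)
    expect_equal(unname(p[, 1]), c(0.25, 0.75))
    expect_equal(unname(p[, 2]), c(1, 0))
    expect_equal(unname(colSums(p)), c(1, 1), tolerance = 1e-12)
    m0 <- matrix(0L, 1, 1, dimnames = list("A", "s1_DNA"))
    expect_error(normalizeProportions(m0), "zero-total")
})

test_that("the filter chain removes one of each defect and keeps the ledger consistent", {
    m <- rbind(
        good     = c(100L, 60L, 50L, 40L, 0L),
        artefact = c(1L, 1L, 0L, 0L, 0L),
        contam   = c(200L, 100L, 50L, 30L, 4L),
        phantom  = c(0L, 9L, 0L, 0L, 0L))
    colnames(m) <- c("s1_DNA", "s1_RNA", "s2_DNA", "s2_RNA", "CTRL1_DNA")
    res <- runFilterChain(makeOtu(m))
    lt <- ledgerTable(res$ledger)
    expect_equal(lt$otus_removed, c(1L, 1L, 1L))
    expect_equal(res$ledger@otuIds,
                 list("artefact", "contam", "phantom"))
    expect_equal(rownames(res$table), "good")
    # read conservation through the chain
    expect_equal(res$ledger@readsIn,
                 res$ledger@readsOut + sum(lt$reads_removed))
})

test_that("a clean table passes the chain unchanged with an all-zero ledger", {
    m <- rbind(A = c(10L, 5L, 0L), B = c(4L, 0L, 0L))
    colnames(m) <- c("s1_DNA", "s1_RNA", "CTRL1_DNA")
    res <- runFilterChain(makeOtu(m))
    expect_equal(unname(otuCounts(res$table)), unname(m[, 1:2]))
    expect_equal(ledgerTable(res$ledger)$otus_removed, c(0L, 0L, 0L))
})

test_that("the chain is idempotent and only ever removes reads", {
    for (seed in c(2L, 13L)) {
        g <- generateCommunity(syntheticConfig(
            nOtus = 150L, depthDna = 6000, depthRna = 6000,
            contaminantCount = 6L, phantomCount = 8L, seed = seed))
        r1 <- runFilterChain(g$table)
        expect_lte(r1$ledger@readsOut, r1$ledger@readsIn)
        r2 <- runFilterChain(r1$table, allowNoControls = TRUE)
        expect_identical(otuCounts(r2$table), otuCounts(r1$table))
        expect_equal(sum(ledgerTable(r2$ledger)$otus_removed), 0L)
        expect_equal(sum(ledgerTable(r2$ledger)$reads_removed), 0)
    }
})

test_that("ledger TSV lists stages and affected OTUs", {
    m <- rbind(a = c(1L, 0L, 0L), b = c(9L, 4L, 0L))
    colnames(m) <- c("s1_DNA", "s1_RNA", "CTRL1_DNA")
    res <- runFilterChain(makeOtu(m))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLedger(res$ledger, f)
    df <- read.delim(f)
    expect_equal(df$stage, c("min_count", "decontaminate", "phantom"))
    expect_equal(df$otu_ids[1], "a")
})
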