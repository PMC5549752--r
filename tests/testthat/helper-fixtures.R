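# Fixtures are built in code; nothing is read from disk except temp files
# the tests themselves write.

# Reads with explicit per-base PHRED scores (constant per read by default).
makeReads <- function(seqs, qual = 30L) {
    x <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs))) names(x) <- sprintf("r%d", seq_along(seqs))
    q <- Biostrings::PhredQuality(vapply(nchar(seqs), function(L)
        strrep(rawToChar(as.raw(qual + 33L)), L), character(1)))
    Biostrings::QualityScaledDNAStringSet(x, q)
}

# Small OtuExperiment from a counts matrix with "<sample>_<DNA|RNA>" columns.
makeOtu <- function(counts, taxonomy = NULL, domain = "prokaryote") {
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("OTU%d", seq_len(nrow(counts)))
    OtuExperiment(counts, taxonomy = taxonomy, domain = domain)
}

# Independent identity oracle: ends-free global alignment through
# Biostrings::pairwiseAlignment with the same objective (match +1,
# mismatch -1, each gap column -1, terminal gaps free).
oracleIdentity <- function(a, b) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1)
    Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# Independent greedy clustering oracle: all-vs-all oracle identities plus
# the same processing order (decreasing length, decreasing abundance, id).
oracleGreedy <- function(seqs, threshold, abundance = NULL) {
    ids <- names(seqs)
    if (is.null(abundance)) abundance <- rep(1, length(seqs))
    ord <- order(-nchar(seqs), -abundance, ids)
    centroids <- character(0)
    assign <- character(length(seqs))
    names(assign) <- ids
    for (k in ord) {
        hit <- NA_character_
        for (cid in centroids) {
            if (oracleIdentity(seqs[[k]], seqs[[cid]]) >= threshold) {
                hit <- cid
                break
            }
        }
        assign[ids[k]] <- if (is.na(hit)) ids[k] else hit
        if (is.na(hit)) centroids <- c(centroids, ids[k])
    }
    assign
}

# Substitution-only mutant of a sequence.
mutateSeq <- function(seq, nSub) {
    b <- strsplit(seq, "")[[1]]
    pos <- sample(length(b), nSub)
    b[pos] <- vapply(b[pos], function(cur)
        sample(setdiff(c("A", "C", "G", "T"), cur), 1), character(1))
    paste(b, collapse = "")
}
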