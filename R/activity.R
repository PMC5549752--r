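#' @include diversity.R
NULL

#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums counts over OTUs sharing the same taxon at \code{rank}; OTUs
#' unassigned at that rank are pooled into a reserved \code{"unclassified"}
#' taxon. Column totals are conserved exactly.
#'
#' @param x an \linkS4class{OtuExperiment}.
#' @param rank a rank from \code{rankVocabulary(otuDomain(x))} (genus is the
#'   conventional prokaryote analysis rank, order the eukaryote one).
#' @param unclassified label for the pooled unassigned OTUs.
#' @return numeric matrix, taxa x sample fractions.
#' @export
aggregateToRank <- function(x, rank, unclassified = "unclassified") {
    tx <- taxonAtRank(x, rank, unclassified)
    m <- otuCounts(x)
    agg <- rowsum(m, group = tx)
    # keep "unclassified" last for readability
    if (unclassified %in% rownames(agg)) {
        keep <- setdiff(rownames(agg), unclassified)
        agg <- agg[c(keep, unclassified), , drop = FALSE]
    }
    agg
}

#' RNA:DNA activity ratio
#'
#' Relative abundance in the RNA fraction divided by relative abundance in
#' the DNA fraction; a proxy for relative metabolic activity. Zero RNA gives
#' ratio 0; zero DNA with positive RNA is a phantom leak and an error (such
#' entries must have been removed upstream by \code{\link{phantomFilter}}).
#'
#' @param dnaRel,rnaRel relative abundances (proportions), recycled.
#' @return non-negative ratio(s).
#' @export
rnaDnaRatio <- function(dnaRel, rnaRel) {
    if (any(dnaRel < 0) || any(rnaRel < 0)) stop("proportions must be >= 0")
    bad <- dnaRel == 0 & rnaRel > 0
    if (any(bad))
        stop("RNA abundance with zero DNA abundance (phantom leak); ",
             "run phantomFilter first")
    out <- numeric(length(dnaRel))
    pos <- dnaRel > 0
    out[pos] <- rnaRel[pos] / dnaRel[pos]
    out
}

#' Classify an RNA:DNA ratio into an activity band
#'
#' Bands follow the conventional 0.1 / 1 / 10 anchors:
#' \code{zero} (ratio 0), \code{lt_0.1}, \code{0.1_to_1}, \code{1_to_10},
#' \code{gt_10}. A ratio of exactly 1 falls in \code{1_to_10} and counts as
#' active; the activity predicate is \code{ratio >= 1}.
#'
#' @param ratio non-negative ratio(s).
#' @return factor with levels
#'   \code{zero, lt_0.1, 0.1_to_1, 1_to_10, gt_10}.
#' @export
classifyBand <- function(ratio) {
    if (any(ratio < 0)) stop("ratio must be non-negative")
    lev <- c("zero", "lt_0.1", "0.1_to_1", "1_to_10", "gt_10")
    band <- ifelse(ratio == 0, "zero",
            ifelse(ratio < 0.1, "lt_0.1",
            ifelse(ratio < 1, "0.1_to_1",
            ifelse(ratio < 10, "1_to_10", "gt_10"))))
    factor(band, levels = lev)
}

#' Is a ratio "active"?
#'
#' @param ratio non-negative ratio(s).
#' @return logical; \code{TRUE} where ratio >= 1.
#' @export
isActive <- function(ratio) {
    if (any(ratio < 0)) stop("ratio must be non-negative")
    ratio >= 1
}

#' Per-taxon, per-sample activity table
#'
#' For every (taxon, sample) pair present in both fractions of a filtered,
#' phantom-free table: DNA and RNA relative abundances (computed on
#' column-normalized proportions, so unequal sequencing depth between
#' fractions cancels), the RNA:DNA ratio and its band.
#'
#' @param x a filtered \linkS4class{OtuExperiment} with paired DNA/RNA
#'   columns (controls, if any, are ignored).
#' @param rank aggregation rank (default: genus for prokaryotes, order for
#'   eukaryotes).
#' @return data.frame with \code{taxon}, \code{sample_id}, \code{dna_rel},
#'   \code{rna_rel}, \code{ratio}, \code{band}; samples lacking either
#'   fraction raise an error.
#' @seealso \code{\link{rareRatioTrend}} for the abundance-vs-ratio
#'   diagnostic.
#' @export
activityTable <- function(x, rank = NULL) {
    if (is.null(rank))
        rank <- if (otuDomain(x) == "prokaryote") "genus" else "order"
    sf <- sampleFractions(x)
    x <- x[, !sf$is_control]
    sf <- sampleFractions(x)
    samples <- unique(sf$sample_id)
    agg <- aggregateToRank(x, rank)
    props <- normalizeProportions(agg)
    out <- lapply(samples, function(sid) {
        d <- which(sf$sample_id == sid & sf$fraction == "DNA")
        r <- which(sf$sample_id == sid & sf$fraction == "RNA")
        if (!length(d) || !length(r))
            stop("sample '", sid, "' lacks a DNA or RNA fraction")
        dna <- props[, d]; rna <- props[, r]
        data.frame(taxon = rownames(props), sample_id = sid,
                   dna_rel = unname(dna), rna_rel = unname(rna),
                   ratio = rnaDnaRatio(dna, rna),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out$band <- classifyBand(out$ratio)
    rownames(out) <- NULL
    out
}

#' Per-OTU RNA:DNA ratios
#'
#' The ratio at its native resolution: every OTU of a filtered, phantom-free
#' table, per sample (\code{perSample = TRUE}) or on relative abundances
#' averaged across samples (\code{perSample = FALSE}, one row per OTU) — the
#' latter is the screen used to call an OTU active overall
#' (\code{ratio >= 1}).
#'
#' @param x a filtered \linkS4class{OtuExperiment} with paired DNA/RNA
#'   columns; controls are ignored.
#' @param perSample one row per (OTU, sample) instead of per OTU.
#' @return data.frame with \code{otu_id}, (\code{sample_id},)
#'   \code{dna_rel}, \code{rna_rel}, \code{ratio}, \code{band},
#'   \code{active}.
#' @export
otuRnaDnaRatios <- function(x, perSample = FALSE) {
    sf <- sampleFractions(x)
    x <- x[, !sf$is_control]
    sf <- sampleFractions(x)
    props <- normalizeProportions(x)
    samples <- unique(sf$sample_id)
    dnaCols <- vapply(samples, function(s)
        which(sf$sample_id == s & sf$fraction == "DNA")[1], integer(1))
    rnaCols <- vapply(samples, function(s)
        which(sf$sample_id == s & sf$fraction == "RNA")[1], integer(1))
    if (any(is.na(dnaCols)) || any(is.na(rnaCols)))
        stop("every sample needs both a DNA and an RNA column")
    if (perSample) {
        out <- do.call(rbind, lapply(seq_along(samples), function(k) {
            dna <- props[, dnaCols[k]]; rna <- props[, rnaCols[k]]
            data.frame(otu_id = rownames(props), sample_id = samples[k],
                       dna_rel = unname(dna), rna_rel = unname(rna),
                       ratio = rnaDnaRatio(dna, rna),
                       stringsAsFactors = FALSE)
        }))
    } else {
        dna <- rowMeans(props[, dnaCols, drop = FALSE])
        rna <- rowMeans(props[, rnaCols, drop = FALSE])
        out <- data.frame(otu_id = rownames(props),
                          dna_rel = unname(dna), rna_rel = unname(rna),
                          ratio = rnaDnaRatio(dna, rna),
                          stringsAsFactors = FALSE)
    }
    out$band <- classifyBand(out$ratio)
    out$active <- isActive(out$ratio)
    rownames(out) <- NULL
    out
}

#' Abundance-vs-ratio diagnostic
#'
#' Spearman correlation between DNA relative abundance and RNA:DNA ratio,
#' per sample, over taxa with positive DNA abundance. Low-abundance taxa
#' tend to exhibit inflated ratios, so a negative coefficient is the
#' expected signature in uneven communities.
#'
#' @param activity an \code{\link{activityTable}} result.
#' @return data.frame with \code{sample_id}, \code{spearman_rho}.
#' @export
rareRatioTrend <- function(activity) {
    samples <- unique(activity$sample_id)
    rho <- vapply(samples, function(sid) {
        a <- activity[activity$sample_id == sid & activity$dna_rel > 0, ]
        stats::cor(a$dna_rel, a$ratio, method = "spearman")
    }, numeric(1))
    data.frame(sample_id = samples, spearman_rho = unname(rho))
}

#' Top taxa by average abundance rank across samples
#'
#' Within each sample, taxa are ranked by decreasing relative abundance in
#' the chosen fraction (rank 1 = most abundant; a taxon absent from a sample
#' gets rank \code{n_taxa + 1}); ranks are averaged across samples and the
#' \code{n} taxa with the smallest average rank are returned, ties broken by
#' total abundance, then name.
#'
#' @param x a filtered \linkS4class{OtuExperiment} (controls ignored), or a
#'   taxon x sample-fraction matrix as from \code{\link{aggregateToRank}}.
#' @param n number of taxa to return (default 20).
#' @param rank aggregation rank when \code{x} is an \code{OtuExperiment}.
#' @param rankBy fraction used for ranking: \code{"dna"} (default),
#'   \code{"rna"} or \code{"mean"} of both.
#' @return character vector of taxon names, best average rank first.
#' @export
topTaxaByAverageRank <- function(x, n = 20L, rank = NULL,
                                 rankBy = c("dna", "rna", "mean")) {
    rankBy <- match.arg(rankBy)
    if (n < 1) stop("n must be >= 1")
    if (methods::is(x, "OtuExperiment")) {
        if (is.null(rank))
            rank <- if (otuDomain(x) == "prokaryote") "genus" else "order"
        sf <- sampleFractions(x)
        x <- x[, !sf$is_control]
        props <- normalizeProportions(aggregateToRank(x, rank))
        sf <- sampleFractions(x)
    } else {
        props <- normalizeProportions(x)
        sf <- parseFractionLabels(colnames(props))
    }
    samples <- unique(sf$sample_id)
    nt <- nrow(props)
    rankOf <- function(v) {
        # decreasing-abundance rank; absent taxa pushed to n_taxa + 1
        r <- rank(-v, ties.method = "min")
        r[v == 0] <- nt + 1
        r
    }
    rmat <- matrix(vapply(samples, function(sid) {
        d <- which(sf$sample_id == sid & sf$fraction == "DNA")
        r <- which(sf$sample_id == sid & sf$fraction == "RNA")
        v <- switch(rankBy,
            dna = props[, d],
            rna = props[, r],
            mean = {
                cols <- c(d, r)
                rowMeans(props[, cols, drop = FALSE])
            })
        rankOf(v)
    }, numeric(nt)), nrow = nt)
    avg <- rowMeans(rmat)
    totalAb <- rowSums(props)
    ord <- order(avg, -totalAb, rownames(props))
    utils::head(rownames(props)[ord], n)
}
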