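#' @include comparison.R
NULL

#' Configuration for the paired DNA/RNA community generator
#'
#' Describes a synthetic cloud-water-like community: heavy-tailed (log-normal)
#' OTU abundances, paired DNA and RNA fractions of fixed sequencing depth, a
#' designated active subset with elevated RNA:DNA multipliers and an inactive
#' subset with depressed ones, optional rare-OTU ratio inflation, control-
#' shared contaminant OTUs and RNA-only phantom OTUs.
#'
#' @param nOtus number of community OTUs (contaminants/phantoms are extra).
#' @param nSamples number of cloud samples (default 3).
#' @param lognormalSigma sd of the log-normal abundance law; controls
#'   unevenness (sigma 2 gives Gini around 0.9 for large communities).
#' @param depthDna,depthRna reads per DNA / RNA column (multinomial totals).
#' @param activeFraction fraction of community OTUs designated active.
#' @param inactiveFraction fraction designated inactive; the remainder is
#'   neutral (multiplier 1).
#' @param activeMultiplierRange RNA:DNA multiplier range for active OTUs
#'   (log-uniform draw; low >= 1).
#' @param inactiveMultiplierRange multiplier range for inactive OTUs
#'   (high <= 1).
#' @param rareRatioInflation strength of the rare-OTU ratio inflation: the
#'   multiplier is scaled by \code{1 + inflation / percentile} where
#'   percentile is the OTU's ascending abundance percentile (rarest smallest),
#'   reproducing the rare-taxa-high-ratio trend; 0 disables it.
#' @param contaminantCount number of contaminant OTUs (present in controls
#'   and, moderately, in samples).
#' @param contaminantControlRate expected control reads per contaminant.
#' @param phantomCount number of RNA-only phantom OTUs.
#' @param nGenera size of the synthetic genus pool for taxonomy assignment.
#' @param unassignedProb probability that an OTU's lineage terminates early.
#' @param domain \code{"prokaryote"} or \code{"eukaryote"}.
#' @param seed integer seed; the generator touches no global RNG state.
#' @return a validated \code{SyntheticConfig} list.
#' @export
syntheticConfig <- function(nOtus = 500L, nSamples = 3L,
                            lognormalSigma = 2,
                            depthDna = 5e4, depthRna = 5e4,
                            activeFraction = 0.1, inactiveFraction = 0.2,
                            activeMultiplierRange = c(3, 10),
                            inactiveMultiplierRange = c(0.1, 1 / 3),
                            rareRatioInflation = 0,
                            contaminantCount = 5L,
                            contaminantControlRate = 20,
                            phantomCount = 10L,
                            nGenera = 50L, unassignedProb = 0.15,
                            domain = c("prokaryote", "eukaryote"),
                            seed = 1L) {
    domain <- match.arg(domain)
    chk <- function(ok, field) if (!ok) stop("invalid config field: ", field)
    chk(nOtus >= 1, "nOtus")
    chk(nSamples >= 1, "nSamples")
    chk(lognormalSigma >= 0, "lognormalSigma")
    chk(depthDna > 0 && depthRna > 0, "depthDna/depthRna")
    chk(activeFraction >= 0 && activeFraction <= 1, "activeFraction")
    chk(inactiveFraction >= 0 && activeFraction + inactiveFraction <= 1,
        "inactiveFraction")
    chk(activeMultiplierRange[1] >= 1 &&
        activeMultiplierRange[2] >= activeMultiplierRange[1],
        "activeMultiplierRange")
    chk(inactiveMultiplierRange[2] <= 1 &&
        inactiveMultiplierRange[1] <= inactiveMultiplierRange[2] &&
        inactiveMultiplierRange[1] > 0,
        "inactiveMultiplierRange")
    chk(rareRatioInflation >= 0, "rareRatioInflation")
    chk(contaminantCount >= 0, "contaminantCount")
    chk(phantomCount >= 0, "phantomCount")
    structure(as.list(environment())[c(
        "nOtus", "nSamples", "lognormalSigma", "depthDna", "depthRna",
        "activeFraction", "inactiveFraction", "activeMultiplierRange",
        "inactiveMultiplierRange", "rareRatioInflation", "contaminantCount",
        "contaminantControlRate", "phantomCount", "nGenera",
        "unassignedProb", "domain", "seed")],
        class = "SyntheticConfig")
}

## One synthetic lineage per genus index, consistent up the vocabulary.
.lineagePool <- function(nGenera, domain) {
    vocab <- rankVocabulary(domain)
    depth <- length(vocab)
    vapply(seq_len(nGenera), function(g) {
        idx <- g
        parts <- character(depth)
        for (k in rev(seq_len(depth))) {
            cap <- paste0(toupper(substring(vocab[k], 1, 1)),
                          substring(vocab[k], 2))
            parts[k] <- sprintf("%s_%02d", cap, idx)
            idx <- (idx - 1L) %/% 2L + 1L
        }
        paste(parts, collapse = ";")
    }, character(1))
}

#' Generate a paired DNA/RNA community with ground truth
#'
#' Per sample, base abundances are drawn log-normal(0, sigma^2) and
#' normalized; DNA counts are a multinomial draw of \code{depthDna} reads.
#' Expected RNA proportions are the base abundances scaled by each OTU's
#' multiplier (active OTUs: log-uniform in the active range; inactive: in the
#' inactive range; neutral: 1), optionally inflated for rare OTUs, then
#' renormalized; RNA counts are a multinomial draw of \code{depthRna}.
#' Contaminant OTUs receive moderate sample abundance and Poisson counts in
#' a control DNA column; phantoms receive RNA-only abundance. Everything is
#' drawn from one seeded generator, so equal seeds give identical output.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return list with \code{table} (an \linkS4class{OtuExperiment} with
#'   DNA + RNA columns per sample and one control DNA column) and
#'   \code{truth}, a list: \code{active_set}, \code{inactive_set},
#'   \code{contaminant_set}, \code{phantom_set}, \code{multipliers} (named,
#'   community OTUs), \code{true_abundances} (community OTU x sample base
#'   proportions).
#' @export
generateCommunity <- function(cfg = syntheticConfig()) {
    stopifnot(inherits(cfg, "SyntheticConfig"))
    withr::with_seed(cfg$seed, .generateCommunity(cfg))
}

.generateCommunity <- function(cfg) {
    nC <- cfg$nOtus; nK <- cfg$contaminantCount; nP <- cfg$phantomCount
    nTot <- nC + nK + nP
    ids <- sprintf("OTU_%05d", seq_len(nTot))
    community <- ids[seq_len(nC)]
    contaminants <- if (nK) ids[nC + seq_len(nK)] else character(0)
    phantoms <- if (nP) ids[nC + nK + seq_len(nP)] else character(0)

    nAct <- round(cfg$activeFraction * nC)
    nIn <- round(cfg$inactiveFraction * nC)
    pick <- sample(community, nAct + nIn)
    activeSet <- pick[seq_len(nAct)]
    inactiveSet <- setdiff(pick, activeSet)
    mult <- rep(1, nC)
    names(mult) <- community
    lu <- function(n, rg) exp(stats::runif(n, log(rg[1]), log(rg[2])))
    mult[activeSet] <- lu(nAct, cfg$activeMultiplierRange)
    mult[inactiveSet] <- lu(nIn, cfg$inactiveMultiplierRange)

    samples <- sprintf("cloud%d", seq_len(cfg$nSamples))
    cols <- c(t(outer(samples, c("DNA", "RNA"), paste, sep = "_")))
    m <- matrix(0L, nTot, length(cols), dimnames = list(ids, cols))
    trueAb <- matrix(0, nC, cfg$nSamples,
                     dimnames = list(community, samples))

    for (s in seq_len(cfg$nSamples)) {
        x <- stats::rlnorm(nC, 0, cfg$lognormalSigma)
        # contaminants: moderate-to-high in samples, so presence-based
        # control removal is genuinely load-bearing
        xK <- if (nK) stats::quantile(x, stats::runif(nK, 0.6, 0.9)) else
            numeric(0)
        pD <- c(x, xK, rep(0, nP))
        pD <- pD / sum(pD)
        m[, 2 * s - 1] <- stats::rmultinom(1, cfg$depthDna, pD)[, 1]
        trueAb[, s] <- x / sum(x)

        infl <- rep(1, nC)
        if (cfg$rareRatioInflation > 0) {
            pct <- rank(x, ties.method = "first") / nC
            infl <- 1 + cfg$rareRatioInflation / pct
        }
        xPh <- if (nP) rep(stats::quantile(x, 0.7), nP) else numeric(0)
        eR <- c(x * mult * infl, xK, xPh)
        eR <- eR / sum(eR)
        m[, 2 * s] <- stats::rmultinom(1, cfg$depthRna, eR)[, 1]
    }
    if (nK) {
        ctrl <- matrix(0L, nTot, 1, dimnames = list(ids, "CTRL1_DNA"))
        ctrl[contaminants, 1] <-
            stats::rpois(nK, cfg$contaminantControlRate) + 1L
        m <- cbind(m, ctrl)
    }

    pool <- .lineagePool(cfg$nGenera, cfg$domain)
    gidx <- sample.int(cfg$nGenera, nTot, replace = TRUE)
    lin <- pool[gidx]
    depth <- length(rankVocabulary(cfg$domain))
    trunc <- stats::runif(nTot) < cfg$unassignedProb
    keepRanks <- sample.int(depth - 1L, nTot, replace = TRUE)
    lin[trunc] <- vapply(which(trunc), function(i)
        paste(strsplit(lin[i], ";", fixed = TRUE)[[1]][seq_len(keepRanks[i])],
              collapse = ";"),
        character(1))
    names(lin) <- ids

    tab <- OtuExperiment(m, taxonomy = lin, domain = cfg$domain)
    truth <- list(active_set = activeSet,
                  inactive_set = inactiveSet,
                  contaminant_set = contaminants,
                  phantom_set = phantoms,
                  multipliers = mult,
                  true_abundances = trueAb)
    list(table = tab, truth = truth)
}

#' Recall and precision of a recovered OTU set
#'
#' Scores a predicted set (e.g. OTUs called active by the ratio >= 1 rule)
#' against a ground-truth set, over a stated universe of scoreable OTUs —
#' conventionally the OTUs observable after the filter chain, since a taxon
#' whose abundance leaves it unsequenced at the configured depth cannot be
#' classified at all. Contaminants and phantoms are excluded upstream by
#' construction of the truth sets.
#'
#' @param predicted character vector of predicted OTU ids.
#' @param truthSet character vector of true OTU ids.
#' @param universe character vector of scoreable OTU ids; both sets are
#'   intersected with it.
#' @return named numeric: \code{recall}, \code{precision},
#'   \code{true_positives}, \code{n_truth}, \code{n_predicted}.
#' @export
recoveryScores <- function(predicted, truthSet, universe) {
    predicted <- intersect(predicted, universe)
    truthSet <- intersect(truthSet, universe)
    tp <- length(intersect(predicted, truthSet))
    c(recall = if (length(truthSet)) tp / length(truthSet) else NA_real_,
      precision = if (length(predicted)) tp / length(predicted) else
          NA_real_,
      true_positives = tp,
      n_truth = length(truthSet),
      n_predicted = length(predicted))
}

#' Random centroid sequences
#'
#' @param n number of sequences.
#' @param length sequence length in bp.
#' @param seed integer seed.
#' @return named \code{DNAStringSet} (\code{OTU_1} ...).
#' @export
randomCentroids <- function(n, length = 250L, seed = 1L) {
    withr::with_seed(seed, {
        x <- Biostrings::DNAStringSet(vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = ""), character(1)))
        names(x) <- sprintf("OTU_%d", seq_len(n))
        x
    })
}

#' Generate point-mutated reads from centroid sequences
#'
#' Emits, for each (OTU, sample-fraction) cell of \code{counts}, that many
#' reads: point-mutated copies of the OTU's centroid at the given per-base
#' divergence, with constant PHRED quality. The returned truth maps every
#' read back to its OTU and column, for clustering- and QC-recovery tests.
#'
#' @param centroids named \code{DNAStringSet} (or character vector).
#' @param counts integer matrix OTU x sample-fraction label, or a named
#'   vector (treated as a single \code{"s1_DNA"} column).
#' @param divergence per-base substitution probability.
#' @param qual constant PHRED score for all bases (default 30).
#' @param seed integer seed.
#' @param threshold optional clustering identity threshold; a warning is
#'   issued when \code{divergence >= 1 - threshold} (clusters may merge).
#' @return list with \code{reads} (\code{QualityScaledDNAStringSet}) and
#'   \code{truth} (data.frame \code{read}, \code{otu}, \code{label}).
#' @export
generateReads <- function(centroids, counts, divergence = 0.01, qual = 30L,
                          seed = 1L, threshold = NULL) {
    if (!is.null(threshold) && divergence >= 1 - threshold)
        warning("divergence ", divergence, " >= 1 - threshold; ",
                "clusters may merge")
    seqs <- vapply(as.character(centroids), identity, character(1))
    if (is.null(dim(counts))) {
        counts <- matrix(as.integer(counts), ncol = 1,
                         dimnames = list(names(counts), "s1_DNA"))
    }
    missing <- setdiff(rownames(counts), names(seqs))
    if (length(missing))
        stop("no centroid for OTU(s): ", paste(missing, collapse = ", "))
    withr::with_seed(seed, {
        reads <- character(0); otus <- character(0); labs <- character(0)
        for (i in rownames(counts)) for (j in colnames(counts)) {
            k <- counts[i, j]
            if (k == 0) next
            base <- strsplit(seqs[[i]], "")[[1]]
            rs <- vapply(seq_len(k), function(r) {
                b <- base
                hit <- which(stats::runif(length(b)) < divergence)
                if (length(hit))
                    b[hit] <- vapply(b[hit], function(cur)
                        sample(setdiff(c("A", "C", "G", "T"), cur), 1),
                        character(1))
                paste(b, collapse = "")
            }, character(1))
            reads <- c(reads, rs)
            otus <- c(otus, rep(i, k))
            labs <- c(labs, rep(j, k))
        }
        ids <- sprintf("read_%06d", seq_along(reads))
        x <- Biostrings::DNAStringSet(reads)
        names(x) <- ids
        q <- Biostrings::PhredQuality(vapply(nchar(reads), function(L)
            paste(rep(rawToChar(as.raw(qual + 33L)), L), collapse = ""),
            character(1)))
        list(reads = Biostrings::QualityScaledDNAStringSet(x, q),
             truth = data.frame(read = ids, otu = otus, label = labs,
                                stringsAsFactors = FALSE))
    })
}
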