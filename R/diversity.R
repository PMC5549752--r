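#' @include filters.R
NULL

#' Shannon-Wiener diversity (natural log)
#'
#' \eqn{H = -\sum p_i \ln p_i} over taxa with positive counts. Natural log,
#' so the maximum for n taxa is \eqn{\ln n}.
#'
#' @param counts non-negative numeric vector of abundances.
#' @return H in nats.
#' @export
shannon <- function(counts) {
    counts <- counts[counts > 0]
    if (!length(counts)) stop("all counts are zero")
    p <- counts / sum(counts)
    -sum(p * log(p))
}

#' ACE richness estimator
#'
#' Classic abundance-based coverage estimator with rare cutoff
#' \code{rareCutoff} (default 10):
#' \deqn{ACE = S_{abund} + S_{rare}/C_{ace} + (F_1/C_{ace})\,\gamma^2}
#' with \eqn{C_{ace} = 1 - F_1/N_{rare}} the sample coverage of the rare
#' group and \eqn{\gamma^2} the (truncated at 0) rare-group coefficient of
#' variation. When every rare read is a singleton (\eqn{C_{ace} = 0}) the
#' estimator is undefined and Chao1
#' (\eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))}) is returned instead.
#'
#' @param counts non-negative integer vector of per-taxon abundances.
#' @param rareCutoff taxa with counts <= this are the "rare" group.
#' @return estimated total richness (>= observed richness when
#'   \eqn{C_{ace} > 0}).
#' @export
ace <- function(counts, rareCutoff = 10L) {
    counts <- counts[counts > 0]
    if (!length(counts)) stop("all counts are zero")
    sAbund <- sum(counts > rareCutoff)
    rare <- counts[counts <= rareCutoff]
    sRare <- length(rare)
    if (sRare == 0) return(sAbund)
    nRare <- sum(rare)
    f <- tabulate(rare, nbins = rareCutoff)
    f1 <- f[1]
    cAce <- 1 - f1 / nRare
    if (cAce == 0) {
        # all rare reads are singletons: fall back to Chao1
        f2 <- if (rareCutoff >= 2L) f[2] else 0
        return(sAbund + sRare + f1 * (f1 - 1) / (2 * (f2 + 1)))
    }
    i <- seq_len(rareCutoff)
    gamma2 <- max(
        (sRare / cAce) * sum(i * (i - 1) * f) / (nRare * (nRare - 1)) - 1,
        0)
    sAbund + sRare / cAce + (f1 / cAce) * gamma2
}

#' Gini coefficient of the abundance distribution
#'
#' Inequality of the observed community: 0 for perfect evenness, towards 1
#' when few taxa dominate. Computed over observed taxa only (count > 0) with
#' the sorted-index (sample) formula
#' \eqn{G = 2\sum_i i\,x_{(i)} / (n\sum x) - (n+1)/n}.
#'
#' @param counts non-negative numeric abundances.
#' @return Gini coefficient in \[0, 1 - 1/n\].
#' @export
gini <- function(counts) {
    x <- sort(counts[counts > 0])
    n <- length(x)
    if (!n) stop("all counts are zero")
    2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

#' Lorenz curve of the abundance distribution
#'
#' Cumulative read fraction against cumulative taxon fraction, taxa sorted
#' ascending; starts at (0, 0) and ends at (1, 1); convex. The further the
#' curve sags below the diagonal, the more uneven the community (the Gini
#' coefficient is twice the area between the two).
#'
#' @param counts non-negative numeric abundances.
#' @return data.frame with \code{otu_fraction}, \code{read_fraction}.
#' @export
lorenz <- function(counts) {
    x <- sort(counts[counts > 0])
    n <- length(x)
    if (!n) stop("all counts are zero")
    data.frame(otu_fraction = c(0, seq_len(n) / n),
               read_fraction = c(0, cumsum(x) / sum(x)))
}

#' Coverage ratio: observed over estimated richness
#'
#' The fraction of the estimated total richness actually observed,
#' \code{observed / estimated} (with ACE as the estimator this reproduces
#' headline coverages such as 72\% and 98\% from observed/ACE richness
#' pairs).
#'
#' @param observed observed richness.
#' @param estimated estimated total richness (> 0).
#' @return coverage ratio (multiply by 100 for percent).
#' @export
coverageRatio <- function(observed, estimated) {
    if (any(estimated <= 0)) stop("estimated richness must be positive")
    observed / estimated
}

#' Good's coverage
#'
#' Secondary coverage measure \eqn{1 - F_1/N} (fraction of reads belonging
#' to taxa seen more than once).
#'
#' @param counts non-negative integer abundances.
#' @return Good's coverage in \[0, 1\].
#' @export
goodsCoverage <- function(counts) {
    counts <- counts[counts > 0]
    if (!length(counts)) stop("all counts are zero")
    1 - sum(counts == 1) / sum(counts)
}

#' Exact (hypergeometric) rarefaction
#'
#' Expected richness in a random subsample of each depth, drawn without
#' replacement: \eqn{E[S_m] = \sum_i 1 - \binom{N-N_i}{m}/\binom{N}{m}},
#' evaluated in log-gamma space so large counts do not overflow.
#'
#' @param counts non-negative integer abundances.
#' @param depths increasing subsample depths, each <= \code{sum(counts)}.
#' @return data.frame with \code{depth}, \code{expected_richness}; attribute
#'   \code{method = "exact"}.
#' @export
rarefactionExact <- function(counts, depths) {
    counts <- counts[counts > 0]
    N <- sum(counts)
    if (any(depths > N)) stop("depth exceeds total reads (", N, ")")
    if (any(depths < 0)) stop("depths must be non-negative")
    er <- vapply(depths, function(m) {
        if (m == 0) return(0)
        sum(1 - exp(lchoose(N - counts, m) - lchoose(N, m)))
    }, numeric(1))
    out <- data.frame(depth = depths, expected_richness = er)
    attr(out, "method") <- "exact"
    out
}

#' Subsample counts without replacement
#'
#' One multivariate hypergeometric draw of \code{depth} reads from the
#' community; reproducible via the explicit \code{seed} (global RNG state is
#' left untouched).
#'
#' @param counts non-negative integer abundances.
#' @param depth number of reads to draw (<= \code{sum(counts)}).
#' @param seed integer seed.
#' @return integer vector of the same length as \code{counts}, summing to
#'   \code{depth}.
#' @export
rarefy <- function(counts, depth, seed) {
    N <- sum(counts)
    if (depth > N) stop("depth exceeds total reads (", N, ")")
    if (depth == N) return(as.integer(counts))
    if (depth == 0) return(integer(length(counts)))
    withr::with_seed(seed, {
        pool <- rep.int(seq_along(counts), counts)
        picked <- sample(pool, depth, replace = FALSE)
        tabulate(picked, nbins = length(counts))
    })
}

#' Per-column diversity report
#'
#' Observed richness, Shannon H (nats), ACE, Gini and coverage
#' (observed/ACE) for every sample fraction of a table.
#'
#' @param x an \linkS4class{OtuExperiment} (or count matrix).
#' @param rareCutoff ACE rare cutoff (default 10).
#' @return data.frame with one row per column: \code{label},
#'   \code{sample_id}, \code{fraction}, \code{reads}, \code{observed},
#'   \code{shannon_h}, \code{ace}, \code{gini}, \code{coverage}.
#' @export
diversityReport <- function(x, rareCutoff = 10L) {
    m <- if (methods::is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
    sf <- if (methods::is(x, "OtuExperiment")) sampleFractions(x) else
        data.frame(sample_id = colnames(m),
                   fraction = NA_character_)
    res <- lapply(seq_len(ncol(m)), function(j) {
        v <- m[, j]
        a <- ace(v, rareCutoff)
        data.frame(label = colnames(m)[j],
                   sample_id = sf$sample_id[j],
                   fraction = sf$fraction[j],
                   reads = sum(v),
                   observed = sum(v > 0),
                   shannon_h = shannon(v),
                   ace = a,
                   gini = gini(v),
                   coverage = coverageRatio(sum(v > 0), a))
    })
    do.call(rbind, res)
}
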