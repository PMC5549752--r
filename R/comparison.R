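#' @include activity.R
NULL

#' Shared-OTU (Venn) partition across samples
#'
#' Assigns every OTU of the chosen fraction to the region defined by the set
#' of samples in which it is present (count > 0), and reports per-region OTU
#' counts and, for each sample, the fraction of that sample's reads carried
#' by the region. Regions partition the OTU set: disjoint and exhaustive.
#'
#' @param x an \linkS4class{OtuExperiment} with >= 2 non-control samples in
#'   the fraction.
#' @param fraction \code{"DNA"} (default) or \code{"RNA"}.
#' @return data.frame with \code{region} (sample ids joined by \code{"+"};
#'   \code{"absent"} collects all-zero OTUs if any), \code{n_samples},
#'   \code{otu_count}, and one \code{readfrac_<sample>} column per sample.
#' @export
vennPartition <- function(x, fraction = c("DNA", "RNA")) {
    fraction <- match.arg(fraction)
    sf <- sampleFractions(x)
    keep <- sf$fraction == fraction & !sf$is_control
    if (sum(keep) < 2)
        stop("need at least 2 non-control samples in the ", fraction,
             " fraction")
    m <- otuCounts(x)[, keep, drop = FALSE]
    samples <- sf$sample_id[keep]
    colnames(m) <- samples
    pres <- m > 0
    region <- apply(pres, 1, function(p)
        if (any(p)) paste(samples[p], collapse = "+") else "absent")
    regs <- unique(region)
    out <- lapply(regs, function(rg) {
        rows <- region == rg
        rf <- colSums(m[rows, , drop = FALSE]) / colSums(m)
        df <- data.frame(region = rg,
                         n_samples = if (rg == "absent") 0L else
                             lengths(strsplit(rg, "+", fixed = TRUE)),
                         otu_count = sum(rows))
        for (s in samples) df[[paste0("readfrac_", s)]] <- unname(rf[s])
        df
    })
    out <- do.call(rbind, out)
    out[order(-out$n_samples, out$region), , drop = FALSE]
}

#' Bray-Curtis similarity matrix
#'
#' Similarity \eqn{1 - \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between all
#' pairs of columns of a proportion matrix (computed via
#' \code{vegan::vegdist}); 1 on identical columns, 0 on disjoint supports.
#'
#' @param props numeric matrix with normalized columns (see
#'   \code{\link{normalizeProportions}}), or an \linkS4class{OtuExperiment}
#'   (normalized internally).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
brayCurtisMatrix <- function(props) {
    if (methods::is(props, "OtuExperiment"))
        props <- normalizeProportions(props)
    d <- as.matrix(vegan::vegdist(t(props), method = "bray"))
    s <- 1 - d
    dimnames(s) <- list(colnames(props), colnames(props))
    s
}

#' Convert a per-mL water concentration to cells per m3 of air
#'
#' Cloud droplets concentrate airborne cells into liquid water; given the
#' sampled water volume and the equivalent volume of cloudy air it
#' represents, \code{conc_per_mL * water_volume_mL / air_volume_m3} recovers
#' the concentration per m3 of air.
#'
#' @param concPerMl cell concentration per mL of cloud water (>= 0).
#' @param waterVolumeMl sampled water volume in mL (> 0).
#' @param airVolumeM3 equivalent air volume in m3 (> 0).
#' @return cells per m3 of air.
#' @examples
#' cellsPerAirVolume(8.67e2, 94, 304)    # ~268 cells m-3
#' @export
cellsPerAirVolume <- function(concPerMl, waterVolumeMl, airVolumeM3) {
    if (any(airVolumeM3 <= 0)) stop("air volume must be positive")
    if (any(waterVolumeMl <= 0)) stop("water volume must be positive")
    if (any(concPerMl < 0)) stop("concentration must be non-negative")
    concPerMl * waterVolumeMl / airVolumeM3
}

#' Round an air concentration for reporting
#'
#' Reporting convention: 2 significant figures for values >= 100, 1
#' significant figure below (268 prints as 270, 7.6 as 8).
#'
#' @param x cells per m3.
#' @return rounded value(s).
#' @export
formatAirConcentration <- function(x) {
    ifelse(x >= 100, signif(x, 2), signif(x, 1))
}
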