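#' @include synthetic.R
NULL

#' Published characteristics of the three puy de Dome cloud samples
#'
#' Per-sample field data for the three cloud water events the pipeline's
#' design is based on: sampled water volume, equivalent air volume, total
#' prokaryotic and eukaryotic cell concentrations per mL of cloud water, and
#' liquid water content. Used by \code{\link{cellsPerAirVolume}} to recover
#' cells per m3 of cloudy air.
#'
#' @return data.frame with one row per cloud sample.
#' @export
cloudSampleCharacteristics <- function() {
    utils::read.delim(system.file("extdata",
                                  "cloud_sample_characteristics.tsv",
                                  package = "cloudAmplicon"),
                      stringsAsFactors = FALSE)
}

#' Published richness/diversity summary of the cloud amplicon datasets
#'
#' Per sample-fraction summary statistics of the processed prokaryote (16S)
#' and eukaryote (18S) communities: read count, observed and ACE-estimated
#' richness, Shannon H (nats) and Gini coefficient. Used to recompute
#' derived headline numbers such as the observed/ACE coverage range.
#'
#' @return data.frame with one row per (domain, sample, fraction).
#' @export
cloudRichnessSummary <- function() {
    utils::read.delim(system.file("extdata", "cloud_richness_summary.tsv",
                                  package = "cloudAmplicon"),
                      stringsAsFactors = FALSE)
}
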