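#' @include reference-data.R
NULL

#' Run the full downstream pipeline
#'
#' Orchestrates the table-level analysis end to end: conservative filter
#' chain (artefacts, contaminants, phantoms), per-column diversity report,
#' per-taxon RNA:DNA activity table with top-taxon selection, shared-OTU
#' partition and Bray-Curtis similarity, writing every artifact plus a run
#' manifest (JSON) that records parameters, seed, package version and
#' per-stage read/OTU counts. Re-running with the same inputs and seed
#' reproduces the outputs byte for byte; input files are never modified.
#'
#' The pipeline can also enter at read level: pass \code{reads} (a
#' \code{QualityScaledDNAStringSet}), \code{readMap} and
#' \code{clusterThreshold}, and QC + greedy clustering build the OTU table
#' first.
#'
#' @param input an \linkS4class{OtuExperiment}, or path to an OTU table TSV.
#' @param outDir output directory (created if needed).
#' @param taxonomyPath optional taxonomy TSV (when \code{input} is a path).
#' @param domain \code{"prokaryote"} or \code{"eukaryote"} (when
#'   \code{input} is a path).
#' @param controlPrefix control sample-id prefix.
#' @param minReads artefact filter threshold (default 3).
#' @param phantomScope \code{"sample"} or \code{"global"}.
#' @param allowNoControls run without control columns (explicit opt-in).
#' @param rank activity aggregation rank (default by domain).
#' @param topN number of top taxa to report (default 20).
#' @param rarefyDepths optional integer depths for a rarefaction summary of
#'   every column (exact expectation).
#' @param reads,readMap,clusterThreshold,qc optional read-level entry: QC
#'   config (\code{\link{qcConfig}}), reads, read-to-label map, identity
#'   threshold.
#' @param seed integer seed recorded in the manifest and used for any
#'   subsampling.
#' @return invisibly, a list with \code{table}, \code{ledger},
#'   \code{diversity}, \code{activity}, \code{topTaxa}, \code{venn},
#'   \code{brayCurtis}, \code{manifest}.
#' @export
runPipeline <- function(input, outDir,
                        taxonomyPath = NULL,
                        domain = c("prokaryote", "eukaryote"),
                        controlPrefix = "CTRL",
                        minReads = 3L,
                        phantomScope = c("sample", "global"),
                        allowNoControls = FALSE,
                        rank = NULL, topN = 20L,
                        rarefyDepths = NULL,
                        reads = NULL, readMap = NULL,
                        clusterThreshold = 0.97, qc = qcConfig(),
                        seed = 1L) {
    domain <- match.arg(domain)
    phantomScope <- match.arg(phantomScope)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stages <- list()

    if (!is.null(reads)) {
        qcRes <- qcFilter(reads, qc)
        writeQcReport(qcRes$report, file.path(outDir, "qc_report.tsv"))
        stages$qc <- list(reads_in = qcRes$report$input_reads,
                          reads_out = qcRes$report$passed)
        cl <- greedyCluster(as.character(qcRes$passed), clusterThreshold)
        input <- clusterCounts(cl, readMap, domain = domain,
                               controlPrefix = controlPrefix)
        stages$cluster <- list(reads_in = nrow(cl),
                               otus_out = nrow(input))
    } else if (is.character(input)) {
        input <- readOtuTable(input, taxonomyPath, domain = domain,
                              controlPrefix = controlPrefix)
    }
    if (is.null(rank))
        rank <- if (otuDomain(input) == "prokaryote") "genus" else "order"

    fc <- runFilterChain(input, minReads = minReads,
                         phantomScope = phantomScope,
                         allowNoControls = allowNoControls)
    tab <- fc$table
    writeOtuTable(tab, file.path(outDir, "filtered_otus.tsv"),
                  file.path(outDir, "filtered_taxonomy.tsv"))
    writeLedger(fc$ledger, file.path(outDir, "filter_ledger.tsv"))
    stages$filter <- list(otus_in = nrow(input), otus_out = nrow(tab),
                          reads_in = fc$ledger@readsIn,
                          reads_out = fc$ledger@readsOut)

    div <- diversityReport(tab)
    utils::write.table(div, file.path(outDir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    act <- activityTable(tab, rank = rank)
    utils::write.table(act, file.path(outDir, "activity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- topTaxaByAverageRank(tab, n = topN, rank = rank)
    writeLines(top, file.path(outDir, "top_taxa.txt"))

    sf <- sampleFractions(tab)
    nDna <- length(unique(sf$sample_id[sf$fraction == "DNA" &
                                           !sf$is_control]))
    venn <- if (nDna >= 2) vennPartition(tab, "DNA") else NULL
    if (!is.null(venn))
        utils::write.table(venn, file.path(outDir, "venn.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    bc <- brayCurtisMatrix(normalizeProportions(tab))
    utils::write.table(data.frame(label = rownames(bc), bc,
                                  check.names = FALSE),
                       file.path(outDir, "braycurtis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    if (!is.null(rarefyDepths)) {
        m <- otuCounts(tab)
        rc <- do.call(rbind, lapply(colnames(m), function(lab) {
            d <- rarefyDepths[rarefyDepths <= sum(m[, lab])]
            if (!length(d)) return(NULL)
            cbind(label = lab, rarefactionExact(m[, lab], d))
        }))
        utils::write.table(rc, file.path(outDir, "rarefaction.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }

    manifest <- list(
        tool = "cloudAmplicon",
        version = as.character(utils::packageVersion("cloudAmplicon")),
        seed = seed,
        parameters = list(domain = otuDomain(tab), minReads = minReads,
                          phantomScope = phantomScope, rank = rank,
                          topN = topN, controlPrefix = controlPrefix),
        stages = stages,
        ledger = ledgerTable(fc$ledger)
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(table = tab, ledger = fc$ledger, diversity = div,
                   activity = act, topTaxa = top, venn = venn,
                   brayCurtis = bc, manifest = manifest))
}
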