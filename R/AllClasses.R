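#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' OtuExperiment: an OTU count table over sample fractions
#'
#' The central container of the package. An \code{OtuExperiment} extends
#' \linkS4class{SummarizedExperiment}: rows are OTUs, columns are sample
#' fractions (one DNA and/or RNA column per biological sample, plus optional
#' negative-control columns). The single assay \code{"counts"} holds
#' non-negative integer read counts; \code{rowData} carries the taxonomy
#' lineage string of every OTU; \code{colData} carries \code{sample_id},
#' \code{fraction} (\code{"DNA"} or \code{"RNA"}) and \code{is_control}.
#'
#' @slot domain either \code{"prokaryote"} or \code{"eukaryote"}; fixes the
#'   rank vocabulary used when taxonomy lineages are split into ranks (see
#'   \code{\link{rankVocabulary}}).
#'
#' @seealso \code{\link{OtuExperiment}} (constructor),
#'   \code{\link{readOtuTable}}, \code{\link{runFilterChain}}
#' @export
setClass("OtuExperiment",
    contains = "SummarizedExperiment",
    slots = c(domain = "character"),
    prototype = prototype(domain = "prokaryote")
)

#' FilterLedger: per-stage record of removed OTUs and reads
#'
#' Records, for each stage of the conservative filter chain, which OTUs were
#' removed (or zeroed) and how many reads were lost, so that every read of the
#' input table is accounted for: \code{readsIn == readsOut + sum(readsRemoved)}.
#'
#' @slot stages character vector of stage names, in application order.
#' @slot otusRemoved integer, OTUs removed per stage.
#' @slot readsRemoved numeric, reads removed per stage.
#' @slot otuIds list of character vectors, the OTU ids affected per stage.
#' @slot readsIn,readsOut numeric scalars, total reads before/after the chain.
#'
#' @seealso \code{\link{runFilterChain}}, \code{\link{ledgerTable}}
#' @export
setClass("FilterLedger",
    slots = c(
        stages = "character",
        otusRemoved = "integer",
        readsRemoved = "numeric",
        otuIds = "list",
        readsIn = "numeric",
        readsOut = "numeric"
    )
)

setValidity("FilterLedger", function(object) {
    msg <- NULL
    k <- length(object@stages)
    if (length(object@otusRemoved) != k || length(object@readsRemoved) != k ||
        length(object@otuIds) != k)
        msg <- c(msg, "per-stage slots must have one entry per stage")
    ids <- unlist(object@otuIds, use.names = FALSE)
    if (anyDuplicated(ids))
        msg <- c(msg, "removed OTU sets must be disjoint across stages")
    tot <- object@readsOut + sum(object@readsRemoved)
    if (length(object@readsIn) == 1 && length(object@readsOut) == 1 &&
        abs(object@readsIn - tot) > 1e-6)
        msg <- c(msg, "reads are not conserved: readsIn != readsOut + sum(readsRemoved)")
    if (is.null(msg)) TRUE else msg
})

## Rank vocabularies are fixed per domain; lineages may terminate early but
## may not contain internal gaps (once unassigned, all deeper ranks are too).
.RANK_VOCAB <- list(
    prokaryote = c("phylum", "class", "order", "family", "genus"),
    eukaryote  = c("kingdom", "phylum", "class", "order")
)

#' Rank vocabulary for a domain
#'
#' Ordered taxonomic ranks used to interpret semicolon-delimited lineage
#' strings: phylum..genus for prokaryotes (analysis rank genus),
#' kingdom..order for eukaryotes (analysis rank order).
#'
#' @param domain \code{"prokaryote"} or \code{"eukaryote"}.
#' @return character vector of rank names, shallowest first.
#' @export
rankVocabulary <- function(domain = c("prokaryote", "eukaryote")) {
    domain <- match.arg(domain)
    .RANK_VOCAB[[domain]]
}

setValidity("OtuExperiment", function(object) {
    msg <- NULL
    if (length(object@domain) != 1 ||
        !object@domain %in% c("prokaryote", "eukaryote"))
        msg <- c(msg, "domain must be 'prokaryote' or 'eukaryote'")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return(c(msg, "assay 'counts' is required"))
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "fraction", "is_control")
    if (!all(need %in% colnames(cd)))
        return(c(msg, paste("colData must contain:", paste(need, collapse = ", "))))
    if (!all(cd$fraction %in% c("DNA", "RNA")))
        msg <- c(msg, "fraction must be 'DNA' or 'RNA'")
    if (anyDuplicated(paste(cd$sample_id, cd$fraction)))
        msg <- c(msg, "(sample_id, fraction) pairs must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "OTU ids must be unique")
    rd <- SummarizedExperiment::rowData(object)
    if (!"lineage" %in% colnames(rd))
        return(c(msg, "rowData must contain a 'lineage' column"))
    bad <- .lineageGapped(rd$lineage)
    if (any(bad))
        msg <- c(msg, paste0("lineage has an internal gap for OTU(s): ",
                             paste(utils::head(rownames(object)[bad], 3),
                                   collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

## TRUE where a lineage string has an empty rank followed by a named one.
.lineageGapped <- function(lineages) {
    vapply(strsplit(as.character(lineages), ";", fixed = TRUE), function(p) {
        p <- trimws(p)
        empt <- !nzchar(p)
        any(empt) && any(which(!empt) > min(which(empt)))
    }, logical(1))
}
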