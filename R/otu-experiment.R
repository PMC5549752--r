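#' @include AllGenerics.R
NULL

#' Construct an OtuExperiment
#'
#' @param counts non-negative integer matrix, OTUs x sample fractions.
#'   Row names are OTU ids; column names are \code{"<sample>_<DNA|RNA>"}
#'   labels unless \code{colData} is supplied explicitly.
#' @param taxonomy named character vector of semicolon-delimited lineage
#'   strings, one per OTU (missing entries are treated as fully unassigned,
#'   i.e. the empty lineage \code{""}).
#' @param domain \code{"prokaryote"} or \code{"eukaryote"}.
#' @param colData optional \code{DataFrame} with \code{sample_id},
#'   \code{fraction}, \code{is_control}; parsed from column names when absent.
#' @param controlPrefix sample-id prefix that flags negative controls when
#'   \code{colData} is parsed from column names (default \code{"CTRL"}).
#' @return an \linkS4class{OtuExperiment}.
#'
#' @examples
#' m <- matrix(c(5L, 1L, 0L, 3L), 2,
#'     dimnames = list(c("OTU1", "OTU2"), c("cloud1_DNA", "cloud1_RNA")))
#' oe <- OtuExperiment(m, c(OTU1 = "Proteobacteria", OTU2 = ""))
#' otuCounts(oe)
#' @export
OtuExperiment <- function(counts, taxonomy = NULL,
                          domain = c("prokaryote", "eukaryote"),
                          colData = NULL, controlPrefix = "CTRL") {
    domain <- match.arg(domain)
    counts <- as.matrix(counts)
    if (is.null(rownames(counts))) {
        if (nrow(counts) > 0)
            stop("counts must have OTU ids as row names")
        rownames(counts) <- character(0)
    }
    storage.mode(counts) <- "integer"
    if (is.null(colData)) {
        colData <- if (ncol(counts) == 0 && is.null(colnames(counts)))
            S4Vectors::DataFrame(sample_id = character(0),
                                 fraction = character(0),
                                 is_control = logical(0))
        else
            parseFractionLabels(colnames(counts), controlPrefix)
    }
    lin <- rep("", nrow(counts))
    names(lin) <- rownames(counts)
    if (!is.null(taxonomy)) {
        if (is.null(names(taxonomy)))
            stop("taxonomy must be named by OTU id")
        hit <- intersect(names(taxonomy), rownames(counts))
        lin[hit] <- unname(taxonomy[hit])
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(lineage = unname(lin),
                                       row.names = rownames(counts)),
        colData = colData
    )
    methods::new("OtuExperiment", se, domain = domain)
}

#' Parse sample-fraction column labels
#'
#' Column labels follow the convention \code{"<sample>_<DNA|RNA>"}; samples
#' whose id starts with \code{controlPrefix} are flagged as negative controls.
#'
#' @param labels character vector of column labels.
#' @param controlPrefix control sample-id prefix (default \code{"CTRL"}).
#' @return \code{DataFrame} with \code{sample_id}, \code{fraction},
#'   \code{is_control}, row names = \code{labels}.
#' @export
parseFractionLabels <- function(labels, controlPrefix = "CTRL") {
    if (is.null(labels)) stop("column labels are required")
    m <- regmatches(labels, regexec("^(.*)_(DNA|RNA)$", labels))
    bad <- lengths(m) != 3
    if (any(bad))
        stop("column label(s) not of the form <sample>_<DNA|RNA>: ",
             paste(labels[bad], collapse = ", "))
    sid <- vapply(m, `[`, character(1), 2)
    frac <- vapply(m, `[`, character(1), 3)
    S4Vectors::DataFrame(
        sample_id = sid,
        fraction = frac,
        is_control = startsWith(sid, controlPrefix),
        row.names = labels
    )
}

#' @rdname otuCounts
#' @return \code{otuCounts}: the integer count matrix (OTUs x fractions).
#' @export
setMethod("otuCounts", "OtuExperiment", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' Taxonomy lineages
#'
#' @rdname taxonomy
#' @param x an \linkS4class{OtuExperiment}.
#' @return named character vector of lineage strings.
#' @export
setMethod("taxonomy", "OtuExperiment", function(x) {
    out <- SummarizedExperiment::rowData(x)$lineage
    names(out) <- rownames(x)
    out
})

#' @rdname otuDomain
#' @return \code{"prokaryote"} or \code{"eukaryote"}.
#' @export
setMethod("otuDomain", "OtuExperiment", function(x) x@domain)

#' Sample-fraction annotation
#'
#' @rdname sampleFractions
#' @param x an \linkS4class{OtuExperiment}.
#' @return data.frame with \code{sample_id}, \code{fraction},
#'   \code{is_control}, one row per table column.
#' @export
setMethod("sampleFractions", "OtuExperiment", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @export
setMethod("show", "OtuExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("OtuExperiment (", object@domain, ")\n", sep = "")
    cat("  ", nrow(object), " OTUs x ", ncol(object), " sample fractions (",
        sum(cd$fraction == "DNA" & !cd$is_control), " DNA, ",
        sum(cd$fraction == "RNA" & !cd$is_control), " RNA, ",
        sum(cd$is_control), " control)\n", sep = "")
    cat("  total reads: ", sum(otuCounts(object)), "\n", sep = "")
})

#' Per-stage summary of a FilterLedger
#'
#' @rdname ledgerTable
#' @param x a \linkS4class{FilterLedger}.
#' @return data.frame with columns \code{stage}, \code{otus_removed},
#'   \code{reads_removed}.
#' @export
setMethod("ledgerTable", "FilterLedger", function(x)
    data.frame(stage = x@stages,
               otus_removed = x@otusRemoved,
               reads_removed = x@readsRemoved,
               row.names = NULL))

#' @export
setMethod("show", "FilterLedger", function(object) {
    cat("FilterLedger: ", object@readsIn, " reads in, ",
        object@readsOut, " reads out\n", sep = "")
    print(ledgerTable(object))
})

## Split a lineage string into named ranks under a domain's vocabulary.
.splitLineage <- function(lineage, domain) {
    vocab <- rankVocabulary(domain)
    parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
    parts <- parts[seq_len(min(length(parts), length(vocab)))]
    out <- rep(NA_character_, length(vocab))
    names(out) <- vocab
    nz <- nzchar(parts)
    out[seq_along(parts)][nz] <- parts[nz]
    out
}

#' Taxon name of each OTU at a given rank
#'
#' @param x an \linkS4class{OtuExperiment}.
#' @param rank a rank name from \code{rankVocabulary(otuDomain(x))}.
#' @param unclassified label used for OTUs unassigned at \code{rank}.
#' @return character vector, one taxon per OTU.
#' @export
taxonAtRank <- function(x, rank, unclassified = "unclassified") {
    vocab <- rankVocabulary(otuDomain(x))
    if (!rank %in% vocab)
        stop("unknown rank '", rank, "' for domain ", otuDomain(x))
    idx <- match(rank, vocab)
    lin <- taxonomy(x)
    out <- vapply(lin, function(l) .splitLineage(l, otuDomain(x))[idx],
                  character(1), USE.NAMES = FALSE)
    out[is.na(out)] <- unclassified
    names(out) <- rownames(x)
    out
}
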