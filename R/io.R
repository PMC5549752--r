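#' @include otu-experiment.R
NULL

#' Read a FASTQ file of amplicon reads
#'
#' Reads Sanger-encoded (PHRED+33) FASTQ into a
#' \link[Biostrings]{QualityScaledDNAStringSet}. The file is first checked
#' record by record so that a malformed record is reported by its index;
#' parsing itself is done by Biostrings.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return \code{QualityScaledDNAStringSet}; per-base PHRED scores are
#'   recovered with \code{\link{readQualities}}.
#' @export
readFastq <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    if (length(lines) && !nzchar(lines[length(lines)]))
        lines <- lines[-length(lines)]
    if (length(lines) %% 4 != 0)
        stop("malformed FASTQ: ", length(lines),
             " lines is not a multiple of 4 (truncated record ",
             length(lines) %/% 4 + 1, ")")
    n <- length(lines) %/% 4
    if (n == 0)
        return(Biostrings::QualityScaledDNAStringSet(
            Biostrings::DNAStringSet(),
            Biostrings::PhredQuality(character(0))))
    idx <- seq_len(n)
    hdr <- lines[(idx - 1) * 4 + 1]
    seq <- lines[(idx - 1) * 4 + 2]
    sep <- lines[(idx - 1) * 4 + 3]
    qua <- lines[(idx - 1) * 4 + 4]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad))
        stop("malformed FASTQ record ", bad[1], ": header does not start with '@'")
    bad <- which(!startsWith(sep, "+"))
    if (length(bad))
        stop("malformed FASTQ record ", bad[1], ": separator line is not '+'")
    bad <- which(nchar(seq) != nchar(qua))
    if (length(bad))
        stop("malformed FASTQ record ", bad[1], ": sequence and quality lengths differ (",
             nchar(seq[bad[1]]), " vs ", nchar(qua[bad[1]]), ")")
    reads <- Biostrings::DNAStringSet(seq)
    names(reads) <- sub("^@", "", sub("\\s.*$", "", hdr))
    Biostrings::QualityScaledDNAStringSet(reads, Biostrings::PhredQuality(qua))
}

#' Per-base PHRED scores of a quality-scaled read set
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @return \code{IntegerList} of PHRED scores, one vector per read.
#' @export
readQualities <- function(reads) {
    methods::as(Biostrings::quality(reads), "IntegerList")
}

#' Write reads to FASTQ (PHRED+33)
#'
#' @param reads \code{QualityScaledDNAStringSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFastq <- function(reads, path) {
    Biostrings::writeQualityScaledXStringSet(reads, path)
    invisible(path)
}

#' Read an OTU count table (and taxonomy) from TSV
#'
#' The table is tab-separated with OTU ids in the first column and
#' \code{"<sample>_<DNA|RNA>"} column labels; the optional taxonomy file maps
#' \code{otu_id <TAB> lineage} with semicolon-delimited ranks.
#'
#' @param path OTU table TSV.
#' @param taxonomyPath optional taxonomy TSV.
#' @param domain \code{"prokaryote"} or \code{"eukaryote"}.
#' @param controlPrefix control sample-id prefix (default \code{"CTRL"}).
#' @return an \linkS4class{OtuExperiment}.
#' @export
readOtuTable <- function(path, taxonomyPath = NULL,
                         domain = c("prokaryote", "eukaryote"),
                         controlPrefix = "CTRL") {
    domain <- match.arg(domain)
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 1) stop("empty OTU table: ", path)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate OTU id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(m) == 0) storage.mode(m) <- "integer"
    if (!is.numeric(m)) stop("non-numeric counts in ", path)
    if (any(m < 0)) stop("negative counts in ", path)
    if (any(m != round(m))) stop("non-integer counts in ", path)
    rownames(m) <- ids
    tax <- NULL
    if (!is.null(taxonomyPath)) {
        tdf <- utils::read.delim(taxonomyPath, header = FALSE,
                                 stringsAsFactors = FALSE,
                                 col.names = c("otu_id", "lineage"),
                                 colClasses = "character")
        tax <- tdf$lineage
        names(tax) <- tdf$otu_id
    }
    OtuExperiment(m, taxonomy = tax, domain = domain,
                  controlPrefix = controlPrefix)
}

#' Write an OtuExperiment to TSV
#'
#' Writes the count matrix as a tab-separated table (first column
#' \code{otu_id}) and, optionally, the taxonomy as a two-column TSV.
#' \code{readOtuTable(writeOtuTable(x))} is an identity on valid tables;
#' fully unassigned lineages are written as empty strings.
#'
#' @param x an \linkS4class{OtuExperiment}.
#' @param path output TSV path.
#' @param taxonomyPath optional taxonomy output path.
#' @return invisibly, \code{path}.
#' @export
writeOtuTable <- function(x, path, taxonomyPath = NULL) {
    m <- otuCounts(x)
    df <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(taxonomyPath)) {
        tl <- taxonomy(x)
        utils::write.table(
            data.frame(otu_id = names(tl), lineage = unname(tl)),
            taxonomyPath, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Read per-sample metadata
#'
#' Accepts YAML (a map keyed by sample id) or TSV (one row per sample with a
#' \code{sample_id} column). Expected fields: \code{water_volume_mL},
#' \code{air_volume_m3}, \code{prok_conc_per_mL}, \code{euk_conc_per_mL} and
#' optionally \code{lwc_g_m3}.
#'
#' @param path metadata file (\code{.yaml}/\code{.yml} or TSV).
#' @return data.frame, one row per sample.
#' @export
readSampleMetadata <- function(path) {
    if (grepl("\\.ya?ml$", path)) {
        y <- yaml::read_yaml(path)
        df <- do.call(rbind, lapply(names(y), function(sid)
            data.frame(sample_id = sid, as.data.frame(y[[sid]]))))
    } else {
        df <- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    if (!"sample_id" %in% colnames(df))
        stop("metadata must contain a sample_id field")
    bad <- df$air_volume_m3 <= 0
    if (!is.null(df$air_volume_m3) && any(bad, na.rm = TRUE))
        stop("air_volume_m3 must be positive for sample(s): ",
             paste(df$sample_id[bad], collapse = ", "))
    df
}
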