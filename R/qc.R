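#' @include io.R
NULL

#' Read-cleaning configuration
#'
#' Thresholds for the amplicon read-cleaning rules, applied in fixed order:
#' forward primer, reverse primer (both trimmed on match), post-trim length,
#' ambiguous bases, mean PHRED quality. The quality rule is a threshold on
#' the mean PHRED score of the trimmed read.
#'
#' @param minLength minimum post-trim read length in bp (default 200).
#' @param forwardPrimer,reversePrimer IUPAC primer strings, or \code{NULL} to
#'   disable primer checking. The reverse primer is searched as its reverse
#'   complement at the 3' end of the (merged) read.
#' @param maxAmbiguous maximum number of \code{N} bases tolerated (default 0).
#' @param minMeanQuality minimum mean PHRED score (default 25).
#' @param maxPrimerMismatches mismatches tolerated in each primer window
#'   (default 0; degenerate IUPAC positions are not mismatches).
#' @return a \code{QcConfig} object (validated list).
#' @export
qcConfig <- function(minLength = 200L, forwardPrimer = NULL,
                     reversePrimer = NULL, maxAmbiguous = 0L,
                     minMeanQuality = 25, maxPrimerMismatches = 0L) {
    if (minLength <= 0) stop("minLength must be positive")
    if (!is.null(forwardPrimer) && !nzchar(forwardPrimer))
        stop("forwardPrimer must be non-empty when supplied")
    if (!is.null(reversePrimer) && !nzchar(reversePrimer))
        stop("reversePrimer must be non-empty when supplied")
    structure(list(minLength = as.integer(minLength),
                   forwardPrimer = forwardPrimer,
                   reversePrimer = reversePrimer,
                   maxAmbiguous = as.integer(maxAmbiguous),
                   minMeanQuality = minMeanQuality,
                   maxPrimerMismatches = as.integer(maxPrimerMismatches)),
              class = "QcConfig")
}

#' Match (and trim) a primer at one end of reads
#'
#' Tests whether the primer matches the terminal window of each read within
#' \code{maxMismatches} Hamming mismatches, IUPAC-aware: a degenerate primer
#' position matches any base of its expansion. Reads shorter than the primer
#' never match. On match the primer window is removed, qualities sliced
#' consistently.
#'
#' @param reads \code{QualityScaledDNAStringSet}.
#' @param primer IUPAC nucleotide string (already reverse-complemented by the
#'   caller if it is a reverse primer searched at the 3' end).
#' @param end \code{"five_prime"} or \code{"three_prime"}.
#' @param maxMismatches tolerated mismatches (default 0).
#' @return list with \code{matched} (logical vector) and \code{trimmed}
#'   (reads with the window removed where matched; unmatched reads are
#'   returned untouched).
#' @export
primerMatch <- function(reads, primer, end = c("five_prime", "three_prime"),
                        maxMismatches = 0L) {
    end <- match.arg(end)
    pl <- nchar(primer)
    w <- Biostrings::width(reads)
    eligible <- w > pl   # primer must be shorter than the read
    matched <- logical(length(reads))
    if (any(eligible)) {
        sub <- reads[eligible]
        win <- if (end == "five_prime")
            Biostrings::subseq(sub, start = 1L, width = pl)
        else
            Biostrings::subseq(sub, start = Biostrings::width(sub) - pl + 1L)
        hits <- Biostrings::vcountPattern(primer,
                                          Biostrings::DNAStringSet(win),
                                          max.mismatch = maxMismatches,
                                          fixed = FALSE) > 0
        matched[eligible] <- hits
    }
    trimmed <- reads
    if (any(matched)) {
        keep <- reads[matched]
        trimmed[matched] <- if (end == "five_prime")
            Biostrings::subseq(keep, start = pl + 1L)
        else
            Biostrings::subseq(keep, end = Biostrings::width(keep) - pl)
    }
    list(matched = matched, trimmed = trimmed)
}

#' Clean amplicon reads
#'
#' Applies the cleaning rules in fixed order — forward primer, reverse primer
#' (reverse complement at the 3' end), post-trim minimum length, ambiguous
#' bases, mean PHRED quality — and attributes each rejected read to the first
#' rule it fails, so counts are conserved:
#' \code{input == passed + sum(rejected)}.
#'
#' @param reads \code{QualityScaledDNAStringSet} (see \code{\link{readFastq}}).
#' @param config a \code{\link{qcConfig}}.
#' @return list with \code{passed} (trimmed reads that pass all rules) and
#'   \code{report}, a \code{QcReport} list: \code{input_reads}, \code{passed},
#'   \code{rejected_by_rule} (named vector over
#'   \code{primer_forward, primer_reverse, length, ambiguous, quality}).
#' @export
qcFilter <- function(reads, config = qcConfig()) {
    stopifnot(inherits(config, "QcConfig"))
    n <- length(reads)
    rules <- c("primer_forward", "primer_reverse", "length",
               "ambiguous", "quality")
    fail <- rep(NA_character_, n)
    cur <- reads
    if (!is.null(config$forwardPrimer)) {
        pm <- primerMatch(cur, config$forwardPrimer, "five_prime",
                          config$maxPrimerMismatches)
        fail[!pm$matched & is.na(fail)] <- "primer_forward"
        cur <- pm$trimmed
    }
    if (!is.null(config$reversePrimer)) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(config$reversePrimer)))
        pm <- primerMatch(cur, rc, "three_prime", config$maxPrimerMismatches)
        fail[!pm$matched & is.na(fail)] <- "primer_reverse"
        cur <- pm$trimmed
    }
    short <- Biostrings::width(cur) < config$minLength
    fail[short & is.na(fail)] <- "length"
    nN <- Biostrings::vcountPattern("N", Biostrings::DNAStringSet(cur),
                                    fixed = TRUE)
    fail[nN > config$maxAmbiguous & is.na(fail)] <- "ambiguous"
    meanQ <- vapply(readQualities(cur), function(q)
        if (length(q)) mean(q) else 0, numeric(1))
    fail[meanQ < config$minMeanQuality & is.na(fail)] <- "quality"
    pass <- is.na(fail)
    rejected <- vapply(rules, function(r) sum(fail == r, na.rm = TRUE),
                       integer(1))
    list(
        passed = cur[pass],
        report = structure(list(input_reads = n,
                                passed = sum(pass),
                                rejected_by_rule = rejected),
                           class = "QcReport")
    )
}

#' Write a QC report as TSV (rule <TAB> count)
#'
#' @param report the \code{report} element of \code{\link{qcFilter}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeQcReport <- function(report, path) {
    df <- data.frame(
        rule = c("input", "passed", names(report$rejected_by_rule)),
        count = c(report$input_reads, report$passed,
                  unname(report$rejected_by_rule)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
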