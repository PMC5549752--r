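#' @include clustering.R
NULL

.ledgerEntry <- function(stage, ids, reads) {
    list(stage = stage, otuIds = ids,
         otusRemoved = length(ids), readsRemoved = reads)
}

#' Minimum-read (artefact) filter
#'
#' Removes OTUs represented by fewer than \code{minReads} reads in total
#' across all sample fractions of the table — the conservative reading of a
#' per-dataset artefact threshold (default 3, i.e. OTUs with < 3 reads go).
#'
#' @param x an \linkS4class{OtuExperiment}.
#' @param minReads minimum total read count for an OTU to be kept (>= 1).
#' @return list with \code{table} (filtered \code{OtuExperiment}) and
#'   \code{entry} (ledger entry).
#' @export
minCountFilter <- function(x, minReads = 3L) {
    if (minReads < 1) stop("minReads must be >= 1")
    tot <- rowSums(otuCounts(x))
    drop <- tot < minReads
    list(table = x[!drop, ],
         entry = .ledgerEntry("min_count", rownames(x)[drop],
                              sum(tot[drop])))
}

#' Negative-control decontamination
#'
#' Any OTU detected (count > 0) in any control column is treated as a
#' contaminant and removed from all fractions; control columns are dropped
#' from the output. The rule is presence-based: a single control read
#' condemns the OTU regardless of its abundance in the samples.
#'
#' @param x an \linkS4class{OtuExperiment} whose \code{colData} flags at
#'   least one control column (\code{is_control}), unless
#'   \code{allowNoControls} is set.
#' @param allowNoControls set \code{TRUE} to explicitly run without controls
#'   (the filter is then the identity); the default errors, so that a
#'   missing control is never silent.
#' @return list with \code{table} and ledger \code{entry}; reads removed
#'   counts both the sample and control reads of condemned OTUs plus the
#'   control reads of the dropped columns.
#' @export
decontaminate <- function(x, allowNoControls = FALSE) {
    ctrl <- sampleFractions(x)$is_control
    if (!any(ctrl)) {
        if (!allowNoControls)
            stop("no control columns in table; pass allowNoControls = TRUE ",
                 "to run without decontamination")
        return(list(table = x,
                    entry = .ledgerEntry("decontaminate", character(0), 0)))
    }
    cnt <- otuCounts(x)
    inCtrl <- rowSums(cnt[, ctrl, drop = FALSE]) > 0
    removed <- sum(cnt[inCtrl, ]) +
        sum(cnt[!inCtrl, ctrl, drop = FALSE])
    list(table = x[!inCtrl, !ctrl],
         entry = .ledgerEntry("decontaminate", rownames(x)[inCtrl], removed))
}

#' Phantom-OTU filter
#'
#' A phantom is an OTU detected in a sample's RNA fraction but absent from
#' the same sample's DNA fraction. With \code{scope = "sample"} (default)
#' the phantom RNA counts are zeroed per sample — an OTU legitimately
#' DNA-backed in another sample keeps its counts there — and OTUs left with
#' zero total count are removed. With \code{scope = "global"} any OTU that is
#' a phantom in at least one sample is removed everywhere. After the filter,
#' every RNA-positive (OTU, sample) pair has DNA count > 0, so all RNA:DNA
#' ratios downstream are finite.
#'
#' @param x an \linkS4class{OtuExperiment}; every sample with an RNA column
#'   must also have a DNA column.
#' @param scope \code{"sample"} or \code{"global"}.
#' @return list with \code{table} and ledger \code{entry} (\code{otuIds}
#'   lists OTUs zeroed or removed).
#' @export
phantomFilter <- function(x, scope = c("sample", "global")) {
    scope <- match.arg(scope)
    sf <- sampleFractions(x)
    rna <- which(sf$fraction == "RNA" & !sf$is_control)
    cnt <- otuCounts(x)
    touched <- character(0)
    removedReads <- 0
    globalDrop <- logical(nrow(x))
    for (j in rna) {
        sid <- sf$sample_id[j]
        d <- which(sf$sample_id == sid & sf$fraction == "DNA")
        if (!length(d))
            stop("sample '", sid, "' has an RNA fraction but no DNA fraction")
        phantom <- cnt[, j] > 0 & cnt[, d] == 0
        if (any(phantom)) {
            touched <- union(touched, rownames(x)[phantom])
            if (scope == "sample") {
                removedReads <- removedReads + sum(cnt[phantom, j])
                cnt[phantom, j] <- 0L
            } else {
                globalDrop <- globalDrop | phantom
            }
        }
    }
    if (scope == "global") {
        removedReads <- sum(cnt[globalDrop, ])
        cnt <- cnt[!globalDrop, , drop = FALSE]
        out <- x[!globalDrop, ]
    } else {
        out <- x
    }
    SummarizedExperiment::assay(out, "counts") <- cnt
    empty <- rowSums(otuCounts(out)) == 0
    dropped <- if (scope == "global") rownames(x)[globalDrop] else
        character(0)
    dropped <- union(dropped, rownames(out)[empty])
    out <- out[!empty, ]
    # the ledger lists OTUs removed outright; reads covers all zeroed RNA
    # (an OTU zeroed in one sample but DNA-backed elsewhere is kept)
    list(table = out,
         entry = .ledgerEntry("phantom", dropped, removedReads))
}

#' Column-wise proportions
#'
#' @param x an \linkS4class{OtuExperiment} or a count matrix.
#' @return numeric matrix with every column summing to 1.
#' @export
normalizeProportions <- function(x) {
    m <- if (methods::is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("zero-total column(s): ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    sweep(m, 2, tot, "/")
}

#' Run the conservative filter chain
#'
#' Applies, in order: minimum-read artefact filter, negative-control
#' decontamination, phantom-OTU filter. The order matters and is fixed (a
#' contaminant with only 2 reads is attributed to the artefact stage). The
#' stages are swept repeatedly until nothing changes — phantom zeroing can
#' drop an OTU's total below the artefact threshold — so the chain is
#' idempotent: re-running it on its own output removes nothing.
#'
#' @param x an \linkS4class{OtuExperiment} (with control columns unless
#'   \code{allowNoControls}).
#' @param minReads minimum total reads per OTU (default 3).
#' @param phantomScope \code{"sample"} or \code{"global"}
#'   (see \code{\link{phantomFilter}}).
#' @param allowNoControls passed to \code{\link{decontaminate}}.
#' @return list with \code{table} (filtered \code{OtuExperiment}) and
#'   \code{ledger} (\linkS4class{FilterLedger}).
#' @export
runFilterChain <- function(x, minReads = 3L,
                           phantomScope = c("sample", "global"),
                           allowNoControls = FALSE) {
    phantomScope <- match.arg(phantomScope)
    readsIn <- sum(otuCounts(x))
    stageNames <- c("min_count", "decontaminate", "phantom")
    acc <- lapply(stageNames, function(s) .ledgerEntry(s, character(0), 0))
    names(acc) <- stageNames
    # Iterate to a fixed point: zeroing phantom RNA can drop an OTU's total
    # back under the artefact threshold, so one sweep is not idempotent.
    cur <- x
    noCtrl <- allowNoControls
    repeat {
        before <- sum(otuCounts(cur))
        s1 <- minCountFilter(cur, minReads)
        s2 <- decontaminate(s1$table, allowNoControls = noCtrl)
        s3 <- phantomFilter(s2$table, scope = phantomScope)
        for (e in list(s1$entry, s2$entry, s3$entry)) {
            a <- acc[[e$stage]]
            a$otuIds <- c(a$otuIds, e$otuIds)
            a$otusRemoved <- a$otusRemoved + e$otusRemoved
            a$readsRemoved <- a$readsRemoved + e$readsRemoved
            acc[[e$stage]] <- a
        }
        cur <- s3$table
        noCtrl <- TRUE   # controls are dropped in the first sweep
        if (sum(otuCounts(cur)) == before) break
    }
    ledger <- methods::new("FilterLedger",
        stages = stageNames,
        otusRemoved = unname(vapply(acc, `[[`, integer(1), "otusRemoved")),
        readsRemoved = unname(vapply(acc, function(e)
            as.numeric(e$readsRemoved), numeric(1))),
        otuIds = unname(lapply(acc, `[[`, "otuIds")),
        readsIn = readsIn,
        readsOut = sum(otuCounts(cur)))
    list(table = cur, ledger = ledger)
}

#' Write a FilterLedger as TSV
#'
#' @param ledger a \linkS4class{FilterLedger}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeLedger <- function(ledger, path) {
    df <- ledgerTable(ledger)
    df$otu_ids <- vapply(ledger@otuIds, paste, character(1), collapse = ",")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
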