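#' @include qc.R
#' @useDynLib cloudAmplicon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Pairwise sequence identity with free terminal gaps
#'
#' Identity between two nucleotide sequences under an optimal global
#' alignment in which terminal gaps are free (semi-global / overlap mode;
#' scoring match +1, mismatch -1, gap -1): matched columns divided by the
#' internal alignment columns. Symmetric; terminal overhangs are excluded, so
#' a sequence has identity 1 to any sequence containing it exactly.
#'
#' @param a,b non-empty nucleotide strings (or \code{DNAString}s).
#' @return identity in \[0, 1\].
#' @examples
#' pairwiseIdentity("ACGT", "ACGA")   # 0.75
#' pairwiseIdentity("ACGT", "TACGT")  # 1: terminal gap is free
#' @export
pairwiseIdentity <- function(a, b) {
    a <- as.character(a); b <- as.character(b)
    if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
    unname(.nwIdentity(a, b)[["identity"]])
}

#' Greedy centroid clustering of sequences into OTUs
#'
#' Reference implementation of length-sorted greedy clustering: sequences are
#' processed in decreasing length order (ties broken by decreasing abundance,
#' then lexicographic id); each sequence joins the first existing centroid to
#' which its identity (\code{\link{pairwiseIdentity}}) reaches the threshold,
#' otherwise it founds a new cluster. 0.97 is the conventional prokaryote
#' threshold, 0.95 the eukaryote one. First-match assignment and the fixed
#' tie-breaks make the partition deterministic.
#'
#' @param seqs named character vector (or \code{DNAStringSet}) of sequences;
#'   names are sequence ids.
#' @param threshold identity threshold in (0, 1].
#' @param abundance optional numeric vector of per-sequence abundances used
#'   in tie-breaking (default 1 for all).
#' @return data.frame with one row per input sequence: \code{id},
#'   \code{centroid} (id of the cluster centroid), \code{identity} (identity
#'   to the centroid; 1 for centroids themselves). Clusters appear in
#'   founding order; attribute \code{"centroids"} holds centroid ids.
#' @export
greedyCluster <- function(seqs, threshold, abundance = NULL) {
    if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
    ids <- names(seqs)
    if (length(seqs) == 0) {
        out <- data.frame(id = character(0), centroid = character(0),
                          identity = numeric(0))
        attr(out, "centroids") <- character(0)
        attr(out, "threshold") <- threshold
        return(out)
    }
    if (is.null(ids) || anyDuplicated(ids))
        stop("sequences must have unique names")
    if (is.null(abundance)) abundance <- rep(1, length(seqs))
    ord <- order(-nchar(seqs), -abundance, ids)
    centroids <- character(0)
    centroidSeq <- character(0)
    assign <- character(length(seqs))
    ident <- numeric(length(seqs))
    names(assign) <- names(ident) <- ids
    for (k in ord) {
        id <- ids[k]; s <- seqs[k]
        hit <- NA_integer_
        if (length(centroids)) {
            idv <- .nwIdentityBatch(s, centroidSeq)
            w <- which(idv >= threshold)
            if (length(w)) hit <- w[1]   # first match, not best match
        }
        if (is.na(hit)) {
            centroids <- c(centroids, id)
            centroidSeq <- c(centroidSeq, s)
            assign[id] <- id
            ident[id] <- 1
        } else {
            assign[id] <- centroids[hit]
            ident[id] <- idv[hit]
        }
    }
    out <- data.frame(id = ids, centroid = unname(assign[ids]),
                      identity = unname(ident[ids]),
                      stringsAsFactors = FALSE)
    attr(out, "centroids") <- centroids
    attr(out, "threshold") <- threshold
    out
}

#' Materialize OTU counts from a clustering
#'
#' @param clusters a \code{\link{greedyCluster}} result.
#' @param readMap named character vector mapping read/sequence id to a
#'   sample-fraction label (\code{"<sample>_<DNA|RNA>"}).
#' @param taxonomy optional named lineage vector, keyed by centroid id.
#' @param domain \code{"prokaryote"} or \code{"eukaryote"}.
#' @param controlPrefix control sample-id prefix.
#' @return an \linkS4class{OtuExperiment} with one row per cluster (row names
#'   = centroid ids, in founding order); total counts equal the number of
#'   clustered reads.
#' @export
clusterCounts <- function(clusters, readMap, taxonomy = NULL,
                          domain = c("prokaryote", "eukaryote"),
                          controlPrefix = "CTRL") {
    domain <- match.arg(domain)
    unmapped <- setdiff(clusters$id, names(readMap))
    if (length(unmapped))
        stop("read id(s) with no sample-fraction mapping: ",
             paste(utils::head(unmapped, 3), collapse = ", "))
    cents <- attr(clusters, "centroids")
    sf <- sort(unique(unname(readMap[clusters$id])))
    m <- matrix(0L, nrow = length(cents), ncol = length(sf),
                dimnames = list(cents, sf))
    if (nrow(clusters)) {
        tab <- table(factor(clusters$centroid, levels = cents),
                     factor(unname(readMap[clusters$id]), levels = sf))
        m[] <- as.integer(tab)
    }
    OtuExperiment(m, taxonomy = taxonomy, domain = domain,
                  controlPrefix = controlPrefix)
}

#' Write cluster centroid sequences as FASTA
#'
#' @param clusters a \code{\link{greedyCluster}} result.
#' @param seqs the sequences that were clustered (named as in the input).
#' @param path output FASTA path.
#' @return invisibly, \code{path}.
#' @export
writeCentroids <- function(clusters, seqs, path) {
    cents <- attr(clusters, "centroids")
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
    x <- Biostrings::DNAStringSet(seqs[cents])
    names(x) <- cents
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}
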