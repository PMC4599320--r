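# k-mer extraction, containment score and the inverted index.

#' Extract the set of overlapping k-mers of a sequence
#'
#' Enumerates every window of length `k`, skips windows containing any
#' character outside A/C/G/T (ambiguity codes and N are never expanded) and
#' collapses duplicates, keeping first-occurrence order.
#'
#' @param sequence A single nucleotide string (character or
#'   [Biostrings::DNAString]).
#' @param k k-mer length (positive integer).
#' @return Character vector of distinct k-mers; empty when the sequence is
#'   shorter than `k`.
#' @examples
#' extractKmers("ATTTGCG", 4)  # ATTT TTTG TTGC TGCG
#' @export
extractKmers <- function(sequence, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) ktx_usage_error("k must be a positive integer")
  x <- toupper(as.character(sequence))
  if (length(x) != 1L) ktx_usage_error("extractKmers takes one sequence")
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  w <- substring(x, starts, starts + k - 1L)
  w <- w[!grepl("[^ACGT]", w)]
  unique(w)
}

#' k-mer containment similarity score
#'
#' The score of a query against a reference is the number of distinct
#' k-mers they share, normalised by the number of distinct k-mers in the
#' query: \eqn{S = |Q_K \cap R_K| / |Q_K|}, a number in [0, 1]. The score
#' is asymmetric (containment, not Jaccard).
#'
#' @param queryKmers Character vector of distinct query k-mers (as from
#'   [extractKmers()]).
#' @param refKmers Character vector of distinct reference k-mers.
#' @return The containment score in [0, 1].
#' @examples
#' similarityScore(extractKmers("GTTTGCG", 4), extractKmers("ATTTGCG", 4))
#' @export
similarityScore <- function(queryKmers, refKmers) {
  if (length(queryKmers) == 0L)
    ktx_parse_error("query has no valid k-mers; score undefined")
  sum(queryKmers %in% refKmers) / length(queryKmers)
}

# Inverted index: named list mapping k-mer -> sorted integer vector of the
# indices of the references containing it. split() over a character key
# yields lexicographically ordered keys and, because reference k-mer sets
# are duplicate-free and scanned in index order, sorted unique postings.
buildKmerIndex <- function(sequences, k) {
  sets <- lapply(as.character(sequences), extractKmers, k = k)
  split(rep(seq_along(sets), lengths(sets)),
        unlist(sets, use.names = FALSE))
}

# Accumulate shared-k-mer counts for one query k-mer set against every
# reference via the index. Returns an integer vector over references.
index_counts <- function(queryKmers, index, nref) {
  if (length(queryKmers) == 0L) return(integer(nref))
  v <- unlist(index[queryKmers], use.names = FALSE)
  if (is.null(v)) return(integer(nref))
  tabulate(v, nbins = nref)
}
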