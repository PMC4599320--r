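# Variable-region extraction with degenerate primer pairs: in-silico PCR
# restricted to substitution mismatches (no indels inside primers).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.check_iupac <- function(primer) {
  ch <- strsplit(toupper(primer), "")[[1]]
  bad <- !(ch %in% names(IUPAC_SETS))
  if (any(bad))
    ktx_parse_error("invalid IUPAC character '%s' at primer position %d",
                    ch[which(bad)[1]], which(bad)[1])
  ch
}

#' Find all matches of a degenerate primer in a sequence
#'
#' A window matches at a position when the sequence base is a member of
#' the primer's IUPAC class there; up to `maxMismatches` violations are
#' allowed. `N` (or any ambiguity code) in the *sequence* matches nothing
#' and counts as a mismatch.
#'
#' @param sequence A single nucleotide string.
#' @param primer IUPAC primer string, written 5' to 3'.
#' @param maxMismatches Maximum number of mismatching positions.
#' @return `data.frame` with 1-based inclusive `start`, `end` and
#'   `mismatches`, one row per matching window, ordered by `start`.
#' @export
matchPrimer <- function(sequence, primer, maxMismatches = 0) {
  s <- toupper(as.character(sequence))
  pch <- .check_iupac(primer)
  p <- length(pch)
  n <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0))
  if (n < p) return(empty)
  sch <- strsplit(s, "")[[1]]
  nwin <- n - p + 1L
  mism <- integer(nwin)
  for (j in seq_len(p)) {
    allowed <- IUPAC_SETS[[pch[j]]]
    mism <- mism + !(sch[j:(j + nwin - 1L)] %in% allowed)
  }
  hit <- which(mism <= maxMismatches)
  data.frame(start = hit, end = hit + p - 1L, mismatches = mism[hit])
}

#' Extract the region between a primer pair
#'
#' Finds the best forward-primer match (fewest mismatches, then leftmost),
#' then the leftmost acceptable match of the reverse complement of the
#' reverse primer strictly downstream of it (the shortest region —
#' deterministic and conservative), and returns the subsequence between
#' the two primer footprints. If the forward orientation of the record
#' yields nothing and `searchBothOrientations` is set, the reverse
#' complement of the record is searched, and the region is reported in the
#' primer pair's forward orientation.
#'
#' @param record A single named nucleotide string (length-1 named
#'   character or [Biostrings::DNAStringSet] of length 1).
#' @param forward,reverse Primer IUPAC strings, each written 5' to 3' on
#'   its own strand.
#' @param maxMismatches Per-primer mismatch tolerance (default 2).
#' @param keepPrimers Include the primer footprints in the output.
#' @param searchBothOrientations Also try the reverse complement of the
#'   record (default TRUE).
#' @param regionName Optional region label appended to the record id.
#' @return A length-1 named [Biostrings::DNAStringSet], or `NULL` when
#'   either primer is absent or the region would be empty.
#' @export
extractRegion <- function(record, forward, reverse, maxMismatches = 2,
                          keepPrimers = FALSE, searchBothOrientations = TRUE,
                          regionName = NULL) {
  id <- names(record)
  s <- toupper(as.character(record))
  if (length(s) != 1L) ktx_usage_error("extractRegion takes one record")
  if (is.null(id)) id <- "region"

  try_orientation <- function(seq) {
    fm <- matchPrimer(seq, forward, maxMismatches)
    if (nrow(fm) == 0L) return(NULL)
    fm <- fm[order(fm$mismatches, fm$start), , drop = FALSE]
    fwd <- fm[1L, ]
    rm_ <- matchPrimer(seq, revComp(reverse), maxMismatches)
    rm_ <- rm_[rm_$start > fwd$end, , drop = FALSE]
    if (nrow(rm_) == 0L) return(NULL)
    rev <- rm_[which.min(rm_$start), ]
    if (keepPrimers) {
      from <- fwd$start; to <- rev$end
    } else {
      from <- fwd$end + 1L; to <- rev$start - 1L
    }
    if (from > to) return(NULL)
    substr(seq, from, to)
  }

  region <- try_orientation(s)
  if (is.null(region) && searchBothOrientations)
    region <- try_orientation(revComp(s))
  if (is.null(region)) return(NULL)
  out <- Biostrings::DNAStringSet(region)
  names(out) <- if (is.null(regionName)) id else paste0(id, "_", regionName)
  out
}

#' Read a primer-pair configuration table
#'
#' TSV with columns `name`, `forward`, `reverse` (IUPAC, each 5' to 3').
#' Primers must be at least 10 bases; names must be unique.
#'
#' @param path Path to the TSV file (a header row is allowed).
#' @return `data.frame` with columns `name`, `forward`, `reverse`.
#' @export
readPrimerConfig <- function(path) {
  if (!file.exists(path)) ktx_parse_error("primer config not found: %s", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) ktx_parse_error("unreadable primer config %s: %s",
                                        path, conditionMessage(e)))
  if (ncol(df) < 3L)
    ktx_parse_error("primer config needs 3 columns: name, forward, reverse")
  df <- df[, 1:3]
  names(df) <- c("name", "forward", "reverse")
  if (identical(tolower(df$name[1]), "name")) df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df$name))
    ktx_parse_error("duplicate primer-pair name(s): %s",
                    paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  for (i in seq_len(nrow(df))) {
    .check_iupac(df$forward[i]); .check_iupac(df$reverse[i])
    if (nchar(df$forward[i]) < 10L || nchar(df$reverse[i]) < 10L)
      ktx_parse_error("primers for '%s' must be at least 10 bases",
                      df$name[i])
  }
  df
}

#' Extract every configured region from a set of sequences
#'
#' Applies [extractRegion()] for each primer pair to each record
#' independently (a record matched by two pairs appears in both outputs).
#'
#' @param records Named [Biostrings::DNAStringSet] (or named character
#'   vector) of source sequences.
#' @param primers `data.frame` as from [readPrimerConfig()].
#' @param maxMismatches,keepPrimers,searchBothOrientations Passed to
#'   [extractRegion()].
#' @return List with `regions` (named list of [Biostrings::DNAStringSet],
#'   one per primer pair) and `summary` (`data.frame` with `region`,
#'   `extracted`, `missed`).
#' @export
ripRegions <- function(records, primers, maxMismatches = 2,
                       keepPrimers = FALSE, searchBothOrientations = TRUE) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  regions <- list()
  summary <- data.frame(region = character(0), extracted = integer(0),
                        missed = integer(0))
  for (i in seq_len(nrow(primers))) {
    nm <- primers$name[i]
    got <- list()
    for (j in seq_along(records)) {
      r <- extractRegion(as.character(records[j]),
                         primers$forward[i], primers$reverse[i],
                         maxMismatches = maxMismatches,
                         keepPrimers = keepPrimers,
                         searchBothOrientations = searchBothOrientations,
                         regionName = nm)
      if (!is.null(r)) got[[length(got) + 1L]] <- r
    }
    regions[[nm]] <- if (length(got)) do.call(c, got)
                     else Biostrings::DNAStringSet()
    summary <- rbind(summary,
                     data.frame(region = nm, extracted = length(got),
                                missed = length(records) - length(got)))
  }
  list(regions = regions, summary = summary)
}
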