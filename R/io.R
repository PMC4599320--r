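# Sequence and taxonomy-map input/output.
#
# FASTA/FASTQ parsing is delegated to Biostrings; this layer normalises
# case, converts RNA-style 'U' to 'T', validates the IUPAC alphabet and
# splits headers into id + description the way amplicon tools expect.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Read sequences from a FASTA or FASTQ file
#'
#' Reads plain or gzip-compressed FASTA/FASTQ. The header token before the
#' first whitespace becomes the sequence id (the remainder is kept as a
#' `description` metadata column), lowercase letters are uppercased and
#' RNA-style `U` is converted to `T` (rRNA databases contain both
#' conventions). FASTQ qualities are discarded: classification uses the
#' sequence only.
#'
#' @param path Path to the sequence file.
#' @param format `"auto"` (guess from the file extension), `"fasta"` or
#'   `"fastq"`.
#' @return A [Biostrings::DNAStringSet] named by sequence id, with a
#'   `description` column in its `mcols()`.
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path))
    ktx_parse_error("sequence file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) ktx_parse_error("failed to parse %s: %s", path,
                                        conditionMessage(e)))
  headers <- names(raw)
  if (is.null(headers) || any(!nzchar(headers)))
    ktx_parse_error("record with empty header in %s", path)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    ktx_parse_error("duplicate sequence id(s) in %s: %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  seqs <- gsub("[ \t\r]", "", seqs)
  seqs <- chartr("U", "T", seqs)
  empty <- !nzchar(seqs)
  if (any(empty))
    ktx_parse_error("empty sequence for record(s): %s",
                    paste(ids[empty], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = "")), seqs)
  if (any(bad))
    ktx_parse_error("non-IUPAC characters in record(s): %s",
                    paste(ids[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences to FASTA
#'
#' @param x A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path; `.gz` suffix triggers compression.
#' @return Invisibly, `path`.
#' @export
writeSequences <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a taxonomy mapping file
#'
#' Tab-separated, one row per reference sequence:
#' `seq_id<TAB>genus<TAB>species[<TAB>cluster]`. The species label must be a
#' complete binomial ("Genus species", at least two whitespace-separated
#' words); rows violating this are skipped with a warning and counted in the
#' `n_rejected` metadata entry. The optional fourth column carries a
#' Clostridium-cluster label.
#'
#' @param path Path to the TSV file.
#' @return A [S4Vectors::DataFrame] with columns `seq_id`, `genus`,
#'   `species`, `cluster` (NA where absent); `metadata()` holds
#'   `n_rejected` and `rejected_ids`.
#' @export
readTaxonomyMap <- function(path) {
  if (!file.exists(path))
    ktx_parse_error("taxonomy map not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    ktx_parse_error("taxonomy map row(s) with fewer than 3 columns (line %s)",
                    paste(which(nf < 3), collapse = ", "))
  seq_id  <- trimws(vapply(fields, `[[`, "", 1L))
  genus   <- trimws(vapply(fields, `[[`, "", 2L))
  species <- trimws(vapply(fields, `[[`, "", 3L))
  cluster <- trimws(vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""))
  cluster[!nzchar(cluster) | is.na(cluster)] <- NA_character_
  if (any(!nzchar(seq_id)))
    ktx_parse_error("taxonomy map row(s) with empty seq_id (line %s)",
                    paste(which(!nzchar(seq_id)), collapse = ", "))
  if (anyDuplicated(seq_id))
    ktx_parse_error("duplicate seq_id(s) in taxonomy map: %s",
                    paste(unique(seq_id[duplicated(seq_id)]), collapse = ", "))
  ok <- is_binomial(species)
  if (any(!ok)) {
    warning(sprintf("%d taxonomy row(s) skipped (species not a binomial): %s",
                    sum(!ok), paste(seq_id[!ok], collapse = ", ")),
            call. = FALSE)
  }
  out <- S4Vectors::DataFrame(seq_id = seq_id[ok], genus = genus[ok],
                              species = species[ok], cluster = cluster[ok])
  S4Vectors::metadata(out) <- list(n_rejected = sum(!ok),
                                   rejected_ids = seq_id[!ok])
  out
}

# A complete binomial: at least two whitespace-separated words.
is_binomial <- function(species) {
  !is.na(species) & lengths(strsplit(trimws(species), "\\s+")) >= 2L
}

#' Read a species-to-cluster lookup table
#'
#' TSV with two columns, `species<TAB>cluster`, mapping binomial species
#' names to Clostridium-cluster labels.
#'
#' @param path Path to the TSV file.
#' @return Named character vector (names are species binomials).
#' @export
readClusterMap <- function(path) {
  if (!file.exists(path))
    ktx_parse_error("cluster lookup not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    ktx_parse_error("cluster lookup row(s) with fewer than 2 columns")
  sp <- trimws(vapply(fields, `[[`, "", 1L))
  cl <- trimws(vapply(fields, `[[`, "", 2L))
  if (anyDuplicated(sp))
    ktx_parse_error("duplicate species in cluster lookup: %s",
                    paste(unique(sp[duplicated(sp)]), collapse = ", "))
  stats::setNames(cl, sp)
}

#' Reverse complement of IUPAC nucleotide strings
#'
#' Vectorised over a character vector; ambiguity codes map to their
#' complements (R to Y, K to M, B to V, D to H, and so on; S, W and N are
#' self-complementary). Queries are searched on both strands with this.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements, names preserved.
#' @export
revComp <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  xu <- toupper(x)
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = "")), xu)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    ktx_parse_error("non-IUPAC character '%s' at position %d",
                    substr(xu[i], bad[i], bad[i]), bad[i])
  }
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(xu)))
  names(out) <- names(x)
  out
}
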