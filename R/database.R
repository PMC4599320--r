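# The species reference database: filtering, deduplication, cluster
# annotation, the KmerRefDB container and its (de)serialisation.

DB_FORMAT <- "kmerTax-refdb"
DB_VERSION <- 1L

#' KmerRefDB: a k-mer indexed species reference database
#'
#' Holds the filtered, per-species deduplicated reference sequences, their
#' taxonomy (genus, species, optional Clostridium cluster), the k-mer size
#' and the inverted index used for classification.
#'
#' @slot sequences [Biostrings::DNAStringSet] of reference sequences, named
#'   by sequence id.
#' @slot taxonomy [S4Vectors::DataFrame] with columns `seq_id`, `genus`,
#'   `species`, `cluster`, row i annotating sequence i.
#' @slot k Integer k-mer size of the index.
#' @slot index Named list mapping each k-mer to the sorted integer indices
#'   of the references containing it.
#' @slot buildInfo List of build metadata (filter settings, per-filter drop
#'   counts, timestamp).
#' @export
setClass("KmerRefDB",
         representation(sequences = "DNAStringSet",
                        taxonomy = "DataFrame",
                        k = "integer",
                        index = "list",
                        buildInfo = "list"))

setValidity("KmerRefDB", function(object) {
  msg <- character(0)
  if (length(object@sequences) != nrow(object@taxonomy))
    msg <- c(msg, "sequences and taxonomy differ in length")
  if (!all(c("seq_id", "genus", "species") %in% colnames(object@taxonomy)))
    msg <- c(msg, "taxonomy must have seq_id, genus and species columns")
  else if (!identical(names(object@sequences),
                      as.character(object@taxonomy$seq_id)))
    msg <- c(msg, "sequence names and taxonomy seq_id do not match")
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "k must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' @describeIn KmerRefDB Reference sequences.
#' @param x,object A `KmerRefDB`.
#' @export
refSequences <- function(x) x@sequences

#' @describeIn KmerRefDB Taxonomy table (`seq_id`, `genus`, `species`,
#'   `cluster`).
#' @export
refTaxonomy <- function(x) x@taxonomy

#' @describeIn KmerRefDB k-mer size of the index.
#' @export
kmerSize <- function(x) x@k

#' @describeIn KmerRefDB The inverted index (k-mer to reference indices).
#' @export
kmerIndex <- function(x) x@index

#' @describeIn KmerRefDB Build metadata (drop counts, settings, timestamp).
#' @export
buildInfo <- function(x) x@buildInfo

#' @describeIn KmerRefDB Number of reference sequences.
#' @export
setMethod("length", "KmerRefDB", function(x) length(x@sequences))

#' @describeIn KmerRefDB Compact display.
#' @export
setMethod("show", "KmerRefDB", function(object) {
  tax <- object@taxonomy
  cat("KmerRefDB with", length(object@sequences), "reference sequences\n")
  cat("  species:", length(unique(tax$species)),
      " genera:", length(unique(tax$genus)), "\n")
  ncl <- sum(!is.na(tax$cluster))
  if (ncl > 0) cat("  cluster-annotated records:", ncl, "\n")
  cat("  k-mer size:", object@k,
      " distinct k-mers:", length(object@index), "\n")
})

#' Length-filter reference sequences
#'
#' Retains sequences of length at least `minLength`; used to keep only
#' full-length marker genes (default 1200 bp for 16S rRNA) in the
#' reference database.
#'
#' @param sequences A [Biostrings::DNAStringSet].
#' @param minLength Minimum retained length in bases.
#' @return The retained subset.
#' @export
filterByLength <- function(sequences, minLength = 1200) {
  if (minLength < 0) ktx_usage_error("minLength must be >= 0")
  sequences[Biostrings::width(sequences) >= minLength]
}

#' Retain only records with complete binomial species names
#'
#' Drops annotations whose species label is missing, has fewer than two
#' words, or contains a placeholder token from the denylist (matched
#' case-insensitively against whole words).
#'
#' @param taxonomy A [S4Vectors::DataFrame] as from [readTaxonomyMap()].
#' @param denylist Character vector of placeholder tokens.
#' @return The retained subset of `taxonomy`.
#' @export
filterBinomial <- function(taxonomy,
                           denylist = c("sp.", "uncultured", "unidentified",
                                        "unclassified")) {
  sp <- as.character(taxonomy$species)
  ok <- is_binomial(sp)
  if (length(denylist)) {
    words <- strsplit(tolower(trimws(sp)), "\\s+")
    deny <- tolower(denylist)
    ok <- ok & !vapply(words, function(w) any(w %in% deny), logical(1))
  }
  ok[is.na(ok)] <- FALSE
  taxonomy[ok, , drop = FALSE]
}

#' Remove duplicate sequences within each species
#'
#' For each species at most one copy of each distinct sequence string
#' survives (the first in input order); identical sequences carried by
#' different species are all retained, since such sequences mark species
#' that the classifier cannot distinguish and must report as ambiguous.
#'
#' @param sequences Named [Biostrings::DNAStringSet].
#' @param taxonomy Matching [S4Vectors::DataFrame] (one row per sequence,
#'   same order).
#' @return Logical vector marking the retained records.
#' @export
deduplicateRefs <- function(sequences, taxonomy) {
  if (length(sequences) != nrow(taxonomy))
    ktx_usage_error("sequences and taxonomy differ in length")
  key <- paste(taxonomy$species, as.character(sequences), sep = "\r")
  !duplicated(key)
}

#' Attach Clostridium-cluster labels to a taxonomy table
#'
#' @param taxonomy A [S4Vectors::DataFrame] with a `species` column.
#' @param clusterLookup Named character vector mapping species binomials to
#'   cluster labels (as from [readClusterMap()]).
#' @return `taxonomy` with its `cluster` column filled where the species is
#'   a key of the lookup.
#' @export
attachClusters <- function(taxonomy, clusterLookup) {
  if (!"cluster" %in% colnames(taxonomy))
    taxonomy$cluster <- NA_character_
  hit <- match(as.character(taxonomy$species), names(clusterLookup))
  taxonomy$cluster[!is.na(hit)] <- unname(clusterLookup[hit[!is.na(hit)]])
  taxonomy
}

#' Build a species reference database
#'
#' Applies the reference-construction rules in order: length filter,
#' binomial-name filter, per-species deduplication; attaches cluster
#' labels; builds the k-mer inverted index. Per-filter drop counts are
#' recorded in `buildInfo()`.
#'
#' @param sequences Path to a FASTA file or a named
#'   [Biostrings::DNAStringSet].
#' @param taxonomy Path to a taxonomy-map TSV or a [S4Vectors::DataFrame]
#'   as from [readTaxonomyMap()].
#' @param k k-mer size of the index (default 8).
#' @param minLength Minimum sequence length; set to 0 (or
#'   `lengthFilter = FALSE`) to disable.
#' @param clusterMap Optional path to a species-to-cluster TSV, or a named
#'   character vector.
#' @param denylist Placeholder tokens for the binomial filter.
#' @param lengthFilter Logical; apply the length filter?
#' @return A [KmerRefDB-class] object.
#' @export
buildDatabase <- function(sequences, taxonomy, k = 8, minLength = 1200,
                          clusterMap = NULL,
                          denylist = c("sp.", "uncultured", "unidentified",
                                       "unclassified"),
                          lengthFilter = TRUE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) ktx_usage_error("k must be a positive integer")
  if (is.character(sequences)) sequences <- readSequences(sequences)
  if (is.character(taxonomy)) taxonomy <- readTaxonomyMap(taxonomy)
  if (is.character(clusterMap) && length(clusterMap) == 1L &&
      file.exists(clusterMap)) clusterMap <- readClusterMap(clusterMap)

  ids <- names(sequences)
  tids <- as.character(taxonomy$seq_id)
  no_tax <- setdiff(ids, tids)
  no_seq <- setdiff(tids, ids)
  if (length(no_tax) || length(no_seq))
    ktx_parse_error(
      "sequence/taxonomy mismatch; without taxonomy: %s; without sequence: %s",
      paste(no_tax, collapse = ", "), paste(no_seq, collapse = ", "))
  taxonomy <- taxonomy[match(ids, tids), , drop = FALSE]

  n_input <- length(sequences)
  if (lengthFilter && minLength > 0) {
    keep <- Biostrings::width(sequences) >= minLength
  } else keep <- rep(TRUE, n_input)
  n_len <- sum(!keep)
  sequences <- sequences[keep]
  taxonomy <- taxonomy[keep, , drop = FALSE]

  tax_keep <- filterBinomial(taxonomy, denylist = denylist)
  n_binom <- nrow(taxonomy) - nrow(tax_keep)
  sequences <- sequences[match(tax_keep$seq_id, names(sequences))]
  taxonomy <- tax_keep

  keep <- deduplicateRefs(sequences, taxonomy)
  n_dup <- sum(!keep)
  sequences <- sequences[keep]
  taxonomy <- taxonomy[keep, , drop = FALSE]

  if (length(sequences) == 0L)
    ktx_parse_error("no reference sequences survive the filters")

  if (!is.null(clusterMap))
    taxonomy <- attachClusters(taxonomy, clusterMap)
  if (!"cluster" %in% colnames(taxonomy))
    taxonomy$cluster <- NA_character_

  methods::new("KmerRefDB",
               sequences = sequences,
               taxonomy = taxonomy,
               k = k,
               index = buildKmerIndex(sequences, k),
               buildInfo = list(min_length = if (lengthFilter) minLength else 0,
                                denylist = denylist,
                                n_input = n_input,
                                dropped_length = n_len,
                                dropped_binomial = n_binom,
                                dropped_duplicate = n_dup,
                                built = format(Sys.time(), tz = "UTC"),
                                format_version = DB_VERSION))
}

#' Save / load a reference database
#'
#' The on-disk artifact is a versioned container; [loadDatabase()] refuses
#' files written under a different major version and rebuilds the inverted
#' index when a different `k` is requested.
#'
#' @param db A [KmerRefDB-class].
#' @param path File path.
#' @return `saveDatabase()` returns `path` invisibly; `loadDatabase()`
#'   returns a [KmerRefDB-class].
#' @export
saveDatabase <- function(db, path) {
  stopifnot(methods::is(db, "KmerRefDB"))
  payload <- list(format = DB_FORMAT,
                  version = DB_VERSION,
                  ids = names(db@sequences),
                  sequences = as.character(db@sequences),
                  taxonomy = as.data.frame(db@taxonomy),
                  k = db@k,
                  index = db@index,
                  buildInfo = db@buildInfo)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveDatabase
#' @param k Optional k-mer size override; the index is rebuilt when it
#'   differs from the stored one.
#' @export
loadDatabase <- function(path, k = NULL) {
  if (!file.exists(path)) ktx_parse_error("database file not found: %s", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    ktx_parse_error("corrupt or unreadable database file %s: %s", path,
                    conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, DB_FORMAT))
    ktx_parse_error("%s is not a kmerTax reference database", path)
  if (!identical(payload$version, DB_VERSION))
    ktx_parse_error("database version mismatch in %s: expected %d, found %s",
                    path, DB_VERSION, as.character(payload$version))
  seqs <- Biostrings::DNAStringSet(payload$sequences)
  names(seqs) <- payload$ids
  k_new <- if (is.null(k)) payload$k else as.integer(k)
  idx <- if (identical(k_new, payload$k)) payload$index
         else buildKmerIndex(seqs, k_new)
  methods::new("KmerRefDB",
               sequences = seqs,
               taxonomy = S4Vectors::DataFrame(payload$taxonomy),
               k = k_new,
               index = idx,
               buildInfo = payload$buildInfo)
}
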