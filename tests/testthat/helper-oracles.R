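# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately avoid the package's index/code paths: k-mers
# by explicit loop, scores by pairwise set intersection, reverse
# complement by chartr.

orc_revcomp <- function(x) {
  ch <- strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                        toupper(x)), "")[[1]]
  paste(rev(ch), collapse = "")
}

orc_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- character(0)
  if (n < k) return(out)
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("^[ACGT]+$", w) && !(w %in% out)) out <- c(out, w)
  }
  out
}

orc_score <- function(q, r, k) {
  qk <- orc_kmers(q, k)
  length(intersect(qk, orc_kmers(r, k))) / length(qk)
}

# Brute-force both-strand top hits over a named character vector of
# references; exact rational strand comparison via integer counts.
orc_top_hits <- function(query, refs, k) {
  rsets <- lapply(refs, orc_kmers, k = k)
  strand_best <- function(qk) {
    if (!length(qk)) return(NULL)
    counts <- vapply(rsets, function(rk) sum(qk %in% rk), 0L)
    list(cmax = max(counts), hits = names(refs)[counts == max(counts)],
         n = length(qk))
  }
  f <- strand_best(orc_kmers(query, k))
  r <- strand_best(orc_kmers(orc_revcomp(query), k))
  none <- list(best_score = 0, hit_ids = character(0),
               strand = NA_character_)
  if (is.null(f) && is.null(r)) return(none)
  pick <- if (is.null(r)) "FORWARD" else if (is.null(f)) "REVERSE" else {
    d <- f$cmax * r$n - r$cmax * f$n
    if (d > 0) "FORWARD" else if (d < 0) "REVERSE" else "BOTH"
  }
  w <- switch(pick, FORWARD = f, REVERSE = r, BOTH = f)
  if (w$cmax == 0) return(none)
  hits <- if (pick == "BOTH") sort(unique(c(f$hits, r$hits))) else w$hits
  list(best_score = w$cmax / w$n, hit_ids = hits, strand = pick)
}

# Brute-force reimplementation of the seeded bootstrap of query i in a
# classifySequences(queries, db, nBoot, seed) call: same per-query seed
# derivation (seed + ordinal), same trial structure (nBoot draws of
# max(1, floor(|Q_K|/k)) k-mers without replacement), scored pairwise.
orc_bootstrap <- function(query, ordinal, refs, tax, k, nBoot, seed) {
  th <- orc_top_hits(query, refs, k)
  if (length(th$hit_ids) == 0) return(NULL)
  qk <- if (th$strand == "REVERSE") orc_kmers(orc_revcomp(query), k)
        else orc_kmers(query, k)
  levels <- c("genus", "species")
  labels <- list()
  for (lv in levels) {
    labs <- tax[[lv]][match(th$hit_ids, tax$seq_id)]
    if (length(unique(labs)) == 1) labels[[lv]] <- labs[1]
  }
  rsets <- lapply(refs, orc_kmers, k = k)
  m <- max(1, length(qk) %/% k)
  matches <- setNames(numeric(length(labels)), names(labels))
  set.seed((seed + ordinal) %% .Machine$integer.max)
  for (t in seq_len(nBoot)) {
    s <- sample(qk, m)
    counts <- vapply(rsets, function(rk) sum(s %in% rk), 0L)
    hits <- names(refs)[counts == max(counts)]
    for (lv in names(labels)) {
      labs <- tax[[lv]][match(hits, tax$seq_id)]
      if (!anyNA(labs) && all(labs == labels[[lv]]))
        matches[[lv]] <- matches[[lv]] + 1
    }
  }
  matches / nBoot
}

# Build a KmerRefDB directly from named character sequences + parallel
# genus/species (and optional cluster) vectors, bypassing file I/O and
# the length filter.
make_db <- function(seqs, genus, species, cluster = NA_character_, k = 8) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  tax <- S4Vectors::DataFrame(seq_id = names(seqs), genus = genus,
                              species = species, cluster = cluster)
  buildDatabase(x, tax, k = k, lengthFilter = FALSE)
}

# Random A/C/G/T string (uses the session RNG; seed at the call site).
rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

# Substitute exactly n positions of a sequence (each to a different base).
mutate_n <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# A small well-separated fixture shared by several files.
small_fixture_db <- function(k = 8, seed = 101) {
  ref <- generateReferenceSet(nGenera = 3, speciesPerGenus = 2,
                              seqsPerSpecies = 2, seqLength = 400,
                              interDivergence = 0.08,
                              intraDivergence = 0.004, seed = seed)
  buildDatabase(ref$sequences, ref$taxonomy, k = k, lengthFilter = FALSE)
}
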