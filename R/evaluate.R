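# Validation machinery: k-fold cross-validation over the reference
# database, confidence-cutoff sweeps (TPR/FPR), mock-community scoring.

#' Split reference ids into k random folds
#'
#' Seeded random partition into folds whose sizes differ by at most one.
#'
#' @param x A [KmerRefDB-class] or a character vector of ids.
#' @param nFolds Number of folds (>= 2).
#' @param seed RNG seed.
#' @return List of `nFolds` disjoint character vectors covering all ids.
#' @export
kfoldSplit <- function(x, nFolds = 10, seed = 1L) {
  ids <- if (methods::is(x, "KmerRefDB")) names(refSequences(x))
         else as.character(x)
  if (nFolds < 2L) ktx_usage_error("nFolds must be >= 2")
  if (length(ids) < nFolds)
    ktx_usage_error("fewer records (%d) than folds (%d)", length(ids), nFolds)
  with_seed(seed, {
    perm <- sample(ids)
    unname(split(perm, rep(seq_len(nFolds), length.out = length(perm))))
  })
}

#' Sweep confidence cutoffs over classification results
#'
#' At cutoff c, a query counts as classified only when its species is
#' `ASSIGNED` with confidence >= c. A classified query is a true positive
#' when its label equals the truth and a false positive otherwise;
#' everything else (ambiguous, unassigned, below cutoff) is unassigned.
#' TPR = TP/(TP+FP) and FPR = FP/(TP+FP), reported `NA` when nothing is
#' classified. `accuracy` counts unassigned queries against the
#' classifier (TP/total); `accuracy_classified` = TP/(TP+FP) is also
#' reported for transparency.
#'
#' @param results A [S4Vectors::DataFrame] from [classifySequences()].
#' @param truth Named character vector mapping `query_id` to the true
#'   species label.
#' @param cutoffs Numeric vector of confidence cutoffs.
#' @return `data.frame`, one row per cutoff: `cutoff`, `total`, `TP`,
#'   `FP`, `unassigned`, `accuracy`, `accuracy_classified`, `TPR`, `FPR`.
#' @export
sweepCutoffs <- function(results, truth, cutoffs = seq(0, 0.9, by = 0.1)) {
  tv <- truth[as.character(results$query_id)]
  if (anyNA(tv)) ktx_usage_error("truth is missing for some query ids")
  st <- results$species_status
  lab <- results$species
  cf <- results$species_confidence
  total <- nrow(results)
  out <- lapply(cutoffs, function(c) {
    classified <- st == "ASSIGNED" & !is.na(cf) & cf >= c
    tp <- sum(classified & lab == tv)
    fp <- sum(classified & lab != tv)
    den <- tp + fp
    data.frame(cutoff = c, total = total, TP = tp, FP = fp,
               unassigned = total - tp - fp,
               accuracy = tp / total,
               accuracy_classified = if (den > 0) tp / den else NA_real_,
               TPR = if (den > 0) tp / den else NA_real_,
               FPR = if (den > 0) fp / den else NA_real_)
  })
  do.call(rbind, out)
}

#' Cross-validate a reference database
#'
#' Partitions the references into `nFolds` random folds; for each fold the
#' database (and its inverted index) is rebuilt from the remaining folds,
#' the held-out sequences — optionally reduced to a variable region with a
#' primer pair first — are classified against it, and species-level
#' correctness is scored against each record's own annotation across the
#' requested confidence cutoffs. Held-out records whose region extraction
#' fails are retained as unassigned.
#'
#' @param db A [KmerRefDB-class].
#' @param nFolds Number of folds (default 10).
#' @param nBoot Bootstrap trials per query (default 10).
#' @param cutoffs Confidence cutoffs for [sweepCutoffs()].
#' @param primers Optional one-row `data.frame` (`name`, `forward`,
#'   `reverse`) selecting a variable region to classify instead of the
#'   full-length held-out sequence.
#' @param maxMismatches Primer mismatch tolerance when `primers` is given.
#' @param seed RNG seed (folds and per-fold classification).
#' @return List with `summary` (the [sweepCutoffs()] table), `results`
#'   (pooled per-query [S4Vectors::DataFrame] plus a `truth` column) and
#'   `folds`.
#' @export
crossValidate <- function(db, nFolds = 10, nBoot = 10,
                          cutoffs = seq(0, 0.9, by = 0.1), primers = NULL,
                          maxMismatches = 2, seed = 1L) {
  stopifnot(methods::is(db, "KmerRefDB"))
  folds <- kfoldSplit(db, nFolds = nFolds, seed = seed)
  seqs <- refSequences(db)
  tax <- refTaxonomy(db)
  all_res <- list()
  truth <- character(0)
  for (f in seq_along(folds)) {
    held <- folds[[f]]
    train_keep <- !(names(seqs) %in% held)
    if (!any(train_keep))
      ktx_usage_error("fold %d leaves an empty training partition", f)
    train_seqs <- seqs[train_keep]
    train_db <- methods::new("KmerRefDB",
                             sequences = train_seqs,
                             taxonomy = tax[train_keep, , drop = FALSE],
                             k = kmerSize(db),
                             index = buildKmerIndex(train_seqs, kmerSize(db)),
                             buildInfo = list(cross_validation_fold = f))
    queries <- seqs[names(seqs) %in% held]
    if (!is.null(primers)) {
      got <- list()
      for (j in seq_along(queries)) {
        r <- extractRegion(as.character(queries[j]), primers$forward[1],
                           primers$reverse[1], maxMismatches = maxMismatches)
        if (!is.null(r)) {
          names(r) <- names(queries)[j]
          got[[length(got) + 1L]] <- r
        }
      }
      extracted <- if (length(got)) do.call(c, got)
                   else Biostrings::DNAStringSet()
      missed <- setdiff(names(queries), names(extracted))
      queries <- extracted
    } else missed <- character(0)

    if (length(queries)) {
      res <- suppressWarnings(
        classifySequences(queries, train_db, nBoot = nBoot,
                          seed = derive_seed(seed, f * 100003L)))
      all_res[[length(all_res) + 1L]] <- res
      truth <- c(truth, stats::setNames(
        as.character(tax$species)[match(res$query_id,
                                        as.character(tax$seq_id))],
        res$query_id))
    }
    if (length(missed)) {
      miss_res <- S4Vectors::DataFrame(
        query_id = missed, best_score = 0, strand = NA_character_,
        n_hits = 0L,
        hit_ids = IRanges::CharacterList(rep(list(character(0)),
                                             length(missed))),
        genus = NA_character_, genus_status = "UNASSIGNED",
        genus_confidence = NA_real_,
        species = NA_character_, species_status = "UNASSIGNED",
        species_confidence = NA_real_,
        cluster = NA_character_, cluster_status = "UNASSIGNED",
        cluster_confidence = NA_real_)
      all_res[[length(all_res) + 1L]] <- miss_res
      truth <- c(truth, stats::setNames(
        as.character(tax$species)[match(missed,
                                        as.character(tax$seq_id))],
        missed))
    }
  }
  results <- do.call(rbind, all_res)
  results$truth <- unname(truth[as.character(results$query_id)])
  list(summary = sweepCutoffs(results, truth, cutoffs),
       results = results, folds = folds)
}

#' Score classifications against a known community panel
#'
#' Mock-community rule: a query is correctly classified when its
#' unambiguously assigned species is a known component of the panel.
#' Ambiguous and unassigned queries are excluded from TP/FP.
#'
#' @param results A [S4Vectors::DataFrame] from [classifySequences()].
#' @param panelSpecies Non-empty character vector of panel species.
#' @return One-row `data.frame`: `total`, `TP`, `FP`, `unassigned`,
#'   `TPR`, `FPR` (`NA` when nothing is assigned).
#' @export
scoreAgainstPanel <- function(results, panelSpecies) {
  if (length(panelSpecies) == 0L)
    ktx_usage_error("panelSpecies must be non-empty")
  assigned <- results$species_status == "ASSIGNED"
  tp <- sum(assigned & results$species %in% panelSpecies)
  fp <- sum(assigned & !(results$species %in% panelSpecies))
  den <- tp + fp
  data.frame(total = nrow(results), TP = tp, FP = fp,
             unassigned = nrow(results) - tp - fp,
             TPR = if (den > 0) tp / den else NA_real_,
             FPR = if (den > 0) fp / den else NA_real_)
}
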