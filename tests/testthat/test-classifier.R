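test_that("k-mer enumeration matches hand-worked sets and skips ambiguity codes", {
  expect_equal(extractKmers("ATTTGCG", 4), c("ATTT", "TTTG", "TTGC", "TGCG"))
  expect_equal(extractKmers("GTTTGCG", 4), c("GTTT", "TTTG", "TTGC", "TGCG"))
  expect_equal(extractKmers("AAAAA", 2), "AA")
  expect_equal(extractKmers("ACNGT", 2), c("AC", "GT"))
  expect_equal(extractKmers("ACG", 4), character(0))
})

test_that("containment score reproduces the desk examples", {
  q <- paste0("ATATTAAATT", "GCCGGGCGGC")
  r <- paste0("GCCGGGCGGC", "ATATTAAATT")
  expect_equal(similarityScore(extractKmers(q, 4), extractKmers(r, 4)),
               14 / 17)
  expect_equal(similarityScore(extractKmers("GTTTGCG", 4),
                               extractKmers("ATTTGCG", 4)), 3 / 4)
  expect_equal(similarityScore(extractKmers("ATTCGCG", 4),
                               extractKmers("ATTTGCG", 4)), 0)
  expect_equal(similarityScore(extractKmers(q, 4), extractKmers(q, 4)), 1)
  expect_error(similarityScore(character(0), "ACGT"), "no valid k-mers")
})

test_that("accumulated posting counts equal direct set intersections", {
  set.seed(31)
  seqs <- setNames(vapply(1:12, function(i) rand_seq(120), ""),
                   paste0("r", 1:12))
  db <- make_db(seqs, genus = "G", species = paste("G sp", 1:12), k = 6)
  idx <- kmerIndex(db)
  q <- rand_seq(90)
  qk <- extractKmers(q, 6)
  counts <- tabulate(unlist(idx[qk], use.names = FALSE), nbins = 12)
  direct <- vapply(seqs, function(r)
    length(intersect(qk, orc_kmers(r, 6))), 0L)
  expect_equal(counts, unname(direct))
})

test_that("single-reference search reproduces the 3/4 scenario", {
  db <- make_db(c(r1 = "ATTTGCG"), genus = "Bacillus",
                species = "Bacillus subtilis", k = 4)
  th <- topHits("GTTTGCG", db)
  expect_equal(th$best_score, 0.75)
  expect_equal(th$hit_ids, "r1")
  expect_equal(th$strand, "FORWARD")
  # identical query
  expect_equal(topHits("ATTTGCG", db)$best_score, 1)
  # reverse-complemented query hits on the other strand
  th2 <- topHits(revComp("ATTTGCG"), db)
  expect_equal(th2$best_score, 1)
  expect_equal(th2$strand, "REVERSE")
})

test_that("index-based top hits equal the brute-force scorer on random databases", {
  set.seed(99)
  for (rep in 1:20) {
    k <- sample(c(4, 8), 1)
    n <- sample(3:12, 1)
    seqs <- setNames(vapply(seq_len(n), function(i)
      rand_seq(sample(40:150, 1)), ""), paste0("r", seq_len(n)))
    db <- make_db(seqs, genus = "G",
                  species = paste("G sp", seq_len(n)), k = k)
    for (j in 1:4) {
      q <- if (j == 1) unname(seqs[1]) else rand_seq(sample(20:100, 1))
      if (j == 3) q <- orc_revcomp(unname(seqs[sample(n, 1)]))
      got <- topHits(q, db)
      want <- orc_top_hits(q, seqs, k)
      expect_equal(got$best_score, want$best_score)
      expect_equal(sort(got$hit_ids), sort(want$hit_ids))
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("per-level assignment handles agreement, ambiguity and missing clusters", {
  tax <- S4Vectors::DataFrame(
    seq_id = c("a", "b", "c", "d"),
    genus = c("Clostridium", "Clostridium", "Bacillus", "Clostridium"),
    species = c("Clostridium butyricum", "Clostridium beijerinckii",
                "Bacillus subtilis", "Clostridium butyricum"),
    cluster = c("Cluster I", "Cluster I", NA, NA))
  # singleton hit: everything assigned
  one <- assignLevels("a", tax)
  expect_equal(one$status, rep("ASSIGNED", 3))
  expect_equal(one$label[one$level == "species"], "Clostridium butyricum")
  # congeneric species, same cluster: species ambiguous, rest assigned
  two <- assignLevels(c("a", "b"), tax)
  expect_equal(two$status[two$level == "genus"], "ASSIGNED")
  expect_equal(two$status[two$level == "species"], "AMBIGUOUS")
  expect_equal(two$label[two$level == "cluster"], "Cluster I")
  # different genera: genus and species ambiguous
  three <- assignLevels(c("a", "c"), tax)
  expect_equal(three$status[three$level %in% c("genus", "species")],
               rep("AMBIGUOUS", 2))
  # annotated + unannotated cluster mix: unassigned, not ambiguous
  four <- assignLevels(c("a", "d"), tax)
  expect_equal(four$status[four$level == "cluster"], "UNASSIGNED")
  expect_equal(four$status[four$level == "species"], "ASSIGNED")
})

test_that("classification composes search, assignment and bootstrap", {
  db <- make_db(c(r1 = "ATTTGCG"), genus = "Bacillus",
                species = "Bacillus subtilis", k = 4)
  res <- classifySequences(c(q1 = "GTTTGCG"), db, nBoot = 25, seed = 3)
  expect_equal(res$best_score, 0.75)
  expect_equal(res$species_status, "ASSIGNED")
  expect_equal(res$species, "Bacillus subtilis")
  # single candidate: every trial retrieves it, confidence 1 regardless
  expect_equal(res$species_confidence, 1)
  expect_equal(res$genus_confidence, 1)

  expect_warning(res0 <- classifySequences(c(q = ""), db, seed = 1),
                 "UNASSIGNED")
  expect_equal(res0$best_score, 0)
  expect_equal(res0$species_status, "UNASSIGNED")
})

test_that("duplicated sequences under two species labels force ambiguity", {
  set.seed(17)
  shared <- rand_seq(300)
  other <- rand_seq(300)
  db <- make_db(c(x1 = shared, y1 = shared, z1 = other),
                genus = c("GenA", "GenA", "GenB"),
                species = c("GenA one", "GenA two", "GenB three"))
  res <- classifySequences(c(q = shared), db, nBoot = 10, seed = 2)
  expect_equal(res$best_score, 1)
  expect_equal(res$species_status, "AMBIGUOUS")
  expect_equal(res$genus_status, "ASSIGNED")
  expect_equal(res$genus, "GenA")
  expect_true(is.na(res$species_confidence))
})

test_that("classifying the reverse complement flips only the strand flag", {
  db <- small_fixture_db()
  seqs <- as.character(refSequences(db))
  set.seed(5)
  for (i in sample(length(seqs), 4)) {
    q <- mutate_n(seqs[[i]], 3)
    a <- classifySequences(setNames(q, "q"), db, nBoot = 10, seed = 9)
    b <- classifySequences(setNames(revComp(q), "q"), db, nBoot = 10,
                           seed = 9)
    expect_equal(a$best_score, b$best_score)
    expect_equal(sort(a$hit_ids[[1]]), sort(b$hit_ids[[1]]))
    expect_equal(a$species, b$species)
    expect_equal(a$species_status, b$species_status)
    expect_true(a$strand != b$strand || a$strand == "BOTH")
  }
})

test_that("bootstrap confidences are invariant under reference input order", {
  set.seed(23)
  ref <- generateReferenceSet(nGenera = 2, speciesPerGenus = 3,
                              seqsPerSpecies = 2, seqLength = 300,
                              interDivergence = 0.06,
                              intraDivergence = 0.01, seed = 77)
  q <- setNames(mutate_n(as.character(ref$sequences)[[1]], 2), "q")
  db1 <- buildDatabase(ref$sequences, ref$taxonomy, k = 8,
                       lengthFilter = FALSE)
  perm <- rev(seq_along(ref$sequences))
  db2 <- buildDatabase(ref$sequences[perm],
                       ref$taxonomy[perm, , drop = FALSE], k = 8,
                       lengthFilter = FALSE)
  r1 <- classifySequences(q, db1, nBoot = 50, seed = 4)
  r2 <- classifySequences(q, db2, nBoot = 50, seed = 4)
  expect_equal(r1$species_confidence, r2$species_confidence)
  expect_equal(r1$genus_confidence, r2$genus_confidence)
  expect_equal(r1$best_score, r2$best_score)
})

test_that("substitutions never increase the score against the source reference", {
  set.seed(41)
  ref <- rand_seq(400)
  rk <- extractKmers(ref, 8)
  for (rep in 1:10) {
    q <- ref
    prev <- 1
    for (step in 1:6) {
      q <- mutate_n(q, 2)
      sc <- similarityScore(extractKmers(q, 8), rk)
      expect_lte(sc, prev + 1e-12)
      prev <- sc
    }
  }
})

test_that("seeded bootstrap equals an independent brute-force reimplementation", {
  set.seed(55)
  ref <- generateReferenceSet(nGenera = 2, speciesPerGenus = 2,
                              seqsPerSpecies = 2, seqLength = 250,
                              interDivergence = 0.08,
                              intraDivergence = 0.01, seed = 13)
  seqs <- setNames(as.character(ref$sequences), names(ref$sequences))
  tax <- as.data.frame(ref$taxonomy)
  db <- buildDatabase(ref$sequences, ref$taxonomy, k = 8,
                      lengthFilter = FALSE)
  queries <- setNames(vapply(seqs[c(1, 3, 5)], mutate_n, "", n = 2),
                      c("qa", "qb", "qc"))
  res <- classifySequences(queries, db, nBoot = 40, seed = 6)
  for (i in seq_along(queries)) {
    want <- orc_bootstrap(queries[[i]], i, seqs, tax, k = 8, nBoot = 40,
                          seed = 6)
    if (is.null(want)) next
    if ("species" %in% names(want))
      expect_equal(res$species_confidence[i], unname(want[["species"]]))
    if ("genus" %in% names(want))
      expect_equal(res$genus_confidence[i], unname(want[["genus"]]))
  }
})

test_that("classification TSV output renders statuses and confidences", {
  db <- make_db(c(r1 = "ATTTGCGATTTGCG"), genus = "Bacillus",
                species = "Bacillus subtilis", k = 4)
  res <- classifySequences(c(q1 = "ATTTGCGATTTGCG"), db, nBoot = 5,
                           seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeClassification(res, f)
  out <- read.delim(f, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = character(0))
  expect_equal(out$query_id, "q1")
  expect_equal(out$best_score, "1.0000")
  expect_equal(out$species, "Bacillus subtilis")
  expect_equal(out$cluster, "UNASSIGNED")
  expect_equal(out$cluster_confidence, "NA")
})
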