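# Seeded synthetic fixtures: reference sets with controlled inter- and
# intra-species divergence, mutated query reads with a truth table, and
# primer-flanked records with known region coordinates. Substitution-only
# mutation model over a uniform A/C/G/T base composition.

BASES <- c("A", "C", "G", "T")

.random_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                   collapse = "")

# Substitute at Binomial(len, rate) positions, each to a different base.
.mutate_seq <- function(seq, rate) {
  len <- nchar(seq)
  nmut <- stats::rbinom(1L, len, rate)
  if (nmut == 0L) return(seq)
  pos <- sample.int(len, nmut)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic species reference set
#'
#' Per genus a random ancestor sequence is drawn; each species is a copy
#' mutated at `interDivergence` (so congeneric species differ at about
#' twice that fraction of sites); each sequence of a species is a copy of
#' the species ancestor mutated at `intraDivergence`. Names follow
#' `Genus_i` / `Genus_i species_j`. Fully deterministic per seed.
#'
#' @param nGenera,speciesPerGenus,seqsPerSpecies Fixture dimensions.
#' @param seqLength Sequence length in bases (default 1500, a full-length
#'   16S rRNA gene).
#' @param interDivergence Substitution fraction between a species ancestor
#'   and its genus ancestor (default 0.05).
#' @param intraDivergence Substitution fraction among sequences of one
#'   species (default 0.002).
#' @param seed RNG seed.
#' @return List with `sequences` (named [Biostrings::DNAStringSet]) and
#'   `taxonomy` ([S4Vectors::DataFrame] with `seq_id`, `genus`,
#'   `species`).
#' @export
generateReferenceSet <- function(nGenera = 5, speciesPerGenus = 4,
                                 seqsPerSpecies = 5, seqLength = 1500,
                                 interDivergence = 0.05,
                                 intraDivergence = 0.002, seed = 1L) {
  stopifnot(nGenera >= 1, speciesPerGenus >= 1, seqsPerSpecies >= 1,
            seqLength >= 1, interDivergence >= 0, interDivergence < 1,
            intraDivergence >= 0, intraDivergence < 1)
  with_seed(seed, {
    ids <- character(0); genus <- character(0); species <- character(0)
    seqs <- character(0)
    for (g in seq_len(nGenera)) {
      gname <- sprintf("Genus_%d", g)
      ancestor <- .random_seq(seqLength)
      for (s in seq_len(speciesPerGenus)) {
        sname <- sprintf("%s species_%d", gname, s)
        sp_anc <- .mutate_seq(ancestor, interDivergence)
        for (r in seq_len(seqsPerSpecies)) {
          ids <- c(ids, sprintf("G%dS%dR%d", g, s, r))
          genus <- c(genus, gname)
          species <- c(species, sname)
          seqs <- c(seqs, .mutate_seq(sp_anc, intraDivergence))
        }
      }
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    list(sequences = out,
         taxonomy = S4Vectors::DataFrame(seq_id = ids, genus = genus,
                                         species = species,
                                         cluster = NA_character_))
  })
}

#' Generate mutated query reads with a truth table
#'
#' Draws `nPerRef` reads from each reference: an optional random substring
#' of length `readLength`, substituted per base at `errorRate`; every
#' second read overall is reverse-complemented to exercise both strands.
#'
#' @param references Named [Biostrings::DNAStringSet] of source sequences.
#' @param taxonomy Optional [S4Vectors::DataFrame] (as from
#'   [generateReferenceSet()]) used to fill the truth table's genus and
#'   species columns.
#' @param nPerRef Reads per reference (default 1).
#' @param errorRate Per-base substitution probability (default 0.002).
#' @param readLength Optional read length; `NULL` keeps full length.
#' @param seed RNG seed.
#' @return List with `reads` (named [Biostrings::DNAStringSet]) and
#'   `truth` (`data.frame` with `read_id`, `source_id`, `genus`,
#'   `species`, `strand`).
#' @export
generateQueries <- function(references, taxonomy = NULL, nPerRef = 1,
                            errorRate = 0.002, readLength = NULL,
                            seed = 1L) {
  stopifnot(errorRate >= 0, errorRate < 1, nPerRef >= 1)
  if (!is.null(readLength) &&
      any(Biostrings::width(references) < readLength))
    ktx_usage_error("readLength exceeds a reference length")
  src <- as.character(references)
  with_seed(seed, {
    read_id <- character(0); source_id <- character(0)
    strand <- character(0); reads <- character(0)
    ordinal <- 0L
    for (i in seq_along(src)) {
      for (n in seq_len(nPerRef)) {
        ordinal <- ordinal + 1L
        s <- src[[i]]
        if (!is.null(readLength)) {
          start <- sample.int(nchar(s) - readLength + 1L, 1L)
          s <- substr(s, start, start + readLength - 1L)
        }
        s <- .mutate_seq(s, errorRate)
        st <- if (ordinal %% 2L == 0L) "REVERSE" else "FORWARD"
        if (st == "REVERSE") s <- revComp(s)
        read_id <- c(read_id, sprintf("q_%s_%d", names(src)[i], n))
        source_id <- c(source_id, names(src)[i])
        strand <- c(strand, st)
        reads <- c(reads, s)
      }
    }
    truth <- data.frame(read_id = read_id, source_id = source_id,
                        stringsAsFactors = FALSE)
    if (!is.null(taxonomy)) {
      m <- match(source_id, as.character(taxonomy$seq_id))
      truth$genus <- as.character(taxonomy$genus)[m]
      truth$species <- as.character(taxonomy$species)[m]
    }
    truth$strand <- strand
    out <- Biostrings::DNAStringSet(reads)
    names(out) <- read_id
    list(reads = out, truth = truth)
  })
}

#' Generate a primer-flanked record with a known insert
#'
#' Concatenates a random flank, a concrete instance of the forward primer
#' (each IUPAC position instantiated uniformly at random from its class),
#' the insert, the reverse complement of an instance of the reverse
#' primer, and a second random flank. Useful as a ground-truth fixture for
#' [extractRegion()].
#'
#' @param forward,reverse Primer IUPAC strings (5' to 3' each).
#' @param insert Non-empty region sequence to embed.
#' @param flankLengths Integer vector of length 2: upstream and downstream
#'   flank lengths.
#' @param seed RNG seed.
#' @return List with `record` (length-1 named [Biostrings::DNAStringSet]),
#'   `insert`, and the concrete `forward`/`reverse` primer instances.
#' @export
generateRipperFixture <- function(forward, reverse, insert,
                                  flankLengths = c(50, 50), seed = 1L) {
  if (!nzchar(insert)) ktx_usage_error("insert must be non-empty")
  fch <- .check_iupac(forward); rch <- .check_iupac(reverse)
  with_seed(seed, {
    inst <- function(ch) paste(vapply(ch, function(c) {
      opts <- IUPAC_SETS[[c]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, ""), collapse = "")
    f_inst <- inst(fch)
    r_inst <- inst(rch)
    rec <- paste0(.random_seq(flankLengths[1]), f_inst, toupper(insert),
                  revComp(r_inst), .random_seq(flankLengths[2]))
    out <- Biostrings::DNAStringSet(rec)
    names(out) <- "synthetic_amplicon"
    list(record = out, insert = toupper(insert),
         forward = f_inst, reverse = r_inst)
  })
}
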