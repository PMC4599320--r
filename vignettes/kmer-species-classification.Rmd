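---
title: "Species-level amplicon classification with a k-mer inverted index"
author: "kmerTax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-level amplicon classification with a k-mer inverted index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerTax)
```

## The problem

Taxonomic profiling of microbial communities usually stops at genus level,
but species identity often matters: within *Streptococcus*, for example,
*S. thermophilus* is a dairy fermenter while *S. pneumoniae* is a
pathogen. `kmerTax` assigns partial marker-gene amplicons (16S rRNA
variable regions, cpn60 Universal Target) to species wherever the
sequence signal allows it, and — crucially — refuses to guess when the
best-matching reference sequences disagree.

## The model

Let $Q$ be a query sequence and $R$ a reference, and let $Q_K$ and $R_K$
be their sets of distinct overlapping k-mers (windows containing
ambiguity codes or `N` are skipped, never expanded). The similarity is
the containment score

$$S_{Q,R} = \frac{|Q_K \cap R_K|}{|Q_K|} \in [0, 1],$$

normalised by the query (not a Jaccard index: references are typically
full-length genes, queries short amplicons). References are indexed by an
inverted index mapping each k-mer to the references containing it, so
scoring a query costs one posting-list accumulation per query k-mer
instead of a pairwise comparison against every reference. Both the query
and its reverse complement are searched; strands are compared by exact
integer cross-multiplication of shared-count/set-size ratios, so ties are
detected rationally, not within floating-point noise (on a tie the hit
sets are unioned and the strand reported `BOTH`).

All references attaining the best score form the hit set. At each
taxonomy level (genus, species, and a Clostridium-cluster level where a
species-to-cluster lookup was supplied) a label is **assigned** only if
every hit carries the same label there; two or more distinct labels make
the level **ambiguous**; a hit set mixing annotated and unannotated
references (possible only for clusters) yields **unassigned** — we
require at least two distinct labels before calling a disagreement
ambiguity. Levels are independent: a query can be species-ambiguous yet
unambiguously placed in a Clostridium cluster, which is exactly why the
cluster level is useful for gut-microbiome work.

### Bootstrap confidence

When at least one level is assigned, the assignment's stability is
estimated by subsampling: each of `nBoot` trials draws, without
replacement, $\max(1, \lfloor |Q_K|/k \rfloor)$ k-mers from the winning
strand's set, retrieves the references attaining the highest containment
score for that subset, and counts as a match at a level when the
retrieved set unanimously carries the full-query label there. The
confidence is the fraction of matching trials. A low value means many
references resemble the query (low distinctiveness); a high value means
few do. Two corner-case decisions, made here because the procedure's
verbal description leaves them open:

* subsampling is **without replacement** (a subset of $Q_K$), and the
  subset size rounds down with a floor of one;
* a trial whose subsample shares no k-mer with any reference retrieves
  *all* references (they tie at score zero); in any multi-species
  database such a trial is never unanimous and counts against the
  confidence, while in a single-reference database it degenerates to a
  match — consistent with the view that the sole candidate is trivially
  the best one.
* a trial whose retrieved set is ambiguous at a level counts as a
  non-match there; the alternative (pooling retrieved references across
  trials) coincides with this rule whenever top sets are singletons,
  which is the common case in practice.

Reproducibility contract: query $i$ of a run with seed $s$ uses RNG seed
$s + i$, so results are independent of batching, identical between
sequential and any concurrent execution, and bit-reproducible for a fixed
seed. Classification is sequential in this implementation; the per-query
seed derivation is what would keep a parallel backend output-identical.

## The reference database

`buildDatabase()` applies the construction rules in order:

1. **Length filter** — only full-length genes (default `minLength =
   1200` bp, the usual full-length 16S threshold) are kept, so that any
   amplicon region is covered by every reference.
2. **Binomial filter** — only records whose species label is a complete
   binomial ("Genus species") survive; labels containing placeholder
   tokens (`sp.`, `uncultured`, `unidentified`, `unclassified`;
   configurable) are dropped.
3. **Per-species deduplication** — within a species, identical sequences
   collapse to the first-seen copy (deterministic builds). Identical
   sequences under *different* species labels are all retained on
   purpose: they mark species the k-mer score cannot distinguish, and
   their persistence is what forces the classifier to report such
   queries as ambiguous rather than picking a species arbitrarily.

Drop counts per filter are recorded in `buildInfo()`. Cluster labels come
from a user-editable species-to-cluster TSV
(`inst/extdata/clostridium_clusters_example.tsv` ships as an editable
illustration, not an authority). The serialised database is a versioned
container; loading rebuilds the index if a different `k` is requested.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 8 | k-mer length; larger k sharpens specificity and shrinks posting lists but tolerates fewer errors (a single substitution invalidates up to k windows) |
| `nBoot` | 10 | bootstrap trials; 100 smooths the confidence at ten times the cost, with only marginal accuracy gain |
| `minLength` | 1200 bp | full-length cutoff for references |
| `maxMismatches` | 2 | per-primer tolerance in region extraction |
| `nFolds` | 10 | cross-validation folds |

## Variable-region extraction

`extractRegion()` performs substitution-only in-silico PCR: the best
forward-primer match (fewest mismatches, then leftmost) is located, then
the leftmost acceptable match of the reverse complement of the reverse
primer strictly downstream — the shortest region, a deterministic and
conservative choice. Primer footprints are excluded by default
(`keepPrimers` reverses this); `N` in the template matches nothing. If
the forward orientation of a record yields nothing, its reverse
complement is searched and the region is reported in the primer pair's
orientation, so a record and its reverse complement produce the same
region string. Indels inside primer sites are out of scope.

## The synthetic generator and what passing tests mean

Real validation at publication scale needs the public reference
databases; the package instead ships a seeded generator
(`generateReferenceSet()`, `generateQueries()`) whose defaults define the
fixture used throughout the tests: 5 genera × 4 species × 5 sequences
(100 references, 20 species) of 1500 bp — full-length 16S size — with 5 %
substitution divergence between congeneric species ancestors, 0.2 %
within a species, and 0.2 % per-base query error. The redundancy of five
sequences per species mirrors the real species database, which averages
about eight records per species; thinner fixtures make random
cross-validation folds orphan entire species, which measures fold
geometry rather than the classifier. Base composition is uniform and
mutations are substitution-only: the score is k-mer-based and indel
robustness is a non-goal, but this also means the fixtures do not model
GC skew, conserved/variable-region structure, homopolymer errors or
chimeras — passing tests demonstrate algorithmic correctness and
parameter recovery under the stated model, not field performance on any
particular sequencing platform.

Under these defaults, 10-fold cross-validation (`crossValidate()`)
recovers at least 95 % of held-out sequences at species level, and the
classified count is non-increasing in the confidence cutoff — the
quantitative surface the test suite asserts. Evaluation follows the
usual conventions: TPR = TP/(TP+FP) and FPR = FP/(TP+FP) over classified
queries; `accuracy` counts unassigned queries against the classifier
(TP/total) while `accuracy_classified` = TP/(TP+FP) is reported
alongside, since publications are not always explicit about the
denominator; mock-community scoring accepts any unambiguously assigned
species that is a member of the panel. Fold sizes differ by at most one
and are drawn over sequences, not species, so a species can lose all its
training representatives by chance in thin databases — such queries stay
in the denominator.

## Numerical and degenerate-input choices

* Scores are compared with exact integer arithmetic (shared-count ×
  set-size cross-products); text output rounds to 4 decimals but
  internal ties are exact.
* A query shorter than `k`, or with no A/C/G/T-only window on either
  strand, is reported `UNASSIGNED` with score 0 and a warning.
* An empty query k-mer set makes the score undefined; `similarityScore`
  errors and the classifier maps the condition to `UNASSIGNED`.
* `U` is silently converted to `T` on input and lowercase is uppercased;
  rRNA repositories mix conventions.
* Dedup keeps the first-seen copy; k-fold partitions are seeded
  permutations — all sources of randomness flow from explicit seeds, and
  generator output is bit-reproducible per seed.

## Worked example

```{r example}
ref <- generateReferenceSet(nGenera = 2, speciesPerGenus = 2,
                            seqsPerSpecies = 2, seqLength = 400,
                            seed = 11)
db <- buildDatabase(ref$sequences, ref$taxonomy, k = 8,
                    lengthFilter = FALSE)
db

qry <- generateQueries(refSequences(db), refTaxonomy(db),
                       errorRate = 0.005, seed = 12)
res <- classifySequences(qry$reads, db, nBoot = 10, seed = 13)
as.data.frame(res[1:4, c("query_id", "best_score", "strand",
                         "species", "species_status",
                         "species_confidence")])
```

The scale used here and in the test suite (hundreds of references,
1500 bp) keeps a full check of the package in well under a minute; the
algorithm itself is linear in query length and, through the inverted
index, independent of pairwise reference comparisons, so the same code
drives databases of tens of thousands of references.

## Known limitations

* No gap-aware alignment: a frame-shifted or indel-rich query loses all
  k-mers spanning the event, deflating the score — by design, since a
  heavily mutated read *should* fail to classify at species level.
* No chimera detection, OTU clustering or abundance estimation.
* Mislabelled reference sequences translate directly into false
  positives; the classifier can only be as clean as its database.
* The cluster level is only as complete as the supplied lookup table.
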