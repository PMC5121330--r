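---
title: "Two-stage prediction of nucleic-acid-binding residues and proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage prediction of nucleic-acid-binding residues and proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nabind)
```

## The model

`nabind` predicts whether a protein binds DNA or RNA, and where, from
sequence-derived features alone — no homology transfer, no structure of the
query. The method has two coupled classifiers:

* **Stage 1** scores every residue for nucleic-acid binding. Ground truth
  comes from co-complex structures: a residue is *binding* when any of its
  heavy atoms lies strictly below 5 Å from any nucleic-acid heavy atom
  (hydrogens are excluded on both sides; the inequality is strict, so a
  pair at exactly 5.000 Å does not count). Chains without any contact, and
  chains shorter than 30 residues or containing an undetermined residue
  `X`, are removed from the dataset.
* **Stage 2** classifies the whole protein from the *distribution* of
  stage-1 scores. The underlying assumption: isolated high-scoring residues
  occur sporadically in any protein, but true binders carry coherent
  stretches and heavy upper tails, which distribution features capture.

Both classifiers are random forests — 1000 trees by default, feature
subsampling `sqrt(p)`, unlimited depth, no class weighting. Only the tree
count is method-prescribed; the other hyperparameters are standard
random-forest defaults and are recorded in each fitted model. Scores are
probability-forest estimates of the positive class in [0, 1] (ranger
backend, single-threaded, seeded and therefore bit-reproducible); the
cutoff semantics of every threshold feature and metric ("positive iff score
above cutoff") only require [0, 1] scores and are unaffected by the choice
of probability estimator.

## The 246-feature residue encoding

The method fixes the total width (246) and two window widths: 9 residues
for evolutionary-profile channels, 7 for predicted-structure channels.
The default schema realises that contract as:

| channel | per-residue dims | window | columns |
|---|---|---|---|
| amino-acid one-hot | 20 | 9 | 180 |
| conservation | 1 | 9 | 9 |
| entropy | 1 | 9 | 9 |
| log10 alignment depth | 1 | 1 | 1 |
| secondary structure (3-state) | 3 | 7 | 21 |
| disorder | 1 | 7 | 7 |
| accessibility (relative + exposed flag) | 2 | 7 | 14 |
| physicochemical (central residue) | 5 | 1 | 5 |
| **total** | | | **246** |

The exact decomposition behind the published total is not fixed by the
method description, so this schema is the package's documented reading; it
lives in a machine-readable YAML file
(`inst/extdata/feature_schema.yaml`) and any alternative schema can be
plugged in, but the default must — and does — total exactly 246. A
relative terminal-distance channel is implemented and available to custom
schemas; it is not part of the default, which already reaches the printed
total without it. Windows extending beyond the termini are padded with 0
(an all-zero one-hot for the amino-acid channel), keeping every vector the
same width; padding is the only out-of-range rule.

Conservation, entropy and alignment depth can be computed from a user MSA
with `conservation_from_msa()`: per column, amino-acid frequencies with a
pseudocount of 1/20, Shannon entropy in bits over the 20 amino acids (gaps
excluded from counts), conservation `1 − H/log2(20)`, and the number of
ungapped rows as depth. This is a documented surrogate for profile-database
conservation fields; secondary structure, accessibility and disorder are
consumed as external predictor tracks (`load_tracks()`) and deliberately
never re-implemented. Residues missing from the crystal structure cannot be
labeled and are excluded as training examples (`resolved = FALSE`), but
they keep their sequence identity and track values and therefore still
contribute to neighbours' windows.

## The 15 protein-level features

Given a score track s_1..s_n: length; max; the counts strictly above
0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1; the number of the n−3 overlapping
4-residue windows holding at least two scores above 0.3; the counts of
within-protein Z-scores above 3, 2, 1, 0.5; and the count below −2.
Z-scores use the population SD of the protein's own track (zero-variance
tracks give all-zero Z), computed per protein and never across the dataset
— the features describe each protein's internal score distribution.
Conventions the method text leaves open, fixed here and configurable:
"above" is strict everywhere (matching the strict 5 Å rule); the
"above/below 3" item is read as the upper tail `Z > 3`, since the list's
final item already covers the lower tail (`z_tail = "abs"` selects the
two-sided reading); windows are contiguous and overlapping (no stride is
stated).

## Redundancy control and grouped cross-validation

Pairwise identity is computed from Needleman–Wunsch global alignments
(BLOSUM62, gap open 10, gap extend 0.5 — the defaults of the standard
global-alignment tool), with both identity and coverage normalised by the
shorter sequence length (the BLASTclust convention). Clustering at 30 %
identity and 50 % coverage is single-linkage with merging: a sequence
linking two existing clusters merges them, so the result equals the
transitive closure of the thresholded pair graph and is independent of
input order (sequences are processed longest-first, ties by id, for
determinism of cluster numbering). Validation-style thresholds (e.g. 90 %
coverage) are plain arguments. One consequence of the shorter-length
denominator worth knowing: short unrelated sequences can exceed 30 %
identity by chance, which is faithful to the convention rather than a bug.

Folds are assigned to *clusters*: shuffled by seed, then greedily placed
into the currently smallest fold, where size is total residue count —
residues, not chains, are the stage-1 training examples. A chain scored by
a model whose training fold contained it is a hard error, and the test
suite verifies the stronger property that perturbing a fold's labels never
changes the scores that fold receives.

Note that in the nested two-stage design, a fold's *residue* labels
legitimately influence other folds' stage-1 models (they are training data
there) and hence, indirectly, the stage-2 features everywhere; leakage
freedom means each fold's own scores never depend on its own labels, at
either stage, and that is what is tested.

## The majority combination

Cross-validation yields three fold models. A protein is deemed positive at
the lowest cutoff at which at least two of the three models call it
positive; the resulting combined score — the largest t with at least two
scores ≥ t — is exactly the median of the three scores. The test suite
proves the equivalence by exhaustive threshold sweep on random triples.
For residue tracks of novel queries the three fold models are averaged;
the majority rule is defined at the protein level only.

## Evaluation

`confusion()` calls a score positive strictly above the cutoff.
`metric_set()` implements precision, recall (= sensitivity = TPR),
specificity, FPR, ACC and MCC exactly as printed, with every
zero-denominator ratio (including MCC's) defined as 0. Curves take one
point per distinct score used as cutoff, ties grouped, cutoffs strictly
decreasing. The ROC carries (0,0) and (1,1) anchors and its AUC is the
trapezoid over FPR. The PRC omits cutoffs at which nothing is predicted
positive (precision is undefined there), starts from the conventional
(recall 0, precision 1) anchor, and stops at the first cutoff reaching
full recall — below the lowest positive score the curve only dilutes
precision at constant recall and carries no ranking information. The
random baseline is the positive fraction, the expected precision of a
random guess. Both ROC and PR AUCs are reported wherever an AUC is
summarised.

## What the synthetic data emulate — and what they do not

* `make_toy_structure()` writes PDB text with a protein chain on a
  stretched backbone trace (10 Å spacing; N, CA, CB per residue) and one
  phosphate-proxy atom per nucleotide placed exactly `contact_distance`
  (default 4.5 Å) from each planted binding residue, with every other
  residue's nearest nucleic-acid heavy atom beyond `non_contact_distance`
  (default 8 Å). The contact rule is atom-agnostic, so this minimal
  geometry tests it exactly; the generator refuses specs whose contact and
  exclusion constraints cannot both hold, optionally plants decoy
  hydrogens that the rule must ignore, and can leave chosen positions out
  of the coordinates to emulate unresolved residues. It does not attempt
  physically realistic protein or base-pair geometry.
* `make_synthetic_msa()` copies conserved columns verbatim and mutates the
  rest i.i.d. at a given rate — controlled column conservation, no
  phylogenetic correlation.
* `make_planted_dataset()` is the benchmark generator: proteins of random
  sequence (default 200 proteins, half binders, lengths 60–120 — sizes
  chosen to exercise the full pipeline at realistic per-chain scale while
  a complete run stays in the minutes range); binders carry 1–3 contiguous
  binding patches of 5–15 residues whose conservation, relative
  accessibility and disorder are shifted upward by δ channel SDs (default
  δ = 2; baseline means 0.45/0.45/0.35, SDs 0.15/0.15/0.12, clamped to
  their ranges); entropy is kept anti-correlated with conservation as in
  real profiles. Because sequences are random, clusters are singletons,
  which is the intended regime for testing fold logic — it does not
  exercise homology structure.

Passing the planted-signal recovery (out-of-fold stage-1 ROC AUC ≥ 0.9 and
stage-2 ≥ 0.85 at δ = 2; both at chance at δ = 0) demonstrates that the
machinery — labeling, windowing, grouped CV, aggregation, combination —
transmits a known signal without leakage. It says nothing about accuracy
on real proteomes, where feature quality, class imbalance and homology
structure are all harsher; the published-scale figures additionally depend
on curated structure sets and external predictor tracks that desk-scale
runs do not reproduce.

## Numerical and design choices

* Distance comparisons are strict (`<`), at 5 Å and at every score cutoff.
* Residue indexing is 0-based over the SEQRES-derived sequence; author
  numbering and insertion codes are honoured only for grouping atoms into
  residues in file order. The first alternate location is kept; modified
  residues map to parent one-letter codes through a fixed table, and
  unmappable residues become `X`, which the dataset filter then removes.
* Contacts are computed per asymmetric unit, each protein chain labeled
  independently; hybrid complexes are labeled for whichever nucleic-acid
  kind the current dataset build targets.
* Zero-variance score tracks, zero-denominator metrics and empty contact
  sets all have defined, tested behaviour (all-zero Z, 0, empty output
  respectively).
* Stage-1 out-of-fold scores feed stage-2 features, so stage-2 training
  never sees optimistic in-fold residue scores.
* Fits are deterministic given a seed; per-fold seeds are derived by fixed
  offsets from the run seed.

## Limitations

External predictor tracks (secondary structure, accessibility, disorder)
are consumed, not produced; prediction quality on real sequences inherits
their quality. The conservation surrogate is simpler than profile-database
fields. The clustering is exact but quadratic — fine for thousands of
chains, not for proteome-scale negative sets without a prefilter. The
synthetic benchmark plants signal in three channels only; a model that
ignored the others would still pass it.
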