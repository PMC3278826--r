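---
title: "Predicting gamma-glutamyl carboxylation sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gamma-glutamyl carboxylation sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glapred)
```

## The problem

Gamma-glutamyl carboxylation converts specific glutamate (Glu, E) residues
to gamma-carboxyglutamate (Gla) in the endoplasmic reticulum, with vitamin K
as cofactor. Gla residues chelate calcium and are essential to the blood
clotting factors, osteocalcin and matrix Gla protein. Experimental mapping
of Gla sites is slow, so a sequence/structure classifier that ranks the
glutamates of a candidate substrate is a useful triage tool: the positive
class is the set of experimentally annotated Gla sites, and the negative
class is every other glutamate in the same (carboxylated) proteins.

`glapred` implements that classifier end to end: window extraction,
two-stage homology reduction, feature encoding, an RBF-kernel SVM, the
five-metric evaluation protocol, the position-specific composition and
structure analyses, and a seeded synthetic-data generator that makes the
whole pipeline testable without any external downloads.

## Windows and fragments

Every glutamate is represented by a window of `2n + 1` residues centred on
it (`window_config()`, `extract_fragments()`). `n` ranges over 4..10; the
default is `n = 7`, the 15-mer that the window-length sweep selects.
Windows truncated by a protein terminus are padded with `-`, the 21st
alphabet symbol ("terminal signal"); the pad never occurs at offset 0.
Unknown residues are carried as `X` and contribute zero to every
composition feature.

## Homology reduction

Redundant sites inflate cross-validation estimates. Reduction is two-stage:

1. **Protein level** — all protein pairs with similarity above 0.30 are
   homologous (`find_homologous_pairs()`).
2. **Fragment level** — among fragments of the same label whose parents are
   homologous, any pair above 0.50 similarity is collapsed to the
   first-encountered fragment (`reduce_fragments()`), positives and
   negatives independently.

Similarity is computed from the best Smith–Waterman local alignment under
BLOSUM62 with affine gap costs 11 (open) / 1 (extend), as the number of
identical aligned pairs divided by the length of the *shorter* sequence.
Normalizing by the alignment length instead is superficially attractive but
degenerate for local alignments: the best-scoring alignment of two
unrelated sequences is typically a very short high-identity segment (a
shared dipeptide already aligns with identity 1), which would declare
nearly every pair homologous and collapse unrelated 15-mers. Dividing by
the shorter sequence length is the convention used by clustering tools
built on identity thresholds and keeps both thresholds meaningful. When no
positive-scoring alignment exists the similarity is 0.

The greedy left-to-right scan is deterministic for a fixed input order,
idempotent, and guarantees that no retained same-label pair from homologous
parents exceeds the threshold — all three are asserted in the test suite,
the alignment itself against an independent dynamic-programming oracle.

## Features

All encodings lie in `[0, 1]`, so no further rescaling precedes the SVM.
Concatenation order is fixed: `AA_PWM`, `AAC`, `ASA`, `SS`.

* **AA_PWM** — a positional weighted matrix (`build_pwm()`) holds the
  frequency of the 21 symbols at each offset over the *positive training
  fragments only*; in cross-validation it is rebuilt inside every training
  split so no validation information leaks. A fragment encodes as the
  `(2n + 1)`-vector of its own symbols' positional frequencies
  (`encode_pwm()`); symbols unseen in training encode as 0, and no
  pseudocounts are added. The matrix-shaped alternative (a flattened
  `(2n + 1) x 21` one-hot-weighted vector) is available via
  `flatten = TRUE` but is not the default: the lookup vector is the compact
  reading and performs equivalently at this training scale.
* **AAC** — the 20-vector of residue frequencies in the window, with `-`
  and `X` excluded from numerator and denominator (a terminal window is
  normalized by its real residue count).
* **ASA** — per-residue solvent accessibility (percent, from a
  RVP-Net-style predictor) ingested as a plain TSV, divided by 100, with
  out-of-range and incomplete tables rejected; padded positions get 0.
* **SS** — PSIPRED `.ss2` states one-hot encoded per position as
  helix `100`, sheet `010`, coil `001`, pad `000`.

The structure predictors themselves are consumed, not reimplemented: the
package defines the ingestion contract (dense ASA TSV; standard `.ss2`
VFORMAT checked residue-by-residue against the FASTA sequence).

## Model and evaluation

`train_model()` wraps libsvm (package `e1071`) with an RBF kernel,
`scale = FALSE`, and a decision threshold fixed at 0; decision values are
oriented so positive means the positive class, and a label-swap retraining
flips their sign (tested). Cost and gamma are the tuned parameters;
`grid_search()` evaluates a grid by stratified k-fold accuracy with
deterministic tie-breaking (smaller cost, then smaller gamma), so the
result is invariant to grid ordering. The default grid is the customary
coarse libsvm lattice; the examples and the acceptance script use a
narrower grid (cost `2^{1,3,5,7}`, gamma `2^{-6,-4,-2}`) that covers the
region where models on `[0,1]`-scaled features of this dimension peak.
Class weighting is available but off by default — the evaluation protocol
is unweighted despite the roughly 1:2 class imbalance.

Evaluation pools the k held-out folds into one confusion table and reports
precision, sensitivity, specificity, accuracy and the Matthews correlation
coefficient; any zero denominator (including MCC's) yields 0. Textual
output *truncates* to three decimals: truncation, not rounding, is what
reproduces every printed value of the reference confusion tables
(0.86092... prints as 0.860, 0.89298... as 0.892). Folds are stratified at
the fragment level with per-class sizes differing by at most one; the
independent split is at the *protein* level (about 15% of proteins), and
`independent_test()` refuses any protein-id overlap with the training set.

```{r worked-example}
cv <- compute_metrics(confusion_counts(tp = 260, fp = 51, tn = 516, fn = 42))
print(cv)
ind <- compute_metrics(confusion_counts(tp = 50, fp = 18, tn = 81, fn = 10))
print(ind)
```

The reference confusion tables label 42 as false positives and 51 as false
negatives, which contradicts the stated class sizes (TP + FN must equal
302 and TN + FP must equal 567); the package treats 42 as FN and 51 as FP
(and 10/18 likewise for the independent column), under which all ten
printed metrics reproduce exactly.

`window_sweep()` re-runs extraction, reduction and CV per half-width
(AAC features by default), and `feature_combination_eval()` runs the ten
canonical feature combinations from single features to all four.

## Composition and structure analyses

`frequency_matrix()` gives the per-offset residue frequencies behind a
sequence logo (pad/`X` excluded, rows renormalized). `two_sample_diff()`
contrasts two fragment sets per (offset, residue) cell with a pooled
two-proportion z-test, two-sided, at `alpha = 0.05` by default; the
underlying two-sample-logo tool family applies no multiple-testing
correction by default, so none is applied here either, but a
`p_adjust_method` switch exposes `stats::p.adjust`. Cells with pooled
frequency 0 or 1 carry no variance and are skipped. The statistic is
antisymmetric under set exchange and calibrated under the null (pooled
flagged fraction ≈ alpha over 1000 seeded repeats; both tested).
`mean_asa_curve()` averages ASA percent per offset excluding padded
positions, and `ss_fractions()` reports the helix/sheet/coil shares at the
central glutamate.

## The synthetic generator

`generate_gla_dataset()` exists so that every stage — parsers included —
can be exercised against known ground truth. It emulates the reported
statistical structure of carboxylation sites:

* **Composition.** Positive windows draw their flanks from per-offset
  distributions with Glu raised to 0.12 at offsets −7, −6, −4, −3, −1, +1,
  +3, +4, +6, +7, depressed to 0.01 at −2/+2, and Arg raised to 0.12 at
  −7, −5, −4, −1, +3, over a background of E = 0.04, R = 0.05 and the rest
  uniform. The enrichment magnitudes are the generator's own choice (the
  source analyses report directions and offsets, not effect sizes), set
  large enough for reliable recovery at desk scale.
* **Structure.** Positive-window ASA is normal (sd 10, clipped to
  `[0, 100]`) with mean 37.8 at the centre, 33 at ±1, a dip of 20 at ±2
  and 24 on the remaining flanks over a background mean of 22 — the
  elevation is concentrated at the site, which mirrors the shape of the
  observed curves, where the positive–negative gap is largest around
  −1..+1 and the ±2 dip coincides with Glu depletion. Secondary structure
  is drawn i.i.d. per position with (H, E, C) = (0.426, 0.044, 0.53)
  inside positive windows and (0.30, 0.25, 0.45) elsewhere.
* **Class balance.** 80 proteins of length 200–600 carry 4 planted
  positive sites and 2 decoy glutamates each; filler sequence between
  planted windows is drawn Glu-free, so the incidental glutamates that
  arise inside Glu-enriched positive flanks (themselves hard negatives,
  adjacent to real sites) bring the negative class to roughly twice the
  positive class, near the reference 302:567 ratio.

What the generator does *not* emulate: real amino-acid background
frequencies, homologous families (beyond optional verbatim duplication for
testing the reduction stage), sequence–structure coupling (SS states are
i.i.d., real helices are runs), correlated ASA along the chain, Gla-domain
architecture, or annotation noise. Passing tests therefore demonstrate
that the machinery is correct and that planted signals of realistic
direction are recovered — not that the reported real-data accuracies
transfer, which would require the original curated data.

With a fixed seed the generator is byte-identical across runs; every file
it writes (FASTA, site TSV, ASA TSV, `.ss2`, truth table) round-trips
through the package's own readers (tested).

## Numerical choices and degenerate inputs

* Similarity of an all-negative-scoring pair is 0; aligning an empty
  (all-pad) sequence is an error.
* A PWM needs at least one fragment; rows over X-free fragments sum to 1
  within 1e-9 (no pseudocounts means `X` mass is simply absent).
* `kfold_split` requires `2 <= k <= n`; assignment is rep-dealt over
  shuffled per-class indices, deterministic per seed.
* Ties in `grid_search` resolve to smaller cost, then smaller gamma.
* MCC with any zero marginal is defined as 0; `compute_metrics` rejects an
  all-zero table.
* Proteins without glutamate yield empty fragment lists and empty
  prediction tables, not errors.

## Problem sizes

The shipped tests run the pipeline at 30 proteins (about 380 fragments),
composition-recovery checks at 250 proteins (about 1000 positive sites),
and the acceptance script at the 80-protein default with a 12-protein
independent hold-out; these sizes give the recovery assertions comfortable
binomial margins while the whole suite completes in a couple of minutes on
a single core.

## Known limitations

* The real curated Gla dataset (and hence the published real-data
  accuracies) is not redistributable here; the worked-example metrics are
  recomputed from the published confusion tables, and everything else is
  demonstrated on synthetic data.
* ASA and secondary structure are consumed from upstream predictors; their
  errors propagate and are not modelled.
* The two-proportion z-test is a large-sample approximation; for very
  small fragment sets use the `p_adjust_method` option conservatively or
  larger samples.
* Fold assignment is fragment-level (the protocol's literal reading);
  homologous fragments surviving reduction can still share folds.
  Protein-level hold-out is available through `independent_test()`.
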