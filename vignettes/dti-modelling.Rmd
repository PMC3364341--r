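---
title: "Chemogenomic DTI modelling with dtiforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemogenomic DTI modelling with dtiforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtiforge)
```

This vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, the synthetic benchmark and what
passing tests on it do and do not show, and the numerical conventions and
design choices a maintainer needs to know.

## The modelling problem

Given a catalog of known drug–target interactions, we want a classifier
over *pairs*: an interaction is a point in the joint chemical–biological
space, encoded by concatenating a drug descriptor vector with a protein
descriptor vector. The core assumptions are:

1. **Sequence suffices for the target.** Proteins are encoded from primary
   sequence only — no structures, no alignments. This is what lets one
   model span unrelated protein families, at the price of ignoring binding-
   site detail.
2. **Unlabelled pairs are mostly negative.** True non-interactions are not
   recorded anywhere, so negatives are *sampled* from the complement of the
   known positives. At realistic catalog sparsity the contamination of this
   negative sample by undiscovered true interactions is small, but it is a
   bias to keep in mind: a "false positive" at screening time may simply be
   undiscovered.
3. **Known/new status is membership in the training sample.** A drug or
   target is "known" iff its id occurs among the training pairs. The four
   evaluation scenarios are defined entirely by this relation.

## Protein featurization

`featurize_protein()` computes seven descriptor families and concatenates
them in a fixed, versioned order (`default_protein_profile()`, profile
`1080-v1`):

| family | length | parameters |
|---|---|---|
| amino-acid composition | 20 | — |
| dipeptide composition | 400 | — |
| Moreau–Broto autocorrelation | 240 | 8 scales × 30 lags |
| composition/transition/distribution | 147 | 7 attribute groupings |
| sequence-order coupling numbers | 60 | 2 distance matrices × 30 lags |
| quasi-sequence-order | 100 | weight w = 0.1 |
| amphiphilic pseudo-AAC | 80 | λ = 30, w = 0.05 |
| averaged residue properties | 33 | 33 scales |

The 1080-dimension total is a convention of the encoding this package
follows; the allocation across families is this package's own, declared in
the profile object so any alternative profile must state its total and is
then checked at run time. Lag-based families require sequence length
> maxlag, so the default profile admits sequences of ≥ 31 residues;
shorter sequences are rejected (or dropped with a warning under
`sanitize = TRUE`, which also strips nonstandard residues — mirroring the
usual benchmark policy of omitting entries whose descriptors cannot be
computed).

Property scales are bundled (`aa_scales()`): 33 residue scales following
common literature compilations (Kyte–Doolittle hydropathy, Hopp–Woods
hydrophilicity, Grantham polarity/composition, Chou–Fasman propensities,
Chothia accessibility, Dayhoff mutability, …) plus exact count/indicator
scales. Every scale is standardized to zero mean and unit (population)
variance over the 20 residues before use, so descriptor values depend on
the *ordering and spacing* of residues along a scale, not on its original
units. The two residue-distance matrices behind the sequence-order
families are likewise constructed from bundled scales: a Euclidean
distance over standardized hydrophobicity/hydrophilicity/side-chain mass,
and a Grantham-style chemical distance (composition, polarity, volume with
the canonical weighting); both are normalized to a maximum entry of 1 so
their coupling numbers share a scale.

Numerical conventions worth knowing:

* Moran and Geary autocorrelation of a zero-variance profile (e.g. a
  homopolymer) is 0/0; the package defines the result as 0.
* CTD distribution positions are 1-based and reported as a percentage of
  sequence length; an absent group reports all five positions as 0.
* Quasi-sequence-order and amphiphilic pseudo-AAC share the standard
  normalization `1 + w·Στ` in the denominator, so the composition block of
  each sums to `1/(1 + w·Στ)` — an identity the test suite checks against
  independent recomputation.

## Chemical featurization

DRAGON-style commercial batteries are out of reach, so
`featurize_molecule()` computes an open 2D battery (`2d-v1`, ~50
descriptors): Open Babel physicochemical estimates (MW, logP, TPSA, molar
refractivity, H-bond counts), constitutional counts, classical topological
indices (Wiener, Zagreb M1/M2, Randić, Platt, a Balaban-type J, diameter,
mean distance) on the heavy-atom graph, and Moreau–Broto 2D
autocorrelations of atomic mass, electronegativity, covalent radius and
polarizability at topological lags 1–5. The framework is deliberately
descriptor-set-agnostic: any TSV descriptor matrix can be supplied in
place of the built-in battery, and none of the downstream machinery
changes.

Three curation rules (`curate_descriptor_matrix()`) run before modelling:
drop descriptors (a) not computable for every molecule — incomputability
is recorded as an `NA` mask, never silently zeroed — (b) constant, or (c)
near-constant, meaning the modal value covers at least `near_const_fraction`
of the rows. The default threshold 0.95 is a design choice (the rule is
standard, the cutoff is not); curation is idempotent and order-preserving,
and both facts are property-tested. Salts and mixtures keep their largest
covalent fragment. Molecules whose SMILES does not parse fail with their
id (or are dropped with a warning under `on_error = "omit"`).

## Pair datasets, negatives, scaling, splits

`sample_negatives()` implements the uniform draw from the non-interaction
space: conceptually enumerate drugs × targets, remove positives, sample
without replacement. The implementation is rejection sampling against a
positives hash with a dense-case fallback that materializes the remainder
(a contract, not a layout: both paths are exercised in tests and agree
with explicit enumeration on small catalogs). The default draw size equals
the positive count, giving the class-balanced experimental dataset the
learners expect.

Scaling maps each feature's training range to [−1, 1]. The default fits
ranges **on the training set only** and applies them to test data (which
may then fall outside [−1, 1]; no clipping) — fitting on everything leaks
test information into preprocessing, so the literal all-data variant is
available as `method = "joint"` but is not the default.

`make_split()` builds the four scenarios. Scenario I is a plain random
split. Scenarios II and III start from the same random initial split and
then *move* initial-test samples into training: II moves every sample with
a known drug or a new target (leaving new-drug/known-target tests), III
the mirror image. Because moving samples changes the training entity sets,
a single pass can leave violations; the implementation iterates to a fixed
point, so the final test sets satisfy their membership predicates exactly
— the property suite verifies this over randomized catalogs. Scenario IV
*deletes* from the initial test every sample whose drug or target is known,
leaving the training set unchanged; train∪test therefore partitions the
input for I–III but not IV.

A desk-scale caveat that shaped the defaults: cold-start test sets only
exist if some entities have *all* their samples in the initial test. In a
dense synthetic catalog (~9–10 samples per entity) this essentially never
happens at a 20% test fraction, so cold-start experiments here use a large
initial test fraction (0.8); sparse real catalogs (a couple of pairs per
drug) produce new entities naturally at 20%.

## Learners and the binding score

`dti_fit()` wraps two learners. The random forest (randomForest package)
uses 500 trees — the conventional "enough for most cases" default — and
`mtry = ⌊√M⌋` candidate features per node; no feature selection is applied
beforehand, since forests tolerate irrelevant descriptors and expose
OOB-based importances if needed. The **binding score** is the fraction of
trees voting for the interaction class: it lives in [0, 1] on a 1/ntree
grid, thresholding at 0.5 reproduces the majority vote, and scores at
exactly the threshold classify as positive (an arbitrary but fixed and
tested tie rule). The raw +1/−1 vote odds are available via
`binding_score(..., ratio = TRUE)` for completeness, but the fraction form
is what the ranked screening tables use. Scores are kept at full precision
internally and rounded (3 decimals) only for presentation.

The RBF-SVM (e1071/libsvm) selects (C, γ) by grid search on 5-fold
cross-validated accuracy over C ∈ 2^{−5..15}, γ ∈ 2^{−15..3} (step 2 in
the exponent — the standard coarse grid; the defaults are overridable and
a single-point grid skips the search). Ties resolve to the smallest C,
then the smallest γ — preferring the smoother model — which also makes the
search invariant to grid ordering. SVM "scores" are decision values; their
sign is the predicted label.

Cross-validation folds are stratified by label so that SE and SP remain
defined in every fold; fold metrics that are still undefined (a degenerate
test fold) are reported as NA and skipped in across-fold means with a
count — never imputed as 0. Pooled-count metrics are reported alongside
means because desk-scale folds are small.

## Evaluation scale

SE, SP and CO are percentages; the ROC is swept over the unique scores
(tied scores grouped, one vertex per unique score) and the trapezoid AUC
is multiplied by 100 — 100 for a perfect inference, 50 for a random one.
This grouped-trapezoid convention is exactly the Mann–Whitney U statistic
with midrank ties, and the test suite asserts that identity against an
explicit pair-counting oracle. The PCA projection (`pca_project()`)
standardizes descriptors by default (their scales are incommensurable) and
the applicability domain (`applicability_domain()`) is the per-feature
min–max box of the training samples: a query is in-domain iff every
feature lies inside, and the offending features are named otherwise.

## The synthetic benchmark

`generate_world()` + `plant_interactions()` build seeded catalogs with a
planted rule: latent score
`s(d,t) = z_d·w_d + z_t·w_t + c·(z_d A z_t)` over standardized
descriptors, thresholded at the empirical (1 − density) quantile. The
bilinear term (default strength c = 0.5) is what makes cold-start
prediction possible-but-harder: the additive marginals generalize to new
entities easily, the interaction part less so, qualitatively reproducing
the general > cold-start performance ordering. Label noise is
density-preserving by design: positives flip with probability λ and
negatives with probability λ·p/(1−p), so the expected positive count stays
at the planted density and the contamination of the positive class is ≈ λ.
(A uniform per-cell flip at a low planted density would turn a "5% noise"
world into a ~40%-contaminated positive class, capping attainable AUC near
80 and contradicting the generator's own expected-count semantics.)
λ = 0.5 is rejected outright — it would destroy the signal.

The default desk-scale fixture is 60 drugs × 60 targets, density 0.08,
noise 0.05, seed 17, in "vectors" mode (Gaussian descriptor blocks of 50
and 60 dimensions). "Structures" mode instead emits valid SMILES from a
small fragment grammar and random protein sequences of 50–500 residues and
pushes them through the real featurizers, exercising the full I/O path.

What the generator does *not* emulate: drug-likeness or real chemistry,
protein families and homology structure, the extreme sparsity and
hub-dominated degree distribution of real interaction catalogs, and
entity-specific effects not expressible through descriptors. Passing the
recovery tests therefore shows the machinery is sound — features carry the
signal end to end, splits isolate entities correctly, scores rank the
planted truth — not that any particular real-data accuracy will be
achieved.

The acceptance-style checks in the test suite run on this fixture: a
scenario-I forest must reach held-out AUC ≥ 85; with permuted labels the
AUC must fall in [45, 55] — averaged over 10 permutation replicates,
because a single ~115-sample test set has an AUC standard error of ~5
points and a one-shot check would be a coin flip; and across 10 split
seeds the mean AUC must degrade from scenario I through II to IV. For that
ordering experiment the scenarios are given comparable training budgets
(I holds out 5%; II's move-back step leaves it ~95% of the data; IV trains
on the initial 20%) so the comparison reflects cold-start difficulty
rather than training-set size.

## Pipeline, provenance, determinism

`run_pipeline()` chains data loading (or synthesis), dataset assembly,
splitting, training, evaluation and screening from one YAML config, which
is schema-validated before any computation and copied, resolved, next to
the outputs. One root seed fans out to per-stage seeds through a
documented derivation (`stage name → distinct 31-bit child seed`), so a
rerun with the same config reproduces the metrics report byte-for-byte;
the test suite asserts this. Problem sizes throughout the examples and
tests (60×60 catalogs, 500-tree forests, 10-seed replications) were chosen
so the full suite completes in about a minute on one core while leaving
the statistical checks well-powered.

## Known limitations

* Negative "ground truth" is sampled, so specificity estimates inherit the
  no-true-negatives assumption of the field.
* The chemical battery is intentionally small and 2D; it is a stand-in
  interface for any descriptor matrix, not a competitor to full
  commercial batteries.
* Network centralization/heterogeneity are computed on the bipartite graph
  as a whole (with a per-mode breakdown reported), and heterogeneity is
  defined as √var(k)/mean(k) — other conventions exist; the formulas are
  fixed and oracle-tested, and values from other tools may differ.
* Scenario II/III tests on dense catalogs can be small or empty; the
  functions fail loudly and the recommended remedy (a larger initial test
  fraction) is described above.
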