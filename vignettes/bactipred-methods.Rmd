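---
title: "Methods: descriptors, feature evaluation and model assessment in bactipred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, feature evaluation and model assessment in bactipred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bactipred` classifies protein sequences as bacteriocins (ribosomally
synthesized bacterial antimicrobial peptides) versus background proteins.
This vignette documents the science: the descriptor definitions, the three
feature-evaluation routes, the model-assessment machinery, the synthetic
data the tests rest on, and the numerical and design choices that were
genuinely open.

## Data handling

Input is amino-acid FASTA over the 20 canonical letters. Ambiguous residues
(B, Z, X, U, O) are rejected rather than imputed: every descriptor below is
defined only on the canonical alphabet, and silently mapping ambiguity codes
would contaminate composition and sequence-order terms.

Three preprocessing operations mirror standard practice for this kind of
classifier:

* **Redundancy reduction** (`reduce_redundancy()`): greedy representative
  selection at a 90% identity ceiling. Sequences are visited longest-first
  and kept only if their global Needleman–Wunsch identity (BLOSUM62, gap
  open 10, extension 0.5; identity = matches / alignment length) to every
  kept sequence is at most the threshold. This reproduces the contract of
  CD-HIT-style clustering — no two survivors above the ceiling — without its
  word-filter heuristics, which only matter for speed at database scale.
* **Class balancing** (`balance_undersample()`): the majority class is
  randomly undersampled, without replacement, to the minority count.
* **Stratified splitting** (`split_dataset()`): per class, `round(0.8 * n)`
  sequences go to training and the rest to test. With 283 sequences per
  class this gives 226 train / 57 test per class. Rounding conventions for
  an 80/20 split are not unique; `round()` was chosen once and is applied
  uniformly.

All randomized operations take an explicit integer seed (default 1) and
restore the caller's RNG state, so a seed fully determines every result.

## The 1,103-dimensional descriptor set

Eleven families, fixed order, fixed 1-based naming (`aac_1` … `pssm_400`);
`assemble_features()` refuses sequences shorter than 22 residues rather than
zero-padding, because padding would corrupt every sequence-order family.

* **`aac` (20)** and **`dipep` (400)**: residue and adjacent-pair
  frequencies in the order `A R N D C E Q G H I L K M F P S T W Y V`; pair
  (i, j) maps to index `20(i-1)+j`. Each family sums to 1.
* **`pseudo` (30)**: pseudo amino acid composition with lambda = 10 tiers
  and weight 0.05. Tier d is the mean over positions of the correlation
  `Theta(r_i, r_{i+d})`, the mean squared difference of three standardized
  scales (hydrophobicity, hydrophilicity, side-chain mass; each centered
  and scaled by its population SD over the 20 letters). The 20 composition
  terms and 10 weighted tiers are jointly normalized to sum 1. Lambda is
  pinned by the 30-dimensional target (20 + lambda); the weight is the
  conventional default.
* **`amphipseudo` (40)**: the amphiphilic variant, 2 tiers per lag —
  hydrophobicity and hydrophilicity separately — with weight 0.5. We use
  squared-difference correlations per scale rather than Chou's original
  product form: products make the components of a homopolymer nonzero and
  can push components negative, whereas the squared-difference form keeps
  the family a nonnegative unit-sum composition vector, consistent with
  every other composition family here. This is a deliberate, documented
  departure; dimensions and the role of the family are unchanged.
* **`comp`/`tran`/`dist` (21/21/105)**: the composition/transition/
  distribution model over seven physicochemical attributes (hydrophobicity,
  normalized van der Waals volume, polarity, polarizability, charge,
  secondary-structure propensity, solvent accessibility), each partitioning
  the alphabet into three groups (the Dubchak grouping; print it with
  `describe_constants()` or the CLI `constants` subcommand). Ordering is
  attribute-major. Transitions count adjacent residues crossing group pairs
  1–2, 1–3, 2–3, divided by L-1. Distribution records the 1-based positions
  of the first, 25%, 50%, 75% and 100% occurrence of each group
  (ceiling rule for quantile indices), divided by L; an absent group
  contributes five zeros. A length-1 sequence has no transitions; those 21
  components are 0 with a warning rather than an error.
* **`ss` (6)**: from a three-state (H/E/C) secondary-structure string:
  `ss_1..ss_3` are the mean 1-based positions of H, E, C divided by length
  (0 for an absent state) — a "location-associated" summary; this mean-
  position definition is our interpretation and is isolated in one
  function should a different convention be needed. `ss_4`/`ss_5` are the
  longest E and H runs over length. `ss_6` flags the motif E-H-E after
  deleting coils and collapsing runs; an opt-in `ehe_mode = "count"`
  returns the (overlap-counted) number of occurrences instead, since both
  an existence and a frequency reading of the motif are defensible.
  Eight-state input is mapped G,H,I→H; E,B→E; else→C.
* **`socn` (20)** and **`qso` (40)**: sequence-order-coupling numbers
  `tau_d = sum_i D2(r_i, r_{i+d})` for lags 1..20, and the quasi-sequence-
  order vector `f_i / (sum f + w sum tau)` (first 20, raw counts) and
  `w tau_d / (sum f + w sum tau)` (last 20), w = 0.1. The squared
  inter-residue distance `D2` (`aa_distance_matrix()`) is derived from the
  same three standardized property scales as the pseudo composition — i.e.
  it equals the `Theta` correlation above. A fixed literature distance
  matrix (e.g. Schneider–Wrede) could be substituted by replacing this one
  function; with the derived matrix the descriptor dimensions, zero
  diagonal, symmetry and all downstream behavior are identical, but
  absolute values differ from implementations using that matrix. The
  single-matrix design is forced by the 20/40 dimensionalities.
* **`pssm` (400)**: from a PSI-BLAST ASCII profile (log-odds block), scores
  are squashed by the logistic function, and the bigram
  `B(m,n) = sum_t P(t,m) P(t+1,n) / (L-1)` is flattened row-major. The
  squash-and-normalize convention keeps values in [0, 1]; `"raw"` and
  `"minmax"` alternatives sit behind a switch because the literature is not
  unanimous. PSI-BLAST itself is never invoked: profiles arrive as files
  (`read_pssm_dir()`), with the residue column cross-checked against the
  FASTA sequence (strictness configurable).

## Feature evaluation

All evaluation is fit on training data only; the held-out matrix is only
ever projected onto the selected columns. This matters: selection is part of
the model, and fitting it on pooled data leaks label information into the
test set (the no-signal experiment below exists to certify this).

**Correlation pruning** (`correlation_filter()`). Zero-variance columns are
dropped first with a warning (the correlation is undefined for them). Then,
repeatedly, the pair with the largest absolute Pearson correlation at or
above 0.9 loses the member with the larger mean absolute correlation to the
remaining features (ties drop the later column). Every surviving pair ends
below the threshold — this post-condition is asserted in the tests, and the
procedure matches `caret::findCorrelation(exact = TRUE)`, which the test
suite uses as an independent cross-check.

**ADTree** (`adtree_fit()` / `select_adtree()`). An alternating decision
tree is an ordered rule list; rule k has a precondition (a conjunction of
ancestor path predicates), a condition `feature < threshold`, and two
scores. Instance weights start at 1/t. The root contributes
`0.5 log((W+ + eps)/(W- + eps))`; each boosting round enumerates every
prediction-node path as a candidate precondition (branches are not mutually
exclusive) crossed with every threshold midpoint between consecutive sorted
unique feature values, and keeps the pair minimizing

```
Z = 2 (sqrt(W+(p&c) W-(p&c)) + sqrt(W+(p&!c) W-(p&!c))) + W(!p)
```

with branch scores `0.5 log((W+ + eps)/(W- + eps))` (eps = 1 by default, the
usual +1 smoothing) and the weight update `w_i <- w_i exp(-y_i r(x_i))`.
The prediction margin is the root score plus the scores of every satisfied
rule; a zero margin predicts positive (an arbitrary, documented tie-break).
Deterministic fitting requires explicit tie-breaking in the search: ties in
Z fall to the earlier feature, then the smaller threshold, then the
precondition with fewer conjuncts. The test suite contains an independent
exhaustive-search learner and requires rule-by-rule, score-by-score,
margin-by-margin agreement on small problems — this oracle caught a real
tree-construction bug during development, which is exactly the failure mode
(silently degraded but still-working boosting) that motivates dual
implementations.

The features used by the tree's conditions are the selected subset; their
count is bounded by the number of boosting rounds B. `adtree_tune_b()`
implements a seeded search over 50 candidate B values scored by stratified
5-fold CV accuracy; `select_adtree()` defaults to a fixed B = 15 because
the search costs O(B^2) tree fits and is rarely decisive on balanced
desk-scale data — pass `tune_b = TRUE` to enable it.

**Genetic algorithm** (`select_ga()`). Binary chromosomes encode subsets;
fitness is the mean stratified 5-fold CV ROC AUC of a random forest on the
encoded features with `mtry = floor(sqrt(#selected))` (100 trees by
default). Defaults follow the conventional GA settings: population 50,
50 generations, uniform crossover, per-bit mutation 0.03, rank-based parent
selection, ~5% elitism. The all-zero chromosome scores 0.5 (a random
classifier) and is never fitted. Fitness values are cached by chromosome;
caching cannot alter the search because fitness is deterministic given the
seed. Elitism makes the best-ever fitness non-decreasing, which the tests
assert, and the best-ever chromosome (not merely the final generation's
best) is returned.

**L1-penalized linear SVC** (`select_l1svc()`). Minimizes
`C sum(max(0, 1 - y(xw + b))^2) + ||w||_1` (squared hinge, unpenalized
intercept) on internally standardized features, by accelerated proximal
gradient descent with adaptive restart; the step size comes from a power-
iteration estimate of the Lipschitz constant, and non-convergence is an
error, never a silent truncation. Features with nonzero coefficients are
selected; C = 0.01 by default, matching the convention that small C forces
sparsity under this parameterization. The tests pin the two limits (empty
selection as C → 0, recovery of informative features at large C) and a
monotone size trend along a C grid, tolerating one violation because
solution paths of non-strictly-convex problems may locally reorder.

## Models and evaluation

Six families (RF, RBF-SVM, decision tree, ridge logistic regression, k-NN,
Gaussian naive Bayes) are tuned by stratified k-fold grid search
(standardization refit inside each fold) selecting by accuracy (AUC
optional), then refit on the full training data. Default grids: SVM
C ∈ {0.1, 1, 10, 100} × gamma ∈ {scale, 0.01, 0.001}; RF trees ∈ {100, 500}
× mtry ∈ {sqrt, log2}; k-NN k ∈ {3, 5, 7, 9}; LR C ∈ {0.01, 0.1, 1, 10};
tree depth ∈ {3, 5, 10, 30}; naive Bayes has a single configuration. These
are stand-in defaults, fully overridable via `model_spec(grid = ...)`. SVM
probabilities come from the cross-validated (Platt-type) calibration layer
of the underlying libsvm fit, because the tool's contract includes
per-sequence probabilities.

Evaluation reports confusion counts; accuracy; MCC; precision; recall; F1
(zero denominators yield 0 with a `degenerate` flag rather than NaN); the
exact Clopper–Pearson 95% interval on accuracy from the Beta-quantile
definition (`qbeta(alpha/2, x, n-x+1)`, `qbeta(1-alpha/2, x+1, n-x)`); and
the midrank (Mann–Whitney) ROC AUC. On a 112-sample test set with confusion
counts TP = 56, TN = 55, FP = 1, FN = 0 these formulas give accuracy
0.9911, MCC 0.9823, precision 0.9825, recall 1.0000, F1 0.9912 and interval
(0.9513, 0.9998) — the worked example pinned in the test suite and
recomputed by `scripts/acceptance.R`.

## Synthetic data: what it emulates and what it does not

`generate_fixtures()` draws negatives i.i.d. from a background composition
(uniform by default; a UniProt-like table by flag) and positives from a
shifted distribution that mimics, loosely, the cationic and amphiphilic
character of bacteriocins: K/R frequencies multiplied by (1 + 4s), a few
fixed dipeptides overwritten at a rate proportional to s, and — with
probability s — a secondary-structure string built around an E/H/E block
architecture. Unforced strings draw a per-sequence architecture (all-alpha
0.4, all-beta 0.4, mixed 0.2) so that the collapsed E-H-E motif has a
moderate (~0.2) base rate; without architecture classes, random run-strings
contain the motif almost surely and the planted motif would carry no
signal. PSSM files are fabricated (Gaussian log-odds noise around a +5
residue-consistent diagonal) purely to exercise parsing and the bigram
computation — they are dialect-correct but biologically meaningless, and
nothing here imitates real bacteriocin families. Passing tests therefore
certify the machinery (descriptor correctness, selector contracts, absence
of leakage, calibration plumbing), not real-data performance, which depends
on genuine profiles and structures.

At `signal_strength = 0` the label is independent of everything generated,
so positives and negatives are exchangeable; at 1 the classes are nearly
separable through several descriptor families at once.

## Experiment scales and pre-registered checks

The recovery experiment uses 100 + 100 sequences (lengths 30–80), an 80/20
split, and requires held-out SVM AUC ≥ 0.95 for each of the three selectors
(ADTree at B = 12; L1-SVC at C = 0.01; GA at population 14 × 6 generations
with 50-tree fitness forests — a reduced GA sufficient on a near-separable
problem, chosen once for desk-scale runtimes). The no-signal experiment
runs 10 seeds at 60 + 60 and requires the mean held-out AUC across seeds to
lie in [0.35, 0.65]: with 12 + 12 test samples a single null-seed AUC has
SD ≈ 0.09–0.13, so a per-seed band would reject a correct pipeline with
high probability, while the mean (SD ≈ 0.03) cleanly separates a leak-free
pipeline from selection leakage, which drives AUC toward 0.7+. The
`scripts/acceptance.R` script repeats these computations at 5 null seeds.

## Known limitations

* Secondary structure and PSSMs are inputs, not computed; predictions on
  real data inherit whatever tool produced them.
* The derived inter-residue distance matrix (see above) makes SOCN/QSO
  values internally consistent but not numerically comparable to
  implementations using the Schneider–Wrede matrix.
* The ADTree search enumerates thresholds within each candidate
  precondition's instance subset; on very wide matrices the fixed-B
  default trades exhaustive B tuning for runtime.
* Binary classification only; no multiclass bacteriocin family typing.
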