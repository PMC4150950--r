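---
title: "Modelling peptide half-life in an intestine-like protease environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling peptide half-life in an intestine-like protease environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short peptides are degraded by intestinal proteases on a time scale of
milliseconds to tens of seconds. Measured half-lives of 10mer and 16mer
peptides in crude intestinal protease preparations span roughly
0.0008–40 s and 0.0008–6.4 s respectively — four orders of magnitude —
and, because the protease preparation is concentrated, these values rank
relative stability rather than predict physiological persistence.
`peplife` regresses this half-life (in seconds) on sequence-derived
features and uses the fitted model to rank single-point mutants, scan
proteins for resistant windows, and filter peptide libraries.

The central assumption is that proteolytic susceptibility is determined
by local sequence content: which residues and short motifs (dipeptides,
tripeptides) a peptide contains, and for the positional encoding, where
they sit. Structure-dependent effects (helicity, disulphide bonds,
cyclisation) and chemically modified or D-amino acids are outside the
model; sequences containing codes other than the 20 standard residues are
rejected rather than imputed.

## Feature encodings

Four encodings, all exposed through `encoder()`:

* **Composition, k = 1, 2, 3** (`aac`, `dpc`, `tpc`): the fraction of each
  of the 20^k possible k-mers among the `L − k + 1` overlapping windows.
  Dimensions 20, 400, 8000. Two conventions had to be fixed because
  common usage varies: compositions are *fractions summing to 1* (not
  percentages) — scale-free for the downstream learners — and the
  denominator is the overlapping window count `L − k + 1`, the standard
  convention that makes every row sum to exactly 1.
* **Binary profile** (`binary`): one indicator block of 20 cells per
  position, alanine first, positions concatenated N→C; 20 × N features.
  Requires uniform peptide length across a dataset.
* Either encoding can be restricted to a terminal window (first or last
  5 or 10 residues in the published configurations). C-terminal windows
  keep N→C orientation; nothing in the modelling problem motivates
  reversal.

Residue order is fixed alphabetically by one-letter code everywhere
(A, C, D, …, Y), which also places Ala first in each binary block, and
feature names are lexicographic, so feature order is stable across runs
and platforms.

## Learners

`hlp_fit()` fits one of three regression techniques on the encoded
features; the regression target is the *raw* half-life in seconds
(`log_target = TRUE` is available but off by default, keeping MAE in
interpretable seconds and matching how this family of models is usually
reported).

* **SVR** — epsilon-insensitive support vector regression via libsvm
  (`e1071::svm`, `scale = FALSE` so the model is an explicit function of
  the raw features). Defaults: RBF kernel, `cost = 10`,
  `epsilon = 0.1`, `gamma = 1/p`. `tune = TRUE` selects
  `cost ∈ {0.1, 1, 10, 100}`, `epsilon ∈ {0.01, 0.1, 0.5}` and (RBF)
  `gamma ∈ 2^(−7…3)` by inner 3-fold cross-validated Pearson R. One
  numerical subtlety: libsvm's termination tolerance is absolute in
  target units, so the package ties it to the target spread
  (`1e-6 · sd(y)`); this makes the fit equivariant under jointly
  rescaling (y, cost, epsilon), which the scale-robustness checks
  exercise at 1e-6 precision.
* **kNN** — Euclidean distance on the encoded features, uniform or
  inverse-distance weights. `k = NULL` picks k in 1…10 by leave-one-out
  correlation on the training set. `k ≥ n` degenerates to the training
  mean, and predictions are always bounded by the training target range.
  Distance ties are broken by training-record order, making prediction
  deterministic. The inverse-distance variant is this package's declared
  stand-in for an entropic instance-based learner whose regression
  behaviour is not specified precisely enough to reproduce.
* **Decision table** — training rows are grouped by their discretised
  pattern on the chosen feature subset (equal-frequency binning, 3 bins
  per feature by default; cut points are training quantiles); each cell
  predicts its members' mean half-life; queries falling in an empty cell,
  and models with an empty feature subset, fall back to the global
  training mean. This is a deliberately simple, documented realisation
  of a rule-table learner whose original discretisation is not published.

Degenerate inputs are handled explicitly: fewer than two training rows is
an error; a constant training target yields a constant predictor for
every technique.

## Feature selection

Subset merit is the standard CFS formula
`merit(S) = k·r̄_cf / √(k + k(k−1)·r̄_ff)` with Pearson correlations
(the natural choice for a continuous target); constant features get
correlation 0 rather than NA, and the empty subset has merit 0. The
search is forward best-first from the empty set: expand the best-merit
unexpanded subset by single-feature additions, stop after 5 consecutive
non-improving expansions. Ties are broken by feature order (lexicographic
by construction), so selection is deterministic.

Two design points deserve emphasis:

* **Locally predictive post-step.** Plain merit maximisation is known to
  saturate at small subsets: once four or five features are in, a
  relevant feature with moderate correlation no longer raises the merit.
  The reference CFS implementation therefore applies, by default, a
  post-step that scans remaining features in decreasing target
  correlation and admits any feature more correlated with the target
  than with every selected feature. `best_first_select()` implements
  this (default on, `locally_predictive = FALSE` for the bare subset).
  Without it, recovery experiments on synthetic data plateau at 4–5 of 8
  planted dipeptides; with it, 6–8 are typically recovered at the cost
  of admitting some weakly correlated extras. The returned `merit` field
  always refers to the best-first subset itself, whose optimality the
  test suite checks against exhaustive enumeration on small feature
  sets.
* **Selection leaks into cross-validation.** Following the original
  modelling protocol, selection runs on the full training set by
  default, which optimistically biases any subsequent cross-validation
  restricted to the selected features. This is faithful reproduction,
  not statistical hygiene; `cross_validate(..., nested_selection =
  TRUE)` re-selects within each training fold for an unbiased estimate.

The published feature subsets (4 and 8/38 features for 10mers; 4, 3 and 5
features for 16mers) ship as named configurations in
`builtin_features()`; since the original training data are not
redistributable, they are configurations to be trained on user or
simulated data, not fitted models.

## Evaluation

`cross_validate()` shuffles records with a seed, splits them into five
near-equal folds (for 189 records: 38, 38, 38, 38, 37), trains on four
and predicts the fifth, and pools the out-of-fold predictions. Metrics
follow `hl_metrics()`: Pearson R; MAE in seconds; and
`R² = 1 − Σ(ŷᵢ−xᵢ)² / Σ(xᵢ−x̄_train)²`, where the reference is the
*training* mean (each record uses its own fold's training mean). This R²
definition can be negative — exactly the behaviour reported for weak
binary-profile models — and `predicted ≡ training mean` gives R² = 0 by
construction. Pooled (rather than fold-averaged) metrics are reported;
fold assignment is an unstratified seeded shuffle by default, with a
`stratified` option that spreads sorted half-lives across folds.

`compare_extremes()` implements the stable-versus-unstable contrast: the
top and bottom 20 peptides by half-life (ties broken by sequence so group
membership is order-independent; groups shrink to ⌊n/2⌋ with a warning
below 40 records), per-residue mean composition with two-sided Welch
t-tests (no distributional assumption beyond approximate normality of
group means; the test the original analysis used is not named), and
group means of the physicochemical panel.

## Physicochemical panel

Seventeen properties per peptide, computed from pinned, citable scales
(see `AA_SCALES`): Kyte–Doolittle hydropathy, Hopp–Woods hydrophilicity,
Eisenberg consensus hydrophobicity, Zamyatnin residue volumes (Å³),
Bhaskaran–Ponnuswamy flexibility, average residue masses (molecular
weight in Da), the EMBOSS pKa set (net charge by Henderson–Hasselbalch
summation over termini and D, E, C, Y, H, K, R side chains; isoelectric
point by bisection to |charge| < 1e-4, guaranteed bracketed in (0, 14) by
the termini), helical hydrophobic moment per residue (100°/residue) as an
amphipathicity index, and residue-class fractions: polar, non-polar,
aromatic {F, W, Y, H}, aliphatic {I, L, V}, tiny {A, C, G, S, T}, small,
positively charged {K, R, H}, negatively charged {D, E}. The original
property list names only four members ("hydrophobicity, volume,
isoelectric point, flexibility"); this panel is a documented superset
with standard class definitions. Mean-scale properties are permutation
invariant and equal the residue's scale value on homopolymers — both are
tested.

## The synthetic-data generator

The original training sets are not redistributable, so
`simulate_hl_dataset()` emulates their *shape* with known ground truth:

* fixed-length peptides (defaults: 189 10mers; 186 16mers with the
  matching clip range);
* half-life `clip(exp(β₀ + w·f(peptide)) + ε, lo, hi)` with `f` the
  dipeptide composition by default, `w` the eight published 10mer
  dipeptides with mixed-sign weights of magnitude 2.5–3
  (`DEFAULT_SYNTH_WEIGHTS`), `β₀ = log 0.5`, and `ε ~ N(0, σ)`;
* the exponential link produces strictly positive, right-skewed
  half-lives, qualitatively matching the published multiplicative
  ranges; the default weight magnitudes keep one motif occurrence worth
  roughly a 1.3-fold change, so the link stays in a moderately nonlinear
  regime in which the planted signal is statistically recoverable — with
  much larger weights a handful of peptides carries all the variance and
  no estimator (not even an oracle regression on the true features) can
  generalise at n ≈ 190;
* `σ` defaults to 5% of the standard deviation of the noise-free
  half-lives ("spread" is taken as the standard deviation; the package
  fixes this definition explicitly);
* the residue sampling distribution (`synth_residue_probs()`) enriches
  the nine residues participating in the planted dipeptides 2.5-fold.
  This emulates a designed stability-motif library: under a uniform
  alphabet a specific dipeptide is expected in only ~4 of 189 10mers, so
  the generative signal would be essentially unobservable regardless of
  method. Uniform sampling remains available via `residue_probs`.

`planted_effect_dataset()` is the single-residue analogue (half-life
`exp(effect · count)` plus noise) used for the group-comparison analysis;
`effect = 0` yields an exchangeable null.

What passing tests on these data do and do not show: they demonstrate
that the pipeline recovers a known composition-linear signal of realistic
dimensionality, sample size and noise, and that every bookkeeping
property (fold partitioning, scale equivariance, determinism) holds. They
do not validate predictive accuracy on real proteolysis data — real
half-lives reflect enzyme specificity, positional context and
higher-order effects that a sparse dipeptide model does not generate —
and the published correlation values on the original datasets are
deliberately not targets, since those data are unavailable.

## Numerical choices and problem sizes

Tie-breaks are fixed everywhere randomness is not intended: feature order
lexicographic, kNN distance ties by training order, best-first merit ties
by insertion order, mutant ranking ties by (position, residue). All
stochastic steps (simulation, fold shuffles, tuning folds) are seeded,
and the RNG state of the caller is preserved. The test suite and the
acceptance script run the recovery experiment at the emulated full size
(189 peptides, 400 features), the search-versus-enumeration check on 100
fixtures of up to 12 features, and the null group-comparison rate over 50
seeds of 200 peptides — sizes chosen so the full suite completes in well
under a minute of compute per component while still exercising the
published problem scale.

## Known limitations

* The decision table and the inverse-distance kNN are documented
  approximations of rule-table and entropic instance-based learners whose
  exact algorithms are not recoverable from their descriptions.
* Published per-model hyperparameters were never printed; the tuning grid
  is this package's choice.
* Selection on the full training set (the reproduced protocol) inflates
  cross-validated correlations on selected features; use
  `nested_selection = TRUE` when an honest generalisation estimate
  matters.
* The physicochemical scales are pinned choices among several reasonable
  published alternatives; the modelling logic is scale-agnostic.
* Only single-point mutants are enumerated (19N per parent); the report
  supports iterative application but no multi-objective search.
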