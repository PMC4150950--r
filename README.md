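# peplife

Sequence-based prediction and design of peptide half-life in an
intestine-like protease environment.

Orally delivered therapeutic peptides are degraded within seconds by
intestinal proteases; measured half-lives of short peptides in crude
intestinal protease preparations span from under a millisecond to tens of
seconds. `peplife` models that half-life from sequence alone and turns the
fitted model into a design tool: which single-residue substitution makes a
peptide live longer, which window of a protein is the most
protease-resistant, and which members of a peptide library clear a
stability and property filter.

## The model

Peptides over the 20 standard residues are encoded as

* **amino acid / dipeptide / tripeptide composition** (AAC/DPC/TPC):
  fractions of overlapping k-mers, `f_i = count_i / (L - k + 1)`, giving
  feature vectors of dimension 20, 400 and 8000, optionally restricted to
  N-/C-terminal windows; or
* **binary profiles**: positional one-hot encoding, 20 indicator cells per
  position (20 × N features).

Half-life (seconds) is regressed on these features with one of three
learners behind a single fitting interface, `hlp_fit()`:
epsilon-insensitive support vector regression (libsvm), k-nearest-neighbour
regression, or a discretised decision table. Feature subsets are chosen by
correlation-based feature selection: subset merit

    merit(S) = k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)

(`r̄_cf` mean |feature–target correlation|, `r̄_ff` mean |pairwise feature
correlation|, k = |S|) maximised by forward best-first search that stops
after five non-improving expansions. Performance is estimated by five-fold
cross-validation with pooled out-of-fold predictions and three statistics:
Pearson R, MAE, and a training-mean-referenced coefficient of
determination `R² = 1 − Σ(ŷᵢ−xᵢ)²/Σ(xᵢ−x̄_train)²`, which is negative
whenever a model underperforms the training-mean baseline.

Because the original 10mer/16mer half-life training sets are not
redistributable, the package ships (a) the published feature-subset
configurations (`builtin_features()`) so the published model forms can be
trained on your own data, and (b) a synthetic-data generator
(`simulate_hl_dataset()`) with known generative structure, so the whole
pipeline is testable against ground truth.

## Worked example

```r
library(peplife)

# a 189-peptide 10mer dataset with 8 planted dipeptide effects
ds <- simulate_hl_dataset(n = 189, length = 10, seed = 11)
range(ds$half_life_s)
#> [1] 0.2802445 1.2809740   (seconds)

# feature selection on dipeptide composition
X   <- encode_peptides(ds, encoder("dpc"))
sel <- best_first_select(X, ds$half_life_s)
sel
#> <hlp_selection> 33 feature(s), merit 0.8248
#>   GF, EK, EL, GD, IE, KP, YL, FE, LP, YY, DK, IF, EN, ML, AE, RK, EV, ...
sum(names(DEFAULT_SYNTH_WEIGHTS) %in% sel$selected)
#> [1] 7          # 7 of the 8 planted dipeptides recovered

# cross-validated SVR on the selected features
cv <- cross_validate(ds, encoder("dpc"), "svr", features = sel$selected,
                     kernel = "rbf", gamma = 1, cost = 100,
                     epsilon = 0.001, seed = 3)
cv
#> <hlp_cv> 5-fold CV, svr on dpc (n = 189, seed 3)
#>   R = 0.932, R2 = 0.868, MAE = 0.01811 s (pooled out-of-fold)

# fit on everything and design a stabler mutant
m   <- hlp_fit(ds, encoder("dpc"), learner = "svr", features = sel$selected,
               kernel = "rbf", gamma = 1, cost = 100, epsilon = 0.001)
top <- rank_mutants(ds$sequence[1], m, top = 3)   # parent ITLFDPCQIY, 0.50 s
top$mutants[, c("position", "original", "substituted",
                "predicted_half_life_s")]
#>   position original substituted predicted_half_life_s
#> 1        2        T           E             0.8346142
#> 2        3        L           G             0.6628321
#> 3        4        F           G             0.6625559
```

The mutant table reads: substituting residue 2 (Thr) with Glu is predicted
to raise this peptide's half-life the most (it creates the stabilising IE
dipeptide the generator planted); `improves_parent` and
per-property `delta_*` columns let you trade stability against charge,
hydropathy and the rest of the 17-property physicochemical panel
(`peptide_properties()`).

A command-line wrapper over the same functions is installed at
`inst/cli/hlp.R`:

```sh
Rscript inst/cli/hlp.R simulate --n 189 --length 10 --seed 11 --output sim.tsv
Rscript inst/cli/hlp.R evaluate --input sim.tsv --encoder dpc --learner svr --output eval.tsv
Rscript inst/cli/hlp.R design --input peptide.txt --train sim.tsv --top 10 --output mutants.tsv
```

Subcommands: `simulate`, `train`, `predict`, `select`, `evaluate`,
`analyze`, `properties`, `design`, `scan`, `batch`. Every artifact is TSV
(or JSON) with a header line recording the package version and seed; all
coordinates are 1-based inclusive.

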