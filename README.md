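# hkmlearn

Exhaustive learning of **human-computable Boolean decision rules** from
tabular data.

Most machine-learning models explain data with coefficients no person can
apply mentally. `hkmlearn` searches the opposite corner: rules an average
person can evaluate in their head — at most **4 variables**, each used
once, combined by at most **4 operators** from AND, OR, NOT and a
thresholded Boolean SUM (an M-of-N count, "at least 2 of these 3
conditions"), with numeric features entering only through simple rounded
thresholds (`age > 60`). Within that class the search is *exhaustive and
deterministic*: every admissible formula (pre-enumerated and minimised
into a catalog, fewer than 100 semantic classes per rule size) is scored
on every eligible feature subset, and the top M rules are returned for a
person to inspect and choose among. Missing values are never imputed:
they become indicator atoms, rules are scored on their fully observed
rows (*coverage*), and predictions abstain when a rule's input is
missing.

The search cost factors as

    O(N, K, L, n) = S(N, K, n) x B(n) x F(n, L),   n <= 4

with `S(N,K,n) = choose(N*K, n)` candidate subsets from `N` features and
`K` thresholds each, `B(n)` the admissible-formula term (bounded by a
constant below 100), and `F(n, L) = O(L)` per-pair scoring over `L`
observations — polynomial in `N*K` despite being exhaustive. A
multi-instance harness quantifies how little these tiny rules overfit via
the stability factor `S = |F1_train - F1_test| / F1_train` and its
empirical curve `P(S)`.

Audience: anyone deriving transparent decision rules from samples-by-
variables tables — clinical risk rules, screening criteria, quality
checks — and anyone studying how close human-sized rules get to black-box
performance on a given dataset.

## Worked example

The package generates its own study data: a planted admissible rule
`(marker_a AND marker_b) OR risk_c` over mixed numeric/Boolean features
with distractors, 5% label noise, 5% missingness, ~30% positive rate,
2000 observations.

```r
library(hkmlearn)

d   <- hkm_generate_planted(hkm_planted_spec(n_obs = 2000), seed = 42)
fit <- hkm_fit(d, target = "outcome", sizes = 1:4, m = 25)
fit
#> <hkm_fit> 25 models (561660 formula-subset pairs scored, metric = f1)
#>    1. [0.8746] risk_c OR (marker_a > 50 AND marker_b)
#>    2. [0.8682] risk_c OR (marker_a > 50 AND marker_b AND noise_d is present)
#>    3. [0.8665] risk_c OR (marker_b AND (marker_a > 50 OR noise_d is missing))
#>    4. [0.8649] (marker_a > 50 AND marker_b) OR (risk_c AND noise_e is present)
#>    5. [0.8644] risk_c OR (marker_b AND (marker_a > 50 OR noise_e is missing))
#>   ... 20 more
```

The top rule is the planted one, recovered with its threshold rounded to
a memorable value; the rest of the stack shows *model multiplicity* —
near-optimal alternatives a user can pick from for practicality. Scores
are train F1 on the rule's covered rows. `tidy(fit)` returns the table,
`glance(fit)` the one-row summary, `predict(fit, newdata)` applies a rule
(with `NA` abstentions on incomplete rows), `autoplot(fit)` shows score
against rule size.

Stability across 10 seeded 80/20 splits:

```r
glance(hkm_experiments(d, n_exp = 10, seed = 7, sizes = 1:3, m = 10))
#> # A tibble: 1 × 7
#>   n_instances skipped metric median_train median_test median_S p_stable_10
#>         <int>   <int> <chr>         <dbl>       <dbl>    <dbl>       <dbl>
#> 1          10       0 f1            0.876       0.869   0.0224           1
```

Median train-to-test degradation is ~2%, and every instance stayed below
`S = 0.1` — the characteristic resistance to overfitting of an
exhaustively searched, four-operator rule class.

Other entry points: `hkm_catalog()` (the minimal-formula catalog; 2, 8,
66, 508 labeled tables at sizes 1–4), `hkm_binarize()` /
`hkm_binarize_report()` (threshold atoms and missingness accounting),
`hkm_complexity()` (search-cost estimates), `hkm_generate_nim()` (a
game-winner dataset whose label is the nim-sum of pile sizes),
`hkm_pr_summary()` (precision–recall of top rules by size), and a shell
wrapper in `inst/scripts/hkm` (`fit`, `evaluate`, `enumerate-formulas`,
`synth`). `vignette("human-rules")` documents the model class, the
conventions and their rationale.

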