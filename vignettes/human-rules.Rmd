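---
title: "Learning human-computable decision rules by exhaustive search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning human-computable decision rules by exhaustive search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkmlearn)
```

## The model class

`hkmlearn` learns Boolean decision rules constrained to what an average
person can evaluate mentally, in real time, without external aids. Cognitive
limits on working memory and mental arithmetic motivate four admissibility
constraints:

* operators drawn from **AND, OR, NOT** and a **thresholded Boolean SUM** —
  an M-of-N count such as "at least 2 of these 3 conditions hold";
* at most **four variables**, each used **at most once** (rules are
  read-once);
* at most **four operators**;
* non-Boolean inputs enter only through **simple numeric thresholds**
  ("age > 60").

Operator accounting uses a binary-connective convention: an a-ary AND or OR
costs `a - 1`, NOT costs 1, and a thresholded SUM costs 1 regardless of
arity, because counting "at least t of these conditions" is a single mental
act — this is what makes the majority-of-3 rule admissible, as the class
intends. Flipping the direction of a threshold comparison (`age > 60`
versus `age <= 60`) costs nothing: both directions are equally easy to
apply. A SUM counts bare variables, not sub-expressions: it is an
arithmetic count of conditions, and its threshold `t` is interior
(`2 <= t <= arity - 1`), since `t = 1` is an OR and `t = arity` an AND.

These conventions were genuinely open design points — no single counting
rule for n-ary connectives is canonical — and the package fixes them once,
everywhere: the admissibility predicate, the catalog, and the searcher all
share them.

## From truth tables to a catalog of minimal rules

A rule's meaning is its truth table. The package enumerates, once per
constraint set, *every* admissible expression tree over up to four
variables, computes each tree's table, and keeps the shortest expression
per table (`hkm_catalog()`). This is the "semantic simplification" step:
the 4-minterm disjunctive normal form of the majority-of-3 table collapses
to `SUM(x1, x2, x3) >= 2`. Tables no admissible expression can produce —
XOR, which needs a repeated variable — are simply absent, and functions
that do not depend on all their declared variables are excluded at that
size (they are found at their true, smaller size, avoiding duplicate
models).

Under the default constraints the reachable proper tables number 2, 8, 66
and 508 for sizes 1–4; modulo variable permutation these collapse to 2, 6,
22 and 70 classes. Every per-size count is below 100, which is why the
formula term in the search-cost estimate (`hkm_complexity()`) can be
treated as a bounded constant: the total search cost is
`O(L * (N*K)^n)` for `L` observations, `N` features, `K` thresholds and
rule size `n <= 4` — polynomial, despite being exhaustive.

Construction is deterministic (children in canonical order, ties between
equal-cost expressions broken by the rendered string) and is cross-checked
in the test suite against an independently coded brute-force enumerator:
same reachable tables, same minimal operator counts.

## Binarization without imputation

`hkm_binarize()` turns each raw column into candidate Boolean atoms:

* numeric columns become up to `K` threshold atoms (default `K = 3`),
  placed at evenly spaced quantiles and rounded to **two significant
  digits** — thresholds a person can remember. Quantile placement is a
  design choice: it adapts to the observed distribution without a
  supervised split search, which would belong to a different (and less
  transparent) model family;
* logical columns pass through; factor/character columns become one
  indicator atom per level;
* every column containing missing cells also yields an `is missing`
  indicator, because missingness is often informative.

Missing cells are **never imputed**. Each atom carries a mask of its
missing source cells; when a candidate rule is scored, rows with any
masked cell among its atoms are excluded, and the retained fraction is the
rule's *coverage*. Candidates below a coverage floor (default 0.8) are
skipped, steering the search toward feature subsets where incomplete rows
are rare. At prediction time the same contract holds: a row missing one of
the rule's inputs abstains (`NA`) rather than guessing.

Atoms derived from the same source column are *siblings* and never enter
one rule together — "each variable is used at most once" extends to source
features, so a rule cannot spend two of its four slots on
`age > 40 AND age <= 60`.

## The exhaustive search

`hkm_fit()` scans every (formula, atom-subset) pair: all subsets of each
size, crossed with every catalog table of that size. Bucketing the covered
rows once per subset by their joint atom assignment makes each formula's
confusion matrix a `2^n`-term lookup, so the per-formula cost is
independent of the observation count. A top-M stack (default `m = 25`,
following the practice of keeping 10–50 nearly optimal rules for a human
to choose among) retains the best models under a fully deterministic
order: score, then fewer variables, fewer operators, higher coverage, and
finally the rendered rule text. Two runs on identical input produce
byte-identical output; the test suite asserts this on the serialized model
files, and separately checks the whole top-M list (scores, semantics,
bookkeeping) against a naive independently coded enumerator on small
instances.

Negated targets need no special handling: the catalog contains the negated
form of every rule whose negation fits the operator budget, so both
polarities of the outcome are covered by the same scan. Optional seeded
subsampling bounds the per-pair cost on very long tables; it is off by
default because the method's results should be exactly reproducible from
the data alone.

The default metric is F1, appropriate for the unbalanced outcomes these
rules are typically learned for; precision, recall and accuracy are
available.

## Stability across resamples

Because the rule class is tiny and the search exhaustive, learned rules
barely overfit. The harness quantifies this: `hkm_experiments()` runs
`n_exp` seeded 80/20 train/test splits (instance seed = master seed +
instance index; binarization happens inside the split), records the best
rule's train and test scores, and the stability factor

S = |Quality_train − Quality_test| / Quality_train,

and reports the empirical curve P(S) — the fraction of instances whose
factor stays below each threshold, i.e. an empirical CDF on a 0.01 grid.
Five-fold cross-validation scores can be recorded diagnostically
(`cv = TRUE`); the 80/20 test score is authoritative, which resolves the
ambiguity of combining the two protocols in favour of the simpler,
assumption-free one. A `baseline` hook slots any external model into the
identical splits, so black-box comparisons use the same protocol without
making the package depend on any modelling library.

`hkm_pr_summary()` profiles the top rules learned at each size on a test
set in precision–recall space — the practical way to see how much quality
each extra variable of human complexity buys, and where it saturates.

## Synthetic study conditions

The package generates its own data, emulating the structure of the
decision datasets this method targets rather than any specific source:

* **Planted rules** (`hkm_planted_spec()` / `hkm_generate_planted()`):
  features with independent Bernoulli or Gaussian marginals, a known
  admissible generating rule, label-flip noise, distractor features, and
  per-feature missingness (never in the target). The default spec plants
  `(marker_a AND marker_b) OR risk_c` with an analytic positive rate of
  about 30% after 5% noise — an unbalanced outcome in the range typical of
  clinical and screening data (roughly 7–40% positive) — 5% missingness,
  and 2000 observations. The analytic prevalence is exact
  (`hkm_planted_prevalence()` enumerates the joint), and the generator is
  byte-reproducible from its seed.
* **Nim games** (`hkm_generate_nim()`): uniformly drawn pile
  configurations labelled by whether the player to move wins under optimal
  play — true exactly when the bitwise XOR of pile sizes is nonzero, a
  fact the tests re-derive by exhaustive game-tree search. The default is
  2000 games and 10 feature columns: three pile sizes padded with
  constant columns, the minimal honest reading of a fixed-width feature
  table (the padding is deliberately uninformative). A `"bits"` layout
  exposing binary digits of each pile is available as a configuration, not
  the default, since under bit features small instances become
  rule-expressible and the task changes character.

What the generators deliberately do **not** emulate: correlated features,
covariate shift, non-monotone threshold effects, or structured (informative)
missingness beyond the independent per-feature rates. Tests passing on
these generators therefore validate the machinery — exhaustiveness,
determinism, missing-value handling, recovery under label noise — not
performance claims on any real dataset.

## Numerical and scale choices

* Truth-table rows follow a fixed convention (variable `i` is bit `i - 1`
  of the row index), making catalog keys and serialized fixtures
  bit-exact.
* Degenerate inputs fail loudly: constant tables cannot be simplified or
  DNF-expanded, a single-class target stops the fit, a zero train score
  makes S undefined, and a search where no subset reaches the coverage
  floor returns an empty model list with a warning.
* Test and example problem sizes are chosen so the full suite exercises
  every path at desk scale: oracle-equivalence datasets use at most 12
  atoms and 70–80 rows (where naive enumeration is exact and fast),
  recovery experiments use 50 replicates of 2000 observations, and the
  multi-instance harness in examples uses tens, not thousands, of
  instances. The method itself has no such limits; the cost model above
  says how runs scale.

## Known limitations

* The class is read-once by construction: XOR-like interactions and rules
  needing a repeated variable are invisible, as are effects requiring
  arithmetic on raw features (for instance a product of two features) —
  that boundary is intrinsic to human computability, not an implementation
  gap.
* Threshold candidates are unsupervised quantile cuts; a true optimal
  split can fall between them. Raising `K` tightens the grid at polynomial
  cost.
* Exhaustive search is polynomial but still steep in `N*K` at size 4;
  beyond a few hundred atoms, subsetting features or sizes (or seeded
  subsampling of rows) is the intended escape valve. Greedy or
  branch-and-bound accelerations are out of scope here.
* The stability harness reports honest out-of-sample scores for the rule
  *selected on each training split*; it does not correct for selecting
  among many near-optimal rules, which is why the top-M list is surfaced
  to the user rather than a single "the" model.
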