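#' Count candidate variable subsets
#'
#' `N` source features with up to `K` thresholds each yield at most `N * K`
#' Boolean atoms; an exhaustive rule search over `n`-variable formulas visits
#' `choose(N * K, n)` atom subsets. With 300 candidate features, one
#' threshold each and 3-variable rules this is already 4,455,100 subsets.
#'
#' @param N number of source features (>= 1).
#' @param K thresholds per feature (>= 1).
#' @param n rule size, 1..4.
#' @return The subset count as a double (exact for all arguments of
#'   practical size; `choose()` is exact well beyond 2^53 here). Zero when
#'   `N * K < n`.
#' @export
hkm_count_subsets <- function(N, K, n) {
  stopifnot(N >= 1, K >= 1, n >= 1, n <= 4)
  choose(N * K, n)
}

#' Search-cost estimate for the exhaustive rule search
#'
#' The total work factors into three terms: the number of atom subsets
#' `choose(N*K, n)`, a bound on the number of admissible formula classes per
#' subset (fewer than 100 across all sizes, so the term is capped at 100),
#' and the per-pair cost of scoring one formula on `L` observations, which
#' is linear in `L`. Because the formula term is a constant and `n <= 4`,
#' the whole search is `O(L * (N*K)^n)` -- polynomial in the feature and
#' threshold counts.
#'
#' @inheritParams hkm_count_subsets
#' @param L observation count (>= 1).
#' @param catalog optionally, a prebuilt [hkm_catalog()]; used to report the
#'   exact admissible-class count entering the (capped) formula bound.
#' @return A tibble with one row: `N`, `K`, `L`, `n`, `subset_count`,
#'   `formula_bound`, `per_pair_cost` and `total` (their product).
#' @export
hkm_complexity <- function(N, K, L, n, catalog = NULL) {
  stopifnot(L >= 1)
  subset_count <- hkm_count_subsets(N, K, n)
  if (is.null(catalog)) catalog <- default_catalog()
  n_classes <- sum(vapply(seq_len(min(n, catalog$max_vars)), function(m) {
    length(unique(catalog$by_n[[m]]$perm_class))
  }, integer(1)))
  formula_bound <- min(n_classes, 100)
  per_pair_cost <- as.numeric(L)
  tibble::tibble(
    N = N, K = K, L = L, n = n,
    subset_count = subset_count,
    formula_bound = formula_bound,
    per_pair_cost = per_pair_cost,
    total = subset_count * formula_bound * per_pair_cost
  )
}
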