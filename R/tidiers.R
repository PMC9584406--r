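#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a rule-learning fit
#'
#' @param x an `hkm_fit`.
#' @param ... unused.
#' @return A tibble with one row per learned rule: `rank`, `rule`, `score`,
#'   `size`, `ops`, `coverage` and the backing `features`.
#' @export
tidy.hkm_fit <- function(x, ...) {
  dplyr::select(x$models, "rank", "rule", "score", "size", "ops", "coverage",
                "features")
}

#' @rdname tidy.hkm_fit
#' @return `glance()` returns a one-row tibble: best score, metric, models
#'   kept, pairs scored, atom count and observation count.
#' @export
glance.hkm_fit <- function(x, ...) {
  tibble::tibble(
    best_score = if (nrow(x$models) > 0) x$models$score[1] else NA_real_,
    metric = x$config$metric,
    n_models = nrow(x$models),
    pairs_scored = x$pairs_scored,
    n_atoms = ncol(x$binarized$atoms),
    n_obs = length(x$binarized$target)
  )
}

#' Tidy an experiment report
#'
#' @param x an `hkm_experiments`.
#' @param ... unused.
#' @return Per-instance records: `instance`, `seed`, `train_score`,
#'   `test_score`, `S`, `rule` (plus CV/baseline columns when recorded).
#' @export
tidy.hkm_experiments <- function(x, ...) x$records

#' @rdname tidy.hkm_experiments
#' @return `glance()` returns a one-row tibble: instance count, skipped
#'   count, median train/test scores, median S and `P(S < 0.1)`.
#' @export
glance.hkm_experiments <- function(x, ...) {
  tibble::tibble(
    n_instances = nrow(x$records),
    skipped = x$skipped,
    metric = x$metric,
    median_train = stats::median(x$records$train_score),
    median_test = stats::median(x$records$test_score),
    median_S = stats::median(x$records$S),
    p_stable_10 = mean(x$records$S < 0.1)
  )
}

#' Plot the scores of the learned rules
#'
#' @param object an `hkm_fit`.
#' @param ... unused.
#' @return A ggplot: score against rule size for every kept rule.
#' @export
autoplot.hkm_fit <- function(object, ...) {
  df <- object$models
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$size), y = .data$score)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::labs(x = "rule size (variables)",
                  y = paste("train", object$config$metric),
                  title = "Learned human-computable rules") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the stability curve of an experiment report
#'
#' @param object an `hkm_experiments`.
#' @param what `"curve"` for the empirical P(S), `"histogram"` for the
#'   test-score distribution.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.hkm_experiments <- function(object, what = c("curve", "histogram"),
                                     ...) {
  what <- match.arg(what)
  if (what == "curve") {
    ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$s, y = .data$p)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "stability threshold S",
                    y = "P(stability factor < S)",
                    title = "Model stability") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$records, ggplot2::aes(x = .data$test_score)) +
      ggplot2::geom_histogram(binwidth = 0.01, boundary = 0) +
      ggplot2::labs(x = paste("test", object$metric), y = "instances",
                    title = "Test-score distribution") +
      ggplot2::theme_minimal()
  }
}

#' Plot a precision-recall summary by rule size
#'
#' @param pr the tibble returned by [hkm_pr_summary()].
#' @return A ggplot: one point per rule in precision-recall space, coloured
#'   by rule size.
#' @export
plot_pr_summary <- function(pr) {
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = factor(.data$size))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "rule size", title = "Rule quality by size") +
    ggplot2::xlim(0, 1) + ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
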