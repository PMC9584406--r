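#' Train/test stability factor
#'
#' The absolute relative change in the quality metric between train and
#' test: `S = |train - test| / train`. Zero means the model carried its
#' training quality to unseen data unchanged; large values flag
#' overfitting.
#'
#' @param train_score,test_score numeric scores (vectorized); every
#'   `train_score` must be positive.
#' @return Numeric vector of S values.
#' @examples
#' hkm_stability(0.8, 0.6)  # 0.25
#' @export
hkm_stability <- function(train_score, test_score) {
  if (any(train_score <= 0)) {
    stop("stability is undefined for a zero train score", call. = FALSE)
  }
  abs(train_score - test_score) / train_score
}

#' Empirical stability curve
#'
#' `P(s)` is the fraction of trained instances whose stability factor stays
#' strictly below `s` -- an empirical CDF over the experiment replicates.
#' Ideally `P` approaches 1 already at small `s`.
#'
#' @param S numeric vector of stability factors.
#' @param thresholds sorted grid of thresholds in `[0, 1]`.
#' @return A tibble with columns `s` and `p`.
#' @export
hkm_stability_curve <- function(S, thresholds = seq(0, 1, by = 0.01)) {
  stopifnot(length(S) >= 1, !is.unsorted(thresholds))
  tibble::tibble(s = thresholds,
                 p = vapply(thresholds, function(t) mean(S < t), numeric(1)))
}

#' Multi-instance train/test experiments
#'
#' Runs `n_exp` independent experiments: each draws a fresh seeded 80/20
#' train/test split, learns the rule list on the training rows (thresholds
#' included -- binarization happens inside the split), and records the best
#' rule's train score, its test score, and the stability factor. Instance
#' `i` uses seed `seed + i - 1`, so the whole report is reproducible from
#' the master seed. Instances whose training split contains a single class
#' are skipped and counted.
#'
#' Five-fold cross-validation scores on the training portion can be
#' recorded diagnostically with `cv = TRUE`; the 80/20 test score is the
#' authoritative quality measure. An optional `baseline` hook --
#' `function(train, test, target)` returning
#' `list(train_score, test_score)` -- slots any external model into the
#' identical split protocol.
#'
#' @param data a data frame with a Boolean target column.
#' @param target target column name.
#' @param n_exp number of experiment replicates.
#' @param seed master seed.
#' @param train_frac training fraction of each split.
#' @param cv record 5-fold CV train scores.
#' @param baseline optional hook for an external model.
#' @param ... passed to [hkm_fit()] (`k`, `sizes`, `m`, `metric`, ...).
#' @return An `hkm_experiments` object: `records` (one tibble row per
#'   instance: seed, train/test scores, `S`, best rule), `curve` (the
#'   empirical `P(S)` on a 0.01 grid), `histogram` (test-score counts in
#'   0.01-wide bins) and metadata. `tidy()` returns the records, `glance()`
#'   a one-row summary.
#' @export
hkm_experiments <- function(data, target = "outcome", n_exp = 30L, seed = 1L,
                            train_frac = 0.8, cv = FALSE, baseline = NULL,
                            ...) {
  stopifnot(n_exp >= 1, train_frac > 0, train_frac < 1)
  metric <- list(...)$metric
  if (is.null(metric)) metric <- "f1"
  L <- nrow(data)
  records <- list()
  skipped <- 0L
  for (i in seq_len(n_exp)) {
    inst_seed <- seed + i - 1L
    idx <- with_seed(inst_seed, sample.int(L, floor(train_frac * L)))
    train <- data[idx, ]
    test <- data[-idx, ]
    if (length(unique(train[[target]])) < 2L ||
        length(unique(test[[target]])) < 2L) {
      skipped <- skipped + 1L
      next
    }
    fit <- hkm_fit(train, target = target, ...)
    if (nrow(fit$models) == 0L) {
      skipped <- skipped + 1L
      next
    }
    train_score <- fit$models$score[1]
    pred <- predict(fit, newdata = test, model = 1L)
    test_score <- hkm_score(pred, test[[target]], metric = metric)
    rec <- tibble::tibble(
      instance = i, seed = inst_seed,
      train_score = train_score, test_score = test_score,
      S = hkm_stability(train_score, test_score),
      rule = fit$models$rule[1]
    )
    # exact names so that partial matching cannot capture `m` from the dots
    if (isTRUE(cv)) {
      rec$cv_score <- cv_score(train = train, target = target,
                               metric = metric, ...)
    }
    if (!is.null(baseline)) {
      b <- baseline(train, test, target)
      rec$baseline_train <- b$train_score
      rec$baseline_test <- b$test_score
    }
    records[[length(records) + 1L]] <- rec
  }
  records <- dplyr::bind_rows(records)
  if (nrow(records) == 0L) stop("every split was degenerate", call. = FALSE)
  structure(list(
    records = records,
    curve = hkm_stability_curve(records$S),
    histogram = score_histogram(records$test_score),
    n_exp = n_exp, seed = seed, skipped = skipped, metric = metric,
    config = list(target = target, train_frac = train_frac, ...)
  ), class = "hkm_experiments")
}

cv_score <- function(train, target, metric, ...) {
  L <- nrow(train)
  fold <- rep_len(1:5, L)
  scores <- vapply(1:5, function(f) {
    tr <- train[fold != f, ]
    ho <- train[fold == f, ]
    if (length(unique(tr[[target]])) < 2L) return(NA_real_)
    fit <- hkm_fit(tr, target = target, ...)
    if (nrow(fit$models) == 0L) return(NA_real_)
    hkm_score(predict(fit, newdata = ho, model = 1L), ho[[target]],
              metric = metric)
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

score_histogram <- function(scores, width = 0.01) {
  bin <- pmin(floor(scores / width), round(1 / width) - 1L)
  counts <- tabulate(bin + 1L, nbins = round(1 / width))
  tibble::tibble(
    bin_lo = (seq_along(counts) - 1L) * width,
    bin_hi = seq_along(counts) * width,
    count = counts
  )
}

#' @export
print.hkm_experiments <- function(x, ...) {
  cat("<hkm_experiments> ", nrow(x$records), " instances (", x$skipped,
      " skipped), metric = ", x$metric, "\n", sep = "")
  cat(sprintf("  train %s: median %.3f | test %s: median %.3f | median S: %.3f\n",
              x$metric, stats::median(x$records$train_score),
              x$metric, stats::median(x$records$test_score),
              stats::median(x$records$S)))
  invisible(x)
}

#' Precision-recall summary of the top rules by size
#'
#' Learns the top `m` rules separately at each size on the training rows
#' and scores every rule's precision and recall on the test rows: the
#' scatter shows how much predictive quality each extra variable of
#' human-rule complexity buys.
#'
#' @param train,test data frames sharing the feature columns and target.
#' @param target target column name.
#' @param sizes rule sizes to profile.
#' @param m rules kept per size.
#' @param ... passed to [hkm_fit()].
#' @return A tibble with `size`, `rank`, `rule`, `train_score`,
#'   `precision`, `recall`.
#' @export
hkm_pr_summary <- function(train, test, target = "outcome", sizes = 1:4,
                           m = 25L, ...) {
  purrr::map_dfr(sizes, function(sz) {
    fit <- hkm_fit(train, target = target, sizes = sz, m = m, ...)
    if (nrow(fit$models) == 0L) return(NULL)
    purrr::map_dfr(seq_len(nrow(fit$models)), function(r) {
      pred <- predict(fit, newdata = test, model = r)
      tibble::tibble(
        size = sz, rank = r, rule = fit$models$rule[r],
        train_score = fit$models$score[r],
        precision = hkm_score(pred, test[[target]], "precision"),
        recall = hkm_score(pred, test[[target]], "recall")
      )
    })
  })
}

#' Write / read an experiment report as JSON
#'
#' Serialises the per-instance records, the stability curve, the test-score
#' histogram and the run metadata; the reader round-trips the tables.
#'
#' @param x an `hkm_experiments` object.
#' @param path output file.
#' @return `hkm_write_report()` returns `path` invisibly;
#'   `hkm_read_report()` a list of tibbles (`records`, `curve`,
#'   `histogram`) plus metadata.
#' @export
hkm_write_report <- function(x, path) {
  stopifnot(inherits(x, "hkm_experiments"))
  payload <- list(
    metric = x$metric, n_exp = x$n_exp, seed = x$seed, skipped = x$skipped,
    records = x$records, curve = x$curve, histogram = x$histogram
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname hkm_write_report
#' @export
hkm_read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$records <- tibble::as_tibble(raw$records)
  raw$curve <- tibble::as_tibble(raw$curve)
  raw$histogram <- tibble::as_tibble(raw$histogram)
  raw
}
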