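#' Confusion-matrix score of Boolean predictions
#'
#' @param predictions,target logical vectors of equal length; `NA`
#'   predictions (abstentions on rows with missing model inputs) are
#'   dropped together with their targets.
#' @param metric one of `"f1"`, `"precision"`, `"recall"`, `"accuracy"`.
#' @return A number in `[0, 1]`; conventionally 0 when the denominator is
#'   empty (e.g. F1 with no true or predicted positives).
#' @examples
#' hkm_score(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
#'           c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))  # TP=2 FP=2 FN=1
#' @export
hkm_score <- function(predictions, target,
                      metric = c("f1", "precision", "recall", "accuracy")) {
  metric <- match.arg(metric)
  if (length(predictions) != length(target)) {
    stop("predictions and target differ in length", call. = FALSE)
  }
  keep <- !is.na(predictions)
  p <- predictions[keep]
  y <- target[keep]
  tp <- sum(p & y)
  fp <- sum(p & !y)
  fn <- sum(!p & y)
  tn <- sum(!p & !y)
  metric_from_counts(tp, fp, fn, tn, metric)
}

metric_from_counts <- function(tp, fp, fn, tn, metric) {
  num <- switch(metric,
    f1 = 2 * tp, precision = tp, recall = tp, accuracy = tp + tn)
  den <- switch(metric,
    f1 = 2 * tp + fp + fn, precision = tp + fp, recall = tp + fn,
    accuracy = tp + fp + fn + tn)
  out <- ifelse(den == 0, 0, num / den)
  as.numeric(out)
}

#' Exhaustively learn the best human-computable rules
#'
#' Scans every admissible (formula, atom-subset) pair: for each rule size
#' `n` it enumerates all size-`n` atom subsets (never combining two atoms
#' derived from the same source feature), drops subsets whose fully observed
#' row fraction falls below `min_coverage`, and scores every catalog formula
#' of that size on the covered rows, keeping the `m` best models overall.
#' Scoring uses the truth-table identity of each formula: rows are bucketed
#' by their joint atom assignment once per subset, after which every
#' formula's confusion matrix is a constant-time lookup, independent of the
#' observation count.
#'
#' The search is deterministic: identical data and settings produce an
#' identical model list. Ties are broken by higher score, fewer variables,
#' fewer operators, higher coverage, then the rule's rendered text.
#'
#' @param data a data frame with a Boolean target column, or an
#'   [hkm_binarize()] result.
#' @param target target column name (ignored when `data` is already
#'   binarized).
#' @param k thresholds per numeric feature.
#' @param sizes rule sizes to search, subset of 1..4.
#' @param m number of models to keep (the top-M stack; 10-50 is typical).
#' @param metric scoring metric; F1 by default.
#' @param min_coverage minimum fraction of fully observed rows for a
#'   candidate subset to be scored.
#' @param constraints an [hkm_constraints()] object.
#' @param subsample optional row count; when smaller than the data, a
#'   seeded random subsample is used for scoring.
#' @param seed seed for the subsample draw (required with `subsample`).
#' @return An `hkm_fit` object; `tidy()` returns the model table, one row
#'   per rule with its rendered text, score, coverage, size and operator
#'   count.
#' @examples
#' d <- hkm_generate_planted(hkm_planted_spec(n_obs = 300), seed = 1)
#' fit <- hkm_fit(d, target = "outcome", sizes = 1:3, m = 5)
#' tidy(fit)
#' @export
hkm_fit <- function(data, target = "outcome", k = 3L, sizes = 1:4, m = 25L,
                    metric = c("f1", "precision", "recall", "accuracy"),
                    min_coverage = 0.8, constraints = hkm_constraints(),
                    subsample = NULL, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(m >= 1)
  binarized <- if (inherits(data, "hkm_binarized")) data
               else hkm_binarize(data, target = target, K = k)
  if (!is.null(subsample) && subsample < length(binarized$target)) {
    if (is.null(seed)) stop("subsampling requires a seed", call. = FALSE)
    rows <- with_seed(seed, sort(sample.int(length(binarized$target), subsample)))
    binarized <- subset_rows(binarized, rows)
  }
  if (length(unique(binarized$target)) < 2L) {
    stop("target has a single class", call. = FALSE)
  }
  catalog <- hkm_catalog(constraints)
  sizes <- sort(unique(as.integer(sizes)))
  stopifnot(all(sizes >= 1), all(sizes <= catalog$max_vars))

  pool <- empty_pool()
  cutoff <- -Inf
  n_atoms <- ncol(binarized$atoms)
  feat_of <- binarized$info$feature
  y <- binarized$target
  scanned <- 0L

  for (size in sizes) {
    if (size > n_atoms) next
    tb <- catalog$by_n[[size]]
    if (nrow(tb) == 0L) next
    bits <- attr(tb, "bits_matrix")           # 2^size x n_tables
    subsets <- utils::combn(n_atoms, size)
    pow <- 2^(seq_len(size) - 1L)
    for (ci in seq_len(ncol(subsets))) {
      atoms <- subsets[, ci]
      if (anyDuplicated(feat_of[atoms])) next  # sibling atoms never co-occur
      cov <- hkm_coverage(binarized, atoms)
      if (cov$coverage < min_coverage || !any(cov$rows)) next
      keep <- cov$rows
      cells <- as.integer(binarized$atoms[keep, atoms, drop = FALSE] %*% pow)
      npos <- tabulate_cells(cells[y[keep]], 2^size)
      nneg <- tabulate_cells(cells[!y[keep]], 2^size)
      tp <- as.numeric(crossprod(bits, npos))
      fp <- as.numeric(crossprod(bits, nneg))
      fn <- sum(npos) - tp
      tn <- sum(nneg) - fp
      scores <- metric_from_counts(tp, fp, fn, tn, metric)
      scanned <- scanned + length(scores)
      hits <- which(scores >= cutoff)
      if (length(hits) == 0L) next
      pool <- append_pool(pool, binarized, tb, hits, scores[hits], atoms,
                          cov$coverage, size)
      if (nrow(pool) > 4L * m) {
        pool <- prune_pool(pool, m)
        cutoff <- pool$score[nrow(pool)]
      }
    }
  }
  pool <- prune_pool(pool, m)
  if (nrow(pool) == 0L) {
    warning("no atom subset met the minimum coverage; returning no models",
            call. = FALSE)
  }
  models <- dplyr::mutate(pool, rank = dplyr::row_number()) |>
    dplyr::relocate("rank")
  structure(list(
    models = models,
    binarized = binarized,
    config = list(k = k, sizes = sizes, m = m, metric = metric,
                  min_coverage = min_coverage, constraints = constraints,
                  subsample = subsample, seed = seed),
    pairs_scored = scanned
  ), class = "hkm_fit")
}

tabulate_cells <- function(cells, n_bins) {
  tabulate(cells + 1L, nbins = n_bins)
}

empty_pool <- function() {
  tibble::tibble(rule = character(0), score = numeric(0), size = integer(0),
                 ops = integer(0), coverage = numeric(0),
                 formula = list(), atoms = list(), features = list(),
                 key = character(0))
}

append_pool <- function(pool, binarized, tb, hits, scores, atoms, coverage,
                        size) {
  info <- binarized$info
  atom_idx <- atoms
  feat <- info$feature[atom_idx]
  rows <- purrr::map2_dfr(hits, scores, function(h, s) {
    f <- tb$formula[[h]]
    tibble::tibble(
      rule = render_model(f, info, atom_idx),
      score = s,
      size = size,
      ops = tb$ops[h],
      coverage = coverage,
      formula = list(f),
      atoms = list(atom_idx),
      features = list(feat),
      key = tb$key[h]
    )
  })
  dplyr::bind_rows(pool, rows)
}

prune_pool <- function(pool, m) {
  if (nrow(pool) == 0L) return(pool)
  ord <- order(-pool$score, pool$size, pool$ops, -pool$coverage, pool$rule,
               method = "radix")
  pool[ord, ][seq_len(min(m, nrow(pool))), ]
}

# substitute atom labels into the formula; NOT over an atom is absorbed into
# the atom's complementary reading (age > 60 vs age <= 60)
render_model <- function(f, info, atoms) {
  lab <- info$label[atoms]
  neg <- info$label_neg[atoms]
  absorb <- function(node) {
    if (node$kind == "not" && node$child$kind == "var") {
      return(new_formula(list(kind = "var", index = node$child$index,
                              flip = TRUE)))
    }
    if (node$kind == "not") return(new_formula(list(kind = "not",
                                                    child = absorb(node$child))))
    if (node$kind == "var") return(node)
    node$children <- lapply(node$children, absorb)
    node
  }
  g <- absorb(f)
  render_labeled(g, lab, neg)
}

render_labeled <- function(f, lab, neg, top = TRUE) {
  out <- switch(f$kind,
    var = if (isTRUE(f$flip)) neg[f$index] else lab[f$index],
    not = paste0("NOT (", render_labeled(f$child, lab, neg, top = TRUE), ")"),
    and = paste(vapply(f$children, render_labeled, character(1), lab = lab,
                       neg = neg, top = FALSE), collapse = " AND "),
    or = paste(vapply(f$children, render_labeled, character(1), lab = lab,
                      neg = neg, top = FALSE), collapse = " OR "),
    sum = paste0("SUM(", paste(vapply(f$children, render_labeled, character(1),
                                      lab = lab, neg = neg, top = FALSE),
                               collapse = ", "), ") >= ", f$t)
  )
  if (!top && f$kind %in% c("and", "or", "sum")) paste0("(", out, ")") else out
}

#' @export
print.hkm_fit <- function(x, n = 5, ...) {
  cat("<hkm_fit> ", nrow(x$models), " models (", x$pairs_scored,
      " formula-subset pairs scored, metric = ", x$config$metric, ")\n",
      sep = "")
  shown <- utils::head(x$models, n)
  for (i in seq_len(nrow(shown))) {
    cat(sprintf("  %2d. [%.4f] %s\n", shown$rank[i], shown$score[i],
                shown$rule[i]))
  }
  if (nrow(x$models) > n) cat("  ... ", nrow(x$models) - n, " more\n", sep = "")
  invisible(x)
}

#' Predict with a learned rule
#'
#' Evaluates one of the fitted rules row by row. Rows with a missing value
#' among the rule's atoms abstain (`NA`): missing cells are never imputed.
#'
#' @param object an `hkm_fit`.
#' @param newdata a data frame with the source feature columns; defaults to
#'   the training data.
#' @param model rank of the rule to apply (1 = best).
#' @param ... unused.
#' @return Logical vector with `NA` abstentions.
#' @export
predict.hkm_fit <- function(object, newdata = NULL, model = 1L, ...) {
  stopifnot(model >= 1, model <= nrow(object$models))
  row <- object$models[model, ]
  atoms <- row$atoms[[1]]
  if (is.null(newdata)) {
    vals <- object$binarized$atoms[, atoms, drop = FALSE]
    msk <- object$binarized$mask[, atoms, drop = FALSE]
  } else {
    applied <- apply_atoms(object$binarized$info[atoms, ], newdata)
    vals <- applied$atoms
    msk <- applied$mask
  }
  out <- hkm_evaluate(row$formula[[1]], vals)
  out[apply(msk, 1, any)] <- NA
  out
}

# recompute atom columns (and their missingness) on new rows
apply_atoms <- function(info, data) {
  missing_feats <- setdiff(info$feature, names(data))
  if (length(missing_feats) > 0L) {
    stop("newdata lacks feature(s): ", paste(missing_feats, collapse = ", "),
         call. = FALSE)
  }
  L <- nrow(data)
  atoms <- matrix(FALSE, L, nrow(info))
  mask <- matrix(FALSE, L, nrow(info))
  for (j in seq_len(nrow(info))) {
    r <- info[j, ]
    col <- data[[r$feature]]
    val <- switch(r$type,
      boolean = col,
      threshold = col > r$threshold,
      indicator = as.character(col) == r$level,
      missing = is.na(col)
    )
    if (r$type != "missing") {
      mask[, j] <- is.na(val)
      val[is.na(val)] <- FALSE
    }
    atoms[, j] <- val
  }
  list(atoms = atoms, mask = mask)
}

subset_rows <- function(binarized, rows) {
  structure(list(
    atoms = binarized$atoms[rows, , drop = FALSE],
    mask = binarized$mask[rows, , drop = FALSE],
    info = binarized$info,
    target = binarized$target[rows],
    target_name = binarized$target_name
  ), class = "hkm_binarized")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Write / read a learned model list as JSON
#'
#' The model file is the deliverable knowledge: a JSON array of rules with
#' their rendered text (real feature names and thresholds), score, metric
#' and coverage. `hkm_read_models()` round-trips it into a tibble.
#'
#' @param fit an `hkm_fit`.
#' @param path output file.
#' @return `hkm_write_models()` returns `path` invisibly;
#'   `hkm_read_models()` a tibble.
#' @export
hkm_write_models <- function(fit, path) {
  stopifnot(inherits(fit, "hkm_fit"))
  out <- list(
    config = fit$config[c("k", "sizes", "m", "metric", "min_coverage")],
    models = purrr::pmap(
      fit$models[, c("rank", "rule", "score", "size", "ops", "coverage")],
      function(rank, rule, score, size, ops, coverage) {
        list(rank = rank, rule = rule, metric = fit$config$metric,
             score = score, size = size, operators = ops, coverage = coverage)
      })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname hkm_write_models
#' @export
hkm_read_models <- function(path) {
  raw <- jsonlite::read_json(path)
  purrr::map_dfr(raw$models, tibble::as_tibble)
}
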