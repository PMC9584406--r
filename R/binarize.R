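#' Propose candidate thresholds for a numeric feature
#'
#' Places up to `K` cut points at evenly spaced quantiles of the non-missing
#' values and rounds each to two significant digits, so the resulting rules
#' read like numbers a person would actually remember (`age > 60`, not
#' `age > 59.73`). Duplicate cuts after rounding are dropped, as are cuts
#' that would make a constant atom.
#'
#' @param column numeric vector (may contain `NA`).
#' @param K maximum number of thresholds (>= 1).
#' @param feature feature name recorded in the rules.
#' @return A tibble of threshold rules with columns `feature`, `direction`
#'   (`">"`; the complementary `"<="` costs nothing and is produced by
#'   negation) and `threshold`. Empty for constant or all-missing columns.
#' @examples
#' hkm_thresholds(1:100, K = 3)
#' @export
hkm_thresholds <- function(column, K = 3L, feature = "x") {
  stopifnot(is.numeric(column), K >= 1)
  vals <- column[!is.na(column)]
  empty <- tibble::tibble(feature = character(0), direction = character(0),
                          threshold = numeric(0))
  if (length(unique(vals)) < 2L) return(empty)
  probs <- seq_len(K) / (K + 1)
  cuts <- unique(signif(stats::quantile(vals, probs, names = FALSE, type = 7), 2))
  # a cut at or beyond the extremes would binarize to a constant
  cuts <- cuts[cuts >= min(vals) & cuts < max(vals)]
  if (length(cuts) == 0L) return(empty)
  tibble::tibble(feature = feature, direction = ">", threshold = cuts)
}

#' Binarize a raw dataset into candidate Boolean atoms
#'
#' Converts every feature column into Boolean atoms while preserving
#' missingness: numeric columns become up to `K` threshold atoms
#' (`value > cut`), logical columns pass through, factors and character
#' columns become one indicator atom per level, and any column containing
#' missing cells additionally yields an `is missing` indicator. Missing
#' source cells are never imputed: they are carried into a mask, and rows
#' with masked cells among a candidate rule's atoms are excluded when that
#' rule is scored (see [hkm_coverage()]).
#'
#' Atoms derived from the same source column are recorded as siblings; the
#' search never puts two siblings into one rule.
#'
#' @param data a data frame.
#' @param target name of the Boolean target column (logical, or 0/1
#'   numeric); must be complete.
#' @param K thresholds per numeric feature.
#' @return An `hkm_binarized` object: list with `atoms` (logical matrix,
#'   observations x atoms; `FALSE` where masked), `mask` (logical matrix,
#'   `TRUE` where the source cell was missing), `info` (tibble of atom
#'   provenance: `atom`, `label`, `label_neg`, `feature`, `type`,
#'   `direction`, `threshold`, `level`), `target` (logical vector) and
#'   `target_name`.
#' @export
hkm_binarize <- function(data, target, K = 3L) {
  stopifnot(is.data.frame(data))
  if (!target %in% names(data)) {
    stop("target column '", target, "' not found", call. = FALSE)
  }
  y <- data[[target]]
  if (is.numeric(y) && all(y %in% c(0, 1))) y <- y == 1
  if (!is.logical(y) || anyNA(y)) {
    stop("target must be Boolean (logical or 0/1) with no missing values",
         call. = FALSE)
  }
  features <- setdiff(names(data), target)
  rules <- purrr::map_dfr(features, function(nm) {
    col <- data[[nm]]
    if (is.logical(col)) {
      tibble::tibble(feature = nm, type = "boolean", direction = NA_character_,
                     threshold = NA_real_, level = NA_character_)
    } else if (is.numeric(col)) {
      th <- hkm_thresholds(col, K = K, feature = nm)
      if (nrow(th) == 0L) return(NULL)
      tibble::tibble(feature = nm, type = "threshold", direction = th$direction,
                     threshold = th$threshold, level = NA_character_)
    } else {
      lv <- sort(unique(as.character(col[!is.na(col)])))
      if (length(lv) == 0L) return(NULL)
      tibble::tibble(feature = nm, type = "indicator", direction = NA_character_,
                     threshold = NA_real_, level = lv)
    }
  })
  # a missingness indicator for every source column with missing cells
  miss_cols <- features[vapply(features, function(nm) anyNA(data[[nm]]), logical(1))]
  rules <- dplyr::bind_rows(
    rules,
    tibble::tibble(feature = miss_cols, type = "missing",
                   direction = NA_character_, threshold = NA_real_,
                   level = NA_character_)
  )
  if (nrow(rules) == 0L) stop("no binarizable feature columns", call. = FALSE)

  L <- nrow(data)
  atoms <- matrix(FALSE, L, nrow(rules))
  mask <- matrix(FALSE, L, nrow(rules))
  labels <- character(nrow(rules))
  labels_neg <- character(nrow(rules))
  for (j in seq_len(nrow(rules))) {
    r <- rules[j, ]
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
    labels[j] <- switch(r$type,
      boolean = r$feature,
      threshold = paste0(r$feature, " > ", format(r$threshold)),
      indicator = paste0(r$feature, " = ", r$level),
      missing = paste0(r$feature, " is missing")
    )
    labels_neg[j] <- switch(r$type,
      boolean = paste("NOT", r$feature),
      threshold = paste0(r$feature, " <= ", format(r$threshold)),
      indicator = paste0(r$feature, " != ", r$level),
      missing = paste0(r$feature, " is present")
    )
  }
  info <- dplyr::bind_cols(
    tibble::tibble(atom = seq_len(nrow(rules)), label = labels,
                   label_neg = labels_neg),
    rules
  )
  structure(list(atoms = atoms, mask = mask, info = info, target = y,
                 target_name = target),
            class = "hkm_binarized")
}

#' @export
print.hkm_binarized <- function(x, ...) {
  cat("<hkm_binarized> ", length(x$target), " observations, ",
      ncol(x$atoms), " atoms from ", length(unique(x$info$feature)),
      " features; positives: ", round(100 * mean(x$target), 1), "%\n", sep = "")
  invisible(x)
}

#' Row coverage of an atom subset
#'
#' Rows with a missing source cell under any of the chosen atoms are
#' excluded rather than imputed; candidate rules are scored only on fully
#' observed rows. Coverage is the fraction retained, and rules are searched
#' preferentially where that fraction is high.
#'
#' @param binarized an [hkm_binarize()] result.
#' @param atoms integer vector of atom indices.
#' @return List with `rows` (logical keep filter) and `coverage` (fraction).
#' @export
hkm_coverage <- function(binarized, atoms) {
  stopifnot(inherits(binarized, "hkm_binarized"),
            all(atoms >= 1), all(atoms <= ncol(binarized$atoms)))
  sub <- binarized$mask[, atoms, drop = FALSE]
  keep <- !apply(sub, 1, any)
  list(rows = keep, coverage = mean(keep))
}

#' Read a delimited file for rule learning
#'
#' Thin wrapper over [readr::read_delim()] that applies declared NA
#' sentinels and optional column-type overrides, returning a tibble ready
#' for [hkm_binarize()].
#'
#' @param path CSV/TSV file path.
#' @param na character vector of NA sentinels.
#' @param col_types optional readr column specification.
#' @param delim field delimiter; guessed from the extension by default.
#' @return A tibble.
#' @export
hkm_read <- function(path, na = c("", "NA"), col_types = NULL, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::read_delim(path, delim = delim, na = na, col_types = col_types,
                    show_col_types = FALSE)
}

#' Binarization report
#'
#' @param binarized an [hkm_binarize()] result.
#' @param path optional file path; when given, the report is also written
#'   as JSON.
#' @return A tibble: one row per atom with its provenance and missingness
#'   fraction.
#' @export
hkm_binarize_report <- function(binarized, path = NULL) {
  stopifnot(inherits(binarized, "hkm_binarized"))
  out <- dplyr::mutate(binarized$info,
                       missing_frac = colMeans(binarized$mask),
                       true_frac = colMeans(binarized$atoms & !binarized$mask))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  out
}
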