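#' Disjunctive normal form of a truth table
#'
#' Builds the canonical minterm expansion: one full conjunction per true row,
#' joined by OR. The result reproduces the table exactly but is usually far
#' from admissible (variables repeat across minterms and the operator count
#' grows with the number of true rows); it is the raw form that catalog
#' simplification shortens.
#'
#' @param table an `hkm_truth_table` with at least one true and one false row.
#' @return An `hkm_formula`.
#' @export
hkm_dnf <- function(table) {
  stopifnot(inherits(table, "hkm_truth_table"))
  if (all(table$bits) || !any(table$bits)) {
    stop("constant table has no DNF over its variables", call. = FALSE)
  }
  rows <- which(table$bits) - 1L
  minterms <- lapply(rows, function(r) {
    lits <- lapply(seq_len(table$n), function(i) {
      if (bitwAnd(r, bitwShiftL(1L, i - 1L)) > 0L) hkm_var(i) else hkm_not(hkm_var(i))
    })
    if (length(lits) == 1L) lits[[1]] else do.call(hkm_and, lits)
  })
  if (length(minterms) == 1L) minterms[[1]] else do.call(hkm_or, minterms)
}

# -- exhaustive catalog construction ----------------------------------------
#
# Dynamic programme over (variable set, operator cost). Every admissible
# expression is read-once (disjoint child variable sets), so entries are
# grouped by the exact set of variables they use; combining entries only adds
# operators, so levels can be processed in increasing cost order. Per
# (variable set, semantics) only the cheapest expression is kept, ties broken
# by the lexicographically smallest rendering, which makes construction
# deterministic.

build_entries <- function(constraints) {
  max_vars <- constraints$max_vars
  max_ops <- constraints$max_ops
  allowed <- constraints$allowed_ops
  full_rows <- assignment_matrix(max_vars)

  entries <- list()   # each: list(f, mask, cost, kind, key, string)
  index <- new.env(parent = emptyenv())  # "mask|key" -> entry position

  mk_entry <- function(f, mask, cost) {
    bits <- hkm_evaluate(f, full_rows)
    list(f = f, mask = mask, cost = cost, kind = f$kind,
         key = table_key(bits), string = format(f))
  }
  # keep the cheapest (then smallest-string) entry per (mask, semantics)
  offer <- function(cand) {
    id <- paste0(cand$mask, "|", cand$key)
    old <- index[[id]]
    if (is.null(old)) {
      entries[[length(entries) + 1L]] <<- cand
      index[[id]] <<- length(entries)
    } else if (cand$cost < entries[[old]]$cost ||
               (cand$cost == entries[[old]]$cost &&
                cand$string < entries[[old]]$string)) {
      entries[[old]] <<- cand
    }
    invisible(NULL)
  }

  for (i in seq_len(max_vars)) {
    offer(mk_entry(hkm_var(i), bitwShiftL(1L, i - 1L), 0L))
  }

  # unordered selections of k stored entries with disjoint variable sets and
  # a given total child cost
  pick <- function(pool, k, cost_left, start, mask_used, acc, found) {
    if (k == 0L) {
      if (cost_left == 0L) found[[length(found) + 1L]] <- acc
      return(found)
    }
    if (start > length(pool)) return(found)
    for (j in start:length(pool)) {
      e <- pool[[j]]
      if (e$cost > cost_left) next
      if (bitwAnd(e$mask, mask_used) != 0L) next
      found <- pick(pool, k - 1L, cost_left - e$cost, j + 1L,
                    bitwOr(mask_used, e$mask), c(acc, list(e)), found)
    }
    found
  }

  for (level in seq_len(max_ops)) {
    snapshot <- entries
    new_cands <- list()
    add <- function(f, mask) {
      new_cands[[length(new_cands) + 1L]] <<- mk_entry(f, mask, level)
    }
    if ("not" %in% allowed) {
      for (e in snapshot) {
        if (e$cost == level - 1L && e$kind != "not") {
          add(hkm_not(e$f), e$mask)
        }
      }
    }
    for (conn in if (max_vars >= 2L) intersect(c("and", "or"), allowed) else character(0)) {
      for (k in 2:min(max_vars, level + 1L)) {
        child_budget <- level - (k - 1L)
        if (child_budget < 0L) next
        pool <- Filter(function(e) e$kind != conn && e$cost <= child_budget,
                       snapshot)
        for (sel in pick(pool, k, child_budget, 1L, 0L, list(), list())) {
          f <- do.call(if (conn == "and") hkm_and else hkm_or,
                       lapply(sel, `[[`, "f"))
          add(f, Reduce(bitwOr, vapply(sel, `[[`, integer(1), "mask")))
        }
      }
    }
    if ("sum" %in% allowed && max_vars >= 3L) {
      for (k in 3:max_vars) {
        child_budget <- level - 1L
        # SUM counts bare variables, not sub-expressions
        pool <- Filter(function(e) e$kind == "var" && e$cost <= child_budget,
                       snapshot)
        for (sel in pick(pool, k, child_budget, 1L, 0L, list(), list())) {
          for (t in 2:(k - 1L)) {
            f <- do.call(hkm_sum, c(lapply(sel, `[[`, "f"), list(t = t)))
            add(f, Reduce(bitwOr, vapply(sel, `[[`, integer(1), "mask")))
          }
        }
      }
    }
    for (cand in new_cands) offer(cand)
  }
  entries
}

perm_class_key <- function(bits, n) {
  perms <- perms_of(n)
  r <- 0:(2^n - 1)
  best <- NULL
  for (p in perms) {
    s <- integer(2^n)
    for (j in seq_len(n)) {
      s <- s + bitwShiftL(as.integer(bitwAnd(r, bitwShiftL(1L, p[j] - 1L)) > 0L),
                          j - 1L)
    }
    key <- table_key(bits[s + 1L])
    if (is.null(best) || key < best) best <- key
  }
  best
}

perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- perms_of(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Build the catalog of minimal admissible expressions
#'
#' Exhaustively enumerates every admissible expression tree over up to
#' `max_vars` variables (all operator kinds, arities, SUM thresholds over
#' bare variables, and NOT placements within the operator budget), computes
#' each one's truth table,
#' and keeps the shortest expression per table. Truth tables no admissible
#' expression can produce (XOR, for instance, which needs a repeated
#' variable) are simply absent. Only proper tables -- those depending on all
#' their variables -- are catalogued at each size; a function with a dummy
#' variable is found at its true, smaller size.
#'
#' The catalog is the model class of the rule search: per rule size `n` it
#' holds one minimal formula per reachable labeled truth table, plus the
#' table's equivalence class under variable permutation. Construction is
#' deterministic and cached per constraints object.
#'
#' @param constraints an [hkm_constraints()] object.
#' @return An `hkm_catalog`: list with `constraints`, `max_vars`, and
#'   `by_n` -- one tibble per size `n` with columns `key` (bit string),
#'   `formula` (list), `ops`, `string`, `perm_class`, plus a logical
#'   `bits_matrix` (`2^n` rows, one column per table) used by the searcher.
#' @examples
#' cat1 <- hkm_catalog(hkm_constraints(max_vars = 2))
#' cat1$by_n[[1]]$string  # the two proper single-variable rules
#' @export
hkm_catalog <- function(constraints = hkm_constraints()) {
  cache_id <- paste(constraints$max_vars, constraints$max_ops,
                    paste(sort(constraints$allowed_ops), collapse = ","),
                    sep = "|")
  cached <- catalog_cache[[cache_id]]
  if (!is.null(cached)) return(cached)

  entries <- build_entries(constraints)
  by_n <- vector("list", constraints$max_vars)
  for (m in seq_len(constraints$max_vars)) {
    full_mask <- bitwShiftL(1L, m) - 1L
    sub <- Filter(function(e) e$mask == full_mask, entries)
    tabs <- lapply(sub, function(e) hkm_truth_table(e$f, n = m))
    proper <- vapply(tabs, hkm_is_proper, logical(1))
    sub <- sub[proper]
    tabs <- tabs[proper]
    keys <- vapply(tabs, function(tt) table_key(tt$bits), character(1))
    ord <- order(keys, method = "radix")
    sub <- sub[ord]
    tabs <- tabs[ord]
    keys <- keys[ord]
    tb <- tibble::tibble(
      key = keys,
      formula = lapply(sub, `[[`, "f"),
      ops = vapply(sub, `[[`, integer(1), "cost"),
      string = vapply(sub, `[[`, character(1), "string"),
      perm_class = vapply(tabs, function(tt) perm_class_key(tt$bits, m),
                          character(1))
    )
    bits_matrix <- if (nrow(tb) > 0) {
      vapply(tabs, `[[`, logical(2^m), "bits")
    } else {
      matrix(logical(0), nrow = 2^m, ncol = 0)
    }
    attr(tb, "bits_matrix") <- bits_matrix
    by_n[[m]] <- tb
  }
  out <- structure(list(constraints = constraints,
                        max_vars = constraints$max_vars, by_n = by_n),
                   class = "hkm_catalog")
  catalog_cache[[cache_id]] <- out
  out
}

catalog_cache <- new.env(parent = emptyenv())

default_catalog <- function() hkm_catalog(hkm_constraints())

#' Shortest admissible expression for a truth table
#'
#' @param table an `hkm_truth_table` (non-constant).
#' @param catalog an [hkm_catalog()] covering `table$n`.
#' @return The minimal `hkm_formula` with that table, or `NULL` when no
#'   admissible expression realises it.
#' @export
hkm_simplify <- function(table, catalog = hkm_catalog()) {
  stopifnot(inherits(table, "hkm_truth_table"))
  if (all(table$bits) || !any(table$bits)) {
    stop("constant table cannot be simplified", call. = FALSE)
  }
  stopifnot(table$n <= catalog$max_vars)
  tb <- catalog$by_n[[table$n]]
  hit <- match(table_key(table$bits), tb$key)
  if (is.na(hit)) NULL else tb$formula[[hit]]
}

#' Count permutation-distinct admissible function classes
#'
#' Reduces each size's reachable proper truth tables modulo variable
#' permutation (relabeling variables does not change what a rule says) and
#' sums the class counts over all sizes. Under the default constraints the
#' total stays below one hundred -- the reason the formula term in the
#' search-cost estimate can be treated as a constant.
#'
#' @param catalog an [hkm_catalog()].
#' @return Integer class count.
#' @export
hkm_semantic_classes <- function(catalog = hkm_catalog()) {
  sum(vapply(catalog$by_n, function(tb) length(unique(tb$perm_class)),
             integer(1)))
}

#' @export
print.hkm_catalog <- function(x, ...) {
  counts <- vapply(x$by_n, nrow, integer(1))
  cat("<hkm_catalog> max_vars = ", x$max_vars,
      ", max_ops = ", x$constraints$max_ops, "\n", sep = "")
  cat("  labeled tables by size: ", paste(counts, collapse = ", "), "\n",
      sep = "")
  cat("  permutation-distinct classes: ", hkm_semantic_classes(x), "\n",
      sep = "")
  invisible(x)
}

#' Export / import a catalog as JSON
#'
#' Writes the table-to-formula mapping (bit string keyed, least significant
#' bit = `x1`) for inspection and regression fixtures, and reads it back by
#' re-parsing the formula strings.
#'
#' @param catalog an [hkm_catalog()].
#' @param path file path.
#' @return `hkm_catalog_export()` returns `path` invisibly;
#'   `hkm_catalog_import()` returns a tibble with `n`, `key`, `string`,
#'   `ops` and a parsed `formula` list-column.
#' @export
hkm_catalog_export <- function(catalog, path) {
  payload <- purrr::imap(catalog$by_n, function(tb, m) {
    purrr::map2(tb$key, tb$string, function(k, s) list(key = k, string = s)) |>
      stats::setNames(tb$key)
  })
  names(payload) <- paste0("n", seq_along(payload))
  jsonlite::write_json(purrr::map(payload, function(x) purrr::map(x, "string")),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname hkm_catalog_export
#' @export
hkm_catalog_import <- function(path) {
  raw <- jsonlite::read_json(path)
  purrr::imap_dfr(raw, function(tab, nm) {
    n <- as.integer(sub("^n", "", nm))
    tibble::tibble(
      n = n,
      key = names(tab),
      string = unlist(tab, use.names = FALSE)
    )
  }) |>
    dplyr::mutate(
      formula = purrr::map(.data$string, hkm_parse),
      ops = purrr::map_int(.data$formula, hkm_operator_count)
    )
}
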