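#' Boolean formula constructors
#'
#' A human-knowledge formula is an expression tree over Boolean variables
#' `x1, x2, ...` built from four node kinds: variable references, negation,
#' n-ary conjunction/disjunction, and a thresholded Boolean SUM (an M-of-N
#' count: true when at least `t` of its inputs are true). Admissible rules
#' (see [hkm_constraints()]) use at most four variables, each at most once,
#' and at most four operators.
#'
#' `hkm_and()` and `hkm_or()` flatten nested nodes of the same kind and sort
#' their children into a canonical order, so structurally equal formulas
#' render identically. `hkm_sum()` requires `2 <= t <= arity - 1`: a count
#' threshold of 1 is an OR and a threshold equal to the arity is an AND, and
#' both must be written as such.
#'
#' @param i positive integer variable index (1-based; rendered `x<i>`).
#' @param x,... child formulas.
#' @param t integer count threshold for `hkm_sum()`.
#' @return An object of class `hkm_formula`.
#' @examples
#' f <- hkm_or(hkm_and(hkm_var(1), hkm_var(2)), hkm_not(hkm_var(3)))
#' format(f)
#' hkm_operator_count(f)
#' @name hkm_formula
NULL

new_formula <- function(node) structure(node, class = "hkm_formula")

#' @rdname hkm_formula
#' @export
hkm_var <- function(i) {
  i <- as.integer(i)
  stopifnot(length(i) == 1L, !is.na(i), i >= 1L)
  new_formula(list(kind = "var", index = i))
}

#' @rdname hkm_formula
#' @export
hkm_not <- function(x) {
  stopifnot(inherits(x, "hkm_formula"))
  new_formula(list(kind = "not", child = x))
}

#' @rdname hkm_formula
#' @export
hkm_and <- function(...) nary_node("and", list(...))

#' @rdname hkm_formula
#' @export
hkm_or <- function(...) nary_node("or", list(...))

#' @rdname hkm_formula
#' @export
hkm_sum <- function(..., t) {
  children <- lapply(list(...), as_hkm_formula)
  t <- as.integer(t)
  if (length(children) < 3L) {
    stop("SUM needs at least 3 children (t = 1 is OR, t = arity is AND)",
         call. = FALSE)
  }
  if (t < 2L || t > length(children) - 1L) {
    stop("SUM threshold must satisfy 2 <= t <= arity - 1", call. = FALSE)
  }
  new_formula(list(kind = "sum", children = sort_children(children), t = t))
}

as_hkm_formula <- function(x) {
  if (inherits(x, "hkm_formula")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(hkm_var(x))
  stop("not a formula", call. = FALSE)
}

nary_node <- function(kind, children) {
  children <- lapply(children, as_hkm_formula)
  # flatten same-kind children so AND(AND(a,b),c) == AND(a,b,c)
  flat <- list()
  for (ch in children) {
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  if (length(flat) < 2L) stop(toupper(kind), " needs >= 2 children", call. = FALSE)
  new_formula(list(kind = kind, children = sort_children(flat)))
}

kind_rank <- c(var = 1L, not = 2L, and = 3L, or = 4L, sum = 5L)

min_var <- function(f) {
  switch(f$kind,
    var = f$index,
    not = min_var(f$child),
    min(vapply(f$children, min_var, integer(1)))
  )
}

sort_children <- function(children) {
  key <- vapply(children, function(ch) {
    sprintf("%d|%04d|%s", kind_rank[[ch$kind]], min_var(ch), format(ch))
  }, character(1))
  children[order(key, method = "radix")]
}

#' Variables used by a formula
#'
#' @param f an `hkm_formula`.
#' @return Sorted integer vector of variable indices (with repeats if a
#'   variable occurs more than once, as in a raw DNF).
#' @export
hkm_variables <- function(f) {
  stopifnot(inherits(f, "hkm_formula"))
  sort(var_indices(f))
}

var_indices <- function(f) {
  switch(f$kind,
    var = f$index,
    not = var_indices(f$child),
    unlist(lapply(f$children, var_indices))
  )
}

#' Count the operators in a formula
#'
#' Operator accounting follows a binary-connective convention: an a-ary AND
#' or OR counts `a - 1` operators, NOT counts 1, and a thresholded SUM counts
#' 1 regardless of arity (counting "at least t of these" is a single mental
#' act). A NOT applied directly to a variable listed in `free_not_vars`
#' counts 0: flipping the direction of a threshold comparison (`age > 60`
#' vs `age <= 60`) costs nothing.
#'
#' @param f an `hkm_formula`.
#' @param free_not_vars integer vector of variable indices whose direct
#'   negation is free (typically threshold atoms).
#' @return Integer operator count.
#' @export
hkm_operator_count <- function(f, free_not_vars = integer(0)) {
  stopifnot(inherits(f, "hkm_formula"))
  op_count(f, as.integer(free_not_vars))
}

op_count <- function(f, free) {
  switch(f$kind,
    var = 0L,
    not = {
      self <- if (f$child$kind == "var" && f$child$index %in% free) 0L else 1L
      self + op_count(f$child, free)
    },
    sum = 1L + sum(vapply(f$children, op_count, integer(1), free = free)),
    # and / or
    (length(f$children) - 1L) +
      sum(vapply(f$children, op_count, integer(1), free = free))
  )
}

#' Evaluate a formula on a Boolean matrix
#'
#' @param f an `hkm_formula`.
#' @param rows logical matrix (observations x variables); column `i` supplies
#'   variable `x<i>`. Must be complete (no `NA`).
#' @return Logical vector, one truth value per row.
#' @examples
#' hkm_evaluate(hkm_sum(1, 2, 3, t = 2), rbind(c(TRUE, FALSE, TRUE)))
#' @export
hkm_evaluate <- function(f, rows) {
  stopifnot(inherits(f, "hkm_formula"))
  rows <- as.matrix(rows)
  idx <- var_indices(f)
  if (max(idx) > ncol(rows)) {
    stop("variable x", max(idx), " out of range: matrix has ", ncol(rows),
         " columns", call. = FALSE)
  }
  storage.mode(rows) <- "logical"
  eval_node(f, rows)
}

eval_node <- function(f, rows) {
  switch(f$kind,
    var = rows[, f$index],
    not = !eval_node(f$child, rows),
    and = Reduce(`&`, lapply(f$children, eval_node, rows = rows)),
    or  = Reduce(`|`, lapply(f$children, eval_node, rows = rows)),
    sum = {
      s <- Reduce(`+`, lapply(f$children, function(ch) as.integer(eval_node(ch, rows))))
      s >= f$t
    }
  )
}

#' Truth table of a formula
#'
#' Enumerates all `2^n` assignments of the formula's variables, which must be
#' `x1..xn` contiguously. Row index `r` (0-based) assigns variable `i` the
#' value of bit `i - 1` of `r`, so `x1` is the least significant bit.
#'
#' @param f an `hkm_formula` over variables `x1..xn`.
#' @param n number of variables; defaults to the largest index used.
#' @return An `hkm_truth_table`: list with `n` and a logical `bits` vector of
#'   length `2^n` (`bits[r + 1]` is the value at assignment `r`).
#' @export
hkm_truth_table <- function(f, n = NULL) {
  stopifnot(inherits(f, "hkm_formula"))
  idx <- unique(var_indices(f))
  if (is.null(n)) n <- max(idx)
  n <- as.integer(n)
  stopifnot(n >= 1L, n <= 16L, max(idx) <= n)
  new_truth_table(n, hkm_evaluate(f, assignment_matrix(n)))
}

new_truth_table <- function(n, bits) {
  stopifnot(length(bits) == 2^n, !anyNA(bits))
  structure(list(n = as.integer(n), bits = as.logical(bits)),
            class = "hkm_truth_table")
}

assignment_matrix <- function(n) {
  r <- 0:(2^n - 1)
  vapply(seq_len(n), function(i) bitwAnd(r, bitwShiftL(1L, i - 1L)) > 0L,
         logical(2^n))
}

#' Does a truth table depend on all of its variables?
#'
#' A "proper" table has no dummy variables: for every variable there is an
#' assignment where flipping it flips the output. Functions that do not use
#' all declared variables are handled at their true, smaller size.
#'
#' @param table an `hkm_truth_table`.
#' @return `TRUE` if every variable is essential.
#' @export
hkm_is_proper <- function(table) {
  stopifnot(inherits(table, "hkm_truth_table"))
  r <- 0:(2^table$n - 1)
  for (i in seq_len(table$n)) {
    flipped <- bitwXor(r, bitwShiftL(1L, i - 1L))
    if (!any(table$bits != table$bits[flipped + 1L])) return(FALSE)
  }
  TRUE
}

#' HKM admissibility constraints
#'
#' The defaults encode the human-computability budget: at most four
#' variables, each used at most once, at most four operators, and operators
#' drawn from AND, OR, NOT and thresholded SUM.
#'
#' @param max_vars,max_ops integer budgets.
#' @param allowed_ops character subset of `c("and", "or", "not", "sum")`.
#' @return An `hkm_constraints` object.
#' @export
hkm_constraints <- function(max_vars = 4L, max_ops = 4L,
                            allowed_ops = c("and", "or", "not", "sum")) {
  allowed_ops <- match.arg(allowed_ops, c("and", "or", "not", "sum"),
                           several.ok = TRUE)
  structure(list(max_vars = as.integer(max_vars), max_ops = as.integer(max_ops),
                 allowed_ops = allowed_ops),
            class = "hkm_constraints")
}

#' Is a formula admissible under the constraints?
#'
#' Checks the variable budget, the once-only rule, the operator budget, the
#' allowed operator set, and that every SUM counts bare variables (a
#' thresholded SUM is an arithmetic count of Boolean variables, not of
#' sub-expressions).
#'
#' @inheritParams hkm_operator_count
#' @param constraints an [hkm_constraints()] object.
#' @return Logical scalar.
#' @export
hkm_is_admissible <- function(f, constraints = hkm_constraints(),
                              free_not_vars = integer(0)) {
  stopifnot(inherits(f, "hkm_formula"))
  idx <- var_indices(f)
  if (anyDuplicated(idx)) return(FALSE)
  if (length(idx) > constraints$max_vars) return(FALSE)
  if (hkm_operator_count(f, free_not_vars) > constraints$max_ops) return(FALSE)
  if (!sums_over_vars(f)) return(FALSE)
  ops <- used_ops(f)
  all(ops %in% constraints$allowed_ops)
}

sums_over_vars <- function(f) {
  switch(f$kind,
    var = TRUE,
    not = sums_over_vars(f$child),
    sum = all(vapply(f$children, function(ch) ch$kind == "var", logical(1))),
    all(vapply(f$children, sums_over_vars, logical(1)))
  )
}

used_ops <- function(f) {
  switch(f$kind,
    var = character(0),
    not = union("not", used_ops(f$child)),
    union(f$kind, unique(unlist(lapply(f$children, used_ops))))
  )
}

#' @export
format.hkm_formula <- function(x, ..., names = NULL) {
  render(x, top = TRUE, names = names)
}

render <- function(f, top = FALSE, names = NULL) {
  nm <- function(i) if (is.null(names)) paste0("x", i) else names[[i]]
  out <- switch(f$kind,
    var = nm(f$index),
    not = {
      if (f$child$kind == "var") {
        paste("NOT", render(f$child, names = names))
      } else {
        paste0("NOT (", render(f$child, top = TRUE, names = names), ")")
      }
    },
    and = paste(vapply(f$children, render, character(1), names = names),
                collapse = " AND "),
    or  = paste(vapply(f$children, render, character(1), names = names),
                collapse = " OR "),
    sum = paste0("SUM(", paste(vapply(f$children, render, character(1),
                                      names = names), collapse = ", "),
                 ") >= ", f$t)
  )
  if (!top && f$kind %in% c("and", "or", "sum")) paste0("(", out, ")") else out
}

#' @export
print.hkm_formula <- function(x, ...) {
  cat("<hkm_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.hkm_truth_table <- function(x, ...) {
  cat("<hkm_truth_table> n = ", x$n, ", bits = ",
      paste(as.integer(x$bits), collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
format.hkm_truth_table <- function(x, ...) paste(as.integer(x$bits), collapse = "")

table_key <- function(bits) paste(as.integer(bits), collapse = "")

#' Parse the formula rendering grammar
#'
#' Round-trips the strings produced by `format()`: variables `x<i>`, prefix
#' `NOT`, infix `AND` / `OR` (NOT binds tightest, then AND, then OR),
#' parentheses, and `SUM(a, b, c) >= t`.
#'
#' @param text a single string.
#' @return An `hkm_formula`.
#' @examples
#' hkm_parse("(x1 AND NOT x3) OR x7")
#' hkm_parse("SUM(x1, x2, x5) >= 2")
#' @export
hkm_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  f <- parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("unexpected token '", st$toks[st$pos], "'", call. = FALSE)
  }
  f
}

tokenize <- function(text) {
  pat <- "x[0-9]+|SUM|AND|OR|NOT|>=|\\(|\\)|,|[0-9]+"
  m <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  rest <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", rest)) {
    stop("cannot tokenize near '", gsub("[[:space:]]+", " ", rest), "'",
         call. = FALSE)
  }
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else ""
take <- function(st, what = NULL) {
  tok <- peek(st)
  if (!is.null(what) && !identical(tok, what)) {
    stop("expected '", what, "' but found '", tok, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tok
}

parse_or <- function(st) {
  parts <- list(parse_and(st))
  while (peek(st) == "OR") {
    take(st)
    parts <- c(parts, list(parse_and(st)))
  }
  if (length(parts) == 1L) parts[[1]] else do.call(hkm_or, parts)
}

parse_and <- function(st) {
  parts <- list(parse_unary(st))
  while (peek(st) == "AND") {
    take(st)
    parts <- c(parts, list(parse_unary(st)))
  }
  if (length(parts) == 1L) parts[[1]] else do.call(hkm_and, parts)
}

parse_unary <- function(st) {
  if (peek(st) == "NOT") {
    take(st)
    return(hkm_not(parse_unary(st)))
  }
  parse_primary(st)
}

parse_primary <- function(st) {
  tok <- peek(st)
  if (tok == "(") {
    take(st)
    f <- parse_or(st)
    take(st, ")")
    return(f)
  }
  if (tok == "SUM") {
    take(st)
    take(st, "(")
    args <- list(parse_or(st))
    while (peek(st) == ",") {
      take(st)
      args <- c(args, list(parse_or(st)))
    }
    take(st, ")")
    take(st, ">=")
    t <- as.integer(take(st))
    return(do.call(hkm_sum, c(args, list(t = t))))
  }
  if (grepl("^x[0-9]+$", tok)) {
    take(st)
    return(hkm_var(as.integer(sub("^x", "", tok))))
  }
  stop("unexpected token '", tok, "'", call. = FALSE)
}
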