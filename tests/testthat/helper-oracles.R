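# Independent oracles, coded apart from the package internals: a plain-list
# formula representation with its own evaluator and operator counter, a
# brute-force enumerator of admissible expressions, a naive exhaustive rule
# search, and a game-tree Nim solver. Used to cross-check the catalog and
# the fast searcher.

o_var <- function(i) list(op = "var", i = as.integer(i))
o_not <- function(f) list(op = "not", x = f)
o_and <- function(kids) list(op = "and", kids = kids)
o_or <- function(kids) list(op = "or", kids = kids)
o_sum <- function(kids, t) list(op = "sum", kids = kids, t = as.integer(t))

o_eval <- function(f, M) {
  switch(f$op,
    var = M[, f$i],
    not = !o_eval(f$x, M),
    and = Reduce(`&`, lapply(f$kids, function(k) o_eval(k, M))),
    or = Reduce(`|`, lapply(f$kids, function(k) o_eval(k, M))),
    sum = Reduce(`+`, lapply(f$kids, function(k) as.integer(o_eval(k, M)))) >= f$t
  )
}

o_ops <- function(f) {
  switch(f$op,
    var = 0L,
    not = 1L + o_ops(f$x),
    sum = 1L + sum(vapply(f$kids, o_ops, integer(1))),
    (length(f$kids) - 1L) + sum(vapply(f$kids, o_ops, integer(1)))
  )
}

# assignment r (0-based) sets variable i to bit i-1 of r
o_assignments <- function(n) {
  r <- 0:(2^n - 1)
  m <- matrix(FALSE, 2^n, n)
  for (i in seq_len(n)) m[, i] <- bitwAnd(r, 2^(i - 1)) > 0
  m
}

o_tablekey <- function(f, n) {
  paste(as.integer(o_eval(f, o_assignments(n))), collapse = "")
}

o_proper_key <- function(key, n) {
  bits <- as.integer(strsplit(key, "")[[1]])
  r <- 0:(2^n - 1)
  for (i in seq_len(n)) {
    if (all(bits == bits[bitwXor(r, 2^(i - 1)) + 1])) return(FALSE)
  }
  TRUE
}

# all partitions of a set into unordered non-empty blocks (restricted-growth)
o_partitions <- function(vars) {
  if (length(vars) == 1) return(list(list(vars)))
  rest <- o_partitions(vars[-1])
  out <- list()
  for (p in rest) {
    for (j in seq_along(p)) {
      q <- p
      q[[j]] <- c(vars[1], q[[j]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(vars[1]), p)
  }
  out
}

o_formula_cache <- new.env(parent = emptyenv())

# every expression tree over exactly `vars`, each variable once, SUM over
# bare variables, no stacked NOTs (a double negation is never minimal),
# filtered to the operator budget
o_formulas <- function(vars, max_ops = 4L) {
  key <- paste(c(max_ops, vars), collapse = ",")
  hit <- o_formula_cache[[key]]
  if (!is.null(hit)) return(hit)
  gen <- function(vars) {
    if (length(vars) == 1) {
      v <- o_var(vars)
      return(list(v, o_not(v)))
    }
    out <- list()
    for (part in o_partitions(vars)) {
      if (length(part) < 2) next
      subs <- lapply(part, gen)
      idx <- expand.grid(lapply(subs, seq_along))
      for (r in seq_len(nrow(idx))) {
        kids <- lapply(seq_along(subs), function(j) subs[[j]][[idx[r, j]]])
        out[[length(out) + 1]] <- o_and(kids)
        out[[length(out) + 1]] <- o_or(kids)
      }
      if (length(part) >= 3 && all(lengths(part) == 1)) {
        kids <- lapply(sort(unlist(part)), o_var)
        for (t in 2:(length(part) - 1)) {
          out[[length(out) + 1]] <- o_sum(kids, t)
        }
      }
    }
    c(out, lapply(Filter(function(f) f$op != "not", out), o_not))
  }
  res <- Filter(function(f) o_ops(f) <= max_ops, gen(vars))
  o_formula_cache[[key]] <- res
  res
}

# minimal operator count per reachable proper table, by brute force
o_min_ops_by_table <- function(n, max_ops = 4L) {
  forms <- o_formulas(seq_len(n), max_ops)
  keys <- vapply(forms, o_tablekey, character(1), n = n)
  ops <- vapply(forms, o_ops, integer(1))
  best <- tapply(ops, keys, min)
  keep <- vapply(names(best), o_proper_key, logical(1), n = n)
  best[keep]
}

o_f1 <- function(p, y) {
  tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

# naive exhaustive search: every (subset, proper table) candidate with its
# best score, sorted by the documented tie order minus the final rendering
# key (score desc, size asc, ops asc, coverage desc)
oracle_candidates <- function(bin, sizes, min_coverage = 0.8, max_ops = 4L) {
  feats <- bin$info$feature
  n_atoms <- ncol(bin$atoms)
  rows <- list()
  for (size in sizes) {
    if (size > n_atoms) next
    forms <- o_formulas(seq_len(size), max_ops)
    keys <- vapply(forms, o_tablekey, character(1), n = size)
    ops <- vapply(forms, o_ops, integer(1))
    reps <- integer(0)
    for (k in unique(keys)) {
      if (!o_proper_key(k, size)) next
      cand <- which(keys == k)
      reps <- c(reps, cand[which.min(ops[cand])])
    }
    for (subset in utils::combn(n_atoms, size, simplify = FALSE)) {
      if (anyDuplicated(feats[subset])) next
      keep <- !apply(bin$mask[, subset, drop = FALSE], 1, any)
      cov <- mean(keep)
      if (cov < min_coverage || !any(keep)) next
      X <- bin$atoms[keep, subset, drop = FALSE]
      y <- bin$target[keep]
      for (ri in reps) {
        rows[[length(rows) + 1]] <- data.frame(
          size = size,
          subset = paste(subset, collapse = ","),
          key = keys[ri],
          ops = ops[ri],
          coverage = cov,
          score = o_f1(o_eval(forms[[ri]], X), y)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$score, out$size, out$ops, -out$coverage,
            out$subset, out$key, method = "radix"), ]
}

# Nim by exhaustive game-tree search: the mover wins iff some move reaches
# a losing position for the opponent
o_nim_cache <- new.env(parent = emptyenv())
o_nim_wins <- function(piles) {
  piles <- sort(as.integer(piles))
  key <- paste(piles, collapse = ",")
  hit <- o_nim_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- FALSE
  for (p in seq_along(piles)) {
    if (piles[p] == 0) next
    for (take in 1:piles[p]) {
      nxt <- piles
      nxt[p] <- nxt[p] - take
      if (!o_nim_wins(nxt)) {
        res <- TRUE
        break
      }
    }
    if (res) break
  }
  o_nim_cache[[key]] <- res
  res
}

# semantic recovery: does any fitted model equal the planted rule up to the
# mapping of its atoms onto the planted features?
recovers_planted <- function(fit, spec) {
  idx <- hkm_variables(spec$formula)
  planted_names <- spec$features$name[idx]
  ptt <- hkm_truth_table(spec$formula)
  v <- ptt$n
  for (r in seq_len(nrow(fit$models))) {
    mfeats <- fit$models$features[[r]]
    types <- fit$models$atoms[[r]]
    if (length(mfeats) != v) next
    if (!setequal(mfeats, planted_names)) next
    atom_types <- fit$binarized$info$type[fit$models$atoms[[r]]]
    if (any(atom_types == "missing")) next
    perm <- match(mfeats, planted_names)
    rr <- 0:(2^v - 1)
    s <- integer(2^v)
    for (j in seq_len(v)) {
      s <- s + bitwShiftL(as.integer(bitwAnd(rr, 2^(j - 1)) > 0),
                          idx[perm[j]] - 1L)
    }
    expected <- paste(as.integer(ptt$bits[s + 1]), collapse = "")
    if (identical(expected, fit$models$key[r])) return(TRUE)
  }
  FALSE
}

# a small all-Bernoulli planted spec: exact atoms, so noiseless recovery is
# exact; three rule features and three distractors
bernoulli_spec <- function(n_obs = 2000L, noise = 0.1,
                           formula = hkm_or(hkm_and(hkm_var(1), hkm_var(2)),
                                            hkm_var(3))) {
  hkm_planted_spec(
    formula = formula,
    features = tibble::tibble(
      name = c("cough", "fever", "exposure", "noise_a", "noise_b", "noise_c"),
      type = "bernoulli",
      p = c(0.45, 0.40, 0.12, 0.30, 0.50, 0.20),
      mean = NA_real_, sd = NA_real_
    ),
    noise = noise, missing = 0, n_obs = n_obs
  )
}
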