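#' Specification of a planted-rule dataset
#'
#' Describes a synthetic tabular dataset whose Boolean outcome is generated
#' by a known admissible rule plus independent label noise, emulating the
#' structure of real decision datasets: a minority positive class, a mix of
#' numeric and Boolean features, uninformative distractor columns, and
#' missing cells (never in the target).
#'
#' Each feature is either `bernoulli` (a native Boolean with success
#' probability `p`) or `numeric` (Gaussian with `mean` and `sd`, entering
#' the rule through the threshold at its upper-`p` tail, i.e.
#' `value > qnorm(1 - p, mean, sd)`). The default spec plants
#' `(marker_a AND marker_b) OR risk_c` with marginals giving an analytic
#' positive rate of about 28%, 5% label noise and 5% missingness --
#' comparable to an unbalanced clinical outcome.
#'
#' @param formula generating `hkm_formula`; variable `x<i>` refers to the
#'   i-th row of `features`. Must be admissible.
#' @param features tibble with columns `name`, `type` (`"bernoulli"` or
#'   `"numeric"`), `p`, `mean`, `sd`. Rows beyond the formula's variables
#'   are distractors.
#' @param noise label-flip probability in `[0, 0.5)`.
#' @param missing per-feature missingness rate (scalar or one per feature).
#' @param n_obs observation count.
#' @param prevalence optional target positive rate; a warning reports the
#'   achievable analytic rate when it differs by more than 2 points.
#' @param target name of the outcome column.
#' @return An `hkm_planted_spec` list.
#' @export
hkm_planted_spec <- function(formula = hkm_or(hkm_and(hkm_var(1), hkm_var(2)),
                                              hkm_var(3)),
                             features = default_planted_features(),
                             noise = 0.05, missing = 0.05, n_obs = 2000L,
                             prevalence = NULL, target = "outcome") {
  stopifnot(inherits(formula, "hkm_formula"), noise >= 0, noise < 0.5,
            n_obs >= 1, all(missing >= 0), all(missing < 1))
  if (!hkm_is_admissible(formula)) {
    stop("the planted formula must itself be admissible", call. = FALSE)
  }
  idx <- hkm_variables(formula)
  if (max(idx) > nrow(features)) {
    stop("formula uses x", max(idx), " but only ", nrow(features),
         " features are declared", call. = FALSE)
  }
  missing <- rep_len(missing, nrow(features))
  spec <- structure(list(formula = formula, features = features,
                         noise = noise, missing = missing,
                         n_obs = as.integer(n_obs), prevalence = prevalence,
                         target = target),
                    class = "hkm_planted_spec")
  if (!is.null(prevalence)) {
    ach <- hkm_planted_prevalence(spec)
    if (abs(ach - prevalence) > 0.02) {
      warning(sprintf(paste("requested prevalence %.3f is not achievable with",
                            "this rule and these marginals; analytic rate is",
                            "%.3f"), prevalence, ach), call. = FALSE)
    }
  }
  spec
}

default_planted_features <- function() {
  tibble::tibble(
    name = c("marker_a", "marker_b", "risk_c", "noise_d", "noise_e", "noise_f"),
    type = c("numeric", "bernoulli", "bernoulli", "numeric", "bernoulli",
             "numeric"),
    p = c(0.45, 0.40, 0.12, 0.50, 0.30, 0.50),
    mean = c(50, NA, NA, 100, NA, 0),
    sd = c(10, NA, NA, 25, NA, 1)
  )
}

#' Analytic positive rate of a planted rule
#'
#' Exact expectation over the independent feature marginals (all `2^v`
#' assignments of the rule's variables) combined with the label-flip noise.
#'
#' @param spec an [hkm_planted_spec()].
#' @return Probability in `[0, 1]`.
#' @export
hkm_planted_prevalence <- function(spec) {
  stopifnot(inherits(spec, "hkm_planted_spec"))
  idx <- hkm_variables(spec$formula)
  v <- max(idx)
  p <- spec$features$p[seq_len(v)]
  rows <- assignment_matrix(v)
  out <- hkm_evaluate(spec$formula, rows)
  w <- apply(rows, 1, function(a) prod(ifelse(a, p, 1 - p)))
  clean <- sum(w[out])
  clean * (1 - spec$noise) + (1 - clean) * spec$noise
}

#' Generate a planted-rule dataset
#'
#' Draws features from their marginals, computes the clean label with the
#' planted rule, flips it with the declared noise probability, and inserts
#' missing cells at the per-feature rates (the target is never missing).
#' Fully seeded: the same seed reproduces the dataset byte for byte.
#'
#' @param spec an [hkm_planted_spec()].
#' @param seed integer seed.
#' @return A tibble with the feature columns and the logical target column.
#' @export
hkm_generate_planted <- function(spec = hkm_planted_spec(), seed = 1L) {
  stopifnot(inherits(spec, "hkm_planted_spec"))
  with_seed(seed, {
    n <- spec$n_obs
    fs <- spec$features
    cols <- list()
    bools <- matrix(FALSE, n, nrow(fs))
    for (j in seq_len(nrow(fs))) {
      if (fs$type[j] == "bernoulli") {
        b <- stats::runif(n) < fs$p[j]
        cols[[fs$name[j]]] <- b
        bools[, j] <- b
      } else {
        v <- stats::rnorm(n, fs$mean[j], fs$sd[j])
        cols[[fs$name[j]]] <- v
        bools[, j] <- v > stats::qnorm(1 - fs$p[j], fs$mean[j], fs$sd[j])
      }
    }
    clean <- hkm_evaluate(spec$formula, bools)
    flip <- stats::runif(n) < spec$noise
    label <- xor(clean, flip)
    for (j in seq_len(nrow(fs))) {
      if (spec$missing[j] > 0) {
        holes <- stats::runif(n) < spec$missing[j]
        cols[[fs$name[j]]][holes] <- NA
      }
    }
    out <- tibble::as_tibble(cols)
    out[[spec$target]] <- label
    out
  })
}

#' Generate a Nim game-winner dataset
#'
#' Draws pile configurations uniformly and labels each with whether the
#' player to move wins under optimal play -- true exactly when the bitwise
#' XOR (nim-sum) of the pile sizes is nonzero. The default produces 2000
#' games described by 10 feature columns.
#'
#' The winner's dependence on *all* bits of every pile makes the label hard
#' to express within the human-rule budget under the default `"piles"`
#' layout (raw pile sizes, zero-padded to `n_features` columns; the padding
#' mirrors a fixed-width feature table and carries no information). The
#' `"bits"` layout instead exposes the binary digits of each pile, under
#' which small instances become rule-expressible.
#'
#' @param games number of games.
#' @param piles number of piles.
#' @param max_objects largest pile size (piles are uniform on
#'   `0..max_objects`).
#' @param n_features total feature columns (padded or truncated).
#' @param layout `"piles"` or `"bits"`.
#' @param seed integer seed.
#' @param target name of the outcome column.
#' @return A tibble of features plus the logical target (`TRUE` = the
#'   player to move wins).
#' @export
hkm_generate_nim <- function(games = 2000L, piles = 3L, max_objects = 7L,
                             n_features = 10L, layout = c("piles", "bits"),
                             seed = 1L, target = "first_win") {
  layout <- match.arg(layout)
  stopifnot(games >= 1, piles >= 1, max_objects >= 1, n_features >= 1)
  with_seed(seed, {
    sizes <- matrix(sample.int(max_objects + 1L, games * piles,
                               replace = TRUE) - 1L,
                    nrow = games, ncol = piles)
    label <- hkm_nim_winner(sizes)
    if (layout == "piles") {
      cols <- as.list(as.data.frame(sizes))
      names(cols) <- paste0("pile", seq_len(piles))
      extra <- n_features - piles
      if (extra > 0) {
        for (j in seq_len(extra)) cols[[paste0("pad", j)]] <- rep(0L, games)
      } else if (extra < 0) {
        cols <- cols[seq_len(n_features)]
      }
    } else {
      n_bits <- ceiling(log2(max_objects + 1))
      cols <- list()
      for (p in seq_len(piles)) {
        for (b in seq_len(n_bits)) {
          cols[[paste0("pile", p, "_bit", b - 1L)]] <-
            bitwAnd(sizes[, p], bitwShiftL(1L, b - 1L)) > 0L
        }
      }
      if (length(cols) > n_features) cols <- cols[seq_len(n_features)]
      extra <- n_features - length(cols)
      if (extra > 0) {
        for (j in seq_len(extra)) cols[[paste0("pad", j)]] <- rep(FALSE, games)
      }
    }
    out <- tibble::as_tibble(cols)
    out[[target]] <- label
    out
  })
}

#' Nim winner under optimal play
#'
#' @param piles integer vector of pile sizes, or a matrix (one position per
#'   row).
#' @return Logical: `TRUE` when the player to move wins, i.e. the nim-sum
#'   (bitwise XOR of the pile sizes) is nonzero. The empty position (all
#'   zeros) is a loss for the mover.
#' @examples
#' hkm_nim_winner(c(1, 0))  # take the single object: win
#' hkm_nim_winner(c(1, 1))  # mirrored play: loss
#' @export
hkm_nim_winner <- function(piles) {
  if (is.matrix(piles)) {
    stopifnot(all(piles >= 0))
    nim <- Reduce(bitwXor, lapply(seq_len(ncol(piles)),
                                  function(j) as.integer(piles[, j])))
    return(nim != 0L)
  }
  stopifnot(all(piles >= 0))
  Reduce(bitwXor, as.integer(piles)) != 0L
}
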