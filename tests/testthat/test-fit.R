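test_that("confusion-matrix scores follow their definitions", {
  y <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(hkm_score(y, y), 1.0)
  p <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)  # TP=2 FP=1 FN=1
  expect_equal(hkm_score(p, y), 2 / 3)
  expect_equal(hkm_score(rep(FALSE, 6), y), 0)
  expect_equal(hkm_score(rep(TRUE, 6), y, "recall"), 1)
  expect_equal(hkm_score(rep(TRUE, 6), y, "precision"), 0.5)  # prevalence
  expect_equal(hkm_score(p, y, "accuracy"), 4 / 6)
  # abstentions are dropped, not imputed
  expect_equal(hkm_score(c(p[1:5], NA), y), hkm_score(p[1:5], y[1:5]))
  expect_error(hkm_score(p[1:3], y), "length")
})

test_that("a single atom identical to the target is found at score 1", {
  d <- tibble::tibble(hit = rep(c(TRUE, FALSE), 20),
                      other = rep(c(1, 5, 2, 7), 10),
                      outcome = rep(c(TRUE, FALSE), 20))
  fit <- hkm_fit(d, sizes = 1:2, m = 3)
  expect_equal(fit$models$score[1], 1.0)
  expect_equal(fit$models$rule[1], "hit")
  expect_equal(fit$models$size[1], 1L)
})

test_that("a noiseless planted rule is recovered exactly", {
  spec <- bernoulli_spec(n_obs = 600, noise = 0)
  d <- hkm_generate_planted(spec, seed = 11)
  fit <- hkm_fit(d, sizes = 1:3, m = 10)
  expect_equal(fit$models$score[1], 1.0)
  expect_true(recovers_planted(fit, spec))
  # and it predicts fresh noiseless draws perfectly
  d2 <- hkm_generate_planted(spec, seed = 12)
  expect_equal(hkm_score(predict(fit, newdata = d2), d2$outcome), 1.0)
})

test_that("the fast search equals the naive exhaustive oracle", {
  set.seed(202)
  m_top <- 15L
  for (rep in 1:6) {
    spec <- hkm_planted_spec(
      formula = hkm_and(hkm_var(1), hkm_var(2)),
      features = tibble::tibble(
        name = paste0("f", 1:5),
        type = c("bernoulli", "numeric", "bernoulli", "numeric", "bernoulli"),
        p = round(runif(5, 0.2, 0.6), 2),
        mean = c(NA, 10, NA, -3, NA), sd = c(NA, 2, NA, 1, NA)
      ),
      noise = 0.1, missing = c(0, 0.05, 0, 0, 0.05), n_obs = 80
    )
    d <- hkm_generate_planted(spec, seed = 300 + rep)
    bin <- hkm_binarize(d, "outcome", K = 2)
    fit <- hkm_fit(bin, sizes = 1:3, m = m_top, min_coverage = 0.7)
    orc <- oracle_candidates(bin, sizes = 1:3, min_coverage = 0.7)
    k <- min(m_top, nrow(orc), nrow(fit$models))
    expect_equal(fit$models$score[seq_len(k)], orc$score[seq_len(k)])
    # every returned model is a real candidate with identical bookkeeping
    for (i in seq_len(k)) {
      sub <- paste(fit$models$atoms[[i]], collapse = ",")
      hit <- orc[orc$subset == sub & orc$key == fit$models$key[i], ]
      expect_equal(nrow(hit), 1L)
      expect_equal(hit$score, fit$models$score[i])
      expect_equal(hit$ops, fit$models$ops[i])
      expect_equal(hit$coverage, fit$models$coverage[i])
      expect_equal(hit$size, fit$models$size[i])
    }
    # optimality: nothing outside the stack strictly beats the last model
    last <- fit$models[k, ]
    better <- orc$score > last$score |
      (orc$score == last$score & orc$size < last$size) |
      (orc$score == last$score & orc$size == last$size & orc$ops < last$ops) |
      (orc$score == last$score & orc$size == last$size &
         orc$ops == last$ops & orc$coverage > last$coverage)
    expect_lte(sum(better), k - 1L)
  }
})

test_that("fitting is deterministic down to the serialized output", {
  d <- hkm_generate_planted(hkm_planted_spec(n_obs = 250), seed = 5)
  f1 <- hkm_fit(d, sizes = 1:3, m = 10)
  f2 <- hkm_fit(d, sizes = 1:3, m = 10)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  hkm_write_models(f1, p1)
  hkm_write_models(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(f1$models, f2$models)
  back <- hkm_read_models(p1)
  expect_equal(back$rule, f1$models$rule)
  expect_equal(back$score, f1$models$score)
})

test_that("sibling atoms from one source feature never co-occur", {
  set.seed(8)
  d <- tibble::tibble(age = rnorm(120, 50, 15), bmi = rnorm(120, 27, 4),
                      outcome = rep(c(TRUE, FALSE), 60))
  fit <- hkm_fit(d, k = 3, sizes = 2, m = 25)
  for (feats in fit$models$features) {
    expect_false(anyDuplicated(feats) > 0)
  }
})

test_that("rows with missing model inputs abstain at prediction", {
  d <- tibble::tibble(flag = c(TRUE, TRUE, NA, FALSE, FALSE, NA),
                      outcome = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  d <- dplyr::bind_rows(d, d, d, d, d)
  fit <- hkm_fit(d, sizes = 1, m = 2, min_coverage = 0.5)
  pred <- predict(fit, newdata = d)
  expect_true(all(is.na(pred[is.na(d$flag)])))
  expect_false(anyNA(pred[!is.na(d$flag)]))
})

test_that("an uncoverable dataset warns and returns no models", {
  # every candidate atom is masked on half the rows, so nothing reaches the
  # coverage floor (built directly: real binarization always adds a fully
  # observed is-missing indicator)
  bin <- structure(list(
    atoms = matrix(rep(c(TRUE, FALSE), 5), ncol = 1),
    mask = matrix(rep(c(TRUE, FALSE), each = 5), ncol = 1),
    info = tibble::tibble(atom = 1L, label = "x > 1", label_neg = "x <= 1",
                          feature = "x", type = "threshold", direction = ">",
                          threshold = 1, level = NA_character_),
    target = rep(c(TRUE, FALSE), 5),
    target_name = "outcome"
  ), class = "hkm_binarized")
  expect_warning(fit <- hkm_fit(bin, sizes = 1, m = 5, min_coverage = 0.9),
                 "coverage")
  expect_equal(nrow(fit$models), 0L)
})

test_that("subsampling is seeded and reproducible", {
  d <- hkm_generate_planted(hkm_planted_spec(n_obs = 400), seed = 21)
  f1 <- hkm_fit(d, sizes = 1:2, m = 5, subsample = 150, seed = 99)
  f2 <- hkm_fit(d, sizes = 1:2, m = 5, subsample = 150, seed = 99)
  expect_identical(f1$models, f2$models)
  expect_error(hkm_fit(d, sizes = 1:2, m = 5, subsample = 150), "seed")
})

test_that("constrained rules overfit less than an unconstrained tree", {
  skip_if_not_installed("rpart")
  spec <- bernoulli_spec(n_obs = 240, noise = 0.2)
  gaps_hkm <- numeric(0)
  gaps_tree <- numeric(0)
  for (rep in 1:30) {
    d <- hkm_generate_planted(spec, seed = 4000 + rep)
    idx <- withr::with_seed(rep, sample.int(nrow(d), 192))
    train <- d[idx, ]; test <- d[-idx, ]
    fit <- hkm_fit(train, sizes = 1:3, m = 3)
    tr <- fit$models$score[1]
    te <- hkm_score(predict(fit, newdata = test), test$outcome)
    gaps_hkm <- c(gaps_hkm, tr - te)
    tree <- rpart::rpart(outcome ~ ., data = train, method = "class",
                         control = rpart::rpart.control(cp = 0, minsplit = 2))
    ptr <- predict(tree, train, type = "class") == "TRUE"
    pte <- predict(tree, test, type = "class") == "TRUE"
    gaps_tree <- c(gaps_tree,
                   hkm_score(ptr, train$outcome) - hkm_score(pte, test$outcome))
  }
  expect_lt(stats::median(gaps_hkm), stats::median(gaps_tree))
})
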