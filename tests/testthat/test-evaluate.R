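test_that("the stability factor is the absolute relative train-test change", {
  expect_equal(hkm_stability(0.8, 0.6), 0.25)
  expect_equal(hkm_stability(0.7, 0.7), 0)
  expect_equal(hkm_stability(0.5, 0.6), 0.2)  # absolute value
  expect_equal(hkm_stability(c(0.8, 0.5), c(0.6, 0.6)), c(0.25, 0.2))
  expect_error(hkm_stability(0, 0.5), "undefined")
})

test_that("the stability curve is a valid empirical CDF", {
  expect_equal(hkm_stability_curve(rep(0, 5), 0.01)$p, 1.0)
  expect_equal(hkm_stability_curve(c(0.1, 0.3), 0.2)$p, 0.5)
  expect_equal(hkm_stability_curve(c(0.1, 0.3), 0)$p, 0)  # strict inequality
  set.seed(31)
  curve <- hkm_stability_curve(runif(200, 0, 0.8))
  expect_true(all(diff(curve$p) >= 0))
  expect_true(all(curve$p >= 0 & curve$p <= 1))
  expect_equal(curve$p[curve$s == 1][1], 1)
})

test_that("noiseless planted data gives perfectly stable experiments", {
  spec <- bernoulli_spec(n_obs = 400, noise = 0)
  d <- hkm_generate_planted(spec, seed = 17)
  ex <- hkm_experiments(d, n_exp = 4, seed = 100, sizes = 1:3, m = 5)
  expect_equal(nrow(ex$records), 4L)
  expect_equal(ex$records$S, rep(0, 4))
  expect_equal(ex$records$train_score, rep(1, 4))
})

test_that("experiments are reproducible from the master seed", {
  d <- hkm_generate_planted(hkm_planted_spec(n_obs = 300), seed = 23)
  e1 <- hkm_experiments(d, n_exp = 3, seed = 9, sizes = 1:2, m = 5)
  e2 <- hkm_experiments(d, n_exp = 3, seed = 9, sizes = 1:2, m = 5)
  expect_identical(e1$records, e2$records)
  expect_equal(e1$records$seed, 9:11)  # instance seed = master + index - 1
})

test_that("a single instance yields a one-count histogram", {
  d <- hkm_generate_planted(hkm_planted_spec(n_obs = 300), seed = 29)
  ex <- hkm_experiments(d, n_exp = 1, seed = 4, sizes = 1:2, m = 5)
  expect_equal(sum(ex$histogram$count), 1L)
  expect_equal(nrow(ex$histogram), 100L)  # fixed 0.01-wide bins
})

test_that("cross-validation and baseline hooks slot into the protocol", {
  skip_if_not_installed("rpart")
  d <- hkm_generate_planted(hkm_planted_spec(n_obs = 300), seed = 37)
  base <- function(train, test, target) {
    tree <- rpart::rpart(stats::reformulate(".", target), data = train,
                         method = "class")
    ptr <- predict(tree, train, type = "class") == "TRUE"
    pte <- predict(tree, test, type = "class") == "TRUE"
    list(train_score = hkm_score(ptr, train[[target]]),
         test_score = hkm_score(pte, test[[target]]))
  }
  ex <- hkm_experiments(d, n_exp = 2, seed = 50, sizes = 1:2, m = 3,
                        cv = TRUE, baseline = base)
  expect_true(all(c("cv_score", "baseline_train", "baseline_test") %in%
                    names(ex$records)))
  expect_true(all(ex$records$cv_score >= 0 & ex$records$cv_score <= 1))
})

test_that("the report round-trips through its JSON reader", {
  d <- hkm_generate_planted(hkm_planted_spec(n_obs = 300), seed = 41)
  ex <- hkm_experiments(d, n_exp = 2, seed = 3, sizes = 1:2, m = 3)
  path <- withr::local_tempfile(fileext = ".json")
  hkm_write_report(ex, path)
  back <- hkm_read_report(path)
  expect_equal(back$records$S, ex$records$S)
  expect_equal(back$curve$p, ex$curve$p)
  expect_equal(sum(back$histogram$count), nrow(ex$records))
})

test_that("larger rule sizes never lower the best attainable train score", {
  d <- hkm_generate_planted(hkm_planted_spec(n_obs = 400), seed = 43)
  best <- vapply(1:3, function(sz) {
    hkm_fit(d, sizes = sz, m = 1)$models$score[1]
  }, numeric(1))
  expect_true(all(diff(best) >= 0))
})

test_that("precision-recall summaries read off the confusion matrix", {
  spec <- bernoulli_spec(n_obs = 500, noise = 0)
  d <- hkm_generate_planted(spec, seed = 47)
  train <- d[1:400, ]; test <- d[401:500, ]
  pr <- hkm_pr_summary(train, test, sizes = c(1, 3), m = 5)
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  expect_true(all(pr$recall >= 0 & pr$recall <= 1))
  # the planted 3-variable rule is perfect on both axes
  top3 <- pr[pr$size == 3 & pr$rank == 1, ]
  expect_equal(top3$precision, 1)
  expect_equal(top3$recall, 1)
  # nested model classes: the best size-1 rule cannot beat the best size-3
  f1 <- function(p, r) ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  expect_lte(max(f1(pr$precision[pr$size == 1], pr$recall[pr$size == 1])),
             max(f1(pr$precision[pr$size == 3], pr$recall[pr$size == 3])))
})
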