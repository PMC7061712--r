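test_that("accuracy and the majority baseline are computed correctly", {
  m <- linear_model(c(1, 0), t = 0)
  d <- toy_dataset(rbind(c(1, 0), c(2, 0), c(-1, 0), c(3, 0)), c(1, 1, 1, 1))
  expect_equal(accuracy(m, d), 0.75)

  const <- linear_model(c(0, 0), t = -1)  # always predicts 1
  bal <- toy_dataset(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
  expect_equal(accuracy(const, bal), 0.5)

  expect_equal(baseline_accuracy(c(rep("a", 13), rep("b", 38))), 38 / 51)
  expect_equal(baseline_accuracy(rep(c(0, 1), 7)), 0.5)
  expect_equal(baseline_accuracy(rep(1, 9)), 1)
  expect_error(accuracy(m, d[0, ]), "empty")
})

test_that("noise-free experiment bookkeeping is complete and consistent", {
  r <- noise_free_experiment(n = 2, d_grid = c(2, 4), r_count = 2,
                             classes = "off", m_per_class = 15, seed = 99)
  # (lin + off) x 2 regularizations x 2 distances x 2 repetitions
  expect_identical(nrow(r), 16L)
  expect_identical(dplyr::n_distinct(r[c("concept_class", "regularization",
                                         "d", "rep")]), 16L)
  expect_true(all(r$accuracy >= 0 & r$accuracy <= 1))
  expect_true(all(r$accuracy_diff_vs_lin[r$concept_class == "lin"] == 0))
  # diff is lin accuracy minus model accuracy within (reg, d, rep)
  one <- r[r$regularization == "R2" & r$d == 4 & r$rep == 1, ]
  expect_equal(one$accuracy_diff_vs_lin[one$concept_class == "off"],
               one$accuracy[one$concept_class == "lin"] -
                 one$accuracy[one$concept_class == "off"])
})

test_that("matched invariant models hold accuracy exactly constant over p", {
  r <- noise_experiment("sample", noise_id = 2, p_grid = 0:3, n = 3,
                        r_count = 2, classes = "off", m_per_class = 15,
                        seed = 100)
  off <- r[r$concept_class == "off", ]
  for (rg in c("R2", "R1")) for (rp in 1:2) {
    acc <- off$accuracy[off$regularization == rg & off$rep == rp]
    expect_identical(length(unique(acc)), 1L)
  }
  expect_true(all(off$accuracy_loss_vs_p0 == 0))
  # the unconstrained model is hit hard at p >= 1 under scaling
  lin <- r[r$concept_class == "lin" & r$p >= 1, ]
  expect_gt(mean(lin$accuracy_loss_vs_p0), 0.1)
})

test_that("the identity noise type reproduces every p = 0 accuracy", {
  r <- noise_experiment("class", noise_id = 1, p_grid = 0:2, n = 2,
                        r_count = 2, classes = "con", m_per_class = 12,
                        seed = 101)
  expect_true(all(r$accuracy_loss_vs_p0 == 0))
})

test_that("stratified folds are balanced per class and in total", {
  set.seed(61)
  y <- c(rep(1L, 23), rep(0L, 37))
  fold <- consvm:::stratified_folds(y, 10)
  sizes <- table(fold)
  expect_lte(diff(range(sizes)), 1)
  for (lab in c(0L, 1L)) {
    cs <- table(fold[y == lab])
    expect_lte(diff(range(cs)), 1)
  }
})

test_that("cross-validation matches the baseline for constant-like data and warns on tiny classes", {
  set.seed(62)
  # labels independent of features: mean CV accuracy near the null 0.5
  # (200 samples keep the null standard error well inside the 0.1 band)
  d <- toy_dataset(matrix(rnorm(400), 200, 2), rep(c(0, 1), 100))
  cv <- cross_validate_10x10(d, classes = "lin", regularizations = "R2",
                             n_perms = 3, seed = 7)
  expect_lt(abs(cv$mean_accuracy - 0.5), 0.1)
  expect_identical(cv$n_folds_evaluated, 30L)

  small <- toy_dataset(matrix(rnorm(52), 26, 2),
                       c(rep(1, 6), rep(0, 20)))
  expect_warning(
    cross_validate_10x10(small, classes = "lin", regularizations = "R2",
                         n_perms = 2, seed = 8),
    "best-effort"
  )
})

test_that("experiment summaries pool means with interquartile ranges", {
  r <- noise_free_experiment(n = 2, d_grid = c(3, 4), r_count = 3,
                             classes = "off", m_per_class = 15, seed = 102)
  s <- summarize_experiment(dplyr::filter(r, concept_class == "off"))
  expect_identical(nrow(s), 1L)
  expect_true(s$iqr_lower <= s$mean | s$iqr_upper >= s$mean)
  expect_identical(s$n_runs, 12L)
})

test_that("experiment tables plot without error", {
  r <- noise_free_experiment(n = 2, d_grid = c(3, 4), r_count = 2,
                             classes = "off", m_per_class = 10, seed = 103)
  p <- ggplot2::autoplot(r)
  expect_s3_class(p, "ggplot")
  set.seed(63)
  fit <- svm_train(simulate_dataset(2, 4, 10), concept_class = "con")
  expect_s3_class(plot_weights(fit), "ggplot")
})
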