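test_that("offset-free R2 recovers the max-margin hyperplane through the origin", {
  d <- toy_dataset(rbind(c(1, 0), c(-1, 0)), c(1, 0))
  for (C in c(1, 10)) {
    fit <- svm_train(d, concept_class = "off", regularization = "R2", C = C)
    expect_identical(fit$status, "solved")
    # closed form: constraint w1 >= 1 active, w = (1, 0), objective 1/2
    expect_equal(fit$model$w, c(1, 0), tolerance = 1e-6)
    expect_identical(fit$model$t, 0)
    expect_equal(fit$objective, 0.5, tolerance = 1e-6)
    expect_true(all(fit$slacks < 1e-8))
  }
})

test_that("imposed structural constraints hold exactly in returned models", {
  set.seed(21)
  d <- simulate_dataset(n = 4, d = 3, m_per_class = 15)
  for (cls in c("off", "con", "off_con", "mon")) {
    for (rg in c("R2", "R1")) {
      fit <- svm_train(d, concept_class = cls, regularization = rg)
      chk <- check_membership(fit$model, cls, tol = 1e-6)
      expect_true(chk$member, label = paste(cls, rg, ":",
                                            paste(chk$violations, collapse = ";")))
    }
  }
})

test_that("in 2-D the offset-free contrast direction is forced to (1,-1)", {
  set.seed(22)
  z <- c(rnorm(20, 3), rnorm(20, -3))
  X <- cbind(5 + z / 2, 5 - z / 2)   # separable exactly along x1 - x2
  d <- toy_dataset(X, rep(c(1, 0), each = 20))
  for (rg in c("R2", "R1")) {
    fit <- svm_train(d, concept_class = "off_con", regularization = rg)
    w <- fit$model$w / max(abs(fit$model$w))
    expect_equal(w, c(1, -1), tolerance = 1e-6)
  }
})

test_that("the L1 penalty drives irrelevant weights to zero", {
  set.seed(23)
  x1 <- c(rnorm(25, 4), rnorm(25, -4))   # informative
  X <- cbind(x1, matrix(rnorm(50 * 3), 50, 3))
  d <- toy_dataset(X, rep(c(1, 0), each = 25))
  fit <- svm_train(d, concept_class = "lin", regularization = "R1")
  expect_identical(sparsity(fit$model$w), 1L)
  expect_gt(abs(fit$model$w[1]), 0)
  # R2 on the same data predicts identically on the training set
  fit2 <- svm_train(d, concept_class = "lin", regularization = "R2")
  expect_identical(predict(fit, d), predict(fit2, d))
  # offset-free L1 keeps the threshold at exactly zero
  fit3 <- svm_train(d, concept_class = "off", regularization = "R1")
  expect_identical(fit3$model$t, 0)
})

test_that("pairwise-comparison training selects the generating pair", {
  set.seed(24)
  X <- matrix(runif(40 * 4, 0, 10), 40, 4)
  y <- as.integer(X[, 1] >= X[, 2])
  d <- toy_dataset(X, y)
  for (rg in c("R2", "R1")) {
    fit <- svm_train(d, concept_class = "mon", regularization = rg)
    expect_identical(unname(fit$pair), c(1L, 2L))
    expect_equal(accuracy(fit, d), 1)
    # negated labels flip the pair orientation
    fit2 <- svm_train(toy_dataset(X, 1L - y), concept_class = "mon",
                      regularization = rg)
    expect_identical(unname(fit2$pair), c(2L, 1L))
  }
})

test_that("pairwise training accuracy matches pair enumeration on a hard 4-point set", {
  # z = x1 - x2 takes values (1, 2, -1, -2); labels agree with z >= 0 on
  # three points only, so the best pairwise rule scores 3/4
  X <- cbind(c(5, 6, 3, 2), c(4, 4, 4, 4))
  y <- c(1, 1, 0, 1)
  expect_equal(mon_best_accuracy_2d(X, y), 0.75)
  fit <- svm_train(toy_dataset(X, y), concept_class = "mon")
  expect_equal(accuracy(fit, toy_dataset(X, y)), 0.75)
})

test_that("objectives are monotone along the nested-class lattice", {
  set.seed(25)
  for (rep in 1:5) {
    d <- simulate_dataset(n = 3, d = 2, m_per_class = 12)
    for (rg in c("R2", "R1")) {
      obj <- vapply(c("lin", "off", "con", "off_con"), function(cls) {
        svm_train(d, concept_class = cls, regularization = rg)$objective
      }, numeric(1))
      tol <- 1e-7 * (1 + abs(obj[["lin"]]))
      expect_lte(obj[["lin"]], obj[["off"]] + tol)
      expect_lte(obj[["lin"]], obj[["con"]] + tol)
      expect_lte(obj[["off"]], obj[["off_con"]] + tol)
      expect_lte(obj[["con"]], obj[["off_con"]] + tol)
    }
  }
})

test_that("QP and LP optima agree with dense grid search in 2-D", {
  set.seed(26)
  for (rep in 1:3) {
    X <- matrix(rnorm(12, sd = 2), 6, 2) + rep(c(2, -2), each = 3)
    ys <- rep(c(1, -1), each = 3)
    d <- toy_dataset(X, as.integer(ys == 1))
    for (cls in c("lin", "off", "con", "off_con")) {
      for (rg in c("R2", "R1")) {
        fit <- svm_train(d, concept_class = cls, regularization = rg)
        oracle <- grid_search_objective_2d(X, ys, rg, C = 1, concept_class = cls)
        # the solver can only beat the finite grid
        expect_lte(fit$objective, oracle * (1 + 1e-6))
        expect_lt(abs(fit$objective - oracle) / oracle, 0.01)
      }
    }
  }
})

test_that("the R2 path agrees with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(27)
  d <- simulate_dataset(n = 5, d = 3, m_per_class = 20)
  X <- as.matrix(d[paste0("x", 1:5)])
  ys <- ifelse(d$label == 1, 1, -1)
  fit <- svm_train(d, concept_class = "lin", regularization = "R2", C = 1)
  ref <- e1071::svm(X, factor(d$label), kernel = "linear", cost = 1,
                    scale = FALSE)
  w_ref <- drop(t(ref$coefs) %*% ref$SV)
  obj_ref <- min(
    svm_objective(w_ref, ref$rho, X, ys, "R2", 1),
    svm_objective(-w_ref, -ref$rho, X, ys, "R2", 1)
  )
  expect_lt(abs(fit$objective - obj_ref) / obj_ref, 0.01)
})

test_that("degenerate and invalid training inputs are handled explicitly", {
  d <- toy_dataset(matrix(rnorm(10), 5, 2), rep(1L, 5))
  expect_error(svm_train(d), "both classes")
  d2 <- toy_dataset(matrix(rnorm(4), 4, 1), c(1, 0, 1, 0))
  expect_error(svm_train(d2, concept_class = "mon"), "n >= 2")
  expect_error(svm_train(d2, concept_class = "stc"), "not trainable")
  # duplicate points with conflicting labels are legal; slack absorbs them
  X <- rbind(c(1, 1), c(1, 1), c(3, 0), c(-3, 0))
  fit <- svm_train(toy_dataset(X, c(1, 0, 1, 0)), concept_class = "lin")
  expect_identical(fit$status, "solved")
  expect_gt(sum(fit$slacks), 0.5)
})

test_that("tidy and glance summarize fits in broom style", {
  set.seed(28)
  d <- simulate_dataset(n = 3, d = 4, m_per_class = 10)
  fit <- svm_train(d, concept_class = "con", regularization = "R1")
  td <- tidy(fit)
  expect_identical(nrow(td), 4L)  # 3 weights + threshold
  expect_identical(td$term[4], "(threshold)")
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$concept_class, "con")
  expect_true(gl$objective > 0)
})
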