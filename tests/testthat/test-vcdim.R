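test_that("any labeling of 3 general-position points is linearly realizable", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  for (code in 0:7) {
    labels <- as.integer(bitwAnd(bitwShiftR(code, 0:2), 1L))
    expect_true(realizable(pts, labels, "lin"), label = paste(labels, collapse = ""))
  }
  expect_true(is_shattered(pts, "lin"))
})

test_that("pairwise rules on tied coordinates realize only the all-ones labeling", {
  pts <- rbind(c(1, 1), c(2, 2))   # x1 == x2 everywhere: both pairs predict 1
  expect_true(realizable(pts, c(1, 1), "mon"))
  for (lab in list(c(0, 0), c(1, 0), c(0, 1))) {
    expect_false(realizable(pts, lab, "mon"))
  }
})

test_that("a single point is shattered by off_con in 2-D but no pair is", {
  pt <- rbind(c(2, 1))
  expect_true(realizable(pt, 1, "off_con"))
  expect_true(realizable(pt, 0, "off_con"))
  expect_true(is_shattered(pt, "off_con"))
  set.seed(31)
  for (k in 1:25) {
    expect_false(is_shattered(matrix(rnorm(4), 2, 2), "off_con"))
    expect_false(is_shattered(matrix(rnorm(4), 2, 2), "mon"))
  }
})

test_that("single-threshold realizability follows the 1-D orderings", {
  pts <- rbind(c(0, 5), c(1, 4), c(2, 3))
  expect_true(realizable(pts, c(0, 0, 1), "stc"))   # x1 >= 1.5
  expect_true(realizable(pts, c(1, 1, 0), "stc"))   # -x1 >= -0.5
  expect_false(realizable(pts, c(1, 0, 1), "stc"))  # not an interval end
  expect_true(realizable(rbind(c(-1, 9), c(2, 9)), c(0, 1), "stc_off"))
})

test_that("constructed sets certify the expected VC lower bounds", {
  set.seed(32)
  for (n in 2:4) {
    expect_identical(vc_lower_bound("lin", n, n_random = 5), n + 1L)
    expect_identical(vc_lower_bound("off", n, n_random = 5), as.integer(n))
    expect_identical(vc_lower_bound("con", n, n_random = 5), as.integer(n))
    expect_identical(vc_lower_bound("off_con", n, n_random = 5), n - 1L)
  }
})

test_that("the pairwise-class lower bound respects the counting ceiling", {
  set.seed(33)
  for (n in 2:5) {
    lb <- vc_lower_bound("mon", n, n_random = 50)
    expect_lte(lb, floor(log2(n * (n - 1))))
    expect_gte(lb, 1L)
  }
})

test_that("claimed VC upper bounds survive random falsification attempts", {
  set.seed(34)
  expect_true(vc_upper_falsify("off_con", n = 2, m = 2, trials = 200))
  expect_true(vc_upper_falsify("lin", n = 2, m = 4, trials = 200))
  expect_true(vc_upper_falsify("off", n = 2, m = 3, trials = 100))
  # mon: 2^3 = 8 > 6 = n(n-1) labelings available -> exact impossibility
  expect_true(vc_upper_falsify("mon", n = 3, m = 3, trials = 50))
})

test_that("lower bounds are monotone along the nested-class lattice", {
  set.seed(35)
  for (n in 2:4) {
    lb <- vapply(c("lin", "off", "con", "off_con"), vc_lower_bound,
                 integer(1), n = n, n_random = 5)
    expect_lte(lb[["off"]], lb[["lin"]])
    expect_lte(lb[["con"]], lb[["lin"]])
    expect_lte(lb[["off_con"]], lb[["off"]])
    expect_lte(lb[["off_con"]], lb[["con"]])
  }
})

test_that("realizability agrees with hard-margin training at large cost", {
  set.seed(36)
  for (rep in 1:6) {
    m <- sample(2:4, 1)
    pts <- matrix(rnorm(m * 2), m, 2)
    for (cls in c("lin", "off", "con", "off_con", "mon")) {
      for (code in 0:(2^m - 1)) {
        labels <- as.integer(bitwAnd(bitwShiftR(code, 0:(m - 1)), 1L))
        feasible <- realizable(pts, labels, cls)
        if (length(unique(labels)) < 2L) next  # trainer needs both classes
        # the L1 path is an exact linear program, so a huge cost is safe
        fit <- svm_train(toy_dataset(pts, labels), concept_class = cls,
                         regularization = "R1", C = 1e6)
        zero_err <- !is.null(fit$model) &&
          accuracy(fit, toy_dataset(pts, labels)) == 1
        expect_identical(feasible, zero_err,
                         label = paste(cls, "labels", paste(labels, collapse = "")))
      }
    }
  }
})
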