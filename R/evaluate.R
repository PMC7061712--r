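#' Empirical accuracy of a classifier on a labeled dataset
#'
#' @param model a [linear_model()] or a fitted [svm_train()] object.
#' @param data data frame with feature columns and a label column.
#' @param label name of the label column.
#' @return fraction of correct predictions in `[0, 1]`.
#' @export
accuracy <- function(model, data, label = "label") {
  if (nrow(data) == 0L) stop("test set is empty", call. = FALSE)
  X <- data[setdiff(names(data), label)]
  mean(predict(model, X) == as.integer(data[[label]]))
}

#' Accuracy of the larger-class baseline
#'
#' The classifier that always predicts the majority class.
#'
#' @param y label vector.
#' @return the largest class frequency.
#' @export
baseline_accuracy <- function(y) {
  if (length(y) == 0L) stop("empty label vector", call. = FALSE)
  max(table(y)) / length(y)
}

# deterministic child seed for a sub-experiment; keeps streams
# re-runnable per cell and below 2^31
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k)) %% 2147483647
  as.integer(s)
}

train_configs <- function(classes, regularizations) {
  grid <- expand.grid(concept_class = classes, regularization = regularizations,
                      stringsAsFactors = FALSE)
  grid[order(grid$regularization, grid$concept_class), , drop = FALSE]
}

# train every (class, reg) config on `train`, score on `test`;
# returns tibble rows with accuracy and the same-regularization
# lin-minus-model accuracy difference
score_configs <- function(train, test, classes, regularizations, C) {
  cfg <- train_configs(unique(c("lin", classes)), regularizations)
  acc <- mapply(function(cl, rg) {
    fit <- svm_train(train, concept_class = cl, regularization = rg, C = C)
    accuracy(fit, test)
  }, cfg$concept_class, cfg$regularization)
  out <- tibble::tibble(concept_class = cfg$concept_class,
                        regularization = cfg$regularization,
                        accuracy = as.numeric(acc))
  lin <- out[out$concept_class == "lin", c("regularization", "accuracy")]
  names(lin)[2] <- "lin_accuracy"
  out <- dplyr::left_join(out, lin, by = "regularization")
  out$accuracy_diff_vs_lin <- out$lin_accuracy - out$accuracy
  out$lin_accuracy <- NULL
  out[out$concept_class %in% c("lin", classes), , drop = FALSE]
}

as_experiment <- function(x) {
  class(x) <- c("consvm_experiment", class(x))
  x
}

#' Noise-free benchmark: accuracy of invariant SVMs versus the standard SVM
#'
#' For every centroid distance `d` and repetition, draws fresh centroids,
#' a 2 x `m_per_class` training set and an equally sized test set from the
#' spherical Gaussian model, trains all configured SVMs on the same
#' training set and scores them on the same test set. Each invariant
#' model is compared against the standard (`lin`) SVM with the same
#' regularization: `accuracy_diff_vs_lin` is lin-minus-model, so positive
#' values mean the unconstrained SVM was more accurate.
#'
#' @param n feature dimension.
#' @param d_grid centroid distances (default the benchmark grid
#'   `seq(1, 5, by = 0.1)`).
#' @param r_count repetitions per distance.
#' @param classes invariant concept classes to train (lin is always
#'   included as the reference).
#' @param regularizations subset of `c("R2", "R1")`.
#' @param C soft-margin cost.
#' @param m_per_class samples per class in train and in test.
#' @param seed root seed; every `(d, repetition)` cell derives its own
#'   child stream, so cells are individually reproducible.
#' @return tibble with columns `concept_class`, `regularization`, `n`,
#'   `d`, `rep`, `accuracy`, `accuracy_diff_vs_lin`.
#' @export
noise_free_experiment <- function(n, d_grid = seq(1, 5, by = 0.1),
                                  r_count = 10,
                                  classes = c("off", "con", "off_con", "mon"),
                                  regularizations = c("R2", "R1"),
                                  C = 1, m_per_class = 50, seed = 1) {
  rows <- list(); k <- 0L
  for (di in seq_along(d_grid)) {
    for (r in seq_len(r_count)) {
      set.seed(child_seed(seed, 1L, di, r))
      cent <- make_centroids(n, d_grid[di])
      train <- simulate_dataset(n, d_grid[di], m_per_class, centroids = cent)
      test <- simulate_dataset(n, d_grid[di], m_per_class, centroids = cent)
      sc <- score_configs(train, test, classes, regularizations, C)
      sc$n <- n; sc$d <- d_grid[di]; sc$rep <- r
      k <- k + 1L; rows[[k]] <- sc
    }
  }
  out <- dplyr::bind_rows(rows)
  as_experiment(out[, c("concept_class", "regularization", "n", "d", "rep",
                        "accuracy", "accuracy_diff_vs_lin")])
}

#' Noise benchmark: sample-wise or class-wise data transformations
#'
#' One repetition draws fresh centroids and a raw 2 x `m_per_class`
#' train/test pair at centroid distance `d`; the same raw pair underlies
#' all noise levels of that repetition, so an invariant model's accuracy
#' trace over `p` is exactly constant under its matched noise family.
#'
#' * `scope = "sample"`: models are trained on the raw training set; for
#'   each noise level every test sample is transformed with its own
#'   parameter draw.
#' * `scope = "class"`: for each noise level, one parameter draw per
#'   class transforms the training set and an independent per-class draw
#'   transforms the test set; models are retrained on the transformed
#'   training set.
#'
#' `accuracy_loss_vs_p0` is the model's own accuracy at `p = 0` minus its
#' accuracy at `p`, computed within (class, regularization, repetition);
#' it requires `0` in `p_grid` and is `NA` otherwise.
#'
#' @param scope `"sample"` or `"class"`.
#' @param noise_id noise type 1..5 (none, scaling, transition,
#'   scaling+transition, exponential).
#' @param p_grid noise levels (default `0:5`).
#' @param n feature dimension.
#' @param d centroid distance (default 4, the benchmark value for noise
#'   runs).
#' @inheritParams noise_free_experiment
#' @return tibble with columns `concept_class`, `regularization`,
#'   `scope`, `noise_id`, `n`, `p`, `rep`, `accuracy`,
#'   `accuracy_loss_vs_p0`, `accuracy_diff_vs_lin`.
#' @export
noise_experiment <- function(scope = c("sample", "class"), noise_id,
                             p_grid = 0:5, n, d = 4, r_count = 10,
                             classes = c("off", "con", "off_con", "mon"),
                             regularizations = c("R2", "R1"),
                             C = 1, m_per_class = 50, seed = 1) {
  scope <- match.arg(scope)
  rows <- list(); k <- 0L
  for (r in seq_len(r_count)) {
    set.seed(child_seed(seed, 2L, r))
    cent <- make_centroids(n, d)
    train <- simulate_dataset(n, d, m_per_class, centroids = cent)
    test <- simulate_dataset(n, d, m_per_class, centroids = cent)

    if (scope == "sample") {
      cfg <- train_configs(unique(c("lin", classes)), regularizations)
      fits <- Map(function(cl, rg) {
        svm_train(train, concept_class = cl, regularization = rg, C = C)
      }, cfg$concept_class, cfg$regularization)
      for (pi in seq_along(p_grid)) {
        set.seed(child_seed(seed, 3L, r, pi))
        te <- samplewise_noisify(test, noise_id, p_grid[pi])
        sc <- tibble::tibble(
          concept_class = cfg$concept_class,
          regularization = cfg$regularization,
          accuracy = vapply(fits, accuracy, numeric(1), data = te)
        )
        sc$p <- p_grid[pi]; sc$rep <- r
        k <- k + 1L; rows[[k]] <- sc
      }
    } else {
      for (pi in seq_along(p_grid)) {
        set.seed(child_seed(seed, 3L, r, pi))
        noisy <- classwise_noisify(train, test, noise_id, p_grid[pi])
        sc <- score_configs(noisy$train, noisy$test, classes,
                            regularizations, C)
        sc$p <- p_grid[pi]; sc$rep <- r
        k <- k + 1L; rows[[k]] <- sc
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$scope <- scope; out$noise_id <- noise_id; out$n <- n

  # lin-minus-model difference (sample scope computes it here; class
  # scope rows already carry it from score_configs)
  if (!"accuracy_diff_vs_lin" %in% names(out)) {
    lin <- out[out$concept_class == "lin",
               c("regularization", "p", "rep", "accuracy")]
    names(lin)[4] <- "lin_accuracy"
    out <- dplyr::left_join(out, lin, by = c("regularization", "p", "rep"))
    out$accuracy_diff_vs_lin <- out$lin_accuracy - out$accuracy
    out$lin_accuracy <- NULL
  }

  # own-p0 reference loss
  if (0 %in% p_grid) {
    p0 <- out[out$p == 0,
              c("concept_class", "regularization", "rep", "accuracy")]
    names(p0)[4] <- "p0_accuracy"
    out <- dplyr::left_join(out, p0,
                            by = c("concept_class", "regularization", "rep"))
    out$accuracy_loss_vs_p0 <- out$p0_accuracy - out$accuracy
    out$p0_accuracy <- NULL
  } else {
    out$accuracy_loss_vs_p0 <- NA_real_
  }
  as_experiment(out[, c("concept_class", "regularization", "scope",
                        "noise_id", "n", "p", "rep", "accuracy",
                        "accuracy_loss_vs_p0", "accuracy_diff_vs_lin")])
}

#' Pooled summary of an experiment table
#'
#' Mean and interquartile range of a result column, pooled over both
#' regularizations (and any column not listed in `by`).
#'
#' @param result a tibble from [noise_free_experiment()] or
#'   [noise_experiment()].
#' @param value column to summarize (default `accuracy_diff_vs_lin`).
#' @param by grouping columns.
#' @return tibble with `mean`, `iqr_lower` (25%), `iqr_upper` (75%) and
#'   `n_runs`.
#' @export
summarize_experiment <- function(result, value = "accuracy_diff_vs_lin",
                                 by = "concept_class") {
  stopifnot(value %in% names(result))
  result |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      iqr_lower = stats::quantile(.data[[value]], 0.25, names = FALSE),
      iqr_upper = stats::quantile(.data[[value]], 0.75, names = FALSE),
      n_runs = dplyr::n(),
      .groups = "drop"
    )
}

stratified_folds <- function(y, n_folds) {
  idx1 <- sample(which(y == 1L)); idx0 <- sample(which(y == 0L))
  ord <- c(idx1, idx0)
  fold <- integer(length(y))
  fold[ord] <- rep_len(seq_len(n_folds), length(ord))
  fold
}

#' Repeated stratified cross-validation
#'
#' The 10 x 10 protocol: `n_perms` random permutations of the data, each
#' split into `n_folds` stratified folds of approximately equal size
#' (sizes differ by at most one); the mean test accuracy over all
#' `n_perms * n_folds` folds is reported per configuration.
#'
#' @param data data frame with feature columns and a binary label column.
#' @param classes concept classes to evaluate.
#' @param regularizations subset of `c("R2", "R1")`.
#' @param C soft-margin cost.
#' @param n_perms,n_folds protocol size (default 10 x 10).
#' @param label name of the label column.
#' @param seed root seed.
#' @param detail if `TRUE`, return the per-fold table instead of the
#'   summary.
#' @return tibble with `concept_class`, `regularization`,
#'   `mean_accuracy`, `sd_accuracy`, `n_folds_evaluated` (or the
#'   per-fold table when `detail = TRUE`).
#' @export
cross_validate_10x10 <- function(data, classes = "lin",
                                 regularizations = c("R2", "R1"),
                                 C = 1, n_perms = 10, n_folds = 10,
                                 label = "label", seed = 1,
                                 detail = FALSE) {
  y <- as.integer(data[[label]])
  if (length(y) < 2 * n_folds) {
    stop("need at least ", 2 * n_folds, " samples for ", n_folds,
         "-fold cross-validation", call. = FALSE)
  }
  if (min(table(y)) < n_folds) {
    warning("a class has fewer than ", n_folds,
            " members; stratification is best-effort and some folds may ",
            "lack that class", call. = FALSE)
  }
  cfg <- train_configs(classes, regularizations)
  rows <- list(); k <- 0L
  for (perm in seq_len(n_perms)) {
    set.seed(child_seed(seed, 4L, perm))
    fold <- stratified_folds(y, n_folds)
    for (fd in seq_len(n_folds)) {
      tr <- data[fold != fd, , drop = FALSE]
      te <- data[fold == fd, , drop = FALSE]
      if (length(unique(tr[[label]])) < 2L) next
      acc <- mapply(function(cl, rg) {
        fit <- svm_train(tr, concept_class = cl, regularization = rg,
                         C = C, label = label)
        accuracy(fit, te, label = label)
      }, cfg$concept_class, cfg$regularization)
      k <- k + 1L
      rows[[k]] <- tibble::tibble(concept_class = cfg$concept_class,
                                  regularization = cfg$regularization,
                                  perm = perm, fold = fd,
                                  accuracy = as.numeric(acc))
    }
  }
  folds <- dplyr::bind_rows(rows)
  if (detail) return(folds)
  folds |>
    dplyr::group_by(.data$concept_class, .data$regularization) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = stats::sd(.data$accuracy),
                     n_folds_evaluated = dplyr::n(),
                     .groups = "drop")
}
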