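#' @useDynLib consvm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# --- internal: extract (X, y01) from a data frame / matrix + label -----------

dataset_xy <- function(data, y = NULL, label = "label") {
  if (is.data.frame(data)) {
    if (!label %in% names(data)) {
      stop("data has no '", label, "' column", call. = FALSE)
    }
    yv <- data[[label]]
    X <- as.matrix(data[setdiff(names(data), label)])
  } else {
    if (is.null(y)) stop("y must be supplied when data is a matrix", call. = FALSE)
    X <- as.matrix(data)
    yv <- y
  }
  if (!is.numeric(X)) stop("feature columns must be numeric", call. = FALSE)
  yv <- as.integer(yv)
  if (!all(yv %in% c(0L, 1L))) {
    stop("labels must be in {0, 1}", call. = FALSE)
  }
  if (length(yv) != nrow(X)) stop("label length does not match rows", call. = FALSE)
  list(X = X, y01 = yv)
}

# labels {0,1} -> {+1,-1}: 1 -> +1, 0 -> -1 (fixed convention)
y_signed <- function(y01) ifelse(y01 == 1L, 1, -1)

hinge_sum <- function(w, t, X, ys) {
  sum(pmax(0, 1 - ys * (drop(X %*% w) - t)))
}

# --- internal solver backends ------------------------------------------------

# R2 primal QP: vars [w, (t), xi]; min .5||w||^2 + C sum xi
# s.t. (sum w = 0 if contrast), y_i (w'x_i - t) >= 1 - xi_i, xi >= 0.
# The t column is eliminated for offset-free classes. A diagonal ridge on
# the t and xi variables makes the quadratic form positive definite for
# quadprog; its contribution at the optimum is negligible (xi is pushed to
# the hinge value, the ridge is 1e-8).
solve_qp_primal <- function(X, ys, C, offset_free, contrast) {
  n <- ncol(X); m <- nrow(X)
  has_t <- !offset_free
  nv <- n + has_t + m
  ridge <- 1e-8
  Dmat <- diag(c(rep(1, n), rep(ridge, has_t), rep(ridge, m)), nv)
  dvec <- c(rep(0, n + has_t), rep(-C, m))

  rows <- list()
  meq <- 0L
  if (contrast) {
    rows[[length(rows) + 1L]] <- c(rep(1, n), rep(0, has_t + m))
    meq <- 1L
  }
  margin <- cbind(X * ys, if (has_t) -ys, diag(m))
  slackpos <- cbind(matrix(0, m, n + has_t), diag(m))
  Amat <- t(rbind(do.call(rbind, rows), margin, slackpos))
  bvec <- c(rep(0, meq), rep(1, m), rep(0, m))

  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = meq),
    error = function(e) e
  )
  if (inherits(sol, "error")) {
    return(list(status = "degenerate", w = rep(0, n), t = 0,
                message = conditionMessage(sol)))
  }
  v <- sol$solution
  list(status = "solved",
       w = v[seq_len(n)],
       t = if (has_t) v[n + 1L] else 0)
}

# R1 LP: vars [w+, w-, (t+, t-), xi]; min sum(w+ + w-) + C sum xi.
solve_lp_primal <- function(X, ys, C, offset_free, contrast) {
  n <- ncol(X); m <- nrow(X)
  has_t <- !offset_free
  nv <- 2 * n + 2 * has_t + m
  cvec <- c(rep(1, 2 * n), rep(0, 2 * has_t), rep(C, m))

  Ge <- cbind(X * ys, -X * ys,
              if (has_t) cbind(-ys, ys),
              diag(m))
  h <- rep(1, m)
  if (contrast) {
    Eq <- matrix(c(rep(1, n), rep(-1, n), rep(0, 2 * has_t + m)), 1, nv)
    f <- 0
  } else {
    Eq <- matrix(0, 0, nv); f <- numeric(0)
  }

  sol <- lp_solve_cpp(cvec, Eq, f, Ge, h)
  if (sol$status != 0) {
    return(list(status = if (sol$status == 1) "infeasible" else "degenerate",
                w = rep(0, n), t = 0))
  }
  v <- sol$x
  w <- v[seq_len(n)] - v[n + seq_len(n)]
  t <- if (has_t) v[2 * n + 1L] - v[2 * n + 2L] else 0
  list(status = "solved", w = w, t = t)
}

# --- user-facing trainer -----------------------------------------------------

#' Train a constrained soft-margin linear SVM
#'
#' Fits a linear classifier `1[<w, x> >= t]` by the soft-margin criterion,
#' with the structural constraints of the requested concept class imposed
#' as hard equality constraints:
#'
#' * `regularization = "R2"` minimises `0.5 ||w||_2^2 + C sum(xi)`
#'   (a convex quadratic program);
#' * `regularization = "R1"` minimises `||w||_1 + C sum(xi)` (a linear
#'   program via the split `w = w+ - w-`; the threshold is not penalised),
#'
#' both subject to `y_i (w' x_i - t) >= 1 - xi_i`, `xi_i >= 0`, plus
#' `t = 0` for offset-free classes and `sum(w) = 0` for contrast classes.
#' For `concept_class = "mon"` the fixed-form pairwise rules
#' `1[x_i - x_j >= 0]` are enumerated exhaustively and the scale of
#' `w = alpha (e_i - e_j)` is optimised exactly in one dimension; ties
#' between pairs break to the lexicographically smallest `(i, j)`.
#'
#' @param data data frame with a binary label column (values 0/1), or a
#'   numeric matrix accompanied by `y`.
#' @param concept_class one of `"lin"`, `"off"`, `"con"`, `"off_con"`,
#'   `"mon"`.
#' @param regularization `"R2"` (Euclidean) or `"R1"` (Manhattan).
#' @param C positive soft-margin cost.
#' @param y labels in `{0, 1}` when `data` is a matrix.
#' @param label name of the label column when `data` is a data frame.
#' @param solver_tol solver tolerance used for the post-fit structural
#'   membership check.
#' @return an object of class `invariant_svm`: a list with `model` (a
#'   [linear_model()]), `objective` (the value of the trained criterion,
#'   recomputed from the solution), `slacks`, `status` (`"solved"`,
#'   `"infeasible"` or `"degenerate"`), and the configuration fields.
#' @examples
#' set.seed(1)
#' d <- simulate_dataset(n = 2, d = 4)
#' fit <- svm_train(d, concept_class = "off")
#' fit$model$t  # exactly 0
#' @export
svm_train <- function(data, concept_class = "lin",
                      regularization = c("R2", "R1"), C = 1,
                      y = NULL, label = "label", solver_tol = 1e-8) {
  regularization <- match.arg(regularization)
  concept_class <- match_concept_class(concept_class)
  if (concept_class %in% c("stc", "stc_off")) {
    stop("single-threshold classes are not trainable by the SVM criterion; ",
         "use concept_class 'mon' for a fixed-form sparse rule", call. = FALSE)
  }
  stopifnot(C > 0, solver_tol > 0)
  dd <- dataset_xy(data, y = y, label = label)
  X <- dd$X; y01 <- dd$y01
  if (length(unique(y01)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  ys <- y_signed(y01)
  n <- ncol(X); m <- nrow(X)

  if (concept_class == "mon") {
    if (n < 2L) stop("pairwise-comparison training needs n >= 2 features", call. = FALSE)
    reg <- if (regularization == "R2") 2L else 1L
    res <- mon_search_cpp(X, ys, C, reg)
    alpha <- if (res$degenerate) 1 else res$alpha
    w <- numeric(n); w[res$i] <- alpha; w[res$j] <- -alpha
    model <- linear_model(w, t = 0, class = "mon", tol = solver_tol)
    out <- list(model = model, objective = res$objective,
                status = if (res$degenerate) "degenerate" else "solved",
                pair = c(i = res$i, j = res$j))
  } else {
    offset_free <- concept_class %in% c("off", "off_con")
    contrast <- concept_class %in% c("con", "off_con")
    fit <- if (regularization == "R2") {
      solve_qp_primal(X, ys, C, offset_free, contrast)
    } else {
      solve_lp_primal(X, ys, C, offset_free, contrast)
    }
    if (fit$status != "solved") {
      # a failed solve reports its status; no silent fallback model
      out <- list(model = NULL, objective = NA_real_,
                  status = fit$status, pair = NULL)
    } else {
      model <- linear_model(fit$w, t = fit$t, class = concept_class,
                            tol = max(solver_tol, 1e-6))
      regterm <- if (regularization == "R2") 0.5 * sum(fit$w^2) else sum(abs(fit$w))
      out <- list(model = model,
                  objective = regterm + C * hinge_sum(fit$w, fit$t, X, ys),
                  status = "solved", pair = NULL)
    }
  }

  if (!is.null(out$model)) {
    out$slacks <- pmax(0, 1 - ys * decision_values(out$model, X))
  } else {
    out$slacks <- rep(NA_real_, m)
  }
  out$concept_class <- concept_class
  out$regularization <- regularization
  out$C <- C
  out$solver_tol <- solver_tol
  out$n <- n
  out$m <- m
  class(out) <- "invariant_svm"
  out
}

#' @export
print.invariant_svm <- function(x, ...) {
  cat("<invariant_svm>", x$regularization, "SVM, class =", x$concept_class,
      ", C =", x$C, "\n")
  cat("  status:", x$status, " objective:", signif(x$objective, 6), "\n")
  if (!is.null(x$model)) {
    cat("  sparsity:", sparsity(x$model$w), "of", x$n, "features\n")
  }
  invisible(x)
}

#' @export
predict.invariant_svm <- function(object, newdata, ...) {
  if (is.null(object$model)) {
    stop("no model available (solver status: ", object$status, ")", call. = FALSE)
  }
  predict(object$model, newdata, ...)
}
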