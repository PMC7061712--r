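#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted constrained SVM
#'
#' One row per feature with its weight; the threshold appears as term
#' `"(threshold)"`.
#'
#' @param x an [svm_train()] fit.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `active`.
#' @export
tidy.invariant_svm <- function(x, ...) {
  if (is.null(x$model)) {
    stop("no model available (solver status: ", x$status, ")", call. = FALSE)
  }
  w <- x$model$w
  mx <- max(abs(w))
  tibble::tibble(
    term = c(paste0("x", seq_along(w)), "(threshold)"),
    estimate = c(w, x$model$t),
    active = c(if (mx > 0) abs(w) > 1e-8 * mx else rep(FALSE, length(w)), NA)
  )
}

#' One-row summary of a fitted constrained SVM
#'
#' @param x an [svm_train()] fit.
#' @param ... unused.
#' @return a tibble with columns `concept_class`, `regularization`, `C`,
#'   `objective`, `sparsity`, `total_slack`, `status`, `n`, `m`.
#' @export
glance.invariant_svm <- function(x, ...) {
  tibble::tibble(
    concept_class = x$concept_class,
    regularization = x$regularization,
    C = x$C,
    objective = x$objective,
    sparsity = if (is.null(x$model)) NA_integer_ else sparsity(x$model$w),
    total_slack = sum(x$slacks),
    status = x$status,
    n = x$n,
    m = x$m
  )
}
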