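#' Data-transformation families
#'
#' The noise / artefact families studied by the package, indexed as in the
#' benchmark protocol:
#'
#' 1. `none` — identity.
#' 2. `scaling` — `x -> a * x`, `a > 0` (global rescaling, e.g. a
#'    normalization artefact).
#' 3. `transition` — `x -> x + b * 1` (a common shift of every feature,
#'    e.g. a reference-point artefact).
#' 4. `affine` — `x -> a * x + b * 1`.
#' 5. `monotone_exp` — `x -> exp(0.2 * c * x)` elementwise, the
#'    representative strictly increasing nonlinear map.
#'
#' @param kind one of `"none"`, `"scaling"`, `"transition"`, `"affine"`,
#'   `"monotone_exp"`.
#' @param a positive scale (scaling / affine).
#' @param b shift applied as `b * 1` (transition / affine).
#' @param c positive exponent parameter (monotone_exp).
#' @return an object of class `transform_params`.
#' @export
transform_params <- function(kind = c("none", "scaling", "transition",
                                      "affine", "monotone_exp"),
                             a = NULL, b = NULL, c = NULL) {
  kind <- match.arg(kind)
  need <- switch(kind,
    none = character(0),
    scaling = "a",
    transition = "b",
    affine = c("a", "b"),
    monotone_exp = "c"
  )
  got <- list(a = a, b = b, c = c)
  for (p in c("a", "b", "c")) {
    if (p %in% need && is.null(got[[p]])) {
      stop("transform kind '", kind, "' requires parameter '", p, "'", call. = FALSE)
    }
    if (!p %in% need) got[[p]] <- NULL
  }
  if (!is.null(got$a) && got$a <= 0) {
    stop("scale parameter a must be positive (got ", got$a, ")", call. = FALSE)
  }
  if (!is.null(got$c) && got$c <= 0) {
    stop("exponent parameter c must be positive (got ", got$c, ")", call. = FALSE)
  }
  structure(c(list(kind = kind), got), class = "transform_params")
}

#' @export
print.transform_params <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat("<transform_params>", x$kind,
      if (length(pars)) paste(names(pars), signif(unlist(pars), 4),
                              sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Apply a transformation to samples
#'
#' @param x numeric vector (one sample) or matrix (samples in rows).
#' @param params a [transform_params()].
#' @return object of the same shape as `x`.
#' @examples
#' apply_transform(c(1, -3), transform_params("scaling", a = 2))
#' @export
apply_transform <- function(x, params) {
  stopifnot(inherits(params, "transform_params"), is.numeric(x), all(is.finite(x)))
  switch(params$kind,
    none = x,
    scaling = params$a * x,
    transition = x + params$b,
    affine = params$a * x + params$b,
    monotone_exp = exp(0.2 * params$c * x)
  )
}

#' Map a noise type id to its transformation kind
#'
#' @param noise_id integer in 1..5.
#' @return the transformation kind string.
#' @export
noise_kind <- function(noise_id) {
  stopifnot(length(noise_id) == 1L, noise_id %in% 1:5)
  c("none", "scaling", "transition", "affine", "monotone_exp")[noise_id]
}

#' Draw transformation parameters for a noise type at level p
#'
#' Parameters follow the benchmark protocol: `a ~ U(1e-5, p)`,
#' `b ~ U(-p, p)`, `c ~ U(1e-5, p)`, as required by the noise type.
#' `p = 0` (or noise type 1) yields the identity: the degenerate uniform
#' support is read as "no noise".
#'
#' Uses the current R random number generator state.
#'
#' @param noise_id integer 1..5 (none, scaling, transition, affine,
#'   exponential).
#' @param p noise level in `[0, 5]`.
#' @return a [transform_params()].
#' @export
draw_transform_params <- function(noise_id, p) {
  stopifnot(length(p) == 1L, is.finite(p))
  if (p < 0) stop("noise level p must be nonnegative (got ", p, ")", call. = FALSE)
  kind <- noise_kind(noise_id)
  if (p == 0 || kind == "none") return(transform_params("none"))
  switch(kind,
    scaling = transform_params("scaling", a = stats::runif(1, 1e-5, p)),
    transition = transform_params("transition", b = stats::runif(1, -p, p)),
    affine = transform_params("affine",
                              a = stats::runif(1, 1e-5, p),
                              b = stats::runif(1, -p, p)),
    monotone_exp = transform_params("monotone_exp", c = stats::runif(1, 1e-5, p))
  )
}

#' Empirically verify invariance of a model against a transformation family
#'
#' For every sample and `n_draws` random parameter draws per sample,
#' compares the model's prediction on the original sample with the
#' prediction on the transformed sample. A disagreement counts as a
#' counterexample only when both decision values lie outside a numerical
#' guard band (default `1e-9 * ||w|| * ||x||` per sample): sign flips at
#' the exact decision boundary are floating-point artefacts, not theory
#' violations. Disagreements inside the band are reported separately as
#' indeterminate.
#'
#' @param model a [linear_model()].
#' @param family transformation kind, or a function `x -> x` applied
#'   row-wise (for testing invariance under arbitrary strictly increasing
#'   maps; the function receives and returns a numeric vector).
#' @param X matrix or data frame of samples (a `label` column is ignored).
#' @param n_draws parameter draws per sample.
#' @param p_max noise level used for the draws.
#' @param margin_tol guard band; `NULL` for the default described above.
#' @return a list with `invariant` (logical), `counterexamples` and
#'   `indeterminate` (tibbles with columns `sample`, `draw`, `kind`,
#'   `a`, `b`, `c`, `decision_original`, `decision_transformed`).
#' @export
verify_invariance <- function(model, family, X, n_draws = 20, p_max = 5,
                              margin_tol = NULL) {
  stopifnot(inherits(model, "linear_model"), n_draws >= 1)
  X <- feature_matrix(X, model$n)
  if (nrow(X) == 0L) stop("X must contain at least one sample", call. = FALSE)
  wn <- sqrt(sum(model$w^2))

  is_fun <- is.function(family)
  if (!is_fun) {
    family <- match.arg(family, c("none", "scaling", "transition", "affine",
                                  "monotone_exp"))
    noise_id <- match(family, c("none", "scaling", "transition", "affine",
                                "monotone_exp"))
  }

  rows <- list(); bad <- logical(0); k <- 0L
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    band_x <- if (is.null(margin_tol)) 1e-9 * wn * sqrt(sum(x^2)) else margin_tol
    f0 <- sum(model$w * x) - model$t
    for (dr in seq_len(n_draws)) {
      if (is_fun) {
        xt <- family(x)
        th <- transform_params("none")
      } else {
        th <- draw_transform_params(noise_id, p_max)
        xt <- apply_transform(x, th)
      }
      f1 <- sum(model$w * xt) - model$t
      if ((f0 >= 0) != (f1 >= 0)) {
        band_t <- if (is.null(margin_tol)) 1e-9 * wn * sqrt(sum(xt^2)) else margin_tol
        outside <- abs(f0) > band_x && abs(f1) > band_t
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          sample = i, draw = dr, kind = th$kind,
          a = th$a %||% NA_real_, b = th$b %||% NA_real_, c = th$c %||% NA_real_,
          decision_original = f0, decision_transformed = f1
        )
        bad[k] <- outside
      }
    }
  }
  disagreements <- if (k) dplyr::bind_rows(rows) else tibble::tibble(
    sample = integer(0), draw = integer(0), kind = character(0),
    a = numeric(0), b = numeric(0), c = numeric(0),
    decision_original = numeric(0), decision_transformed = numeric(0)
  )
  list(
    invariant = !any(bad),
    counterexamples = disagreements[bad, , drop = FALSE],
    indeterminate = disagreements[!bad, , drop = FALSE]
  )
}
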