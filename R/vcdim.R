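#' Can a concept class realize a labeling of fixed points?
#'
#' Decides whether some classifier of the class produces exactly `labels`
#' on `points`. For the continuously parameterized classes the strict
#' separation `sign(<w, x_i> - t) = y_i` is encoded as the feasibility of
#' the linear system `y'_i (<w, x_i> - t) >= 1` (unit margin; valid
#' because every class is closed under positive rescaling of `(w, t)`),
#' with the class's structural equalities imposed, and decided by linear
#' programming. For the finite classes (`mon`, `stc`, `stc_off`) the
#' classifiers are enumerated directly.
#'
#' @param points m x n numeric matrix (rows = points).
#' @param labels vector in `{0, 1}` of length m.
#' @param class a concept class id, see [concept_classes()].
#' @return logical.
#' @export
realizable <- function(points, labels, class) {
  class <- match_concept_class(class)
  points <- as.matrix(points)
  m <- nrow(points); n <- ncol(points)
  labels <- as.integer(labels)
  stopifnot(length(labels) == m, all(labels %in% c(0L, 1L)))
  ys <- y_signed(labels)

  if (class == "mon") {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (all((points[, i] >= points[, j]) == (labels == 1L))) return(TRUE)
    }
    return(FALSE)
  }
  if (class %in% c("stc", "stc_off")) {
    for (i in seq_len(n)) for (s in c(1, -1)) {
      v <- s * points[, i]
      if (class == "stc_off") {
        if (all((v >= 0) == (labels == 1L))) return(TRUE)
      } else {
        lo <- suppressWarnings(min(v[labels == 1L]))  #  Inf if no 1s
        hi <- suppressWarnings(max(v[labels == 0L]))  # -Inf if no 0s
        if (lo > hi) return(TRUE)  # any t in (hi, lo] separates with >=
      }
    }
    return(FALSE)
  }

  offset_free <- class %in% c("off", "off_con")
  contrast <- class %in% c("con", "off_con")
  has_t <- !offset_free
  nv <- 2 * n + 2 * has_t
  Ge <- cbind(points * ys, -points * ys, if (has_t) cbind(-ys, ys))
  if (contrast) {
    Eq <- matrix(c(rep(1, n), rep(-1, n), rep(0, 2 * has_t)), 1, nv)
    f <- 0
  } else {
    Eq <- matrix(0, 0, nv); f <- numeric(0)
  }
  sol <- lp_solve_cpp(rep(0, nv), Eq, f, Ge, rep(1, m))
  sol$status == 0
}

#' Is a point set shattered by a concept class?
#'
#' Checks [realizable()] for every one of the `2^m` labelings.
#'
#' @inheritParams realizable
#' @param max_m enumeration guard; point sets larger than this are
#'   refused.
#' @return logical.
#' @export
is_shattered <- function(points, class, max_m = 20) {
  points <- as.matrix(points)
  m <- nrow(points)
  stopifnot(m >= 1)
  if (m > max_m) {
    stop("refusing to enumerate 2^", m, " labelings (max_m = ", max_m, ")",
         call. = FALSE)
  }
  for (code in 0:(2^m - 1)) {
    labels <- as.integer(bitwAnd(bitwShiftR(code, 0:(m - 1)), 1L))
    if (!realizable(points, labels, class)) return(FALSE)
  }
  TRUE
}

# the VC dimension each class is expected to have (mon: upper bound)
claimed_vcdim <- function(class, n) {
  switch(class,
    lin = n + 1,
    off = n,
    con = n,
    off_con = n - 1,
    mon = floor(log2(n * (n - 1))),
    stop("no claimed VC dimension for class '", class, "'", call. = FALSE)
  )
}

# deterministic candidate point sets expected to be shattered
constructed_sets <- function(class, n, m) {
  sets <- list()
  if (class == "lin" && m == n + 1) sets <- list(rbind(rep(0, n), diag(n)))
  if (class %in% c("off", "con") && m == n) sets <- list(diag(n))
  if (class == "off_con" && m == n - 1) {
    sets <- list(diag(n)[seq_len(n - 1), , drop = FALSE])
  }
  sets
}

#' Lower-bound the VC dimension by searching for shattered sets
#'
#' Tries point sets of decreasing size m, starting from the expected VC
#' dimension of the class: first deterministic constructed sets (simplex
#' vertices / unit vectors, which are shattered by the continuous classes
#' by linear-algebra arguments), then random Gaussian sets. Returns the
#' largest m for which a shattered set was found — by construction a
#' valid lower bound on the true VC dimension.
#'
#' Uses the current R random number generator state.
#'
#' @param class one of `"lin"`, `"off"`, `"con"`, `"off_con"`, `"mon"`.
#' @param n feature dimension (small; every candidate set triggers a
#'   `2^m`-labeling enumeration).
#' @param n_random random candidate sets per size.
#' @return integer lower bound (0 if nothing was shattered).
#' @export
vc_lower_bound <- function(class, n, n_random = 100) {
  class <- match_concept_class(class)
  m_start <- claimed_vcdim(class, n)
  for (m in seq(m_start, 1)) {
    for (pts in constructed_sets(class, n, m)) {
      if (is_shattered(pts, class)) return(as.integer(m))
    }
    for (k in seq_len(n_random)) {
      pts <- matrix(stats::rnorm(m * n), m, n)
      if (is_shattered(pts, class)) return(as.integer(m))
    }
  }
  0L
}

#' Try to falsify a claimed VC-dimension upper bound
#'
#' Attempts `trials` random point sets of size `m` (intended:
#' `m = claimed VC dimension + 1`) and reports `TRUE` iff none of them is
#' shattered. For `mon` the classifier set is finite, so each per-set
#' check is exact — and whenever `2^m > n (n - 1)` no set of size m can
#' be shattered by a counting argument, which the enumeration confirms.
#' For the continuous classes a `TRUE` is probabilistic evidence for the
#' bound, not a proof.
#'
#' Uses the current R random number generator state.
#'
#' @inheritParams vc_lower_bound
#' @param m point-set size to try.
#' @param trials number of random point sets.
#' @return logical: `TRUE` if the bound survived (no shattered set found).
#' @export
vc_upper_falsify <- function(class, n, m, trials = 200) {
  class <- match_concept_class(class)
  for (k in seq_len(trials)) {
    pts <- matrix(stats::rnorm(m * n), m, n)
    if (is_shattered(pts, class)) return(FALSE)
  }
  TRUE
}
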