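#' Concept classes of constrained linear classifiers
#'
#' The package works with five structural subclasses of linear decision
#' rules `1[<w, x> >= t]`:
#'
#' * `lin` — unconstrained linear classifier.
#' * `stc` — single-threshold classifier (decision stump), `||w||_0 = 1`.
#' * `off` — offset-free: `t = 0`; hyperplane through the origin;
#'   invariant to global positive scaling of a profile.
#' * `stc_off` — offset-free decision stump.
#' * `con` — contrast classifier: weights sum to zero; invariant to adding
#'   a common constant to every feature (reference-point shifts).
#' * `off_con` — both constraints; invariant to any positive affine map
#'   `x -> a x + b 1`.
#' * `mon` — pairwise comparison `1[x_i >= x_j]`; invariant to every
#'   feature-wise strictly increasing transformation (rank-type rule, in
#'   the spirit of top-scoring-pair classifiers).
#'
#' The classes form a lattice: `mon` is contained in `off_con`, which is
#' contained in both `off` and `con`; `stc_off` is contained in `stc` and
#' `off`; everything is contained in `lin`.
#'
#' @return `concept_classes()` returns a character vector of the class ids.
#' @export
concept_classes <- function() {
  c("lin", "stc", "off", "stc_off", "con", "off_con", "mon")
}

# superclasses implied by the lattice, excluding the class itself
.concept_superclasses <- list(
  lin     = character(0),
  stc     = "lin",
  off     = "lin",
  stc_off = c("stc", "off", "lin"),
  con     = "lin",
  off_con = c("off", "con", "lin"),
  mon     = c("off_con", "off", "con", "lin")
)

#' Superclasses of a concept class
#'
#' @param class a concept class id, see [concept_classes()].
#' @return character vector of all classes implied by membership in
#'   `class` (not including `class` itself).
#' @export
concept_superclasses <- function(class) {
  class <- match_concept_class(class)
  .concept_superclasses[[class]]
}

match_concept_class <- function(class) {
  if (!is.character(class) || length(class) != 1L || !class %in% concept_classes()) {
    stop("unknown concept class: ", paste(class, collapse = ", "),
         " (expected one of ", paste(concept_classes(), collapse = ", "), ")",
         call. = FALSE)
  }
  class
}

#' Construct a linear classifier
#'
#' A linear classifier predicts `1[<w, x> >= t]`, with ties at the decision
#' boundary assigned to class 1. If `class` is not `"lin"`, the structural
#' constraints of that class are checked at tolerance `tol` and violations
#' raise an error.
#'
#' @param w numeric weight vector.
#' @param t numeric threshold (default 0).
#' @param class concept class id the model claims, see [concept_classes()].
#' @param tol nonnegative relative tolerance for the structural checks.
#' @return an object of class `linear_model` with fields `w`, `t`, `n`,
#'   `class`.
#' @examples
#' m <- linear_model(c(1, -1, 0), t = 0, class = "mon")
#' predict(m, rbind(c(5, 7, 100)))  # 0: feature 1 < feature 2
#' @export
linear_model <- function(w, t = 0, class = "lin", tol = 1e-8) {
  stopifnot(is.numeric(w), length(w) >= 1L, all(is.finite(w)),
            is.numeric(t), length(t) == 1L, is.finite(t))
  class <- match_concept_class(class)
  model <- structure(
    list(w = as.numeric(w), t = as.numeric(t), n = length(w), class = class),
    class = "linear_model"
  )
  if (class != "lin") {
    chk <- check_membership(model, class, tol = tol)
    if (!chk$member) {
      stop("model violates the structural constraints of class '", class,
           "': ", paste(chk$violations, collapse = "; "), call. = FALSE)
    }
  }
  model
}

#' @export
print.linear_model <- function(x, ...) {
  cat("<linear_model> class =", x$class, " n =", x$n, "\n")
  cat("  w =", paste(signif(x$w, 4), collapse = " "), "\n")
  cat("  t =", signif(x$t, 4), "\n")
  invisible(x)
}

# coerce data (matrix / data.frame with optional label column) to a
# feature matrix with exactly n columns
feature_matrix <- function(newdata, n, label = "label") {
  if (is.data.frame(newdata)) {
    if (label %in% names(newdata)) {
      newdata <- newdata[setdiff(names(newdata), label)]
    }
    newdata <- as.matrix(newdata)
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (!is.numeric(newdata)) stop("feature columns must be numeric", call. = FALSE)
  if (ncol(newdata) != n) {
    stop("dimension mismatch: model has n = ", n,
         " features but data has ", ncol(newdata), " columns", call. = FALSE)
  }
  newdata
}

#' Predict class labels with a linear classifier
#'
#' @param object a [linear_model()].
#' @param newdata matrix or data frame of samples (rows); a column named
#'   `label` is ignored if present. A bare numeric vector is treated as a
#'   single sample.
#' @param ... unused.
#' @return integer vector of labels in `{0, 1}`; the tie `<w, x> = t`
#'   yields 1.
#' @export
predict.linear_model <- function(object, newdata, ...) {
  X <- feature_matrix(newdata, object$n)
  as.integer(drop(X %*% object$w) >= object$t)
}

#' Decision values of a linear classifier
#'
#' Returns `<w, x> - t` per sample; the predicted label is 1 exactly when
#' this is nonnegative.
#'
#' @inheritParams predict.linear_model
#' @param model a [linear_model()].
#' @param newdata samples as in [predict.linear_model()].
#' @return numeric vector.
#' @export
decision_values <- function(model, newdata) {
  X <- feature_matrix(newdata, model$n)
  drop(X %*% model$w) - model$t
}

#' Number of active weights
#'
#' Counts the entries of `w` whose magnitude exceeds `tol` times the
#' largest magnitude; the all-zero vector has sparsity 0 (a constant
#' classifier).
#'
#' @param w numeric vector.
#' @param tol nonnegative relative tolerance.
#' @return nonnegative integer count.
#' @examples
#' sparsity(c(0, 3, -1e-15))  # 1
#' @export
sparsity <- function(w, tol = 1e-8) {
  stopifnot(is.numeric(w), tol >= 0)
  mx <- max(abs(w))
  if (mx == 0) return(0L)
  sum(abs(w) > tol * mx)
}

#' Check structural membership of a linear model in a concept class
#'
#' Verifies the defining constraints of a concept class at a relative
#' tolerance: `off` requires `|t| <= tol`; `con` requires
#' `|sum(w)| <= tol * max|w|`; `stc` requires exactly one active weight;
#' `mon` requires exactly two active weights of equal magnitude and
#' opposite sign with `t = 0`. Compound classes require all parts.
#'
#' @param model a [linear_model()].
#' @param class a concept class id.
#' @param tol nonnegative tolerance (relative where a scale exists).
#' @return a list with elements `member` (logical) and `violations`
#'   (character vector naming each failed constraint).
#' @export
check_membership <- function(model, class, tol = 1e-8) {
  stopifnot(inherits(model, "linear_model"), tol >= 0)
  class <- match_concept_class(class)
  w <- model$w; t <- model$t
  mx <- max(abs(w))
  viol <- character(0)

  needs_off <- class %in% c("off", "stc_off", "off_con", "mon")
  needs_con <- class %in% c("con", "off_con")
  needs_stc <- class %in% c("stc", "stc_off")

  if (needs_off && abs(t) > tol) {
    viol <- c(viol, sprintf("offset-free: |t| = %.3g exceeds tol", abs(t)))
  }
  # the relative scale gets an absolute floor so that near-zero weight
  # vectors (degenerate solver output) are not rejected on roundoff
  if (needs_con && abs(sum(w)) > tol * max(mx, 1e-8)) {
    viol <- c(viol, sprintf("contrast: |sum(w)| = %.3g exceeds tol * max|w|", abs(sum(w))))
  }
  if (needs_stc && sparsity(w, tol) != 1L) {
    viol <- c(viol, sprintf("single-threshold: sparsity %d != 1", sparsity(w, tol)))
  }
  if (class == "mon") {
    k <- sparsity(w, tol)
    if (k != 2L) {
      viol <- c(viol, sprintf("pairwise: sparsity %d != 2", k))
    } else {
      idx <- order(abs(w), decreasing = TRUE)[1:2]
      wi <- w[idx[1]]; wj <- w[idx[2]]
      if (abs(wi + wj) > tol * mx) {
        viol <- c(viol, "pairwise: active weights are not equal in magnitude and opposite in sign")
      }
    }
  }
  list(member = length(viol) == 0L, violations = viol)
}

#' Serialize a linear model to JSON
#'
#' Writes the flat representation `{"w": [...], "t": ..., "class": ...}`.
#'
#' @param model a [linear_model()].
#' @param path file path; if `NULL` the JSON string is returned.
#' @return the path (invisibly) or a JSON string.
#' @export
write_model_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "linear_model"))
  obj <- list(w = model$w, t = model$t, class = model$class)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Read a linear model from JSON
#'
#' @param path file path or a JSON string produced by [write_model_json()].
#' @return a [linear_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  linear_model(w = as.numeric(obj$w), t = as.numeric(obj$t),
               class = as.character(obj$class))
}
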