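#' Draw a pair of class centroids at a fixed Euclidean distance
#'
#' The positive-class centroid has i.i.d. `U(0, 10)` components (so it is
#' always in the positive orthant, as expression-like data would be); the
#' negative-class centroid is displaced by distance `d` along a uniformly
#' random direction (standard normal vector, normalised).
#'
#' Uses the current R random number generator state.
#'
#' @param n feature dimension (>= 2).
#' @param d centroid distance (> 0).
#' @return list with numeric vectors `c1` and `c0`;
#'   `sqrt(sum((c1 - c0)^2)) == d` to machine precision.
#' @export
make_centroids <- function(n, d) {
  stopifnot(n >= 2)
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    stop("centroid distance d must be positive (got ", d, ")", call. = FALSE)
  }
  c1 <- stats::runif(n, 0, 10)
  dir <- stats::rnorm(n)
  c0 <- c1 + d * dir / sqrt(sum(dir^2))
  list(c1 = c1, c0 = c0)
}

new_dataset <- function(X, y, provenance, applied_params = NULL) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- tibble::as_tibble(X)
  out$label <- as.integer(y)
  attr(out, "provenance") <- provenance
  attr(out, "applied_params") <- applied_params
  class(out) <- c("consvm_dataset", class(out))
  out
}

#' Provenance record of a simulated dataset
#'
#' @param data a dataset produced by [simulate_dataset()] or one of the
#'   noise functions.
#' @return list with at least `kind` (`"raw"`, `"samplewise"` or
#'   `"classwise"`) and, for noisy data, `noise_id` and `p`.
#' @export
dataset_provenance <- function(data) attr(data, "provenance")

#' Simulate a two-class spherical Gaussian dataset
#'
#' Draws `m_per_class` samples per class from `N(c_y, I)` around the two
#' centroids. With the default `m_per_class = 50` a dataset has 2 x 50
#' samples, the benchmark sample size.
#'
#' Uses the current R random number generator state; fix it with
#' `set.seed()` for reproducible datasets.
#'
#' @inheritParams make_centroids
#' @param m_per_class samples per class (>= 1).
#' @param centroids optional list `(c1, c0)` from [make_centroids()]; a
#'   fresh pair is drawn when `NULL`.
#' @return a tibble with feature columns `x1..xn` and an integer `label`
#'   column in `{0, 1}`, carrying a `provenance` attribute
#'   (see [dataset_provenance()]).
#' @examples
#' set.seed(7)
#' d <- simulate_dataset(n = 2, d = 4)
#' table(d$label)
#' @export
simulate_dataset <- function(n, d, m_per_class = 50, centroids = NULL) {
  stopifnot(n >= 2, m_per_class >= 1)
  if (is.null(centroids)) centroids <- make_centroids(n, d)
  stopifnot(length(centroids$c1) == n, length(centroids$c0) == n)
  m <- as.integer(m_per_class)
  X1 <- matrix(stats::rnorm(m * n), m, n, byrow = TRUE) +
    matrix(centroids$c1, m, n, byrow = TRUE)
  X0 <- matrix(stats::rnorm(m * n), m, n, byrow = TRUE) +
    matrix(centroids$c0, m, n, byrow = TRUE)
  new_dataset(rbind(X1, X0), c(rep(1L, m), rep(0L, m)),
              provenance = list(kind = "raw", n = n, d = d,
                                m_per_class = m, centroids = centroids))
}

stop_if_not_raw <- function(data, fun) {
  prov <- dataset_provenance(data)
  if (!is.null(prov) && !identical(prov$kind, "raw")) {
    stop(fun, "() refuses to transform already-noisified data (provenance: ",
         prov$kind, ")", call. = FALSE)
  }
}

dataset_matrix <- function(data) {
  as.matrix(data[setdiff(names(data), "label")])
}

#' Apply independent per-sample noise to a test set
#'
#' Each sample receives its own transformation parameter draw from the
#' requested noise family at level `p`; this emulates test profiles that
#' each went through a different processing artefact. The training set is
#' deliberately untouched in this regime.
#'
#' @param data a raw dataset (tibble with `label` column).
#' @param noise_id noise type 1..5 (none, scaling, transition,
#'   scaling+transition, exponential).
#' @param p noise level in `[0, 5]`; `p = 0` is the identity.
#' @return the transformed dataset; the per-sample parameter draws are
#'   recorded in the `applied_params` attribute.
#' @export
samplewise_noisify <- function(data, noise_id, p) {
  stop_if_not_raw(data, "samplewise_noisify")
  X <- dataset_matrix(data)
  params <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    params[[i]] <- draw_transform_params(noise_id, p)
    X[i, ] <- apply_transform(X[i, ], params[[i]])
  }
  prov <- dataset_provenance(data)
  new_dataset(X, data$label,
              provenance = list(kind = "samplewise", noise_id = noise_id,
                                p = p, parent = prov),
              applied_params = params)
}

#' Apply class-wise noise independently to a training and a test set
#'
#' One transformation parameter is drawn per class for the training set
#' and an independent one per class for the test set (a batch-effect-like
#' regime: the whole class shares its artefact, but the artefact differs
#' between training and deployment).
#'
#' @param train,test raw datasets.
#' @inheritParams samplewise_noisify
#' @return list with transformed `train` and `test`; each carries the
#'   per-class draws (named by label value) in `applied_params`.
#' @export
classwise_noisify <- function(train, test, noise_id, p) {
  stop_if_not_raw(train, "classwise_noisify")
  stop_if_not_raw(test, "classwise_noisify")
  one <- function(data) {
    X <- dataset_matrix(data)
    params <- list("0" = draw_transform_params(noise_id, p),
                   "1" = draw_transform_params(noise_id, p))
    for (lab in c(0L, 1L)) {
      idx <- which(data$label == lab)
      th <- params[[as.character(lab)]]
      if (length(idx)) X[idx, ] <- apply_transform(X[idx, , drop = FALSE], th)
    }
    new_dataset(X, data$label,
                provenance = list(kind = "classwise", noise_id = noise_id,
                                  p = p, parent = dataset_provenance(data)),
                applied_params = params)
  }
  list(train = one(train), test = one(test))
}
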