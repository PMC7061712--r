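# Independent oracles used across the suite. These deliberately avoid the
# package's solver code paths: the grid search scans raw (w, t) space and
# evaluates the soft-margin objective directly.

svm_objective <- function(w, t, X, ys, reg, C) {
  regterm <- if (reg == "R2") 0.5 * sum(w^2) else sum(abs(w))
  regterm + C * sum(pmax(0, 1 - ys * (drop(X %*% w) - t)))
}

# dense 2-D grid search over direction angle, magnitude and threshold,
# restricted by the structural constraints of the concept class; a coarse
# global scan is refined locally so the grid optimum lands well inside 1%
# of the continuous optimum
grid_search_objective_2d <- function(X, ys, reg, C, concept_class) {
  stopifnot(ncol(X) == 2)
  offset_free <- concept_class %in% c("off", "off_con", "mon")
  contrast <- concept_class %in% c("con", "off_con", "mon")
  scale0 <- max(abs(X)) + 1

  scan <- function(angles, rhos, ts) {
    best <- list(obj = Inf)
    for (phi in angles) {
      dir <- c(cos(phi), sin(phi))
      f1 <- drop(X %*% dir)
      for (r in rhos) {
        f <- r * f1
        H <- matrix(pmax(0, 1 - ys * outer(f, ts, "-")), nrow = nrow(X))
        regterm <- if (reg == "R2") 0.5 * r^2 else r * sum(abs(dir))
        tot <- regterm + C * colSums(H)
        j <- which.min(tot)
        if (tot[j] < best$obj) best <- list(obj = tot[j], phi = phi, r = r, t = ts[j])
      }
    }
    best
  }

  angles <- if (contrast) c(3 * pi / 4, 7 * pi / 4)
            else seq(0, 2 * pi, length.out = 181)[-181]
  rhos <- exp(seq(log(1e-2), log(30), length.out = 120))
  ts <- if (offset_free) 0 else seq(-3 * scale0, 3 * scale0, length.out = 121)

  cur <- scan(angles, rhos, ts)

  # polish in the constraint-reduced natural parameters, where the
  # objective is convex, so the local search reaches the global optimum
  w0 <- cur$r * c(cos(cur$phi), sin(cur$phi))
  fn <- function(par) {
    if (contrast) {
      w <- c(par[1], -par[1])
      t <- if (offset_free) 0 else par[2]
    } else {
      w <- par[1:2]
      t <- if (offset_free) 0 else par[3]
    }
    svm_objective(w, t, X, ys, reg, C)
  }
  par0 <- if (contrast) c(w0[1], if (!offset_free) cur$t)
          else c(w0, if (!offset_free) cur$t)
  if (length(par0) == 1L) {
    opt <- stats::optimize(function(p) fn(p), interval = par0 + c(-5, 5) * (abs(par0) + 1))
    min(cur$obj, opt$objective)
  } else {
    opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 20000))
    min(cur$obj, opt$value)
  }
}

# exhaustive evaluation of both pairwise rules in 2-D
mon_best_accuracy_2d <- function(X, labels) {
  acc12 <- mean((X[, 1] >= X[, 2]) == (labels == 1))
  acc21 <- mean((X[, 2] >= X[, 1]) == (labels == 1))
  max(acc12, acc21)
}

# small labeled tibble from a matrix
toy_dataset <- function(X, y) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  d <- tibble::as_tibble(X)
  d$label <- as.integer(y)
  d
}

# random model satisfying the structural constraints of a class exactly
random_member <- function(class, n) {
  w <- stats::rnorm(n)
  t <- stats::rnorm(1)
  if (class %in% c("con", "off_con")) w <- w - mean(w)
  if (class %in% c("off", "off_con", "mon")) t <- 0
  if (class == "mon") {
    ij <- sample(n, 2)
    w <- numeric(n)
    a <- abs(stats::rnorm(1)) + 0.1
    w[ij[1]] <- a; w[ij[2]] <- -a
  }
  if (class %in% c("stc", "stc_off")) {
    w <- numeric(n)
    w[sample(n, 1)] <- sample(c(-1, 1), 1)
    if (class == "stc_off") t <- 0
  }
  linear_model(w, t, class = class)
}
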