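# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: costs are computed by explicit per-sample loops,
# minimizers by coordinate descent or an SVD least-squares solve.

# random dataset satisfying the norm/range invariants
rand_dataset <- function(n, d, task = "regression", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(runif(n * d, -1, 1), n, d)
  X <- X / pmax(1, sqrt(rowSums(X^2)))
  y <- if (task == "regression") runif(n, -1, 1) else sample(0:1, n, TRUE)
  labeled_dataset(X, y, task = task)
}

# empirical average squared-error cost, per-sample loop
direct_linear_cost <- function(ds, w) {
  total <- 0
  for (i in seq_len(nrow(ds$features))) {
    total <- total + (ds$labels[i] - sum(ds$features[i, ] * w))^2
  }
  total / nrow(ds$features)
}

# exact logistic cost, per-sample loop
direct_logistic_cost <- function(ds, w) {
  total <- 0
  for (i in seq_len(nrow(ds$features))) {
    z <- sum(ds$features[i, ] * w)
    total <- total + log(1 + exp(z)) - ds$labels[i] * z
  }
  total / nrow(ds$features)
}

# cyclic coordinate descent on beta + a'w + w'Mw (strictly positive diagonal)
coord_descent <- function(obj, sweeps = 500) {
  M <- obj$quadratic
  a <- obj$linear
  w <- rep(0, length(a))
  for (it in seq_len(sweeps)) {
    for (d in seq_along(w)) {
      w[d] <- (-a[d] / 2 - sum(M[d, -d] * w[-d])) / M[d, d]
    }
  }
  w
}

# least squares via SVD of X (independent of the decomposition path)
svd_lstsq <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep]))
}
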