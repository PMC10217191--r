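#' Quadratic objective from the Stone-Weierstrass decomposition
#'
#' Both private regression objectives in this package are represented exactly
#' (linear regression) or via an order-2 Taylor surrogate (logistic
#' regression) as \eqn{f_D(w) = \beta + \alpha^\top w + w^\top M w}, where the
#' constant, linear and quadratic coefficient arrays are the only
#' data-dependent parts. Privacy noise is injected into these three arrays.
#'
#' @param constant scalar coefficient \eqn{\beta} (order 0).
#' @param linear length-D vector \eqn{\alpha} (order 1).
#' @param quadratic D x D symmetric matrix \eqn{M} (order 2).
#' @param model `"linear"` or `"logistic"`.
#' @return An object of class `quadratic_objective`.
#' @export
quadratic_objective <- function(constant, linear, quadratic,
                                model = c("linear", "logistic")) {
  model <- match.arg(model)
  linear <- as.numeric(linear)
  quadratic <- as.matrix(quadratic)
  d <- length(linear)
  if (!all(dim(quadratic) == c(d, d))) {
    stop("quadratic part must be ", d, " x ", d, " to match the linear part")
  }
  if (max(abs(quadratic - t(quadratic))) > 1e-12) {
    stop("quadratic part must be symmetric to within 1e-12")
  }
  structure(list(constant = as.numeric(constant)[1], linear = linear,
                 quadratic = quadratic, model = model),
            class = "quadratic_objective")
}

#' @export
print.quadratic_objective <- function(x, ...) {
  cat("<quadratic_objective> model = ", x$model, ", D = ", length(x$linear),
      ", constant = ", format(x$constant), "\n", sep = "")
  invisible(x)
}

#' Decompose the least-squares cost into quadratic coefficients
#'
#' For the empirical cost \eqn{(1/N) \sum_n (y_n - x_n^\top w)^2} the exact
#' order-0/1/2 coefficient arrays are
#' \deqn{\beta = \frac1N \sum_n y_n^2, \quad
#'       \alpha = -\frac2N \sum_n y_n x_n, \quad
#'       M = \frac1N \sum_n x_n x_n^\top.}
#'
#' @param ds a regression [labeled_dataset()] satisfying the invariants.
#' @return A `quadratic_objective` with `model = "linear"`.
#' @export
decompose_linear <- function(ds) {
  if (ds$task != "regression") stop("decompose_linear needs a regression dataset")
  n <- n_samples(ds)
  if (n < 1L) stop("empty dataset")
  X <- ds$features
  y <- ds$labels
  quadratic_objective(
    constant = sum(y^2) / n,
    linear = -2 * drop(crossprod(X, y)) / n,
    quadratic = crossprod(X) / n,
    model = "linear"
  )
}

#' Taylor constants of the logistic loss at zero
#'
#' The k = 0, 1, 2 derivatives of \eqn{\log(1 + e^z)} at \eqn{z = 0}:
#' \eqn{\log 2}, \eqn{1/2}, \eqn{1/4}. These are the constants entering the
#' order-2 polynomial surrogate of the logistic cost.
#'
#' @return numeric vector `c(log(2), 0.5, 0.25)`.
#' @export
logistic_taylor_constants <- function() c(log(2), 0.5, 0.25)

#' Decompose the logistic cost into quadratic coefficients
#'
#' Order-2 Taylor surrogate of the logistic cost
#' \eqn{(1/N)\sum_n [\log(1 + e^{x_n^\top w}) - y_n x_n^\top w]} around
#' \eqn{w = 0}, using the derivative values \eqn{\log 2}, \eqn{1/2},
#' \eqn{1/4}:
#' \deqn{\beta = \log 2, \quad
#'       \alpha = \frac1N \sum_n (\tfrac12 - y_n) x_n, \quad
#'       M = \frac{1}{8N} \sum_n x_n x_n^\top.}
#'
#' @param ds a classification [labeled_dataset()].
#' @return A `quadratic_objective` with `model = "logistic"`.
#' @export
decompose_logistic <- function(ds) {
  if (ds$task != "classification") {
    stop("decompose_logistic needs a classification dataset")
  }
  n <- n_samples(ds)
  if (n < 1L) stop("empty dataset")
  X <- ds$features
  y <- ds$labels
  k <- logistic_taylor_constants()
  quadratic_objective(
    constant = k[1],
    linear = drop(crossprod(X, k[2] - y)) / n,
    # second-order Taylor coefficient is f''(0)/2! = 1/8
    quadratic = (k[3] / 2) * crossprod(X) / n,
    model = "logistic"
  )
}

# Dispatch on the dataset's task.
decompose_dataset <- function(ds) {
  if (ds$task == "regression") decompose_linear(ds) else decompose_logistic(ds)
}

#' Evaluate a quadratic objective
#'
#' @param obj a [quadratic_objective()].
#' @param w length-D parameter vector.
#' @return \eqn{\beta + \alpha^\top w + w^\top M w}.
#' @export
evaluate_objective <- function(obj, w) {
  w <- as.numeric(w)
  if (length(w) != length(obj$linear)) {
    stop("w has length ", length(w), " but the objective has dimension ",
         length(obj$linear))
  }
  obj$constant + sum(obj$linear * w) + drop(crossprod(w, obj$quadratic %*% w))
}

#' Closed-form minimizer of a PSD quadratic objective
#'
#' Solves the stationarity condition \eqn{2 M w = -\alpha} by pseudoinverse.
#' Noisy objectives must be run through [repair_psd()] first so that the
#' quadratic part is positive semidefinite and the minimum exists.
#'
#' @param obj a [quadratic_objective()] with symmetric PSD quadratic part.
#' @return length-D numeric minimizer.
#' @export
minimize_objective <- function(obj) {
  if (!all(is.finite(obj$constant), is.finite(obj$linear),
           is.finite(obj$quadratic))) {
    stop("objective has non-finite coefficients")
  }
  M <- obj$quadratic
  a <- obj$linear
  if (max(abs(M)) == 0) {
    if (max(abs(a)) > 0) {
      stop("objective is unbounded below: zero quadratic part with a ",
           "nonzero linear part")
    }
    return(rep(0, length(a)))
  }
  drop(MASS::ginv(2 * M) %*% (-a))
}

#' Symmetric Gaussian noise matrix
#'
#' Draws i.i.d. Gaussian entries (sd `sd`) for the diagonal and upper triangle
#' and mirrors the strict upper triangle below, so the result is exactly
#' symmetric; diagonal entries are drawn once. This is the noise shape used
#' for the order-2 coefficient matrix.
#'
#' @param d matrix dimension.
#' @param sd nonnegative entry standard deviation.
#' @return A d x d symmetric numeric matrix.
#' @export
symmetric_gaussian_matrix <- function(d, sd) {
  stopifnot(d >= 1, sd >= 0)
  E <- matrix(0, d, d)
  upper <- upper.tri(E, diag = TRUE)
  E[upper] <- stats::rnorm(sum(upper), 0, sd)
  E[lower.tri(E)] <- t(E)[lower.tri(E)]
  E
}

#' Restore positive semidefiniteness of a noisy objective
#'
#' Eigen-decomposes the (symmetric) quadratic part, clips negative eigenvalues
#' to zero and rebuilds the matrix; the constant and linear parts are
#' unchanged. If every eigenvalue is negative the quadratic part collapses to
#' zero and the result carries the attribute `"all_negative"` = `TRUE`
#' (minimization of such an objective fails unless the linear part is also
#' zero).
#'
#' @param obj a [quadratic_objective()] with symmetric quadratic part.
#' @return A `quadratic_objective` with PSD quadratic part; attribute
#'   `"psd_repaired"` records whether any eigenvalue was clipped.
#' @export
repair_psd <- function(obj) {
  M <- obj$quadratic
  if (max(abs(M - t(M))) > 1e-12) stop("quadratic part must be symmetric")
  eig <- eigen(M, symmetric = TRUE)
  clipped <- eig$values < 0
  vals <- pmax(eig$values, 0)
  M_fixed <- eig$vectors %*% (vals * t(eig$vectors))
  M_fixed <- (M_fixed + t(M_fixed)) / 2
  out <- quadratic_objective(obj$constant, obj$linear, M_fixed, obj$model)
  attr(out, "psd_repaired") <- any(clipped)
  if (all(clipped)) {
    warning("all eigenvalues of the noisy quadratic part are negative; ",
            "the repaired objective has a zero quadratic part")
    attr(out, "all_negative") <- TRUE
  }
  out
}

#' Serialize a quadratic objective to JSON
#'
#' @param obj a [quadratic_objective()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly when writing to file).
#' @export
objective_to_json <- function(obj, path = NULL) {
  payload <- list(constant = obj$constant, linear = obj$linear,
                  quadratic = obj$quadratic, model = obj$model)
  if (is.null(path)) {
    as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname objective_to_json
#' @param json JSON string or file path produced by [objective_to_json()].
#' @export
objective_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json)
  quadratic_objective(payload$constant, payload$linear, payload$quadratic,
                      model = payload$model)
}
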