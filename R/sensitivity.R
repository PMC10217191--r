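#' Per-order L2 sensitivities for the Gaussian functional mechanism
#'
#' Maximum L2 change of each coefficient array when one record of the dataset
#' is replaced (bounded neighboring). Under the norm/range assumptions
#' enforced by [preprocess()] the bounds are, for linear regression,
#' \eqn{\Delta_0 = 1/N}, \eqn{\Delta_1 = 4/N}, \eqn{\Delta_2 = 1/N} and, for
#' logistic regression, \eqn{\Delta_0 = 0}, \eqn{\Delta_1 = 1/N},
#' \eqn{\Delta_2 = 1/(8N)}. None of them depends on the feature dimension —
#' the key advantage over the scheme-wide sensitivities of the older
#' functional mechanisms ([fm_l1_sensitivity()], [rlx_fm_l2_sensitivity()]).
#'
#' @param model `"linear"` or `"logistic"`.
#' @param n number of samples.
#' @return Named numeric vector `c(delta0, delta1, delta2)`.
#' @export
gauss_fm_sensitivities <- function(model = c("linear", "logistic"), n) {
  model <- match.arg(model)
  if (n <= 0) stop("n must be positive")
  if (model == "linear") {
    c(delta0 = 1 / n, delta1 = 4 / n, delta2 = 1 / n)
  } else {
    c(delta0 = 0, delta1 = 1 / n, delta2 = 1 / (8 * n))
  }
}

#' Scheme-wide L1 sensitivity of the Laplace functional mechanism
#'
#' The single sensitivity used for every polynomial coefficient:
#' \eqn{(2/N)(1+D)^2} for linear regression and \eqn{(1/N)(D^2/4 + 3D)} for
#' logistic regression. Grows quadratically with the dimension.
#'
#' @inheritParams gauss_fm_sensitivities
#' @param d feature dimension.
#' @return scalar sensitivity.
#' @export
fm_l1_sensitivity <- function(model = c("linear", "logistic"), n, d) {
  model <- match.arg(model)
  if (any(n <= 0) || any(d <= 0)) stop("n and d must be positive")
  if (model == "linear") (2 / n) * (1 + d)^2 else (1 / n) * (d^2 / 4 + 3 * d)
}

#' Scheme-wide L2 sensitivity of the relaxed functional mechanism
#'
#' \eqn{(2/N)\sqrt{1 + 4D + D^2}} for linear regression and
#' \eqn{(1/N)\sqrt{D^2/16 + D}} for logistic regression; grows linearly with
#' the dimension.
#'
#' @inheritParams fm_l1_sensitivity
#' @return scalar sensitivity.
#' @export
rlx_fm_l2_sensitivity <- function(model = c("linear", "logistic"), n, d) {
  model <- match.arg(model)
  if (any(n <= 0) || any(d <= 0)) stop("n and d must be positive")
  if (model == "linear") (2 / n) * sqrt(1 + 4 * d + d^2)
  else (1 / n) * sqrt(d^2 / 16 + d)
}

#' Sensitivity profile of a mechanism
#'
#' Bundles the sensitivities used by one scheme: per-order triple for the
#' Gaussian functional mechanism, a single scalar for the Laplace and relaxed
#' variants.
#'
#' @param scheme `"gauss_fm"`, `"fm"`, or `"rlx_fm"`.
#' @inheritParams fm_l1_sensitivity
#' @return An object of class `sensitivity_profile` with fields `scheme`,
#'   `model`, `n`, `d`, and either `per_order` or `delta`.
#' @export
sensitivity_profile <- function(scheme = c("gauss_fm", "fm", "rlx_fm"),
                                model = c("linear", "logistic"), n, d) {
  scheme <- match.arg(scheme)
  model <- match.arg(model)
  out <- list(scheme = scheme, model = model, n = n, d = d)
  if (scheme == "gauss_fm") {
    out$per_order <- gauss_fm_sensitivities(model, n)
  } else if (scheme == "fm") {
    out$delta <- fm_l1_sensitivity(model, n, d)
  } else {
    out$delta <- rlx_fm_l2_sensitivity(model, n, d)
  }
  structure(out, class = "sensitivity_profile")
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat("<sensitivity_profile> scheme = ", x$scheme, ", model = ", x$model,
      ", N = ", x$n, ", D = ", x$d, "\n", sep = "")
  if (!is.null(x$per_order)) {
    cat("  per-order:", paste(format(x$per_order), collapse = ", "), "\n")
  } else {
    cat("  delta:", format(x$delta), "\n")
  }
  invisible(x)
}

#' Coefficient change from replacing one record
#'
#' Exact L2 norm of the change in the order-`j` coefficient array when one
#' sample `(x, y)` of an N-sample dataset is replaced by `(x_alt, y_alt)`.
#' The contributions of the unchanged samples cancel, so only the swapped
#' pair matters. The matrix norm for order 2 is the spectral norm, computed
#' from a symmetric eigen-decomposition.
#'
#' @inheritParams gauss_fm_sensitivities
#' @param order coefficient order, 0, 1 or 2.
#' @param x,x_alt feature vectors with L2 norm at most 1.
#' @param y,y_alt labels (regression: in \eqn{[-1,1]}; classification: 0/1).
#' @return nonnegative scalar.
#' @export
pair_sensitivity <- function(model = c("linear", "logistic"), order, n,
                             x, y, x_alt, y_alt) {
  model <- match.arg(model)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  if (model == "linear") {
    if (order == 0) return(abs(y^2 - y_alt^2) / n)
    if (order == 1) {
      return(sqrt(sum((-2 * y * x / n + 2 * y_alt * x_alt / n)^2)))
    }
    diff <- (tcrossprod(x) - tcrossprod(x_alt)) / n
  } else {
    if (order == 0) return(0)
    if (order == 1) {
      return(sqrt(sum(((0.5 - y) * x / n - (0.5 - y_alt) * x_alt / n)^2)))
    }
    diff <- (tcrossprod(x) - tcrossprod(x_alt)) / (8 * n)
  }
  max(abs(eigen(diff, symmetric = TRUE, only.values = TRUE)$values))
}

#' Brute-force empirical sensitivity
#'
#' Monte-Carlo lower bound on the order-`j` sensitivity: the maximum
#' coefficient change over `trials` random replace-one pairs drawn inside the
#' admissible region (feature norm at most 1, valid labels). Always at most
#' the corresponding closed-form bound of [gauss_fm_sensitivities()].
#'
#' @inheritParams pair_sensitivity
#' @param d feature dimension.
#' @param trials number of random neighboring pairs.
#' @param seed integer seed (optional).
#' @return the maximum observed coefficient change.
#' @export
empirical_sensitivity <- function(model = c("linear", "logistic"), order,
                                  n, d, trials = 1000, seed = NULL) {
  model <- match.arg(model)
  stopifnot(trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw_x <- function() {
    x <- stats::runif(d, -1, 1)
    x / max(1, sqrt(sum(x^2)))
  }
  draw_y <- function() {
    if (model == "linear") stats::runif(1, -1, 1) else sample(0:1, 1)
  }
  worst <- 0
  for (i in seq_len(trials)) {
    val <- pair_sensitivity(model, order, n,
                            draw_x(), draw_y(), draw_x(), draw_y())
    if (val > worst) worst <- val
  }
  worst
}
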