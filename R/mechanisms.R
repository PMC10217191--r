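#' Privacy budget
#'
#' Exactly one of two parameterizations: an \eqn{(\epsilon, \delta)} pair, or
#' a per-unit-sensitivity Gaussian noise multiplier \eqn{\sigma} (the noise
#' standard deviation added per unit of L2 sensitivity). The two are linked
#' by the Gaussian-mechanism calibration
#' \eqn{\sigma = (1/\epsilon)\sqrt{2\ln(1.25/\delta)}}, so sweeping
#' \eqn{\sigma} puts mechanisms with different sensitivities on one
#' comparable noise axis.
#'
#' @param epsilon positive privacy parameter (with `delta`).
#' @param delta failure probability in (0, 1) (with `epsilon`).
#' @param noise_multiplier nonnegative noise sd per unit sensitivity
#'   (alternative to the pair).
#' @return An object of class `privacy_budget`.
#' @export
privacy_budget <- function(epsilon = NULL, delta = NULL,
                           noise_multiplier = NULL) {
  pair <- !is.null(epsilon) || !is.null(delta)
  if (pair && !is.null(noise_multiplier)) {
    stop("give either (epsilon, delta) or noise_multiplier, not both")
  }
  if (pair) {
    if (is.null(epsilon) || is.null(delta)) {
      stop("epsilon and delta must be supplied together")
    }
    if (epsilon <= 0) stop("epsilon must be positive")
    if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  } else {
    if (is.null(noise_multiplier)) {
      stop("supply (epsilon, delta) or noise_multiplier")
    }
    if (noise_multiplier < 0) stop("noise_multiplier must be nonnegative")
  }
  structure(list(epsilon = epsilon, delta = delta,
                 noise_multiplier = noise_multiplier),
            class = "privacy_budget")
}

#' @export
print.privacy_budget <- function(x, ...) {
  if (!is.null(x$noise_multiplier)) {
    cat("<privacy_budget> noise multiplier sigma =",
        format(x$noise_multiplier), "\n")
  } else {
    cat("<privacy_budget> epsilon =", format(x$epsilon), ", delta =",
        format(x$delta), "\n")
  }
  invisible(x)
}

#' Gaussian-mechanism noise calibration
#'
#' Standard deviation required for \eqn{(\epsilon, \delta)}-differential
#' privacy of a release with L2 sensitivity \eqn{\Delta}:
#' \deqn{\tau = \frac{\Delta}{\epsilon}\sqrt{2 \ln(1.25/\delta)}.}
#' The classical analysis requires \eqn{\epsilon < 1}; larger values are
#' accepted with a warning.
#'
#' @param delta_f L2 sensitivity (nonnegative).
#' @param epsilon positive privacy parameter.
#' @param delta failure probability in (0, 1).
#' @return noise standard deviation \eqn{\tau}.
#' @export
calibrate_gaussian <- function(delta_f, epsilon, delta) {
  if (delta_f < 0) stop("sensitivity must be nonnegative")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  if (epsilon >= 1) {
    warning("the Gaussian-mechanism calibration is stated for epsilon < 1; ",
            "got epsilon = ", format(epsilon))
  }
  (delta_f / epsilon) * sqrt(2 * log(1.25 / delta))
}

#' Noise multiplier implied by a budget
#'
#' \eqn{\sigma = (1/\epsilon)\sqrt{2\ln(1.25/\delta)}} for an
#' \eqn{(\epsilon,\delta)} budget, or the stored multiplier. Multiplying by a
#' mechanism's sensitivity gives its actual noise sd.
#'
#' @param budget a [privacy_budget()].
#' @return nonnegative scalar.
#' @export
noise_multiplier <- function(budget) {
  stopifnot(inherits(budget, "privacy_budget"))
  if (!is.null(budget$noise_multiplier)) return(budget$noise_multiplier)
  suppressWarnings(calibrate_gaussian(1, budget$epsilon, budget$delta))
}

#' Single-shot epsilon implied by a noise multiplier
#'
#' Inverts the Gaussian-mechanism calibration at a target `delta`:
#' \eqn{\epsilon = \sqrt{2\ln(1.25/\delta)}/\sigma}.
#'
#' @param sigma positive noise multiplier.
#' @param delta failure probability in (0, 1).
#' @return epsilon.
#' @export
epsilon_from_multiplier <- function(sigma, delta) {
  stopifnot(sigma > 0, delta > 0, delta < 1)
  sqrt(2 * log(1.25 / delta)) / sigma
}

# internal fit-result constructor
fit_result <- function(weights, mechanism, seed = NULL, noise_levels = NULL,
                       psd_repair_applied = FALSE, overall_epsilon = NA_real_) {
  if (!all(is.finite(weights))) stop("fit produced non-finite weights")
  structure(list(weights = as.numeric(weights), mechanism = mechanism,
                 seed = seed, noise_levels = noise_levels,
                 psd_repair_applied = isTRUE(psd_repair_applied),
                 overall_epsilon = overall_epsilon),
            class = "gaussfm_fit")
}

#' @export
print.gaussfm_fit <- function(x, ...) {
  cat("<gaussfm_fit> mechanism = ", x$mechanism, ", D = ", length(x$weights),
      if (is.finite(x$overall_epsilon))
        paste0(", overall epsilon = ", format(x$overall_epsilon)) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.gaussfm_fit <- function(object, ...) object$weights

# model implied by the task, with optional consistency check
infer_model <- function(ds, model = NULL) {
  implied <- if (ds$task == "regression") "linear" else "logistic"
  if (!is.null(model) && model != implied) {
    stop("model '", model, "' does not match task '", ds$task, "'")
  }
  implied
}

# Shared tail of all functional mechanisms: symmetrize already done upstream,
# repair PSD, minimize.
finish_fm_fit <- function(obj_noisy, mechanism, seed, noise_levels,
                          overall_epsilon = NA_real_) {
  repaired <- suppressWarnings(repair_psd(obj_noisy))
  w <- minimize_objective(repaired)
  out <- fit_result(w, mechanism, seed = seed, noise_levels = noise_levels,
                    psd_repair_applied = isTRUE(attr(repaired, "psd_repaired")),
                    overall_epsilon = overall_epsilon)
  # the released (post-repair) objective; PSD repair leaves the constant and
  # linear parts untouched, so their noise can be audited from here
  out$objective <- repaired
  out
}

#' Gaussian functional mechanism
#'
#' Decomposes the cost into its order-0/1/2 coefficient arrays, adds Gaussian
#' noise calibrated to the *per-order* sensitivities
#' ([gauss_fm_sensitivities()]) — a scalar draw for the constant, i.i.d.
#' vector noise for the linear part, and a [symmetric_gaussian_matrix()] for
#' the quadratic part — then repairs positive semidefiniteness and minimizes
#' in closed form. With a zero noise multiplier the result equals the
#' non-private minimizer exactly.
#'
#' @param ds a preprocessed [labeled_dataset()].
#' @param budget a [privacy_budget()].
#' @param seed integer seed (optional, recorded in the result).
#' @param model optional `"linear"`/`"logistic"` consistency check; inferred
#'   from the task.
#' @return A `gaussfm_fit`.
#' @export
gaussian_fm_fit <- function(ds, budget, seed = NULL, model = NULL) {
  model <- infer_model(ds, model)
  assert_dataset(ds)
  if (!is.null(seed)) set.seed(seed)
  obj <- decompose_dataset(ds)
  mult <- noise_multiplier(budget)
  tau <- gauss_fm_sensitivities(model, n_samples(ds)) * mult
  d <- n_features(ds)
  noisy <- quadratic_objective(
    obj$constant + stats::rnorm(1, 0, tau[["delta0"]]),
    obj$linear + stats::rnorm(d, 0, tau[["delta1"]]),
    obj$quadratic + symmetric_gaussian_matrix(d, tau[["delta2"]]),
    model = model
  )
  eps <- if (!is.null(budget$epsilon)) budget$epsilon
         else if (mult > 0) epsilon_from_multiplier(mult, 1e-5) else 0
  finish_fm_fit(noisy, "gauss-fm", seed, tau, overall_epsilon = eps)
}

# Laplace draws: difference of two unit-rate exponentials, scaled.
r_laplace <- function(n, scale) {
  if (scale == 0) return(rep(0, n))
  scale * (stats::rexp(n) - stats::rexp(n))
}

#' Laplace functional mechanism (pure DP baseline)
#'
#' The classical functional mechanism: every entry of every coefficient array
#' receives i.i.d. Laplace noise with scale \eqn{\Delta_{fm}/\epsilon}
#' (variance \eqn{2\Delta_{fm}^2/\epsilon^2}), where \eqn{\Delta_{fm}} is the
#' scheme-wide L1 sensitivity of [fm_l1_sensitivity()]. The quadratic part is
#' symmetrized before PSD repair. When called with `noise_multiplier`, the
#' entry noise sd is \eqn{\Delta_{fm}\sigma} (scale \eqn{\Delta_{fm}
#' \sigma/\sqrt2}) so the mechanism sits on the same noise axis as the
#' Gaussian variants in sweeps.
#'
#' @inheritParams gaussian_fm_fit
#' @param epsilon pure-DP budget (give this or `noise_multiplier`).
#' @param noise_multiplier alternative per-unit-sensitivity noise sd.
#' @return A `gaussfm_fit`.
#' @export
laplace_fm_fit <- function(ds, epsilon = NULL, noise_multiplier = NULL,
                           seed = NULL, model = NULL) {
  model <- infer_model(ds, model)
  assert_dataset(ds)
  if (is.null(epsilon) == is.null(noise_multiplier)) {
    stop("give exactly one of epsilon or noise_multiplier")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples(ds)
  d <- n_features(ds)
  delta_fm <- fm_l1_sensitivity(model, n, d)
  scale <- if (!is.null(epsilon)) delta_fm / epsilon
           else delta_fm * noise_multiplier / sqrt(2)
  obj <- decompose_dataset(ds)
  E2 <- matrix(r_laplace(d * d, scale), d, d)
  E2 <- (E2 + t(E2)) / 2
  noisy <- quadratic_objective(
    obj$constant + r_laplace(1, scale),
    obj$linear + r_laplace(d, scale),
    obj$quadratic + E2,
    model = model
  )
  eps <- if (!is.null(epsilon)) epsilon
         else if (noise_multiplier > 0) sqrt(2) / noise_multiplier else 0
  finish_fm_fit(noisy, "fm", seed, c(scale = scale), overall_epsilon = eps)
}

#' Relaxed functional mechanism (Gaussian, scheme-wide sensitivity)
#'
#' Replaces the Laplace draws of the classical functional mechanism with
#' Gaussian noise calibrated to the scheme-wide L2 sensitivity of
#' [rlx_fm_l2_sensitivity()]; every coefficient entry receives the same noise
#' sd \eqn{\tau = \Delta_{rlx}\,\sigma(\epsilon,\delta)}. Because the single
#' sensitivity grows with the dimension, this noise always exceeds the
#' largest per-order noise of [gaussian_fm_fit()] for \eqn{D \ge 2}.
#'
#' @inheritParams gaussian_fm_fit
#' @return A `gaussfm_fit`.
#' @export
relaxed_fm_fit <- function(ds, budget, seed = NULL, model = NULL) {
  model <- infer_model(ds, model)
  assert_dataset(ds)
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples(ds)
  d <- n_features(ds)
  tau <- rlx_fm_l2_sensitivity(model, n, d) * noise_multiplier(budget)
  obj <- decompose_dataset(ds)
  noisy <- quadratic_objective(
    obj$constant + stats::rnorm(1, 0, tau),
    obj$linear + stats::rnorm(d, 0, tau),
    obj$quadratic + symmetric_gaussian_matrix(d, tau),
    model = model
  )
  eps <- if (!is.null(budget$epsilon)) budget$epsilon
         else if (noise_multiplier(budget) > 0)
           epsilon_from_multiplier(noise_multiplier(budget), 1e-5) else 0
  finish_fm_fit(noisy, "rlx-fm", seed, c(tau = tau), overall_epsilon = eps)
}

#' Non-private reference fit
#'
#' Minimizes the noiseless quadratic decomposition — the exact least-squares
#' solution for regression, the order-2 surrogate optimum for classification.
#'
#' @inheritParams gaussian_fm_fit
#' @return A `gaussfm_fit` with mechanism `"non-priv"`.
#' @export
nonprivate_fit <- function(ds, model = NULL) {
  model <- infer_model(ds, model)
  assert_dataset(ds)
  obj <- repair_psd(decompose_dataset(ds))
  fit_result(minimize_objective(obj), "non-priv", overall_epsilon = Inf)
}

# per-sample gradients of the true (unapproximated) cost, as an N x D matrix
per_sample_gradients <- function(ds, w, model) {
  X <- ds$features
  if (model == "linear") {
    resid <- drop(X %*% w) - ds$labels
    2 * resid * X
  } else {
    (sigmoid(drop(X %*% w)) - ds$labels) * X
  }
}

#' Noisy gradient descent baseline
#'
#' Iterative differentially private optimization of the true cost: per-sample
#' gradients are clipped to L2 norm `clip`, averaged, perturbed with Gaussian
#' noise calibrated to the replace-one gradient sensitivity
#' \eqn{2\,\mathrm{clip}/N} at the per-iteration budget, and a fixed-step
#' descent step is taken. The cumulative privacy loss over the `iters`
#' compositions is computed with the Renyi-DP conversion of
#' [rdp_overall_epsilon()] and reported in the result.
#'
#' @inheritParams gaussian_fm_fit
#' @param iters number of gradient iterations T.
#' @param clip per-sample gradient clipping norm.
#' @param step fixed step size.
#' @param delta_r target delta for the Renyi-DP conversion (defaults to the
#'   per-iteration delta).
#' @return A `gaussfm_fit` with `overall_epsilon` from the accountant.
#' @export
noisy_gd_fit <- function(ds, budget, iters = 100, clip = 1, step = 0.5,
                         delta_r = NULL, seed = NULL, model = NULL) {
  model <- infer_model(ds, model)
  assert_dataset(ds)
  stopifnot(iters >= 1, clip > 0, step > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples(ds)
  d <- n_features(ds)
  sens <- 2 * clip / n
  tau <- sens * noise_multiplier(budget)
  w <- rep(0, d)
  for (t in seq_len(iters)) {
    G <- per_sample_gradients(ds, w, model)
    norms <- pmax(row_norms(G) / clip, 1)
    g <- colMeans(G / norms) + stats::rnorm(d, 0, tau)
    w <- w - step * g
    if (!all(is.finite(w))) {
      stop("noisy gradient descent diverged at iteration ", t)
    }
  }
  mult <- noise_multiplier(budget)
  if (is.null(delta_r)) delta_r <- if (!is.null(budget$delta)) budget$delta else 1e-5
  overall <- if (mult > 0) {
    rdp_overall_epsilon(iters, mult, delta_r)$epsilon_opt
  } else 0
  fit_result(w, "noisy-gd", seed = seed, noise_levels = c(tau = tau),
             overall_epsilon = overall)
}
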