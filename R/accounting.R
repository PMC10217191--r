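#' Overall privacy loss of composed Gaussian mechanisms via Renyi DP
#'
#' A single Gaussian mechanism with noise-to-sensitivity ratio
#' \eqn{\sigma = \tau/\Delta} satisfies \eqn{(\alpha, \alpha/(2\sigma^2))}-RDP;
#' T-fold composition scales the Renyi loss by T, and converting back to
#' \eqn{(\epsilon, \delta_r)}-DP at the optimal order gives
#' \deqn{\alpha_{opt} = 1 + \sqrt{2 \sigma^2 \ln(1/\delta_r) / T}, \qquad
#'       \epsilon_{opt} = \frac{\alpha_{opt} T}{2\sigma^2}
#'         + \frac{\ln(1/\delta_r)}{\alpha_{opt} - 1}.}
#' Natural logarithms throughout.
#'
#' @param iters number of compositions T.
#' @param noise_to_sensitivity positive ratio \eqn{\tau/\Delta}.
#' @param delta_r target failure probability in (0, 1).
#' @return An object of class `rdp_account` with fields `iters`,
#'   `noise_to_sensitivity`, `delta_r`, `alpha_opt`, `epsilon_opt`.
#' @export
rdp_overall_epsilon <- function(iters, noise_to_sensitivity, delta_r) {
  if (iters <= 0 || noise_to_sensitivity <= 0) {
    stop("iters and noise_to_sensitivity must be positive")
  }
  if (delta_r <= 0 || delta_r >= 1) stop("delta_r must lie in (0, 1)")
  s2 <- noise_to_sensitivity^2
  alpha <- 1 + sqrt(2 * s2 * log(1 / delta_r) / iters)
  eps <- rdp_epsilon_at_alpha(alpha, iters, noise_to_sensitivity, delta_r)
  structure(list(iters = iters, noise_to_sensitivity = noise_to_sensitivity,
                 delta_r = delta_r, alpha_opt = alpha, epsilon_opt = eps),
            class = "rdp_account")
}

#' @rdname rdp_overall_epsilon
#' @param alpha Renyi order (> 1); the conversion is minimized over this.
#' @export
rdp_epsilon_at_alpha <- function(alpha, iters, noise_to_sensitivity, delta_r) {
  stopifnot(alpha > 1)
  alpha * iters / (2 * noise_to_sensitivity^2) + log(1 / delta_r) / (alpha - 1)
}

#' @export
print.rdp_account <- function(x, ...) {
  cat("<rdp_account> T = ", x$iters, ", tau/Delta = ",
      format(x$noise_to_sensitivity), ", delta_r = ", format(x$delta_r),
      "\n  alpha_opt = ", format(x$alpha_opt), ", overall epsilon = ",
      format(x$epsilon_opt), "\n", sep = "")
  invisible(x)
}

#' Tolerated number of colluding sites
#'
#' The correlated-noise protocol tolerates up to
#' \eqn{S_C = \lceil S/3 \rceil - 1} sites colluding with the aggregator
#' after execution.
#'
#' @param S number of sites (>= 1).
#' @return integer collusion threshold.
#' @export
collusion_threshold <- function(S) {
  if (S < 1) stop("S must be at least 1")
  as.integer(ceiling(S / 3) - 1)
}

#' Privacy failure probability of the correlated-noise protocol
#'
#' For the symmetric decentralized setting (equal site sizes, equal per-site
#' noise sd `tau_s`) with up to [collusion_threshold()] colluding sites, the
#' per-site \eqn{(\epsilon, \delta)} guarantee follows a Gaussian
#' privacy-loss variable with mean
#' \deqn{\mu_z = \frac{S^3}{2 \tau_s^2 N^2}\left[\frac{1+S}{S-S_C} +
#'   \frac{2}{S-S_C} + \frac{9 (S-S_C) S_C^2}{S(1+S) - 3 S_C^2}\right]}
#' and variance \eqn{\sigma_z^2 = 2\mu_z}; the failure probability is the
#' two-sided Gaussian tail bound
#' \eqn{\delta = \frac{2\sigma_z}{\epsilon - \mu_z}\,
#'   \varphi\!\left(\frac{\epsilon - \mu_z}{\sigma_z}\right)} with
#' \eqn{\varphi} the standard normal density. Values outside (0, 1) are
#' clamped with a warning.
#'
#' @param S number of sites (>= 3 for a meaningful collusion model).
#' @param N total number of samples across sites.
#' @param tau_s per-site noise standard deviation.
#' @param epsilon privacy parameter in (0, 1).
#' @return list with `delta` and a `cape_account` holding `S`, `SC`, `N`,
#'   `tau_s`, `mu_z`, `sigma_z`, `epsilon`, `delta`.
#' @export
cape_delta <- function(S, N, tau_s, epsilon) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must lie in (0, 1)")
  if (S < 3) stop("the collusion model needs S >= 3")
  stopifnot(N >= 1, tau_s > 0)
  SC <- collusion_threshold(S)
  mu_z <- S^3 / (2 * tau_s^2 * N^2) *
    ((1 + S) / (S - SC) + 2 / (S - SC) +
       9 * (S - SC) * SC^2 / (S * (1 + S) - 3 * SC^2))
  sigma_z <- sqrt(2 * mu_z)
  t <- (epsilon - mu_z) / sigma_z
  delta <- 2 * sigma_z / (epsilon - mu_z) * stats::dnorm(t)
  if (!is.finite(delta) || delta <= 0 || delta >= 1) {
    warning("delta = ", format(delta), " outside (0, 1); clamped")
    delta <- min(1 - 1e-12, max(1e-300, delta))
  }
  account <- structure(list(S = S, SC = SC, N = N, tau_s = tau_s,
                            mu_z = mu_z, sigma_z = sigma_z,
                            epsilon = epsilon, delta = delta),
                       class = "cape_account")
  list(delta = delta, account = account)
}

#' @export
print.cape_account <- function(x, ...) {
  cat("<cape_account> S = ", x$S, " (SC = ", x$SC, "), N = ", x$N,
      ", tau_s = ", format(x$tau_s), "\n  mu_z = ", format(x$mu_z),
      ", epsilon = ", format(x$epsilon), ", delta = ", format(x$delta),
      "\n", sep = "")
  invisible(x)
}

#' Variance split of the correlated-noise protocol
#'
#' Each site's privacy noise of variance \eqn{\tau_s^2} is split into a
#' correlated zero-sum part with variance \eqn{\tau_e^2 = (1 - 1/S)\tau_s^2}
#' and an independent local part with variance \eqn{\tau_g^2 = \tau_s^2/S};
#' the two sum back to \eqn{\tau_s^2}.
#'
#' @param tau_s per-site noise standard deviation.
#' @param S number of sites.
#' @return list with `tau_e` and `tau_g` (standard deviations).
#' @export
cape_noise_split <- function(tau_s, S) {
  stopifnot(S >= 1, tau_s >= 0)
  list(tau_e = sqrt((1 - 1 / S) * tau_s^2), tau_g = sqrt(tau_s^2 / S))
}

#' Variance gain over the conventional decentralized scheme
#'
#' In the symmetric setting the conventional aggregate has noise variance
#' \eqn{\tau_s^2/S} while the correlated-noise aggregate has
#' \eqn{\tau_s^2/S^2}; the ratio is \eqn{G = S}.
#'
#' @param S number of sites.
#' @return the gain `S`.
#' @export
cape_gain <- function(S) {
  stopifnot(S >= 1)
  S
}

#' Aggregate-to-pooled variance ratio for general site sizes
#'
#' For per-site sensitivities \eqn{\Delta(N_s)} and pooled sensitivity
#' \eqn{\Delta(N)},
#' \deqn{H = \frac{\sum_s \Delta^2(N_s)}{S^3 \Delta^2(N)};}
#' the correlated-noise aggregate matches the pooled noise exactly when
#' \eqn{H = 1} (e.g. symmetric sites with \eqn{\Delta(N/S) = S\Delta(N)}).
#'
#' @param site_sensitivities vector of per-site sensitivities
#'   \eqn{\Delta(N_s)}.
#' @param total_sensitivity pooled sensitivity \eqn{\Delta(N)}.
#' @param S number of sites (defaults to the length of
#'   `site_sensitivities`).
#' @return the ratio H.
#' @export
cape_H <- function(site_sensitivities, total_sensitivity,
                   S = length(site_sensitivities)) {
  if (length(site_sensitivities) < 1) stop("need at least one site sensitivity")
  stopifnot(all(site_sensitivities > 0), total_sensitivity > 0, S >= 1)
  sum(site_sensitivities^2) / (S^3 * total_sensitivity^2)
}
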