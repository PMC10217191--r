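#' Correlated zero-sum noise shares
#'
#' Each site draws a raw array of i.i.d. Gaussian entries (sd `tau_s`) and
#' subtracts the across-site mean, so the centered shares sum to zero exactly
#' while each share keeps variance \eqn{(1 - 1/S)\tau_s^2} per entry. The
#' secure-aggregation exchange that would compute the across-site sum without
#' revealing individual draws is simulated at a single trusted point; only
#' the sum of the raw draws is ever exposed outside the sites.
#'
#' @param S number of sites.
#' @param tau_s raw per-site noise standard deviation.
#' @param shape entry count (scalar or vector length) or `c(d, d)` for a
#'   matrix-shaped order; with `symmetric = TRUE` matrix draws use
#'   [symmetric_gaussian_matrix()] so shares stay symmetric.
#' @param symmetric draw symmetric matrix noise (order-2 coefficients).
#' @param seed integer seed (optional).
#' @return list of S centered arrays summing to zero entry-wise.
#' @export
zero_sum_noise <- function(S, tau_s, shape = 1, symmetric = FALSE,
                           seed = NULL) {
  stopifnot(S >= 1, tau_s >= 0)
  if (!is.null(seed)) set.seed(seed)
  draw <- function() {
    if (symmetric) {
      if (length(shape) != 2 || shape[1] != shape[2]) {
        stop("symmetric draws need shape = c(d, d)")
      }
      symmetric_gaussian_matrix(shape[1], tau_s)
    } else if (length(shape) == 2) {
      matrix(stats::rnorm(prod(shape), 0, tau_s), shape[1], shape[2])
    } else {
      stats::rnorm(shape, 0, tau_s)
    }
  }
  hats <- lapply(seq_len(S), function(s) draw())
  center <- Reduce(`+`, hats) / S
  lapply(hats, function(h) h - center)
}

# shared site-side decomposition and sensitivity bookkeeping
site_objectives <- function(sites, model) {
  lapply(sites$sites, function(ds) {
    assert_dataset(ds)
    decompose_dataset(ds)
  })
}

check_sites <- function(sites) {
  stopifnot(inherits(sites, "site_collection"))
  if (sites$S < 1) stop("empty site collection")
  dims <- vapply(sites$sites, n_features, integer(1))
  if (length(unique(dims)) != 1) stop("sites have heterogeneous dimensions")
  tasks <- vapply(sites$sites, function(d) d$task, character(1))
  if (length(unique(tasks)) != 1) stop("sites have heterogeneous tasks")
  invisible(sites)
}

# average a list of quadratic_objective coefficient-wise
average_objectives <- function(objs, model) {
  S <- length(objs)
  quadratic_objective(
    mean(vapply(objs, function(o) o$constant, numeric(1))),
    Reduce(`+`, lapply(objs, function(o) o$linear)) / S,
    Reduce(`+`, lapply(objs, function(o) o$quadratic)) / S,
    model = model
  )
}

#' Decentralized Gaussian functional mechanism with correlated noise
#'
#' Each site decomposes its local data, calibrates per-order noise to its
#' *local* sensitivities \eqn{\Delta_j(N_s)}, and perturbs each coefficient
#' array with the sum of a correlated zero-sum share ([zero_sum_noise()])
#' and a small independent local term with sd \eqn{\tau_{js}/\sqrt S}. The
#' aggregator averages the site releases — the zero-sum parts cancel exactly
#' — repairs positive semidefiniteness once, and minimizes. In the symmetric
#' setting the surviving aggregated noise variance
#' \eqn{\tau_{js}^2/S^2} equals the pooled-data Gaussian FM variance.
#'
#' @param sites a [partition_sites()] collection (symmetric; S >= 3
#'   recommended for the collusion model).
#' @param budget a [privacy_budget()].
#' @param seed integer seed (optional).
#' @param model optional consistency check.
#' @return A `gaussfm_fit` with mechanism `"cape-fm"`.
#' @export
cape_fm_fit <- function(sites, budget, seed = NULL, model = NULL) {
  check_sites(sites)
  model <- infer_model(sites$sites[[1]], model)
  if (!is.null(seed)) set.seed(seed)
  S <- sites$S
  d <- n_features(sites$sites[[1]])
  mult <- noise_multiplier(budget)
  objs <- site_objectives(sites, model)
  # per-site, per-order noise sd from the local sample count
  tau_site <- lapply(sites$Ns, function(ns) gauss_fm_sensitivities(model, ns) * mult)
  noisy <- vector("list", S)
  for (j in 0:2) {
    key <- paste0("delta", j)
    tau_js <- vapply(tau_site, `[[`, numeric(1), key)
    # symmetric setting: one shared sd for the zero-sum generation
    shape <- if (j == 2) c(d, d) else if (j == 1) d else 1
    es <- zero_sum_noise(S, tau_js[1], shape = shape, symmetric = j == 2)
    for (s in seq_len(S)) {
      g_sd <- tau_js[s] / sqrt(S)
      gs <- if (j == 2) symmetric_gaussian_matrix(d, g_sd)
            else stats::rnorm(shape, 0, g_sd)
      noisy[[s]][[key]] <- objective_order(objs[[s]], j) + es[[s]] + gs
    }
  }
  released <- lapply(noisy, function(parts) {
    quadratic_objective(parts$delta0, parts$delta1, parts$delta2, model)
  })
  agg <- average_objectives(released, model)
  eps <- if (!is.null(budget$epsilon)) budget$epsilon else NA_real_
  finish_fm_fit(agg, "cape-fm", seed,
                noise_levels = tau_site[[1]], overall_epsilon = eps)
}

# pull the order-j coefficient array out of an objective
objective_order <- function(obj, j) {
  switch(as.character(j), "0" = obj$constant, "1" = obj$linear,
         "2" = obj$quadratic)
}

#' Conventional decentralized baseline
#'
#' Each site runs the full pooled-style Gaussian functional mechanism on its
#' local data — independent noise at the local calibration
#' \eqn{\tau_{js} = \Delta_j(N_s)\sigma} — and the aggregator averages the
#' releases, repairs and minimizes. The aggregated noise variance is
#' \eqn{\tau_{js}^2/S}, a factor S worse than the correlated-noise scheme.
#'
#' @inheritParams cape_fm_fit
#' @return A `gaussfm_fit` with mechanism `"conventional"`.
#' @export
conventional_decentralized_fit <- function(sites, budget, seed = NULL,
                                           model = NULL) {
  check_sites(sites)
  model <- infer_model(sites$sites[[1]], model)
  if (!is.null(seed)) set.seed(seed)
  S <- sites$S
  d <- n_features(sites$sites[[1]])
  mult <- noise_multiplier(budget)
  objs <- site_objectives(sites, model)
  released <- lapply(seq_len(S), function(s) {
    tau <- gauss_fm_sensitivities(model, sites$Ns[s]) * mult
    quadratic_objective(
      objs[[s]]$constant + stats::rnorm(1, 0, tau[["delta0"]]),
      objs[[s]]$linear + stats::rnorm(d, 0, tau[["delta1"]]),
      objs[[s]]$quadratic + symmetric_gaussian_matrix(d, tau[["delta2"]]),
      model
    )
  })
  agg <- average_objectives(released, model)
  eps <- if (!is.null(budget$epsilon)) budget$epsilon else NA_real_
  finish_fm_fit(agg, "conventional", seed,
                noise_levels = gauss_fm_sensitivities(model, sites$Ns[1]) * mult,
                overall_epsilon = eps)
}
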