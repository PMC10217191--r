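#' Test-set mean squared error
#'
#' \eqn{\mathrm{MSE} = (1/N_{test}) \sum_n (\hat y_n - y_n)^2} with
#' \eqn{\hat y = x^\top w}; predictions are not clipped.
#'
#' @param fit a `gaussfm_fit` or a numeric weight vector.
#' @param test a regression [labeled_dataset()].
#' @return nonnegative scalar.
#' @export
mse <- function(fit, test) {
  w <- if (inherits(fit, "gaussfm_fit")) fit$weights else as.numeric(fit)
  if (test$task != "regression") stop("mse needs a regression test set")
  if (n_samples(test) < 1L) stop("empty test set")
  pred <- drop(test$features %*% w)
  mean((pred - test$labels)^2)
}

#' Test-set classification accuracy
#'
#' Fraction of test samples whose predicted label
#' \eqn{1\{x^\top w \ge 0\}} (equivalently, the sigmoid output rounded
#' half-up, so a tie at \eqn{x^\top w = 0} predicts class 1) equals the true
#' label.
#'
#' @param fit a `gaussfm_fit` or a numeric weight vector.
#' @param test a classification [labeled_dataset()].
#' @return fraction in \eqn{[0, 1]}.
#' @export
accuracy <- function(fit, test) {
  w <- if (inherits(fit, "gaussfm_fit")) fit$weights else as.numeric(fit)
  if (test$task != "classification") {
    stop("accuracy needs a classification test set")
  }
  if (n_samples(test) < 1L) stop("empty test set")
  pred <- as.numeric(drop(test$features %*% w) >= 0)
  mean(pred == test$labels)
}

# one private fit dispatched by mechanism tag; budget is a privacy_budget
fit_mechanism <- function(mechanism, train, budget, seed, sites = NULL,
                          gd = list(iters = 100, clip = 1, step = 0.5)) {
  switch(mechanism,
    "non-priv" = nonprivate_fit(train),
    "gauss-fm" = gaussian_fm_fit(train, budget, seed = seed),
    "rlx-fm" = relaxed_fm_fit(train, budget, seed = seed),
    "fm" = if (!is.null(budget$epsilon)) {
      laplace_fm_fit(train, epsilon = budget$epsilon, seed = seed)
    } else {
      laplace_fm_fit(train, noise_multiplier = budget$noise_multiplier,
                     seed = seed)
    },
    "noisy-gd" = noisy_gd_fit(train, budget, iters = gd$iters,
                              clip = gd$clip, step = gd$step, seed = seed),
    "cape-fm" = cape_fm_fit(sites, budget, seed = seed),
    "conventional" = conventional_decentralized_fit(sites, budget,
                                                    seed = seed),
    stop("unknown mechanism: ", mechanism)
  )
}

default_w_true <- function(d, task) {
  # fixed, reproducible ground truth with norm well inside the label range
  w <- rep_len(c(1, -1), d) * 0.5 / sqrt(d)
  if (task == "classification") w * 6 else w
}

sweep_dataset <- function(data_cfg, n, seed) {
  task <- data_cfg$task
  d <- data_cfg$d
  w_true <- if (!is.null(data_cfg$w_true)) data_cfg$w_true
            else default_w_true(d, task)
  if (task == "regression") {
    noise_sd <- if (!is.null(data_cfg$noise_sd)) data_cfg$noise_sd else 0.05
    synth_linear(n, d, w_true, noise_sd = noise_sd, seed = seed)
  } else {
    synth_logistic(n, d, w_true, seed = seed)
  }
}

#' Privacy-utility sweep
#'
#' Runs the full evaluation design: synthetic data generation, a 90:10
#' train/test split, `n_runs` seeded private fits per mechanism at each grid
#' point of the sweep variable, and the run-averaged utility metric (MSE for
#' regression, accuracy for classification) together with the overall
#' privacy loss of each mechanism. The sweep axis `"tau"` is the
#' per-unit-sensitivity noise multiplier
#' \eqn{\sigma = (1/\epsilon)\sqrt{2\ln(1.25/\delta)}}; each mechanism's
#' actual noise sd is its own sensitivity times \eqn{\sigma}. A non-private
#' reference row is always included.
#'
#' @param config a list with elements
#'   \describe{
#'     \item{data}{list(task, n, d, and optionally w_true, noise_sd)}
#'     \item{mechanisms}{character vector of mechanism tags (any of
#'       `"gauss-fm"`, `"rlx-fm"`, `"fm"`, `"noisy-gd"`, `"cape-fm"`,
#'       `"conventional"`); `"non-priv"` is added automatically}
#'     \item{sweep}{list(variable = one of `"tau"`, `"n_train"`, `"delta"`,
#'       `"sites"`; grid = numeric vector)}
#'     \item{fixed}{optional overrides: epsilon (0.5), delta (1e-5), n_runs
#'       (10), test_fraction (0.1), sites (5), gd (iters/clip/step)}
#'     \item{seed_base}{integer; every source of randomness derives from it}
#'   }
#' @param output optional CSV path for the records.
#' @return data.frame of evaluation records (one row per grid point and
#'   mechanism) with attribute `"per_run"` holding the per-run metrics.
#' @export
run_sweep <- function(config, output = NULL) {
  data_cfg <- config$data
  stopifnot(!is.null(data_cfg$task), !is.null(data_cfg$n), !is.null(data_cfg$d))
  sweep <- config$sweep
  if (!sweep$variable %in% c("tau", "n_train", "delta", "sites")) {
    stop("unknown sweep variable: ", sweep$variable)
  }
  if (length(sweep$grid) < 1) stop("empty sweep grid")
  fixed <- config$fixed
  if (is.null(fixed)) fixed <- list()
  epsilon <- fixed$epsilon %||% 0.5
  delta <- fixed$delta %||% 1e-5
  n_runs <- fixed$n_runs %||% 10
  test_fraction <- fixed$test_fraction %||% 0.1
  n_sites <- fixed$sites %||% 5
  gd <- fixed$gd %||% list(iters = 100, clip = 1, step = 0.5)
  seed_base <- config$seed_base %||% 1
  mechanisms <- unique(c("non-priv", config$mechanisms))
  decentral <- sweep$variable == "sites" ||
    any(mechanisms %in% c("cape-fm", "conventional"))
  metric <- if (data_cfg$task == "regression") "mse" else "accuracy"

  records <- list()
  per_run <- list()
  for (gi in seq_along(sweep$grid)) {
    g <- sweep$grid[gi]
    n_total <- if (sweep$variable == "n_train") {
      round(g / (1 - test_fraction))
    } else data_cfg$n
    delta_g <- if (sweep$variable == "delta") g else delta
    budget <- if (sweep$variable == "tau") {
      privacy_budget(noise_multiplier = g)
    } else {
      privacy_budget(epsilon = epsilon, delta = delta_g)
    }
    S_g <- if (sweep$variable == "sites") g else n_sites
    ds <- sweep_dataset(data_cfg, n_total, seed = seed_base + 7919L * gi)
    parts <- split_dataset(ds, test_fraction, seed = seed_base + 7919L * gi + 1L)
    train <- preprocess(parts$train)
    test <- if (ds$task == "regression") {
      preprocess(parts$test, transform = attr(train, "label_transform"))
    } else preprocess(parts$test)
    for (mech in mechanisms) {
      use_sites <- mech %in% c("cape-fm", "conventional")
      sites <- if (use_sites) {
        partition_sites(train, S_g, seed = seed_base + 7919L * gi + 2L)
      } else NULL
      vals <- vapply(seq_len(n_runs), function(r) {
        seed_r <- seed_base + 7919L * gi + 101L * r
        fit <- fit_mechanism(mech, train, budget, seed_r, sites = sites,
                             gd = gd)
        if (metric == "mse") mse(fit, test) else accuracy(fit, test)
      }, numeric(1))
      overall_eps <- sweep_overall_epsilon(mech, budget, delta_g, gd)
      records[[length(records) + 1L]] <- data.frame(
        mechanism = mech, sweep_variable = sweep$variable, sweep_value = g,
        metric = metric, metric_value = mean(vals),
        overall_epsilon = overall_eps, n_runs = n_runs,
        seed_base = seed_base, stringsAsFactors = FALSE)
      per_run[[length(per_run) + 1L]] <- data.frame(
        mechanism = mech, sweep_value = g, run = seq_len(n_runs),
        metric_value = vals, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, records)
  attr(out, "per_run") <- do.call(rbind, per_run)
  if (!is.null(output)) utils::write.csv(out, output, row.names = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# overall privacy loss reported per evaluation record
sweep_overall_epsilon <- function(mechanism, budget, delta, gd) {
  if (mechanism == "non-priv") return(Inf)
  mult <- noise_multiplier(budget)
  if (mult <= 0) return(0)
  if (mechanism == "noisy-gd") {
    return(rdp_overall_epsilon(gd$iters, mult, delta)$epsilon_opt)
  }
  if (mechanism == "fm") {
    # pure-DP Laplace: epsilon as given, or inverted from the noise scale
    return(if (!is.null(budget$epsilon)) budget$epsilon else sqrt(2) / mult)
  }
  if (!is.null(budget$epsilon)) return(budget$epsilon)
  epsilon_from_multiplier(mult, delta)
}
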