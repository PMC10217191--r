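# hand-evaluated two-sample example used in several blocks:
# x1 = (1,0), y1 = 1; x2 = (0,1), y2 = -1
toy_linear <- labeled_dataset(rbind(c(1, 0), c(0, 1)), c(1, -1),
                              task = "regression")

test_that("linear decomposition matches hand-evaluated sums", {
  obj <- decompose_linear(toy_linear)
  expect_equal(obj$constant, 1)
  expect_equal(obj$linear, c(-1, 1))
  expect_equal(obj$quadratic, diag(0.5, 2))
  # all-zero data gives the zero objective
  zero <- labeled_dataset(matrix(0, 3, 2), rep(0, 3), task = "regression")
  zobj <- decompose_linear(zero)
  expect_equal(zobj$constant, 0)
  expect_equal(zobj$linear, c(0, 0))
  expect_equal(zobj$quadratic, matrix(0, 2, 2))
  # quadratic part is (1/N) X'X in the rows-as-samples orientation
  ds <- rand_dataset(40, 4, seed = 2)
  expect_equal(decompose_linear(ds)$quadratic,
               crossprod(ds$features) / 40)
})

test_that("decomposed objective evaluates to the direct average cost", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(2:200, 1)
    d <- sample(1:10, 1)
    ds <- rand_dataset(n, d)
    w <- runif(d, -2, 2)
    expect_equal(evaluate_objective(decompose_linear(ds), w),
                 direct_linear_cost(ds, w), tolerance = 1e-10)
  }
})

test_that("logistic decomposition matches hand sums and Taylor constants", {
  expect_equal(logistic_taylor_constants(), c(log(2), 0.5, 0.25))
  one <- labeled_dataset(matrix(c(1, 0), 1), 1, task = "classification")
  obj <- decompose_logistic(one)
  expect_equal(obj$constant, log(2))
  expect_equal(obj$linear, c(-0.5, 0))
  expect_equal(obj$quadratic, rbind(c(0.125, 0), c(0, 0)))
  # the constant is log 2 regardless of the data
  ds <- rand_dataset(30, 3, "classification", seed = 6)
  expect_equal(decompose_logistic(ds)$constant, log(2))
})

test_that("logistic surrogate is a second-order expansion of the true cost", {
  ds <- rand_dataset(50, 4, "classification", seed = 7)
  obj <- decompose_logistic(ds)
  # at w = 0 the surrogate equals the exact cost exactly (both log 2 - ...)
  expect_equal(evaluate_objective(obj, rep(0, 4)),
               direct_logistic_cost(ds, rep(0, 4)))
  # cubic remainder: |surrogate - exact| <= c * ||w||^3 for small w
  set.seed(8)
  for (i in 1:20) {
    w <- runif(4, -1, 1)
    w <- w / sqrt(sum(w^2)) * runif(1, 1e-3, 0.01)
    err <- abs(evaluate_objective(obj, w) - direct_logistic_cost(ds, w))
    expect_lte(err, 0.1 * sqrt(sum(w^2))^3)
  }
})

test_that("evaluation respects the quadratic-form identities", {
  obj <- decompose_linear(toy_linear)
  expect_equal(evaluate_objective(obj, c(0, 0)), obj$constant)
  expect_equal(evaluate_objective(obj, c(1, -1)), 0)
  expect_error(evaluate_objective(obj, c(1, 2, 3)), "dimension")
})

test_that("closed-form minimization solves the stationarity condition", {
  obj <- decompose_linear(toy_linear)
  expect_equal(minimize_objective(obj), c(1, -1))
  # pure quadratic form has its minimum at the origin
  pure <- quadratic_objective(0, c(0, 0), diag(2), "linear")
  expect_equal(minimize_objective(pure), c(0, 0))
  # unbounded and non-finite inputs fail loudly
  flat <- quadratic_objective(0, c(1, 0), matrix(0, 2, 2), "linear")
  expect_error(minimize_objective(flat), "unbounded")
  bad <- quadratic_objective(NaN, c(0, 0), diag(2), "linear")
  expect_error(minimize_objective(bad), "non-finite")
})

test_that("minimizer agrees with a coordinate-descent oracle", {
  set.seed(13)
  for (i in 1:50) {
    d <- sample(2:5, 1)
    A <- matrix(rnorm(d * d), d, d)
    M <- crossprod(A) / d + diag(0.2, d)
    obj <- quadratic_objective(runif(1), rnorm(d), M, "linear")
    expect_equal(minimize_objective(obj), coord_descent(obj),
                 tolerance = 1e-6)
  }
})

test_that("minimize after repair reproduces the least-squares solution", {
  set.seed(14)
  for (i in 1:10) {
    ds <- rand_dataset(sample(30:100, 1), sample(2:6, 1))
    w_pkg <- minimize_objective(repair_psd(decompose_linear(ds)))
    expect_equal(w_pkg, svd_lstsq(ds$features, ds$labels), tolerance = 1e-8)
  }
})

test_that("symmetric noise matrices are exactly symmetric with the right law", {
  set.seed(15)
  expect_equal(symmetric_gaussian_matrix(4, 0), matrix(0, 4, 4))
  E <- symmetric_gaussian_matrix(6, 2)
  expect_identical(E, t(E))
  # Monte-Carlo audit of one off-diagonal entry
  draws <- replicate(1e5, symmetric_gaussian_matrix(2, 0.7)[1, 2])
  expect_lt(abs(var(draws) / 0.49 - 1), 0.05)
})

test_that("PSD repair clips eigenvalues and only eigenvalues", {
  # hand case: eigenvalues +/-1, the -1 clipped, reconstruct by hand
  obj <- quadratic_objective(0.3, c(1, 2), rbind(c(0, 1), c(1, 0)), "linear")
  fixed <- repair_psd(obj)
  expect_equal(fixed$quadratic, matrix(0.5, 2, 2))
  expect_equal(fixed$constant, 0.3)
  expect_equal(fixed$linear, c(1, 2))
  expect_true(attr(fixed, "psd_repaired"))
  # diagonal case
  dobj <- quadratic_objective(0, c(0, 0), diag(c(1, -2)), "linear")
  expect_equal(repair_psd(dobj)$quadratic, diag(c(1, 0)))
  # PSD input unchanged, and repair is idempotent
  psd <- quadratic_objective(0, c(1, 1), diag(c(2, 3)), "linear")
  expect_equal(repair_psd(psd)$quadratic, psd$quadratic, tolerance = 1e-12)
  once <- repair_psd(dobj)
  expect_equal(repair_psd(once)$quadratic, once$quadratic, tolerance = 1e-12)
  # eigenvalues never decrease
  set.seed(16)
  for (i in 1:10) {
    M <- symmetric_gaussian_matrix(4, 1)
    before <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    after <- eigen(repair_psd(quadratic_objective(0, rep(0, 4), M, "linear"))$quadratic,
                   symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(after >= before - 1e-10))
    expect_gte(min(after), -1e-10)
  }
  # all-negative spectrum is flagged, not silently resolved
  neg <- quadratic_objective(0, c(0, 0), diag(c(-1, -2)), "linear")
  expect_warning(res <- repair_psd(neg), "negative")
  expect_true(attr(res, "all_negative"))
})

test_that("objectives survive a JSON round-trip", {
  obj <- decompose_linear(toy_linear)
  path <- withr::local_tempfile(fileext = ".json")
  objective_to_json(obj, path)
  back <- objective_from_json(path)
  expect_equal(back$constant, obj$constant)
  expect_equal(back$linear, obj$linear)
  expect_equal(back$quadratic, obj$quadratic)
  expect_equal(back$model, obj$model)
})
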