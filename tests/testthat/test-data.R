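test_that("CSV round-trip reproduces a dataset bit-exactly", {
  ds <- rand_dataset(3, 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_csv_dataset(ds, path)
  back <- load_csv(path, "y", task = "regression")
  expect_equal(unname(back$features), unname(ds$features))
  expect_equal(back$labels, ds$labels)
  expect_equal(n_samples(back), 3L)
  expect_equal(n_features(back), 2L)
})

test_that("load_csv fails descriptively on bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x1,x2,y", "0.1,0.2,1", "0.3,oops,0"), path)
  expect_error(load_csv(path, "y", "regression"), "x2")
  writeLines(c("a,b", "1,2"), path)
  expect_error(load_csv(path, "y", "regression"), "label column")
  expect_error(load_csv(file.path(tempdir(), "nope.csv"), "y", "regression"),
               "not found")
})

test_that("preprocess enforces the norm and label assumptions", {
  raw <- labeled_dataset(rbind(c(1.2, 1.6), c(0.3, 0.4)), c(0, 5),
                         task = "regression", validate = FALSE)
  out <- preprocess(raw)
  # row with norm 2 is scaled onto the unit sphere; norm 0.5 is untouched
  expect_equal(sqrt(sum(out$features[1, ]^2)), 1)
  expect_equal(out$features[2, ], c(0.3, 0.4))
  # min-max to [-1, 1]
  raw2 <- labeled_dataset(diag(3) * 0.5, c(0, 5, 10),
                          task = "regression", validate = FALSE)
  expect_equal(preprocess(raw2)$labels, c(-1, 0, 1))
  # fitted transform re-applies (and clips) on unseen labels
  tf <- attr(preprocess(raw2), "label_transform")
  test_raw <- labeled_dataset(diag(3) * 0.5, c(2.5, 12, -3),
                              task = "regression", validate = FALSE)
  expect_equal(preprocess(test_raw, transform = tf)$labels, c(-0.5, 1, -1))
  # degenerate cases
  const <- labeled_dataset(diag(2), c(3, 3), task = "regression",
                           validate = FALSE)
  expect_error(preprocess(const), "constant")
})

test_that("preprocess is idempotent and transforms serialize through JSON", {
  raw <- labeled_dataset(matrix(runif(60, -2, 2), 20, 3), runif(20, -5, 5),
                         task = "regression", validate = FALSE)
  once <- preprocess(raw)
  twice <- preprocess(once)
  expect_equal(twice$features, once$features)
  expect_equal(twice$labels, once$labels)
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(attr(once, "label_transform"), path)
  tf <- read_transform(path)
  expect_equal(tf$lo, attr(once, "label_transform")$lo)
  expect_equal(tf$hi, attr(once, "label_transform")$hi)
})

test_that("generated and preprocessed data always satisfy the norm bound", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(2:50, 1)
    d <- sample(1:8, 1)
    ds <- if (i %% 2) synth_linear(n, d, runif(d, -1, 1), seed = i)
          else synth_logistic(n, d, runif(d, -1, 1), seed = i)
    expect_lte(max(sqrt(rowSums(ds$features^2))), 1 + 1e-9)
    expect_true(all(ds$labels >= -1 & ds$labels <= 1))
  }
})

test_that("synth_linear is deterministic and OLS recovers the truth", {
  a <- synth_linear(50, 3, c(0.2, -0.1, 0.3), seed = 11)
  b <- synth_linear(50, 3, c(0.2, -0.1, 0.3), seed = 11)
  expect_identical(a, b)
  # forced zero case
  z <- synth_linear(20, 3, rep(0, 3), noise_sd = 0, seed = 1)
  expect_equal(z$labels, rep(0, 20))
  # closed-form OLS on a large draw recovers each coordinate within 3 SE
  w_true <- rep(0.1, 10)
  ds <- synth_linear(10000, 10, w_true, noise_sd = 0.05, seed = 42)
  cm <- summary(lm(ds$labels ~ 0 + ds$features))$coefficients
  expect_lt(max(abs((cm[, 1] - w_true) / cm[, 2])), 3)
})

test_that("synth_logistic labels follow the sigmoid link", {
  a <- synth_logistic(40, 4, runif(4), seed = 5)
  b <- synth_logistic(40, 4, runif(4), seed = 5)
  expect_identical(a$labels, b$labels)
  # null model: positive rate near 1/2
  n <- 5000
  ds0 <- synth_logistic(n, 10, rep(0, 10), seed = 12)
  expect_lt(abs(mean(ds0$labels) - 0.5), 4 / sqrt(n))
  # strong signal: labels mostly agree with the decision boundary
  w <- rep(c(1, -1), 5) * 30 / sqrt(10)
  ds1 <- synth_logistic(n, 10, w, seed = 11)
  agree <- mean(ds1$labels == as.numeric(ds1$features %*% w >= 0))
  expect_gt(agree, 0.9)
})

test_that("split_dataset makes disjoint deterministic partitions", {
  ds <- rand_dataset(100, 2, seed = 3)
  sp <- split_dataset(ds, 0.1, seed = 9)
  expect_equal(n_samples(sp$test), 10L)
  expect_equal(n_samples(sp$train), 90L)
  idx <- c(attr(sp, "train_idx"), attr(sp, "test_idx"))
  expect_setequal(idx, 1:100)
  expect_length(intersect(attr(sp, "train_idx"), attr(sp, "test_idx")), 0)
  sp2 <- split_dataset(ds, 0.1, seed = 9)
  expect_identical(attr(sp2, "test_idx"), attr(sp, "test_idx"))
  expect_error(split_dataset(ds, 1.2), "between 0 and 1")
})

test_that("partition_sites conserves samples across equal-size sites", {
  ds <- rand_dataset(100, 3, seed = 4)
  sc <- partition_sites(ds, 4, seed = 8)
  expect_equal(sc$S, 4L)
  expect_equal(sc$Ns, rep(25, 4))
  pooled <- do.call(rbind, lapply(sc$sites, function(s) s$features))
  # concatenation is a permutation of the input rows
  expect_equal(pooled[order(pooled[, 1]), ],
               ds$features[order(ds$features[, 1]), ])
  sc2 <- partition_sites(ds, 4, seed = 8)
  expect_identical(sc2$sites[[2]]$labels, sc$sites[[2]]$labels)
  # single site is the whole dataset
  s1 <- partition_sites(ds, 1, seed = 1)
  expect_equal(sort(s1$sites[[1]]$labels), sort(ds$labels))
  expect_error(partition_sites(ds, 101), "cannot partition")
})
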