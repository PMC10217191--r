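#' Labeled dataset for private regression
#'
#' Container for a tabular supervised dataset: an N x D feature matrix with one
#' sample per row and a length-N label vector. The privacy analysis in this
#' package assumes every feature vector satisfies \eqn{\|x_n\|_2 \le 1} and that
#' regression labels lie in \eqn{[-1, 1]} (classification labels in \{0, 1\});
#' use [preprocess()] to enforce those assumptions on raw data.
#'
#' @param features numeric matrix, N rows (samples) by D columns (features).
#' @param labels numeric vector of length N.
#' @param task `"regression"` or `"classification"`.
#' @param validate if `TRUE` (default), enforce the norm/range invariants; raw
#'   data read from disk is constructed with `validate = FALSE` and must be run
#'   through [preprocess()] before fitting.
#' @return An object of class `labeled_dataset`: a list with elements
#'   `features`, `labels`, `task`.
#' @seealso [preprocess()], [synth_linear()], [synth_logistic()]
#' @export
labeled_dataset <- function(features, labels,
                            task = c("regression", "classification"),
                            validate = TRUE) {
  task <- match.arg(task)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.numeric(labels)
  if (nrow(features) != length(labels)) {
    stop("features has ", nrow(features), " rows but labels has length ",
         length(labels))
  }
  if (nrow(features) < 1L || ncol(features) < 1L) {
    stop("dataset must have at least one sample and one feature")
  }
  if (anyNA(features) || anyNA(labels)) stop("missing values are not allowed")
  ds <- structure(list(features = features, labels = labels, task = task),
                  class = "labeled_dataset")
  if (validate) assert_dataset(ds)
  ds
}

# Invariant checks shared by the constructor and the mechanisms.
assert_dataset <- function(ds) {
  norms <- row_norms(ds$features)
  if (any(norms > 1 + 1e-9)) {
    stop("feature rows must have L2 norm <= 1 (max found ",
         format(max(norms)), "); run preprocess() first")
  }
  if (ds$task == "regression") {
    if (any(ds$labels < -1 - 1e-9 | ds$labels > 1 + 1e-9)) {
      stop("regression labels must lie in [-1, 1]; run preprocess() first")
    }
  } else {
    if (!all(ds$labels %in% c(0, 1))) {
      stop("classification labels must be 0 or 1")
    }
  }
  invisible(ds)
}

row_norms <- function(X) sqrt(rowSums(X * X))

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", n_samples(x), " samples x ", n_features(x),
      " features, task = ", x$task, "\n", sep = "")
  invisible(x)
}

#' Number of samples / features in a dataset
#' @param ds a [labeled_dataset()].
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$features)

#' @rdname n_samples
#' @export
n_features <- function(ds) ncol(ds$features)

# Row subset preserving class and task (no re-validation: subsets of a valid
# dataset are valid).
subset_dataset <- function(ds, idx) {
  structure(list(features = ds$features[idx, , drop = FALSE],
                 labels = ds$labels[idx], task = ds$task),
            class = "labeled_dataset")
}

#' Read a labeled dataset from CSV
#'
#' Reads an RFC-4180 CSV with a header row into a raw [labeled_dataset()]. The
#' norm/range invariants are *not* enforced at this stage; call [preprocess()]
#' before fitting. Row order is preserved.
#'
#' @param path path to a CSV file.
#' @param label_column name of the label column; all remaining columns are
#'   treated as features.
#' @param task `"regression"` or `"classification"`.
#' @return A raw `labeled_dataset` (invariants unchecked).
#' @export
load_csv <- function(path, label_column,
                     task = c("regression", "classification")) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  }
  for (cn in names(df)) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      stop("non-numeric value in column '", cn, "', row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  feat <- as.matrix(df[, setdiff(names(df), label_column), drop = FALSE])
  if (ncol(feat) < 1L) stop("no feature columns besides '", label_column, "'")
  labeled_dataset(feat, df[[label_column]], task = task, validate = FALSE)
}

#' Write a labeled dataset to CSV
#'
#' @param ds a [labeled_dataset()].
#' @param path output path.
#' @param label_column name to use for the label column (default `"y"`).
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(ds, path, label_column = "y") {
  feat <- ds$features
  if (is.null(colnames(feat))) colnames(feat) <- paste0("x", seq_len(ncol(feat)))
  df <- as.data.frame(feat)
  df[[label_column]] <- ds$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Enforce the norm and label-range assumptions
#'
#' Scales every feature row by \eqn{1/\max(1, \|x_n\|_2)} so that all sample
#' norms are at most 1, and (for regression) min-max maps the labels onto
#' \eqn{[-1, 1]}. The fitted label transform is attached as the
#' `"label_transform"` attribute so it can be re-applied to a held-out test
#' split via the `transform` argument (values are then clipped to stay inside
#' \eqn{[-1, 1]}).
#'
#' @param raw a raw [labeled_dataset()].
#' @param transform optional label transform (as returned in the attribute) to
#'   apply instead of fitting a new one; used for test splits.
#' @return A `labeled_dataset` satisfying all invariants, with attribute
#'   `"label_transform"` (regression only).
#' @export
preprocess <- function(raw, transform = NULL) {
  if (n_samples(raw) < 1L) stop("cannot preprocess an empty dataset")
  norms <- row_norms(raw$features)
  feat <- raw$features / pmax(1, norms)
  labels <- raw$labels
  if (raw$task == "regression") {
    if (is.null(transform)) {
      lo <- min(labels)
      hi <- max(labels)
      if (hi - lo < .Machine$double.eps) {
        stop("regression labels are constant; min-max scaling is undefined")
      }
      transform <- list(lo = lo, hi = hi)
    }
    labels <- 2 * (labels - transform$lo) / (transform$hi - transform$lo) - 1
    labels <- pmin(1, pmax(-1, labels))
  } else {
    if (!all(labels %in% c(0, 1))) {
      stop("classification labels must already be binary 0/1")
    }
  }
  out <- labeled_dataset(feat, labels, task = raw$task)
  if (raw$task == "regression") attr(out, "label_transform") <- transform
  out
}

#' Serialize / restore a fitted label transform
#'
#' @param transform the `"label_transform"` attribute of a preprocessed
#'   dataset.
#' @param path JSON file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns the transform list.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(transform, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  jsonlite::fromJSON(path)
}

#' Synthetic linear-regression data
#'
#' Draws features i.i.d. uniform on \eqn{[-1,1]^D}, scales each row by
#' \eqn{1/\max(1, \|x\|_2)}, and sets \eqn{y = x^\top w + \varepsilon} with
#' Gaussian noise of standard deviation `noise_sd`, clipped to \eqn{[-1,1]}.
#' Output satisfies all [labeled_dataset()] invariants and is deterministic
#' given `seed`.
#'
#' @param n,d sample count and feature dimension.
#' @param w_true length-`d` coefficient vector.
#' @param noise_sd nonnegative label-noise standard deviation.
#' @param seed integer seed (optional).
#' @return A regression `labeled_dataset`.
#' @export
synth_linear <- function(n, d, w_true, noise_sd = 0.05, seed = NULL) {
  stopifnot(n >= 1, d >= 1, noise_sd >= 0, length(w_true) == d)
  if (!is.null(seed)) set.seed(seed)
  X <- draw_bounded_features(n, d)
  y <- drop(X %*% w_true) + stats::rnorm(n, 0, noise_sd)
  y <- pmin(1, pmax(-1, y))
  labeled_dataset(X, y, task = "regression")
}

#' Synthetic logistic-regression data
#'
#' Features as in [synth_linear()]; labels drawn
#' \eqn{y_n \sim \mathrm{Bernoulli}(f_{sig}(x_n^\top w))} with the sigmoid
#' link. Deterministic given `seed`.
#'
#' @inheritParams synth_linear
#' @return A classification `labeled_dataset`.
#' @export
synth_logistic <- function(n, d, w_true, seed = NULL) {
  stopifnot(n >= 1, d >= 1, length(w_true) == d)
  if (!is.null(seed)) set.seed(seed)
  X <- draw_bounded_features(n, d)
  p <- sigmoid(drop(X %*% w_true))
  y <- as.numeric(stats::runif(n) < p)
  labeled_dataset(X, y, task = "classification")
}

draw_bounded_features <- function(n, d) {
  X <- matrix(stats::runif(n * d, -1, 1), nrow = n, ncol = d)
  X / pmax(1, row_norms(X))
}

#' Sigmoid link
#' @param z numeric vector.
#' @return \eqn{1 / (1 + e^{-z})}.
#' @export
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train/test split
#'
#' Shuffles the rows and returns disjoint train and test partitions with
#' `round(N * test_fraction)` test samples (the evaluation default is a 90:10
#' split). Deterministic given `seed`.
#'
#' @param ds a [labeled_dataset()].
#' @param test_fraction fraction in (0, 1).
#' @param seed integer seed (optional).
#' @return list with elements `train` and `test`, plus the index vectors as
#'   attributes `"train_idx"` and `"test_idx"`.
#' @export
split_dataset <- function(ds, test_fraction = 0.1, seed = NULL) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be strictly between 0 and 1")
  }
  n <- n_samples(ds)
  if (n < 2L) stop("need at least 2 samples to split")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  n_test <- round(n * test_fraction)
  n_test <- max(1L, min(n - 1L, n_test))
  test_idx <- perm[seq_len(n_test)]
  train_idx <- perm[-seq_len(n_test)]
  out <- list(train = subset_dataset(ds, train_idx),
              test = subset_dataset(ds, test_idx))
  attr(out, "train_idx") <- train_idx
  attr(out, "test_idx") <- test_idx
  out
}

#' Partition a dataset across sites
#'
#' Splits the samples into `S` disjoint sites of equal size
#' \eqn{N_s = \lfloor N/S \rfloor} (the symmetric decentralized setting);
#' surplus rows beyond `S * floor(N/S)` are dropped. Deterministic given
#' `seed`.
#'
#' @param ds a [labeled_dataset()].
#' @param S number of sites.
#' @param seed integer seed (optional).
#' @return A `site_collection`: list with `sites` (list of S datasets), `S`,
#'   and `Ns` (per-site sample counts).
#' @export
partition_sites <- function(ds, S, seed = NULL) {
  stopifnot(S >= 1)
  n <- n_samples(ds)
  if (S > n) stop("cannot partition ", n, " samples across ", S, " sites")
  if (!is.null(seed)) set.seed(seed)
  ns <- n %/% S
  perm <- sample.int(n)[seq_len(ns * S)]
  sites <- lapply(seq_len(S), function(s) {
    subset_dataset(ds, perm[((s - 1) * ns + 1):(s * ns)])
  })
  structure(list(sites = sites, S = as.integer(S), Ns = rep(ns, S)),
            class = "site_collection")
}

#' @export
print.site_collection <- function(x, ...) {
  cat("<site_collection> ", x$S, " sites, Ns = ", x$Ns[1], ", D = ",
      n_features(x$sites[[1]]), "\n", sep = "")
  invisible(x)
}
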