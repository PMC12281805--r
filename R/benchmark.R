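#' Train/test split
#'
#' Seeded random or group-aware holdout split. Under the group scheme no
#' group identifier appears on both sides (scaffold-split semantics): groups
#' are accumulated into the test side in seeded random order until the
#' requested fraction is reached.
#'
#' @param data a [labeled_dataset()].
#' @param scheme `"random"` or `"group"` (requires `group_ids`).
#' @param test_fraction fraction of molecules held out, default 0.2.
#' @param seed integer seed.
#' @return list of class `data_split` with integer index vectors `train`
#'   and `test` and attributes `scheme` and `seed`.
#' @export
make_split <- function(data, scheme = c("random", "group"),
                       test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(data, "labeled_dataset"))
  scheme <- match.arg(scheme)
  n <- length(data$labels)
  target <- round(test_fraction * n)
  if (scheme == "random") {
    test <- sort(with_seed(seed, sample.int(n, target)))
  } else {
    if (is.null(data$group_ids))
      stop("group split requested but the dataset has no group_ids")
    sizes <- table(data$group_ids)
    if (max(sizes) > (1 - test_fraction) * n)
      stop("infeasible group split: one group covers more than ",
           "(1 - test_fraction) of the data")
    groups <- with_seed(seed, sample(names(sizes)))
    test_groups <- character(0)
    tot <- 0
    for (g in groups) {
      if (tot >= target) break
      test_groups <- c(test_groups, g)
      tot <- tot + sizes[[g]]
    }
    test <- sort(which(data$group_ids %in% test_groups))
  }
  structure(list(train = setdiff(seq_len(n), test), test = test),
            class = "data_split", scheme = scheme, seed = seed)
}

default_grid <- function(model_family) {
  switch(model_family,
    forest = expand.grid(num_trees = c(100, 500), max_depth = c(0, 10)),
    neural = expand.grid(size = c(16, 64), decay = c(1e-4, 1e-3)))
}

fit_predict <- function(model_family, params, x_train, y_train, x_test,
                        seed) {
  if (is.null(colnames(x_train))) {
    colnames(x_train) <- paste0("f", seq_len(ncol(x_train)))
    colnames(x_test) <- colnames(x_train)
  }
  if (model_family == "forest") {
    fit <- ranger::ranger(
      x = x_train, y = y_train,
      num.trees = params$num_trees,
      max.depth = if (params$max_depth == 0) NULL else params$max_depth,
      seed = seed, num.threads = 1)
    predict(fit, data = x_test, num.threads = 1)$predictions
  } else {
    mu <- colMeans(x_train)
    sdv <- apply(x_train, 2, sd)
    sdv[sdv == 0] <- 1
    xs <- scale(x_train, mu, sdv)
    fit <- with_seed(seed, nnet::nnet(
      x = xs, y = y_train, size = params$size, decay = params$decay,
      linout = TRUE, maxit = 300, trace = FALSE,
      MaxNWts = (ncol(xs) + 2) * params$size + 10))
    as.numeric(predict(fit, scale(x_test, mu, sdv)))
  }
}

#' Train and evaluate one model configuration
#'
#' Hyperparameters are selected by mean cross-validated RMSE on the training
#' side (seeded fold assignment), the winning configuration is refit on the
#' full training side, and test-side RMSE, MAE and R-squared are reported.
#'
#' @param data a [labeled_dataset()].
#' @param split a [make_split()] result.
#' @param model_family `"forest"` (ranger random forest) or `"neural"`
#'   (single-hidden-layer network with standardized inputs).
#' @param grid data.frame of hyperparameter combinations; per-family default
#'   when `NULL` (forest: 100/500 trees x unlimited/depth-10; neural: hidden
#'   size 16/64 x weight decay 1e-4/1e-3).
#' @param cv_folds number of CV folds, default 5.
#' @param seed integer seed controlling folds and model fits.
#' @return one-row data.frame (`run_record`): identifiers, `sample_size`,
#'   `split_scheme`, `model_family`, `seed`, best hyperparameters as `hp_*`
#'   columns, and test `rmse`, `mae`, `r2`.
#' @export
train_eval <- function(data, split, model_family = c("forest", "neural"),
                       grid = NULL, cv_folds = 5, seed = 1) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(split, "data_split"))
  model_family <- match.arg(model_family)
  if (is.null(grid)) grid <- default_grid(model_family)
  if (nrow(grid) < 1) stop("hyperparameter grid is empty")
  x <- data$features$values
  y <- data$labels
  tr <- split$train
  te <- split$test

  if (diff(range(y[tr])) == 0)
    warning("constant training labels: R2 will be undefined")

  folds <- with_seed(derive_seed(seed, 1),
                     sample(rep_len(seq_len(cv_folds), length(tr))))
  cv_rmse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(cv_folds), function(f) {
      hold <- tr[folds == f]
      fit_tr <- tr[folds != f]
      if (length(hold) == 0 || length(fit_tr) < 2) return(NA_real_)
      p <- fit_predict(model_family, grid[g, , drop = FALSE],
                       x[fit_tr, , drop = FALSE], y[fit_tr],
                       x[hold, , drop = FALSE], derive_seed(seed, g, f))
      sqrt(mean((p - y[hold])^2))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- which.min(cv_rmse)

  pred <- fit_predict(model_family, grid[best, , drop = FALSE],
                      x[tr, , drop = FALSE], y[tr],
                      x[te, , drop = FALSE], derive_seed(seed, 0, 0))
  resid <- pred - y[te]
  rmse <- sqrt(mean(resid^2))
  mae <- mean(abs(resid))
  ss_tot <- sum((y[te] - mean(y[te]))^2)
  r2 <- if (diff(range(y[tr])) == 0 || ss_tot == 0) NA_real_
        else 1 - sum(resid^2) / ss_tot

  rec <- data.frame(dataset_id = data$dataset_id,
                    representation_id = data$features$representation_id,
                    sample_size = length(y),
                    split_scheme = attr(split, "scheme"),
                    model_family = model_family, seed = seed,
                    rmse = rmse, mae = mae, r2 = r2,
                    stringsAsFactors = FALSE)
  bp <- grid[best, , drop = FALSE]
  for (nm in names(bp)) rec[[paste0("hp_", nm)]] <- bp[[nm]]
  class(rec) <- c("run_record", "data.frame")
  rec
}

#' Min-max error normalization within dataset batches
#'
#' Normalizes a raw error column to `[0, 1]` within each dataset:
#' `E_rel = (E - E_min) / (E_max - E_min)` over the records sharing a
#' `dataset_id`. The minimum maps to 0 and the maximum to 1, making
#' representation performance comparable across datasets of different
#' difficulty.
#'
#' @param records data.frame of run records (rows from [train_eval()]).
#' @param metric error column to normalize, default `"rmse"`.
#' @param by grouping column(s) defining a batch, default `"dataset_id"`
#'   (use e.g. `c("dataset_id", "split_scheme")` to normalize each splitting
#'   strategy separately).
#' @return `records` with an added `<metric>_rel` column. A batch whose
#'   errors are all equal gets 0 with a warning.
#' @export
normalize_errors <- function(records, metric = "rmse", by = "dataset_id") {
  stopifnot(is.data.frame(records), metric %in% names(records),
            all(by %in% names(records)))
  out <- rep(NA_real_, nrow(records))
  batch <- do.call(paste, c(records[by], sep = "/"))
  for (g in unique(batch)) {
    idx <- which(batch == g)
    if (length(idx) < 2)
      stop("normalize_errors needs at least 2 records per batch (", g, ")")
    e <- records[[metric]][idx]
    r <- range(e)
    if (diff(r) == 0) {
      warning("all raw errors equal in batch '", g, "': E_rel set to 0")
      out[idx] <- 0
    } else {
      out[idx] <- (e - r[1]) / diff(r)
    }
  }
  records[[paste0(metric, "_rel")]] <- out
  records
}

#' Subsample a labelled dataset without replacement
#'
#' @param data a [labeled_dataset()].
#' @param size number of molecules to keep; must not exceed `n` (larger
#'   sizes are skipped with a message and `NULL` is returned).
#' @param seed integer seed.
#' @return a [labeled_dataset()] (group identifiers carried along), or
#'   `NULL` when `size > n`.
#' @export
subsample_dataset <- function(data, size, seed = 1) {
  stopifnot(inherits(data, "labeled_dataset"))
  n <- length(data$labels)
  if (size > n) {
    message("requested size ", size, " exceeds dataset size ", n, "; skipped")
    return(NULL)
  }
  idx <- sort(with_seed(seed, sample.int(n, size)))
  subset_dataset(data, idx)
}

# index-based subsetting (internal); row order follows idx
subset_dataset <- function(data, idx) {
  f <- data$features
  labeled_dataset(
    feature_matrix(f$values[idx, , drop = FALSE], f$row_ids[idx],
                   f$representation_id, f$representation_kind),
    data$labels[idx], data$dataset_id,
    if (is.null(data$group_ids)) NULL else data$group_ids[idx])
}
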