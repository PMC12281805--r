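#' Assemble the meta-dataset linking topology with model error
#'
#' Joins benchmark run records with their topological descriptor vectors to
#' form the meta-regression problem `(X_t, y_t)`: one row per run record,
#' target `y_t = rmse_rel` (the min-max normalized test RMSE from
#' [normalize_errors()]). The join key is the intersection of
#' `dataset_id`, `representation_id`, `sample_size`, `metric_name` present
#' in both tables; records without a matching descriptor row are dropped
#' with a message, never silently.
#'
#' Feature sets: `"PH"` uses only the topological descriptor and dimension
#' columns; `"C"` adds control columns (sample size, feature dimensionality
#' when available, one-hot model family / split scheme / distance metric,
#' and `hp_*` hyperparameters). Missing descriptor values (e.g. absent
#' dimension-1 signal on tiny clouds) are encoded by a sentinel one unit
#' below the observed minimum plus a per-feature `*_na` indicator column.
#'
#' @param records run-record data.frame containing `rmse_rel`.
#' @param descriptors data.frame keyed by dataset/representation/size with
#'   descriptor columns (e.g. from [compute_descriptors()] plus
#'   [dimension_estimates()]).
#' @param feature_set `"PH"` (default) or `"C"`.
#' @return list of class `meta_dataset`: numeric feature data.frame `x`,
#'   target `y`, `groups` (dataset/representation ids per row), and
#'   `feature_set`.
#' @export
assemble_meta <- function(records, descriptors, feature_set = c("PH", "C")) {
  feature_set <- match.arg(feature_set)
  stopifnot(is.data.frame(records), is.data.frame(descriptors))
  if (!"rmse_rel" %in% names(records))
    stop("records lack 'rmse_rel'; run normalize_errors() first")
  key <- intersect(c("dataset_id", "representation_id", "sample_size",
                     "metric_name"),
                   intersect(names(records), names(descriptors)))
  if (length(key) == 0) stop("no shared key columns between records and descriptors")
  rk <- do.call(paste, c(records[key], sep = "\r"))
  dk <- do.call(paste, c(descriptors[key], sep = "\r"))
  hit <- match(rk, dk)
  if (anyNA(hit)) {
    miss <- unique(rk[is.na(hit)])
    message("dropping ", sum(is.na(hit)), " record(s) without descriptors: ",
            paste(gsub("\r", "/", head(miss, 5)), collapse = "; "))
  }
  keep <- which(!is.na(hit))
  records <- records[keep, , drop = FALSE]
  desc <- descriptors[hit[keep], , drop = FALSE]

  num_cols <- names(desc)[vapply(desc, is.numeric, logical(1))]
  x <- desc[, setdiff(num_cols, c(key, "seed")), drop = FALSE]

  if (feature_set == "C") {
    x$sample_size <- records$sample_size
    onehot <- function(v, prefix) {
      lv <- sort(unique(as.character(v)))
      cols <- lapply(lv, function(l) as.numeric(v == l))
      stats::setNames(as.data.frame(cols), paste0(prefix, "_", lv))
    }
    for (ctl in c("model_family", "split_scheme")) {
      if (ctl %in% names(records))
        x <- cbind(x, onehot(records[[ctl]], ctl))
    }
    if ("metric_name" %in% names(records) && !"metric_name" %in% key)
      x <- cbind(x, onehot(records$metric_name, "metric"))
    for (hp in grep("^hp_", names(records), value = TRUE)) {
      v <- records[[hp]]
      if (is.numeric(v)) x[[hp]] <- v else x <- cbind(x, onehot(v, hp))
    }
  }

  # sentinel + indicator encoding of missing descriptor values
  for (cn in names(x)) {
    v <- x[[cn]]
    if (anyNA(v)) {
      x[[paste0(cn, "_na")]] <- as.numeric(is.na(v))
      fill <- if (all(is.na(v))) 0 else min(v, na.rm = TRUE) - 1
      v[is.na(v)] <- fill
      x[[cn]] <- v
    }
  }
  rownames(x) <- NULL

  structure(list(x = x, y = records$rmse_rel,
                 groups = data.frame(
                   dataset_id = records$dataset_id,
                   representation_id = records$representation_id,
                   stringsAsFactors = FALSE),
                 feature_set = feature_set),
            class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("<meta_dataset> %d rows x %d features (set %s)\n",
              length(x$y), ncol(x$x), x$feature_set))
  invisible(x)
}

default_meta_grid <- function() {
  expand.grid(num_trees = 300, max_depth = c(0, 12), min_node = c(1, 5))
}

fit_meta_forest <- function(x, y, params, seed) {
  ranger::ranger(
    x = x, y = y, num.trees = params$num_trees,
    max.depth = if (params$max_depth == 0) NULL else params$max_depth,
    min.node.size = params$min_node, importance = "impurity",
    seed = seed, num.threads = 1)
}

select_and_fit <- function(x, y, grid, seed, cv_folds = 5) {
  folds <- with_seed(derive_seed(seed, 7),
                     sample(rep_len(seq_len(cv_folds), length(y))))
  cv_rmse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      if (sum(tr) < 2 || sum(!tr) == 0) return(NA_real_)
      fit <- fit_meta_forest(x[tr, , drop = FALSE], y[tr],
                             grid[g, , drop = FALSE], derive_seed(seed, g, f))
      p <- predict(fit, data = x[!tr, , drop = FALSE],
                   num.threads = 1)$predictions
      sqrt(mean((p - y[!tr])^2))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- which.min(cv_rmse)
  list(fit = fit_meta_forest(x, y, grid[best, , drop = FALSE],
                             derive_seed(seed, 0)),
       best = grid[best, , drop = FALSE])
}

#' Fit the error-predicting meta-model
#'
#' Random-forest regressor over the meta-dataset, with hyperparameters
#' selected by internal 5-fold cross-validated RMSE. Because the target is
#' a normalized error in `[0, 1]`, all predictions of the fitted model are
#' clipped to that interval.
#'
#' @param meta a [assemble_meta()] result with at least `min_rows` rows and
#'   a non-constant target.
#' @param grid hyperparameter grid; default 300 trees x depth
#'   unlimited/12 x min node size 1/5.
#' @param seed integer seed.
#' @param min_rows minimum meta-dataset size, default 30.
#' @return object of class `meta_model` (use `predict()`; predictions are
#'   clipped to `[0, 1]`).
#' @export
fit_meta <- function(meta, grid = NULL, seed = 1, min_rows = 30) {
  stopifnot(inherits(meta, "meta_dataset"))
  if (length(meta$y) < min_rows)
    stop("meta-dataset has fewer than ", min_rows, " rows")
  if (length(unique(meta$y)) < 2) stop("degenerate target: all y_t identical")
  if (ncol(meta$x) == 0) stop("empty feature set")
  if (is.null(grid)) grid <- default_meta_grid()
  sel <- select_and_fit(meta$x, meta$y, grid, seed)
  structure(list(fit = sel$fit, best_hyperparams = sel$best,
                 feature_names = names(meta$x), feature_set = meta$feature_set,
                 seed = seed, version = "topogen-0.1.0"),
            class = "meta_model")
}

#' @export
predict.meta_model <- function(object, newdata, ...) {
  if (inherits(newdata, "meta_dataset")) newdata <- newdata$x
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing) > 0)
    stop("newdata lacks feature columns: ", paste(missing, collapse = ", "))
  p <- predict(object$fit,
               data = newdata[, object$feature_names, drop = FALSE],
               num.threads = 1)$predictions
  pmin(pmax(p, 0), 1)
}

#' Leave-one-group-out cross-validation of the meta-model
#'
#' Leave-one-dataset-out (LODO, `group_by = "dataset_id"`) or
#' leave-one-representation-out (LORO, `group_by = "representation_id"`)
#' cross-validation. For every group the meta-model is refit on all other
#' rows and evaluated on the held-out group; the report carries the
#' per-fold Pearson correlations, their mean and standard deviation
#' (`r_cv`), the Pearson correlation on the concatenated holdout
#' predictions (`r_a`), and impurity-based feature importances averaged
#' over the fold models (normalized to sum 1).
#'
#' @param meta a [assemble_meta()] result with at least 3 distinct groups.
#' @param group_by `"dataset_id"` or `"representation_id"`.
#' @param grid meta-model hyperparameter grid (default [fit_meta()]'s).
#' @param seed integer seed.
#' @param min_rows minimum training rows per fold, default 10.
#' @return object of class `cv_report`; `fold_indices` carries the exact
#'   train/holdout row partition of every fold for leakage audits.
#' @export
leave_one_out_cv <- function(meta, group_by = c("dataset_id",
                                                "representation_id"),
                             grid = NULL, seed = 1, min_rows = 10) {
  stopifnot(inherits(meta, "meta_dataset"))
  group_by <- match.arg(group_by)
  if (is.null(grid)) grid <- default_meta_grid()
  g <- meta$groups[[group_by]]
  lv <- sort(unique(g))
  if (length(lv) < 3) stop("need at least 3 distinct groups for CV")

  fold_r <- stats::setNames(rep(NA_real_, length(lv)), lv)
  preds <- rep(NA_real_, length(meta$y))
  imp <- NULL
  fold_indices <- vector("list", length(lv))
  names(fold_indices) <- lv
  for (k in seq_along(lv)) {
    hold <- g == lv[k]
    fold_indices[[k]] <- list(train = which(!hold), holdout = which(hold))
    if (sum(!hold) < min_rows) stop("fold '", lv[k], "' leaves too few training rows")
    sel <- select_and_fit(meta$x[!hold, , drop = FALSE], meta$y[!hold],
                          grid, derive_seed(seed, k))
    p <- pmin(pmax(predict(sel$fit, data = meta$x[hold, , drop = FALSE],
                           num.threads = 1)$predictions, 0), 1)
    preds[hold] <- p
    yk <- meta$y[hold]
    if (sum(hold) >= 3 && sd(yk) > 0 && sd(p) > 0) {
      fold_r[k] <- cor(p, yk)
    } else {
      message("fold '", lv[k], "': correlation undefined (recorded as NA)")
    }
    ik <- sel$fit$variable.importance
    imp <- if (is.null(imp)) ik else imp + ik
  }
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  ok <- !is.na(fold_r)
  r_a <- if (sd(preds) > 0 && sd(meta$y) > 0) cor(preds, meta$y) else NA_real_
  structure(list(scheme = if (group_by == "dataset_id") "LODO" else "LORO",
                 fold_r = fold_r,
                 r_cv_mean = mean(fold_r[ok]), r_cv_sd = sd(fold_r[ok]),
                 r_a = r_a, feature_importances = imp,
                 fold_indices = fold_indices,
                 predictions = data.frame(group = g, y = meta$y,
                                          pred = preds)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: r_cv = %.3f +/- %.3f over %d folds, r_a = %.3f\n",
              x$scheme, x$r_cv_mean, x$r_cv_sd, length(x$fold_r), x$r_a))
  invisible(x)
}

#' Descriptor-error correlation screen
#'
#' Pearson and Spearman correlations of every meta-feature with the
#' normalized error target, with two-tailed p-values; rows with missing
#' values are dropped pairwise and constant features are recorded as `NA`.
#'
#' @param meta a [assemble_meta()] result with at least 10 rows.
#' @return data.frame with `feature`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, ordered by `|pearson_r|` descending.
#' @export
correlation_screen <- function(meta) {
  stopifnot(inherits(meta, "meta_dataset"))
  if (length(meta$y) < 10) stop("correlation screen requires at least 10 rows")
  rows <- lapply(names(meta$x), function(cn) {
    v <- meta$x[[cn]]
    ok <- is.finite(v) & is.finite(meta$y)
    if (sum(ok) < 3 || sd(v[ok]) == 0 || sd(meta$y[ok]) == 0)
      return(data.frame(feature = cn, pearson_r = NA_real_,
                        pearson_p = NA_real_, spearman_rho = NA_real_,
                        spearman_p = NA_real_))
    pe <- cor.test(v[ok], meta$y[ok], method = "pearson")
    sp <- suppressWarnings(cor.test(v[ok], meta$y[ok], method = "spearman",
                                    exact = FALSE))
    data.frame(feature = cn, pearson_r = unname(pe$estimate),
               pearson_p = pe$p.value, spearman_rho = unname(sp$estimate),
               spearman_p = sp$p.value)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$pearson_r)), , drop = FALSE]
}
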