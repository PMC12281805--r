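#' Labelled dataset
#'
#' A feature matrix with per-molecule scalar property labels (activities)
#' and optional group identifiers (e.g. precomputed scaffold groups), the
#' unit of benchmarking and of the modelability indices.
#'
#' @param features a [feature_matrix()] or numeric matrix.
#' @param labels numeric vector of length `n`, finite.
#' @param dataset_id dataset label.
#' @param group_ids optional length-`n` vector of group identifiers.
#' @return object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, dataset_id = "dataset",
                            group_ids = NULL) {
  features <- as_feature_matrix(features)
  labels <- as.numeric(labels)
  n <- nrow(features$values)
  if (length(labels) != n)
    stop("labels length (", length(labels), ") != number of rows (", n, ")")
  if (any(!is.finite(labels))) stop("labels must be finite")
  if (!is.null(group_ids)) {
    if (length(group_ids) != n)
      stop("group_ids length does not match the number of rows")
    group_ids <- as.character(group_ids)
  }
  structure(list(features = features, labels = labels,
                 dataset_id = dataset_id, group_ids = group_ids),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> '%s': n=%d d=%d%s\n", x$dataset_id,
              nrow(x$features$values), ncol(x$features$values),
              if (is.null(x$group_ids)) "" else
                sprintf(", %d groups", length(unique(x$group_ids)))))
  invisible(x)
}

#' Default molecular similarity matrix
#'
#' Tanimoto similarity (`1 - jaccard distance`) for binary fingerprints and
#' `1 / (1 + euclidean distance)` otherwise.
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @return symmetric `n x n` similarity matrix with unit diagonal.
#' @export
default_similarity <- function(X) {
  X <- as_feature_matrix(X)
  if (X$representation_kind == "binary_fingerprint") {
    1 - pairwise_distances(X, "jaccard")$values
  } else {
    1 / (1 + pairwise_distances(X, "euclidean")$values)
  }
}

#' Structure-Activity Landscape Index (SALI)
#'
#' Pairwise index `SALI_ij = |A_i - A_j| / (1 - sim(i, j))`. Pairs with
#' similarity 1 (duplicates under the similarity, the NaN source in naive
#' implementations) are masked out and counted; summary statistics are
#' computed over the unmasked pairs only.
#'
#' @param data a [labeled_dataset()].
#' @param similarity optional symmetric similarity matrix in `[0, 1]`;
#'   defaults to [default_similarity()] of the features.
#' @return list of class `sali_scores`: `sali_matrix` (masked entries `NA`),
#'   `sali_mean`, `sali_max`, `masked_pairs`.
#' @export
sali <- function(data, similarity = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.null(similarity)) similarity <- default_similarity(data$features)
  n <- length(data$labels)
  stopifnot(nrow(similarity) == n, ncol(similarity) == n)
  if (any(similarity < -1e-9) || any(similarity > 1 + 1e-9))
    stop("similarity values must lie in [0, 1]")
  dA <- abs(outer(data$labels, data$labels, "-"))
  masked <- similarity >= 1 - 1e-12
  S <- dA / (1 - similarity)
  S[masked] <- NA_real_
  diag(S) <- NA_real_
  diag(masked) <- FALSE
  ut <- upper.tri(S)
  vals <- S[ut]
  n_masked <- sum(masked[ut])
  if (all(is.na(vals))) {
    warning("all molecule pairs are masked (similarity 1); SALI summary is NA")
    sm <- NA_real_; sx <- NA_real_
  } else {
    sm <- mean(vals, na.rm = TRUE)
    sx <- max(vals, na.rm = TRUE)
  }
  structure(list(sali_matrix = S, sali_mean = sm, sali_max = sx,
                 masked_pairs = n_masked), class = "sali_scores")
}

sari_raw_scores <- function(data, similarity, sim_threshold) {
  n <- length(data$labels)
  ut <- upper.tri(similarity)
  sim <- similarity[ut]
  dA <- abs(outer(data$labels, data$labels, "-"))[ut]
  below <- sim < sim_threshold
  cont_raw <- if (any(below) && sum(dA[below]) > 0)
    sum(dA[below] * sim[below]) / sum(dA[below]) else 0
  above <- sim >= sim_threshold
  if (!any(above)) {
    warning("no molecule pair at or above the similarity threshold; ",
            "discontinuity component set to 0")
    disc_raw <- 0
  } else {
    disc_raw <- mean(dA[above])
  }
  list(cont_raw = cont_raw, disc_raw = disc_raw)
}

#' Structure-Activity Relationship Index (SARI)
#'
#' Single-value landscape continuity score in `[0, 1]`; lower values
#' indicate a more discontinuous (cliff-rich) landscape. The raw continuity
#' score is the potency-difference-weighted mean similarity over pairs below
#' the similarity threshold; the raw discontinuity score is the mean
#' absolute activity difference over pairs at or above it. For a single
#' dataset the continuity score is used as-is (it is a weighted mean of
#' similarities, hence already in `[0, 1]`) and the discontinuity score is
#' divided by the label range; `SARI = (score_cont + (1 - score_disc)) / 2`.
#' For comparable scores across a batch of datasets use [sari_batch()],
#' which min-max normalizes the raw scores within the batch.
#'
#' @param data a [labeled_dataset()] with at least 3 molecules.
#' @param similarity optional similarity matrix (default
#'   [default_similarity()]).
#' @param sim_threshold structural-similarity threshold, default 0.65.
#' @return list of class `sari_score`: `sari`, `score_cont`, `score_disc`,
#'   and the raw components.
#' @export
sari <- function(data, similarity = NULL, sim_threshold = 0.65) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (length(data$labels) < 3) stop("sari requires at least 3 molecules")
  if (is.null(similarity)) similarity <- default_similarity(data$features)
  raw <- sari_raw_scores(data, similarity, sim_threshold)
  rng <- diff(range(data$labels))
  score_cont <- min(max(raw$cont_raw, 0), 1)
  score_disc <- if (rng > 0) min(raw$disc_raw / rng, 1) else 0
  structure(list(sari = (score_cont + (1 - score_disc)) / 2,
                 score_cont = score_cont, score_disc = score_disc,
                 cont_raw = raw$cont_raw, disc_raw = raw$disc_raw,
                 sim_threshold = sim_threshold),
            class = "sari_score")
}

#' Batch-normalized SARI
#'
#' Computes the raw SARI continuity/discontinuity scores for every dataset
#' in a batch, min-max normalizes both raw scores to `[0, 1]` within the
#' batch, and returns `SARI = (score_cont + (1 - score_disc)) / 2` per
#' dataset.
#'
#' @param datasets list of [labeled_dataset()] objects (>= 2).
#' @param similarities optional list of similarity matrices matching
#'   `datasets`.
#' @param sim_threshold structural-similarity threshold, default 0.65.
#' @return data.frame with `dataset_id`, `score_cont`, `score_disc`, `sari`.
#' @export
sari_batch <- function(datasets, similarities = NULL, sim_threshold = 0.65) {
  stopifnot(length(datasets) >= 2)
  raw <- lapply(seq_along(datasets), function(i) {
    sim <- if (is.null(similarities)) default_similarity(datasets[[i]]$features)
           else similarities[[i]]
    sari_raw_scores(datasets[[i]], sim, sim_threshold)
  })
  minmax <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  }
  cont <- minmax(vapply(raw, `[[`, numeric(1), "cont_raw"))
  disc <- minmax(vapply(raw, `[[`, numeric(1), "disc_raw"))
  data.frame(dataset_id = vapply(datasets, `[[`, character(1), "dataset_id"),
             score_cont = cont, score_disc = disc,
             sari = (cont + (1 - disc)) / 2)
}

#' Regression Modelability Index (RMODI)
#'
#' Fraction of molecules whose first nearest neighbor has a similar
#' activity. The rivality index of molecule `i` is
#' `RI_i = |y_i - y_nn(i)| / range(y) - label_tolerance`; RMODI is the
#' fraction of molecules with `RI_i < 0`. Values near 1 indicate a smooth,
#' modelable landscape.
#'
#' @param data a [labeled_dataset()] with at least 2 molecules.
#' @param distance optional `dist_matrix`; defaults to
#'   [pairwise_distances()] of the features.
#' @param label_tolerance tolerance in (0, 1) on the normalized label gap,
#'   default 0.1.
#' @return RMODI in `[0, 1]`. Constant labels give 1 with a warning.
#' @export
rmodi <- function(data, distance = NULL, label_tolerance = 0.1) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (label_tolerance <= 0 || label_tolerance >= 1)
    stop("label_tolerance must be in (0, 1)")
  y <- data$labels
  n <- length(y)
  if (n < 2) stop("rmodi requires at least 2 molecules")
  rng <- diff(range(y))
  if (rng == 0) {
    warning("constant labels: every neighbor is trivially similar, RMODI = 1")
    return(1)
  }
  if (is.null(distance)) distance <- pairwise_distances(data$features)
  D <- as_dist_matrix(distance)$values
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  ri <- abs(y - y[nn]) / rng - label_tolerance
  mean(ri < 0)
}

#' Roughness Index (ROGI) and its cluster-count variant
#'
#' Global roughness of a property landscape, measured as the loss in label
#' dispersion under progressive coarse-graining by complete-linkage
#' clustering. At each threshold `t` on an even grid of `[0, 1]` the
#' dendrogram is cut, every molecule's label is replaced by its cluster
#' mean, and the population standard deviation `sigma_t` of the
#' coarse-grained label vector is recorded;
#' `ROGI = integral of 2 (sigma_0 - sigma_t) dt` by the trapezoid rule.
#'
#' For `variant = "classic"` the distances are normalized to `[0, 1]` by
#' their maximum and `t` is the distance threshold. For `variant = "xd"`
#' the merge sequence is traversed by cluster count `k` with
#' `t = 1 - (k - 1)/(n - 1)`, which removes the dependence on the
#' representation's distance scale and dimensionality.
#'
#' @param data a [labeled_dataset()] with at least 3 molecules.
#' @param distance optional `dist_matrix` (default [pairwise_distances()]).
#' @param n_thresholds grid size for the classic variant, default 51.
#' @param variant `"classic"` or `"xd"`.
#' @return nonnegative scalar; 0 for constant labels.
#' @export
rogi <- function(data, distance = NULL, n_thresholds = 51,
                 variant = c("classic", "xd")) {
  stopifnot(inherits(data, "labeled_dataset"))
  variant <- match.arg(variant)
  y <- data$labels
  n <- length(y)
  if (n < 3) stop("rogi requires at least 3 molecules")
  if (is.null(distance)) distance <- pairwise_distances(data$features)
  D <- as_dist_matrix(distance)$values
  sigma0 <- pop_sd(y)
  if (sigma0 == 0) return(0)

  coarse_sd <- function(cl) {
    means <- tapply(y, cl, mean)
    pop_sd(as.numeric(means[as.character(cl)]))
  }

  if (variant == "classic") {
    mx <- max(D)
    if (mx > 0) D <- D / mx
    hc <- hclust(as.dist(D), method = "complete")
    ts <- seq(0, 1, length.out = n_thresholds)
    sig <- vapply(ts, function(t) coarse_sd(cutree(hc, h = t)), numeric(1))
  } else {
    hc <- hclust(as.dist(D), method = "complete")
    ks <- n:1
    ts <- 1 - (ks - 1) / (n - 1)
    sig <- vapply(ks, function(k) coarse_sd(cutree(hc, k = k)), numeric(1))
  }
  f <- 2 * (sigma0 - sig)
  sum(diff(ts) * (head(f, -1) + f[-1]) / 2)
}

#' All modelability indices of a labelled dataset
#'
#' Convenience wrapper computing SALI summaries, SARI, RMODI, and both ROGI
#' variants with default settings.
#'
#' @param data a [labeled_dataset()].
#' @return one-row data.frame with columns `sali_mean`, `sali_max`,
#'   `masked_pairs`, `sari`, `rmodi`, `rogi`, `rogi_xd`.
#' @export
modelability_scores <- function(data) {
  distance <- pairwise_distances(data$features)
  sim <- default_similarity(data$features)
  sa <- sali(data, sim)
  sr <- sari(data, sim)
  data.frame(sali_mean = sa$sali_mean, sali_max = sa$sali_max,
             masked_pairs = sa$masked_pairs, sari = sr$sari,
             rmodi = rmodi(data, distance),
             rogi = rogi(data, distance, variant = "classic"),
             rogi_xd = rogi(data, distance, variant = "xd"))
}
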