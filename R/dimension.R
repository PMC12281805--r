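#' Persistent-homology dimension
#'
#' Fractal-type intrinsic dimension estimated from the growth rate of total
#' persistence with sample size. For each subsample size `s`, `repeats`
#' seeded subsamples are drawn without replacement and the alpha-weighted
#' total persistence `E^alpha = sum (death - birth)^alpha` of the requested
#' homological dimension is computed (dimension 0 via the spanning-forest
#' fast path). The slope `m` of an ordinary least-squares fit of
#' `log E^alpha` on `log s` yields the estimate `alpha / (1 - m)`.
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @param metric_name distance metric (default per representation kind).
#' @param hom_dim homological dimension, 0 (default) or 1.
#' @param sizes integer vector of subsample sizes; default
#'   `seq(100, 2000, by = 50)` intersected with sizes not exceeding `n`.
#'   At least 4 usable sizes are required.
#' @param alpha persistence weight exponent, default 1.
#' @param seed integer seed controlling the subsample draws.
#' @param repeats subsample draws averaged per size (default 1).
#' @return list of class `ph_dimension` with `estimate` (`NA` when the
#'   geometry is degenerate or the slope is >= 1), `slope`, `alpha`,
#'   `sizes`, `E_alpha` and a `degenerate` flag.
#' @export
ph_dimension <- function(X, metric_name = NULL, hom_dim = 0, sizes = NULL,
                         alpha = 1, seed = 1, repeats = 1) {
  X <- as_feature_matrix(X)
  n <- nrow(X$values)
  if (is.null(sizes)) sizes <- seq(100L, 2000L, by = 50L)
  sizes <- sort(unique(as.integer(sizes[sizes <= n & sizes >= 2])))
  if (length(sizes) < 4)
    stop("ph_dimension needs at least 4 usable subsample sizes (n = ", n, ")")
  if (!hom_dim %in% c(0, 1)) stop("hom_dim must be 0 or 1")

  E <- vapply(seq_along(sizes), function(si) {
    s <- sizes[si]
    vals <- vapply(seq_len(repeats), function(r) {
      idx <- with_seed(derive_seed(seed, si, r),
                       sample.int(n, s, replace = FALSE))
      sub <- feature_matrix(X$values[idx, , drop = FALSE],
                            row_ids = X$row_ids[idx],
                            representation_id = X$representation_id,
                            representation_kind = X$representation_kind)
      D <- pairwise_distances(sub, metric_name)
      if (hom_dim == 0) {
        sum(mst_deaths(D)^alpha)
      } else {
        dg <- vr_persistence(D, max_hom_dim = 1)
        h1 <- dg[dg$hom_dim == 1, , drop = FALSE]
        if (nrow(h1) == 0) 0 else sum((h1$death - h1$birth)^alpha)
      }
    }, numeric(1))
    mean(vals)
  }, numeric(1))

  out <- list(estimate = NA_real_, slope = NA_real_, alpha = alpha,
              sizes = sizes, E_alpha = E, hom_dim = hom_dim,
              degenerate = FALSE)
  class(out) <- "ph_dimension"
  usable <- E > 0
  if (!any(usable)) {
    out$degenerate <- TRUE
    warning("all E^alpha are zero (degenerate geometry); estimate is NA")
    return(out)
  }
  if (sum(usable) < 4)
    stop("fewer than 4 sizes with nonzero total persistence")
  fit <- lm(log(E[usable]) ~ log(sizes[usable]))
  m <- unname(coef(fit)[2])
  out$slope <- m
  if (m >= 1) {
    out$degenerate <- TRUE
    warning("regression slope >= 1 (degenerate geometry); estimate is NA")
  } else {
    out$estimate <- alpha / (1 - m)
  }
  out
}

#' @export
print.ph_dimension <- function(x, ...) {
  cat(sprintf("<ph_dimension> hom_dim=%d alpha=%g slope=%.4f estimate=%s\n",
              x$hom_dim, x$alpha, x$slope, format(x$estimate)))
  invisible(x)
}

#' TwoNN intrinsic dimension
#'
#' Global intrinsic dimension from the ratio `mu = r2/r1` of each point's
#' two nearest-neighbor distances. The ratios are sorted ascending, the top
#' `discard_fraction` (noisiest) ratios are discarded, and the slope of a
#' least-squares line through the origin of `-log(1 - F(mu))` on `log(mu)`
#' (with `F` the empirical CDF) is returned.
#'
#' @param X a [feature_matrix()] or numeric matrix with `n >= 20` rows and
#'   no duplicated rows (duplicates give `r1 = 0` and are an error).
#' @param metric_name distance metric (default per representation kind).
#' @param discard_fraction fraction of the largest ratios discarded,
#'   default 0.1.
#' @return the dimension estimate (scalar).
#' @export
twonn_dimension <- function(X, metric_name = NULL, discard_fraction = 0.1) {
  X <- as_feature_matrix(X)
  n <- nrow(X$values)
  if (n < 20) stop("twonn_dimension requires at least 20 points")
  D <- pairwise_distances(X, metric_name)$values
  diag(D) <- Inf
  r1 <- apply(D, 1, min)
  if (any(r1 == 0)) {
    bad <- X$row_ids[r1 == 0]
    stop("duplicate points (r1 = 0) for: ",
         paste(head(bad, 10), collapse = ", "))
  }
  r2 <- apply(D, 1, function(row) sort(row, partial = 2)[2])
  mu <- sort(r2 / r1)
  Fmu <- seq_len(n) / n
  keep <- seq_len(n - floor(discard_fraction * n))
  x <- log(mu[keep])
  y <- -log(1 - Fmu[keep])
  sum(x * y) / sum(x * x)
}

#' Local-PCA intrinsic dimension
#'
#' Fukunaga-style local estimate: for every point, the covariance
#' eigenvalues of its `k` nearest neighbors (Euclidean) are computed and
#' the eigenvalues exceeding `eigen_threshold` times the largest one are
#' counted; the estimate is the mean count over all points.
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @param k_neighbors neighborhood size, default 100, capped at `n - 1`.
#' @param eigen_threshold relative eigenvalue cutoff in (0, 1), default 0.05.
#' @return mean local dimension (scalar; `NA` with a warning for a constant
#'   feature matrix).
#' @export
lpca_dimension <- function(X, k_neighbors = 100, eigen_threshold = 0.05) {
  X <- as_feature_matrix(X)
  v <- X$values
  n <- nrow(v)
  if (eigen_threshold <= 0 || eigen_threshold >= 1)
    stop("eigen_threshold must be in (0, 1)")
  k <- min(as.integer(k_neighbors), n - 1L)
  if (k < 2) stop("k_neighbors must allow at least 2 neighbors")
  D <- as.matrix(dist(v))
  counts <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[2:(k + 1)]
    M <- scale(v[nb, , drop = FALSE], center = TRUE, scale = FALSE)
    ev <- svd(M, nu = 0, nv = 0)$d^2 / (k - 1)
    if (ev[1] <= 0) return(NA_real_)
    sum(ev > eigen_threshold * ev[1])
  }, numeric(1))
  if (all(is.na(counts))) {
    warning("constant feature matrix: local covariance is zero everywhere")
    return(NA_real_)
  }
  mean(counts, na.rm = TRUE)
}

#' All dimension estimates of a feature matrix
#'
#' Convenience wrapper bundling [ph_dimension()] (dimensions 0 and,
#' optionally, 1), [twonn_dimension()] and [lpca_dimension()].
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @param metric_name distance metric.
#' @param sizes subsample sizes for the persistence-dimension fit.
#' @param include_ph1 also estimate the dimension-1 persistence dimension
#'   (slower); default `FALSE`.
#' @param seed integer seed.
#' @param ... passed through to [lpca_dimension()].
#' @return one-row data.frame with columns `dim_ph_0`, `dim_ph_1`,
#'   `dim_twonn`, `dim_pca`.
#' @export
dimension_estimates <- function(X, metric_name = NULL, sizes = NULL,
                                include_ph1 = FALSE, seed = 1, ...) {
  ph0 <- tryCatch(suppressWarnings(
    ph_dimension(X, metric_name, hom_dim = 0, sizes = sizes, seed = seed)),
    error = function(e) NULL)
  ph1 <- if (include_ph1) tryCatch(suppressWarnings(
    ph_dimension(X, metric_name, hom_dim = 1, sizes = sizes, seed = seed)),
    error = function(e) NULL) else NULL
  tw <- tryCatch(twonn_dimension(X, metric_name), error = function(e) NA_real_)
  lp <- suppressWarnings(lpca_dimension(X, ...))
  data.frame(dim_ph_0 = if (is.null(ph0)) NA_real_ else ph0$estimate,
             dim_ph_1 = if (is.null(ph1)) NA_real_ else ph1$estimate,
             dim_twonn = tw, dim_pca = lp)
}
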