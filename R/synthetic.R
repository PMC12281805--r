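#' Synthetic point clouds of known topology and dimension
#'
#' Seeded generators emulating the feature spaces the descriptor pipeline
#' consumes: manifolds of known topology/intrinsic dimension with isotropic
#' Gaussian noise, and fingerprint-like i.i.d. Bernoulli bit matrices.
#'
#' Shapes: `circle` (unit circle in 2-D), `sphere` (unit sphere in 3-D),
#' `hypercube` (uniform on `[0, 1]^d`), `gaussian_blobs` (`k` isotropic
#' Gaussians with seeded centers in `d` dimensions), `line` (segment
#' embedded in `d` dimensions), `fingerprint` (Bernoulli bits).
#'
#' @param shape one of `"circle"`, `"sphere"`, `"hypercube"`,
#'   `"gaussian_blobs"`, `"line"`, `"fingerprint"`.
#' @param n number of points (>= 10).
#' @param d ambient dimension for `hypercube`/`gaussian_blobs`/`line`, or
#'   number of bits for `fingerprint` (default 2; 128 for fingerprints).
#' @param k number of blobs, default 3.
#' @param noise_sd isotropic Gaussian noise level, default 0.
#' @param bit_density Bernoulli rate for fingerprint mode, default 0.3.
#' @param seed integer seed; generation is fully determined by the
#'   arguments plus the seed.
#' @return a [feature_matrix()].
#' @export
make_point_cloud <- function(shape = c("hypercube", "circle", "sphere",
                                       "gaussian_blobs", "line",
                                       "fingerprint"),
                             n, d = NULL, k = 3, noise_sd = 0,
                             bit_density = 0.3, seed = 1) {
  shape <- match.arg(shape)
  if (n < 10) stop("n must be at least 10")
  if (is.null(d)) d <- if (shape == "fingerprint") 128L else 2L
  v <- with_seed(seed, switch(shape,
    circle = {
      theta <- runif(n, 0, 2 * pi)
      cbind(cos(theta), sin(theta)) + matrix(rnorm(2 * n, 0, noise_sd), n)
    },
    sphere = {
      g <- matrix(rnorm(3 * n), n)
      g / sqrt(rowSums(g^2)) + matrix(rnorm(3 * n, 0, noise_sd), n)
    },
    hypercube = matrix(runif(n * d), n) + matrix(rnorm(n * d, 0, noise_sd), n),
    gaussian_blobs = {
      centers <- matrix(runif(k * d, 0, 10), k)
      assign <- sample.int(k, n, replace = TRUE)
      centers[assign, , drop = FALSE] + matrix(rnorm(n * d, 0, 1), n) +
        matrix(rnorm(n * d, 0, noise_sd), n)
    },
    line = {
      t <- runif(n)
      dir <- rep(1, d) / sqrt(d)
      outer(t, dir) + matrix(rnorm(n * d, 0, noise_sd), n)
    },
    fingerprint = matrix(rbinom(n * d, 1, bit_density), n)))
  feature_matrix(v, representation_id = shape,
                 representation_kind = if (shape == "fingerprint")
                   "binary_fingerprint" else "embedding")
}

#' Property landscape with planted activity cliffs
#'
#' Builds a labelled dataset over a point cloud. Base labels are a smooth
#' radial sinusoid `cos(pi * r / r_max)` of the distance `r` to the cloud
#' centroid (Lipschitz constant `pi / r_max` in the feature metric). A
#' seeded fraction `cliff_fraction` of points then has its label offset by
#' three times the base label range, creating nearest-neighbor
#' discontinuities (activity cliffs); i.i.d. Gaussian label noise is added
#' last. Group identifiers for scaffold-style splits are assigned by seeded
#' k-means clustering of the coordinates.
#'
#' @param cloud a [feature_matrix()].
#' @param cliff_fraction fraction of planted cliff points in `[0, 1]`.
#' @param label_noise_sd label noise standard deviation, default 0.
#' @param seed integer seed.
#' @param n_groups number of spatial groups (default `max(5, n / 40)`).
#' @param dataset_id dataset label.
#' @param cliff_mode `"scattered"` (default) plants cliffs at independently
#'   sampled points, making them irreducible noise for any regressor;
#'   `"clustered"` plants them on the points nearest a seeded center, a
#'   spatially coherent cliff region (as scaffold-driven activity cliffs
#'   are) that a faithful representation can learn.
#' @return a [labeled_dataset()] with group identifiers.
#' @export
make_landscape <- function(cloud, cliff_fraction = 0, label_noise_sd = 0,
                           seed = 1, n_groups = NULL,
                           dataset_id = NULL,
                           cliff_mode = c("scattered", "clustered")) {
  cliff_mode <- match.arg(cliff_mode)
  cloud <- as_feature_matrix(cloud)
  if (cliff_fraction < 0 || cliff_fraction > 1)
    stop("cliff_fraction must be in [0, 1]")
  v <- cloud$values
  n <- nrow(v)
  ctr <- colMeans(v)
  r <- sqrt(rowSums(sweep(v, 2, ctr)^2))
  rmax <- max(r)
  base <- if (rmax > 0) cos(pi * r / rmax) else rep(0, n)

  y <- base
  n_cliff <- round(cliff_fraction * n)
  cliff_idx <- integer(0)
  if (n_cliff > 0) {
    cliff_idx <- if (cliff_mode == "scattered") {
      with_seed(derive_seed(seed, 11), sample.int(n, n_cliff))
    } else {
      center <- with_seed(derive_seed(seed, 11), sample.int(n, 1))
      d2c <- sqrt(rowSums(sweep(v, 2, v[center, ])^2))
      order(d2c)[seq_len(n_cliff)]
    }
    offset <- 3 * max(diff(range(base)), 1)
    y[cliff_idx] <- y[cliff_idx] + offset
  }
  if (label_noise_sd > 0)
    y <- y + with_seed(derive_seed(seed, 13), rnorm(n, 0, label_noise_sd))

  if (is.null(n_groups)) n_groups <- max(5L, round(n / 40))
  n_groups <- min(n_groups, n)
  km <- with_seed(derive_seed(seed, 17),
                  kmeans(v, centers = n_groups, nstart = 1, iter.max = 25))
  ds_id <- if (is.null(dataset_id))
    sprintf("%s_cliff%02d", cloud$representation_id,
            round(100 * cliff_fraction)) else dataset_id
  out <- labeled_dataset(cloud, y, ds_id,
                         group_ids = paste0("g", km$cluster))
  attr(out, "cliff_idx") <- sort(cliff_idx)
  attr(out, "cliff_fraction") <- cliff_fraction
  out
}

#' Full descriptor vector of one representation
#'
#' Persistence-diagram descriptors ([compute_descriptors()]) joined with
#' dimension estimates ([twonn_dimension()], [lpca_dimension()],
#' dimension-0 [ph_dimension()]) and the feature dimensionality.
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @param metric_name distance metric (default per representation kind).
#' @param ph_sizes subsample sizes for the persistence dimension; default
#'   five sizes between 40% and 100% of `n`.
#' @param lpca_k local-PCA neighborhood size, default `min(50, n - 1)`.
#' @param seed integer seed.
#' @return one-row data.frame of descriptors.
#' @export
representation_descriptors <- function(X, metric_name = NULL,
                                       ph_sizes = NULL, lpca_k = 50,
                                       seed = 1) {
  X <- as_feature_matrix(X)
  n <- nrow(X$values)
  D <- pairwise_distances(X, metric_name)
  diag_ <- vr_persistence(D, max_hom_dim = 1)
  desc <- compute_descriptors(diag_)
  if (is.null(ph_sizes))
    ph_sizes <- unique(round(seq(max(20, 0.4 * n), n, length.out = 5)))
  ph0 <- tryCatch(suppressWarnings(
    ph_dimension(X, D$metric_name, hom_dim = 0, sizes = ph_sizes,
                 seed = seed)),
    error = function(e) NULL)
  tw <- tryCatch(twonn_dimension(X, D$metric_name),
                 error = function(e) NA_real_)
  lp <- suppressWarnings(lpca_dimension(X, k_neighbors = min(lpca_k, n - 1)))
  cbind(desc,
        data.frame(dim_ph_0 = if (is.null(ph0)) NA_real_ else ph0$estimate,
                   dim_twonn = tw, dim_pca = lp,
                   n_features = ncol(X$values),
                   metric_name = D$metric_name))
}

#' Planted end-to-end meta-benchmark
#'
#' Generates a grid of synthetic (dataset x representation) landscapes and
#' runs the real descriptor and benchmarking pipelines at reduced scale,
#' producing the inputs of the meta-model stage with a verifiable planted
#' structure:
#'
#' * datasets differ in geometry and planted cliff fraction (roughness);
#' * representations re-encode the same molecules with increasing
#'   distortion (coordinate noise plus pure-noise dimensions), so that
#'   within every dataset the realized test error rises with representation
#'   distortion while the topological descriptors shift with it —
#'   the association the meta-model is meant to learn.
#'
#' All randomness is derived from `seed`; a fixed seed reproduces the
#' records and descriptors exactly.
#'
#' @param n_datasets number of datasets (>= 4).
#' @param n_representations representations per dataset (>= 4).
#' @param seed integer seed.
#' @param sizes molecule counts evaluated per dataset, default
#'   `c(150, 300)`.
#' @param splits split schemes, default `c("random", "group")`.
#' @param model_families model families trained, default `"forest"`.
#' @param base_n molecules generated per dataset, default `max(sizes)`.
#' @param cliff_fractions planted cliff fractions per dataset; default an
#'   even grid from 0 to 0.45.
#' @return list of class `meta_benchmark` with `records` (normalized run
#'   records) and `descriptors` (one row per dataset/representation/size).
#' @export
make_meta_benchmark <- function(n_datasets = 8, n_representations = 6,
                                seed = 1, sizes = c(150, 300),
                                splits = c("random", "group"),
                                model_families = "forest",
                                base_n = NULL, cliff_fractions = NULL) {
  if (n_datasets < 4 || n_representations < 4)
    stop("need at least 4 datasets and 4 representations")
  if (is.null(base_n)) base_n <- max(sizes)
  if (is.null(cliff_fractions))
    cliff_fractions <- seq(0, 0.24, length.out = n_datasets)
  shapes <- rep(list(list(shape = "hypercube", d = 2),
                     list(shape = "hypercube", d = 3),
                     list(shape = "gaussian_blobs", d = 3),
                     list(shape = "hypercube", d = 4)),
                length.out = n_datasets)
  # convex distortion ladder: gentle early steps so errors grade smoothly
  # instead of saturating at the first distorted level
  rep_noise <- 0.7 * seq(0, 1, length.out = n_representations)^1.3
  rep_extra_dims <- 3L * (seq_len(n_representations) - 1L)

  records <- list()
  descriptors <- list()
  for (i in seq_len(n_datasets)) {
    sh <- shapes[[i]]
    cloud <- make_point_cloud(sh$shape, n = base_n, d = sh$d,
                              seed = derive_seed(seed, 100, i))
    land <- make_landscape(cloud, cliff_fraction = cliff_fractions[i],
                           label_noise_sd = 0.05,
                           seed = derive_seed(seed, 200, i),
                           dataset_id = sprintf("D%02d", i),
                           cliff_mode = "clustered")
    scale_ref <- mean(apply(cloud$values, 2, sd))
    for (j in seq_len(n_representations)) {
      nj <- base_n
      noise <- with_seed(derive_seed(seed, 300, i, j),
                         matrix(rnorm(nj * sh$d, 0, rep_noise[j] * scale_ref),
                                nj))
      extra <- if (rep_extra_dims[j] > 0)
        with_seed(derive_seed(seed, 400, i, j),
                  matrix(runif(nj * rep_extra_dims[j], 0, scale_ref), nj))
        else NULL
      repv <- cbind(cloud$values + noise, extra)
      repX <- feature_matrix(repv, row_ids = cloud$row_ids,
                             representation_id = sprintf("R%02d", j),
                             representation_kind = "embedding")
      rep_data <- labeled_dataset(repX, land$labels, land$dataset_id,
                                  group_ids = land$group_ids)
      # one fixed holdout per (dataset, scheme): evaluating every
      # representation and training size against the same molecules keeps
      # the planted quality ladder visible above test-set sampling noise
      full_splits <- lapply(seq_along(splits), function(sc)
        make_split(rep_data, splits[sc], test_fraction = 0.2,
                   seed = derive_seed(seed, 700, i, sc)))
      for (s in sizes) {
        sub <- subsample_dataset(rep_data, s, seed = derive_seed(seed, 500, i,
                                                                 s))
        if (is.null(sub)) next
        desc <- representation_descriptors(sub$features, "euclidean",
                                           seed = derive_seed(seed, 600, i, j,
                                                              s))
        desc$dataset_id <- sub$dataset_id
        desc$representation_id <- repX$representation_id
        desc$sample_size <- s
        descriptors[[length(descriptors) + 1L]] <- desc
        for (sc in seq_along(splits)) {
          test_idx <- full_splits[[sc]]$test
          n_train <- s - length(test_idx)
          if (n_train < 10) next
          train_idx <- sort(with_seed(
            derive_seed(seed, 750, i, s, sc),
            sample(full_splits[[sc]]$train, n_train)))
          eval_data <- subset_dataset(rep_data, c(train_idx, test_idx))
          split <- structure(list(train = seq_len(n_train),
                                  test = n_train + seq_along(test_idx)),
                             class = "data_split", scheme = splits[sc],
                             seed = seed)
          for (fam in model_families) {
            rec <- train_eval(eval_data, split, fam,
                              seed = derive_seed(seed, 800, i, j, s, sc))
            records[[length(records) + 1L]] <- rec
          }
        }
      }
    }
  }
  records <- do.call(rbind, records)
  # each splitting strategy is its own benchmark table, so errors are
  # normalized per dataset within each split scheme
  records <- normalize_errors(records, "rmse", by = c("dataset_id",
                                                      "split_scheme"))
  records <- normalize_errors(records, "mae", by = c("dataset_id",
                                                     "split_scheme"))
  descriptors <- do.call(rbind, descriptors)
  structure(list(records = records, descriptors = descriptors,
                 seed = seed,
                 spec = list(n_datasets = n_datasets,
                             n_representations = n_representations,
                             sizes = sizes, splits = splits,
                             model_families = model_families,
                             cliff_fractions = cliff_fractions,
                             base_n = base_n)),
            class = "meta_benchmark")
}

#' @export
print.meta_benchmark <- function(x, ...) {
  cat(sprintf("<meta_benchmark> %d run records, %d descriptor rows (seed %d)\n",
              nrow(x$records), nrow(x$descriptors), x$seed))
  invisible(x)
}
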