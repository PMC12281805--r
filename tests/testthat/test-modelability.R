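toy_dataset <- function(y, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(seq_len(n), ncol = 1)
  labeled_dataset(X, y)
}

test_that("sali follows the pairwise formula and masks duplicate pairs", {
  sim <- matrix(c(1, 0.5, 0.5, 1), 2)
  sc <- sali(toy_dataset(c(5, 3)), sim)
  expect_equal(sc$sali_matrix[1, 2], 4)
  expect_equal(sc$masked_pairs, 0)

  ident <- sali(toy_dataset(c(2, 2, 2)),
                matrix(c(1, .4, .6, .4, 1, .5, .6, .5, 1), 3))
  expect_equal(ident$sali_mean, 0)
  expect_equal(ident$sali_max, 0)

  simdup <- matrix(c(1, 1, 0.3, 1, 1, 0.2, 0.3, 0.2, 1), 3)
  dup <- sali(toy_dataset(c(1, 2, 3)), simdup)
  expect_equal(dup$masked_pairs, 1)
  expect_true(is.na(dup$sali_matrix[1, 2]))

  expect_warning(allm <- sali(toy_dataset(c(1, 2)), matrix(1, 2, 2)),
                 "masked")
  expect_true(is.na(allm$sali_mean))
  expect_equal(allm$masked_pairs, 1)
})

test_that("sari matches a brute-force hand computation on a 3-molecule toy", {
  sim <- matrix(c(1, 0.9, 0.2,
                  0.9, 1, 0.4,
                  0.2, 0.4, 1), 3, byrow = TRUE)
  y <- c(1, 5, 2)
  sc <- sari(toy_dataset(y), sim, sim_threshold = 0.65)
  # pairs: (1,2) sim .9 |dA| 4; (1,3) sim .2 |dA| 1; (2,3) sim .4 |dA| 3
  cont <- (1 * 0.2 + 3 * 0.4) / (1 + 3)
  disc <- 4 / diff(range(y))
  expect_equal(sc$score_cont, cont, tolerance = 1e-12)
  expect_equal(sc$score_disc, disc, tolerance = 1e-12)
  expect_equal(sc$sari, (cont + (1 - disc)) / 2, tolerance = 1e-12)
})

test_that("sari stays in [0, 1] and warns without similar pairs", {
  for (s in 1:5) {
    set.seed(s)
    ds <- labeled_dataset(matrix(runif(60), 30), rnorm(30, sd = 3))
    sc <- sari(ds)
    expect_gte(sc$sari, 0)
    expect_lte(sc$sari, 1)
  }
  far <- labeled_dataset(matrix(c(0, 50, 100), 3), c(0, 1, 2))
  expect_warning(sc <- sari(far), "threshold")
  expect_equal(sc$score_disc, 0)
})

test_that("sari ranks smooth landscapes above cliff-rich ones", {
  for (s in 1:5) {
    cloud <- make_point_cloud("hypercube", n = 200, d = 2, seed = s)
    smooth <- make_landscape(cloud, cliff_fraction = 0, seed = s)
    rough <- make_landscape(cloud, cliff_fraction = 0.4, seed = s)
    expect_gt(sari(smooth)$sari, sari(rough)$sari)
  }
})

test_that("sari_batch min-max normalizes raw scores within the batch", {
  clouds <- lapply(1:3, function(s)
    make_point_cloud("hypercube", n = 100, d = 2, seed = s))
  sets <- lapply(seq_along(clouds), function(i)
    make_landscape(clouds[[i]], cliff_fraction = (i - 1) * 0.25, seed = i))
  out <- sari_batch(sets)
  expect_equal(nrow(out), 3)
  expect_equal(min(out$score_disc), 0)
  expect_equal(max(out$score_disc), 1)
  expect_true(all(out$sari >= 0 & out$sari <= 1))
})

test_that("rmodi counts rivality below tolerance", {
  # labels follow position closely: every NN gap is far below tol * range
  y_smooth <- seq(0, 1, length.out = 50)
  expect_equal(rmodi(toy_dataset(y_smooth)), 1)
  # alternating extreme labels: every NN gap exceeds tol * range
  y_cliff <- rep(c(0, 100), 25)
  expect_equal(rmodi(toy_dataset(y_cliff)), 0)
  expect_warning(r <- rmodi(toy_dataset(rep(2, 10))), "constant")
  expect_equal(r, 1)
})

test_that("rmodi on half-planted cliffs is near one half", {
  cloud <- make_point_cloud("hypercube", n = 500, d = 2, seed = 21)
  land <- make_landscape(cloud, cliff_fraction = 0.5, seed = 21)
  r <- rmodi(land)
  expect_equal(r, 0.5, tolerance = 0.05)
  # independent brute-force recount of the rivality rule
  D <- as.matrix(dist(cloud$values))
  diag(D) <- Inf
  gap <- abs(land$labels - land$labels[apply(D, 1, which.min)])
  expect_equal(r, mean(gap / diff(range(land$labels)) < 0.1))
})

test_that("rogi is zero for constant labels and exact on two tight clusters", {
  expect_equal(rogi(toy_dataset(rep(3, 10))), 0)
  a <- 0.005
  x <- matrix(c(0, a, 2 * a, 1, 1 + a, 1 + 2 * a), ncol = 1)
  ds <- labeled_dataset(x, c(0, 0, 0, 1, 1, 1))
  # labels are constant within each tight cluster, so sigma_t stays sigma_0
  # until the final merge at normalized height 1; with a 51-point grid the
  # trapezoid rule contributes only the last interval: 2 * sigma_0 * 0.02 / 2
  expect_equal(rogi(ds, n_thresholds = 51), 0.5 * 0.02, tolerance = 1e-10)
})

test_that("label noise monotonically increases rogi", {
  for (s in 1:5) {
    cloud <- make_point_cloud("hypercube", n = 150, d = 2, seed = s)
    vals <- vapply(c(0, 0.3, 0.6), function(ns)
      rogi(make_landscape(cloud, 0, label_noise_sd = ns, seed = s)),
      numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("rogi-xd responds to roughness without distance normalization", {
  cloud <- make_point_cloud("hypercube", n = 120, d = 2, seed = 8)
  smooth <- make_landscape(cloud, 0, seed = 8)
  rough <- make_landscape(cloud, 0.4, seed = 8)
  expect_gt(rogi(rough, variant = "xd"), rogi(smooth, variant = "xd"))
  # xd is invariant to scaling the feature space; classic rescales anyway
  big <- labeled_dataset(100 * cloud$values, smooth$labels)
  expect_equal(rogi(smooth, variant = "xd"), rogi(big, variant = "xd"),
               tolerance = 1e-10)
})

test_that("all indices are invariant to molecule reordering", {
  cloud <- make_point_cloud("hypercube", n = 80, d = 2, seed = 13)
  land <- make_landscape(cloud, 0.3, seed = 13)
  perm <- with(list(), {set.seed(1); sample(80)})
  landp <- labeled_dataset(cloud$values[perm, ], land$labels[perm])
  land0 <- labeled_dataset(cloud$values, land$labels)
  expect_equal(rmodi(land0), rmodi(landp))
  expect_equal(rogi(land0), rogi(landp), tolerance = 1e-9)
  expect_equal(sari(land0)$sari, sari(landp)$sari, tolerance = 1e-9)
  expect_equal(sali(land0)$sali_mean, sali(landp)$sali_mean,
               tolerance = 1e-9)
})

test_that("indices rank planted roughness consistently", {
  fracs <- seq(0, 0.475, length.out = 20)
  scores <- t(vapply(seq_along(fracs), function(i) {
    cloud <- make_point_cloud("hypercube", n = 150, d = 2, seed = 777)
    land <- make_landscape(cloud, fracs[i], seed = 900 + i)
    c(rogi = rogi(land), rmodi = rmodi(land), sari = sari(land)$sari)
  }, numeric(3)))
  expect_gt(cor(fracs, scores[, "rogi"], method = "spearman"), 0.8)
  expect_lt(cor(fracs, scores[, "rmodi"], method = "spearman"), -0.8)
  expect_lt(cor(fracs, scores[, "sari"], method = "spearman"), -0.8)
})
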