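linear_dataset <- function(n, seed, noise_sd = 0, pure_noise = FALSE) {
  set.seed(seed)
  X <- matrix(runif(n * 2), n)
  y <- if (pure_noise) rnorm(n) else
    2 * X[, 1] - 3 * X[, 2] + rnorm(n, sd = noise_sd)
  labeled_dataset(X, y, "lin",
                  group_ids = paste0("g", rep(1:10, length.out = n)))
}

test_that("random splits are deterministic, disjoint and covering", {
  ds <- linear_dataset(100, 1)
  s1 <- make_split(ds, "random", seed = 5)
  s2 <- make_split(ds, "random", seed = 5)
  expect_identical(s1$test, s2$test)
  expect_length(s1$test, 20)
  expect_setequal(c(s1$train, s1$test), 1:100)
  expect_length(intersect(s1$train, s1$test), 0)
})

test_that("group splits never leak and respect group counting", {
  ds <- linear_dataset(100, 2)  # 10 groups of 10
  sp <- make_split(ds, "group", test_fraction = 0.2, seed = 3)
  expect_length(intersect(unique(ds$group_ids[sp$train]),
                          unique(ds$group_ids[sp$test])), 0)
  expect_length(unique(ds$group_ids[sp$test]), 2)

  nog <- labeled_dataset(ds$features, ds$labels)
  expect_error(make_split(nog, "group"), "group_ids")
  huge <- labeled_dataset(ds$features, ds$labels,
                          group_ids = c(rep("big", 90), rep("small", 10)))
  expect_error(make_split(huge, "group", test_fraction = 0.2), "infeasible")
})

test_that("both model families learn a noiseless linear response", {
  ds <- linear_dataset(300, 7)
  sp <- make_split(ds, "random", seed = 7)
  forest <- train_eval(ds, sp, "forest",
                       grid = data.frame(num_trees = 500, max_depth = 0),
                       seed = 7)
  expect_gt(forest$r2, 0.95)
  neural <- train_eval(ds, sp, "neural",
                       grid = data.frame(size = 16, decay = 1e-4), seed = 7)
  expect_gt(neural$r2, 0.95)
  # a grid of one forces the returned hyperparameters
  expect_equal(forest$hp_num_trees, 500)
  expect_equal(neural$hp_size, 16)
})

test_that("pure-noise labels give near-zero test R2", {
  for (s in 1:5) {
    ds <- linear_dataset(200, 100 + s, pure_noise = TRUE)
    sp <- make_split(ds, "random", seed = s)
    rec <- train_eval(ds, sp, "forest",
                      grid = data.frame(num_trees = 100, max_depth = 0),
                      seed = s)
    expect_lte(rec$r2, 0.1)
  }
})

test_that("hyperparameter selection picks the better grid point", {
  ds <- linear_dataset(250, 9, noise_sd = 0.05)
  sp <- make_split(ds, "random", seed = 9)
  rec <- train_eval(ds, sp, "forest",
                    grid = data.frame(num_trees = c(5, 300),
                                      max_depth = c(1, 0)), seed = 9)
  expect_equal(rec$hp_num_trees, 300)
})

test_that("constant training labels warn and record missing R2", {
  ds <- labeled_dataset(matrix(runif(80), 40), rep(1, 40), "const")
  sp <- make_split(ds, "random", seed = 1)
  expect_warning(rec <- train_eval(ds, sp, "forest",
                                   grid = data.frame(num_trees = 50,
                                                     max_depth = 0)),
                 "constant")
  expect_true(is.na(rec$r2))
})

test_that("error normalization maps min to 0, max to 1 and is affine-invariant", {
  rec <- data.frame(dataset_id = "d", rmse = c(2, 4, 6))
  out <- normalize_errors(rec)
  expect_equal(out$rmse_rel, c(0, 0.5, 1))
  aff <- normalize_errors(transform(rec, rmse = 10 * rmse + 3))
  expect_equal(aff$rmse_rel, out$rmse_rel)
  tied <- data.frame(dataset_id = "d", rmse = c(1, 1, 1))
  expect_warning(tout <- normalize_errors(tied), "equal")
  expect_equal(tout$rmse_rel, c(0, 0, 0))
  # attains both 0 and 1 per batch with >= 2 distinct values
  two <- normalize_errors(data.frame(dataset_id = rep(c("a", "b"), each = 3),
                                     rmse = c(1, 5, 9, 0.1, 0.2, 0.2)))
  for (g in c("a", "b")) {
    e <- two$rmse_rel[two$dataset_id == g]
    expect_equal(range(e), c(0, 1))
  }
})

test_that("subsampling is seeded, order-preserving and carries groups", {
  ds <- linear_dataset(1000, 3)
  full <- subsample_dataset(ds, 1000, seed = 1)
  expect_equal(full$labels, ds$labels)
  s1 <- subsample_dataset(ds, 500, seed = 1)
  s2 <- subsample_dataset(ds, 500, seed = 1)
  expect_identical(s1$features$row_ids, s2$features$row_ids)
  expect_length(s1$group_ids, 500)
  s3 <- subsample_dataset(ds, 500, seed = 2)
  overlap <- length(intersect(s1$features$row_ids, s3$features$row_ids))
  expect_gt(overlap, 200)  # hypergeometric: 250 +/- 50
  expect_lt(overlap, 300)
  expect_message(expect_null(subsample_dataset(ds, 2000)), "skipped")
})

test_that("more training data does not worsen median test error", {
  # same generator and identical held-out molecules at every training size
  med <- vapply(c(100, 400), function(n) {
    median(vapply(1:3, function(s) {
      ds <- linear_dataset(600, 50 + s, noise_sd = 0.3)
      sp <- structure(list(train = seq_len(n), test = 401:600),
                      class = "data_split", scheme = "random", seed = s)
      train_eval(ds, sp, "forest",
                 grid = data.frame(num_trees = 100, max_depth = 0),
                 seed = s)$rmse
    }, numeric(1)))
  }, numeric(1))
  expect_lte(med[2], med[1])
})
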