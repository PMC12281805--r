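toy_records <- function(n_ds = 5, n_rep = 4) {
  grid <- expand.grid(dataset_id = paste0("d", seq_len(n_ds)),
                      representation_id = paste0("r", seq_len(n_rep)),
                      stringsAsFactors = FALSE)
  grid$sample_size <- 100L
  grid$model_family <- "forest"
  grid$split_scheme <- "random"
  grid$hp_num_trees <- 100
  grid$rmse <- NA_real_
  grid
}

toy_meta <- function(seed = 1, n_ds = 5, n_rep = 8, noise_sd = 0,
                     y_fun = function(f) 0.1 + 0.8 * f) {
  set.seed(seed)
  rec <- toy_records(n_ds, n_rep)
  desc <- unique(rec[c("dataset_id", "representation_id", "sample_size")])
  desc$h0_lifetime_avg <- runif(nrow(desc))
  desc$h0_betti <- sample(50:200, nrow(desc), replace = TRUE)
  rec$rmse <- y_fun(desc$h0_lifetime_avg[match(
    paste(rec$dataset_id, rec$representation_id),
    paste(desc$dataset_id, desc$representation_id))]) +
    rnorm(nrow(rec), sd = noise_sd)
  rec <- normalize_errors(rec)
  list(records = rec, descriptors = desc)
}

test_that("assemble_meta joins on keys and respects the feature-set contract", {
  tm <- toy_meta()
  meta <- assemble_meta(tm$records, tm$descriptors, "PH")
  expect_equal(length(meta$y), nrow(tm$records))
  expect_false(any(c("sample_size", "model_family_forest", "hp_num_trees")
                   %in% names(meta$x)))
  metaC <- assemble_meta(tm$records, tm$descriptors, "C")
  expect_true(all(c("sample_size", "model_family_forest",
                    "split_scheme_random", "hp_num_trees") %in%
                    names(metaC$x)))
  expect_true(all(meta$y >= 0 & meta$y <= 1))
})

test_that("records without descriptors are dropped loudly", {
  tm <- toy_meta()
  desc <- tm$descriptors[-1, ]
  expect_message(meta <- assemble_meta(tm$records, desc), "dropping")
  expect_equal(length(meta$y),
               nrow(tm$records) - sum(tm$records$dataset_id == "d1" &
                                        tm$records$representation_id == "r1"))
})

test_that("missing descriptor values become sentinel plus indicator", {
  tm <- toy_meta()
  tm$descriptors$h1_entropy <- c(NA, runif(nrow(tm$descriptors) - 1))
  meta <- assemble_meta(tm$records, tm$descriptors)
  expect_true("h1_entropy_na" %in% names(meta$x))
  expect_false(anyNA(meta$x$h1_entropy))
  filled <- meta$x$h1_entropy[meta$x$h1_entropy_na == 1]
  expect_true(all(filled < min(meta$x$h1_entropy[meta$x$h1_entropy_na == 0])))
})

test_that("fit_meta learns a planted monotone signal and clips predictions", {
  tm <- toy_meta(seed = 2)
  meta <- assemble_meta(tm$records, tm$descriptors)
  fit <- fit_meta(meta, seed = 2)
  p <- predict(fit, meta)
  expect_gt(cor(p, meta$y), 0.95)
  extreme <- meta$x
  extreme$h0_lifetime_avg <- extreme$h0_lifetime_avg + 100
  pe <- predict(fit, extreme)
  expect_true(all(pe >= 0 & pe <= 1))
})

test_that("fit_meta rejects degenerate inputs", {
  tm <- toy_meta()
  meta <- assemble_meta(tm$records, tm$descriptors)
  constant <- meta
  constant$y <- rep(0.5, length(meta$y))
  expect_error(fit_meta(constant), "degenerate")
  tiny <- meta
  tiny$y <- meta$y[1:10]
  tiny$x <- meta$x[1:10, ]
  expect_error(fit_meta(tiny), "fewer than")
  empty <- meta
  empty$x <- meta$x[, 0, drop = FALSE]
  expect_error(fit_meta(empty), "empty feature set")
})

test_that("leave-one-out CV partitions by group with no leakage", {
  tm <- toy_meta(seed = 3, noise_sd = 0.02)
  meta <- assemble_meta(tm$records, tm$descriptors)
  cv <- leave_one_out_cv(meta, "dataset_id", seed = 3)
  expect_equal(cv$scheme, "LODO")
  expect_length(cv$fold_r, 5)
  all_hold <- integer(0)
  for (k in seq_along(cv$fold_indices)) {
    fi <- cv$fold_indices[[k]]
    expect_length(intersect(fi$train, fi$holdout), 0)
    g <- names(cv$fold_indices)[k]
    expect_true(all(meta$groups$dataset_id[fi$holdout] == g))
    expect_false(any(meta$groups$dataset_id[fi$train] == g))
    all_hold <- c(all_hold, fi$holdout)
  }
  expect_setequal(all_hold, seq_along(meta$y))
  expect_gt(cv$r_cv_mean, 0.5)
  expect_true(all(cv$feature_importances >= 0))
  expect_equal(sum(cv$feature_importances), 1)

  loro <- leave_one_out_cv(meta, "representation_id", seed = 3)
  expect_equal(loro$scheme, "LORO")
  expect_length(loro$fold_r, 8)
})

test_that("correlation screen recovers self, sign-flipped and null features", {
  tm <- toy_meta(seed = 4)
  meta <- assemble_meta(tm$records, tm$descriptors)
  meta$x$self <- meta$y
  meta$x$flip <- -meta$y
  scr <- correlation_screen(meta)
  expect_equal(scr$pearson_r[scr$feature == "self"], 1, tolerance = 1e-12)
  expect_equal(scr$spearman_rho[scr$feature == "self"], 1, tolerance = 1e-12)
  expect_equal(scr$pearson_r[scr$feature == "flip"], -1, tolerance = 1e-12)
  meta$x$constant <- 1
  expect_true(is.na(
    correlation_screen(meta)$pearson_r[
      correlation_screen(meta)$feature == "constant"]))
})

test_that("independent noise features show no spurious correlation", {
  tm <- toy_meta(seed = 6, n_ds = 20, n_rep = 10)  # 200 meta rows
  meta <- assemble_meta(tm$records, tm$descriptors)
  hits <- vapply(1:20, function(s) {
    meta$x$noise <- with_seed_test(s, rnorm(length(meta$y)))
    scr <- correlation_screen(meta)
    abs(scr$pearson_r[scr$feature == "noise"]) < 0.2
  }, logical(1))
  expect_gte(sum(hits), 18)
})
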