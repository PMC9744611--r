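test_that("the stratified split honours the 3:2 ratio and the seed", {
  meta <- make_meta(sprintf("s%03d", 1:100),
                    group = rep(c("case", "control"), each = 50))
  sp <- split_train_holdout(meta, seed = 7)
  expect_identical(sum(sp == "train"), 60L)
  expect_identical(sum(sp == "holdout"), 40L)
  grp <- meta$group[match(names(sp), meta$sample_id)]
  expect_lte(abs(sum(sp == "train" & grp == "case") - 30L), 1L)
  expect_identical(split_train_holdout(meta, seed = 7), sp)
  expect_false(identical(split_train_holdout(meta, seed = 8), sp))

  # uneven groups still get a stratified assignment covering every sample
  meta2 <- make_meta(sprintf("s%03d", 1:37),
                     group = rep(c("case", "control"), c(21, 16)))
  sp2 <- split_train_holdout(meta2, seed = 1)
  expect_setequal(names(sp2), meta2$sample_id)

  expect_error(split_train_holdout(make_meta("s1", group = "case")),
               ">= 2 samples")
})

test_that("standardisation uses training statistics only", {
  x <- make_matrix(5, 10, seed = 6)
  train <- colnames(x)[1:6]
  hold <- colnames(x)[7:10]
  std <- fit_standardizer(x, train)
  z <- apply_standardizer(std, x)
  expect_lt(max(abs(rowMeans(z[, train]))), 1e-10)
  expect_equal(apply(z[, train], 1, sd), rep(1, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # holdout transform equals the hand formula with frozen parameters
  expect_equal(z[, hold],
               (x[, hold] - rowMeans(x[, train])) /
                 apply(x[, train], 1, sd), tolerance = 1e-12)
  # constant gene maps to zero with sd 1
  xc <- x; xc[2, ] <- 3
  expect_warning(stdc <- fit_standardizer(xc, train), "zero training variance")
  expect_identical(stdc$sd[[2]], 1)
  expect_equal(unname(apply_standardizer(stdc, xc)[2, ]), rep(0, 10))
})

test_that("the network has the described shape and parameter count", {
  cfg <- ae_config()
  expect_identical(ae_layer_sizes(266, cfg),
                   c(266L, 128L, 64L, 10L, 1L, 10L, 64L, 128L, 266L))
  s <- ae_layer_sizes(266, cfg)
  expect_identical(ae_param_count(266, cfg),
                   sum(s[-9] * s[-1] + s[-1]))
  # closed form checked against the engine's own tally
  set.seed(1)
  layers <- crosscoder:::nn_init(ae_layer_sizes(40, fast_ae()))
  expect_identical(crosscoder:::nn_param_count(layers),
                   as.numeric(ae_param_count(40, fast_ae())))

  expect_error(ae_config(widths = c(64, 64, 10)), "strictly decreasing")
  expect_error(ae_config(widths = c(64, 32, 1)), "> 1")
  expect_error(ae_config(dropout = 1), "dropout")
})

test_that("training is seeded-deterministic and improves reconstruction", {
  pair <- small_synthetic(seed = 41, n_genes = 266, n_shared_deg = 50,
                          n_private_deg = 0, n_cases = 30, n_controls = 30,
                          n_batches = 1)
  cfg <- fast_ae(seed = 5, max_epochs = 40)
  f1 <- autoencoder(pair$expr_a, pair$meta_a, config = cfg)
  f2 <- autoencoder(pair$expr_a, pair$meta_a, config = cfg)
  expect_identical(f1$layers, f2$layers)
  expect_identical(f1$history, f2$history)

  h <- f1$history
  expect_identical(h$epoch[1], 0L)   # untrained baseline
  expect_lt(h$holdout_mse[nrow(h)], h$holdout_mse[1])
  # restored weights come from the epoch whose holdout MSE is within
  # min_delta of the global minimum, never from a later epoch
  expect_lte(h$holdout_mse[h$epoch == f1$best_epoch],
             min(h$holdout_mse) + cfg$min_delta)
  expect_lte(f1$best_epoch, max(h$epoch))
  expect_error(autoencoder(pair$expr_a, pair$meta_a,
                           config = fast_ae(max_epochs = 0)), "max_epochs")
})

test_that("encoder scores are 1-D, deterministic, and oriented", {
  pair <- small_synthetic(seed = 42, n_batches = 1)
  fit <- autoencoder(pair$expr_a, pair$meta_a, config = fast_ae(seed = 2))
  sc1 <- predict(fit, pair$expr_a)
  sc2 <- predict(fit, pair$expr_a)
  expect_identical(sc1, sc2)                     # inference has no dropout
  expect_identical(length(sc1), ncol(pair$expr_a))
  expect_true(is.numeric(sc1) && all(is.finite(sc1)))

  # orientation contract: training cases score at least training controls
  train <- names(fit$split)[fit$split == "train"]
  grp <- pair$meta_a$group[match(train, pair$meta_a$sample_id)]
  expect_gte(mean(sc1[train][grp == "case"]),
             mean(sc1[train][grp == "control"]))
  # negating the orientation negates every score
  flipped <- fit
  flipped$orientation <- -flipped$orientation
  expect_equal(predict(flipped, pair$expr_a), -sc1, tolerance = 1e-15)

  # missing genes are reported by name
  expect_error(predict(fit, pair$expr_a[-1, ]), rownames(pair$expr_a)[1])

  rec <- predict(fit, pair$expr_a[, 1:5], type = "reconstruction")
  expect_identical(dim(rec), c(nrow(pair$expr_a), 5L))
  expect_identical(length(residuals(fit, pair$expr_a[, 1:5])), 5L)
})

test_that("the bottleneck recovers a planted rank-1 latent factor", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- synthetic_config(n_genes = 100, n_shared_deg = 60,
                            frac_concordant = 1, n_private_deg = 0,
                            effect_sd = 1, latent_sd = 0.8, noise_sd = 0.3,
                            n_batches = 1, batch_shift_sd = 0,
                            n_cases = 50, n_controls = 50, seed = 600 + s)
    pair <- simulate_cohort_pair(cfg)
    fit <- autoencoder(pair$expr_a, pair$meta_a,
                       config = fast_ae(seed = 600 + s))
    hold <- names(fit$split)[fit$split == "holdout"]
    sc <- predict(fit, pair$expr_a[, hold])
    z <- pair$truth$latent$A[hold]
    if (abs(cor(rank(sc), rank(z))) >= 0.8) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("training improves holdout MSE across seeds", {
  wins <- 0L
  for (s in 1:10) {
    pair <- small_synthetic(seed = 700 + s, n_genes = 266, n_shared_deg = 50,
                            n_private_deg = 0, n_cases = 25, n_controls = 25,
                            n_batches = 1)
    fit <- autoencoder(pair$expr_a, pair$meta_a,
                       config = fast_ae(seed = s, max_epochs = 40))
    h <- fit$history
    if (h$holdout_mse[nrow(h)] < h$holdout_mse[1]) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("grid search returns the exhaustive minimum deterministically", {
  pair <- small_synthetic(seed = 55, n_genes = 60, n_shared_deg = 20,
                          n_private_deg = 0, n_cases = 15, n_controls = 15,
                          n_batches = 1)
  grid <- ae_hyper_grid(learning_rate = c(5e-4, 2e-3), depth = 8,
                        w1 = 16, w2 = 8, w3 = 4, dropout = c(0.1, 0.3))
  gs <- grid_search(pair$expr_a, pair$meta_a, grid,
                    config_base = fast_ae(max_epochs = 20, seed = 9))
  expect_identical(nrow(gs$records), 4L)
  expect_equal(min(gs$records$holdout_mse, na.rm = TRUE),
               gs$records$holdout_mse[gs$best_index])
  expect_identical(gs$config$learning_rate,
                   gs$records$learning_rate[gs$best_index])

  # singleton grid -> that configuration
  g1 <- ae_hyper_grid(learning_rate = 1e-3, depth = 8, w1 = 16, w2 = 8,
                      w3 = 4, dropout = 0.2)
  gs1 <- grid_search(pair$expr_a, pair$meta_a, g1,
                     config_base = fast_ae(max_epochs = 5, seed = 9))
  expect_identical(gs1$config$widths, c(16L, 8L, 4L))
  expect_identical(gs1$config$learning_rate, 1e-3)

  # the full default grid enumerates 4*3*3*3*3*3 combinations
  full <- ae_hyper_grid()
  expect_identical(as.integer(prod(lengths(full))), 972L)
})
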