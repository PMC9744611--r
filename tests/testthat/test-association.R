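test_that("Spearman correlation matches hand formulas", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$p, 0)
  expect_equal(spearman_cor(1:5, -(1:5))$rho, -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d^2 = 4 -> rho 0.8
  sp <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(sp$rho, 0.8)
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(sp$p, 2 * pt(-tstat, df = 3), tolerance = 1e-12)

  expect_error(spearman_cor(1:3, 1:3), "n >= 4")
  expect_error(spearman_cor(1:5, rep(2, 5)), "constant")
})

test_that("Spearman agrees with the standard test and is rank-invariant", {
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(15)
    y <- 0.5 * x + rnorm(15)
    sp <- spearman_cor(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(sp$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(sp$p, ref$p.value, tolerance = 1e-10)
    # invariance under strictly monotone transforms
    expect_equal(spearman_cor(exp(x), y)$rho, sp$rho)
    expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, sp$rho)
  }
  # exact permutation p on a tiny sample is close to the t approximation
  sp_t <- spearman_cor(1:6, c(2, 1, 4, 3, 6, 5))
  sp_p <- spearman_cor(1:6, c(2, 1, 4, 3, 6, 5), method = "permutation")
  expect_equal(sp_p$rho, sp_t$rho)
  expect_gt(sp_p$p, 0)
  expect_lt(abs(sp_p$p - sp_t$p), 0.1)
})

test_that("direction calls follow the rho/p/alpha rule", {
  expect_identical(infer_direction(0.825, 1e-4)$direction, "positive")
  expect_identical(infer_direction(-0.9, 1e-5)$direction, "inverse")
  expect_identical(infer_direction(0.1, 0.4)$direction, "indeterminate")
  expect_identical(infer_direction(0.9, 0.2, alpha = 0.3)$direction,
                   "positive")
  expect_error(infer_direction(1.5, 0.01), "rho")
})

test_that("cross-projection pairs holdout cases under both encoders", {
  pair <- small_synthetic(seed = 60, n_batches = 1)
  split <- split_train_holdout(pair$meta_a, seed = 3)
  cfg <- fast_ae(seed = 3, max_epochs = 30)
  enc <- autoencoder(pair$expr_a, pair$meta_a, split = split, config = cfg)

  sc <- cross_project(enc, enc, pair$expr_a, pair$meta_a, split)
  # self-comparison: identical score vectors, rho exactly 1
  expect_equal(sc$score_a, sc$score_b)
  expect_equal(spearman_cor(sc$score_a, sc$score_b)$rho, 1)
  # paired length equals holdout case count
  hold <- names(split)[split == "holdout"]
  n_hold_cases <- sum(pair$meta_a$group[match(hold, pair$meta_a$sample_id)]
                      == "case")
  expect_identical(nrow(sc), n_hold_cases)
  # with controls included, all holdout samples are scored
  sc_all <- cross_project(enc, enc, pair$expr_a, pair$meta_a, split,
                          cases_only = FALSE)
  expect_identical(nrow(sc_all), length(hold))
})

test_that("flipping one encoder's orientation negates the correlation", {
  pair <- small_synthetic(seed = 61, n_batches = 1)
  split <- split_train_holdout(pair$meta_a, seed = 4)
  enc1 <- autoencoder(pair$expr_a, pair$meta_a, split = split,
                      config = fast_ae(seed = 4, max_epochs = 30))
  enc2 <- autoencoder(pair$expr_a, pair$meta_a, split = split,
                      config = fast_ae(seed = 99, max_epochs = 30))
  sc <- cross_project(enc1, enc2, pair$expr_a, pair$meta_a, split)
  rho <- spearman_cor(sc$score_a, sc$score_b)$rho

  enc2f <- enc2
  enc2f$orientation <- -enc2f$orientation
  scf <- cross_project(enc1, enc2f, pair$expr_a, pair$meta_a, split)
  expect_equal(spearman_cor(scf$score_a, scf$score_b)$rho, -rho,
               tolerance = 1e-12)
  # swapping the encoder roles leaves |rho| unchanged
  sc_swap <- cross_project(enc2, enc1, pair$expr_a, pair$meta_a, split)
  expect_equal(spearman_cor(sc_swap$score_a, sc_swap$score_b)$rho, rho,
               tolerance = 1e-12)
})

test_that("the full estimator recovers a planted positive association", {
  pair <- small_synthetic(seed = 62, frac_concordant = 1)
  fit <- crosscoder(pair$expr_a, pair$meta_a, pair$expr_b, pair$meta_b,
                    ae = fast_ae(), seed = 63)
  expect_s3_class(fit, "crosscoder")
  expect_identical(fit$direction, "positive")
  expect_gt(fit$assoc_a$rho, 0)
  expect_gt(fit$assoc_b$rho, 0)
  expect_identical(sum(fit$overlap$counts), fit$overlap$n_shared)
  expect_identical(fit$features_a, fit$overlap$table$gene)
  # methods
  expect_named(coef(fit), c("rho_A", "rho_B"))
  expect_output(print(fit), "Overall direction: positive")
  expect_output(print(summary(fit)), "Spearman rho")
  pred <- predict(fit, pair$expr_a[, 1:6])
  expect_identical(nrow(pred), 6L)
})
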