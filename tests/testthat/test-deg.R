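test_that("two-group fits match hand computations", {
  # 2v2 fixture: case {2,4}, control {1,1}
  x <- matrix(c(2, 4, 1, 1), 1, 4,
              dimnames = list("g1", sprintf("s%d", 1:4)))
  meta <- make_meta(colnames(x), group = c("case", "case", "control", "control"))
  f <- fit_two_group(x, meta)
  expect_equal(f$logFC, 2)
  expect_equal(f$s2, 1)       # ((4-3)^2+(2-3)^2 + 0) / 2
  expect_equal(f$df, 2)

  # identical values in both groups -> logFC 0, s2 0
  x0 <- matrix(5, 2, 4, dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4)))
  f0 <- fit_two_group(x0, meta)
  expect_equal(f0$logFC, c(0, 0))
  expect_equal(f0$s2, c(0, 0))

  # permutation invariance
  xp <- make_matrix(5, 8, seed = 3)
  metap <- make_meta(colnames(xp), group = rep(c("case", "control"), 4))
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  f1 <- fit_two_group(xp, metap)
  f2 <- fit_two_group(xp[, perm], metap)
  expect_equal(f1, f2, ignore_attr = TRUE)

  expect_error(fit_two_group(xp[, 1:3],
                             metap[1:3, ]), ">= 2 samples")
})

test_that("trigamma inversion round-trips on the half-df scale", {
  for (d in c(0.5, 2, 5, 10, 40, 200)) {
    y <- trigamma(d / 2)
    expect_equal(trigamma_inverse(y), d, tolerance = 1e-8)
    expect_equal(trigamma(trigamma_inverse(y) / 2), y, tolerance = 1e-8)
  }
  expect_error(trigamma_inverse(-1), "positive")
})

test_that("equal sample variances give an infinite prior", {
  fits <- data.frame(gene = sprintf("g%d", 1:10), logFC = 0,
                     s2 = rep(0.7, 10), df = 6)
  pr <- estimate_variance_prior(fits)
  expect_identical(pr$d0, Inf)
  expect_gt(pr$s02, 0)
})

test_that("the variance prior is recovered from simulated truth", {
  set.seed(101)
  d0 <- 4; s02 <- 0.05; dg <- 10; ng <- 2000
  sigma2 <- s02 * d0 / rchisq(ng, d0)          # scaled inverse-chi-square
  s2 <- sigma2 * rchisq(ng, dg) / dg           # sampling given sigma2
  fits <- data.frame(gene = sprintf("g%04d", 1:ng), logFC = 0, s2 = s2, df = dg)
  pr <- estimate_variance_prior(fits)
  expect_gte(pr$d0, 2.5)
  expect_lte(pr$d0, 6)
  expect_equal(pr$s02, s02, tolerance = 0.3)
})

test_that("moderated t matches a formula-by-hand oracle", {
  x <- matrix(c(1, 2, 3, 4, 2, 3, 4, 5,
                5, 5, 6, 6, 4, 4, 5, 5,
                1, 1, 2, 2, 8, 8, 9, 9), 3, 8, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:8)))
  meta <- make_meta(colnames(x), group = rep(c("case", "control"), each = 4))
  fits <- fit_two_group(x, meta)
  prior <- list(d0 = 3, s02 = 0.8)
  tab <- moderated_t_table(fits, prior)
  for (i in 1:3) {
    ca <- x[i, 1:4]; co <- x[i, 5:8]
    lfc <- mean(ca) - mean(co)
    s2 <- (sum((ca - mean(ca))^2) + sum((co - mean(co))^2)) / 6
    s2p <- (3 * 0.8 + 6 * s2) / (3 + 6)
    tt <- lfc / sqrt(s2p * (1 / 4 + 1 / 4))
    expect_equal(tab$t[i], tt, tolerance = 1e-8)
    expect_equal(tab$p[i], 2 * pt(-abs(tt), df = 9), tolerance = 1e-8)
  }
})

test_that("prior limits recover the classical t and the d0 = Inf shrinkage", {
  x <- make_matrix(6, 8, seed = 12)
  meta <- make_meta(colnames(x), group = rep(c("case", "control"), each = 4))
  fits <- fit_two_group(x, meta)

  tab0 <- moderated_t_table(fits, list(d0 = 0, s02 = 1))
  classical <- apply(x, 1, function(r)
    t.test(r[1:4], r[5:8], var.equal = TRUE)$statistic)
  expect_equal(tab0$t, unname(classical), tolerance = 1e-10)

  tabInf <- moderated_t_table(fits, list(d0 = Inf, s02 = 0.5))
  expect_equal(tabInf$t, fits$logFC / sqrt(0.5 * 0.5), tolerance = 1e-12)

  # finite d0: t lies strictly between the classical and the d0 = Inf value
  tab3 <- moderated_t_table(fits, list(d0 = 3, s02 = 0.5))
  for (i in seq_len(nrow(fits))) {
    lo <- min(tab0$t[i], tabInf$t[i]); hi <- max(tab0$t[i], tabInf$t[i])
    expect_gt(tab3$t[i], lo); expect_lt(tab3$t[i], hi)
  }

  # equal group means -> t 0, p 1
  xe <- matrix(c(1, 2, 1, 2, 2, 1, 2, 1), 1, 8,
               dimnames = list("g1", colnames(x)))
  fe <- fit_two_group(xe, meta)
  te <- moderated_t_table(fe, list(d0 = 4, s02 = 0.3))
  expect_equal(te$t, 0)
  expect_equal(te$p, 1)
})

test_that("the whole moderated pipeline agrees with an independent EB fit", {
  skip_if_not_installed("limma")
  x <- make_matrix(200, 11, seed = 31)
  x[1:20, 1:6] <- x[1:20, 1:6] + 1.5
  grp <- rep(c("case", "control"), c(6, 5))
  meta <- make_meta(colnames(x), group = grp)
  fits <- fit_two_group(x, meta)
  pr <- estimate_variance_prior(fits)
  tab <- moderated_t_table(fits, pr)
  design <- model.matrix(~ factor(grp, levels = c("control", "case")))
  ref <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(pr$d0, unname(ref$df.prior), tolerance = 1e-8)
  expect_equal(pr$s02, unname(ref$s2.prior), tolerance = 1e-8)
  expect_equal(tab$t, unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(tab$p, unname(ref$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone along ascending p and bounded
  set.seed(8)
  p <- runif(50)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("DEG calls apply the FDR/logFC thresholds as specified", {
  tab <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    logFC = c(0.6, 0.3, 1.0, -0.5, 0.5),
                    fdr = c(0.04, 0.04, 0.06, 0.01, 0.05))
  out <- call_degs(tab)
  expect_identical(out$direction, c("up", "none", "none", "down", "none"))
})

test_that("overlap classification matches an enumeration oracle", {
  dA <- data.frame(gene = c("g1", "g2", "g3"),
                   direction = c("up", "down", "up"))
  dB <- data.frame(gene = c("g2", "g3", "g4"),
                   direction = c("down", "down", "up"))
  ov <- classify_overlap(dA, dB)
  expect_identical(unname(ov$counts), c(0L, 1L, 1L))
  expect_identical(ov$table$class[ov$table$gene == "g2"], "co-down")
  expect_identical(ov$table$class[ov$table$gene == "g3"], "inverse")
  expect_identical(ov$n_shared, 2L)
  expect_equal(ov$concordant_fraction, 0.5)

  # disjoint DEG sets
  ov0 <- classify_overlap(
    data.frame(gene = "g1", direction = "up"),
    data.frame(gene = "g2", direction = "up"))
  expect_identical(unname(ov0$counts), c(0L, 0L, 0L))
  expect_identical(ov0$n_shared, 0L)

  # counts always sum to the shared total on random tables
  set.seed(4)
  for (i in 1:5) {
    g <- sprintf("g%02d", 1:40)
    dA <- data.frame(gene = g, direction = sample(c("up", "down", "none"),
                                                  40, TRUE))
    dB <- data.frame(gene = g, direction = sample(c("up", "down", "none"),
                                                  40, TRUE))
    ov <- classify_overlap(dA, dB)
    expect_identical(sum(ov$counts), ov$n_shared)
  }
})

test_that("null data yields calls consistent with FDR control", {
  # effect-free cohorts: the shared-DEG caller should almost never fire
  n_with_deg <- 0L
  for (s in 1:20) {
    cfg <- synthetic_config(n_genes = 2000, n_shared_deg = 0,
                            n_private_deg = 0, effect_sd = 0,
                            case_latent_mean = 0, batch_shift_sd = 0,
                            n_batches = 1, n_cases = 30, n_controls = 30,
                            seed = 500 + s)
    pair <- simulate_cohort_pair(cfg)
    deg <- deg_table(pair$expr_a, pair$meta_a)
    if (any(deg$direction != "none")) n_with_deg <- n_with_deg + 1L
  }
  expect_lte(n_with_deg, 2L)   # <= ~10% of 20 null seeds
})
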