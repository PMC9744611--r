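#' Configuration for a synthetic two-cohort simulation
#'
#' Describes paired case/control cohorts measured on a common gene universe,
#' with a planted latent "disease severity" factor per cohort.  A subset of
#' genes load on the latent factor in both cohorts (shared dysregulated
#' genes); `frac_concordant` of them carry the same loading sign in both
#' cohorts and the rest carry opposite signs, which fixes the true sign of
#' the cross-disease association.  Additional genes load in only one cohort,
#' per-study batch shifts are additive on the log2 scale, and residual noise
#' is Gaussian.
#'
#' The generative model for gene g in sample i of cohort c is
#' \deqn{x_{gi} = \mu_g + \lambda^c_g z_i + \gamma_{g,b(i)} + \epsilon_{gi}}
#' with baseline \eqn{\mu_g \sim N(7, 1)} shared by both cohorts (a common
#' platform), latent severity \eqn{z_i \sim N(m \cdot 1[\mathrm{case}],
#' \mathrm{latent\_sd}^2)}, and \eqn{\epsilon \sim N(0,
#' \mathrm{noise\_sd}^2)}.  Loadings of dysregulated genes have magnitude
#' `effect_sd` with planted signs; all other loadings are zero.
#'
#' @param n_genes number of genes in the common universe.
#' @param n_shared_deg number of genes dysregulated in both cohorts.
#' @param frac_concordant fraction of shared dysregulated genes whose loading
#'   has the same sign in both cohorts (in `[0, 1]`).
#' @param n_private_deg number of genes dysregulated in each cohort alone.
#' @param effect_sd latent loading magnitude, log2 units.
#' @param case_latent_mean mean latent severity of cases (controls are 0).
#' @param latent_sd within-group spread of the latent severity.
#' @param n_batches number of batches (studies) per cohort; samples are
#'   assigned round-robin.
#' @param batch_shift_sd standard deviation of additive per-(gene, batch)
#'   shifts, log2 units.
#' @param batch_scale_sd standard deviation of per-batch log variance
#'   inflation; 0 (default) disables the multiplicative batch component.
#' @param noise_sd residual standard deviation, log2 units.
#' @param n_cases,n_controls per-cohort sample sizes.
#' @param seed integer RNG seed; the simulation is bit-reproducible given
#'   the full configuration.
#' @return an object of class `synthetic_config`.
#' @seealso [simulate_cohort_pair()]
#' @export
synthetic_config <- function(n_genes = 2000, n_shared_deg = 200,
                             frac_concordant = 0.5, n_private_deg = 100,
                             effect_sd = 1.0, case_latent_mean = 1.0,
                             latent_sd = 0.5, n_batches = 3,
                             batch_shift_sd = 0.5, batch_scale_sd = 0,
                             noise_sd = 0.5, n_cases = 60, n_controls = 60,
                             seed = 1) {
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes"),
    n_shared_deg = assert_count(n_shared_deg, "n_shared_deg", min = 0L),
    frac_concordant = assert_number(frac_concordant, "frac_concordant", 0, 1),
    n_private_deg = assert_count(n_private_deg, "n_private_deg", min = 0L),
    effect_sd = assert_number(effect_sd, "effect_sd", min = 0),
    case_latent_mean = assert_number(case_latent_mean, "case_latent_mean"),
    latent_sd = assert_number(latent_sd, "latent_sd", min = 0),
    n_batches = assert_count(n_batches, "n_batches"),
    batch_shift_sd = assert_number(batch_shift_sd, "batch_shift_sd", min = 0),
    batch_scale_sd = assert_number(batch_scale_sd, "batch_scale_sd", min = 0),
    noise_sd = assert_number(noise_sd, "noise_sd", min = 0),
    n_cases = assert_count(n_cases, "n_cases"),
    n_controls = assert_count(n_controls, "n_controls"),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$n_shared_deg + 2L * cfg$n_private_deg > cfg$n_genes) {
    stop_("n_shared_deg + 2 * n_private_deg exceeds n_genes")
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic cohort-pair configuration\n")
  cat(sprintf("  genes: %d (%d shared + 2 x %d private dysregulated)\n",
              x$n_genes, x$n_shared_deg, x$n_private_deg))
  cat(sprintf("  concordant fraction: %.2f; loading magnitude: %.2f log2\n",
              x$frac_concordant, x$effect_sd))
  cat(sprintf("  per cohort: %d cases / %d controls in %d batches\n",
              x$n_cases, x$n_controls, x$n_batches))
  cat(sprintf("  latent: mean %.2f sd %.2f; batch shift sd %.2f; noise sd %.2f\n",
              x$case_latent_mean, x$latent_sd, x$batch_shift_sd, x$noise_sd))
  invisible(x)
}

simulate_one_cohort <- function(cfg, cohort, mu, loadings) {
  n <- cfg$n_cases + cfg$n_controls
  sample_id <- sprintf("%s_s%03d", cohort, seq_len(n))
  group <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  batch_idx <- rep_len(seq_len(cfg$n_batches), n)
  batch <- sprintf("%s_b%d", cohort, batch_idx)

  z <- stats::rnorm(n, mean = ifelse(group == "case", cfg$case_latent_mean, 0),
                    sd = cfg$latent_sd)
  gamma <- matrix(stats::rnorm(cfg$n_genes * cfg$n_batches, 0, cfg$batch_shift_sd),
                  cfg$n_genes, cfg$n_batches,
                  dimnames = list(names(mu), sprintf("%s_b%d", cohort,
                                                     seq_len(cfg$n_batches))))
  scale_fac <- exp(stats::rnorm(cfg$n_batches, 0, cfg$batch_scale_sd))
  eps <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd), cfg$n_genes, n)
  eps <- sweep(eps, 2L, scale_fac[batch_idx], "*")

  x <- mu + outer(loadings, z) + gamma[, batch_idx, drop = FALSE] + eps
  dimnames(x) <- list(names(mu), sample_id)
  meta <- data.frame(sample_id = sample_id, cohort = cohort, group = group,
                     batch = batch, stringsAsFactors = FALSE)
  list(expr = x, meta = meta, latent = stats::setNames(z, sample_id),
       batch_offsets = gamma, batch_scale = stats::setNames(scale_fac,
                                                            colnames(gamma)))
}

#' Simulate a pair of case/control cohorts with a known association sign
#'
#' Draws two cohorts from the generative model described in
#' [synthetic_config()].  The returned truth object records each cohort's
#' per-gene latent loadings, the planted per-gene regulation directions, the
#' per-(gene, batch) shifts, each sample's latent severity, and
#' `true_sign = sign(sum_g lambda^A_g lambda^B_g)` — the ground-truth
#' association direction the downstream pipeline should recover.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `cohort_pair`: a list with elements `expr_a`,
#'   `meta_a`, `expr_b`, `meta_b` (log2 gene-by-sample matrices plus
#'   metadata) and `truth`.
#' @examples
#' pair <- simulate_cohort_pair(synthetic_config(n_genes = 100,
#'   n_shared_deg = 20, n_private_deg = 5, n_cases = 10, n_controls = 10))
#' dim(pair$expr_a)
#' pair$truth$true_sign
#' @export
simulate_cohort_pair <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_("'config' must be created by synthetic_config()")
  }
  cfg <- config
  with_seed(cfg$seed, {
    genes <- sprintf("g%05d", seq_len(cfg$n_genes))
    mu <- stats::setNames(stats::rnorm(cfg$n_genes, 7, 1), genes)

    idx <- sample.int(cfg$n_genes, cfg$n_shared_deg + 2L * cfg$n_private_deg)
    shared <- idx[seq_len(cfg$n_shared_deg)]
    priv_a <- idx[cfg$n_shared_deg + seq_len(cfg$n_private_deg)]
    priv_b <- idx[cfg$n_shared_deg + cfg$n_private_deg + seq_len(cfg$n_private_deg)]

    lam_a <- lam_b <- stats::setNames(numeric(cfg$n_genes), genes)
    if (cfg$n_shared_deg > 0L) {
      sign_a <- sample(c(-1, 1), cfg$n_shared_deg, replace = TRUE)
      n_conc <- round(cfg$frac_concordant * cfg$n_shared_deg)
      conc <- c(rep(TRUE, n_conc), rep(FALSE, cfg$n_shared_deg - n_conc))
      sign_b <- ifelse(conc, sign_a, -sign_a)
      lam_a[shared] <- sign_a * cfg$effect_sd
      lam_b[shared] <- sign_b * cfg$effect_sd
    }
    if (cfg$n_private_deg > 0L) {
      lam_a[priv_a] <- sample(c(-1, 1), cfg$n_private_deg, TRUE) * cfg$effect_sd
      lam_b[priv_b] <- sample(c(-1, 1), cfg$n_private_deg, TRUE) * cfg$effect_sd
    }

    a <- simulate_one_cohort(cfg, "A", mu, lam_a)
    b <- simulate_one_cohort(cfg, "B", mu, lam_b)

    dir_of <- function(l) ifelse(l > 0, "up", ifelse(l < 0, "down", "none"))
    truth <- list(
      loadings_A = lam_a, loadings_B = lam_b,
      planted_direction_A = stats::setNames(dir_of(lam_a), genes),
      planted_direction_B = stats::setNames(dir_of(lam_b), genes),
      shared_genes = genes[sort(shared)],
      batch_offsets = list(A = a$batch_offsets, B = b$batch_offsets),
      latent = list(A = a$latent, B = b$latent),
      true_sign = sign(sum(lam_a * lam_b))
    )
    structure(list(expr_a = a$expr, meta_a = a$meta,
                   expr_b = b$expr, meta_b = b$meta,
                   truth = truth, config = cfg),
              class = "cohort_pair")
  })
}

#' @export
print.cohort_pair <- function(x, ...) {
  cat(sprintf("Synthetic cohort pair: %d genes; A %d samples, B %d samples\n",
              nrow(x$expr_a), ncol(x$expr_a), ncol(x$expr_b)))
  cat(sprintf("  planted association sign: %+d\n", x$truth$true_sign))
  invisible(x)
}

#' Write a simulated cohort pair to disk
#'
#' Expression matrices go to gene-by-sample TSV, metadata to four-column TSV,
#' and the simulation truth (loadings, planted directions, true sign) to a
#' JSON sidecar.
#'
#' @param pair a [simulate_cohort_pair()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "cohort_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expr_a = file.path(dir, "cohortA_expression.tsv"),
    meta_a = file.path(dir, "cohortA_metadata.tsv"),
    expr_b = file.path(dir, "cohortB_expression.tsv"),
    meta_b = file.path(dir, "cohortB_metadata.tsv"),
    truth  = file.path(dir, "truth.json")
  )
  write_expression(pair$expr_a, paths["expr_a"])
  write_expression(pair$expr_b, paths["expr_b"])
  utils::write.table(pair$meta_a, paths["meta_a"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pair$meta_b, paths["meta_b"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- pair$truth
  tr$batch_offsets <- lapply(tr$batch_offsets, function(m) {
    lst <- as.data.frame(m)
    lst$gene <- rownames(m)
    lst
  })
  tr$latent <- lapply(tr$latent, as.list)
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
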