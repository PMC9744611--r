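#' Parametric empirical-Bayes batch adjustment
#'
#' Removes additive (location) and multiplicative (scale) per-batch effects
#' from a log2-scale expression matrix by the classic location/scale
#' empirical-Bayes procedure: (1) gene-wise standardisation after a
#' least-squares fit of batch means plus, optionally, the case/control
#' effect; (2) per-(gene, batch) location and scale estimates; (3) shrinkage
#' of those estimates under a normal prior on locations and an inverse-gamma
#' prior on scales, hyperparameters by method of moments, with the coupled
#' posterior updates iterated to convergence; (4) adjustment and
#' back-transformation restoring the grand mean and any protected covariate
#' effects.
#'
#' A single-batch matrix is returned unchanged: with one batch the
#' empirical-Bayes machinery is degenerate and there is nothing to remove.
#'
#' @param x gene-by-sample log2 expression matrix.
#' @param meta sample metadata; `batch` defines the batches and, when
#'   `protect_group` is `TRUE`, `group` is kept as a covariate during
#'   standardisation so true case/control signal is not absorbed into the
#'   batch correction.
#' @param protect_group keep case/control as a covariate (default `TRUE`).
#' @param conv convergence tolerance for the coupled posterior updates
#'   (maximum relative change, default `1e-4`).
#' @param max_iter iteration cap for the posterior updates.
#' @return the adjusted matrix, same dimensions and dimnames.
#' @examples
#' pair <- simulate_cohort_pair(synthetic_config(n_genes = 50,
#'   n_shared_deg = 10, n_private_deg = 0, n_cases = 10, n_controls = 10,
#'   n_batches = 2, batch_shift_sd = 1))
#' adj <- combat_adjust(pair$expr_a, pair$meta_a)
#' @export
combat_adjust <- function(x, meta, protect_group = TRUE,
                          conv = 1e-4, max_iter = 100L) {
  validate_expression(x)
  validate_metadata(meta, x)
  m <- meta[match(colnames(x), meta$sample_id), ]
  batch <- factor(m$batch)
  n_batch <- nlevels(batch)
  n_array <- ncol(x)
  if (n_batch == 1L) {
    message("combat_adjust: single batch, returning input unchanged")
    return(x)
  }
  n_batches <- as.vector(table(batch))
  if (any(n_batches < 2L)) {
    stop_("batch(es) with a single sample: ",
          paste(levels(batch)[n_batches < 2L], collapse = ", "))
  }

  batchmod <- stats::model.matrix(~ -1 + batch)
  design <- batchmod
  if (protect_group) {
    grp <- stats::model.matrix(~ factor(m$group, levels = c("control", "case")))
    design <- cbind(batchmod, grp[, -1L, drop = FALSE])
    if (qr(design)$rank < ncol(design)) {
      stop_("case/control group is confounded with batch; ",
            "cannot protect the group effect")
    }
  }

  # least-squares fit of batch (+ covariate) effects
  B_hat <- solve(crossprod(design), t(design) %*% t(x))
  grand_mean <- crossprod(n_batches / n_array,
                          B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- as.vector(((x - t(design %*% B_hat))^2) %*%
                            rep(1 / n_array, n_array))
  stand_mean <- t(grand_mean) %*% t(rep(1, n_array))
  if (ncol(design) > n_batch) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (x - stand_mean) / (sqrt(var_pooled) %*% t(rep(1, n_array)))

  # per-(gene, batch) location/scale estimates
  gamma_hat <- solve(crossprod(batchmod), t(batchmod) %*% t(s_data))
  batch_idx <- lapply(levels(batch), function(b) which(batch == b))
  delta_hat <- t(vapply(batch_idx, function(ii)
    apply(s_data[, ii, drop = FALSE], 1L, stats::var), numeric(nrow(x))))

  # method-of-moments hyperpriors
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, stats::var)
  a_prior <- apply(delta_hat, 1L, function(d) {
    m0 <- mean(d); s2 <- stats::var(d); (2 * s2 + m0^2) / s2
  })
  b_prior <- apply(delta_hat, 1L, function(d) {
    m0 <- mean(d); s2 <- stats::var(d); (m0 * s2 + m0^3) / s2
  })

  gamma_star <- matrix(NA_real_, n_batch, nrow(x))
  delta_star <- matrix(NA_real_, n_batch, nrow(x))
  for (i in seq_len(n_batch)) {
    sdat <- s_data[, batch_idx[[i]], drop = FALSE]
    n_i <- ncol(sdat)
    g_hat <- gamma_hat[i, ]
    g_old <- g_hat
    d_old <- delta_hat[i, ]
    for (it in seq_len(max_iter)) {
      g_new <- (t2[i] * n_i * g_hat + d_old * gamma_bar[i]) /
        (t2[i] * n_i + d_old)
      sum2 <- rowSums((sdat - g_new %*% t(rep(1, n_i)))^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (n_i / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < conv) break
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
  }

  # adjust and back-transform
  bayes <- s_data
  for (i in seq_len(n_batch)) {
    ii <- batch_idx[[i]]
    bayes[, ii] <- (bayes[, ii, drop = FALSE] - gamma_star[i, ]) /
      (sqrt(delta_star[i, ]) %*% t(rep(1, length(ii))))
  }
  out <- bayes * (sqrt(var_pooled) %*% t(rep(1, n_array))) + stand_mean
  dimnames(out) <- dimnames(x)
  out
}
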