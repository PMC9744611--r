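#' Spearman rank correlation with a two-sided p-value
#'
#' Average ranks for ties; `rho` is the Pearson correlation of the ranks.
#' The default p-value uses the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom;
#' `|rho| = 1` gives `p = 0`.  For small samples an exact permutation
#' p-value (full enumeration, `n <= 8`) is available.
#'
#' @param x,y numeric vectors of equal length, `n >= 4`.
#' @param method `"t"` (default) or `"permutation"`.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 4L) stop_("need n >= 4 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_("Spearman correlation is undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "permutation") {
    if (n > 8L) stop_("exact permutation p-value limited to n <= 8")
    perms <- all_permutations(n)
    obs <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      r <- stats::cor(rx, ry[perms[i, ]])
      if (abs(r) >= obs - 1e-12) cnt <- cnt + 1L
    }
    return(list(rho = rho, p = cnt / nrow(perms), n = n))
  }
  p <- if (abs(rho) >= 1 - 1e-15) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  # insert n at each position of every (n-1)-permutation
  out <- matrix(0L, factorial(n), n)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

#' Call an association direction from a correlation
#'
#' `positive` when `rho > 0` and `p < alpha`; `inverse` when `rho < 0` and
#' `p < alpha`; otherwise `indeterminate`.
#'
#' @param rho Spearman correlation.
#' @param p two-sided p-value.
#' @param alpha significance level (default 0.05).
#' @param n number of paired samples (recorded in the result).
#' @param cohort label of the evaluated cohort.
#' @return object of class `association_result`.
#' @export
infer_direction <- function(rho, p, alpha = 0.05, n = NA_integer_,
                            cohort = NA_character_) {
  if (is.na(rho)) {
    return(structure(list(cohort = cohort, n = n, rho = NA_real_,
                          p = NA_real_, alpha = alpha,
                          direction = "indeterminate"),
                     class = "association_result"))
  }
  if (!is.finite(rho) || abs(rho) > 1 + 1e-12) stop_("'rho' must be in [-1, 1]")
  direction <- if (p < alpha && rho > 0) "positive"
  else if (p < alpha && rho < 0) "inverse"
  else "indeterminate"
  structure(list(cohort = cohort, n = n, rho = rho, p = p, alpha = alpha,
                 direction = direction), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Association (%s, n = %s): rho = %.3f, p = %.3g -> %s\n",
              x$cohort, x$n, x$rho, x$p, x$direction))
  invisible(x)
}

#' Project held-out samples through both diseases' encoders
#'
#' For every holdout sample of one cohort (cases only by default, matching
#' the patient-level evaluation), computes the paired pseudogene scores
#' under the cohort's own encoder and the opposite disease's encoder.  The
#' score under the opposite encoder is counterfactual: it asks where this
#' patient would fall on the other disease's severity axis.
#'
#' @param enc_a,enc_b [autoencoder()] fits.
#' @param x gene-by-sample matrix of the evaluated cohort (must cover both
#'   encoders' gene lists).
#' @param meta the cohort's sample metadata.
#' @param split `sample_id -> train/holdout` assignment for this cohort.
#' @param cases_only evaluate cases only (default `TRUE`).
#' @return data.frame `sample_id`, `score_a`, `score_b`.
#' @export
cross_project <- function(enc_a, enc_b, x, meta, split, cases_only = TRUE) {
  validate_expression(x)
  validate_metadata(meta, x)
  ids <- names(split)[split == "holdout"]
  ids <- intersect(ids, colnames(x))
  if (cases_only) {
    grp <- meta$group[match(ids, meta$sample_id)]
    ids <- ids[grp == "case"]
  }
  if (length(ids) == 0L) stop_("no holdout samples to project")
  sub <- x[, ids, drop = FALSE]
  data.frame(sample_id = ids,
             score_a = unname(predict(enc_a, sub)),
             score_b = unname(predict(enc_b, sub)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Combine the two per-cohort direction calls into one verdict.
combine_directions <- function(dir_a, dir_b) {
  ds <- c(dir_a, dir_b)
  ds <- ds[ds != "indeterminate"]
  if (length(ds) == 0L) return("indeterminate")
  if (length(unique(ds)) == 1L) return(ds[1L])
  "indeterminate"
}

#' Infer the direction of transcriptomic association between two diseases
#'
#' The package's main fitting function.  Given two case/control cohorts on
#' a common platform it (1) aligns the gene universes; (2) optionally
#' removes per-study batch effects within each cohort
#' ([combat_adjust()]); (3) identifies each cohort's differentially
#' expressed genes with moderated t-tests and calls the shared DEGs and
#' their concordance ([deg_table()], [classify_overlap()]); (4) trains one
#' one-dimensional-bottleneck autoencoder per disease on the selected
#' feature genes ([autoencoder()]); (5) projects each cohort's held-out
#' cases through both encoders and correlates the paired pseudogene scores
#' (Spearman); and (6) calls the association direction per cohort and
#' overall.
#'
#' With `feature_set = "shared_degs"` (default) both encoders use the
#' shared-DEG gene list.  With `"pathway_genes"` each disease's encoder
#' instead uses the genes of that cohort's significantly enriched gene sets
#' (over-representation of its own DEGs against `gene_sets` at
#' `ora_fdr_cutoff`).
#'
#' @param expr_a,meta_a,expr_b,meta_b the two cohorts: gene-by-sample log2
#'   matrices plus sample metadata.
#' @param fdr_cutoff,lfc_cutoff DEG thresholds (defaults 0.05 and 0.5).
#' @param alpha significance level of the direction call (default 0.05).
#' @param feature_set `"shared_degs"` or `"pathway_genes"`.
#' @param gene_sets named list of gene sets (see [read_gmt()]); required for
#'   `feature_set = "pathway_genes"`.
#' @param ora_fdr_cutoff enrichment FDR cutoff for the pathway-gene feature
#'   set (default 0.2).
#' @param ae an [ae_config()] shared by both encoders.
#' @param train_frac training fraction of the per-cohort split.
#' @param batch_adjust adjust batches within each multi-batch cohort first.
#' @param cases_only evaluate the correlation on holdout cases only.
#' @param min_features minimum feature-gene count required to train.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return object of class `crosscoder`.
#' @examples
#' \donttest{
#' pair <- simulate_cohort_pair(synthetic_config(
#'   n_genes = 300, n_shared_deg = 60, frac_concordant = 1,
#'   n_private_deg = 20, n_cases = 30, n_controls = 30))
#' fit <- crosscoder(pair$expr_a, pair$meta_a, pair$expr_b, pair$meta_b,
#'                   ae = ae_config(widths = c(32, 16, 4), max_epochs = 100))
#' fit$direction
#' }
#' @export
crosscoder <- function(expr_a, meta_a, expr_b, meta_b,
                       fdr_cutoff = 0.05, lfc_cutoff = 0.5, alpha = 0.05,
                       feature_set = c("shared_degs", "pathway_genes"),
                       gene_sets = NULL, ora_fdr_cutoff = 0.2,
                       ae = ae_config(), train_frac = 0.6,
                       batch_adjust = TRUE, cases_only = TRUE,
                       min_features = 5L, seed = 1) {
  feature_set <- match.arg(feature_set)
  cl <- match.call()
  aligned <- align_cohorts(expr_a, expr_b)
  expr_a <- aligned[[1L]]
  expr_b <- aligned[[2L]]
  validate_metadata(meta_a, expr_a)
  validate_metadata(meta_b, expr_b)

  if (batch_adjust) {
    if (length(unique(meta_a$batch[meta_a$sample_id %in% colnames(expr_a)])) > 1L)
      expr_a <- combat_adjust(expr_a, meta_a)
    if (length(unique(meta_b$batch[meta_b$sample_id %in% colnames(expr_b)])) > 1L)
      expr_b <- combat_adjust(expr_b, meta_b)
  }

  deg_a <- deg_table(expr_a, meta_a, fdr_cutoff, lfc_cutoff)
  deg_b <- deg_table(expr_b, meta_b, fdr_cutoff, lfc_cutoff)
  overlap <- classify_overlap(deg_a, deg_b)

  if (feature_set == "shared_degs") {
    features_a <- features_b <- overlap$table$gene
  } else {
    if (is.null(gene_sets)) stop_("'gene_sets' required for pathway_genes")
    universe <- rownames(expr_a)
    pick <- function(deg) {
      hits <- deg$gene[deg$direction != "none"]
      ora <- hypergeom_ora(hits, gene_sets, universe,
                           fdr_cutoff = ora_fdr_cutoff)
      sig <- ora$set[ora$significant]
      sort(unique(intersect(unlist(gene_sets[sig]), universe)))
    }
    features_a <- pick(deg_a)
    features_b <- pick(deg_b)
  }
  if (length(features_a) < min_features || length(features_b) < min_features) {
    stop_(sprintf(
      "too few feature genes to train (A: %d, B: %d; need >= %d)",
      length(features_a), length(features_b), min_features))
  }

  split_a <- split_train_holdout(meta_a, train_frac, seed = seed + 1L)
  split_b <- split_train_holdout(meta_b, train_frac, seed = seed + 2L)
  cfg_a <- ae
  cfg_a$seed <- seed + 3L
  cfg_b <- ae
  cfg_b$seed <- seed + 4L
  enc_a <- autoencoder(expr_a[features_a, , drop = FALSE], meta_a,
                       split = split_a, config = cfg_a)
  enc_b <- autoencoder(expr_b[features_b, , drop = FALSE], meta_b,
                       split = split_b, config = cfg_b)
  # orientation needs the metadata; autoencoder() skips it when split given
  enc_a <- orient_encoder(enc_a, expr_a, meta_a)
  enc_b <- orient_encoder(enc_b, expr_b, meta_b)

  scores_a <- cross_project(enc_a, enc_b, expr_a, meta_a, split_a, cases_only)
  scores_b <- cross_project(enc_a, enc_b, expr_b, meta_b, split_b, cases_only)
  # a collapsed (constant) score vector leaves the correlation undefined;
  # report it as an indeterminate evaluation rather than aborting
  safe_sp <- function(sc) tryCatch(
    spearman_cor(sc$score_a, sc$score_b),
    error = function(e) list(rho = NA_real_, p = NA_real_, n = nrow(sc)))
  sp_a <- safe_sp(scores_a)
  sp_b <- safe_sp(scores_b)
  assoc_a <- infer_direction(sp_a$rho, sp_a$p, alpha, sp_a$n, "A")
  assoc_b <- infer_direction(sp_b$rho, sp_b$p, alpha, sp_b$n, "B")

  structure(list(
    call = cl, deg_a = deg_a, deg_b = deg_b, overlap = overlap,
    feature_set = feature_set, features_a = features_a,
    features_b = features_b, encoder_a = enc_a, encoder_b = enc_b,
    split_a = split_a, split_b = split_b,
    scores_a = scores_a, scores_b = scores_b,
    assoc_a = assoc_a, assoc_b = assoc_b,
    direction = combine_directions(assoc_a$direction, assoc_b$direction),
    alpha = alpha, seed = seed
  ), class = "crosscoder")
}

# Re-derive the canonical orientation of a trained encoder from the full
# cohort matrix and metadata (training samples only).
orient_encoder <- function(enc, x, meta) {
  train_ids <- names(enc$split)[enc$split == "train"]
  sc <- predict(enc, x[enc$genes, train_ids, drop = FALSE])
  grp <- meta$group[match(train_ids, meta$sample_id)]
  if (any(grp == "case") && any(grp == "control") &&
      mean(sc[grp == "case"]) < mean(sc[grp == "control"])) {
    enc$orientation <- -enc$orientation
  }
  enc
}

#' @export
print.crosscoder <- function(x, ...) {
  cat("Cross-disease association from paired autoencoder pseudogenes\n\n")
  cat(sprintf("Shared DEGs: %d (co-up %d, co-down %d, inverse %d)\n",
              x$overlap$n_shared, x$overlap$counts["co_up"],
              x$overlap$counts["co_down"], x$overlap$counts["inverse"]))
  cat(sprintf("Feature set: %s (A: %d genes, B: %d genes)\n\n", x$feature_set,
              length(x$features_a), length(x$features_b)))
  print(x$assoc_a)
  print(x$assoc_b)
  cat(sprintf("\nOverall direction: %s\n", x$direction))
  invisible(x)
}

#' @export
summary.crosscoder <- function(object, ...) {
  out <- list(
    n_deg_a = sum(object$deg_a$direction != "none"),
    n_deg_b = sum(object$deg_b$direction != "none"),
    overlap = object$overlap,
    rho = c(A = object$assoc_a$rho, B = object$assoc_b$rho),
    p = c(A = object$assoc_a$p, B = object$assoc_b$p),
    direction = object$direction,
    best_epoch = c(A = object$encoder_a$best_epoch,
                   B = object$encoder_b$best_epoch),
    holdout_mse = c(A = object$encoder_a$holdout_mse,
                    B = object$encoder_b$holdout_mse))
  class(out) <- "summary.crosscoder"
  out
}

#' @export
print.summary.crosscoder <- function(x, ...) {
  cat(sprintf("DEGs: %d (cohort A), %d (cohort B); shared %d (%.0f%% concordant)\n",
              x$n_deg_a, x$n_deg_b, x$overlap$n_shared,
              100 * x$overlap$concordant_fraction))
  cat(sprintf("Spearman rho: A %.3f (p %.3g), B %.3f (p %.3g)\n",
              x$rho["A"], x$p["A"], x$rho["B"], x$p["B"]))
  cat(sprintf("Direction: %s\n", x$direction))
  invisible(x)
}

#' Correlation coefficients of a crosscoder fit
#' @param object a [crosscoder()] fit.
#' @param ... unused.
#' @return named vector of the two per-cohort Spearman correlations.
#' @export
coef.crosscoder <- function(object, ...) {
  c(rho_A = object$assoc_a$rho, rho_B = object$assoc_b$rho)
}

#' Scatterplots of the paired pseudogene scores
#'
#' One panel per evaluated cohort: the cohort's own-encoder score against
#' its counterfactual score under the opposite disease's encoder, with the
#' Spearman correlation annotated.
#'
#' @param x a [crosscoder()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.crosscoder <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  panel <- function(sc, assoc, cohort) {
    graphics::plot(sc$score_a, sc$score_b,
                   xlab = "encoder A score", ylab = "encoder B score",
                   main = sprintf("%s holdout cases\nrho = %.3f, p = %.2g",
                                  cohort, assoc$rho, assoc$p), ...)
  }
  panel(x$scores_a, x$assoc_a, "Cohort A")
  panel(x$scores_b, x$assoc_b, "Cohort B")
  invisible(x)
}

#' Project new samples of either cohort through both encoders
#'
#' @param object a [crosscoder()] fit.
#' @param newdata gene-by-sample matrix covering both encoders' gene lists.
#' @param ... unused.
#' @return data.frame `sample_id`, `score_a`, `score_b`.
#' @export
predict.crosscoder <- function(object, newdata, ...) {
  data.frame(sample_id = colnames(newdata),
             score_a = unname(predict(object$encoder_a, newdata)),
             score_b = unname(predict(object$encoder_b, newdata)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sign-recovery simulation for the full pipeline
#'
#' Repeatedly simulates a cohort pair with a planted association sign, runs
#' the full [crosscoder()] pipeline, and tabulates whether the inferred
#' direction matches the planted one.  This is the package's primary
#' self-check: the generator's truth is known, so recovery can be scored
#' exactly.
#'
#' @param n_seeds number of independent simulated pairs.
#' @param frac_concordant concordant fraction passed to the generator
#'   (1 plants a positive association, 0 an inverse one).
#' @param config a [synthetic_config()] giving the study conditions; its
#'   `frac_concordant` and `seed` are overridden per run.
#' @param ae an [ae_config()] for the encoders.
#' @param seed base seed; run `i` uses `seed + 1000 * i` for the generator
#'   and derived seeds for the pipeline.
#' @return data.frame with one row per run: planted sign, the two Spearman
#'   correlations, the direction call and whether it matches.
#' @export
simulate_direction_recovery <- function(n_seeds = 10, frac_concordant = 1.0,
                                        config = synthetic_config(),
                                        ae = ae_config(), seed = 1) {
  out <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$frac_concordant <- frac_concordant
    cfg$seed <- seed + 1000L * i
    pair <- simulate_cohort_pair(cfg)
    fit <- crosscoder(pair$expr_a, pair$meta_a, pair$expr_b, pair$meta_b,
                      ae = ae, seed = cfg$seed + 1L)
    planted <- c("-1" = "inverse", "0" = "indeterminate",
                 "1" = "positive")[as.character(pair$truth$true_sign)]
    out[[i]] <- data.frame(
      run = i, true_sign = pair$truth$true_sign,
      rho_a = fit$assoc_a$rho, rho_b = fit$assoc_b$rho,
      n_shared_deg = fit$overlap$n_shared,
      direction = fit$direction,
      match = fit$direction == planted,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
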