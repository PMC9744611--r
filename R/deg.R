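#' Per-gene two-group summary statistics
#'
#' For each gene: the log2 fold change `mean(case) - mean(control)`, the
#' pooled two-sample residual variance, and the common residual degrees of
#' freedom `n_case + n_control - 2`.
#'
#' @param x gene-by-sample log2 matrix.
#' @param meta sample metadata with `group` in `case`/`control`.
#' @return data.frame with columns `gene`, `logFC`, `s2`, `df` and
#'   attributes `n_case`, `n_control`.
#' @export
fit_two_group <- function(x, meta) {
  validate_expression(x)
  validate_metadata(meta, x)
  m <- meta[match(colnames(x), meta$sample_id), ]
  cs <- m$group == "case"
  n1 <- sum(cs)
  n2 <- sum(!cs)
  if (n1 < 2L || n2 < 2L) {
    stop_("each group needs >= 2 samples (got ", n1, " cases, ", n2, " controls)")
  }
  xc <- x[, cs, drop = FALSE]
  xk <- x[, !cs, drop = FALSE]
  mc <- rowMeans(xc)
  mk <- rowMeans(xk)
  ssc <- rowSums((xc - mc)^2)
  ssk <- rowSums((xk - mk)^2)
  out <- data.frame(gene = rownames(x),
                    logFC = mc - mk,
                    s2 = (ssc + ssk) / (n1 + n2 - 2L),
                    df = n1 + n2 - 2L,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_case") <- n1
  attr(out, "n_control") <- n2
  out
}

#' Invert the trigamma function on the half-degrees-of-freedom scale
#'
#' Returns `d` such that `trigamma(d / 2) = y`, by Newton iteration on
#' `x = d / 2`.  Used to estimate the prior degrees of freedom from the
#' excess spread of log sample variances.
#'
#' @param y positive target value.
#' @return degrees of freedom `d` with `trigamma(d / 2) == y`.
#' @export
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) stop_("'y' must be a positive finite number")
  if (y > 1e7) return(2 / sqrt(y))        # trigamma(x) ~ 1/x for small x... guard
  if (y < 1e-8) return(2 / y)             # trigamma(x) ~ 1/x for large x
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-12) break
  }
  2 * x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matching of the log sample variances to a scaled-F model:
#' the prior degrees of freedom `d0` solve
#' `trigamma(d0 / 2) = var(log s2) - trigamma(df / 2)` (monotone root
#' finding via [trigamma_inverse()]); the prior variance `s02` follows from
#' the mean of `log s2` corrected by the corresponding digamma terms.  When
#' the observed spread of `log s2` does not exceed the sampling spread
#' `trigamma(df / 2)`, there is no evidence of gene-to-gene variance
#' heterogeneity and `d0 = Inf`.
#'
#' @param fits a [fit_two_group()] table (columns `s2`, `df`).
#' @return list with `d0` (possibly `Inf`) and `s02`.
#' @export
estimate_variance_prior <- function(fits) {
  s2 <- fits$s2[fits$s2 > 0]
  if (length(s2) < 2L) stop_("need >= 2 genes with positive sample variance")
  df <- fits$df[1L]
  z <- log(s2)
  excess <- stats::var(z) - trigamma(df / 2)
  base <- mean(z) - digamma(df / 2) + log(df / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s02 = exp(base)))
  }
  d0 <- trigamma_inverse(excess)
  s02 <- exp(base + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each gene's pooled variance toward the prior,
#' `s2_post = (d0 * s02 + df * s2) / (d0 + df)`, and tests
#' `t = logFC / sqrt(s2_post * (1/n_case + 1/n_control))` against a
#' t-distribution with `d0 + df` degrees of freedom (normal when
#' `d0 = Inf`).  Two-sided p-values.  With `d0 = 0` the statistic is the
#' ordinary pooled two-sample t.
#'
#' @param fits a [fit_two_group()] table.
#' @param prior list with `d0`, `s02` (see [estimate_variance_prior()]).
#' @return data.frame `gene`, `logFC`, `t`, `p`.
#' @export
moderated_t_table <- function(fits, prior) {
  if (!is.numeric(prior$d0) || (is.finite(prior$d0) && prior$d0 < 0) ||
      !is.numeric(prior$s02) || prior$s02 < 0) {
    stop_("invalid variance prior")
  }
  d0 <- prior$d0
  df <- fits$df
  n1 <- attr(fits, "n_case")
  n2 <- attr(fits, "n_control")
  if (is.null(n1) || is.null(n2)) stop_("fits must come from fit_two_group()")
  s2_post <- if (is.infinite(d0)) rep(prior$s02, nrow(fits)) else
    (d0 * prior$s02 + df * fits$s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, fits$logFC / se,
              ifelse(fits$logFC > 0, Inf, ifelse(fits$logFC < 0, -Inf, 0)))
  df_total <- d0 + df
  p <- ifelse(is.finite(t),
              2 * stats::pt(-abs(t), df = df_total),
              ifelse(t == 0, 1, 0))
  p[!is.finite(t) & t == 0] <- 1   # logFC 0 with zero variance
  data.frame(gene = fits$gene, logFC = fits$logFC, t = t, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted values (FDR), same order as input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Direction is `up` when `fdr < fdr_cutoff` and `logFC >= lfc_cutoff`,
#' `down` when `fdr < fdr_cutoff` and `logFC <= -lfc_cutoff`, otherwise
#' `none`.  The fold-change threshold is inclusive, the FDR threshold
#' exclusive.
#'
#' @param table data.frame with `logFC` and `fdr` columns.
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @param lfc_cutoff absolute log2-fold-change threshold (default 0.5).
#' @return the table with a `direction` column filled in.
#' @export
call_degs <- function(table, fdr_cutoff = 0.05, lfc_cutoff = 0.5) {
  stopifnot(all(c("logFC", "fdr") %in% names(table)))
  table$direction <- ifelse(
    table$fdr < fdr_cutoff & table$logFC >= lfc_cutoff, "up",
    ifelse(table$fdr < fdr_cutoff & table$logFC <= -lfc_cutoff, "down", "none"))
  table
}

#' Full differential-expression table for one cohort
#'
#' Convenience wrapper: [fit_two_group()], [estimate_variance_prior()],
#' [moderated_t_table()], [bh_adjust()], [call_degs()].
#'
#' @inheritParams fit_two_group
#' @inheritParams call_degs
#' @return data.frame `gene`, `logFC`, `t`, `p`, `fdr`, `direction`.
#' @export
deg_table <- function(x, meta, fdr_cutoff = 0.05, lfc_cutoff = 0.5) {
  fits <- fit_two_group(x, meta)
  prior <- estimate_variance_prior(fits)
  tab <- moderated_t_table(fits, prior)
  tab$fdr <- bh_adjust(tab$p)
  tab <- call_degs(tab, fdr_cutoff, lfc_cutoff)
  attr(tab, "prior") <- prior
  tab
}

#' Classify the overlap of two cohorts' DEG calls
#'
#' Shared DEGs are genes called (direction not `none`) in both cohorts; each
#' is classified `co-up`, `co-down` or `inverse` from its direction pair.
#' The concordant fraction is `(co-up + co-down) / total`.
#'
#' @param deg_a,deg_b DEG tables with `gene` and `direction` columns.
#' @return list with `table` (gene, dir_a, dir_b, class), `counts`
#'   (named vector co_up/co_down/inverse), `n_shared` and
#'   `concordant_fraction` (NA when no shared DEG).
#' @export
classify_overlap <- function(deg_a, deg_b) {
  da <- deg_a[deg_a$direction != "none", c("gene", "direction")]
  db <- deg_b[deg_b$direction != "none", c("gene", "direction")]
  shared <- intersect(da$gene, db$gene)
  dir_a <- da$direction[match(shared, da$gene)]
  dir_b <- db$direction[match(shared, db$gene)]
  cls <- ifelse(dir_a == dir_b,
                ifelse(dir_a == "up", "co-up", "co-down"), "inverse")
  tab <- data.frame(gene = shared, dir_a = dir_a, dir_b = dir_b, class = cls,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene), , drop = FALSE]
  counts <- c(co_up = sum(cls == "co-up"),
              co_down = sum(cls == "co-down"),
              inverse = sum(cls == "inverse"))
  list(table = tab, counts = counts, n_shared = length(shared),
       concordant_fraction = if (length(shared))
         unname((counts["co_up"] + counts["co_down"]) / length(shared))
       else NA_real_)
}

#' Write a DEG table as TSV
#' @param table a [deg_table()] result.
#' @param path output file.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table[, c("gene", "logFC", "t", "p", "fdr", "direction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
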