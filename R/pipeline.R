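#' Build a pipeline run configuration
#'
#' Either a synthetic simulation (`synthetic = synthetic_config(...)`) or
#' file inputs (`expr_a`, `meta_a`, `expr_b`, `meta_b` TSV paths; optional
#' `probe_map_a`/`probe_map_b`), plus thresholds, the autoencoder
#' configuration and named seeds.  Can also be loaded from a YAML file with
#' the same keys.
#'
#' @param synthetic optional [synthetic_config()] (or a list of its
#'   arguments) to simulate the cohorts instead of reading files.
#' @param expr_a,meta_a,expr_b,meta_b input TSV paths (ignored when
#'   `synthetic` is given).
#' @param probe_map_a,probe_map_b optional probe-map TSV paths; when given,
#'   the corresponding matrix is collapsed probe-to-gene first.
#' @param gene_sets_gmt optional GMT path for enrichment and the
#'   pathway-gene feature set.
#' @param edge_list optional interaction edge-list TSV for hub-gene
#'   ranking.
#' @param feature_set `"shared_degs"` (default) or `"pathway_genes"`.
#' @param fdr_cutoff,lfc_cutoff,alpha,ora_fdr_cutoff,confidence thresholds.
#' @param ae an [ae_config()].
#' @param train_frac training fraction of the split.
#' @param batch_adjust adjust batches per cohort first.
#' @param seed master seed for split/training/simulation.
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, expr_a = NULL, meta_a = NULL,
                       expr_b = NULL, meta_b = NULL,
                       probe_map_a = NULL, probe_map_b = NULL,
                       gene_sets_gmt = NULL, edge_list = NULL,
                       feature_set = "shared_degs",
                       fdr_cutoff = 0.05, lfc_cutoff = 0.5, alpha = 0.05,
                       ora_fdr_cutoff = 0.2, confidence = 0.7,
                       ae = ae_config(), train_frac = 0.6,
                       batch_adjust = TRUE, seed = 1) {
  if (is.null(synthetic)) {
    for (p in c(expr_a, meta_a, expr_b, meta_b)) {
      if (is.null(p) || !file.exists(p)) {
        stop_("input file missing or not found: ", p %||% "(NULL)")
      }
    }
  } else if (!inherits(synthetic, "synthetic_config")) {
    synthetic <- do.call(synthetic_config, as.list(synthetic))
  }
  if (!inherits(ae, "ae_config")) ae <- do.call(ae_config, as.list(ae))
  structure(list(
    synthetic = synthetic, expr_a = expr_a, meta_a = meta_a,
    expr_b = expr_b, meta_b = meta_b,
    probe_map_a = probe_map_a, probe_map_b = probe_map_b,
    gene_sets_gmt = gene_sets_gmt, edge_list = edge_list,
    feature_set = feature_set,
    fdr_cutoff = assert_number(fdr_cutoff, "fdr_cutoff", 0, 1),
    lfc_cutoff = assert_number(lfc_cutoff, "lfc_cutoff", 0),
    alpha = assert_number(alpha, "alpha", 0, 1),
    ora_fdr_cutoff = assert_number(ora_fdr_cutoff, "ora_fdr_cutoff", 0, 1),
    confidence = assert_number(confidence, "confidence", 0, 1),
    ae = ae, train_frac = train_frac, batch_adjust = isTRUE(batch_adjust),
    seed = assert_count(seed, "seed", 0L)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full association pipeline
#'
#' Orchestrates ingest (or simulation), probe collapsing, per-cohort batch
#' adjustment, differential expression, overlap classification, encoder
#' training, cross-projection, the direction call, optional enrichment and
#' hub-gene ranking, plots, and a JSON run manifest.  Every intermediate
#' table is written to `outdir`.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @param plot also write score scatterplots (PNG).
#' @return the [crosscoder()] fit, invisibly, with the manifest attached as
#'   attribute `manifest`.
#' @export
run_pipeline <- function(config, outdir, plot = TRUE) {
  if (!inherits(config, "run_config")) stop_("'config' must be a run_config()")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- "ingest"
  res <- tryCatch({
    if (!is.null(config$synthetic)) {
      pair <- simulate_cohort_pair(config$synthetic)
      write_cohort_pair(pair, file.path(outdir, "inputs"))
      expr_a <- pair$expr_a; meta_a <- pair$meta_a
      expr_b <- pair$expr_b; meta_b <- pair$meta_b
    } else {
      ina <- read_expression(config$expr_a, config$meta_a)
      inb <- read_expression(config$expr_b, config$meta_b)
      expr_a <- ina$expr; meta_a <- ina$meta
      expr_b <- inb$expr; meta_b <- inb$meta
      if (!is.null(config$probe_map_a)) {
        expr_a <- collapse_probes(expr_a, read_probe_map(config$probe_map_a),
                                  meta_a)
      }
      if (!is.null(config$probe_map_b)) {
        expr_b <- collapse_probes(expr_b, read_probe_map(config$probe_map_b),
                                  meta_b)
      }
    }
    gene_sets <- if (!is.null(config$gene_sets_gmt))
      read_gmt(config$gene_sets_gmt) else NULL

    stage <- "association"
    fit <- crosscoder(expr_a, meta_a, expr_b, meta_b,
                      fdr_cutoff = config$fdr_cutoff,
                      lfc_cutoff = config$lfc_cutoff,
                      alpha = config$alpha,
                      feature_set = config$feature_set,
                      gene_sets = gene_sets,
                      ora_fdr_cutoff = config$ora_fdr_cutoff,
                      ae = config$ae, train_frac = config$train_frac,
                      batch_adjust = config$batch_adjust,
                      seed = config$seed)

    stage <- "write"
    write_deg_table(fit$deg_a, file.path(outdir, "deg_cohortA.tsv"))
    write_deg_table(fit$deg_b, file.path(outdir, "deg_cohortB.tsv"))
    utils::write.table(fit$overlap$table,
                       file.path(outdir, "overlap_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$scores_a, file.path(outdir, "scores_cohortA.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$scores_b, file.path(outdir, "scores_cohortB.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    assoc <- data.frame(
      cohort = c("A", "B"),
      n = c(fit$assoc_a$n, fit$assoc_b$n),
      rho = c(fit$assoc_a$rho, fit$assoc_b$rho),
      p = c(fit$assoc_a$p, fit$assoc_b$p),
      direction = c(fit$assoc_a$direction, fit$assoc_b$direction))
    utils::write.table(assoc, file.path(outdir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "enrichment"
    enrich <- hubs <- NULL
    if (!is.null(gene_sets)) {
      enrich <- hypergeom_ora(fit$overlap$table$gene, gene_sets,
                              rownames(expr_a),
                              fdr_cutoff = config$ora_fdr_cutoff)
      utils::write.table(enrich, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(config$edge_list)) {
      hubs <- hub_genes_by_degree(read_edge_list(config$edge_list),
                                  confidence = config$confidence)
      utils::write.table(hubs, file.path(outdir, "hub_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (plot) {
      stage <- "plots"
      try({
        grDevices::png(file.path(outdir, "score_scatter.png"),
                       width = 1200, height = 600, res = 120)
        plot(fit)
        grDevices::dev.off()
      }, silent = TRUE)
    }
    list(fit = fit, enrich = enrich, hubs = hubs)
  }, error = function(e) {
    stop_(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })

  fit <- res$fit
  manifest <- list(
    package_version = as.character(utils::packageVersion("crosscoder")),
    seed = config$seed,
    feature_set = config$feature_set,
    thresholds = list(fdr = config$fdr_cutoff, lfc = config$lfc_cutoff,
                      alpha = config$alpha, ora_fdr = config$ora_fdr_cutoff,
                      confidence = config$confidence),
    counts = list(
      genes = length(fit$deg_a$gene),
      deg_a = sum(fit$deg_a$direction != "none"),
      deg_b = sum(fit$deg_b$direction != "none"),
      shared_deg = fit$overlap$n_shared,
      overlap = as.list(fit$overlap$counts),
      features_a = length(fit$features_a),
      features_b = length(fit$features_b)),
    association = list(
      rho_a = fit$assoc_a$rho, p_a = fit$assoc_a$p,
      rho_b = fit$assoc_b$rho, p_b = fit$assoc_b$p,
      direction = fit$direction),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(fit, "manifest") <- manifest
  invisible(fit)
}
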