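#' Autoencoder hyperparameter configuration
#'
#' The network is a symmetric dense stack: input of `n` genes, encoder
#' hidden layers of the given widths (ReLU), a one-node linear bottleneck,
#' the mirrored decoder hidden layers (ReLU), and a linear output back to
#' `n` genes.  Dropout follows every hidden layer except the bottleneck and
#' the output.  Training minimises mean-squared reconstruction error with
#' the Adam optimiser, monitoring the held-out samples for early stopping.
#'
#' Defaults follow the reference design for expression profiles: encoder
#' widths 128/64/10, dropout 0.2, learning rate 5e-4, and early stopping
#' when the holdout MSE stops improving by more than `min_delta` for
#' `patience` consecutive epochs.
#'
#' @param widths encoder hidden-layer widths, strictly decreasing, all > 1.
#' @param dropout dropout rate in `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience, epochs.
#' @param min_delta minimum holdout-MSE improvement that resets patience.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return object of class `ae_config`.
#' @export
ae_config <- function(widths = c(128, 64, 10), dropout = 0.2,
                      learning_rate = 5e-4, batch_size = 16,
                      max_epochs = 500, patience = 10, min_delta = 1e-4,
                      seed = 1) {
  if (!is.numeric(widths) || length(widths) < 1L || any(widths != round(widths)) ||
      any(widths <= 1)) {
    stop_("'widths' must be integer layer widths, all > 1")
  }
  if (any(diff(widths) >= 0)) {
    stop_("'widths' must be strictly decreasing toward the bottleneck")
  }
  structure(list(
    widths = as.integer(widths),
    dropout = assert_number(dropout, "dropout", 0, 1 - 1e-12),
    learning_rate = assert_number(learning_rate, "learning_rate", 1e-12),
    batch_size = assert_count(batch_size, "batch_size"),
    max_epochs = assert_count(max_epochs, "max_epochs"),
    patience = assert_count(patience, "patience"),
    min_delta = assert_number(min_delta, "min_delta", 0),
    seed = assert_count(seed, "seed", min = 0L)
  ), class = "ae_config")
}

#' @export
print.ae_config <- function(x, ...) {
  cat(sprintf(
    "Autoencoder config: widths [%s] -> 1; dropout %.2f; lr %g; batch %d\n",
    paste(x$widths, collapse = ", "), x$dropout, x$learning_rate, x$batch_size))
  cat(sprintf("  early stopping: patience %d, min_delta %g, max %d epochs; seed %d\n",
              x$patience, x$min_delta, x$max_epochs, x$seed))
  invisible(x)
}

# Full layer-size vector input -> encoder -> bottleneck -> decoder -> output.
ae_layer_sizes <- function(n_genes, config) {
  as.integer(c(n_genes, config$widths, 1L, rev(config$widths), n_genes))
}

ae_activations <- function(config) {
  k <- length(config$widths)
  c(rep("relu", k), "linear", rep("relu", k), "linear")
}

# dropout after every hidden ReLU layer, never after bottleneck or output
ae_dropout_after <- function(config) {
  k <- length(config$widths)
  c(rep(TRUE, k), FALSE, rep(TRUE, k), FALSE)
}

#' Number of trainable parameters of the configured network
#'
#' Closed form: `sum(w_in * w_out + w_out)` over the dense maps.
#'
#' @param n_genes input dimension.
#' @param config an [ae_config()].
#' @return integer parameter count.
#' @export
ae_param_count <- function(n_genes, config) {
  s <- ae_layer_sizes(n_genes, config)
  sum(s[-length(s)] * s[-1L] + s[-1L])
}

#' Stratified train/holdout split
#'
#' Partitions samples into a training and a holdout part at the requested
#' ratio (default 3:2), stratified by case/control so both parts keep
#' roughly the cohort's case fraction.  Deterministic for a given seed.
#'
#' @param meta sample metadata.
#' @param train_frac training fraction (default 0.6).
#' @param seed RNG seed.
#' @return named character vector, `sample_id -> "train"/"holdout"`.
#' @export
split_train_holdout <- function(meta, train_frac = 0.6, seed = 1) {
  validate_metadata(meta)
  train_frac <- assert_number(train_frac, "train_frac", 1e-9, 1 - 1e-9)
  counts <- table(meta$group)
  if (any(counts < 2L)) {
    stop_("each group needs >= 2 samples to split")
  }
  with_seed(seed, {
    assign_ <- character(0)
    for (g in sort(unique(meta$group))) {
      ids <- meta$sample_id[meta$group == g]
      n_tr <- round(train_frac * length(ids))
      n_tr <- max(1L, min(length(ids) - 1L, n_tr))
      tr <- sample(ids, n_tr)
      a <- stats::setNames(ifelse(ids %in% tr, "train", "holdout"), ids)
      assign_ <- c(assign_, a)
    }
    assign_[meta$sample_id]
  })
}

#' Fit / apply per-gene standardisation
#'
#' `fit_standardizer` computes each gene's mean and standard deviation over
#' the training samples only; `apply_standardizer` z-scores any matrix with
#' those frozen parameters, so holdout and external samples are scaled
#' exactly as the training data was.  Genes with zero training variance get
#' sd 1 (with a warning), mapping them to constant zero.
#'
#' @param x gene-by-sample matrix.
#' @param train_ids sample ids of the training split.
#' @return `fit_standardizer`: list with `mean`, `sd` (named by gene);
#'   `apply_standardizer`: the standardised matrix.
#' @export
fit_standardizer <- function(x, train_ids) {
  missing_ids <- setdiff(train_ids, colnames(x))
  if (length(missing_ids)) {
    stop_("training sample(s) absent from matrix: ",
          paste(missing_ids, collapse = ", "))
  }
  xt <- x[, train_ids, drop = FALSE]
  mu <- rowMeans(xt)
  sd_ <- apply(xt, 1L, stats::sd)
  zero <- sd_ == 0 | !is.finite(sd_)
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero training variance; using sd = 1")
    sd_[zero] <- 1
  }
  list(mean = mu, sd = sd_)
}

#' @rdname fit_standardizer
#' @param std a standardizer from `fit_standardizer`.
#' @export
apply_standardizer <- function(std, x) {
  genes <- names(std$mean)
  missing_genes <- setdiff(genes, rownames(x))
  if (length(missing_genes)) {
    stop_("matrix is missing gene(s): ", paste(missing_genes, collapse = ", "))
  }
  (x[genes, , drop = FALSE] - std$mean) / std$sd
}

#' Fit a one-dimensional-bottleneck autoencoder to an expression cohort
#'
#' The model object of this package.  Samples are split (stratified 3:2 by
#' default) into a training part, used for gradient updates, and a holdout
#' part, used to monitor reconstruction MSE for early stopping and later as
#' the evaluation set for cross-disease association.  Inputs are per-gene
#' z-scored with training-split statistics.  After training, the bottleneck
#' sign is canonicalised so that the mean score of training cases is at
#' least that of training controls — an autoencoder's latent axis has no
#' intrinsic sign, and without this convention the sign of any downstream
#' correlation would be arbitrary.
#'
#' @param x gene-by-sample log2 expression matrix (the genes to embed).
#' @param meta sample metadata (used for the stratified split and the sign
#'   convention); may be `NULL` if `split` is given, in which case the
#'   orientation is left at `+1`.
#' @param split optional precomputed [split_train_holdout()] assignment.
#' @param config an [ae_config()].
#' @param train_frac training fraction when the split is computed here.
#' @return object of class `autoencoder`: layer weights, gene list,
#'   standardizer, orientation, split, per-epoch history, best epoch.
#' @examples
#' pair <- simulate_cohort_pair(synthetic_config(n_genes = 40,
#'   n_shared_deg = 10, n_private_deg = 0, n_cases = 15, n_controls = 15,
#'   n_batches = 1))
#' fit <- autoencoder(pair$expr_a, pair$meta_a,
#'                    config = ae_config(widths = c(8, 4, 2), max_epochs = 30))
#' head(predict(fit, pair$expr_a))
#' @export
autoencoder <- function(x, meta = NULL, split = NULL, config = ae_config(),
                        train_frac = 0.6) {
  validate_expression(x)
  if (!inherits(config, "ae_config")) stop_("'config' must be an ae_config()")
  if (is.null(split)) {
    if (is.null(meta)) stop_("either 'meta' or 'split' must be supplied")
    split <- split_train_holdout(meta, train_frac = train_frac,
                                 seed = config$seed)
  }
  split <- split[intersect(names(split), colnames(x))]
  train_ids <- names(split)[split == "train"]
  hold_ids <- names(split)[split == "holdout"]
  if (length(train_ids) < 2L || length(hold_ids) < 1L) {
    stop_("split must leave >= 2 training and >= 1 holdout samples")
  }

  std <- fit_standardizer(x, train_ids)
  Xtr <- t(apply_standardizer(std, x[, train_ids, drop = FALSE]))
  Xho <- t(apply_standardizer(std, x[, hold_ids, drop = FALSE]))

  sizes <- ae_layer_sizes(nrow(x), config)
  acts <- ae_activations(config)
  drop_after <- ae_dropout_after(config)

  fit <- with_seed(config$seed, {
    layers <- nn_init(sizes)
    state <- adam_init(layers)
    best <- list(layers = layers, mse = nn_mse(layers, Xho, acts), epoch = 0L)
    # epoch 0 records the untrained network as the improvement baseline
    history <- data.frame(epoch = 0L, train_mse = nn_mse(layers, Xtr, acts),
                          holdout_mse = best$mse)
    wait <- 0L
    step <- 0L
    n_tr <- nrow(Xtr)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = config$batch_size)
      for (s in starts) {
        ii <- ord[s:min(s + config$batch_size - 1L, n_tr)]
        Xb <- Xtr[ii, , drop = FALSE]
        fwd <- nn_forward(layers, Xb, acts, drop_after,
                          config$dropout, training = TRUE)
        grads <- nn_backward(layers, Xb, Xb, fwd, acts)
        step <- step + 1L
        upd <- adam_step(layers, grads, state, step, config$learning_rate)
        layers <- upd$layers
        state <- upd$state
      }
      tr_mse <- nn_mse(layers, Xtr, acts)
      ho_mse <- nn_mse(layers, Xho, acts)
      if (!is.finite(tr_mse) || !is.finite(ho_mse)) {
        stop_("non-finite training loss; reduce the learning rate (",
              config$learning_rate, ")")
      }
      history <- rbind(history, data.frame(epoch = epoch, train_mse = tr_mse,
                                           holdout_mse = ho_mse))
      if (ho_mse < best$mse - config$min_delta) {
        best <- list(layers = layers, mse = ho_mse, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    list(layers = best$layers, best_epoch = best$epoch,
         best_mse = best$mse, history = history)
  })

  obj <- structure(list(
    layers = fit$layers, config = config, genes = rownames(x),
    standardizer = std, orientation = 1,
    split = split, history = fit$history, best_epoch = fit$best_epoch,
    holdout_mse = fit$best_mse, n_train = length(train_ids),
    n_holdout = length(hold_ids)
  ), class = "autoencoder")

  # canonical sign: training cases score at least as high as controls
  if (!is.null(meta)) {
    sc <- predict(obj, x[, train_ids, drop = FALSE])
    grp <- meta$group[match(train_ids, meta$sample_id)]
    if (any(grp == "case") && any(grp == "control") &&
        mean(sc[grp == "case"]) < mean(sc[grp == "control"])) {
      obj$orientation <- -1
    }
  }
  obj
}

encoder_scores <- function(object, x) {
  std <- object$standardizer
  Xs <- t(apply_standardizer(std, x))
  k <- length(object$config$widths)
  enc_layers <- object$layers[seq_len(k + 1L)]
  acts <- c(rep("relu", k), "linear")
  out <- nn_forward(enc_layers, Xs, acts, training = FALSE)$out
  stats::setNames(as.vector(out) * object$orientation, colnames(x))
}

#' Predict method for autoencoder fits
#'
#' `type = "score"` (default) returns the oriented one-dimensional
#' bottleneck score per sample — the "pseudogene".  `type =
#' "reconstruction"` returns the decoded matrix on the standardised scale.
#' Inference is deterministic: dropout is disabled.
#'
#' @param object an [autoencoder()] fit.
#' @param newdata gene-by-sample matrix covering the fit's gene list; an
#'   error lists any missing genes.
#' @param type `"score"` or `"reconstruction"`.
#' @param ... unused.
#' @return named numeric vector of scores, or a genes-by-samples matrix.
#' @export
predict.autoencoder <- function(object, newdata,
                                type = c("score", "reconstruction"), ...) {
  type <- match.arg(type)
  if (type == "score") return(encoder_scores(object, newdata))
  Xs <- t(apply_standardizer(object$standardizer, newdata))
  acts <- ae_activations(object$config)
  out <- nn_forward(object$layers, Xs, acts, training = FALSE)$out
  t(structure(out, dimnames = list(colnames(newdata), object$genes)))
}

#' Per-sample reconstruction error
#'
#' Mean squared reconstruction residual per sample on the standardised
#' scale.
#'
#' @inheritParams predict.autoencoder
#' @return named numeric vector.
#' @export
residuals.autoencoder <- function(object, newdata, ...) {
  Xs <- apply_standardizer(object$standardizer, newdata)
  rec <- predict(object, newdata, type = "reconstruction")
  colMeans((Xs - rec)^2)
}

#' @export
coef.autoencoder <- function(object, ...) {
  stats::setNames(lapply(object$layers, `[[`, "W"),
                  sprintf("dense%d", seq_along(object$layers)))
}

#' @export
print.autoencoder <- function(x, ...) {
  s <- ae_layer_sizes(length(x$genes), x$config)
  cat("One-dimensional-bottleneck autoencoder\n")
  cat(sprintf("  layers: [%s]; %d parameters\n", paste(s, collapse = ", "),
              ae_param_count(length(x$genes), x$config)))
  cat(sprintf("  trained on %d samples, monitored on %d; best epoch %d (holdout MSE %.4f)\n",
              x$n_train, x$n_holdout, x$best_epoch, x$holdout_mse))
  cat(sprintf("  orientation: %+d (training cases score >= controls)\n",
              x$orientation))
  invisible(x)
}

#' @export
plot.autoencoder <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$holdout_mse), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "reconstruction MSE", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "holdout"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Hyperparameter grid for the autoencoder
#'
#' Option lists for an exhaustive search: learning rate, total dense depth
#' (6, 8 or 10 maps, i.e. 2, 3 or 4 encoder hidden layers), the first three
#' encoder widths, and the dropout rate.  The full default grid enumerates
#' `4 * 3 * 3 * 3 * 3 * 3 = 972` combinations.  For depth 6 the third
#' width is unused (the encoder stops at `w2`); for depth 10 a fourth
#' hidden layer of 4 nodes is inserted between `w3` and the bottleneck.
#'
#' @param learning_rate,depth,w1,w2,w3,dropout option vectors.
#' @return object of class `ae_grid`.
#' @export
ae_hyper_grid <- function(learning_rate = c(1e-4, 5e-4, 1e-3, 2e-3),
                          depth = c(6, 8, 10),
                          w1 = c(64, 96, 128), w2 = c(32, 48, 64),
                          w3 = c(10, 12, 16), dropout = c(0.1, 0.2, 0.3)) {
  g <- list(learning_rate = learning_rate, depth = depth,
            w1 = w1, w2 = w2, w3 = w3, dropout = dropout)
  if (any(vapply(g, length, integer(1)) == 0L)) {
    stop_("every grid option list must be non-empty")
  }
  structure(g, class = "ae_grid")
}

grid_widths <- function(depth, w1, w2, w3) {
  switch(as.character(depth),
         "6" = c(w1, w2),
         "8" = c(w1, w2, w3),
         "10" = c(w1, w2, w3, 4),
         stop_("depth must be 6, 8 or 10"))
}

#' Exhaustive hyperparameter search
#'
#' Trains one autoencoder per grid combination (all with the same seed and
#' split) and returns the configuration minimising holdout reconstruction
#' MSE; ties keep the first combination in enumeration order.
#'
#' @param x gene-by-sample matrix.
#' @param meta sample metadata (for the stratified split).
#' @param grid an [ae_hyper_grid()].
#' @param config_base an [ae_config()] supplying the non-searched settings
#'   (batch size, epochs, patience, seed).
#' @param train_frac training fraction.
#' @return list with `config` (the winning [ae_config()]) and `records`
#'   (one row per combination with its holdout MSE).
#' @export
grid_search <- function(x, meta, grid = ae_hyper_grid(),
                        config_base = ae_config(), train_frac = 0.6) {
  if (!inherits(grid, "ae_grid")) stop_("'grid' must be an ae_hyper_grid()")
  combos <- expand.grid(learning_rate = grid$learning_rate,
                        depth = grid$depth, w1 = grid$w1, w2 = grid$w2,
                        w3 = grid$w3, dropout = grid$dropout,
                        KEEP.OUT.ATTRS = FALSE)
  split <- split_train_holdout(meta, train_frac = train_frac,
                               seed = config_base$seed)
  records <- combos
  records$holdout_mse <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    cfg <- tryCatch(
      ae_config(widths = grid_widths(co$depth, co$w1, co$w2, co$w3),
                dropout = co$dropout, learning_rate = co$learning_rate,
                batch_size = config_base$batch_size,
                max_epochs = config_base$max_epochs,
                patience = config_base$patience,
                min_delta = config_base$min_delta,
                seed = config_base$seed),
      error = function(e) NULL)
    if (is.null(cfg)) next  # e.g. non-decreasing width combination
    fit <- autoencoder(x, meta = NULL, split = split, config = cfg)
    records$holdout_mse[i] <- fit$holdout_mse
    if (is.null(best) || fit$holdout_mse < best$mse) {
      best <- list(config = cfg, mse = fit$holdout_mse, index = i)
    }
  }
  list(config = best$config, records = records, best_index = best$index)
}
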