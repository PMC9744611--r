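# Small fixtures built in code, shared across test files.

make_matrix <- function(ng, ns, seed = 1, mean = 7, sd = 1,
                        genes = sprintf("g%03d", seq_len(ng)),
                        samples = sprintf("s%03d", seq_len(ns))) {
  set.seed(seed)
  matrix(rnorm(ng * ns, mean, sd), ng, ns, dimnames = list(genes, samples))
}

make_meta <- function(samples, group, batch = "b1", cohort = "A") {
  data.frame(sample_id = samples, cohort = cohort, group = group,
             batch = rep_len(batch, length(samples)),
             stringsAsFactors = FALSE)
}

# two-batch fixture with a planted additive shift on batch 2
make_batch_fixture <- function(ng = 50, per_batch = 50, shift = 2,
                               seed = 42) {
  ns <- 2L * per_batch
  x <- make_matrix(ng, ns, seed = seed)
  batch <- rep(c("b1", "b2"), each = per_batch)
  x[, batch == "b2"] <- x[, batch == "b2"] + shift
  meta <- make_meta(colnames(x), group = rep_len(c("case", "control"), ns),
                    batch = batch)
  list(x = x, meta = meta, batch = batch)
}

small_synthetic <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    n_genes = 300, n_shared_deg = 60, frac_concordant = 1,
    n_private_deg = 20, n_cases = 30, n_controls = 30, seed = seed), list(...))
  simulate_cohort_pair(do.call(synthetic_config, args))
}

fast_ae <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    widths = c(32, 16, 4), max_epochs = 150, seed = seed), list(...))
  do.call(ae_config, args)
}

# brute-force upper-tail hypergeometric by pmf enumeration
hyper_tail_enum <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
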