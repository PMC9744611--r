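# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the global stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

stop_ <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop_(sprintf("'%s' must be a single integer >= %d (got %s)",
                  name, min, deparse(substitute(x, parent.frame()))))
  }
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max) {
    stop_(sprintf("'%s' must be a single number in [%s, %s]", name, min, max))
  }
  as.numeric(x)
}

# Validate an expression matrix: numeric, finite, unique dimnames.
validate_expression <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_(sprintf("%s must be a numeric matrix", what))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_(sprintf("%s must have gene rownames and sample colnames", what))
  }
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1L]
    stop_(sprintf("duplicate gene id in %s: '%s'", what, dup))
  }
  if (anyDuplicated(colnames(x))) {
    dup <- colnames(x)[duplicated(colnames(x))][1L]
    stop_(sprintf("duplicate sample id in %s: '%s'", what, dup))
  }
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop_(sprintf("non-finite value in %s at gene '%s', sample '%s'",
                  what, rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  invisible(x)
}

# Validate sample metadata and (optionally) its agreement with a matrix.
validate_metadata <- function(meta, matrix = NULL) {
  need <- c("sample_id", "cohort", "group", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop_("metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    dup <- meta$sample_id[duplicated(meta$sample_id)][1L]
    stop_(sprintf("duplicate sample_id in metadata: '%s'", dup))
  }
  bad <- setdiff(unique(meta$group), c("case", "control"))
  if (length(bad)) {
    stop_(sprintf("unknown group value '%s' (expected 'case' or 'control')", bad[1L]))
  }
  if (!is.null(matrix)) {
    absent <- setdiff(meta$sample_id, colnames(matrix))
    if (length(absent)) {
      stop_(sprintf("sample(s) in metadata but absent from the matrix: %s",
                    paste(absent, collapse = ", ")))
    }
  }
  invisible(meta)
}

# Group means of matrix columns; meta rows matched to columns by sample_id.
group_logfc <- function(x, meta) {
  m <- meta[match(colnames(x), meta$sample_id), ]
  cs <- m$group == "case"
  if (!any(cs) || !all(cs == (m$group == "case"))) {} # no-op; clarity only
  n_case <- sum(cs)
  n_ctrl <- sum(!cs)
  if (n_case == 0L || n_ctrl == 0L) {
    stop_("both a case and a control group are required")
  }
  rowMeans(x[, cs, drop = FALSE]) - rowMeans(x[, !cs, drop = FALSE])
}
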