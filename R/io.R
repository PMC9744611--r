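#' Write an expression matrix as tab-delimited text
#'
#' Layout: first column `gene` holds gene (or probe) identifiers, remaining
#' columns are samples, values are log2-scale expression.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @param path output file.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (and optionally sample metadata)
#'
#' Expects the layout written by [write_expression()]: a header row of sample
#' ids, a first column of gene ids, tab-delimited numeric cells.  Every cell
#' is checked; a non-numeric value, a duplicate gene or sample id, or a
#' metadata sample missing from the matrix raises an error naming the
#' offending row/column.
#'
#' @param path expression TSV.
#' @param metadata_path optional metadata TSV with columns
#'   `sample_id`, `cohort`, `group` (`case`/`control`), `batch`.
#' @return with metadata: `list(expr =, meta =)`; otherwise the matrix.
#' @export
read_expression <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop_("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop_("expression file needs a gene column plus >= 1 sample")
  genes <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      stop_(sprintf(
        "non-numeric value '%s' at gene '%s' (row %d), sample '%s'",
        vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]], bad[1L, 1L],
        colnames(vals)[bad[1L, 2L]]))
    }
    bad <- which(is.na(num), arr.ind = TRUE)
    stop_(sprintf("missing value at gene '%s', sample '%s'",
                  genes[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  dimnames(num) <- list(genes, colnames(vals))
  validate_expression(num)
  if (is.null(metadata_path)) return(num)
  meta <- read_metadata(metadata_path)
  validate_metadata(meta, num)
  list(expr = num, meta = meta)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `cohort`, `group`, `batch`.
#' @return a data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
  validate_metadata(meta)
  meta
}

#' Read a probe-to-gene mapping table
#'
#' @param path TSV with columns `probe_id`, `gene_symbol`; many probes may
#'   map to one gene but probe ids must be unique.
#' @return a data.frame.
#' @export
read_probe_map <- function(path) {
  map <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  miss <- setdiff(c("probe_id", "gene_symbol"), names(map))
  if (length(miss)) stop_("probe map missing column(s): ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(map$probe_id)) {
    stop_("duplicate probe_id in probe map: ",
          map$probe_id[duplicated(map$probe_id)][1L])
  }
  map
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member genes, all
#' tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop_(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    out[[parts[1L]]] <- unique(parts[-(1:2)])
  }
  out
}

#' Read a gene-gene interaction edge list
#'
#' @param path TSV with columns `gene1`, `gene2`, `confidence`
#'   (confidence in `[0, 1]`).
#' @return a data.frame.
#' @export
read_edge_list <- function(path) {
  el <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("gene1", "gene2", "confidence"), names(el))
  if (length(miss)) stop_("edge list missing column(s): ",
                          paste(miss, collapse = ", "))
  el$confidence <- as.numeric(el$confidence)
  if (any(is.na(el$confidence) | el$confidence < 0 | el$confidence > 1)) {
    stop_("edge confidence values must be numeric in [0, 1]")
  }
  el
}

#' Collapse probe-level rows to one row per gene
#'
#' When several probes map to the same gene, the probe with the largest
#' absolute log2 fold change between cases and controls
#' (`mean(case) - mean(control)`) is retained.  Ties keep the
#' lexicographically smallest probe id.  Probes absent from the map are
#' dropped, with a message reporting the count.
#'
#' @param x probe-by-sample matrix.
#' @param map data.frame with `probe_id`, `gene_symbol` (see
#'   [read_probe_map()]).
#' @param meta sample metadata assigning each sample to `case` or `control`.
#' @return gene-by-sample matrix, rows sorted by gene symbol; the retained
#'   probe id per gene is kept in `attr(, "probe")`.
#' @export
collapse_probes <- function(x, map, meta) {
  validate_expression(x, "probe matrix")
  validate_metadata(meta, x)
  m <- meta[match(colnames(x), meta$sample_id), ]
  if (!any(m$group == "case") || !any(m$group == "control")) {
    stop_("both groups must be non-empty to collapse probes")
  }
  gene_of <- stats::setNames(map$gene_symbol, map$probe_id)
  mapped <- rownames(x) %in% names(gene_of)
  if (!all(mapped)) {
    message(sprintf("collapse_probes: dropping %d unmapped probe(s)",
                    sum(!mapped)))
    x <- x[mapped, , drop = FALSE]
    if (nrow(x) == 0L) stop_("no probes left after dropping unmapped probes")
  }
  lfc <- group_logfc(x, meta)
  probe <- rownames(x)
  gene <- unname(gene_of[probe])
  # per-gene argmax of |logFC|; ties -> smallest probe id
  ord <- order(gene, -abs(lfc), probe)
  keep <- ord[!duplicated(gene[ord])]
  keep <- keep[order(gene[keep])]
  out <- x[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  attr(out, "probe") <- stats::setNames(probe[keep], gene[keep])
  out
}

#' Restrict two cohorts to their common gene universe
#'
#' Both matrices are subset to the sorted intersection of their gene sets so
#' that rows align; an empty intersection is an error.
#'
#' @param m1,m2 gene-by-sample matrices.
#' @return list of the two restricted matrices.
#' @export
align_cohorts <- function(m1, m2) {
  validate_expression(m1, "cohort 1")
  validate_expression(m2, "cohort 2")
  common <- sort(intersect(rownames(m1), rownames(m2)))
  if (length(common) == 0L) stop_("cohorts share no genes")
  list(m1[common, , drop = FALSE], m2[common, , drop = FALSE])
}

#' Expand per-study case/control counts to sample-level metadata
#'
#' Utility for building a cohort's metadata from a summary table of its
#' constituent studies (one row per study with the number of cases and
#' controls), as reported in publications.
#'
#' @param counts data.frame with columns `cohort`, `study`, `n_cases`,
#'   `n_controls`; or the path of a TSV with those columns.
#' @return sample-level metadata (`sample_id`, `cohort`, `group`, `batch`),
#'   one row per sample, with the study accession as the batch.
#' @export
expand_study_counts <- function(counts) {
  if (is.character(counts)) {
    counts <- utils::read.delim(counts, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  miss <- setdiff(c("cohort", "study", "n_cases", "n_controls"), names(counts))
  if (length(miss)) stop_("counts table missing column(s): ",
                          paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    n <- r$n_cases + r$n_controls
    data.frame(
      sample_id = sprintf("%s_%s%03d", r$study,
                          rep(c("case", "ctrl"), c(r$n_cases, r$n_controls)),
                          c(seq_len(r$n_cases), seq_len(r$n_controls))),
      cohort = r$cohort,
      group = rep(c("case", "control"), c(r$n_cases, r$n_controls)),
      batch = r$study, stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, rows)
  validate_metadata(meta)
  meta
}
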