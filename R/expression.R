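#' Build an expression set for one gene class
#'
#' Wraps a genes-by-samples table of (already normalised, typically
#' log-scale) expression values together with its gene class and the
#' case/control group labels. The package never re-normalises or transforms
#' the values; correlation-based steps consume them as given.
#'
#' @param data A data frame whose first column holds unique gene identifiers
#'   and whose remaining columns are numeric, one per sample.
#' @param gene_class One of `"miRNA"`, `"lncRNA"`, `"mRNA"`.
#' @param groups A data frame with columns `sample_id` and `group`
#'   (values `"case"` / `"control"`) covering every sample column of `data`.
#'   Samples are reordered to match the order of `groups`.
#' @return A `cer_expr` object: a list with elements `values` (numeric
#'   matrix, genes x samples), `gene_class`, and `samples` (a tibble of
#'   `sample_id`, `group`).
#' @examples
#' expr <- cer_expr(
#'   data.frame(gene_id = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4)),
#'   gene_class = "mRNA",
#'   groups = data.frame(sample_id = c("s1", "s2"),
#'                       group = c("case", "control"))
#' )
#' dim(expr)
#' @export
cer_expr <- function(data, gene_class = c("miRNA", "lncRNA", "mRNA"), groups) {
  gene_class <- match.arg(gene_class)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (ncol(data) < 2L) abort("`data` needs a gene id column plus sample columns")
  gene_ids <- as.character(data[[1L]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    abort(sprintf("duplicated gene id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  vals <- data[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(vals[[j]])))))[1]
      abort(sprintf("non-numeric expression value in column '%s' (row %s)",
                    names(vals)[j], gene_ids[bad %||% 1L]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("duplicated sample id(s): %s",
                  paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  }
  if (!all(is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite expression value at gene '%s', sample '%s'",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  groups <- as_tibble(as.data.frame(groups, stringsAsFactors = FALSE))
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort("`groups` must have columns sample_id and group")
  }
  groups <- groups[, c("sample_id", "group")]
  groups$sample_id <- as.character(groups$sample_id)
  groups$group <- as.character(groups$group)
  if (!all(groups$group %in% c("case", "control"))) {
    abort("group labels must be 'case' or 'control'")
  }
  missing <- setdiff(colnames(m), groups$sample_id)
  if (length(missing)) {
    abort(sprintf("sample(s) missing from group labels: %s",
                  paste(missing, collapse = ", ")))
  }
  groups <- groups[groups$sample_id %in% colnames(m), , drop = FALSE]
  m <- m[, groups$sample_id, drop = FALSE]
  structure(
    list(values = m, gene_class = gene_class, samples = groups),
    class = "cer_expr"
  )
}

#' @export
dim.cer_expr <- function(x) dim(x$values)

#' @export
print.cer_expr <- function(x, ...) {
  cat(sprintf("<cer_expr> %s: %d genes x %d samples (%d case / %d control)\n",
              x$gene_class, nrow(x$values), ncol(x$values),
              sum(x$samples$group == "case"), sum(x$samples$group == "control")))
  invisible(x)
}

#' @export
as_tibble.cer_expr <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$values), .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene_id = rownames(x$values)), out)
}

gene_ids <- function(expr) rownames(expr$values)
sample_ids <- function(expr) colnames(expr$values)

#' Subset an expression set to a gene list
#'
#' @param expr A [cer_expr] object.
#' @param genes Character vector of gene ids to keep (order preserved).
#' @return A `cer_expr` restricted to `genes`.
#' @export
expr_subset <- function(expr, genes) {
  stopifnot(inherits(expr, "cer_expr"))
  missing <- setdiff(genes, gene_ids(expr))
  if (length(missing)) {
    abort(sprintf("gene(s) not in matrix: %s", paste(head(missing, 5), collapse = ", ")))
  }
  expr$values <- expr$values[genes, , drop = FALSE]
  expr
}

#' Check that expression sets share one sample ordering
#'
#' All downstream pair-scoring and sponge inference assumes the miRNA,
#' lncRNA and mRNA matrices are column-aligned; this enforces it.
#'
#' @param ... Two or more [cer_expr] objects.
#' @return Invisibly `TRUE`; errors if sample ids or orders differ.
#' @export
check_alignment <- function(...) {
  exprs <- list(...)
  stopifnot(length(exprs) >= 2L)
  ref <- sample_ids(exprs[[1L]])
  for (e in exprs[-1L]) {
    if (!identical(sample_ids(e), ref)) {
      abort("expression matrices are not sample-aligned; reorder via shared group labels")
    }
  }
  invisible(TRUE)
}
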