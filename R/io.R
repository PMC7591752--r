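# Readers and writers for the on-disk formats: expression TSV, two-column
# interaction TSV, GMT gene sets, edge lists (TSV + GraphML).
#
# Canonical expression dialect: TSV, header row of sample ids, first column
# gene ids. CSV accepted via `delim = ","`. Doubles are written with 17
# significant digits so a write -> read round trip is bit-exact.

#' Read an expression matrix with group labels
#'
#' @param path Path to a delimited genes-by-samples table (first column gene
#'   ids, header row of sample ids).
#' @param gene_class One of `"miRNA"`, `"lncRNA"`, `"mRNA"`.
#' @param labels_path Path to a two-column delimited file mapping
#'   `sample_id` to `group` (`case`/`control`); matrix columns are reordered
#'   to the label file's order.
#' @param delim Field delimiter, `"\t"` (default) or `","`.
#' @return A [cer_expr] object.
#' @export
read_expression <- function(path, gene_class, labels_path, delim = "\t") {
  # base parser: correctly-rounded doubles, so the round trip is bit-exact
  tab <- utils::read.delim(path, sep = delim, check.names = FALSE,
                           colClasses = "character")
  tab[-1L] <- lapply(tab[-1L], as.numeric)
  tab[[1L]] <- as.character(tab[[1L]])
  labs <- utils::read.delim(labels_path, sep = delim, check.names = FALSE,
                            colClasses = "character")
  names(labs)[1:2] <- c("sample_id", "group")
  cer_expr(tab, gene_class = gene_class, groups = labs)
}

#' Write an expression set (matrix + labels)
#'
#' Inverse of [read_expression()]: values are emitted with 17 significant
#' digits so the round trip reproduces doubles exactly.
#'
#' @param expr A [cer_expr] object.
#' @param path Output path for the expression table.
#' @param labels_path Optional output path for the sample label table.
#' @param delim Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, labels_path = NULL, delim = "\t") {
  stopifnot(inherits(expr, "cer_expr"))
  m <- expr$values
  chr <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  out <- cbind(gene_id = rownames(m), as.data.frame(chr, stringsAsFactors = FALSE))
  names(out) <- c("gene_id", colnames(m))
  utils::write.table(out, path, sep = delim, quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(expr$samples, labels_path, sep = delim,
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

header_words <- c("mirna", "mirna_id", "mir", "target", "target_id",
                  "gene", "gene_id", "lncrna", "mrna", "node1", "node2")

#' Read a putative or validated interaction table
#'
#' Two-column delimited file (miRNA id, target id); duplicates are collapsed
#' to set semantics. A header row is detected when both fields match common
#' column-name words; pass `header` explicitly to override.
#'
#' @param path Path to the table.
#' @param target_class `"lncRNA"` or `"mRNA"`; stored per pair.
#' @param header `TRUE`, `FALSE`, or `NULL` (auto-detect).
#' @param provenance Free-text label stored as an attribute.
#' @return A tibble with columns `mirna_id`, `target_id`, `target_class`.
#' @export
read_interactions <- function(path, target_class = c("mRNA", "lncRNA"),
                              header = NULL, provenance = basename(path)) {
  target_class <- match.arg(target_class)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn(sprintf("empty interaction file: %s", path))
    out <- tibble(mirna_id = character(), target_id = character(),
                  target_class = character())
    attr(out, "provenance") <- provenance
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    abort(sprintf("malformed interaction line %d in %s (need 2 tab-separated fields)",
                  bad[1L], path))
  }
  if (is.null(header)) {
    f1 <- tolower(fields[[1L]])
    header <- all(f1[1:2] %in% header_words)
  }
  if (isTRUE(header)) fields <- fields[-1L]
  out <- tibble(
    mirna_id = vapply(fields, `[[`, "", 1L),
    target_id = vapply(fields, `[[`, "", 2L),
    target_class = target_class
  )
  out <- distinct(out)
  attr(out, "provenance") <- provenance
  out
}

#' Write an interaction table
#'
#' @param interactions Tibble with `mirna_id` and `target_id` columns.
#' @param path Output path; tab-separated, with header.
#' @return Invisibly, `path`.
#' @export
write_interactions <- function(interactions, path) {
  utils::write.table(
    distinct(interactions[, c("mirna_id", "target_id")]),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("mirna", "target")
  )
  invisible(path)
}

#' Read gene-set collections from a GMT file
#'
#' @param path Path to a standard GMT file (set name, description, members,
#'   tab-separated).
#' @return Named list of character vectors (one per set).
#' @export
read_gene_sets <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a network as an edge-list TSV and/or GraphML
#'
#' @param edges Data frame whose first two columns are node ids; an optional
#'   third numeric column is kept as the edge weight/score.
#' @param path Output path.
#' @param format `"tsv"` (3-column node1/node2/weight) or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_edges <- function(edges, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) abort("`edges` needs at least two node columns")
  weight <- if (ncol(edges) >= 3L && is.numeric(edges[[3L]])) edges[[3L]] else 1
  out <- data.frame(node1 = as.character(edges[[1L]]),
                    node2 = as.character(edges[[2L]]),
                    weight = weight)
  if (format == "tsv") {
    chr <- out
    chr$weight <- sprintf("%.17g", chr$weight)
    utils::write.table(chr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(out, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
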