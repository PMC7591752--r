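# Generic over-representation analysis: hypergeometric upper-tail test of a
# query gene list against GMT gene-set collections, BH-adjusted within each
# collection.

#' Over-representation analysis of a gene list
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected under hypergeometric sampling from the universe:
#' `p = P(X >= overlap)` with `X ~ Hypergeometric(universe, set, query)`.
#' Sets are intersected with the universe first; sets outside
#' `[min_set, max_set]` (after intersection) are skipped. BH adjustment is
#' applied across all tested sets of the collection.
#'
#' @param query Character vector of gene ids; must be non-empty and a
#'   subset of `universe`.
#' @param universe Character vector of background gene ids (typically all
#'   genes in the expression matrices).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gene_sets()]).
#' @param min_set,max_set Size bounds for tested sets (defaults 5 and 5000).
#' @return Tibble sorted by adjusted p: `set_name`, `overlap_count`,
#'   `set_size`, `query_size`, `universe_size`, `p_value`, `adj_p_value`.
#' @export
ora <- function(query, universe, gene_sets, min_set = 5L, max_set = 5000L) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!length(query)) abort("empty query gene list")
  extra <- setdiff(query, universe)
  if (length(extra)) {
    abort(sprintf("query gene(s) outside the universe: %s",
                  paste(head(extra, 5), collapse = ", ")))
  }
  empty <- tibble(set_name = character(), overlap_count = integer(),
                  set_size = integer(), query_size = integer(),
                  universe_size = integer(), p_value = double(),
                  adj_p_value = double())
  if (!length(gene_sets)) return(empty)
  n_u <- length(universe)
  n_q <- length(query)
  rows <- purrr::imap(gene_sets, function(members, name) {
    set <- intersect(unique(members), universe)
    if (length(set) < min_set || length(set) > max_set) return(NULL)
    ov <- length(intersect(set, query))
    p <- phyper(ov - 1L, length(set), n_u - length(set), n_q,
                lower.tail = FALSE)
    tibble(set_name = name, overlap_count = ov, set_size = length(set),
           query_size = n_q, universe_size = n_u, p_value = min(p, 1))
  })
  out <- bind_rows(rows)
  if (!nrow(out)) return(empty)
  out$adj_p_value <- p.adjust(out$p_value, method = "BH")
  arrange(out, .data$adj_p_value, .data$p_value, .data$set_name)
}
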