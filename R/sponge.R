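# miRNA-sponge (ceRNA) interaction inference by sensitivity partial Pearson
# correlation. A candidate RNA pair (lncRNA/mRNA transcripts sharing miRNA
# regulators) becomes a sponge edge when it passes three constraints:
#   1. significant sharing of common miRNAs (hypergeometric upper tail),
#   2. significant positive expression correlation (one-sided t on r),
#   3. adequate sensitivity correlation SC = rho_ij - rho_ij|n,
# where rho_ij|n is the partial Pearson correlation of the pair given the
# expression of their n shared miRNAs.

#' Hypergeometric test for shared miRNA regulators
#'
#' Tests whether two RNAs share more miRNA regulators than expected when
#' the second regulator set is drawn at random from a universe of
#' `universe_size` miRNAs: `p = P(X >= n_shared)` with
#' `X ~ Hypergeometric(universe_size, |reg_i|, |reg_j|)`.
#'
#' @param regulators_i,regulators_j Character vectors of miRNA ids.
#' @param universe_size Number of miRNAs in the universe (>= both set sizes).
#' @return List with `n_shared` and `p_share`; an empty regulator set gives
#'   `n_shared = 0`, `p_share = 1`.
#' @examples
#' shared_mirna_test(letters[1:5], letters[1:5], 10) # p = 1/252
#' @export
shared_mirna_test <- function(regulators_i, regulators_j, universe_size) {
  regulators_i <- unique(regulators_i)
  regulators_j <- unique(regulators_j)
  universe_size <- assert_count(universe_size, "universe_size", lower = 1L)
  if (universe_size < max(length(regulators_i), length(regulators_j))) {
    abort("universe_size is smaller than a regulator set")
  }
  if (!length(regulators_i) || !length(regulators_j)) {
    return(list(n_shared = 0L, p_share = 1))
  }
  n_shared <- length(intersect(regulators_i, regulators_j))
  p <- phyper(n_shared - 1L, length(regulators_i),
              universe_size - length(regulators_i),
              length(regulators_j), lower.tail = FALSE)
  list(n_shared = n_shared, p_share = min(p, 1))
}

# Partial correlation of variables 1 and 2 of a correlation matrix given
# the rest, via the precision matrix (pseudoinverse when rank-deficient).
pcor_from_cor <- function(C) {
  P <- tryCatch(solve(C), error = function(e) MASS_pinv(C))
  denom <- P[1, 1] * P[2, 2]
  if (denom <= 0) return(NA_real_)
  max(min(-P[1, 2] / sqrt(denom), 1), -1)
}

#' Sensitivity correlation of an RNA pair given shared miRNAs
#'
#' Computes the Pearson correlation of the pair, the partial Pearson
#' correlation conditioned jointly on all shared miRNAs, and their
#' difference, the sensitivity correlation `SC = rho_ij - rho_ij|n`. A
#' large SC means the pair's co-expression is mostly explained by the
#' shared miRNAs — the sponge signature.
#'
#' With an empty conditioning set the partial equals the raw correlation
#' and SC is exactly 0. When the conditioning set is larger than
#' `length(x) - 3` it is truncated to the shared miRNAs most correlated
#' with the elementwise product `x * y` (flagged in the result).
#'
#' @param x,y Numeric expression vectors of the two RNAs (same samples).
#' @param z Matrix of shared-miRNA expression (miRNAs x samples), or
#'   `NULL`/zero rows for no conditioning.
#' @return One-row tibble: `rho_ij`, `rho_ij_given_n`, `sc`,
#'   `n_conditioned`, `truncated`, `degenerate` (constant input; all
#'   statistics `NA`).
#' @export
sensitivity_correlation <- function(x, y, z = NULL) {
  m <- length(x)
  stopifnot(length(y) == m)
  if (is.null(z)) z <- matrix(numeric(0), 0, m)
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  stopifnot(ncol(z) == m)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho_ij = NA_real_, rho_ij_given_n = NA_real_, sc = NA_real_,
                  n_conditioned = 0L, truncated = FALSE, degenerate = TRUE))
  }
  rho <- cor(x, y)
  if (!nrow(z)) {
    return(tibble(rho_ij = rho, rho_ij_given_n = rho, sc = 0,
                  n_conditioned = 0L, truncated = FALSE, degenerate = FALSE))
  }
  truncated <- FALSE
  if (nrow(z) > m - 3L) {
    keep <- order(-abs(suppressWarnings(cor(t(z), x * y))))[seq_len(max(m - 3L, 1L))]
    z <- z[keep, , drop = FALSE]
    truncated <- TRUE
  }
  C <- suppressWarnings(cor(t(rbind(x, y, z))))
  C[is.na(C)] <- 0
  diag(C) <- 1
  partial <- pcor_from_cor(C)
  tibble(rho_ij = rho, rho_ij_given_n = partial, sc = rho - partial,
         n_conditioned = nrow(z), truncated = truncated, degenerate = FALSE)
}

# Full candidate-pair statistics table: every unordered target pair sharing
# >= min_shared miRNA regulators, with sharing test, correlation test and
# sensitivity correlation. The sc_min threshold is NOT applied here so a
# cutoff scan can reuse one table.
sponge_pair_stats <- function(mirna, lnc, mrna, interactions,
                              p_share_max = 0.05, p_corr_max = 0.05,
                              min_shared = 1L) {
  check_alignment(mirna, lnc, mrna)
  mir_ids <- gene_ids(mirna)
  class_of <- c(
    setNames(rep("lncRNA", nrow(lnc$values)), gene_ids(lnc)),
    setNames(rep("mRNA", nrow(mrna$values)), gene_ids(mrna))
  )
  expr_all <- rbind(lnc$values, mrna$values)
  ints <- interactions[interactions$mirna_id %in% mir_ids &
                         interactions$target_id %in% rownames(expr_all), ]
  empty <- tibble(rna_i = character(), rna_j = character(),
                  pair_class = character(), n_shared = integer(),
                  p_share = double(), rho = double(), rho_partial = double(),
                  sc = double())
  if (!nrow(ints)) {
    warn("no candidate sponge pairs (no interactions map onto the expression data)")
    return(empty)
  }
  genes <- sort(unique(ints$target_id))
  universe <- length(mir_ids)
  inc <- matrix(FALSE, length(genes), universe,
                dimnames = list(genes, mir_ids))
  inc[cbind(match(ints$target_id, genes), match(ints$mirna_id, mir_ids))] <- TRUE
  shared_counts <- inc %*% t(inc)
  set_sizes <- rowSums(inc)
  cand <- which(upper.tri(shared_counts) & shared_counts >= min_shared,
                arr.ind = TRUE)
  if (!nrow(cand)) {
    warn("no candidate sponge pairs share the required number of miRNAs")
    return(empty)
  }
  m <- ncol(expr_all)
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    gi <- genes[cand[r, 1]]
    gj <- genes[cand[r, 2]]
    ns <- shared_counts[cand[r, 1], cand[r, 2]]
    p_share <- phyper(ns - 1L, set_sizes[gi], universe - set_sizes[gi],
                      set_sizes[gj], lower.tail = FALSE)
    if (p_share >= p_share_max) next
    x <- expr_all[gi, ]
    y <- expr_all[gj, ]
    if (sd(x) == 0 || sd(y) == 0) next # degenerate pair, skipped
    rho <- cor(x, y)
    if (rho <= 0) next
    tstat <- rho * sqrt((m - 2) / (1 - rho^2))
    p_corr <- pt(tstat, m - 2, lower.tail = FALSE)
    if (p_corr >= p_corr_max) next
    shared <- mir_ids[inc[gi, ] & inc[gj, ]]
    sens <- sensitivity_correlation(x, y, mirna$values[shared, , drop = FALSE])
    pair <- sort(c(gi, gj))
    cls <- sort(unname(class_of[pair]))
    rows[[r]] <- tibble(
      rna_i = pair[1], rna_j = pair[2],
      pair_class = paste(cls, collapse = "-"),
      n_shared = as.integer(ns), p_share = p_share,
      rho = rho, rho_partial = sens$rho_ij_given_n, sc = sens$sc
    )
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    warn("no candidate sponge pairs pass the sharing and correlation constraints")
    return(empty)
  }
  arrange(out, .data$rna_i, .data$rna_j)
}

#' Infer the miRNA-sponge interaction network
#'
#' Applies the three sponge constraints over every pair of lncRNA/mRNA
#' transcripts that shares at least `min_shared` putative miRNA regulators:
#' hypergeometric sharing p below `p_share_max`, positive Pearson
#' correlation with one-sided p below `p_corr_max`, and sensitivity
#' correlation at least `sc_min`. Edges are undirected (`rna_i < rna_j`)
#' and partitioned into lncRNA-lncRNA, lncRNA-mRNA and mRNA-mRNA classes.
#'
#' @param mirna,lnc,mrna Sample-aligned [cer_expr] objects.
#' @param interactions Putative miRNA-target tibble (`mirna_id`,
#'   `target_id`); regulator sets and the miRNA universe are taken from its
#'   overlap with the expression data.
#' @param p_share_max,p_corr_max Raw significance thresholds (default 0.05).
#' @param sc_min Sensitivity-correlation cutoff (default 0.25).
#' @param min_shared Minimum shared-miRNA count for a candidate pair.
#' @return Tibble of sponge edges: `rna_i`, `rna_j`, `pair_class`,
#'   `n_shared`, `p_share`, `rho`, `rho_partial`, `sc`.
#' @export
infer_sponge_network <- function(mirna, lnc, mrna, interactions,
                                 p_share_max = 0.05, p_corr_max = 0.05,
                                 sc_min = 0.25, min_shared = 1L) {
  assert_scalar_number(p_share_max, "p_share_max", 0, 1)
  assert_scalar_number(p_corr_max, "p_corr_max", 0, 1)
  assert_scalar_number(sc_min, "sc_min", -1, 1)
  stats <- sponge_pair_stats(mirna, lnc, mrna, interactions,
                             p_share_max = p_share_max,
                             p_corr_max = p_corr_max,
                             min_shared = min_shared)
  filter(stats, .data$sc >= sc_min)
}
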