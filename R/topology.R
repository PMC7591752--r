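# Degree-distribution power-law fitting (Network-Analyzer convention:
# least squares on log10-log10 raw counts), the SC-cutoff scan that picks
# the sponge network with the best power-law fit, and hub extraction.

#' Fit a power law to a degree distribution
#'
#' Least-squares line on `(log10 k, log10 P(k))` over the observed degrees
#' `k >= 1`, where `P(k)` is the number of nodes with degree `k`. Returns
#' `P(k) = a * k^b` with the coefficient of determination of the log-log
#' regression — the convention under which scale-free fits like
#' `P(k) = 67.593 k^-1.022` are reported, rather than a maximum-likelihood
#' tail fit.
#'
#' @param degrees Vector of positive integer node degrees (the multiset),
#'   or a named table of degree counts.
#' @return A `power_law_fit` object: fields `a`, `b`, `r_squared` and the
#'   degree histogram. See [tidy.power_law_fit()], [autoplot.power_law_fit()].
#' @examples
#' fit_power_law(rep(c(1, 2, 4), c(16, 4, 1))) # a = 16, b = -2, R^2 = 1
#' @export
fit_power_law <- function(degrees) {
  if (is.table(degrees)) {
    k <- as.numeric(names(degrees))
    cnt <- as.numeric(degrees)
  } else {
    degrees <- degrees[degrees >= 1]
    tab <- table(degrees)
    k <- as.numeric(names(tab))
    cnt <- as.numeric(tab)
  }
  keep <- k >= 1 & cnt > 0
  k <- k[keep]
  cnt <- cnt[keep]
  if (length(k) < 3L) abort("degenerate degree distribution (need >= 3 distinct degrees)")
  lx <- log10(k)
  ly <- log10(cnt)
  fit <- lm(ly ~ lx)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(a = 10^unname(coef(fit)[1]), b = unname(coef(fit)[2]),
         r_squared = r2,
         histogram = tibble(degree = k, count = cnt)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> P(k) = %.4g * k^%.4g, R^2 = %.4g (%d degree levels)\n",
              x$a, x$b, x$r_squared, nrow(x$histogram)))
  invisible(x)
}

#' Tidy and glance methods for power-law fits
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return `tidy()`: the degree histogram with fitted counts; `glance()`:
#'   one row with `a`, `b`, `r_squared`, `n_degrees`.
#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  mutate(x$histogram, fitted = x$a * .data$degree^x$b)
}

#' @rdname tidy.power_law_fit
#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, r_squared = x$r_squared,
         n_degrees = nrow(x$histogram))
}

# degrees of all endpoints of an undirected edge table
edge_degrees <- function(edges) {
  table(c(as.character(edges[[1L]]), as.character(edges[[2L]])))
}

#' Scan sensitivity-correlation cutoffs by power-law goodness of fit
#'
#' Infers the sponge network at each SC cutoff of `cutoffs` (the candidate
#' statistics are computed once and re-thresholded) and fits a power law to
#' each network's degree distribution. The selected cutoff maximises the
#' log-log R-squared; ties go to the larger (sparser) cutoff. Cutoffs whose
#' network is degenerate (fewer than 3 distinct degrees) carry `NA` and are
#' skipped in the argmax.
#'
#' @inheritParams infer_sponge_network
#' @param cutoffs Numeric vector of SC cutoffs (default
#'   `seq(0.1, 0.3, by = 0.05)`).
#' @return An `sc_scan` object: `$table` (cutoff, n_edges, a, b,
#'   r_squared), `$selected` (the argmax-R^2 cutoff), `$edges` (the full
#'   candidate edge statistics). See [tidy.sc_scan()].
#' @export
scan_sc_cutoff <- function(mirna, lnc, mrna, interactions,
                           cutoffs = seq(0.1, 0.3, by = 0.05),
                           p_share_max = 0.05, p_corr_max = 0.05,
                           min_shared = 1L) {
  if (!length(cutoffs)) abort("`cutoffs` must be non-empty")
  cutoffs <- sort(unique(cutoffs))
  stats <- sponge_pair_stats(mirna, lnc, mrna, interactions,
                             p_share_max = p_share_max,
                             p_corr_max = p_corr_max,
                             min_shared = min_shared)
  rows <- purrr::map_dfr(cutoffs, function(cut) {
    edges <- filter(stats, .data$sc >= cut)
    fit <- if (nrow(edges)) {
      tryCatch(fit_power_law(as.integer(edge_degrees(edges[, c("rna_i", "rna_j")]))),
               error = function(e) NULL)
    }
    if (is.null(fit)) {
      tibble(cutoff = cut, n_edges = nrow(edges), a = NA_real_,
             b = NA_real_, r_squared = NA_real_)
    } else {
      tibble(cutoff = cut, n_edges = nrow(edges), a = fit$a, b = fit$b,
             r_squared = fit$r_squared)
    }
  })
  ok <- which(!is.na(rows$r_squared))
  if (!length(ok)) abort("all cutoffs give degenerate networks; nothing to select")
  best <- ok[order(-rows$r_squared[ok], -rows$cutoff[ok])][1L]
  structure(list(table = rows, selected = rows$cutoff[best], edges = stats),
            class = "sc_scan")
}

#' @export
print.sc_scan <- function(x, ...) {
  cat(sprintf("<sc_scan> %d cutoffs, selected SC >= %.2f\n",
              nrow(x$table), x$selected))
  print(x$table)
  invisible(x)
}

#' Tidy method for SC-cutoff scans
#'
#' @param x An `sc_scan` object.
#' @param ... Unused.
#' @return The per-cutoff summary table with a `selected` flag column.
#' @method tidy sc_scan
#' @export
tidy.sc_scan <- function(x, ...) {
  mutate(x$table, selected = .data$cutoff == x$selected)
}

#' Select hub nodes by degree
#'
#' Ranks the eligible nodes of a network by degree and keeps the top
#' `ceiling(fraction * n_eligible)` (the hub rule is the top 20% of
#' miRNAs in the regulatory network, resp. sponges in the sponge network).
#' Ties at the boundary are broken by node id (ascending).
#'
#' @param edges Data frame whose first two columns are node ids.
#' @param fraction Fraction of eligible nodes to keep, in (0, 1].
#' @param nodes Optional character vector restricting eligibility (e.g.
#'   only the miRNA side of a bipartite network).
#' @return Tibble `node`, `degree`, ordered (degree desc, node asc).
#' @export
select_hubs <- function(edges, fraction = 0.2, nodes = NULL) {
  assert_scalar_number(fraction, "fraction", lower = 1e-12, upper = 1)
  if (!nrow(edges)) return(tibble(node = character(), degree = integer()))
  deg <- edge_degrees(edges)
  tab <- tibble(node = names(deg), degree = as.integer(deg))
  if (!is.null(nodes)) tab <- filter(tab, .data$node %in% nodes)
  if (!nrow(tab)) return(tibble(node = character(), degree = integer()))
  tab <- arrange(tab, desc(.data$degree), .data$node)
  head(tab, ceiling(fraction * nrow(tab)))
}
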