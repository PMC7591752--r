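# Two-group differential expression: empirical-Bayes moderated t with
# Benjamini-Hochberg adjustment, then deterministic top-N selection.
#
# The moderated t shrinks each gene's pooled variance toward a common prior
# (Smyth-style): s2_tilde = (d0 * s0^2 + dg * s2_g) / (d0 + dg), with the
# prior (s0^2, d0) estimated by matching moments of the log sample variances.
# When the log variances show no excess variability over chi-square sampling
# noise the moments have no solution and the ordinary pooled-variance t is
# used instead.

# Solve trigamma(x) = y by Newton iteration (y > 0).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Moment estimate of the variance prior from per-gene pooled variances.
# Returns list(d0, s0_sq, ok); ok = FALSE means no excess variability.
fit_variance_prior <- function(s2, df) {
  pos <- s2 > 0
  if (sum(pos) < 2L) return(list(d0 = Inf, s0_sq = mean(s2), ok = FALSE))
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  excess <- mean((e - ebar)^2) * length(e) / (length(e) - 1) - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 1e-8) {
    return(list(d0 = Inf, s0_sq = exp(ebar), ok = FALSE))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq, ok = TRUE)
}

#' Moderated-t differential expression for one gene class
#'
#' Computes, per gene, the case-minus-control mean difference on the input
#' scale (`log_fc`), an empirical-Bayes moderated t statistic, its two-sided
#' p-value, and the Benjamini-Hochberg adjusted p-value. Adjustment is
#' applied within the matrix, i.e. per gene class.
#'
#' @param expr A [cer_expr] with at least two samples in each group.
#' @return A tibble with columns `gene_id`, `log_fc`, `t_stat`, `p_value`,
#'   `adj_p_value`, `rank` (1-based by adjusted p, ties broken by larger
#'   `|log_fc|`, then id), and `zero_variance` (flag for genes whose pooled
#'   sample variance was zero; their t uses the shrunken variance only).
#' @examples
#' set.seed(1)
#' expr <- cer_expr(
#'   data.frame(gene_id = paste0("g", 1:20),
#'              matrix(rnorm(20 * 8), 20, dimnames = list(NULL, paste0("s", 1:8)))),
#'   "mRNA",
#'   data.frame(sample_id = paste0("s", 1:8),
#'              group = rep(c("case", "control"), each = 4))
#' )
#' diff_expr(expr)
#' @export
diff_expr <- function(expr) {
  stopifnot(inherits(expr, "cer_expr"))
  grp <- expr$samples$group
  n1 <- sum(grp == "case")
  n0 <- sum(grp == "control")
  if (n1 < 2L || n0 < 2L) {
    abort(sprintf("each group needs >= 2 samples (case: %d, control: %d)", n1, n0))
  }
  m <- expr$values
  x1 <- m[, grp == "case", drop = FALSE]
  x0 <- m[, grp == "control", drop = FALSE]
  mu1 <- rowMeans(x1)
  mu0 <- rowMeans(x0)
  log_fc <- mu1 - mu0
  ss <- rowSums((x1 - mu1)^2) + rowSums((x0 - mu0)^2)
  dg <- n1 + n0 - 2L
  s2 <- ss / dg
  prior <- fit_variance_prior(s2, dg)
  if (prior$ok) {
    s2_tilde <- (prior$d0 * prior$s0_sq + dg * s2) / (prior$d0 + dg)
    df_total <- prior$d0 + dg
  } else {
    # fallback: ordinary pooled-variance two-sample t
    s2_tilde <- s2
    df_total <- dg
    zero <- s2 <= 0
    if (any(zero)) s2_tilde[zero] <- max(mean(s2), .Machine$double.eps)
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n0))
  t_stat <- log_fc / se
  p <- 2 * pt(-abs(t_stat), df = df_total)
  out <- tibble(
    gene_id = rownames(m),
    log_fc = unname(log_fc),
    t_stat = unname(t_stat),
    p_value = unname(p),
    adj_p_value = p.adjust(unname(p), method = "BH"),
    zero_variance = unname(s2 <= 0)
  )
  out <- arrange(out, .data$adj_p_value, desc(abs(.data$log_fc)), .data$gene_id)
  out$rank <- seq_len(nrow(out))
  out
}

#' Select the top differential genes
#'
#' Deterministic top-N selection by (adjusted p ascending, `|log_fc|`
#' descending, gene id ascending) — the ordering [diff_expr()] already
#' applies.
#'
#' @param results A [diff_expr()] result tibble.
#' @param n Number of genes to keep; must not exceed the rows available.
#' @return The first `n` rows of `results` in rank order.
#' @export
select_top <- function(results, n) {
  n <- assert_count(n, "n")
  if (n > nrow(results)) {
    abort(sprintf("requested top %d genes but only %d available", n, nrow(results)))
  }
  ord <- order(results$adj_p_value, -abs(results$log_fc), results$gene_id)
  as_tibble(results[ord, , drop = FALSE][seq_len(n), , drop = FALSE])
}
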