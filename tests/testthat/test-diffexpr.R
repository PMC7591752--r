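make_two_group <- function(n_genes, n_per_group, shift = NULL, seed = 1) {
  withr::local_seed(seed)
  mat <- matrix(rnorm(n_genes * 2 * n_per_group), n_genes)
  if (!is.null(shift)) mat[, seq_len(n_per_group)] <- mat[, seq_len(n_per_group)] + shift
  expr_from_matrix(mat, "mRNA", rep(c("case", "control"), each = n_per_group))
}

test_that("a gene identical in both groups gets log_fc 0 and p near 1", {
  expr <- make_two_group(10, 5, seed = 2)
  expr$values[1, ] <- 3
  res <- diff_expr(expr)
  row <- res[res$gene_id == "g001", ]
  expect_equal(row$log_fc, 0)
  expect_true(row$zero_variance)
  expect_equal(row$p_value, 1)
})

test_that("with equal pooled sample variances the moderated t is the ordinary t", {
  expr <- make_two_group(50, 8, seed = 3)
  grp <- expr$values[, 1:8]
  ctl <- expr$values[, 9:16]
  # rescale each gene so the pooled sample variance is exactly 1
  for (g in 1:50) {
    mu1 <- mean(expr$values[g, 1:8])
    mu0 <- mean(expr$values[g, 9:16])
    ss <- sum((expr$values[g, 1:8] - mu1)^2) + sum((expr$values[g, 9:16] - mu0)^2)
    s <- sqrt(ss / 14)
    expr$values[g, 1:8] <- mu1 + (expr$values[g, 1:8] - mu1) / s
    expr$values[g, 9:16] <- mu0 + (expr$values[g, 9:16] - mu0) / s
  }
  res <- diff_expr(expr)
  # ordinary pooled-variance two-sample t, computed directly
  for (g in c(1, 17, 42)) {
    id <- sprintf("g%03d", g)
    x1 <- expr$values[id, 1:8]
    x0 <- expr$values[id, 9:16]
    sp2 <- (sum((x1 - mean(x1))^2) + sum((x0 - mean(x0))^2)) / 14
    t_ref <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / 8 + 1 / 8))
    expect_equal(res$t_stat[res$gene_id == id], t_ref, tolerance = 1e-10)
  }
})

test_that("moderated t agrees closely with the limma reference on random data", {
  skip_if_not_installed("limma")
  withr::local_seed(8)
  n <- 200
  mat <- matrix(rnorm(n * 12, sd = rep(sqrt(1 / rgamma(n, 4, 4)), 12)), n)
  expr <- expr_from_matrix(mat, "mRNA", rep(c("case", "control"), each = 6))
  res <- diff_expr(expr)
  design <- cbind(1, rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  ref <- fit$t[, 2]
  names(ref) <- sprintf("g%03d", seq_len(n))
  expect_gt(cor(res$t_stat, ref[res$gene_id]), 0.999)
})

test_that("BH adjustment follows the step-up rule and respects input order", {
  expr <- make_two_group(40, 6, seed = 5)
  res <- diff_expr(expr)
  # independent step-up: sort p, p_(i) * G / i, cumulative min from the top
  ord <- order(res$p_value)
  g <- nrow(res)
  stepped <- rev(cummin(rev(res$p_value[ord] * g / seq_len(g))))
  expect_equal(res$adj_p_value[ord], pmin(stepped, 1), tolerance = 1e-12)
  expect_true(all(res$adj_p_value >= res$p_value - 1e-15))
  expect_setequal(res$rank, seq_len(g))
  # permuting gene rows leaves per-gene adjusted values unchanged
  expr2 <- expr
  perm <- sample(nrow(expr2$values))
  expr2$values <- expr2$values[perm, ]
  res2 <- diff_expr(expr2)
  expect_equal(
    res2$adj_p_value[match(res$gene_id, res2$gene_id)],
    res$adj_p_value
  )
})

test_that("under the global null about 5% of raw p-values fall below 0.05", {
  expr <- make_two_group(1000, 30, seed = 11)
  res <- diff_expr(expr)
  frac <- mean(res$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("top-N selection is deterministic with documented tie-breaks", {
  res <- tibble::tibble(
    gene_id = c("gB", "gA", "gC", "gD"),
    log_fc = c(1, -2, 0.5, 3),
    t_stat = 0, p_value = c(0.01, 0.01, 0.2, 0.3),
    adj_p_value = c(0.02, 0.02, 0.3, 0.3),
    zero_variance = FALSE, rank = 1:4
  )
  top2 <- select_top(res, 2)
  # tie on adj_p: larger |log_fc| first
  expect_identical(top2$gene_id, c("gA", "gB"))
  top4 <- select_top(res, 4)
  expect_identical(top4$gene_id, c("gA", "gB", "gD", "gC"))
  expect_error(select_top(res, 5), "only 4")
})

test_that("groups with fewer than two samples are rejected", {
  mat <- matrix(rnorm(12), 4)
  expr <- expr_from_matrix(mat, "mRNA", c("case", "control", "control"))
  expect_error(diff_expr(expr), ">= 2 samples")
})
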