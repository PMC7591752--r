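test_that("shared-miRNA hypergeometric test reproduces analytic values", {
  expect_equal(shared_mirna_test(letters[1:5], letters[1:5], 10)$p_share,
               1 / 252, tolerance = 1e-12)
  res <- shared_mirna_test(c("a", "b"), c("b", "c"), 4)
  expect_equal(res$n_shared, 1L)
  expect_equal(res$p_share, 5 / 6, tolerance = 1e-12)
  expect_equal(shared_mirna_test(c("a"), c("b"), 10)$p_share, 1)
  expect_equal(shared_mirna_test(character(0), c("b"), 10),
               list(n_shared = 0L, p_share = 1))
})

test_that("sensitivity correlation matches the closed-form first-order case", {
  C <- matrix(c(1, 0.8, 0.6,
                0.8, 1, 0.6,
                0.6, 0.6, 1), 3)
  d <- exact_cor_data(C, m = 50, seed = 3)
  res <- sensitivity_correlation(d[, 1], d[, 2], t(d[, 3, drop = FALSE]))
  expect_equal(res$rho_ij, 0.8, tolerance = 1e-10)
  expect_equal(res$rho_ij_given_n, 0.6875, tolerance = 1e-10)
  expect_equal(res$sc, 0.1125, tolerance = 1e-10)
})

test_that("an empty conditioning set gives sc exactly zero", {
  withr::local_seed(61)
  x <- rnorm(40)
  y <- 0.4 * x + rnorm(40)
  res <- sensitivity_correlation(x, y)
  expect_identical(res$sc, 0)
  expect_equal(res$rho_ij_given_n, res$rho_ij)
})

test_that("the shared-driver model recovers population SC 0.5 at m = 2000", {
  withr::local_seed(62)
  m <- 2000
  z <- rnorm(m)
  x <- z + rnorm(m)
  y <- z + rnorm(m)
  res <- sensitivity_correlation(x / sqrt(2), y / sqrt(2), matrix(z, 1))
  expect_lt(abs(res$rho_ij - 0.5), 0.05)
  expect_lt(abs(res$sc - 0.5), 0.05)
})

test_that("partial correlation via precision matrix matches residual regression", {
  withr::local_seed(63)
  for (rep in 1:10) {
    n_cond <- sample(1:4, 1)
    d <- matrix(rnorm(100 * (2 + n_cond)), 100)
    d[, 1] <- d[, 1] + 0.5 * rowSums(d[, 3:(2 + n_cond), drop = FALSE])
    d[, 2] <- d[, 2] + 0.4 * rowSums(d[, 3:(2 + n_cond), drop = FALSE])
    res <- sensitivity_correlation(d[, 1], d[, 2], t(d[, -(1:2), drop = FALSE]))
    r1 <- lm(d[, 1] ~ d[, -(1:2)])$residuals
    r2 <- lm(d[, 2] ~ d[, -(1:2)])$residuals
    expect_equal(res$rho_ij_given_n, cor(r1, r2), tolerance = 1e-10)
    expect_equal(res$sc, res$rho_ij - res$rho_ij_given_n, tolerance = 1e-12)
  }
})

test_that("oversized conditioning sets are truncated and flagged", {
  withr::local_seed(64)
  m <- 12
  z <- matrix(rnorm(15 * m), 15)
  res <- sensitivity_correlation(rnorm(m), rnorm(m), z)
  expect_true(res$truncated)
  expect_equal(res$n_conditioned, m - 3L)
})

make_sponge_fixture <- function(seed = 70, rho_sign = 1) {
  withr::local_seed(seed)
  m <- 120
  z <- matrix(rnorm(3 * m), 3, dimnames = list(paste0("mir", 1:3), NULL))
  shared <- colSums(z) / sqrt(3)
  x <- sqrt(0.5) * shared + sqrt(0.5) * rnorm(m)
  y <- rho_sign * sqrt(0.5) * shared + sqrt(0.5) * rnorm(m)
  lnc <- expr_from_matrix(rbind(ce1 = x, ce2 = y), "lncRNA")
  mrna <- expr_from_matrix(matrix(rnorm(2 * m), 2,
                                  dimnames = list(c("r1", "r2"), NULL)), "mRNA")
  nulls <- matrix(rnorm(7 * m), 7, dimnames = list(paste0("other", 1:7), NULL))
  mirna <- expr_from_matrix(rbind(z, nulls), "miRNA")
  ints <- tidyr::expand_grid(mirna_id = paste0("mir", 1:3),
                             target_id = c("ce1", "ce2"))
  ints$target_class <- "lncRNA"
  list(mirna = mirna, lnc = lnc, mrna = mrna, interactions = ints)
}

test_that("the three constraints gate sponge edges", {
  fx <- make_sponge_fixture()
  net <- infer_sponge_network(fx$mirna, fx$lnc, fx$mrna, fx$interactions,
                              sc_min = 0.25)
  expect_equal(nrow(net), 1L)
  expect_equal(c(net$rna_i, net$rna_j), c("ce1", "ce2"))
  expect_equal(net$pair_class, "lncRNA-lncRNA")
  expect_equal(net$n_shared, 3L)
  expect_equal(net$sc, net$rho - net$rho_partial, tolerance = 1e-12)
  # a negatively correlated pair passing the sharing test is excluded
  fx_neg <- make_sponge_fixture(seed = 71, rho_sign = -1)
  expect_warning(
    net_neg <- infer_sponge_network(fx_neg$mirna, fx_neg$lnc, fx_neg$mrna,
                                    fx_neg$interactions, sc_min = 0.25),
    "constraints"
  )
  expect_equal(nrow(net_neg), 0L)
})

test_that("no shared regulators means an empty network with a warning", {
  fx <- make_sponge_fixture()
  ints <- fx$interactions[fx$interactions$target_id == "ce1", ]
  expect_warning(
    net <- infer_sponge_network(fx$mirna, fx$lnc, fx$mrna, ints),
    "share"
  )
  expect_equal(nrow(net), 0L)
})

test_that("edge count is monotone in the thresholds", {
  sim <- simulate_cernet(sim_config_small(seed = 12))
  scan <- scan_sc_cutoff(sim$mirna, sim$lnc, sim$mrna, sim$interactions,
                         cutoffs = seq(0.05, 0.45, by = 0.05))
  expect_true(all(diff(scan$table$n_edges) <= 0))
  strict <- infer_sponge_network(sim$mirna, sim$lnc, sim$mrna,
                                 sim$interactions, p_share_max = 0.01,
                                 p_corr_max = 0.01, sc_min = 0.25)
  loose <- infer_sponge_network(sim$mirna, sim$lnc, sim$mrna,
                                sim$interactions, sc_min = 0.25)
  expect_lte(nrow(strict), nrow(loose))
  expect_true(all(loose$sc == loose$rho - loose$rho_partial))
})

test_that("planted sponge pairs are recovered with high precision and recall", {
  # the spec-scale stochastic study: 20 true pairs, 200 sharing-only decoys
  comps <- tibble::tibble(
    n_genes = rep(2L, 220),
    sc = c(rep(0.5, 20), rep(1e-9, 200)),
    role = c(rep("true", 20), rep("null", 200))
  )
  comps$sc[comps$role == "null"] <- 0.0001
  cfg <- sim_config(seed = 77, m_case = 150, m_control = 150, pool_size = 46,
                    n_mirna_null = 2, n_lnc_decoy = 2, n_mrna_decoy = 2,
                    n_reg_lnc = 1, n_reg_mrna = 1, components = comps,
                    pin_components = FALSE, decoys_per_target = 1L)
  sim <- simulate_cernet(cfg)
  net <- infer_sponge_network(sim$mirna, sim$lnc, sim$mrna, sim$interactions,
                              sc_min = 0.25)
  truth <- sim$truth$sponge_pairs[sim$truth$sponge_pairs$role == "true", ]
  pred <- pair_key(net$rna_i, net$rna_j)
  tr <- pair_key(truth$rna_i, truth$rna_j)
  recall <- mean(tr %in% pred)
  precision <- if (length(pred)) mean(pred %in% tr) else 0
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.8)
})
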