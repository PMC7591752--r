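test_that("the same seed reproduces the simulation byte for byte", {
  a <- simulate_cernet(sim_config_small(seed = 3))
  b <- simulate_cernet(sim_config_small(seed = 3))
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$truth, b$truth)
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  pa <- write_simulation(a, dir_a)
  pb <- write_simulation(b, dir_b)
  for (i in seq_along(pa)) {
    expect_identical(readLines(pa[i]), readLines(pb[i]))
  }
  c_ <- simulate_cernet(sim_config_small(seed = 4))
  expect_false(identical(a$mirna$values, c_$mirna$values))
})

test_that("infeasible sponge correlation levels are rejected with the bound", {
  comps <- tibble::tibble(n_genes = 2L, sc = 1.2, role = "backbone")
  expect_error(sim_config(components = comps), "at most")
  comps0 <- tibble::tibble(n_genes = 2L, sc = 0, role = "backbone")
  expect_error(sim_config(components = comps0), "0, 1")
})

test_that("a null effect size leaves planted pairs uncorrelated", {
  cfg <- sim_config(seed = 5, beta = 0, m_case = 100, m_control = 100,
                    components = tibble::tibble(n_genes = integer(),
                                                sc = double(),
                                                role = character()),
                    pool_size = 3, n_reg_lnc = 10, n_reg_mrna = 20)
  sim <- simulate_cernet(cfg)
  m <- ncol(sim$mirna$values)
  targets <- rbind(sim$lnc$values, sim$mrna$values)
  reg <- sim$truth$regulation
  cors <- vapply(seq_len(nrow(reg)), function(i) {
    abs(cor(sim$mirna$values[reg$mirna_id[i], ], targets[reg$target_id[i], ]))
  }, numeric(1))
  expect_gte(mean(cors <= 3 / sqrt(m)), 0.99)
})

test_that("planted pair statistics converge to their population values", {
  # pinned components hit the nominal correlation exactly
  sim <- simulate_cernet(sim_config_small(seed = 6))
  tp <- sim$truth$sponge_pairs
  ex <- rbind(sim$lnc$values, sim$mrna$values)
  for (i in c(1, 10, nrow(tp))) {
    expect_equal(cor(ex[tp$rna_i[i], ], ex[tp$rna_j[i], ]), tp$sc[i],
                 tolerance = 1e-8)
  }
  # the unpinned z + noise model converges at m = 2000
  comps <- tibble::tibble(n_genes = 2L, sc = 0.5, role = "true")
  cfg <- sim_config(seed = 8, m_case = 1000, m_control = 1000, pool_size = 3,
                    n_mirna_null = 1, n_lnc_decoy = 1, n_mrna_decoy = 1,
                    n_reg_lnc = 1, n_reg_mrna = 1, components = comps,
                    pin_components = FALSE)
  sim2 <- simulate_cernet(cfg)
  tp2 <- sim2$truth$sponge_pairs
  ex2 <- rbind(sim2$lnc$values, sim2$mrna$values)
  x <- ex2[tp2$rna_i[1], ]
  y <- ex2[tp2$rna_j[1], ]
  shared <- intersect(
    sim2$interactions$mirna_id[sim2$interactions$target_id == tp2$rna_i[1]],
    sim2$interactions$mirna_id[sim2$interactions$target_id == tp2$rna_j[1]]
  )
  res <- sensitivity_correlation(x, y, sim2$mirna$values[shared, , drop = FALSE])
  expect_lt(abs(res$rho_ij - 0.5), 0.05)
  expect_lt(abs(res$sc - 0.5), 0.05)
})

test_that("planted regulations dominate the differential ranking", {
  sim <- simulate_cernet(sim_config_small(seed = 10))
  de <- diff_expr(sim$mirna)
  planted <- sim$truth$differential$gene_id
  top <- select_top(de, 15)$gene_id
  expect_gte(length(intersect(top, planted)), 14)
})
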