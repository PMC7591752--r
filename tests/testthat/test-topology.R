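test_that("a log-log collinear histogram is recovered exactly", {
  fit <- fit_power_law(rep(c(1, 2, 4), c(16, 4, 1)))
  expect_equal(fit$a, 16, tolerance = 1e-10)
  expect_equal(fit$b, -2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_power_law(rep(3, 100)), "degenerate")
  expect_error(fit_power_law(rep(c(1, 2), c(10, 5))), "degenerate")
})

test_that("a preferential-attachment network fits a plausible exponent", {
  g <- igraph::sample_pa(1000, m = 2, directed = FALSE,
                         start.graph = igraph::make_full_graph(3))
  withr::local_seed(80)
  fit <- fit_power_law(igraph::degree(g))
  expect_gte(fit$b, -3)
  expect_lte(fit$b, -1)
  expect_gt(fit$r_squared, 0.5)
})

test_that("hub selection keeps the top degree fraction with id tie-breaks", {
  edges <- tibble::tibble(
    a = c("h", "h", "h", "x", "y"),
    b = c("n1", "n2", "n3", "n4", "n5")
  )
  # degrees: h = 3, x = y = n* = 1
  hubs <- select_hubs(edges, fraction = 0.2)
  expect_equal(nrow(hubs), 2L)
  expect_equal(hubs$node[1], "h")
  expect_equal(hubs$node[2], "n1") # tie at degree 1 -> smallest id
  all_nodes <- select_hubs(edges, fraction = 1)
  expect_equal(nrow(all_nodes), 8L)
  expect_true(all(diff(all_nodes$degree) <= 0))
  # invariant to edge order
  hubs2 <- select_hubs(edges[sample(5), ], fraction = 0.2)
  expect_identical(hubs2, hubs)
  expect_equal(nrow(select_hubs(edges[0, ], 0.2)), 0L)
})

test_that("eligibility filtering restricts hub candidates to one side", {
  edges <- tibble::tibble(a = c("m1", "m1", "m2"), b = c("t1", "t2", "t1"))
  hubs <- select_hubs(edges, fraction = 0.5, nodes = c("m1", "m2"))
  expect_identical(hubs$node, "m1")
})

test_that("the cutoff scan reports one row per cutoff and honours ties", {
  sim <- simulate_cernet(sim_config_small(seed = 9))
  scan <- scan_sc_cutoff(sim$mirna, sim$lnc, sim$mrna, sim$interactions)
  expect_equal(nrow(scan$table), 5L)
  expect_equal(scan$table$cutoff, seq(0.1, 0.3, by = 0.05))
  # both 0.20 and 0.25 keep the full planted backbone; the tie resolves
  # to the larger cutoff
  r2 <- scan$table$r_squared
  expect_equal(r2[3], r2[4], tolerance = 1e-12)
  expect_equal(scan$selected, 0.25)
  single <- scan_sc_cutoff(sim$mirna, sim$lnc, sim$mrna, sim$interactions,
                           cutoffs = 0.2)
  expect_equal(single$selected, 0.2)
  expect_equal(nrow(single$table), 1L)
})
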