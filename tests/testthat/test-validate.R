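hand_scores <- function() {
  scores <- matrix(c(
    0.9, 0.5, 0.5, 0.1,
    0.2, 0.8, 0.6, 0.4
  ), 2, 4, byrow = TRUE,
  dimnames = list(c("mA", "mB"), c("t1", "t2", "t3", "t4")))
  cernet:::new_score_matrix("pearson", scores, scores,
                            matrix(FALSE, 2, 4, dimnames = dimnames(scores)),
                            "mRNA")
}

test_that("validated counts match exhaustive top-K intersection", {
  sm <- hand_scores()
  truth <- tibble::tibble(mirna_id = c("mA", "mA", "mB"),
                          target_id = c("t2", "t4", "t3"))
  rep2 <- rank_and_validate(sm, truth, 2)
  # top-2: mA -> t1, t2 (tie 0.5/0.5 broken toward t2 by id); mB -> t2, t3
  expect_equal(rep2$n_predicted, 4L)
  expect_equal(rep2$n_validated, 2L) # (mA,t2) and (mB,t3)
  # truth superset of all predictions
  all_truth <- tidyr::expand_grid(mirna_id = c("mA", "mB"),
                                  target_id = paste0("t", 1:4))
  rep_all <- rank_and_validate(sm, all_truth, 3)
  expect_equal(rep_all$n_validated, rep_all$n_predicted)
  # empty truth
  expect_equal(rank_and_validate(sm, all_truth[0, ], 2)$n_validated, 0L)
})

test_that("K beyond the target universe is clamped with a warning", {
  sm <- hand_scores()
  expect_warning(rep_big <- rank_and_validate(sm, tibble::tibble(
    mirna_id = character(), target_id = character()), 10), "clamp")
  expect_equal(rep_big$n_predicted, 8L)
})

test_that("the merged network unions per-class top-K predictions", {
  withr::local_seed(41)
  X <- matrix(rnorm(2 * 30), 2, dimnames = list(c("mA", "mB"), NULL))
  Yl <- matrix(rnorm(10 * 30), 10, dimnames = list(paste0("l", 1:10), NULL))
  Ym <- matrix(rnorm(10 * 30), 10, dimnames = list(paste0("r", 1:10), NULL))
  sl <- score_correlation(X, Yl, "pearson", target_class = "lncRNA")
  sm_ <- score_correlation(X, Ym, "pearson", target_class = "mRNA")
  net <- build_target_network(list(sl, sm_), k = 3)
  expect_equal(nrow(net), 12L) # 2 miRNAs x 3 x 2 classes
  full <- build_target_network(list(sl, sm_), k = 10)
  expect_equal(nrow(full), 40L) # complete bipartite per class
})

test_that("best-method selection sums validated counts with stated tie-breaks", {
  val <- tibble::tibble(
    method = rep(c("a_method", "b_method"), each = 2),
    k = rep(c(1, 2), 2), target_class = "mRNA",
    n_predicted = c(10, 20, 8, 16),
    n_validated = c(3, 5, 3, 5)
  )
  # tie on total validated (8 vs 8): fewer predicted wins
  expect_equal(best_method(val), "b_method")
  val$n_predicted <- c(10, 20, 10, 20)
  expect_equal(best_method(val), "a_method") # full tie: name ascending
})
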