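# Independent oracle: the naive alternating-allocation loop, iterated a
# fixed 200 times with no convergence shortcut.
promise_oracle <- function(x_means, z_means, mask) {
  b <- mask / pmax(rowSums(mask), 1)
  a <- b
  for (it in 1:200) {
    a <- x_means * b
    cs <- colSums(a)
    cs[cs == 0] <- 1
    a <- sweep(a, 2, cs, "/")
    b <- sweep(a, 2, z_means, "*")
    rs <- rowSums(b)
    rs[rs == 0] <- 1
    b <- b / rs
  }
  a * b
}

test_that("degenerate and symmetric allocations behave as expected", {
  X <- matrix(2, 1, 4, dimnames = list("m1", NULL))
  Y1 <- matrix(1, 1, 4, dimnames = list("t1", NULL))
  expect_equal(unname(score_promise(X, Y1)$scores[1, 1]), 1)
  Yeq <- matrix(3, 2, 4, dimnames = list(c("t1", "t2"), NULL))
  s <- score_promise(X, Yeq)
  expect_equal(unname(s$scores[1, ]), c(0.5, 0.5)) # A = 0.5 each, B = 1
})

test_that("unequal mean expression drives the first allocation and fixed point", {
  X <- matrix(1, 1, 4, dimnames = list("m1", NULL))
  Y <- matrix(rep(c(3, 1), each = 4), 2, 4, byrow = TRUE,
              dimnames = list(c("t1", "t2"), NULL))
  s <- score_promise(X, Y)
  oracle <- promise_oracle(c(3, 1), 1, matrix(1, 2, 1))
  expect_equal(unname(s$scores[1, ]), as.vector(oracle), tolerance = 1e-10)
  expect_equal(as.vector(oracle), c(0.75, 0.25), tolerance = 1e-10)
})

test_that("the fixed point matches the brute-force iteration on random masks", {
  withr::local_seed(31)
  n_m <- 4
  n_t <- 7
  X <- matrix(abs(rnorm(n_m * 10)) + 0.5, n_m,
              dimnames = list(paste0("m", 1:n_m), NULL))
  Y <- matrix(abs(rnorm(n_t * 10)) + 0.5, n_t,
              dimnames = list(paste0("t", 1:n_t), NULL))
  mask_tbl <- expand.grid(mirna_id = rownames(X), target_id = rownames(Y),
                          stringsAsFactors = FALSE)
  mask_tbl <- mask_tbl[runif(nrow(mask_tbl)) < 0.6, ]
  s <- score_promise(X, Y, candidate_mask = mask_tbl, tol = 1e-12,
                     max_iter = 500)
  mask <- matrix(0, n_t, n_m, dimnames = list(rownames(Y), rownames(X)))
  mask[cbind(match(mask_tbl$target_id, rownames(Y)),
             match(mask_tbl$mirna_id, rownames(X)))] <- 1
  oracle <- promise_oracle(rowMeans(Y), rowMeans(X), mask)
  expect_equal(unname(s$scores), unname(t(oracle)), tolerance = 1e-8)
  # pairs outside the mask never receive probability
  expect_true(all(s$scores[t(mask) == 0] == 0))
})
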