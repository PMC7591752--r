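test_that("worked examples of the correlation family reproduce exactly", {
  x <- matrix(c(1, 2, 3, 4), 1, dimnames = list("m", NULL))
  y <- matrix(c(1, 3, 2, 4), 1, dimnames = list("t", NULL))
  expect_equal(score_correlation(x, y, "pearson")$raw[1, 1], 0.8,
               tolerance = 1e-12)
  k <- score_correlation(matrix(1:3, 1, dimnames = list("m", NULL)),
                         matrix(c(1, 3, 2), 1, dimnames = list("t", NULL)),
                         "kendall")
  expect_equal(k$raw[1, 1], 1 / 3, tolerance = 1e-12)
  expect_equal(hoeffding_d(1:5, 1:5), 1, tolerance = 1e-12)
  withr::local_seed(1)
  v <- rnorm(10)
  expect_equal(distance_correlation(v, v), 1, tolerance = 1e-12)
  withr::local_seed(2)
  w <- rnorm(100)
  expect_equal(mutual_information(w, w, n_bins = 2), log(2), tolerance = 1e-12)
})

test_that("matrix scoring agrees with per-pair oracles on random vectors", {
  withr::local_seed(42)
  n <- 20
  X <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("m", 1:5), NULL))
  Y <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("t", 1:5), NULL))
  sp <- score_correlation(X, Y, "pearson")
  ss <- score_correlation(X, Y, "spearman")
  sk <- score_correlation(X, Y, "kendall")
  sh <- score_correlation(X, Y, "hoeffding")
  sd_ <- score_correlation(X, Y, "dcor")
  for (i in 1:5) for (j in 1:5) {
    expect_equal(sp$raw[i, j], pearson_oracle(X[i, ], Y[j, ]), tolerance = 1e-12)
    expect_equal(ss$raw[i, j], spearman_oracle(X[i, ], Y[j, ]), tolerance = 1e-12)
    expect_equal(sk$raw[i, j], kendall_oracle(X[i, ], Y[j, ]), tolerance = 1e-12)
    expect_equal(sh$raw[i, j], hoeffding_oracle(X[i, ], Y[j, ]), tolerance = 1e-12)
    expect_equal(sd_$raw[i, j], distance_correlation(X[i, ], Y[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("canonical scores are permutation-equivariant in the samples", {
  withr::local_seed(7)
  n <- 30
  X <- matrix(rnorm(3 * n), 3, dimnames = list(paste0("m", 1:3), NULL))
  Y <- matrix(rnorm(4 * n), 4, dimnames = list(paste0("t", 1:4), NULL))
  perm <- sample(n)
  for (method in c("pearson", "spearman", "kendall", "dcor", "hoeffding", "mi")) {
    a <- score_correlation(X, Y, method)$scores
    b <- score_correlation(X[, perm], Y[, perm], method)$scores
    expect_equal(a, b, tolerance = 1e-12, label = method)
  }
})

test_that("rank-based measures are invariant to strictly monotone transforms", {
  withr::local_seed(9)
  n <- 60
  x <- rnorm(n)
  y <- x^2 + rnorm(n, sd = 0.3)
  mono_x <- exp(x)
  mono_y <- y^3
  expect_equal(mutual_information(x, y), mutual_information(mono_x, mono_y),
               tolerance = 1e-12)
  expect_equal(rdc(x, y, seed = 5), rdc(mono_x, mono_y, seed = 5),
               tolerance = 1e-12)
  expect_equal(spearman_oracle(x, y), spearman_oracle(mono_x, mono_y),
               tolerance = 1e-12)
})

test_that("constant genes are flagged with score zero, not dropped", {
  X <- matrix(c(1, 1, 1, 1, 1, 2, 3, 4, 5, 6), 2, byrow = TRUE,
              dimnames = list(c("flat", "ok"), NULL))
  Y <- matrix(rnorm(10), 2, dimnames = list(c("t1", "t2"), NULL))
  for (method in c("pearson", "dcor", "hoeffding", "mi")) {
    sm <- score_correlation(X, Y, method)
    expect_equal(dim(sm), c(2L, 2L))
    expect_true(all(sm$flagged["flat", ]))
    expect_equal(unname(sm$scores["flat", ]), c(0, 0))
    expect_false(any(is.na(sm$scores)))
  }
})

test_that("Hoeffding's D requires at least five samples", {
  X <- matrix(rnorm(4), 1, dimnames = list("m", NULL))
  expect_error(score_correlation(X, X, "hoeffding"), "n >= 5")
  expect_error(hoeffding_d(1:4, 1:4), "n >= 5")
})

test_that("signed ranking mode orders the most negative correlation first", {
  withr::local_seed(3)
  z <- rnorm(50)
  X <- matrix(z, 1, dimnames = list("m", NULL))
  Y <- rbind(neg = -z + rnorm(50, sd = 0.1), pos = z + rnorm(50, sd = 0.1))
  abs_mode <- score_correlation(X, Y, "pearson")
  sgn_mode <- score_correlation(X, Y, "pearson", ranking = "signed")
  expect_true(abs(abs_mode$scores[1, "neg"] - abs_mode$scores[1, "pos"]) < 0.1)
  expect_gt(sgn_mode$scores[1, "neg"], sgn_mode$scores[1, "pos"])
})

test_that("knockdown z-score reproduces the hand-computed example", {
  X <- matrix(c(5, 1, 3), 1, dimnames = list("m", NULL))
  Y <- matrix(c(2, 8, 4), 1, dimnames = list("t", NULL))
  expect_equal(score_zscore(X, Y)$scores[1, 1],
               abs(8 - 14 / 3) / sd(c(2, 8, 4)), tolerance = 1e-12)
  # constant target and a target sitting at its mean in the knockdown sample
  Y2 <- rbind(flat = c(2, 2, 2), atmean = c(4, 3, 2))
  s2 <- score_zscore(X, Y2)
  expect_equal(unname(s2$scores[1, ]), c(0, 0))
  expect_true(s2$flagged[1, "flat"])
})
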