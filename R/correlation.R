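# Correlation-family association measures between miRNAs and targets:
# Pearson, Spearman, Kendall, distance correlation, Hoeffding's D,
# the randomized dependence coefficient (RDC), and plug-in mutual
# information. Signed statistics are canonicalised to |statistic| so that
# "higher is stronger" holds for every method; the signed value is kept in
# the `raw` slot.

#' Hoeffding's D statistic for one pair
#'
#' Rank-based test of bivariate dependence; D lies in \[-0.5, 1\] and equals
#' 1 for a strictly monotone relationship without ties. Assumes (near-)
#' continuous data; ties get average ranks and strict-inequality counts.
#'
#' @param x,y Numeric vectors of equal length `n >= 5`.
#' @return The D statistic (scaled by 30, the classical convention).
#' @examples
#' hoeffding_d(1:5, 1:5) # 1
#' @export
hoeffding_d <- function(x, y) {
  n <- length(x)
  if (n < 5L) abort("Hoeffding's D needs n >= 5")
  r <- rank(x)
  s <- rank(y)
  q <- vapply(seq_len(n), function(i) {
    1 + sum(x < x[i] & y < y[i])
  }, numeric(1))
  d1 <- sum((q - 1) * (q - 2))
  d2 <- sum((r - 1) * (r - 2) * (s - 1) * (s - 2))
  d3 <- sum((r - 2) * (s - 2) * (q - 1))
  30 * ((n - 2) * (n - 3) * d1 + d2 - 2 * (n - 2) * d3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

# All-pairs Hoeffding D between rows of X and rows of Y (samples in columns),
# using per-variable precomputed strict-order indicator matrices.
hoeffding_matrix <- function(X, Y) {
  n <- ncol(X)
  if (n < 5L) abort("Hoeffding's D needs n >= 5")
  lt <- function(v) outer(v, v, ">") # lt[i, j] == TRUE iff v[j] < v[i]
  ltx <- lapply(seq_len(nrow(X)), function(i) lt(X[i, ]))
  lty <- lapply(seq_len(nrow(Y)), function(j) lt(Y[j, ]))
  rx <- t(apply(X, 1, rank))
  ry <- t(apply(Y, 1, rank))
  denom <- n * (n - 1) * (n - 2) * (n - 3) * (n - 4)
  out <- matrix(0, nrow(X), nrow(Y), dimnames = list(rownames(X), rownames(Y)))
  for (i in seq_len(nrow(X))) {
    r <- rx[i, ]
    for (j in seq_len(nrow(Y))) {
      s <- ry[j, ]
      q <- 1 + rowSums(ltx[[i]] & lty[[j]])
      d1 <- sum((q - 1) * (q - 2))
      d2 <- sum((r - 1) * (r - 2) * (s - 1) * (s - 2))
      d3 <- sum((r - 2) * (s - 2) * (q - 1))
      out[i, j] <- 30 * ((n - 2) * (n - 3) * d1 + d2 - 2 * (n - 2) * d3) / denom
    }
  }
  out
}

# Double-centered Euclidean distance matrix of a vector.
dist_centered <- function(v) {
  d <- abs(outer(v, v, "-"))
  rm <- rowMeans(d)
  d - rm - rep(rm, each = length(v)) + mean(d)
}

#' Distance correlation for one pair
#'
#' Standard (Szekely) distance correlation with double-centered distance
#' matrices; 0 iff (empirically) independent in the limit, 1 when `y` is a
#' non-degenerate affine image of `x`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Distance correlation in \[0, 1\]; 0 if either vector is constant.
#' @export
distance_correlation <- function(x, y) {
  a <- dist_centered(x)
  b <- dist_centered(y)
  dvx <- mean(a * a)
  dvy <- mean(b * b)
  if (dvx <= 0 || dvy <= 0) return(0)
  dc2 <- mean(a * b) / sqrt(dvx * dvy)
  sqrt(max(dc2, 0))
}

#' Plug-in mutual information for one pair
#'
#' Maximum-likelihood (plug-in) entropy estimate on an equal-frequency
#' discretisation, in nats. Binning is rank-based, so the estimate is
#' invariant to strictly monotone transforms of either variable.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_bins Number of equal-frequency bins per axis; default
#'   `max(2, floor(sqrt(n / 5)))`.
#' @return Estimated mutual information (nats), `>= 0`.
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  n <- length(x)
  b <- n_bins %||% max(2L, floor(sqrt(n / 5)))
  bx <- ceiling(rank(x, ties.method = "first") * b / n)
  by <- ceiling(rank(y, ties.method = "first") * b / n)
  joint <- table(bx, by) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  max(sum(terms[joint > 0]), 0)
}

# Random sinusoidal feature block for RDC: copula (rank) transform, then
# k random normal projections at scale `s`, passed through sin().
rdc_features <- function(v, k, s) {
  u <- cbind(rank(v, ties.method = "average") / length(v), 1)
  w <- matrix(rnorm(2 * k, sd = s), 2, k)
  sin(u %*% w)
}

#' Randomized dependence coefficient for one pair
#'
#' Largest canonical correlation between random sinusoidal features of the
#' two copula-transformed variables (k features each). Rank-based, hence
#' invariant to strictly monotone transforms. Randomised: pass `seed` for
#' reproducibility.
#'
#' @param x,y Numeric vectors of equal length.
#' @param k Number of random features per variable (default 20).
#' @param s Projection scale (default 1/6).
#' @param seed Optional integer seed for the random projections.
#' @return RDC value in \[0, 1\].
#' @export
rdc <- function(x, y, k = 20L, s = 1 / 6, seed = NULL) {
  with_seed(seed, {
    fx <- rdc_features(x, k, s)
    fy <- rdc_features(y, k, s)
    cc <- tryCatch(cancor(fx, fy)$cor, error = function(e) 0)
    if (!length(cc)) 0 else max(min(cc[1], 1), 0)
  })
}

signed_methods <- c("pearson", "spearman", "kendall")

#' Score miRNA-target pairs with a correlation-family method
#'
#' Computes the chosen association statistic for every miRNA (rows of `X`)
#' against every target (rows of `Y`) over their matched samples. Signed
#' statistics are canonicalised to `|statistic|` by default (`ranking =
#' "absolute"`); `ranking = "signed"` ranks by the most negative value
#' first, the repression-oriented alternative.
#'
#' @param X miRNA [cer_expr] (or genes-by-samples matrix).
#' @param Y Target [cer_expr] (or matrix), sample-aligned with `X`.
#' @param method One of `"pearson"`, `"spearman"`, `"kendall"`, `"dcor"`,
#'   `"hoeffding"`, `"rdc"`, `"mi"`.
#' @param ranking `"absolute"` (default) or `"signed"` (negative-first) for
#'   the signed methods.
#' @param target_class Class label carried into the result.
#' @param n_bins Bin count for `method = "mi"` (default `sqrt(n/5)` rule).
#' @param seed Seed for `method = "rdc"` random projections.
#' @return A `score_matrix`; see [tidy.score_matrix()].
#' @export
score_correlation <- function(X, Y,
                              method = c("pearson", "spearman", "kendall",
                                         "dcor", "hoeffding", "rdc", "mi"),
                              ranking = c("absolute", "signed"),
                              target_class = "mRNA", n_bins = NULL,
                              seed = NULL) {
  method <- match.arg(method)
  ranking <- match.arg(ranking)
  X <- as_values(X)
  Y <- as_values(Y)
  if (ncol(X) != ncol(Y)) abort("X and Y must share the sample columns")
  n <- ncol(X)
  if (n < 5L && method == "hoeffding") abort("Hoeffding's D needs n >= 5 samples")
  const_x <- apply(X, 1, function(v) sd(v) == 0)
  const_y <- apply(Y, 1, function(v) sd(v) == 0)
  raw <- switch(
    method,
    pearson = ,
    spearman = ,
    kendall = suppressWarnings(cor(t(X), t(Y), method = method)),
    dcor = {
      ax <- lapply(seq_len(nrow(X)), function(i) dist_centered(X[i, ]))
      ay <- lapply(seq_len(nrow(Y)), function(j) dist_centered(Y[j, ]))
      dvx <- vapply(ax, function(a) mean(a * a), numeric(1))
      dvy <- vapply(ay, function(a) mean(a * a), numeric(1))
      out <- matrix(0, nrow(X), nrow(Y), dimnames = list(rownames(X), rownames(Y)))
      for (i in seq_len(nrow(X))) {
        if (dvx[i] <= 0) next
        for (j in seq_len(nrow(Y))) {
          if (dvy[j] <= 0) next
          out[i, j] <- sqrt(max(mean(ax[[i]] * ay[[j]]) / sqrt(dvx[i] * dvy[j]), 0))
        }
      }
      out
    },
    hoeffding = hoeffding_matrix(X, Y),
    rdc = with_seed(seed, {
      k <- 20L
      s <- 1 / 6
      fx <- lapply(seq_len(nrow(X)), function(i) rdc_features(X[i, ], k, s))
      fy <- lapply(seq_len(nrow(Y)), function(j) rdc_features(Y[j, ], k, s))
      out <- matrix(0, nrow(X), nrow(Y), dimnames = list(rownames(X), rownames(Y)))
      for (i in seq_len(nrow(X))) {
        for (j in seq_len(nrow(Y))) {
          cc <- tryCatch(cancor(fx[[i]], fy[[j]])$cor, error = function(e) 0)
          out[i, j] <- if (!length(cc)) 0 else max(min(cc[1], 1), 0)
        }
      }
      out
    }),
    mi = {
      b <- n_bins %||% max(2L, floor(sqrt(n / 5)))
      bx <- t(apply(X, 1, function(v) ceiling(rank(v, ties.method = "first") * b / n)))
      by <- t(apply(Y, 1, function(v) ceiling(rank(v, ties.method = "first") * b / n)))
      out <- matrix(0, nrow(X), nrow(Y), dimnames = list(rownames(X), rownames(Y)))
      for (i in seq_len(nrow(X))) {
        for (j in seq_len(nrow(Y))) {
          joint <- table(factor(bx[i, ], 1:b), factor(by[j, ], 1:b)) / n
          px <- rowSums(joint)
          py <- colSums(joint)
          terms <- joint * log(joint / outer(px, py))
          out[i, j] <- max(sum(terms[joint > 0]), 0)
        }
      }
      out
    }
  )
  dimnames(raw) <- list(rownames(X), rownames(Y))
  flagged <- outer(const_x, const_y, "|")
  raw[is.na(raw)] <- 0
  raw[flagged] <- 0
  scores <- if (method %in% signed_methods) {
    if (ranking == "absolute") abs(raw) else -raw
  } else {
    raw
  }
  new_score_matrix(method, scores, raw, flagged, target_class)
}

#' Score miRNA-target pairs by the knockdown Z score
#'
#' Emulates a per-miRNA knockdown: for miRNA i the "knockdown" sample is the
#' one where i is least expressed (ties -> smallest sample index); the score
#' for target j is the standardised displacement of j's expression in that
#' sample, `|y_j(k*) - mean(y_j)| / sd(y_j)` (sample sd).
#'
#' @inheritParams score_correlation
#' @return A `score_matrix` (scores are non-negative; constant targets
#'   score 0 and are flagged).
#' @export
score_zscore <- function(X, Y, target_class = "mRNA") {
  X <- as_values(X)
  Y <- as_values(Y)
  if (ncol(X) != ncol(Y)) abort("X and Y must share the sample columns")
  kstar <- apply(X, 1, which.min)
  mu <- rowMeans(Y)
  sdy <- apply(Y, 1, sd)
  raw <- vapply(seq_len(nrow(X)), function(i) {
    z <- abs(Y[, kstar[i]] - mu) / sdy
    z[sdy == 0] <- 0
    z
  }, numeric(nrow(Y)))
  raw <- t(matrix(raw, nrow = nrow(Y)))
  dimnames(raw) <- list(rownames(X), rownames(Y))
  const_x <- apply(X, 1, function(v) sd(v) == 0)
  flagged <- outer(const_x, sdy == 0, "|")
  raw[flagged] <- 0
  new_score_matrix("zscore", raw, raw, flagged, target_class)
}
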