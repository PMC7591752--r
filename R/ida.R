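# Causal-effect scoring: a stable PC skeleton over the joint
# (miRNA + target) data with Gaussian (Fisher-z) conditional-independence
# tests, followed by a local IDA summary. Edge orientation uses background
# knowledge: miRNAs are upstream of their targets, so miRNA-target edges
# are directed miRNA -> target and only miRNA-miRNA edges stay undirected.
# The score of (miRNA, target) is the minimum absolute regression effect of
# the miRNA on the target over the valid parent sets of the miRNA
# (subsets of its undirected miRNA neighbours that do not create a new
# collider), the usual lower-bound convention.

fisher_z_p <- function(r, n, k) {
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  stat <- sqrt(max(n - k - 3, 1)) * abs(atanh(r))
  2 * pnorm(-stat)
}

partial_cor <- function(C, i, j, S) {
  if (!length(S)) return(C[i, j])
  idx <- c(i, j, S)
  P <- tryCatch(solve(C[idx, idx]), error = function(e) MASS_pinv(C[idx, idx]))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Moore-Penrose pseudoinverse via SVD (rank-deficient conditioning sets).
MASS_pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Stable-PC skeleton on a correlation matrix. Returns a logical adjacency.
pc_skeleton <- function(C, n, alpha = 0.05, max_order = 3L) {
  p <- ncol(C)
  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  # order 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (fisher_z_p(C[i, j], n, 0) > alpha) adj[i, j] <- adj[j, i] <- FALSE
  }
  for (ord in seq_len(max_order)) {
    snapshot <- adj
    if (!any(snapshot)) break
    pairs <- which(snapshot & upper.tri(snapshot), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]
      j <- pairs[r, 2]
      if (!adj[i, j]) next
      for (anchor in c(i, j)) {
        other <- if (anchor == i) j else i
        nb <- setdiff(which(snapshot[anchor, ]), other)
        if (length(nb) < ord) next
        subsets <- if (length(nb) == ord) list(nb) else
          utils::combn(nb, ord, simplify = FALSE)
        for (S in subsets) {
          r_p <- partial_cor(C, i, j, S)
          if (fisher_z_p(r_p, n, ord) > alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            break
          }
        }
        if (!adj[i, j]) break
      }
    }
  }
  adj
}

# Minimum |effect| of variable i on j over valid parent sets drawn from
# `sibs` (undirected neighbours of i), given covariance Sigma and skeleton.
local_ida_effect <- function(Sigma, adj, i, j, sibs) {
  best <- Inf
  best_signed <- 0
  sets <- list(integer(0))
  if (length(sibs)) {
    for (k in seq_along(sibs)) {
      sets <- c(sets, utils::combn(sibs, k, simplify = FALSE))
    }
  }
  for (S in sets) {
    if (length(S) > 1L) {
      # orienting S -> i must not create a new collider: members pairwise adjacent
      ok <- all(utils::combn(S, 2, function(pr) adj[pr[1], pr[2]]))
      if (!ok) next
    }
    idx <- c(i, S)
    beta <- tryCatch(
      solve(Sigma[idx, idx, drop = FALSE], Sigma[idx, j])[1],
      error = function(e) NA_real_
    )
    if (is.na(beta)) next
    if (abs(beta) < best) {
      best <- abs(beta)
      best_signed <- beta
    }
  }
  if (!is.finite(best)) best_signed <- 0
  best_signed
}

#' Score miRNA-target pairs by causal-effect lower bounds (IDA)
#'
#' Learns a stable-PC skeleton over the pooled miRNA + target data with
#' Fisher-z conditional-independence tests at level `alpha`, orients
#' miRNA-target edges by regulatory direction, and scores each adjacent
#' pair by the minimum absolute causal effect over the valid parent sets of
#' the miRNA (local IDA). Non-adjacent pairs score 0.
#'
#' @inheritParams score_correlation
#' @param alpha Level for the conditional-independence tests (default 0.05).
#' @param max_order Largest conditioning-set size searched by PC (default 3).
#' @param max_parents Cap on the number of sibling miRNAs enumerated per
#'   parent-set search; the strongest-correlated siblings are kept.
#' @param var_budget Maximum variables handled in one PC run; larger
#'   problems are chunked over targets with a warning.
#' @return A `score_matrix` of minimum absolute effects (`raw` holds the
#'   signed effect attaining the minimum magnitude).
#' @export
score_ida <- function(X, Y, alpha = 0.05, target_class = "mRNA",
                      max_order = 3L, max_parents = 8L, var_budget = 300L) {
  X <- as_values(X)
  Y <- as_values(Y)
  if (ncol(X) != ncol(Y)) abort("X and Y must share the sample columns")
  n_m <- nrow(X)
  if (n_m + nrow(Y) > var_budget) {
    warn(sprintf("IDA problem exceeds %d variables; chunking targets", var_budget))
    chunk_size <- max(1L, var_budget - n_m)
    chunks <- split(seq_len(nrow(Y)), ceiling(seq_len(nrow(Y)) / chunk_size))
    parts <- lapply(chunks, function(idx) {
      score_ida(X, Y[idx, , drop = FALSE], alpha = alpha,
                target_class = target_class, max_order = max_order,
                max_parents = max_parents, var_budget = .Machine$integer.max)
    })
    raw <- do.call(cbind, lapply(parts, function(p) p$raw))
    scores <- do.call(cbind, lapply(parts, function(p) p$scores))
    flagged <- do.call(cbind, lapply(parts, function(p) p$flagged))
    return(new_score_matrix("ida", scores, raw, flagged, target_class))
  }
  dat <- rbind(X, Y)
  n <- ncol(dat)
  const <- apply(dat, 1, function(v) sd(v) == 0)
  C <- suppressWarnings(cor(t(dat)))
  C[is.na(C)] <- 0
  diag(C) <- 1
  Sigma <- cov(t(dat))
  adj <- pc_skeleton(C, n, alpha = alpha, max_order = max_order)
  adj[const, ] <- FALSE
  adj[, const] <- FALSE
  raw <- matrix(0, n_m, nrow(Y), dimnames = list(rownames(X), rownames(Y)))
  for (i in seq_len(n_m)) {
    sibs <- which(adj[i, seq_len(n_m)])
    if (length(sibs) > max_parents) {
      sibs <- sibs[order(-abs(C[i, sibs]))][seq_len(max_parents)]
    }
    for (jj in seq_len(nrow(Y))) {
      j <- n_m + jj
      if (!adj[i, j]) next
      raw[i, jj] <- local_ida_effect(Sigma, adj, i, j, sibs)
    }
  }
  flagged <- outer(const[seq_len(n_m)], const[-seq_len(n_m)], "|")
  new_score_matrix("ida", abs(raw), raw, flagged, target_class)
}
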