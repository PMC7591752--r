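# Shared fixtures and independent oracles. Everything here is built in
# code at test time; the oracles deliberately use different algorithmic
# routes than the package implementation.

# Data matrix (m x p) whose sample correlation matrix equals C exactly:
# orthonormalised Gaussian scores times a Cholesky factor of C.
exact_cor_data <- function(C, m, seed = 1) {
  p <- ncol(C)
  stopifnot(m > p + 1)
  withr::local_seed(seed)
  b <- matrix(rnorm(m * p), m, p)
  b <- sweep(b, 2, colMeans(b))
  q <- qr.Q(qr(b))
  q %*% chol(C)
}

# cer_expr from a genes-x-samples matrix with half/half groups.
expr_from_matrix <- function(mat, gene_class = "mRNA",
                             groups = rep(c("case", "control"),
                                          length.out = ncol(mat))) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  samples <- sprintf("s%03d", seq_len(ncol(mat)))
  colnames(mat) <- samples
  cer_expr(
    data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
    gene_class = gene_class,
    groups = data.frame(sample_id = samples, group = groups)
  )
}

# --- brute-force association oracles (O(n^2) pair counting) ---

pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) / n - mean(x) * mean(y)
  sxx <- sum(x^2) / n - mean(x)^2
  syy <- sum(y^2) / n - mean(y)^2
  sxy / sqrt(sxx * syy)
}

spearman_oracle <- function(x, y) pearson_oracle(rank(x), rank(y))

kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- 0
  disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(n, 2)
}

# Hoeffding D via explicit per-point loops over the defining counts.
hoeffding_oracle <- function(x, y) {
  n <- length(x)
  r <- rank(x)
  s <- rank(y)
  d1 <- d2 <- d3 <- 0
  for (i in seq_len(n)) {
    qi <- 1 + sum(x < x[i] & y < y[i])
    d1 <- d1 + (qi - 1) * (qi - 2)
    d2 <- d2 + (r[i] - 1) * (r[i] - 2) * (s[i] - 1) * (s[i] - 2)
    d3 <- d3 + (r[i] - 2) * (s[i] - 2) * (qi - 1)
  }
  30 * ((n - 2) * (n - 3) * d1 + d2 - 2 * (n - 2) * d3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

# --- brute-force maximal bicliques via bitmask subset closure ---

random_bipartite <- function(n_left, n_right, density, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  e <- expand.grid(mirna_id = sprintf("m%02d", seq_len(n_left)),
                   target_id = sprintf("t%02d", seq_len(n_right)),
                   stringsAsFactors = FALSE)
  e[runif(nrow(e)) < density, , drop = FALSE]
}

brute_bicliques <- function(edges) {
  left <- sort(unique(edges$mirna_id))
  right <- sort(unique(edges$target_id))
  nl <- length(left)
  # bitmask of left neighbours per right vertex
  rmask <- vapply(right, function(t) {
    sum(bitwShiftL(1L, which(left %in% edges$mirna_id[edges$target_id == t]) - 1L))
  }, integer(1))
  full <- sum(bitwShiftL(1L, seq_len(nl) - 1L))
  seen <- new.env(parent = emptyenv())
  for (sub in seq_len(2^length(right) - 1L)) {
    in_sub <- bitwAnd(sub, bitwShiftL(1L, seq_along(right) - 1L)) != 0L
    lmask <- full
    for (t in which(in_sub)) lmask <- bitwAnd(lmask, rmask[t])
    if (lmask == 0L) next
    # right closure of lmask
    rc <- which(vapply(rmask, function(m) bitwAnd(m, lmask) == lmask, TRUE))
    key <- paste(lmask, paste(rc, collapse = ","))
    if (is.null(seen[[key]])) {
      seen[[key]] <- list(
        left = left[bitwAnd(lmask, bitwShiftL(1L, seq_len(nl) - 1L)) != 0L],
        right = right[rc]
      )
    }
  }
  out <- as.list(seen)
  unname(out[order(names(out))])
}

biclique_keys <- function(left_right_list) {
  sort(vapply(left_right_list, function(b) {
    paste(paste(sort(b$left), collapse = ";"),
          paste(sort(b$right), collapse = ";"), sep = "|")
  }, ""))
}

module_keys <- function(modules) sort(paste(modules$mirnas, modules$targets, sep = "|"))

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b))
}
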