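# Probabilistic interaction signature: targets compete for each miRNA and
# miRNAs compete for each target, iterated to a fixed point. The two views
# are proportional-allocation matrices over the admissible (masked) pairs:
#   A(t, m) ∝ x_t * B(t, m), normalised over targets t for each miRNA m
#   B(t, m) ∝ z_m * A(t, m), normalised over miRNAs m for each target t
# where x_t and z_m are mean expression levels shifted to be non-negative.
# The final score of a pair is A * B elementwise.

#' Score miRNA-target pairs by competitive probabilistic allocation
#'
#' @inheritParams score_correlation
#' @param candidate_mask Optional interaction tibble (`mirna_id`,
#'   `target_id`) restricting the admissible pairs; default all pairs.
#' @param tol Convergence tolerance on the L-infinity change of both views
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 200); non-convergence returns the
#'   last iterate with a warning and `converged = FALSE` in the object.
#' @return A `score_matrix` with the fixed-point allocation products.
#' @export
score_promise <- function(X, Y, candidate_mask = NULL, target_class = "mRNA",
                          tol = 1e-6, max_iter = 200L) {
  X <- as_values(X)
  Y <- as_values(Y)
  if (ncol(X) != ncol(Y)) abort("X and Y must share the sample columns")
  z <- rowMeans(X)
  x <- rowMeans(Y)
  z <- z - min(0, min(z))
  x <- x - min(0, min(x))
  if (all(z == 0)) z[] <- 1
  if (all(x == 0)) x[] <- 1
  n_m <- nrow(X)
  n_t <- nrow(Y)
  mask <- matrix(TRUE, n_t, n_m, dimnames = list(rownames(Y), rownames(X)))
  if (!is.null(candidate_mask)) {
    mask[] <- FALSE
    keep <- candidate_mask$mirna_id %in% rownames(X) &
      candidate_mask$target_id %in% rownames(Y)
    mask[cbind(match(candidate_mask$target_id[keep], rownames(Y)),
               match(candidate_mask$mirna_id[keep], rownames(X)))] <- TRUE
  }
  norm_cols <- function(m) {
    cs <- colSums(m)
    cs[cs == 0] <- 1
    sweep(m, 2, cs, "/")
  }
  norm_rows <- function(m) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m / rs
  }
  b <- norm_rows(mask * 1)
  a <- norm_cols(x * b)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a_new <- norm_cols(x * b)
    b_new <- norm_rows(sweep(a_new, 2, z, "*"))
    delta <- max(abs(a_new - a), abs(b_new - b))
    a <- a_new
    b <- b_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warn("promise allocation did not converge; returning last iterate")
  scores <- t(a * b)
  flagged <- t(!mask)
  new_score_matrix("promise", scores, scores, flagged, target_class,
                   extra = list(converged = converged, iterations = it))
}
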