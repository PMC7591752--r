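# Markov clustering (MCL) of an undirected weighted network: alternate
# expansion (matrix squaring) and inflation (elementwise power + column
# renormalisation) of the column-stochastic transition matrix with self
# loops, prune small entries, read clusters off the attractor structure.

#' Cluster an undirected network with the Markov cluster algorithm
#'
#' Deterministic MCL: the adjacency matrix (plus unit self loops) is column
#' normalised, then expansion (power 2) and inflation are alternated,
#' entries below `prune` are zeroed, and iteration stops when the largest
#' entrywise change drops below `tol` (or at `max_iter`, with a warning).
#' Clusters are the attractor systems of the limit matrix; in the rare
#' overlapping case a node is assigned to the larger cluster (ties:
#' lexicographically first).
#'
#' @param edges Data frame whose first two columns are node ids; an
#'   optional third numeric column gives edge weights (default 1).
#' @param inflation Inflation exponent, > 1 (default 2).
#' @param min_size Drop clusters smaller than this (default 3, the sponge
#'   module rule; use 1 to keep everything).
#' @param self_loops Self-loop weight added to every node (default 1).
#' @param prune Entry threshold (default 1e-5).
#' @param tol Convergence threshold on the L-infinity change (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return Long tibble: `module_id`, `member`, `module_size`; modules
#'   ordered by size (desc) then first member.
#' @examples
#' tri2 <- data.frame(a = c("a", "b", "c", "x", "y", "z"),
#'                    b = c("b", "c", "a", "y", "z", "x"))
#' mcl_cluster(tri2)
#' @export
mcl_cluster <- function(edges, inflation = 2, min_size = 3L, self_loops = 1,
                        prune = 1e-5, tol = 1e-6, max_iter = 100L) {
  assert_scalar_number(inflation, "inflation", lower = 1 + 1e-9)
  min_size <- assert_count(min_size, "min_size")
  edges <- as.data.frame(edges)
  if (!nrow(edges)) abort("empty network")
  n1 <- as.character(edges[[1L]])
  n2 <- as.character(edges[[2L]])
  w <- if (ncol(edges) >= 3L && is.numeric(edges[[3L]])) abs(edges[[3L]]) else
    rep(1, nrow(edges))
  nodes <- sort(unique(c(n1, n2)))
  p <- length(nodes)
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  A[cbind(match(n1, nodes), match(n2, nodes))] <- w
  A <- pmax(A, t(A))
  diag(A) <- diag(A) + self_loops
  norm_cols <- function(m) {
    cs <- colSums(m)
    cs[cs == 0] <- 1
    sweep(m, 2, cs, "/")
  }
  M <- norm_cols(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- norm_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warn("MCL did not converge; clustering the last iterate")
  eps <- prune
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- unique(apply(M, 2, which.max))
  # attractor systems: attractors linked by flow between them
  sys_id <- seq_along(attractors)
  for (a in seq_along(attractors)) for (b in seq_along(attractors)) {
    if (a < b && (M[attractors[a], attractors[b]] > eps ||
                  M[attractors[b], attractors[a]] > eps)) {
      old <- sys_id[b]
      sys_id[sys_id == old] <- sys_id[a]
    }
  }
  systems <- split(attractors, sys_id)
  # membership: column j flows into the attractors with M[a, j] > eps
  member_sets <- lapply(systems, function(atts) {
    which(colSums(M[atts, , drop = FALSE] > eps) > 0)
  })
  # resolve overlaps: larger cluster wins, ties -> first member order
  sizes <- lengths(member_sets)
  ord <- order(-sizes, vapply(member_sets, function(s) nodes[min(s)], ""))
  assigned <- rep(NA_integer_, p)
  for (s in ord) {
    take <- member_sets[[s]][is.na(assigned[member_sets[[s]]])]
    assigned[take] <- s
  }
  # any node never attracted: follow its column's strongest flow
  for (j in which(is.na(assigned))) {
    assigned[j] <- assigned[which.max(M[, j])]
  }
  clusters <- split(nodes, assigned)
  clusters <- clusters[lengths(clusters) >= min_size]
  if (!length(clusters)) {
    return(tibble(module_id = integer(), member = character(),
                  module_size = integer()))
  }
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters), vapply(clusters, `[[`, "", 1L))
  clusters <- clusters[ord]
  tibble(
    module_id = rep(seq_along(clusters), lengths(clusters)),
    member = unlist(clusters, use.names = FALSE),
    module_size = rep(lengths(clusters), lengths(clusters))
  )
}
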