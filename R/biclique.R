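# Maximal biclique enumeration on the bipartite miRNA-target network,
# branch-and-bound in the style of the MBEA/iMBEA family: the recursion
# extends the right-hand (target) side, keeps the left side as the common
# neighbourhood, and uses an excluded set to reject non-maximal branches.
# Correctness is defined by the brute-force subset oracle in the tests.

# rn: named list, right vertex -> character vector of left neighbours.
# Invariant on entry: L is the common left neighbourhood of R. Candidates P
# extend R; Q holds right vertices already processed at an ancestor, used
# to reject non-maximal branches. Results are appended to environment `env`.
mbea_recurse <- function(rn, L, R, P, Q, min_left, min_right, env) {
  while (length(P)) {
    x <- P[1L]
    P <- P[-1L]
    L2 <- intersect(L, rn[[x]])
    if (length(L2) >= min_left) {
      R2 <- c(R, x)
      P2 <- character(0)
      Q2 <- character(0)
      maximal <- TRUE
      for (v in Q) {
        ncommon <- length(intersect(L2, rn[[v]]))
        if (ncommon == length(L2)) {
          maximal <- FALSE
          break
        }
        if (ncommon > 0) Q2 <- c(Q2, v)
      }
      if (maximal) {
        for (v in P) {
          ncommon <- length(intersect(L2, rn[[v]]))
          if (ncommon == length(L2)) {
            R2 <- c(R2, v)
          } else if (ncommon > 0) {
            P2 <- c(P2, v)
          }
        }
        if (length(R2) >= min_right) {
          env$acc[[length(env$acc) + 1L]] <-
            list(left = sort(L2), right = sort(R2))
        }
        if (length(P2) && length(R2) + length(P2) >= min_right) {
          mbea_recurse(rn, L2, R2, P2, Q2, min_left, min_right, env)
        }
      }
    }
    Q <- c(Q, x)
  }
  invisible(NULL)
}

#' Enumerate maximal bicliques of a miRNA-target network
#'
#' A biclique is a miRNA set and a target set with every cross pair present
#' in the network; maximal means no vertex of either side can be added.
#' Enumeration is exact and order-deterministic (modules sorted by
#' miRNA-count x target-count descending, then lexicographically). Optional
#' minima prune the search, which keeps dense networks tractable; the
#' result then equals the full enumeration filtered by
#' [filter_modules()].
#'
#' @param network Edge tibble with `mirna_id` and `target_id` columns.
#' @param min_mirnas,min_targets Minimum side sizes enforced during the
#'   search (default 1: all maximal bicliques with both sides non-empty).
#' @return Tibble with one module per row: `module_id`, `mirnas`,
#'   `targets` (`;`-joined, sorted), `n_mirna`, `n_target`.
#' @examples
#' net <- tibble::tibble(mirna_id = c("a", "a", "b", "b", "b"),
#'                       target_id = c("t1", "t2", "t1", "t2", "t3"))
#' enumerate_maximal_bicliques(net)
#' @export
enumerate_maximal_bicliques <- function(network, min_mirnas = 1L,
                                        min_targets = 1L) {
  min_mirnas <- assert_count(min_mirnas, "min_mirnas")
  min_targets <- assert_count(min_targets, "min_targets")
  edges <- distinct(tibble(mirna_id = as.character(network$mirna_id),
                           target_id = as.character(network$target_id)))
  empty <- tibble(module_id = integer(), mirnas = character(),
                  targets = character(), n_mirna = integer(),
                  n_target = integer())
  if (!nrow(edges)) return(empty)
  rn <- lapply(split(edges$mirna_id, edges$target_id),
               function(v) sort(unique(v)))
  left_all <- sort(unique(edges$mirna_id))
  right_all <- sort(names(rn))
  env <- new.env(parent = emptyenv())
  env$acc <- list()
  mbea_recurse(rn, left_all, character(0), right_all, character(0),
               min_mirnas, min_targets, env)
  acc <- env$acc
  if (!length(acc)) return(empty)
  out <- tibble(
    mirnas = vapply(acc, function(m) paste(m$left, collapse = ";"), ""),
    targets = vapply(acc, function(m) paste(m$right, collapse = ";"), ""),
    n_mirna = vapply(acc, function(m) length(m$left), 1L),
    n_target = vapply(acc, function(m) length(m$right), 1L)
  )
  out <- distinct(out)
  out <- arrange(out, desc(.data$n_mirna * .data$n_target),
                 desc(.data$n_mirna), .data$mirnas, .data$targets)
  out$module_id <- seq_len(nrow(out))
  select(out, "module_id", "mirnas", "targets", "n_mirna", "n_target")
}

#' Filter biclique modules by side minima
#'
#' Keeps modules with at least `min_left` miRNAs and `min_right` targets
#' (the regulatory-module rule is 3 and 3).
#'
#' @param modules Tibble from [enumerate_maximal_bicliques()].
#' @param min_left,min_right Side minima (>= 1).
#' @return The filtered tibble, module ids renumbered.
#' @export
filter_modules <- function(modules, min_left = 3L, min_right = 3L) {
  min_left <- assert_count(min_left, "min_left")
  min_right <- assert_count(min_right, "min_right")
  out <- filter(modules, .data$n_mirna >= min_left, .data$n_target >= min_right)
  out$module_id <- seq_len(nrow(out))
  out
}
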