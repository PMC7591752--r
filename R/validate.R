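# Ranking per-miRNA targets, benchmarking methods against a ground-truth
# interaction set, and assembling the merged predicted network.

all_methods <- c("pearson", "spearman", "kendall", "dcor", "hoeffding",
                 "rdc", "mi", "lasso", "elasticnet", "ida", "zscore",
                 "promise")

#' Score miRNA-target pairs with any of the twelve methods
#'
#' Thin dispatcher over [score_correlation()], [score_regression()],
#' [score_ida()], [score_zscore()] and [score_promise()].
#'
#' @inheritParams score_correlation
#' @param method One of `"pearson"`, `"spearman"`, `"kendall"`, `"dcor"`,
#'   `"hoeffding"`, `"rdc"`, `"mi"`, `"lasso"`, `"elasticnet"`, `"ida"`,
#'   `"zscore"`, `"promise"`.
#' @param candidate_mask Admissible pairs for `"promise"`.
#' @param ... Passed to the underlying scorer.
#' @export
score_targets <- function(X, Y, method, target_class = "mRNA",
                          candidate_mask = NULL, seed = NULL, ...) {
  method <- match.arg(method, all_methods)
  if (method %in% c("pearson", "spearman", "kendall", "dcor", "hoeffding",
                    "rdc", "mi")) {
    score_correlation(X, Y, method = method, target_class = target_class,
                      seed = seed, ...)
  } else if (method %in% c("lasso", "elasticnet")) {
    score_regression(X, Y, method = method, target_class = target_class,
                     seed = seed, ...)
  } else if (method == "ida") {
    score_ida(X, Y, target_class = target_class, ...)
  } else if (method == "zscore") {
    score_zscore(X, Y, target_class = target_class)
  } else {
    score_promise(X, Y, candidate_mask = candidate_mask,
                  target_class = target_class, ...)
  }
}

# Top-k target ids for one miRNA row of a score matrix (ties -> id asc).
top_k_idx <- function(scores_row, ids, k) {
  ord <- order(-scores_row, ids)
  ids[ord[seq_len(min(k, length(ids)))]]
}

#' Rank targets per miRNA and count ground-truth hits
#'
#' For every miRNA takes its top-`k` targets by canonical score (ties
#' broken by target id) and counts how many of the predicted pairs appear
#' in the validated interaction set — the benchmarking statistic used to
#' compare prediction methods ("the more validated interactions, the
#' better").
#'
#' @param scores A `score_matrix`.
#' @param truth Interaction tibble (`mirna_id`, `target_id`) of
#'   experimentally validated pairs.
#' @param k Targets kept per miRNA; clamped (with a warning) to the target
#'   universe size.
#' @return One-row tibble: `method`, `k`, `target_class`, `n_predicted`,
#'   `n_validated`.
#' @export
rank_and_validate <- function(scores, truth, k) {
  stopifnot(inherits(scores, "score_matrix"))
  k <- assert_count(k, "k")
  n_t <- ncol(scores$scores)
  if (k > n_t) {
    warn(sprintf("k = %d exceeds the %d-target universe; clamping", k, n_t))
    k <- n_t
  }
  ids <- colnames(scores$scores)
  truth_keys <- paste(truth$mirna_id, truth$target_id, sep = "\r")
  n_pred <- 0L
  n_val <- 0L
  for (i in seq_len(nrow(scores$scores))) {
    top <- top_k_idx(scores$scores[i, ], ids, k)
    keys <- paste(rownames(scores$scores)[i], top, sep = "\r")
    n_pred <- n_pred + length(top)
    n_val <- n_val + sum(keys %in% truth_keys)
  }
  tibble(method = scores$method, k = k, target_class = scores$target_class,
         n_predicted = n_pred, n_validated = n_val)
}

#' Benchmark several methods over a grid of cutoffs
#'
#' @param scores_list List of `score_matrix` objects (possibly several
#'   target classes per method).
#' @param truth Validated interaction tibble.
#' @param k_list Integer vector of per-miRNA cutoffs (the paper-style grid
#'   is `c(50, 100, 150, 200)`).
#' @return Tibble with one row per (method, k, target_class).
#' @export
validate_methods <- function(scores_list, truth, k_list = c(50L, 100L, 150L, 200L)) {
  purrr::map_dfr(scores_list, function(sm) {
    purrr::map_dfr(k_list, function(k) rank_and_validate(sm, truth, k))
  })
}

#' Pick the best-performing method from a validation table
#'
#' The winner maximises the total validated-interaction count summed over
#' the `k` grid (and target classes); ties go to the method with fewer
#' predicted pairs, then to the alphabetically first name.
#'
#' @param validation A [validate_methods()] table.
#' @return The winning method name (length-1 character).
#' @export
best_method <- function(validation) {
  tab <- validation |>
    group_by(.data$method) |>
    summarise(total_validated = sum(.data$n_validated),
              total_predicted = sum(.data$n_predicted), .groups = "drop") |>
    arrange(desc(.data$total_validated), .data$total_predicted, .data$method)
  tab$method[1L]
}

#' Merge per-miRNA top-k predictions into a bipartite network
#'
#' Takes each miRNA's top-`k` lncRNA targets and top-`k` mRNA targets
#' (ranked separately per class) and unions them into the predicted
#' miRNA-target regulatory network.
#'
#' @param scores_list List of `score_matrix` objects, one per target class
#'   (same method).
#' @param k Per-miRNA, per-class cutoff (the paper merges top 200).
#' @return Edge tibble: `mirna_id`, `target_id`, `target_class`, `score`.
#' @export
build_target_network <- function(scores_list, k) {
  if (inherits(scores_list, "score_matrix")) scores_list <- list(scores_list)
  k <- assert_count(k, "k")
  purrr::map_dfr(scores_list, function(sm) {
    ids <- colnames(sm$scores)
    purrr::map_dfr(seq_len(nrow(sm$scores)), function(i) {
      top <- top_k_idx(sm$scores[i, ], ids, k)
      tibble(mirna_id = rownames(sm$scores)[i], target_id = top,
             target_class = sm$target_class,
             score = sm$scores[i, top])
    })
  }) |>
    distinct(.data$mirna_id, .data$target_id, .keep_all = TRUE)
}
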