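# ScoreMatrix container: one prediction method's miRNA x target scores.

new_score_matrix <- function(method, scores, raw, flagged, target_class,
                             extra = list()) {
  stopifnot(is.matrix(scores), identical(dim(scores), dim(raw)))
  if (any(is.na(scores))) abort("internal: NA scores after canonicalisation")
  structure(
    c(list(method = method, scores = scores, raw = raw, flagged = flagged,
           target_class = target_class, higher_is_stronger = TRUE), extra),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> method %s: %d miRNAs x %d %s targets\n",
              x$method, nrow(x$scores), ncol(x$scores), x$target_class))
  invisible(x)
}

#' @export
dim.score_matrix <- function(x) dim(x$scores)

#' Tidy a score matrix into a long pair table
#'
#' @param x A `score_matrix` as returned by the `score_*()` functions.
#' @param ... Unused.
#' @return A tibble with one row per miRNA-target pair: `mirna_id`,
#'   `target_id`, `target_class`, `method`, `score` (canonical,
#'   higher-is-stronger), `raw` (the signed/raw statistic), `flagged`
#'   (degenerate pair, score forced to 0).
#' @method tidy score_matrix
#' @export
tidy.score_matrix <- function(x, ...) {
  tibble(
    mirna_id = rep(rownames(x$scores), times = ncol(x$scores)),
    target_id = rep(colnames(x$scores), each = nrow(x$scores)),
    target_class = x$target_class,
    method = x$method,
    score = as.vector(x$scores),
    raw = as.vector(x$raw),
    flagged = as.vector(x$flagged)
  )
}

#' @rdname tidy.score_matrix
#' @method glance score_matrix
#' @export
glance.score_matrix <- function(x, ...) {
  tibble(method = x$method, n_mirna = nrow(x$scores), n_target = ncol(x$scores),
         target_class = x$target_class, n_flagged = sum(x$flagged))
}

# Coerce a cer_expr or genes-x-samples matrix to a plain matrix.
as_values <- function(x) {
  if (inherits(x, "cer_expr")) x$values
  else if (is.matrix(x)) x
  else abort("expected a cer_expr or a genes-by-samples matrix")
}
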