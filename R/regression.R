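# Regression-based scoring: one penalised regression per target gene with
# all miRNAs as (standardised) predictors; the score of a miRNA for that
# target is |coefficient| at the cross-validation-selected penalty.

# Closed-form single-predictor elastic net (glmnet objective, standardised
# predictor), used when only one miRNA is available.
single_predictor_coef <- function(x, y, lambda, alpha) {
  n <- length(x)
  sdx <- sqrt(mean((x - mean(x))^2))
  if (sdx == 0) return(0)
  z <- (x - mean(x)) / sdx
  rho <- mean(z * (y - mean(y)))
  b <- sign(rho) * max(abs(rho) - lambda * alpha, 0) / (1 + lambda * (1 - alpha))
  b / sdx
}

#' Score miRNA-target pairs with lasso or elastic-net regression
#'
#' For each target gene, fits `y_target ~ all miRNAs` with glmnet
#' (predictors standardised) and scores each miRNA by the absolute
#' coefficient at the penalty minimising the cross-validation error.
#'
#' @inheritParams score_correlation
#' @param method `"lasso"` (alpha = 1) or `"elasticnet"` (alpha = 0.5).
#' @param n_folds CV folds (default 5); reduced with a warning when there
#'   are fewer samples than folds.
#' @param lambda Optional fixed penalty; skips cross-validation (0 gives the
#'   unpenalised least-squares coefficients).
#' @param seed Seed controlling the CV fold assignment.
#' @return A `score_matrix` of `|coefficient|` values.
#' @export
score_regression <- function(X, Y, method = c("lasso", "elasticnet"),
                             target_class = "mRNA", n_folds = 5L,
                             lambda = NULL, seed = NULL) {
  method <- match.arg(method)
  alpha <- if (method == "lasso") 1 else 0.5
  X <- as_values(X)
  Y <- as_values(Y)
  if (ncol(X) != ncol(Y)) abort("X and Y must share the sample columns")
  n <- ncol(X)
  if (is.null(lambda) && n < n_folds) {
    warn(sprintf("only %d samples: reducing CV folds from %d to %d", n, n_folds, max(3L, n)))
    n_folds <- max(3L, min(n, n_folds))
  }
  preds <- t(X)
  raw <- matrix(0, nrow(X), nrow(Y), dimnames = list(rownames(X), rownames(Y)))
  const_x <- apply(X, 1, function(v) sd(v) == 0)
  const_y <- apply(Y, 1, function(v) sd(v) == 0)
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(n_folds), n))
    for (j in seq_len(nrow(Y))) {
      if (const_y[j]) next
      y <- Y[j, ]
      if (nrow(X) == 1L) {
        lam <- lambda %||% 0
        raw[1L, j] <- single_predictor_coef(X[1L, ], y, lam, alpha)
        next
      }
      cf <- tryCatch({
        if (is.null(lambda)) {
          fit <- glmnet::cv.glmnet(preds, y, alpha = alpha, foldid = foldid,
                                   standardize = TRUE)
          as.numeric(coef(fit, s = "lambda.min"))[-1L]
        } else {
          fit <- glmnet::glmnet(preds, y, alpha = alpha, standardize = TRUE)
          as.numeric(coef(fit, s = lambda, exact = TRUE, x = preds, y = y))[-1L]
        }
      }, error = function(e) rep(0, nrow(X)))
      raw[, j] <- cf
    }
  })
  flagged <- outer(const_x, const_y, "|")
  raw[flagged] <- 0
  new_score_matrix(method, abs(raw), raw, flagged, target_class)
}
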