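#' Point-biserial correlation
#'
#' Correlation between a continuous feature and a binary outcome, i.e. the
#' Pearson product-moment correlation of `x` with `y` coded 0/1. A constant
#' feature carries no information and returns 0 by convention (it is ranked
#' last by the selection step).
#'
#' @param x numeric feature vector.
#' @param y binary outcome (0/1), both classes present.
#' @return correlation in [-1, 1].
#' @export
#' @examples
#' point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 0.8944
point_biserial <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (stats::sd(x) == 0) return(0)
  stats::cor(x, y)
}

#' Logistic regression fit with likelihood-ratio p-value
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `glm`), reporting the likelihood-ratio-test p-value of the
#' fitted model against a stated null model (by default the intercept-only
#' model). Quasi-complete separation is detected when any coefficient
#' exceeds `cap` in magnitude; such coefficients are capped (and the fit
#' flagged) so that iterative selection loops always terminate.
#'
#' @param X numeric design matrix (no intercept column; one is added).
#' @param y binary outcome vector.
#' @param null_deviance deviance of the reference (nested) model for the
#'   LRT; default the intercept-only deviance.
#' @param null_df residual df of the reference model.
#' @param cap separation cap on |coefficient|.
#' @return object of class `logistic_fit`: list with `coefficients`
#'   (including intercept), `converged`, `separation`, `log_lik`,
#'   `deviance`, `df_residual`, `p` (LRT vs the reference model) and
#'   `fitted`.
#' @export
logistic_fit <- function(X, y, null_deviance = NULL, null_df = NULL,
                         cap = 30) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < ncol(X) + 1L) stop("need more rows than columns")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial())
  )
  beta <- fit$coefficients
  separation <- any(abs(beta[-1]) > cap, na.rm = TRUE) ||
    fit$deviance < 1e-6  # perfect fit: likelihood at its supremum
  beta <- pmin(pmax(beta, -cap), cap)
  if (!fit$converged && !separation)
    stop("IRLS did not converge (", fit$iter, " iterations) without separation")
  if (is.null(null_deviance)) {
    null_deviance <- fit$null.deviance
    null_df <- nrow(X) - 1L
  }
  dev_drop <- max(null_deviance - fit$deviance, 0)
  df_drop <- max(null_df - fit$df.residual, 0L)
  p <- if (df_drop == 0L) 1 else stats::pchisq(dev_drop, df_drop,
                                               lower.tail = FALSE)
  structure(list(coefficients = beta, converged = fit$converged,
                 separation = separation, log_lik = -fit$deviance / 2,
                 deviance = fit$deviance, df_residual = fit$df.residual,
                 p = p, fitted = fit$fitted.values),
            class = "logistic_fit")
}

#' Hybrid descriptive-inferential feature selection
#'
#' The two-stage selection at the heart of the computational model:
#' (1) *descriptive* — every feature is scored by the absolute
#' point-biserial correlation with the outcome and sorted in descending
#' order (ties broken by original column order; constant features score 0
#' and sink to the bottom); (2) *inferential* — a cycle adds one feature at
#' a time in rank order, fits a logistic regression on the current set, and
#' compares the model p-value with the previous iteration's: the cycle is
#' interrupted as soon as the p-value does not decrease. The first ranked
#' feature is always retained (it has no predecessor to improve on).
#'
#' The iteration p-value is, by default, the 1-df likelihood-ratio test of
#' the current model against the previous iteration's nested model (for the
#' first iteration, against the intercept-only model). The Wald p-value of
#' the newly added coefficient is available as an alternative.
#'
#' Features are z-scored internally before the logistic fits for numeric
#' stability; the point-biserial ranking is scale-invariant so the ranking
#' is unaffected.
#'
#' @param X numeric feature matrix with column names.
#' @param y binary outcome (0/1).
#' @param p_method `"lrt"` (default) or `"wald"`.
#' @param max_features optional cap on the number of iterations.
#' @return object of class `selection_result`: list with `ranked_names`,
#'   `rpb` (named, in ranked order), `p_trajectory`, `stop_index`,
#'   `retained_names`.
#' @export
hybrid_select <- function(X, y, p_method = c("lrt", "wald"),
                          max_features = NULL) {
  p_method <- match.arg(p_method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y), ncol(X) >= 1)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")

  rpb <- vapply(seq_len(ncol(X)), function(j) point_biserial(X[, j], y),
                numeric(1))
  if (all(rpb == 0)) stop("no informative features")
  ord <- order(-abs(rpb), seq_along(rpb))     # ties: original column order
  ranked <- colnames(X)[ord]

  # z-score non-constant columns for the fits
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0

  kmax <- if (is.null(max_features)) ncol(X) else min(max_features, ncol(X))
  # cap iterations at n - 2 so the model stays identifiable
  kmax <- min(kmax, nrow(X) - 2L)
  p_traj <- numeric(0)
  prev_dev <- NULL; prev_df <- NULL
  prev_p <- Inf
  stop_index <- 0L
  for (i in seq_len(kmax)) {
    Xi <- Xs[, ord[seq_len(i)], drop = FALSE]
    fit <- logistic_fit(Xi, y, null_deviance = prev_dev, null_df = prev_df)
    p_i <- if (p_method == "lrt") fit$p else wald_p_last(fit, Xi)
    p_traj <- c(p_traj, p_i)
    if (i > 1L && p_i >= prev_p) break     # did not decrease: interrupt
    stop_index <- i
    prev_p <- p_i
    prev_dev <- fit$deviance
    prev_df <- fit$df_residual
    if (fit$separation) break              # deviance ~ 0, nothing to gain
  }
  structure(list(ranked_names = ranked,
                 rpb = stats::setNames(rpb[ord], ranked),
                 p_trajectory = p_traj,
                 stop_index = stop_index,
                 retained_names = ranked[seq_len(stop_index)]),
            class = "selection_result")
}

# Wald p of the most recently added coefficient, from the observed
# information at the fitted values
wald_p_last <- function(fit, X) {
  if (fit$separation) return(0)  # deviance collapses; treat as significant
  Xd <- cbind(1, X)
  w <- fit$fitted * (1 - fit$fitted)
  info <- crossprod(Xd, Xd * w)
  v <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(v)) return(1)
  b <- fit$coefficients[length(fit$coefficients)]
  se <- sqrt(diag(v)[length(fit$coefficients)])
  2 * stats::pnorm(-abs(b / se))
}
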