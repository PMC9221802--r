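#' Linear discriminant analysis with pooled covariance
#'
#' Gaussian classifier with class-specific means, a pooled within-class
#' covariance (within-class scatter divided by `n - 2`) and class priors.
#' Priors default to the empirical training prevalences, which preserves
#' the cohort's imbalance in the decision rule. A singular pooled
#' covariance (collinear or constant features) is regularized by adding
#' `eps * trace / d` to the diagonal and flagged.
#'
#' @param X numeric feature matrix.
#' @param y binary outcome (0/1), at least two samples per class.
#' @param priors length-2 vector (negative, positive), summing to 1;
#'   default empirical.
#' @param eps relative ridge regularization for singular covariances.
#' @return object of class `rtae_lda`: means, pooled covariance (possibly
#'   regularized), priors, `regularized` flag.
#' @export
lda_fit <- function(X, y, priors = NULL, eps = 1e-6) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (sum(y == 0) < 2 || sum(y == 1) < 2)
    stop("need at least two samples per class")
  n <- nrow(X); d <- ncol(X)
  if (is.null(priors)) priors <- c(mean(y == 0), mean(y == 1))
  stopifnot(length(priors) == 2, abs(sum(priors) - 1) < 1e-8)

  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  c0 <- sweep(X[y == 0, , drop = FALSE], 2, mu0)
  c1 <- sweep(X[y == 1, , drop = FALSE], 2, mu1)
  S <- (crossprod(c0) + crossprod(c1)) / (n - 2)

  regularized <- FALSE
  chol_ok <- function(M) !inherits(tryCatch(chol(M), error = identity),
                                   "error")
  if (!chol_ok(S)) {
    S <- S + diag(eps * sum(diag(S)) / d + 1e-12, d)
    regularized <- TRUE
    if (!chol_ok(S)) {  # still singular (e.g. zero trace): larger ridge
      S <- S + diag(max(eps, 1e-8), d)
    }
  }
  structure(list(means = rbind(`0` = mu0, `1` = mu1), cov = S,
                 priors = stats::setNames(priors, c("0", "1")),
                 regularized = regularized, features = colnames(X)),
            class = "rtae_lda")
}

#' Posterior probabilities and discriminant scores from an LDA model
#'
#' Applies the Gaussian Bayes rule with the pooled covariance: the linear
#' discriminant score is `x' S^{-1} (mu1 - mu0) - (mu1 + mu0)' S^{-1}
#' (mu1 - mu0) / 2 + log(pi1 / pi0)`, and the positive-class posterior is
#' its logistic transform.
#'
#' @param object an `rtae_lda` model.
#' @param newdata matrix of observations (columns matching the fit).
#' @param ... unused.
#' @return data.frame with `score` (log posterior odds) and `posterior`
#'   (positive-class probability).
#' @export
predict.rtae_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X)))
    X <- X[, object$features, drop = FALSE]
  w <- solve(object$cov, object$means["1", ] - object$means["0", ])
  b <- -sum((object$means["1", ] + object$means["0", ]) * w) / 2 +
    log(object$priors["1"] / object$priors["0"])
  score <- drop(X %*% w) + b
  data.frame(score = score, posterior = stats::plogis(score))
}

#' Stratified k-fold assignment with disjoint test sets
#'
#' Divides the cohort into k disjoint folds whose sizes differ by at most
#' one and whose class counts follow the cohort prevalence to within one
#' patient per fold, so every held-out fold preserves the outcome mix. For
#' 51 patients with 14 positives and k = 5 this gives fold sizes
#' 11,10,10,10,10 with 3,3,3,3,2 positives. Deterministic given the seed.
#'
#' @param y binary outcome vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list with `fold` (integer vector in 1..k), `k`, `seed`.
#' @export
stratified_kfold <- function(y, k = 5, seed = 1L) {
  n <- length(y)
  if (k > n) stop("k exceeds the number of patients")
  n_pos <- sum(y == 1)
  if (n_pos > 0 && n_pos < k)
    warning("fewer positives than folds: some folds have no positive")
  set.seed(as.integer(seed))

  lr_alloc <- function(total, k) {      # largest-remainder allocation
    base <- rep(floor(total / k), k)
    extra <- total - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  sizes <- lr_alloc(n, k)               # total fold sizes, extras first
  pos_cnt <- lr_alloc(n_pos, k)         # positive counts, extras first
  neg_cnt <- sizes - pos_cnt
  # rebalance if a fold got both extras short (can happen when the two
  # remainders overlap badly); negatives proportional +/- 1 is preserved
  while (any(neg_cnt < 0)) {
    i <- which.min(neg_cnt); j <- which.max(neg_cnt)
    pos_cnt[i] <- pos_cnt[i] - 1L; pos_cnt[j] <- pos_cnt[j] + 1L
    neg_cnt <- sizes - pos_cnt
  }
  fold <- integer(n)
  fold[sample(which(y == 1))] <- rep(seq_len(k), pos_cnt)
  fold[sample(which(y == 0))] <- rep(seq_len(k), neg_cnt)
  list(fold = fold, k = k, seed = as.integer(seed))
}

#' Model 2 pipeline: hybrid selection + LDA under stratified 5-fold CV
#'
#' For each fold: the hybrid descriptive-inferential selection
#' ([hybrid_select()]) runs on the training portion only, an LDA is fit on
#' the retained features (z-scored on training statistics), and the
#' held-out fold is scored — so no information from a test fold ever
#' reaches selection or fitting. Per-fold sensitivity, specificity,
#' accuracy and AUC (operating point by Youden's index on the fold's
#' training scores) are arithmetically averaged; the AUC of the pooled
#' out-of-fold scores is also reported, matching the single-ROC view of
#' the cross-validated model.
#'
#' If a fold's training portion is single-class the folds are re-drawn with
#' the next seed, with a warning.
#'
#' @param dataset a `cohort_dataset`.
#' @param endpoint `"cr"` or `"or"`.
#' @param k number of folds.
#' @param seed integer seed.
#' @param p_method passed to [hybrid_select()].
#' @return list with `performance` (one-row data.frame of fold-averaged
#'   metrics plus `auc_pooled` and its CI), `per_fold` (data.frame),
#'   `selected` (list of per-fold retained names), `folds`, and the pooled
#'   out-of-fold `scores`.
#' @export
model2_pipeline <- function(dataset, endpoint = c("cr", "or"), k = 5,
                            seed = 1L, p_method = "lrt") {
  endpoint <- match.arg(endpoint)
  y <- endpoint_vector(dataset$labels, endpoint)
  X <- build_design_matrix(dataset)

  fold <- NULL
  s <- as.integer(seed)
  for (try in 1:10) {
    f <- stratified_kfold(y, k = k, seed = s)$fold
    ok <- all(vapply(seq_len(k), function(i)
      length(unique(y[f != i])) == 2, logical(1)))
    if (ok) { fold <- f; break }
    warning("single-class training fold; re-drawing folds")
    s <- s + 1L
  }
  if (is.null(fold)) stop("could not build folds with both classes in training")

  per_fold <- list()
  selected <- list()
  oof_scores <- numeric(length(y))
  for (i in seq_len(k)) {
    tr <- fold != i; te <- fold == i
    z <- standardize_train_test(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    sel <- hybrid_select(z$train, y[tr], p_method = p_method)
    selected[[i]] <- sel$retained_names
    model <- lda_fit(z$train[, sel$retained_names, drop = FALSE], y[tr])
    sc_tr <- predict(model, z$train[, sel$retained_names, drop = FALSE])$score
    sc_te <- predict(model, z$test[, sel$retained_names, drop = FALSE])$score
    oof_scores[te] <- sc_te

    # operating threshold chosen on the fold's training scores
    thr <- operating_point(sc_tr, y[tr])$threshold
    pred <- sc_te >= thr
    sens <- if (any(y[te] == 1)) 100 * mean(pred[y[te] == 1]) else NA_real_
    spec <- if (any(y[te] == 0)) 100 * mean(!pred[y[te] == 0]) else NA_real_
    auc_i <- if (length(unique(y[te])) == 2)
      roc_auc(sc_te, y[te])$auc else NA_real_
    per_fold[[i]] <- data.frame(fold = i, sensitivity = sens,
                                specificity = spec,
                                accuracy = 100 * mean(pred == (y[te] == 1)),
                                auc = auc_i, n_selected = length(selected[[i]]))
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- auc_ci(oof_scores, y)
  performance <- data.frame(
    sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
    specificity = mean(per_fold$specificity, na.rm = TRUE),
    accuracy = mean(per_fold$accuracy, na.rm = TRUE),
    auc = mean(per_fold$auc, na.rm = TRUE),
    auc_pooled = pooled$auc, ci_lo = pooled$lo, ci_hi = pooled$hi,
    p = pooled$p, endpoint = endpoint, k = k
  )
  list(performance = performance, per_fold = per_fold, selected = selected,
       folds = fold, scores = list(oof = oof_scores, y = y))
}
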