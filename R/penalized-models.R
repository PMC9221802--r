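#' Stratified 80/20 train/test split
#'
#' The test set holds `round(0.2 * n)` patients, allocated across outcome
#' classes proportionally (largest-remainder rounding), so both classes are
#' always represented in the training set even at low prevalence.
#' Deterministic given the seed.
#'
#' @param y binary outcome vector.
#' @param seed integer seed.
#' @param test_frac test fraction (default 0.2).
#' @return list with integer index vectors `train` and `test`.
#' @export
split_80_20 <- function(y, seed = 1L, test_frac = 0.2) {
  n <- length(y)
  stopifnot(n >= 10)
  set.seed(as.integer(seed))
  n_test <- round(test_frac * n)
  classes <- sort(unique(y))
  raw <- vapply(classes, function(k) test_frac * sum(y == k), numeric(1))
  cnt <- floor(raw)
  rem <- n_test - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  test <- unlist(lapply(seq_along(classes), function(i) {
    idx <- which(y == classes[i])
    if (cnt[i] >= length(idx))  # keep at least one per class in train
      cnt[i] <- length(idx) - 1L
    sample(idx, cnt[i])
  }))
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Elastic-net logistic path with (alpha, lambda) grid search
#'
#' Fits the penalized logistic model minimizing
#' `-(1/n) loglik + lambda * (alpha ||b||_1 + (1 - alpha) ||b||_2^2 / 2)`
#' (intercept unpenalized) over a log-spaced lambda path for each alpha in
#' the grid, choosing the pair with the smallest mean 5-fold
#' cross-validated binomial deviance. The elastic net (alpha < 1) is used
#' rather than the pure LASSO to reduce the chance of selecting zero
#' features among highly correlated inputs; if the CV-optimal lambda still
#' selects nothing, the next smaller lambda on the path with a non-empty
#' active set is taken, with a warning.
#'
#' Inputs are expected already standardized (`standardize = FALSE` is
#' passed to the solver); CV folds are stratified by outcome and shared
#' across the alpha grid so the comparison is paired.
#'
#' @param X numeric matrix (standardized), `y` binary outcome.
#' @param y binary outcome vector.
#' @param alpha_grid mixing parameters in [0.5, 1].
#' @param k_cv number of CV folds.
#' @param seed integer seed (fold assignment).
#' @return object of class `penalized_fit`: list with `alpha`, `lambda`,
#'   `coefficients` (named, incl. intercept), `nonzero_names`, `cv_curve`
#'   (lambda, mean CV deviance for the chosen alpha), and the underlying
#'   `glmnet_fit`.
#' @export
enet_logistic_path <- function(X, y, alpha_grid = seq(0.5, 1, by = 0.1),
                               k_cv = 5, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  foldid <- stratified_kfold(y, k = k_cv, seed = seed)$fold
  best <- NULL
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = a,
                            foldid = foldid, type.measure = "deviance",
                            standardize = FALSE)
    cvm_min <- min(cv$cvm)
    if (is.null(best) || cvm_min < best$cvm) {
      best <- list(cv = cv, alpha = a, cvm = cvm_min)
    }
  }
  cv <- best$cv
  lam_idx <- which.min(cv$cvm)
  lam <- cv$lambda[lam_idx]
  nz <- function(l) {
    b <- as.matrix(stats::coef(cv$glmnet.fit, s = l, exact = FALSE))
    rownames(b)[-1][b[-1, 1] != 0]
  }
  sel <- nz(lam)
  while (length(sel) == 0 && lam_idx < length(cv$lambda)) {
    lam_idx <- lam_idx + 1L
    lam <- cv$lambda[lam_idx]
    sel <- nz(lam)
    if (length(sel) > 0)
      warning("empty selection at the CV-optimal lambda; stepped down the path")
  }
  b <- as.matrix(stats::coef(cv$glmnet.fit, s = lam))
  structure(list(alpha = best$alpha, lambda = lam,
                 coefficients = stats::setNames(b[, 1], rownames(b)),
                 nonzero_names = sel,
                 cv_curve = data.frame(lambda = cv$lambda, cvm = cv$cvm),
                 glmnet_fit = cv$glmnet.fit),
            class = "penalized_fit")
}

#' Ridge logistic refit on the selected features
#'
#' Decorrelation step: a pure ridge (`alpha = 0`) logistic model on the
#' columns chosen by [enet_logistic_path()], with lambda newly estimated by
#' 5-fold cross-validation. All coefficients are dense (nonzero).
#'
#' @param X_selected matrix restricted to the selected features.
#' @param y binary outcome.
#' @param k_cv,seed as in [enet_logistic_path()].
#' @return a `penalized_fit` with `alpha = 0`.
#' @export
ridge_refit <- function(X_selected, y, k_cv = 5, seed = 1L) {
  X_selected <- as.matrix(X_selected)
  if (ncol(X_selected) == 0) stop("no selected features to refit")
  # glmnet needs >= 2 columns; duplicate guard column is dropped after
  dup <- ncol(X_selected) == 1L
  Xf <- if (dup) cbind(X_selected, .guard = 0) else X_selected
  foldid <- stratified_kfold(y, k = k_cv, seed = seed)$fold
  cv <- glmnet::cv.glmnet(Xf, y, family = "binomial", alpha = 0,
                          foldid = foldid, type.measure = "deviance",
                          standardize = FALSE)
  b <- as.matrix(stats::coef(cv$glmnet.fit, s = cv$lambda.min))
  coefs <- stats::setNames(b[, 1], rownames(b))
  if (dup) coefs <- coefs[names(coefs) != ".guard"]
  structure(list(alpha = 0, lambda = cv$lambda.min,
                 coefficients = coefs,
                 nonzero_names = names(coefs)[-1],
                 cv_curve = data.frame(lambda = cv$lambda, cvm = cv$cvm),
                 glmnet_fit = cv$glmnet.fit),
            class = "penalized_fit")
}

predict_penalized <- function(fit, X) {
  b <- fit$coefficients
  eta <- b[1] + as.matrix(X[, names(b)[-1], drop = FALSE]) %*% b[-1]
  stats::plogis(drop(eta))
}

#' Build the modelling design matrix from a cohort dataset
#'
#' Column-binds the radiomics features with numerically encoded clinical
#' variables (factors/characters expanded to 0/1 dummies, first level as
#' reference) and the LI-RADS table, as the models are constructed on the
#' combined dataset.
#'
#' @param dataset a `cohort_dataset`.
#' @return numeric matrix with named columns.
#' @export
build_design_matrix <- function(dataset) {
  enc <- function(df) {
    cols <- lapply(names(df), function(nm) {
      v <- df[[nm]]
      if (is.numeric(v)) {
        out <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
      } else {
        f <- factor(v)
        out <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(out) <- paste0(nm, "_", levels(f)[-1])
      }
      out
    })
    do.call(cbind, cols)
  }
  cbind(dataset$features, enc(dataset$clinical), enc(dataset$lirads))
}

# z-score with training statistics; constant columns map to 0
standardize_train_test <- function(X_train, X_test = NULL) {
  mu <- colMeans(X_train)
  sd <- apply(X_train, 2, stats::sd)
  sd[sd == 0] <- 1
  zt <- sweep(sweep(X_train, 2, mu), 2, sd, "/")
  if (is.null(X_test)) return(list(train = zt))
  list(train = zt, test = sweep(sweep(X_test, 2, mu), 2, sd, "/"))
}

#' Model 1 pipeline: elastic-net selection + ridge refit on an 80/20 split
#'
#' Splits the cohort (stratified 80/20), z-scores features on training
#' statistics, selects features by elastic-net logistic regression with the
#' (alpha, lambda) grid search on the training set, refits a ridge logistic
#' model on the selected columns, and scores both sets.
#'
#' @param dataset a `cohort_dataset`.
#' @param endpoint `"cr"` or `"or"`.
#' @param seed integer seed (split and CV folds).
#' @param alpha_grid passed to [enet_logistic_path()].
#' @return list with `performance` (two-row data.frame, train and test),
#'   `selected` (feature names), `enet_fit`, `ridge_fit`, `split`, and the
#'   raw `scores`.
#' @export
model1_pipeline <- function(dataset, endpoint = c("cr", "or"), seed = 1L,
                            alpha_grid = seq(0.5, 1, by = 0.1)) {
  endpoint <- match.arg(endpoint)
  y <- endpoint_vector(dataset$labels, endpoint)
  X <- build_design_matrix(dataset)
  sp <- split_80_20(y, seed = seed)
  z <- standardize_train_test(X[sp$train, , drop = FALSE],
                              X[sp$test, , drop = FALSE])
  enet <- enet_logistic_path(z$train, y[sp$train], alpha_grid = alpha_grid,
                             seed = seed)
  ridge <- ridge_refit(z$train[, enet$nonzero_names, drop = FALSE],
                       y[sp$train], seed = seed)
  sc_train <- predict_penalized(ridge, z$train)
  sc_test <- predict_penalized(ridge, z$test)
  perf <- rbind(
    model_performance(sc_train, y[sp$train],
                      list(set = "train", endpoint = endpoint)),
    model_performance(sc_test, y[sp$test],
                      list(set = "test", endpoint = endpoint))
  )
  list(performance = perf, selected = enet$nonzero_names,
       enet_fit = enet, ridge_fit = ridge, split = sp,
       scores = list(train = sc_train, test = sc_test,
                     y_train = y[sp$train], y_test = y[sp$test]))
}
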