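#' ROC curve and area under the curve
#'
#' AUC is the probability that a random positive's score exceeds a random
#' negative's, with ties counted one half — computed exactly from ranks
#' (equivalent to the trapezoidal area under the empirical ROC). The curve
#' is returned over all distinct score thresholds with the convention that
#' a case is called positive when its score is `>=` the threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels binary outcome (0/1), both classes present.
#' @return list with `auc` and a data.frame `curve` (threshold, fpr, tpr).
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # ties get average ranks => 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, th),
    fpr = vapply(c(Inf, th), function(t) mean(scores[labels == 0] >= t),
                 numeric(1)),
    tpr = vapply(c(Inf, th), function(t) mean(scores[labels == 1] >= t),
                 numeric(1))
  )
  list(auc = auc, curve = curve)
}

#' AUC confidence interval and test against 0.5
#'
#' DeLong's method by default: the AUC variance is estimated from the
#' placement values of positives and negatives, the CI is a normal-theory
#' interval clamped to [0, 1], and the p-value tests AUC = 0.5 on the same
#' scale. A percentile bootstrap (stratified by class) is available as an
#' alternative. When the DeLong variance is degenerate (all placements
#' equal, e.g. perfect separation) the CI collapses to the point estimate
#' and is flagged.
#'
#' @param scores,labels as in [roc_auc()].
#' @param method `"delong"` or `"bootstrap"`.
#' @param conf confidence level.
#' @param B bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return list with `auc`, `lo`, `hi`, `p`, `se`, `degenerate`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   conf = 0.95, B = 2000, seed = 1L) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  auc <- roc_auc(scores, labels)$auc
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  m <- length(s1); n <- length(s0)
  z <- stats::qnorm(1 - (1 - conf) / 2)

  # placement values (shared by the DeLong variance and the p-value)
  v10 <- vapply(s1, function(s) mean((s > s0) + 0.5 * (s == s0)), numeric(1))
  v01 <- vapply(s0, function(s) mean((s1 > s) + 0.5 * (s1 == s)), numeric(1))
  var_d <- stats::var(v10) / m + stats::var(v01) / n
  degenerate <- !is.finite(var_d) || var_d <= 0
  se <- sqrt(max(var_d, 0))

  if (method == "delong") {
    if (degenerate) {
      lo <- hi <- auc
    } else {
      lo <- max(0, auc - z * se)
      hi <- min(1, auc + z * se)
    }
  } else {
    set.seed(seed)
    reps <- replicate(B, {
      roc_auc(c(sample(s1, m, TRUE), sample(s0, n, TRUE)),
              c(rep(1L, m), rep(0L, n)))$auc
    })
    qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    lo <- max(0, qs[1]); hi <- min(1, qs[2])
  }
  p <- if (degenerate) {
    if (auc == 0.5) 1 else 0
  } else 2 * stats::pnorm(-abs(auc - 0.5) / se)
  list(auc = auc, lo = lo, hi = hi, p = p, se = se, degenerate = degenerate)
}

#' Operating point by Youden's index
#'
#' Scans all distinct score thresholds (positive call when score `>=`
#' threshold) and returns sensitivity, specificity and accuracy (percent)
#' at the threshold maximizing Youden's J = sensitivity + specificity - 1.
#' Ties are broken toward the lower threshold, i.e. the higher-sensitivity
#' operating point.
#'
#' @param scores,labels as in [roc_auc()].
#' @return list with `threshold`, `sensitivity`, `specificity`, `accuracy`
#'   (percentages).
#' @export
operating_point <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(any(labels == 1), any(labels == 0))
  th <- sort(unique(scores))
  stats_at <- function(t) {
    pred <- scores >= t
    sens <- mean(pred[labels == 1])
    spec <- mean(!pred[labels == 0])
    c(sens = sens, spec = spec, acc = mean(pred == (labels == 1)))
  }
  grid <- vapply(th, stats_at, numeric(3))
  j <- grid["sens", ] + grid["spec", ] - 1
  best <- which(j == max(j))[1]           # ties: lowest threshold
  list(threshold = unname(th[best]),
       sensitivity = unname(100 * grid["sens", best]),
       specificity = unname(100 * grid["spec", best]),
       accuracy = unname(100 * grid["acc", best]))
}

#' Full performance summary for one score set
#'
#' Sensitivity/specificity/accuracy at the Youden operating point, AUC with
#' DeLong 95\% CI and the DeLong p-value against AUC = 0.5 — the columns of
#' a standard diagnostic-performance table.
#'
#' @param scores,labels as in [roc_auc()].
#' @param context optional named list tagging the row (phase, endpoint, set).
#' @return one-row data.frame.
#' @export
model_performance <- function(scores, labels, context = list()) {
  op <- operating_point(scores, labels)
  ci <- auc_ci(scores, labels)
  out <- data.frame(sensitivity = op$sensitivity,
                    specificity = op$specificity,
                    accuracy = op$accuracy,
                    auc = ci$auc, ci_lo = ci$lo, ci_hi = ci$hi, p = ci$p)
  for (nm in names(context)) out[[nm]] <- context[[nm]]
  out
}
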