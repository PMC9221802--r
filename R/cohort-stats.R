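#' mRECIST response classification
#'
#' Classifies treatment response of a target lesion from its arterial-phase
#' enhancement and size before and after therapy, following the modified
#' RECIST (mRECIST) criteria for HCC: complete response (CR) is the
#' disappearance of any intratumoral arterial enhancement; progressive
#' disease (PD) a >= 20\% increase in target-lesion size; partial response
#' (PR) a >= 30\% decrease of intratumoral enhancement; stable disease (SD)
#' anything else. Precedence is CR > PD > PR > SD, so a lesion whose
#' enhancement drops but whose size grows by >= 20\% is classified PD.
#'
#' @param pre_enhancement,post_enhancement intratumoral arterial enhancement
#'   before/after treatment (percent, or any consistent positive unit).
#' @param pre_size,post_size target-lesion size before/after treatment (mm).
#' @return character vector of categories among `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
#' @examples
#' mrecist_classify(100, 0, 20, 15)   # "CR"
#' mrecist_classify(100, 70, 20, 20)  # "PR" (30% decrease, boundary inclusive)
#' mrecist_classify(100, 90, 20, 24)  # "PD" (20% size increase dominates)
mrecist_classify <- function(pre_enhancement, post_enhancement,
                             pre_size, post_size) {
  n <- max(length(pre_enhancement), length(post_enhancement),
           length(pre_size), length(post_size))
  pre_enhancement <- rep_len(pre_enhancement, n)
  post_enhancement <- rep_len(post_enhancement, n)
  pre_size <- rep_len(pre_size, n)
  post_size <- rep_len(post_size, n)
  if (any(pre_enhancement <= 0) || any(pre_size <= 0))
    stop("baseline enhancement and size must be positive")
  if (any(post_enhancement < 0) || any(post_size < 0))
    stop("post-treatment measurements must be non-negative")
  size_change <- (post_size - pre_size) / pre_size
  enh_change <- (pre_enhancement - post_enhancement) / pre_enhancement
  ifelse(post_enhancement == 0, "CR",
    ifelse(size_change >= 0.20, "PD",
      ifelse(enh_change >= 0.30, "PR", "SD")))
}

#' Per-patient response labels with derived binary endpoints
#'
#' Wraps mRECIST categories into the label table used throughout the
#' pipelines: `complete_response` is CR vs the rest; `objective_response`
#' pools CR and PR against SD and PD.
#'
#' @param category character vector of mRECIST categories (CR/PR/SD/PD).
#' @return data.frame with columns `category`, `complete_response` (0/1) and
#'   `objective_response` (0/1).
#' @export
response_labels <- function(category) {
  stopifnot(all(category %in% c("CR", "PR", "SD", "PD")))
  data.frame(
    category = category,
    complete_response = as.integer(category == "CR"),
    objective_response = as.integer(category %in% c("CR", "PR")),
    stringsAsFactors = FALSE
  )
}

#' Summarize a cohort's response categories and endpoints
#'
#' @param labels data.frame as returned by [response_labels()].
#' @return list with data.frames `categories` (count, pct per mRECIST
#'   category) and `endpoints` (count, pct for complete and objective
#'   response). Percentages are 100 * count / n rounded to one decimal.
#' @export
summarize_cohort <- function(labels) {
  if (NROW(labels) == 0L) stop("empty label set")
  n <- nrow(labels)
  cats <- c("CR", "PR", "SD", "PD")
  counts <- vapply(cats, function(k) sum(labels$category == k), integer(1))
  categories <- data.frame(
    category = cats, count = counts,
    pct = round(100 * counts / n, 1), row.names = NULL
  )
  ep_counts <- c(
    complete_response = sum(labels$complete_response),
    objective_response = sum(labels$objective_response)
  )
  endpoints <- data.frame(
    endpoint = names(ep_counts), count = as.integer(ep_counts),
    pct = round(100 * ep_counts / n, 1), row.names = NULL
  )
  list(n = n, categories = categories, endpoints = endpoints)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with the two-sided p-value defined as the sum of
#' probabilities of all tables (margins fixed) whose point probability does
#' not exceed that of the observed table (up to a relative tolerance of
#' 1e-7). This is the convention that reproduces p-values printed by the
#' major statistics packages. A table with a zero margin carries no
#' information and returns p = 1.
#'
#' @param a,b,c,d the four cell counts: rows are feature present/absent,
#'   columns the two response groups. Alternatively `a` may be a 2x2 matrix.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(0, 4, 14, 33)   # 0.565 (feature in 0/14 vs 4/37)
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2, 2)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Pearson chi-squared test of independence
#'
#' Without continuity correction, matching the classic formula
#' sum((O - E)^2 / E) on df = (r-1)(c-1). Errors on a zero expected cell
#' (such tables should be routed to the Fisher exact test).
#'
#' @param tab contingency table (matrix of counts).
#' @return list with `statistic`, `df` and `p`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("zero expected cell: use the Fisher exact test")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Mann-Whitney U test
#'
#' Exact enumeration for small samples without ties (total n <= 12 in this
#' package's exact regime and whenever base R's exact path applies), normal
#' approximation with tie correction otherwise. No continuity correction is
#' applied in the approximate regime.
#'
#' @param x0,x1 numeric samples for the two groups.
#' @return list with `U` (statistic for group `x1` relative to `x0`) and
#'   two-sided `p`.
#' @export
mann_whitney_u <- function(x0, x1) {
  if (length(x0) == 0L || length(x1) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x0, x1)) > 0L
  exact <- !ties && (length(x0) + length(x1)) <= 12L
  wt <- suppressWarnings(
    stats::wilcox.test(x1, x0, exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Group comparison report (baseline-table style)
#'
#' Compares every clinical and LI-RADS variable between the two groups of a
#' binary endpoint: continuous variables are summarized as median (IQR) and
#' tested with the Mann-Whitney U test; categorical variables as counts (%)
#' and tested with the Fisher exact test when any expected cell is below 5,
#' else the Pearson chi-squared test. A variable that is constant over the
#' whole cohort (e.g. a LI-RADS feature never encountered) is reported as
#' untestable (`p = NA`).
#'
#' @param dataset a cohort dataset as produced by [generate_feature_table()],
#'   or any list with `clinical`, `lirads` and `labels` components.
#' @param endpoint `"cr"` (complete response) or `"or"` (objective response).
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame with one row per variable: `variable`, `type`, summary
#'   strings for each group, `test`, `p`, `significant`.
#' @export
compare_groups <- function(dataset, endpoint = c("cr", "or"), alpha = 0.05) {
  endpoint <- match.arg(endpoint)
  y <- endpoint_vector(dataset$labels, endpoint)
  vars <- cbind(dataset$clinical, dataset$lirads)
  rows <- lapply(names(vars), function(nm) {
    v <- vars[[nm]]
    if (is.numeric(v) && length(unique(v)) > 6L) {
      summ <- vapply(0:1, function(g) {
        q <- stats::quantile(v[y == g], c(0.5, 0.25, 0.75), names = FALSE)
        sprintf("%.1f (%.1f, %.1f)", q[1], q[2], q[3])
      }, character(1))
      p <- mann_whitney_u(v[y == 0], v[y == 1])$p
      test <- "mann-whitney"
      type <- "continuous"
    } else {
      vf <- factor(v)
      type <- "categorical"
      if (nlevels(vf) < 2L) {
        # constant variable (e.g. a feature never encountered): untestable
        summ <- vapply(0:1, function(g) {
          ng <- sum(y == g)
          cnt <- if (isTRUE(v[1] != 0)) ng else 0L
          sprintf("%d (%.1f)", cnt, 100 * cnt / ng)
        }, character(1))
        return(data.frame(variable = nm, type = type,
                          group0 = summ[1], group1 = summ[2],
                          test = NA_character_, p = NA_real_,
                          significant = NA, stringsAsFactors = FALSE))
      }
      tab <- table(vf, factor(y, levels = 0:1))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- pearson_chi2(tab)$p
        test <- "chi2"
      }
      # summary for the level conventionally reported (last level: "present")
      lev <- levels(vf)[nlevels(vf)]
      summ <- vapply(0:1, function(g) {
        ng <- sum(y == g)
        cnt <- sum(y == g & vf == lev)
        sprintf("%d (%.1f)", cnt, 100 * cnt / ng)
      }, character(1))
    }
    data.frame(variable = nm, type = type, group0 = summ[1], group1 = summ[2],
               test = test, p = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "group0"] <- "non_responder"
  names(out)[names(out) == "group1"] <- "responder"
  out
}

#' Printed contingency counts from the reference cohort tables
#'
#' Loads the 2x2 counts of the published baseline/LI-RADS comparison tables
#' (feature present counts in each response group, for both binary
#' endpoints) together with the p-values printed alongside them. Shipped as
#' a plain-text fixture so the exact-test implementation can be checked
#' against published values without any patient data.
#'
#' @return data.frame with columns `endpoint`, `variable`, `pos_yes`,
#'   `pos_n`, `neg_yes`, `neg_n`, `printed_p`.
#' @export
printed_group_counts <- function() {
  path <- system.file("extdata", "tables_1_2_counts.csv", package = "rtae")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# endpoint selector shared by the modelling pipelines
endpoint_vector <- function(labels, endpoint = c("cr", "or")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "cr") labels$complete_response else labels$objective_response
}
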