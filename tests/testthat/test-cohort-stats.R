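test_that("mRECIST categories follow the response criteria with CR > PD > PR > SD precedence", {
  expect_equal(mrecist_classify(100, 0, 20, 15), "CR")
  expect_equal(mrecist_classify(100, 70, 20, 20), "PR")   # 30% drop, boundary in
  expect_equal(mrecist_classify(100, 71, 20, 20), "SD")   # 29% drop: not enough
  expect_equal(mrecist_classify(100, 90, 20, 24), "PD")   # 20% size increase
  expect_equal(mrecist_classify(100, 50, 20, 24), "PD")   # progression dominates PR
  expect_equal(mrecist_classify(100, 0, 20, 30), "CR")    # CR dominates everything
  expect_error(mrecist_classify(0, 0, 20, 20), "positive")
  expect_error(mrecist_classify(100, -1, 20, 20), "non-negative")

  # exhaustive grid: categories are exclusive and cover all cases
  grid <- expand.grid(post_enh = seq(0, 120, by = 10),
                      post_size = seq(10, 40, by = 2))
  cats <- mrecist_classify(100, grid$post_enh, 20, grid$post_size)
  expect_true(all(cats %in% c("CR", "PR", "SD", "PD")))
  expect_length(cats, nrow(grid))
})

test_that("cohort summary reproduces count/percentage arithmetic", {
  labs <- response_labels(rep(c("CR", "PR", "SD", "PD"), c(14, 15, 19, 3)))
  s <- summarize_cohort(labs)
  expect_equal(s$n, 51)
  ep <- s$endpoints
  expect_equal(ep$count[ep$endpoint == "objective_response"], 29)
  expect_equal(ep$pct[ep$endpoint == "objective_response"], 56.9)
  expect_equal(s$categories$pct[s$categories$category == "PR"], 29.4)
  expect_equal(s$categories$pct[s$categories$category == "SD"], 37.3)
  # percentages sum to 100 up to rounding
  expect_lt(abs(sum(s$categories$pct) - 100), 0.3)

  one <- summarize_cohort(response_labels("CR"))
  expect_equal(one$categories$pct[1], 100)
  expect_error(summarize_cohort(response_labels(character(0))), "empty")
})

test_that("Fisher exact p equals exhaustive table enumeration and printed table values", {
  # printed 2x2 rows from the baseline tables (fixture)
  counts <- printed_group_counts()
  rows <- counts[counts$variable %in% c("threshold_growth", "nonrim_aphe",
                                        "blood_products") &
                   counts$endpoint == "cr", ]
  p <- mapply(function(a, n1, b, n2)
    fisher_exact_2x2(a, b, n1 - a, n2 - b), rows$pos_yes, rows$pos_n,
    rows$neg_yes, rows$neg_n)
  expect_equal(round(p, 3), rows$printed_p)

  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1.0)
  expect_equal(fisher_exact_2x2(0, 0, 5, 7), 1.0)   # zero margin convention

  # exhaustive-enumeration oracle on random tables with n <= 60
  set.seed(42)
  for (i in 1:50) {
    tab <- as.vector(stats::rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
    expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                 oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
    # invariance under row and column swaps
    expect_equal(fisher_exact_2x2(tab[2], tab[1], tab[4], tab[3]),
                 fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[3], tab[4], tab[1], tab[2]),
                 fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
})

test_that("Pearson chi-squared matches the hand formula and a permutation null", {
  # perfectly proportional table
  prop <- pearson_chi2(matrix(c(10, 20, 5, 10), 2))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)

  res <- pearson_chi2(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)  # hand computation
  expect_equal(res$df, 1)

  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2)), "Fisher")

  # Monte-Carlo permutation oracle; large n so the asymptotic p and the
  # (discrete) conditional permutation p are comparable
  tab <- matrix(c(520, 480, 480, 520), 2)
  g <- rep(0:1, colSums(tab))
  x <- c(rep(0:1, tab[, 1]), rep(0:1, tab[, 2]))
  set.seed(7)
  stat_of <- function(gg) {
    a <- sum(x == 0 & gg == 0); b <- sum(x == 0 & gg == 1)
    cc <- sum(x == 1 & gg == 0); d <- sum(x == 1 & gg == 1)
    sum(tab) * (as.numeric(a) * d - as.numeric(b) * cc)^2 /
      (as.numeric(a + b) * (cc + d) * (a + cc) * (b + d))
  }
  obs <- stat_of(g)
  null <- replicate(3000, stat_of(sample(g)))
  expect_lt(abs(pearson_chi2(tab)$p - mean(null >= obs - 1e-9)), 0.025)
})

test_that("Mann-Whitney U matches full enumeration and handles identical groups", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p, 0.1)                       # 2 extreme of C(6,3)=20
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(same$U), 4 * 4 / 2)

  set.seed(11)
  for (i in 1:10) {
    x0 <- round(stats::rnorm(sample(3:5, 1)), 2)
    x1 <- round(stats::rnorm(sample(3:5, 1), 0.5), 2)
    if (anyDuplicated(c(x0, x1))) next
    expect_equal(mann_whitney_u(x0, x1)$p, oracle_mann_whitney(x0, x1),
                 tolerance = 1e-10)
  }
})

test_that("group comparison report routes tests and flags untestable variables", {
  d <- generate_feature_table(cohort_config(n_patients = 60, n_radiomics = 5,
                                            prevalence = 0.3, seed = 9))
  d$lirads$never_seen <- 0L                    # constant: untestable
  rep <- compare_groups(d, "cr")
  expect_equal(nrow(rep), ncol(d$clinical) + ncol(d$lirads))
  expect_true(is.na(rep$p[rep$variable == "never_seen"]))
  expect_true(all(rep$test[rep$type == "continuous"] == "mann-whitney",
                  na.rm = TRUE))
  expect_true(all(rep$p >= 0 & rep$p <= 1, na.rm = TRUE))
})
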