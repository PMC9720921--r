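test_that("cohort simulation is a pure function of n, params and seed", {
  a <- simulate_cohort(50, seed = 5)
  b <- simulate_cohort(50, seed = 5)
  expect_identical(a, b)
  c <- simulate_cohort(50, seed = 6)
  expect_false(identical(a, c))
  expect_true(all(a$gcs >= 3 & a$gcs <= 15))
  expect_true(all(a$baseline_volume_mL > 0))
  expect_true(all(a$hii > 100))
})

test_that("intercept-only generator reproduces its expansion rate", {
  p0 <- cohort_params(beta = c(intercept = qlogis(0.3), age = 0, female = 0,
                               alcohol = 0, smoking = 0, hypertension = 0,
                               diabetes = 0, gcs = 0, onset_to_ct_h = 0,
                               baseline_volume_mL = 0, hii = 0))
  d <- simulate_cohort(5000, p0, seed = 1)
  # binomial 3-sigma band around 0.3 at n = 5000
  expect_lt(abs(mean(d$expansion) - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
})

test_that("cohort_params validates inputs", {
  expect_error(cohort_params(nonsense = 1), class = "hii_domain_error")
  expect_error(cohort_params(female = 1.4), class = "hii_domain_error")
  expect_error(cohort_params(age = c(mean = 60, sd = -1)),
               class = "hii_domain_error")
})

test_that("baseline summary picks tests by the normality gate", {
  set.seed(7)
  d <- simulate_cohort(120, seed = 7)
  tab <- summarize_baseline(d)
  expect_true(all(c("hii", "age", "female") %in% tab$variable))
  expect_identical(tab$test[tab$variable == "female"],
                   "chi-square")
  # heavy-tailed log-normal volume must fail the gate
  expect_identical(tab$test[tab$variable == "baseline_volume_mL"],
                   "mann-whitney")
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
})

test_that("two-point groups give the exact Mann-Whitney p of 1/3", {
  d <- data.frame(hii = c(1, 2, 3, 4), expansion = c(0, 0, 1, 1))
  tab <- summarize_baseline(d, variables = "hii")
  expect_identical(tab$test, "mann-whitney")
  expect_equal(tab$p_value, 1 / 3, tolerance = 1e-12)
})

test_that("identical groups and balanced flags give p = 1", {
  set.seed(8)
  x <- c(rnorm(10, 50, 5))
  d <- data.frame(age = rep(x, 2),
                  female = rep(rep(c(0, 1), each = 5), 2),
                  expansion = rep(c(0, 1), each = 10))
  tab <- summarize_baseline(d, variables = c("age", "female"))
  expect_equal(tab$p_value[tab$variable == "age"], 1, tolerance = 1e-9)
  expect_equal(tab$p_value[tab$variable == "female"], 1, tolerance = 1e-12)
})

test_that("zero-variance variables are flagged rather than crashing", {
  d <- data.frame(age = rep(5, 20), expansion = rep(c(0, 1), 10))
  tab <- summarize_baseline(d, variables = "age")
  expect_identical(tab$flag, "zero variance")
  expect_true(is.na(tab$p_value))
})

test_that("logistic OR on a 2x2 table equals ad/bc", {
  d <- data.frame(x = c(rep(1, 15), rep(0, 15)),
                  expansion = c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10)))
  fit <- fit_logistic(d, "expansion", "x")
  or <- fit$table$odds_ratio[fit$table$term == "x"]
  expect_equal(or, (10 * 10) / (5 * 5), tolerance = 1e-6)
  expect_true(fit$table$ci_low[2] <= or && or <= fit$table$ci_high[2])
})

test_that("degenerate logistic designs are rejected", {
  d <- data.frame(x = rnorm(30), expansion = rep(1, 30))
  expect_error(fit_logistic(d, "expansion", "x"), class = "hii_stats_error")

  d <- simulate_cohort(60, seed = 2)
  d$hii2 <- d$hii
  err <- expect_error(fit_logistic(d, "expansion", c("hii", "hii2")),
                      class = "hii_stats_error")
  expect_match(conditionMessage(err), "hii2")

  # complete separation must not yield inflated odds ratios
  d <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)),
                  expansion = rep(c(0, 1), each = 20))
  expect_error(fit_logistic(d, "expansion", "x"), class = "hii_stats_error")
})

test_that("multivariate selection keeps p < 0.1 strictly, in order", {
  univ <- data.frame(term = c("age", "volume", "gcs", "hii", "border"),
                     p_value = c(0.072, 0.008, 0.023, 0.0005, 0.10))
  expect_identical(select_for_multivariate(univ),
                   c("age", "volume", "gcs", "hii"))
  expect_identical(select_for_multivariate(univ[0, ]), character(0))
})

test_that("Hosmer-Lemeshow is zero under perfect calibration and errors when g > n", {
  p <- rep((1:10) / 11, each = 22)
  y <- unlist(lapply(1:10, function(k) rep(c(1, 0), c(2 * k, 22 - 2 * k))))
  hl <- hosmer_lemeshow(p, y)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$p_value, 1, tolerance = 1e-12)
  expect_error(hosmer_lemeshow(runif(5), rbinom(5, 1, 0.5), g = 10),
               class = "hii_stats_error")
})

test_that("ROC handles the textbook cases", {
  r <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$youden_j, 1)
  expect_gt(r$youden_cutoff, 2); expect_lte(r$youden_cutoff, 3)

  r <- roc_youden(c(3, 1, 2, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75, tolerance = 1e-12)
  expect_error(roc_youden(1:5, rep(1, 5)), class = "hii_stats_error")
})

test_that("trapezoidal AUC equals pair counting on random tied instances", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_youden(scores, labels)$auc,
                 pair_count_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("DeLong interval matches the independent pROC implementation", {
  set.seed(17)
  for (i in 1:5) {
    s <- rnorm(80); y <- rbinom(80, 1, plogis(1.5 * s))
    if (length(unique(y)) < 2) next
    r <- roc_youden(s, y)
    pr <- pROC::roc(y, s, quiet = TRUE, direction = "<")
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(c(r$auc_ci_low, r$auc_ci_high), ci[c(1, 3)],
                 tolerance = 1e-9)
  }
})

test_that("permuted labels give chance-level AUC on average", {
  set.seed(23)
  s <- rnorm(200)
  aucs <- replicate(100, {
    y <- sample(rep(c(0, 1), each = 100))
    roc_youden(s, y)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("ICC(1,1) matches hand ANOVA and behaves under agreement changes", {
  ic <- icc_oneway(matrix(c(1, 2, 3, 2, 3, 4), ncol = 2))
  expect_equal(ic$ms_between, 2, tolerance = 1e-12)
  expect_equal(ic$ms_within, 0.5, tolerance = 1e-12)
  expect_equal(ic$icc, 0.6, tolerance = 1e-12)

  x <- rnorm(5, 100, 10)
  expect_equal(icc_oneway(cbind(x, x))$icc, 1.0, tolerance = 1e-12)
  expect_error(icc_oneway(matrix(5, 4, 2)), class = "hii_stats_error")

  # invariant under a common shift; degraded by one-column noise
  set.seed(3)
  base <- rnorm(40, 120, 10)
  g0 <- cbind(base, base + rnorm(40, 0, 2))
  expect_equal(icc_oneway(g0 + 7)$icc, icc_oneway(g0)$icc, tolerance = 1e-9)
  iccs <- sapply(c(2, 6, 12), function(sd_noise) {
    set.seed(4)
    icc_oneway(cbind(base, base + rnorm(40, 0, sd_noise)))$icc
  })
  expect_true(all(diff(iccs) < 0))
})

test_that("independently shuffled rating columns have chance-level ICC", {
  set.seed(29)
  iccs <- replicate(100, {
    g <- matrix(rnorm(100), ncol = 2)
    icc_oneway(apply(g, 2, sample))$icc
  })
  expect_lt(abs(mean(iccs)), 0.1)
})

test_that("simulated crude and adjusted HII odds ratios exceed 1 when the generator says so", {
  d <- simulate_cohort(400, seed = 11)
  univ <- univariate_logistic(d)
  expect_gt(univ$odds_ratio[univ$term == "hii"], 1)
  sel <- select_for_multivariate(univ)
  expect_true("hii" %in% sel)
  adj <- fit_logistic(d, "expansion", sel)
  expect_gt(adj$table$odds_ratio[adj$table$term == "hii"], 1)
})
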