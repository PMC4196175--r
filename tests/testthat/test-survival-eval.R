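test_that("Kaplan-Meier estimate matches the hand product-limit", {
  # no events: flat at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # all events at distinct times
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # survival non-increasing from 1
  set.seed(80)
  for (r in 1:10) {
    d <- random_surv_data(25)
    km <- km_estimate(d$time, d$event)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv <= 1))
    bf <- bf_km(d$time, d$event)
    expect_lt(max(abs(km$surv[match(bf$time, km$time)] - bf$surv)), 1e-12)
  }
})

test_that("logrank test agrees with the risk-set brute force and is symmetric", {
  g <- rep(c("A", "B"), each = 3)
  tm <- c(1, 2, 3, 4, 5, 6); ev <- rep(1, 6)
  lr <- logrank_test(g, tm, ev)
  expect_equal(lr$chi2, bf_logrank(g, tm, ev), tolerance = 1e-10)
  # label swap leaves the statistic unchanged
  lr2 <- logrank_test(rev(g), tm, ev)
  expect_equal(lr$chi2, lr2$chi2, tolerance = 1e-12)
  # internal consistency: chi2 = (O - E)^2 / V is what the brute force uses
  set.seed(81)
  for (r in 1:10) {
    d <- random_surv_data(30)
    g <- sample(c("A", "B"), 30, replace = TRUE)
    if (length(unique(g)) < 2 || sum(d$event) == 0) next
    expect_equal(logrank_test(g, d$time, d$event)$chi2,
                 bf_logrank(g, d$time, d$event), tolerance = 1e-8)
  }
  expect_error(logrank_test(rep("A", 5), 1:5, rep(1, 5)), "two")
})

test_that("logrank type-I error is calibrated under the null", {
  set.seed(82)
  rej <- vapply(1:2000, function(r) {
    tm <- rexp(40, 0.2); ev <- rbinom(40, 1, 0.8)
    g <- rep(c("A", "B"), 20)
    logrank_test(g, tm, ev)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.012)
})

test_that("cox_hr satisfies reciprocity and recovers a known rate ratio", {
  set.seed(83)
  g <- factor(rep(c("low", "high"), each = 1000), c("low", "high"))
  tm <- c(rexp(1000, 0.1), rexp(1000, 0.2))
  ev <- rep(1L, 2000)
  h <- cox_hr(g, tm, ev)
  expect_gt(h$hr, 1.8); expect_lt(h$hr, 2.2)
  expect_true(h$ci[1] < h$hr && h$hr < h$ci[2])
  # reciprocity under group relabelling
  g_rev <- factor(as.character(g), c("high", "low"))
  h2 <- cox_hr(g_rev, tm, ev)
  expect_equal(h$hr, 1 / h2$hr, tolerance = 1e-8)
  # exchangeable groups: |log HR| < 3 SE
  g0 <- sample(g)
  h0 <- cox_hr(g0, tm, ev)
  expect_lt(abs(h0$log_hr), 3 * h0$se)
  # monotone likelihood warns
  expect_warning(cox_hr(factor(c("low", "low", "high", "high"), c("low", "high")),
                        c(5, 6, 1, 2), c(0, 0, 1, 1)), "monotone")
})

test_that("concordance index matches exhaustive pair enumeration", {
  # perfect ordering of uncensored times
  ci1 <- concordance_index(score = 4:1, time = 1:4, event = rep(1, 4))
  expect_equal(ci1$c, 1)
  # independent score is near 0.5
  set.seed(84)
  d <- random_surv_data(300)
  ci0 <- concordance_index(rnorm(300), d$time, d$event)
  expect_lt(abs(ci0$c - 0.5), 3 * ci0$se)
  # oracle equivalence incl. ties and censoring
  for (r in 1:15) {
    d <- random_surv_data(sample(10:30, 1))
    ci <- concordance_index(d$score, d$time, d$event)
    bf <- bf_cindex(d$score, d$time, d$event)
    expect_equal(ci$c, unname(bf["c"]), tolerance = 1e-12)
    expect_equal(ci$n_pairs, unname(bf["n_pairs"]))
    # antisymmetry on tie-free data
    if (!anyDuplicated(d$score) && !anyDuplicated(d$time))
      expect_equal(concordance_index(-d$score, d$time, d$event)$c, 1 - ci$c,
                   tolerance = 1e-12)
    # survival::concordance as an independent second route
    cref <- survival::concordance(survival::Surv(d$time, d$event) ~ d$score,
                                  reverse = TRUE)
    expect_equal(ci$c, unname(cref$concordance), tolerance = 1e-12)
  }
  expect_error(concordance_index(1, 1, 1), "two")
  expect_error(concordance_index(c(1, 2), c(3, 3), c(0, 0)), "usable")
})

test_that("horizon metrics reduce to the confusion matrix", {
  # definitional case: sens 0.8, spec 0.6 -> BCR 0.7
  grp <- factor(c(rep("high", 8), rep("low", 2),    # 10 cases
                  rep("low", 6), rep("high", 4)),   # 10 controls
                c("low", "high"))
  tm <- c(rep(2, 10), rep(9, 10)); ev <- c(rep(1, 10), rep(0, 10))
  bm <- binary_metrics_at_horizon(grp, tm, ev, 5)
  expect_equal(bm$sensitivity, 0.8)
  expect_equal(bm$specificity, 0.6)
  expect_equal(bm$bcr, 0.7)
  # everyone high risk: sens 1, spec 0, BCR 0.5
  bm2 <- binary_metrics_at_horizon(factor(rep("high", 20), c("low", "high")),
                                   tm, ev, 5)
  expect_equal(c(bm2$sensitivity, bm2$specificity, bm2$bcr), c(1, 0, 0.5))
  # brute-force equivalence with exclusions
  set.seed(85)
  for (r in 1:15) {
    d <- random_surv_data(40)
    g <- factor(sample(c("low", "high"), 40, TRUE), c("low", "high"))
    bf <- bf_binary_metrics(g, d$time, d$event, 5)
    if (!is.finite(bf["sensitivity"]) || !is.finite(bf["specificity"])) next
    bm <- binary_metrics_at_horizon(g, d$time, d$event, 5)
    expect_equal(bm$sensitivity, unname(bf["sensitivity"]))
    expect_equal(bm$specificity, unname(bf["specificity"]))
    expect_equal(bm$bcr, unname(bf["bcr"]))
  }
  expect_error(binary_metrics_at_horizon(grp, rep(1, 20), rep(0, 20), 5),
               "case")
})

test_that("fixed-effect pooling is the inverse-variance mean", {
  p1 <- pool_estimates(0.7, 0.1, "log-hr")
  expect_equal(p1$estimate, 0.7)
  expect_equal(p1$se, 0.1)
  p2 <- pool_estimates(c(0.6, 0.6), c(0.2, 0.2), "bcr")
  expect_equal(p2$estimate, 0.6)
  expect_equal(p2$se, 0.2 / sqrt(2))
  set.seed(86)
  for (r in 1:20) {
    k <- sample(2:6, 1)
    est <- rnorm(k); se <- runif(k, 0.05, 0.5)
    p <- pool_estimates(est, se, "log-hr")
    bf <- bf_pooled(est, se)
    expect_equal(p$estimate, unname(bf["estimate"]), tolerance = 1e-12)
    expect_equal(p$se, unname(bf["se"]), tolerance = 1e-12)
    # pooled estimate within the cohort range
    expect_gte(p$estimate, min(est)); expect_lte(p$estimate, max(est))
  }
  expect_error(pool_estimates(1, 0, "bcr"), "positive")
})

test_that("per-cohort evaluation composes into a pooled report", {
  set.seed(87)
  mk <- function(n, hr) {
    g <- factor(sample(c("low", "high"), n, TRUE), c("low", "high"))
    tm <- rexp(n, 0.1 * ifelse(g == "high", hr, 1))
    list(group = g, time = pmin(tm, 10), event = as.integer(tm <= 10),
         score = as.integer(g == "high") + rnorm(n, sd = 0.1))
  }
  strata <- list(A = mk(120, 2.5), B = mk(150, 2.5))
  rep <- evaluate_cohorts(strata, horizon = 5)
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$cohort_id, c("A", "B", "pooled"))
  pooled <- rep[3, ]
  expect_true(pooled$log_hr >= min(rep$log_hr[1:2]) - 1e-12 &&
              pooled$log_hr <= max(rep$log_hr[1:2]) + 1e-12)
  expect_true(all(rep$bcr == (rep$sensitivity + rep$specificity) / 2,
                  na.rm = TRUE))
  expect_true(all(rep$hr_lo <= rep$hr & rep$hr <= rep$hr_hi))
})

test_that("paired bootstrap comparison is symmetric and null-calibrated", {
  set.seed(88)
  n <- 200
  act <- rnorm(n)
  tm <- rexp(n, 0.1 * exp(log(2.5) * act)); ev <- as.integer(tm <= 10)
  tm <- pmin(tm, 10)
  informative <- factor(ifelse(act > 0, "high", "low"), c("low", "high"))
  random_g <- factor(sample(c("low", "high"), n, TRUE), c("low", "high"))
  metric <- function(g, t, e) -log10(logrank_test(g, t, e)$p)

  # identical stratifications: zero difference, p = 1
  expect_warning(same <- compare_paired(metric, informative, informative,
                                        tm, ev, n_boot = 50, seed = 1),
                 "degenerate")
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)

  cmp <- compare_paired(metric, informative, random_g, tm, ev,
                        n_boot = 200, seed = 2)
  expect_lt(cmp$p, 0.05)
  # two-sided symmetry
  cmp_rev <- compare_paired(metric, random_g, informative, tm, ev,
                            n_boot = 200, seed = 2)
  expect_equal(cmp$p, cmp_rev$p, tolerance = 1e-12)
  expect_equal(cmp$diff, -cmp_rev$diff)
})
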