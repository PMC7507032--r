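# Kaplan-Meier, log-rank, ROC cutoff, Pearson correlation.

test_that("KM estimate reproduces the hand product-limit computation", {
  # 6 subjects: event at t=1 (6 at risk), censor at t=2, event at t=3
  # (4 at risk), three censored later
  rec <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                    event = c(1, 0, 1, 0, 0, 0))
  km <- km_estimate(rec)
  expect_equal(km$survival[km$time == 1], 5 / 6)
  expect_equal(km$survival[km$time == 3], (5 / 6) * (3 / 4))
  expect_equal(km$n_risk[km$time == 3], 4)
})

test_that("KM reduces to the empirical survival without censoring", {
  rec <- data.frame(time = c(2, 5, 1, 9, 7), event = 1)
  km <- km_estimate(rec)
  expect_equal(km$survival, 1 - ecdf(rec$time)(km$time))
  expect_true(all(diff(km$survival) <= 0))
})

test_that("KM handles all-censored cohorts and rejects negative times", {
  rec <- data.frame(time = c(1, 2, 3), event = 0)
  expect_true(all(km_estimate(rec)$survival == 1))
  expect_error(km_estimate(data.frame(time = -1, event = 1)), "negative")
  # moving a censoring time beyond the last event even later changes nothing
  base <- data.frame(time = c(1, 2, 4), event = c(1, 1, 0))
  moved <- base; moved$time[3] <- 9
  k1 <- km_estimate(base); k2 <- km_estimate(moved)
  expect_equal(k2$survival, k1$survival)
  expect_equal(k2$n_event, k1$n_event)
})

test_that("log-rank equals the brute-force O/E/V accumulation", {
  set.seed(40)
  for (i in 1:15) {
    n <- sample(20:60, 1)
    rec <- data.frame(time = round(rexp(n, 0.1), 1),
                      event = rbinom(n, 1, 0.7),
                      group = sample(c("A", "B"), n, replace = TRUE))
    if (length(unique(rec$group)) < 2 || sum(rec$event) == 0) next
    got <- logrank_test(rec)
    expect_equal(got$chisq,
                 logrank_oracle(rec$time, rec$event, rec$group),
                 tolerance = 1e-8)
  }
})

test_that("log-rank is symmetric in group labels and null on identical groups", {
  rec <- data.frame(time = rep(c(1, 3, 5, 7), 2),
                    event = rep(c(1, 1, 0, 1), 2),
                    group = rep(c("A", "B"), each = 4))
  got <- logrank_test(rec)
  expect_equal(got$chisq, 0, tolerance = 1e-12)
  expect_equal(got$p_value, 1, tolerance = 1e-12)
  swapped <- rec
  swapped$group <- ifelse(rec$group == "A", "B", "A")
  expect_equal(logrank_test(swapped)$chisq, got$chisq, tolerance = 1e-12)
  expect_error(logrank_test(data.frame(time = 1:3, event = 1,
                                       group = c("A", "A", "A"))),
               "two non-empty groups")
})

test_that("roc_cutoff equals the exhaustive scan and separates clean data", {
  sep <- roc_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$youden, 1)
  expect_gt(sep$cutoff, 3); expect_lt(sep$cutoff, 10)
  set.seed(41)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    marker <- round(rnorm(n), 1)
    outcome <- rbinom(n, 1, 0.4)
    if (length(unique(outcome)) < 2 || length(unique(marker)) < 2) next
    got <- roc_cutoff(marker, outcome)
    want <- roc_oracle(marker, outcome)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden, want$youden)
  }
  expect_error(roc_cutoff(1:5, rep(1, 5)), "both outcome classes")
})

test_that("roc_cutoff agrees with pROC's Youden-best threshold", {
  skip_if_not_installed("pROC")
  set.seed(42)
  marker <- rnorm(80)
  outcome <- rbinom(80, 1, plogis(marker))
  got <- roc_cutoff(marker, outcome)
  r <- pROC::roc(outcome, marker, quiet = TRUE, direction = "<")
  best <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
  expect_equal(got$sensitivity + got$specificity,
               max(best$sensitivity + best$specificity), tolerance = 1e-9)
})

test_that("pearson_correlation matches cor.test and rejects degenerate input", {
  x <- c(1, 4, 2, 8, 5)
  y <- c(2, 5, 1, 9, 4)
  got <- pearson_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p_value, ct$p.value)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(2, 5)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "3 observations")
})

test_that("dichotomize_and_compare splits at the cutoff and compares groups", {
  coh <- simulate_survival_cohort(200, hazard_ratio = 3, censor_rate = 0.2,
                                  seed = 43)
  dc <- dichotomize_and_compare(coh)
  expect_true(all(coh$marker[dc$group == "high"] > dc$cutoff))
  # marker-high group dies faster: smaller survival at a shared time horizon
  surv_at <- function(km, t) {
    s <- km$survival[km$time <= t]
    if (length(s) == 0) 1 else tail(s, 1)
  }
  t_mid <- median(coh$time)
  expect_lt(surv_at(dc$km$high, t_mid), surv_at(dc$km$low, t_mid))
  expect_lt(dc$logrank$p_value, 0.05)
  expect_error(dichotomize_and_compare(coh, cutoff = max(coh$marker) + 1),
               "empty")
})
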