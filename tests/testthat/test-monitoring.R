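# Landmark/fast-fail cuts, change direction, limit of blank, KM/log-rank
# and multivariate Cox.

test_that("median cut splits distinct scores evenly, ties go to nonresponders", {
  d20 <- tibble::tibble(s = seq(0.01, 0.95, length.out = 20))
  g20 <- landmark_median_cut(d20, s)
  expect_equal(unname(table(g20$group)["responder"]), 10L)
  expect_equal(unname(table(g20$group)["nonresponder"]), 10L)

  d2 <- tibble::tibble(s = c(0.1, 0.9))
  g2 <- landmark_median_cut(d2, s)
  expect_equal(sort(as.character(g2$group)),
               c("nonresponder", "responder"))

  # 5 scores, 3 tied at the median: the 2 strictly below respond
  d5 <- tibble::tibble(s = c(0.1, 0.2, 0.5, 0.5, 0.5))
  g5 <- landmark_median_cut(d5, s)
  expect_equal(sum(g5$group == "responder"), 2L)
  expect_equal(attr(g5, "cut"), 0.5)

  # odd n with distinct scores: groups differ by at most one
  d7 <- tibble::tibble(s = runif(7))
  g7 <- landmark_median_cut(dplyr::distinct(d7), s)
  expect_lte(abs(diff(as.integer(table(g7$group)))), 1)
})

test_that("fast-fail flags scores strictly above the 75th percentile", {
  d36 <- tibble::tibble(s = seq_len(36) / 37)
  for (conv in c("linear", "nearest_rank")) {
    g <- fast_fail_cut(d36, s, convention = conv)
    expect_equal(sum(g$group == "high"), 9L, info = conv)
    expect_equal(sum(g$group == "low"), 27L, info = conv)
  }
  d4 <- tibble::tibble(s = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(sum(fast_fail_cut(d4, s)$group == "high"), 1L)
  dflat <- tibble::tibble(s = rep(0.5, 8))
  expect_equal(sum(fast_fail_cut(dflat, s)$group == "high"), 0L)
})

test_that("change direction is strict, ties fall to decreasing with a flag", {
  d <- tibble::tibble(b = c(0.2, 0.5, 0.3), l = c(0.5, 0.2, 0.3))
  res <- change_direction(d, b, l)
  expect_equal(as.character(res$direction),
               c("increasing", "decreasing", "decreasing"))
  expect_equal(res$tie, c(FALSE, FALSE, TRUE))
})

test_that("limit of blank is the max negative score; positives must exceed it", {
  lob <- limit_of_blank(c(0.01, 0.02, 0.04))
  expect_equal(lob, 0.04)
  expect_false(call_positive(0.04, lob))
  expect_true(call_positive(0.0401, lob))
  set.seed(8)
  negs <- runif(100, 0, 0.05)
  expect_equal(sum(call_positive(negs, limit_of_blank(negs))), 0L)
  expect_error(limit_of_blank(c(0.1, 0.2)), ">= 3")
})

test_that("identical group survival gives a null log-rank test", {
  base <- tibble::tibble(time = c(5, 8, 12, 20, 33, 40),
                         event = c(1, 1, 0, 1, 1, 0))
  df <- dplyr::bind_rows(dplyr::mutate(base, group = "a"),
                         dplyr::mutate(base, group = "b"))
  res <- km_logrank(df, time, event, group)
  expect_lt(res$logrank_chisq, 1e-10)
  expect_equal(res$logrank_p, 1, tolerance = 1e-6)
  expect_equal(res$hr, 1, tolerance = 1e-6)
})

test_that("log-rank matches an independent life-table computation", {
  # 6 vs 6 toy cohort; oracle computes O-E and hypergeometric variance
  df <- tibble::tibble(
    time = c(6, 13, 21, 30, 31, 37, 38, 47, 49, 50, 63, 79),
    event = c(1, 1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1),
    group = rep(c("ctrl", "trt"), 6))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(df$time[df$event == 1]))) {
    at_risk <- df$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & df$group == "trt")
    d <- sum(df$time == t & df$event == 1)
    d1 <- sum(df$time == t & df$event == 1 & df$group == "trt")
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq_oracle <- o_minus_e^2 / v
  res <- km_logrank(df, time, event, group)
  expect_equal(res$logrank_chisq, chisq_oracle, tolerance = 1e-8)
  expect_equal(res$logrank_p,
               pchisq(chisq_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("degenerate stratifications are errors", {
  df <- tibble::tibble(time = c(3, 4, 5), event = c(1, 1, 0),
                       group = "only")
  expect_error(km_logrank(df, time, event, group),
               class = "cfmonitor_single_group")
  df2 <- tibble::tibble(time = c(3, 4), event = c(0, 0),
                        group = c("a", "b"))
  expect_error(km_logrank(df2, time, event, group),
               class = "cfmonitor_no_events")
})

test_that("a binary covariate with true HR 2 is recovered within its CI", {
  set.seed(9)
  n <- 300
  x <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, rate = 0.01 * 2^x)
  df <- tibble::tibble(time = time, event = 1L, x = x)
  fit <- cox_multivariate(df, "time", "event", "x")
  td <- tidy(fit)
  expect_true(td$ci_low <= 2 && 2 <= td$ci_high)
})

test_that("constant covariates are dropped, collinear ones rejected", {
  set.seed(10)
  df <- tibble::tibble(time = rexp(40, 0.02), event = 1L,
                       x = rnorm(40), bilirubin_high = 0)
  expect_warning(fit <- cox_multivariate(df, "time", "event",
                                         c("x", "bilirubin_high")),
                 "bilirubin_high")
  expect_equal(fit$covariates, "x")

  df$x2 <- df$x
  expect_error(cox_multivariate(df, "time", "event", c("x", "x2")),
               class = "cfmonitor_collinear")
  df0 <- dplyr::mutate(df, event = 0L)
  expect_error(cox_multivariate(df0, "time", "event", "x"),
               class = "cfmonitor_no_events")
})

test_that("standardizing a score scales its log-HR by the SD, p unchanged", {
  set.seed(11)
  n <- 200
  s <- rnorm(n, 5, 2.5)
  time <- rexp(n, rate = 0.005 * exp(0.3 * s))
  df <- tibble::tibble(time = time, event = 1L, s = s)
  raw <- tidy(cox_multivariate(df, "time", "event", "s"))
  std <- tidy(cox_multivariate(df, "time", "event", "s",
                               standardize = "s"))
  expect_equal(std$log_hr, raw$log_hr * sd(s), tolerance = 1e-6)
  expect_equal(std$p_value, raw$p_value, tolerance = 1e-6)
})

test_that("timepoint roles follow treatment start", {
  d <- tibble::tibble(patient_id = 1, draw_day = c(-3, 14, 56))
  roles <- select_timepoints(d)
  expect_equal(roles$role[order(roles$draw_day)],
               c("baseline", "fast_fail", "landmark"))

  d2 <- tibble::tibble(patient_id = 1, draw_day = c(10, 50))
  r2 <- select_timepoints(d2)
  expect_false("baseline" %in% r2$role)
  miss <- attr(r2, "patients_missing_roles")
  expect_true(miss$baseline[miss$patient_id == 1])

  d3 <- tibble::tibble(patient_id = 1, draw_day = c(-3, 14, 14, 56))
  expect_warning(r3 <- select_timepoints(d3), "duplicate")
  expect_equal(nrow(r3), 3)
})

test_that("cohort-level landmark stratification separates true responders", {
  co <- simulate_cohort(sim_config(seed = 131, n_patients = 60,
                                   fragments_per_sample = 1000))
  landmark <- dplyr::filter(select_timepoints(co$cohort),
                            role == "landmark")
  cut <- landmark_median_cut(landmark, tf_score)
  res <- km_logrank(cut, os_days, os_event, group)
  expect_lt(res$hr, 1)           # responders (below cut) live longer
  expect_lt(res$logrank_p, 0.05)
  td <- tidy(res)
  expect_equal(sum(td$n), 60)
})
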