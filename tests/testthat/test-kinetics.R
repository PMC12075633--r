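test_that("a noiseless step yields one change point at the right frame", {
  x <- c(rep(0.60, 200), rep(0.08, 250))
  d <- detect_transitions(x)
  expect_identical(d$changepoints, 201L)
  expect_identical(d$segments$state, c("high", "low"))
  expect_error(detect_transitions(x[1:4], min_dwell = 3), "shorter")
})

test_that("pure noise rarely produces spurious transitions", {
  set.seed(21)
  n_fp <- 0
  for (i in 1:300) {
    x <- chung_kennedy(stats::rnorm(450, 0.6, 0.07))
    if (length(detect_transitions(x)$changepoints) > 0) n_fp <- n_fp + 1
  }
  expect_lt(n_fp / 300, 0.01)
  # the permissive over-segmentation used by the dwell pipeline is guarded
  # by the same two-state merge
  set.seed(22)
  n_fp <- 0
  for (i in 1:300) {
    x <- fretdyn:::run_median(stats::rnorm(450, 0.6, 0.09), 3)
    if (length(detect_transitions(x, alpha = 0.05)$changepoints) > 0)
      n_fp <- n_fp + 1
  }
  expect_lt(n_fp / 300, 0.01)
})

test_that("transitions of a noisy multi-step trace are recovered to +-2 frames", {
  sc <- clean_scenario()
  cf <- default_cf()
  true_cp <- c(20, 45, 70)  # seconds into the green segment
  trc <- render_trace(manual_truth(90, "associated", true_cp), sc, seed = 31)
  p <- process_trace(trc, cf)
  d <- detect_transitions(p$E_raw, alpha = 0.05)
  expect_length(d$changepoints, 3)
  found_s <- (d$changepoints - 1) * 0.2
  expect_true(all(abs(found_s - true_cp) <= 0.4))
})

test_that("dwell harvesting keeps only interior dwells as complete", {
  # transitions at 20 s and 50 s -> exactly one complete dwell of 30 s
  x <- c(rep(0.6, 100), rep(0.08, 150), rep(0.6, 200))
  d <- detect_transitions(x)
  dw <- harvest_dwells(d, frame_time = 0.2)
  expect_identical(dw$censoring, c("first", "complete", "last"))
  comp <- dw[dw$censoring == "complete", ]
  expect_equal(comp$duration_s, 30)
  expect_identical(comp$state, "low")
  # static trace contributes zero complete dwells
  d0 <- detect_transitions(rep(0.6, 450))
  dw0 <- harvest_dwells(d0, frame_time = 0.2)
  expect_identical(sum(dw0$censoring == "complete"), 0L)
  # single transition: first and last dwell only
  d1 <- detect_transitions(c(rep(0.6, 200), rep(0.08, 250)))
  dw1 <- harvest_dwells(d1, frame_time = 0.2)
  expect_identical(sum(dw1$censoring == "complete"), 0L)
})

test_that("exponential MLE recovers the mean dwell on untruncated data", {
  set.seed(41)
  x <- stats::rexp(10000, 1 / 8)
  x <- x[x < 900]
  f <- fit_exponential_dwells(x, window_s = 900, method = "window")
  expect_equal(f$tau, 8, tolerance = 0.25 / 8 * 3)
  expect_true(f$ci[1] < f$tau && f$tau < f$ci[2])
  expect_error(fit_exponential_dwells(x[1:10], window_s = 900), "refused")
})

test_that("degenerate equal dwells are flagged non-exponential", {
  f <- fit_exponential_dwells(rep(5, 30), window_s = 90)
  expect_identical(f$flag, "non_exponential")
  expect_true(is.na(f$tau))
})

test_that("window-corrected MLE beats the naive mean under censoring", {
  # truncated-exponential oracle: interior dwells in a finite window are
  # length-biased; the naive mean underestimates tau, the corrected MLE
  # does not
  set.seed(42)
  window <- 90
  for (tau in c(4, 8, 20)) {
    sc <- clean_scenario(k_assoc = 1 / tau, k_diss_max = 1 / tau, atp = 1e9,
                         K_atp = 380)
    dw <- c()
    while (length(dw) < 4000) {
      tr <- fretdyn:::sim_path_(sc, window)
      tt <- tr$trans_times
      if (length(tt) >= 2) dw <- c(dw, diff(tt))
    }
    naive <- fit_exponential_dwells(dw, window_s = window, method = "naive")
    corr <- fit_exponential_dwells(dw, window_s = window, method = "window")
    expect_lt(abs(corr$tau - tau), abs(naive$tau - tau))
    expect_lt(naive$tau, tau)  # the direction of the naive bias
    expect_equal(corr$tau, tau, tolerance = 0.10)
  }
})

test_that("full pipeline recovers the generating rates within 15%", {
  cf <- default_cf()
  for (rates in list(c(0.05, 0.125), c(0.125, 0.05), c(0.1, 0.1))) {
    ok <- 0
    for (seed in 1:3) {
      sc <- clean_scenario(k_assoc = rates[1], k_diss_max = rates[2],
                           atp = 1e9, K_atp = 380)
      sim <- simulate_traces(sc, 200, seed = seed)
      res <- estimate_rates(sim$traces, cf)
      err_a <- abs(res$k_assoc / rates[1] - 1)
      err_d <- abs(res$k_diss / rates[2] - 1)
      if (err_a <= 0.15 && err_d <= 0.15) ok <- ok + 1
    }
    expect_gte(ok, 2)
  }
})

test_that("survival analysis handles steps, censoring and recovery", {
  # all events at exactly 5 s: the curve is a single step
  fe <- first_event_analysis(rep(5, 20), window_s = 90)
  expect_equal(fe$curve$surv[1], 1)
  expect_equal(fe$curve$surv[-1], (19:0) / 20)
  expect_true(all(diff(fe$curve$surv) <= 0))
  # exponential sampling oracle: half-life 7 s at n = 200
  set.seed(51)
  ev <- stats::rexp(200, log(2) / 7)
  f7 <- first_event_analysis(ev, window_s = 1e6)
  expect_equal(f7$half_life, 7, tolerance = 1 / 7)
  # censored traces push the estimate up relative to dropping them
  ev2 <- c(stats::rexp(100, log(2) / 7), rep(NA, 100))
  fc <- first_event_analysis(ev2, window_s = 90)
  fd <- first_event_analysis(ev2[1:100], window_s = 90)
  expect_gt(fc$half_life, fd$half_life)
  # no events: curve only
  f0 <- first_event_analysis(rep(NA_real_, 10), window_s = 90)
  expect_true(is.na(f0$rate))
  expect_equal(f0$curve$surv, 1)
})

test_that("censored exponential fit agrees with a survival-model oracle", {
  skip_if_not_installed("survival")
  set.seed(52)
  ev <- stats::rexp(300, log(2) / 7)
  cens <- ev > 30
  obs <- pmin(ev, 30)
  fe <- first_event_analysis(ifelse(cens, NA, ev), window_s = 30)
  sr <- survival::survreg(survival::Surv(obs, !cens) ~ 1,
                          dist = "exponential")
  expect_equal(fe$rate, exp(-unname(stats::coef(sr))), tolerance = 1e-6)
})

test_that("decay-rate comparison behaves like a two-tailed t test", {
  same <- compare_decay_rates(0.2, 0.02, 40, 0.2, 0.02, 40)
  expect_equal(same$p, 1)
  diff <- compare_decay_rates(0.1, 0.01, 40, 0.3, 0.01, 40)
  expect_lt(diff$p, 1e-4)
  expect_error(compare_decay_rates(0.1, NA, 40, 0.3, 0.01, 40), "standard")
  # null calibration: p approximately uniform for same-rate replicates
  set.seed(53)
  ps <- replicate(400, {
    a <- stats::rexp(80, 0.2); b <- stats::rexp(80, 0.2)
    ra <- 1 / mean(a); rb <- 1 / mean(b)
    compare_decay_rates(ra, ra / sqrt(80), 80, rb, rb / sqrt(80), 80)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("EC50 fit is exact on noiseless hyperbolas and unit-equivariant", {
  d <- c(0, 25, 50, 100, 200, 400, 800, 1600)
  y <- 0.1 + 1.9 * d / (200 + d)
  f <- fit_ec50(d, y)
  expect_equal(f$ec50, 200, tolerance = 1e-6)
  expect_equal(f$floor, 0.1, tolerance = 1e-6)
  expect_equal(f$ceiling, 2.0, tolerance = 1e-6)
  # relabeling uM -> mM scales the estimate exactly
  f_mm <- fit_ec50(d / 1000, y)
  expect_equal(f_mm$ec50 * 1000, f$ec50, tolerance = 1e-4)
  # constant readout: flagged with an unbounded interval
  f0 <- fit_ec50(d, rep(1, 8))
  expect_identical(f0$flag, "no_dose_dependence")
  expect_identical(f0$ci, c(0, Inf))
})

test_that("dose-response panels recover the kinetic half-saturation constant", {
  sc <- clean_scenario(k_assoc = 0.05, k_diss_max = 0.125, K_atp = 380)
  grid <- c(0, 38, 100, 200, 380, 760, 1700, 3800, 38000)
  cf <- default_cf()
  ec <- vapply(1:3, function(seed) {
    panel <- simulate_dose_response(sc, grid, n_traces = 150,
                                    seed = seed * 100)
    r <- vapply(panel, function(lv) {
      occupancy_ratio(efficiency_histogram(process_traces(lv$traces, cf)))
    }, numeric(1))
    fit_ec50(grid, r)$ec50
  }, numeric(1))
  expect_equal(mean(ec), 380, tolerance = 0.15)
  # seed reproducibility: independent panels agree within the profile CI
  panel_a <- simulate_dose_response(sc, grid, n_traces = 150, seed = 100)
  r_a <- vapply(panel_a, function(lv)
    occupancy_ratio(efficiency_histogram(process_traces(lv$traces, cf))),
    numeric(1))
  f_a <- fit_ec50(grid, r_a)
  expect_true(ec[2] > f_a$ci[1] && ec[2] < f_a$ci[2])
})

test_that("Welch ANOVA from summaries matches the raw-data oracle", {
  set.seed(61)
  y <- c(stats::rnorm(8, 10, 2), stats::rnorm(12, 12, 4),
         stats::rnorm(10, 9, 1))
  g <- factor(rep(1:3, c(8, 12, 10)))
  ours <- welch_anova_tukey(tapply(y, g, mean), tapply(y, g, sd),
                            tapply(y, g, length))
  ref <- stats::oneway.test(y ~ g, var.equal = FALSE)
  expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  expect_equal(ours$df2, unname(ref$parameter[2]), tolerance = 1e-10)
  # two-group pairwise comparison collapses to the Welch t test
  y2 <- y[g != 3]; g2 <- droplevels(g[g != 3])
  o2 <- welch_anova_tukey(tapply(y2, g2, mean), tapply(y2, g2, sd),
                          tapply(y2, g2, length))
  expect_equal(o2$pairwise$p, stats::t.test(y2 ~ g2)$p.value,
               tolerance = 1e-10)
  expect_error(welch_anova_tukey(c(1, 2), c(0, 1), c(5, 5)), "variance")
})

test_that("identical groups give a null omnibus result", {
  res <- welch_anova_tukey(c(5, 5, 5), c(1.2, 1.2, 1.2), c(9, 9, 9))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$pairwise$p > 0.999))
})
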