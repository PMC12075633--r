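test_that("median prefilter rejects singleton spikes and keeps constants", {
  sc <- clean_scenario(noise_sd = 0, bg_sd = 0, leakage = 0, direct_exc = 0)
  trc <- render_trace(manual_truth(90, "associated", numeric(0)), sc, seed = 1)
  out <- median_prefilter(trc)
  expect_equal(out$I_D, trc$I_D)
  expect_equal(out$bg_A, trc$bg_A)
  spiked <- trc
  g <- which(spiked$segment == "green")
  spiked$I_D[g[100]] <- spiked$I_D[g[100]] + 5000
  out <- median_prefilter(spiked)
  expect_equal(out$I_D[g[100]], trc$I_D[g[100]])
})

test_that("median of three flattens an alternating square wave", {
  # direct evaluation: median(a, -a, a) = a for every interior point, so a
  # period-2 wave collapses to the level of the majority in each window
  x <- rep(c(10, -10), 50)
  m <- fretdyn:::run_median(x, 3)
  # every interior point becomes the value of its two equal neighbours
  expect_equal(m[2:99], x[1:98])
  # edges use shrinking windows: the first point keeps a 2-point window
  expect_equal(m[1], stats::median(x[1:2]))
})

test_that("correction factors are recovered from single-dye populations", {
  sc_d <- kinetic_scenario(frac_donor_only = 1, leakage = 0.10,
                           direct_exc = 0.05)
  sc_a <- kinetic_scenario(frac_acceptor_only = 1, leakage = 0.10,
                           direct_exc = 0.05)
  don <- simulate_traces(sc_d, 15, seed = 1)$traces
  acc <- simulate_traces(sc_a, 15, seed = 2)$traces
  cf <- estimate_corrections(don, acc)
  expect_equal(cf$lk, 0.10, tolerance = 0.01)
  expect_equal(cf$dir, 0.05, tolerance = 0.01)
  sc_d0 <- kinetic_scenario(frac_donor_only = 1, leakage = 0,
                            direct_exc = 0)
  don0 <- simulate_traces(sc_d0, 12, seed = 3)$traces
  cf0 <- estimate_corrections(don0, acc)
  expect_lt(abs(cf0$lk), 5e-3)
  expect_error(estimate_corrections(list(), acc), "non-empty")
})

test_that("noiseless correction round trip reproduces the state efficiency", {
  sc <- clean_scenario(noise_sd = 0, bg_sd = 0, leakage = 0.08,
                       direct_exc = 0.05)
  cf <- correction_factors(lk = 0.08, dir = 0.05)
  for (st in c("associated", "dissociated")) {
    trc <- render_trace(manual_truth(90, st, numeric(0)), sc, seed = 1)
    cor <- correct_trace(trc, cf)
    E_true <- if (st == "associated") sc$E_assoc else sc$E_diss
    expect_lt(max(abs(cor$E_raw - E_true)), 1e-10)
  }
})

test_that("simple corrected-efficiency identities hold", {
  # lk = dir = 0, no background, equal channels -> E = 0.5
  trc <- render_trace(manual_truth(90, "associated", numeric(0)),
                      clean_scenario(noise_sd = 0, bg_sd = 0, bg_d = 0,
                                     bg_a = 0, leakage = 0, direct_exc = 0,
                                     E_assoc = 0.5),
                      seed = 1)
  cor <- correct_trace(trc, correction_factors())
  expect_equal(unique(round(cor$E_raw, 12)), 0.5)
})

test_that("dissociated-state efficiency lands near its generative value", {
  sc <- clean_scenario(leakage = 0.08, direct_exc = 0.05)
  trcs <- lapply(1:20, function(s)
    render_trace(manual_truth(90, "dissociated", numeric(0)), sc, seed = s))
  cf <- correction_factors(lk = 0.08, dir = 0.05)
  mean_e <- mean(vapply(trcs, function(tr) {
    mean(correct_trace(median_prefilter(tr), cf)$E_raw)
  }, numeric(1)))
  expect_lt(abs(mean_e - sc$E_diss), 0.02)
})

test_that("Chung-Kennedy filter is identity on constants and idempotent on steps", {
  x <- rep(7.5, 120)
  expect_equal(chung_kennedy(x), x, tolerance = 1e-12)
  step <- c(rep(100, 250), rep(200, 250))
  f1 <- chung_kennedy(step)
  expect_equal(f1, step, tolerance = 1e-6)       # edge preserved exactly
  expect_equal(chung_kennedy(f1), f1, tolerance = 1e-6)  # idempotent
  expect_error(chung_kennedy(rep(1, 15), K = 10), "length")
})

test_that("Chung-Kennedy preserves edges where a moving average smears them", {
  step <- c(rep(0.6, 200), rep(0.08, 250))
  f <- chung_kennedy(step)
  trans_frames <- sum(f > 0.09 & f < 0.59)
  expect_lte(trans_frames, 2)
  ma <- stats::filter(step, rep(1 / 21, 21), sides = 2)
  expect_gte(sum(ma > 0.09 & ma < 0.59, na.rm = TRUE), 20)
})

test_that("Chung-Kennedy suppresses stationary noise at least 2.5-fold", {
  # brute-force oracle: direct loop implementation of the two-predictor form
  ck_loop <- function(x, K = 10, M = 10, p = 1, eps = 1e-12) {
    n <- length(x)
    f <- rep(NA_real_, n); b <- rep(NA_real_, n)
    for (t in seq_len(n)) {
      if (t > 1) f[t] <- mean(x[max(1, t - K):(t - 1)])
      if (t < n) b[t] <- mean(x[(t + 1):min(n, t + K)])
    }
    ef <- (x - f)^2; eb <- (x - b)^2
    out <- numeric(n)
    for (t in seq_len(n)) {
      sf <- sum(ef[max(1, t - M + 1):t], na.rm = TRUE)
      sb <- sum(eb[t:min(n, t + M - 1)], na.rm = TRUE)
      wf <- if (is.na(f[t])) 0 else (sf + eps)^(-p)
      wb <- if (is.na(b[t])) 0 else (sb + eps)^(-p)
      out[t] <- (wf * ifelse(is.na(f[t]), 0, f[t]) +
                   wb * ifelse(is.na(b[t]), 0, b[t])) / (wf + wb)
    }
    out
  }
  set.seed(11)
  x <- stats::rnorm(500, 100, 20)
  f <- chung_kennedy(x)
  expect_gte(stats::sd(x) / stats::sd(f), 2.5)
  expect_equal(f, ck_loop(x), tolerance = 1e-10)
  step <- c(rep(0, 60), rep(50, 60)) + stats::rnorm(120, 0, 3)
  expect_equal(chung_kennedy(step, K = 5, M = 5, p = 2),
               ck_loop(step, K = 5, M = 5, p = 2), tolerance = 1e-10)
})

test_that("single-pair selection accepts clean pairs and rejects artifacts", {
  sc <- clean_scenario()
  calib <- simulate_traces(sc, 40, seed = 1)$traces
  crit <- estimate_selection_criteria(calib)

  good <- simulate_traces(sc, 40, seed = 2)$traces
  acc_good <- vapply(good, function(tr) select_single_pair(tr, crit)$accepted,
                     logical(1))
  expect_gte(mean(acc_good), 0.9)  # sensitivity

  # acceptor bleached mid-movie: rejected with the end-low reason
  sc0 <- clean_scenario(noise_sd = 0, bg_sd = 0)
  bl <- render_trace(manual_truth(90, "associated", numeric(0),
                                  bleach_a = 50), sc0, seed = 3)
  v <- select_single_pair(bl, crit)
  expect_false(v$accepted)
  expect_true("acceptor_end_low" %in% v$reasons)

  # doubled intensity (two pairs in one spot): intensity-window rejection
  sc2 <- clean_scenario(total_intensity = 2000)
  dbl <- simulate_traces(sc2, 20, seed = 4)$traces
  acc_dbl <- vapply(dbl, function(tr) select_single_pair(tr, crit)$accepted,
                    logical(1))
  expect_lte(mean(acc_dbl), 0.1)
  rs <- select_single_pair(dbl[[1]], crit)$reasons
  expect_true(any(grepl("intensity_window|acceptor", rs)))

  # donor-only spot: no acceptor in the red segments
  scd <- kinetic_scenario(frac_donor_only = 1)
  don <- simulate_traces(scd, 20, seed = 5)$traces
  acc_don <- vapply(don, function(tr) select_single_pair(tr, crit)$accepted,
                    logical(1))
  expect_lte(mean(acc_don), 0.1)  # specificity on single-dye spots
})

test_that("processing pipeline flags undefined efficiencies instead of failing", {
  sc <- kinetic_scenario(frac_donor_only = 1, noise_sd = 0, bg_sd = 0,
                         leakage = 0)
  trc <- simulate_traces(sc, 1, seed = 1)$traces[[1]]
  cor <- correct_trace(trc, correction_factors())
  # donor-only, no leakage: acceptor channel is exactly background -> E = 1?
  # no: I_A' = 0, I_D' = total, E = 0; zero-total frames are the NA case
  expect_true(all(is.finite(cor$E_raw)))
  scz <- kinetic_scenario(frac_acceptor_only = 1, noise_sd = 0, bg_sd = 0,
                          direct_exc = 0)
  trz <- simulate_traces(scz, 1, seed = 1)$traces[[1]]
  corz <- correct_trace(trz, correction_factors())
  expect_true(all(corz$undefined))
  expect_true(all(is.na(corz$E_raw)))
})
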