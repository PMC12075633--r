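test_that("background estimation recovers homogeneous Poisson rates", {
  st <- simulate_photon_stream(n_bursts = 0, burst_size = 0, E_true = 0.5,
                               S_true = 0.5, bg_dd = 1000, bg_da = 600,
                               bg_aa = 400, duration = 120, seed = 1)
  bg <- estimate_background(st)
  all_rate <- bg$rate[bg$stream == "all"]
  expect_equal(mean(all_rate), 2000, tolerance = 0.05)
  dd <- bg$rate[bg$stream == "dd"]
  expect_equal(mean(dd), 1000, tolerance = 0.08)
  expect_false(any(bg$flagged[bg$stream == "all"]))
})

test_that("sparse windows carry the previous rate with a flag", {
  st <- simulate_photon_stream(n_bursts = 0, burst_size = 0, E_true = 0.5,
                               S_true = 0.5, bg_dd = 500, bg_da = 0.2,
                               bg_aa = 500, duration = 90, seed = 2)
  bg <- estimate_background(st)
  da <- bg[bg$stream == "da", ]
  expect_true(all(da$flagged))
})

test_that("background is recovered within 10% in the presence of bursts", {
  st <- simulate_photon_stream(n_bursts = 60, burst_size = 500,
                               E_true = 0.5, S_true = 0.5, bg_dd = 1000,
                               bg_da = 500, bg_aa = 500, duration = 60,
                               burst_rate = 5e4, seed = 3)
  bg <- estimate_background(st)
  expect_equal(mean(bg$rate[bg$stream == "all"]), 2000, tolerance = 0.10)
})

test_that("an isolated bright burst is found with most of its photons", {
  st <- simulate_photon_stream(n_bursts = 1, burst_size = 100,
                               E_true = 0.5, S_true = 0.5, bg_dd = 400,
                               bg_da = 300, bg_aa = 300, duration = 40,
                               burst_rate = 5e4, seed = 4)
  b <- burst_search(st)
  truth <- attr(st, "truth")
  hit <- b[b$stop >= truth$start[1] - 1e-3 & b$start <= truth$stop[1] + 1e-3, ]
  expect_identical(nrow(hit), 1L)
  n_inside <- sum(st$timestamps >= truth$start[1] &
                    st$timestamps <= truth$stop[1])
  expect_gte(hit$n_photons, 0.85 * n_inside)
})

test_that("burst count is monotone non-increasing in m and F", {
  st <- simulate_photon_stream(n_bursts = 150, burst_size = 80,
                               E_true = 0.4, S_true = 0.5, bg_dd = 800,
                               bg_da = 800, bg_aa = 800, duration = 60,
                               seed = 5)
  bg <- estimate_background(st)
  # the in-burst photon set is nested under stricter thresholds, so total
  # in-burst photons are monotone even when a weakening run splits in two
  ph_at <- function(m, F) sum(burst_search(st, m = m, F = F, bg = bg)$n_photons)
  expect_gte(ph_at(10, 6), ph_at(10, 9))
  expect_gte(ph_at(10, 9), ph_at(10, 12))
  n_at <- function(m, F) nrow(burst_search(st, m = m, F = F, bg = bg))
  expect_gte(n_at(10, 6), n_at(20, 6))
})

test_that("burst search is deterministic for identical input", {
  st <- simulate_photon_stream(n_bursts = 50, burst_size = 80, E_true = 0.3,
                               S_true = 0.5, duration = 45, seed = 6)
  b1 <- burst_search(st)
  b2 <- burst_search(st)
  expect_identical(b1, b2)
})

test_that("pure background yields no bursts after the 40-photon selection", {
  st <- simulate_photon_stream(n_bursts = 0, burst_size = 0, E_true = 0.5,
                               S_true = 0.5, bg_dd = 700, bg_da = 700,
                               bg_aa = 700, duration = 600, seed = 7)
  h <- es_select_and_histogram(burst_search(st))
  expect_identical(h$n_traces, 0L)
  expect_identical(sum(h$counts), 0L)
})

test_that("stoichiometry selection removes single-dye species", {
  don <- simulate_photon_stream(n_bursts = 120, burst_size = 100,
                                E_true = 0, S_true = 0.98, bg_dd = 300,
                                bg_da = 300, bg_aa = 300, duration = 60,
                                seed = 8)
  b <- burst_es(burst_search(don))
  big <- b[b$n_photons >= 40, ]
  expect_gt(stats::median(big$S), 0.9)
  h <- es_select_and_histogram(burst_search(don))
  expect_lte(h$n_traces, 0.1 * nrow(big))
})

test_that("burst correction factors are recovered from single-dye populations", {
  mix <- function(seed, lk, dir) {
    a <- simulate_photon_stream(n_bursts = 150, burst_size = 150,
                                E_true = 0.4, S_true = 0.5, duration = 60,
                                bg_dd = 100, bg_da = 100, bg_aa = 100,
                                leakage = lk, direct_exc = dir, seed = seed)
    d <- simulate_photon_stream(n_bursts = 150, burst_size = 150,
                                E_true = 0, S_true = 1, duration = 60,
                                bg_dd = 100, bg_da = 100, bg_aa = 100,
                                leakage = lk, direct_exc = dir,
                                seed = seed + 1)
    # acceptor-only: no donor, so no donor-period photons except the
    # direct-excitation ones the generator adds on top
    o <- simulate_photon_stream(n_bursts = 150, burst_size = 150,
                                E_true = 0, S_true = 0, duration = 60,
                                bg_dd = 100, bg_da = 100, bg_aa = 100,
                                leakage = lk, direct_exc = dir,
                                seed = seed + 2)
    ts <- c(a$timestamps, d$timestamps + 61, o$timestamps + 122)
    structure(list(timestamps = ts,
                   detector = c(a$detector, d$detector, o$detector),
                   excitation = c(a$excitation, d$excitation, o$excitation),
                   duration = 183), class = "photon_stream")
  }
  st <- mix(9, lk = 0.07, dir = 0.06)
  o <- order(st$timestamps)
  st$timestamps <- st$timestamps[o]
  st$detector <- st$detector[o]; st$excitation <- st$excitation[o]
  cf <- estimate_burst_corrections(burst_search(st))
  expect_lt(abs(cf$lk - 0.07), 0.02)
  expect_lt(abs(cf$dir - 0.06), 0.02)
})

test_that("burst efficiency histograms peak at the true efficiency", {
  for (E in c(0.2, 0.56, 0.8)) {
    st <- simulate_photon_stream(n_bursts = 400, burst_size = 120,
                                 E_true = E, S_true = 0.5, bg_dd = 500,
                                 bg_da = 400, bg_aa = 400, duration = 90,
                                 seed = round(100 * E))
    h <- es_select_and_histogram(burst_search(st))
    expect_gt(h$n_traces, 200)
    mode <- h$mids[which.max(h$counts)]
    expect_lte(abs(mode - E), 0.04)
  }
})

test_that("mean burst efficiency converges to truth with burst size", {
  errs <- vapply(c(40, 100, 400), function(sz) {
    st <- simulate_photon_stream(n_bursts = 300, burst_size = sz,
                                 E_true = 0.56, S_true = 0.5, bg_dd = 0,
                                 bg_da = 0, bg_aa = 0, duration = 300,
                                 seed = sz)
    b <- burst_es(burst_search(st, bg = data.frame(window = 1, t_start = 0,
                                                   stream = "all",
                                                   rate = 10,
                                                   flagged = FALSE)))
    abs(mean(b$E[b$n_photons >= 0.5 * sz]) - 0.56)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_true(errs[3] <= errs[1] + 0.005)
})

test_that("a 50:50 mixture gives a bimodal burst histogram", {
  a <- simulate_photon_stream(n_bursts = 250, burst_size = 120,
                              E_true = 0.2, S_true = 0.5, duration = 60,
                              seed = 11)
  b2 <- simulate_photon_stream(n_bursts = 250, burst_size = 120,
                               E_true = 0.8, S_true = 0.5, duration = 60,
                               seed = 12)
  st <- list(timestamps = c(a$timestamps, b2$timestamps + 61),
             detector = c(a$detector, b2$detector),
             excitation = c(a$excitation, b2$excitation), duration = 121)
  class(st) <- "photon_stream"
  h <- es_select_and_histogram(burst_search(st))
  lo <- h$mids >= 0.0 & h$mids <= 0.4
  hi <- h$mids >= 0.6 & h$mids <= 1.0
  m_lo <- h$mids[lo][which.max(h$counts[lo])]
  m_hi <- h$mids[hi][which.max(h$counts[hi])]
  expect_lte(abs(m_lo - 0.2), 0.04)
  expect_lte(abs(m_hi - 0.8), 0.04)
})

test_that("photon streams survive the text round trip", {
  st <- simulate_photon_stream(n_bursts = 20, burst_size = 50, E_true = 0.5,
                               S_true = 0.5, duration = 30, seed = 13)
  path <- tempfile(fileext = ".tsv")
  write_photon_stream(st, path)
  back <- read_photon_stream(path)
  expect_equal(back$timestamps, st$timestamps, tolerance = 1e-9)
  expect_identical(back$detector, st$detector)
  expect_equal(back$duration, st$duration)
  unlink(path)
})
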