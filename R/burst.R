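#' Simulate a confocal PIE photon stream with known burst ground truth
#'
#' Bursts are intervals of elevated Poisson rate produced by molecules
#' diffusing through the confocal volume: burst start times are uniform over
#' the acquisition, each burst carries a Poisson-distributed number of
#' photons emitted at `burst_rate` (so its duration is the photon count over
#' the rate). Within a burst, acceptor-period photons are drawn with
#' probability `1 - S_true` and the remaining donor-period photons fall on
#' the acceptor detector with probability `E_true` (plus leakage and direct
#' excitation when set). Background photons arrive as independent Poisson
#' processes per detection stream.
#'
#' @param n_bursts number of bursts.
#' @param burst_size mean photons per burst.
#' @param E_true FRET efficiency of the species.
#' @param S_true stoichiometry of the species.
#' @param bg_dd,bg_da,bg_aa background rates (photons/s) of the
#'   donor-excitation donor / donor-excitation acceptor / acceptor-excitation
#'   acceptor streams.
#' @param duration acquisition duration (s).
#' @param burst_rate in-burst photon rate (photons/s).
#' @param leakage,direct_exc crosstalk and direct-excitation probabilities
#'   applied inside bursts.
#' @param seed integer seed.
#' @return object of class `photon_stream`: list with sorted `timestamps`
#'   (s), `detector` (`"donor"`/`"acceptor"`), `excitation`
#'   (`"donor_period"`/`"acceptor_period"`), `duration`, and attribute
#'   `truth` (data frame of burst start/stop times).
#' @export
simulate_photon_stream <- function(n_bursts, burst_size, E_true, S_true,
                                   bg_dd = 1000, bg_da = 1000, bg_aa = 1000,
                                   duration = 60, burst_rate = 5e4,
                                   leakage = 0, direct_exc = 0, seed = 1) {
  stopifnot(bg_dd >= 0, bg_da >= 0, bg_aa >= 0, duration > 0)
  set.seed(seed)
  ts <- numeric(0); det <- character(0); exc <- character(0)
  truth <- NULL
  if (n_bursts > 0) {
    starts <- sort(stats::runif(n_bursts, 0, duration * 0.98))
    sizes <- stats::rpois(n_bursts, burst_size)
    for (i in seq_len(n_bursts)) {
      ni <- sizes[i]
      if (ni == 0) next
      dur_i <- ni / burst_rate
      t_i <- sort(stats::runif(ni, starts[i], starts[i] + dur_i))
      aex <- stats::runif(ni) < (1 - S_true)
      n_dex <- sum(!aex)
      # donor-period photons split by the FRET efficiency
      acc <- stats::runif(n_dex) < E_true
      det_i <- character(ni)
      det_i[aex] <- "acceptor"
      det_i[!aex] <- ifelse(acc, "acceptor", "donor")
      exc_i <- ifelse(aex, "acceptor_period", "donor_period")
      ts <- c(ts, t_i); det <- c(det, det_i); exc <- c(exc, exc_i)
      # crosstalk and direct excitation add acceptor-detector photons on top
      # of the ideal split, proportional to the donor emission and to the
      # acceptor content respectively -- the additive convention the
      # standard correction formula inverts
      n_extra <- stats::rpois(1, leakage * sum(!acc) + direct_exc * sum(aex))
      if (n_extra > 0) {
        ts <- c(ts, stats::runif(n_extra, starts[i], starts[i] + dur_i))
        det <- c(det, rep("acceptor", n_extra))
        exc <- c(exc, rep("donor_period", n_extra))
      }
    }
    truth <- data.frame(start = starts, stop = starts + sizes / burst_rate)
  }
  add_bg <- function(rate, d, e) {
    m <- stats::rpois(1, rate * duration)
    if (m == 0) return(NULL)
    list(t = stats::runif(m, 0, duration), d = rep(d, m), e = rep(e, m))
  }
  for (bg in list(add_bg(bg_dd, "donor", "donor_period"),
                  add_bg(bg_da, "acceptor", "donor_period"),
                  add_bg(bg_aa, "acceptor", "acceptor_period"))) {
    if (!is.null(bg)) {
      ts <- c(ts, bg$t); det <- c(det, bg$d); exc <- c(exc, bg$e)
    }
  }
  o <- order(ts)
  structure(list(timestamps = ts[o], detector = det[o], excitation = exc[o],
                 duration = duration),
            class = "photon_stream", truth = truth)
}

#' Per-window background rates of a photon stream
#'
#' For every window of `window` seconds and every detection stream (and for
#' all photons pooled), the background rate is the maximum-likelihood
#' exponential fit of the inter-photon delays above an automatic threshold
#' (delays larger than the mean delay, which excludes the fast in-burst
#' delays); by the memoryless property the rate is
#' `1 / (mean(delays above threshold) - threshold)`. Windows with fewer than
#' 50 photons carry the previous window's rate with a flag.
#'
#' @param stream a `photon_stream`.
#' @param window window length (s), 30 by default.
#' @return data frame with `window` (index), `t_start`, `stream`
#'   (`"all"`, `"dd"`, `"da"`, `"aa"`), `rate` (photons/s), `flagged`.
#' @export
estimate_background <- function(stream, window = 30) {
  if (stream$duration < window)
    stop("stream shorter than one background window")
  n_win <- max(1L, floor(stream$duration / window))
  stream_of <- function(d, e) stream$timestamps[stream$detector == d &
                                                  stream$excitation == e]
  streams <- list(all = stream$timestamps,
                  dd = stream_of("donor", "donor_period"),
                  da = stream_of("acceptor", "donor_period"),
                  aa = stream_of("acceptor", "acceptor_period"))
  out <- list()
  for (s in names(streams)) {
    prev <- NA_real_
    for (wi in seq_len(n_win)) {
      t0 <- (wi - 1) * window
      tt <- streams[[s]]
      tt <- tt[tt >= t0 & tt < t0 + window]
      flagged <- FALSE
      if (length(tt) < 50) {
        rate <- prev; flagged <- TRUE
      } else {
        dl <- diff(tt)
        thr <- mean(dl)
        tail_dl <- dl[dl > thr]
        rate <- if (length(tail_dl) == 0) 1 / thr
                else 1 / (mean(tail_dl) - thr)
      }
      prev <- rate
      out[[length(out) + 1L]] <- data.frame(window = wi, t_start = t0,
                                            stream = s, rate = rate,
                                            flagged = flagged)
    }
  }
  do.call(rbind, out)
}

#' All-photon sliding-window burst search
#'
#' A photon belongs to a burst when the local rate over `m` consecutive
#' photons exceeds `F` times the local background rate: photon `i` opens a
#' qualifying window when `(m - 1) / (t[i+m-1] - t[i]) > F * bg`, and all
#' `m` photons of a qualifying window are marked in-burst. Maximal runs of
#' in-burst photons form bursts; counts are split by detector and excitation
#' period. Deterministic given the stream and parameters.
#'
#' @param stream a `photon_stream`.
#' @param m sliding-window size (photons).
#' @param F rate-threshold multiplier over background.
#' @param bg optional result of [estimate_background()]; computed when
#'   missing. The `"all"`-stream per-window rates are used.
#' @param bg_window background window length (s) when `bg` is missing.
#' @return data frame of bursts: `start`, `stop` (s), `n_photons`, `n_dd`,
#'   `n_da`, `n_aa`.
#' @export
burst_search <- function(stream, m = 10L, F = 6, bg = NULL, bg_window = 30) {
  if (is.null(bg)) bg <- estimate_background(stream, window = bg_window)
  bga <- bg[bg$stream == "all", , drop = FALSE]
  ts <- stream$timestamps
  n <- length(ts)
  if (n < m) return(empty_bursts())
  if (nrow(bga) > 1) {
    win_len <- bga$t_start[2] - bga$t_start[1]
    wi <- pmin(pmax(floor(ts / win_len) + 1L, 1L), max(bga$window))
  } else wi <- rep(1L, n)
  bg_rate <- bga$rate[match(wi, bga$window)]
  i <- seq_len(n - m + 1L)
  local_rate <- (m - 1) / (ts[i + m - 1L] - ts[i])
  qual <- local_rate > F * bg_rate[i]
  in_burst <- logical(n)
  qi <- which(qual)
  for (j in qi) in_burst[j:(j + m - 1L)] <- TRUE
  if (!any(in_burst)) return(empty_bursts())
  r <- rle(in_burst)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    d <- stream$detector[idx]; e <- stream$excitation[idx]
    data.frame(start = ts[idx[1]], stop = ts[idx[length(idx)]],
               n_photons = length(idx),
               n_dd = sum(d == "donor" & e == "donor_period"),
               n_da = sum(d == "acceptor" & e == "donor_period"),
               n_aa = sum(d == "acceptor" & e == "acceptor_period"))
  })
  do.call(rbind, out)
}

empty_bursts <- function() {
  data.frame(start = numeric(0), stop = numeric(0), n_photons = integer(0),
             n_dd = integer(0), n_da = integer(0), n_aa = integer(0))
}

#' Per-burst corrected FRET efficiency and stoichiometry
#'
#' `E = (n_da - lk * n_dd - dir * n_aa) / (n_da - lk * n_dd - dir * n_aa + n_dd)`
#' and `S = (n_dd + n_da') / (n_dd + n_da' + n_aa)` with the same corrected
#' acceptor count `n_da'`.
#'
#' @param bursts burst table from [burst_search()].
#' @param cf a [correction_factors()].
#' @return the burst table with columns `E` and `S` appended.
#' @export
burst_es <- function(bursts, cf = correction_factors()) {
  nda <- bursts$n_da - cf$lk * bursts$n_dd - cf$dir * bursts$n_aa
  denom_e <- nda + bursts$n_dd
  denom_s <- bursts$n_dd + nda + bursts$n_aa
  bursts$E <- ifelse(denom_e > 0, nda / denom_e, NA_real_)
  bursts$S <- ifelse(denom_s > 0, (bursts$n_dd + nda) / denom_s, NA_real_)
  bursts
}

#' Estimate burst correction factors from single-dye sub-populations
#'
#' Leakage from the donor-only sub-population (uncorrected stoichiometry
#' above `s_donor`): median of `n_da / n_dd`. Direct excitation from the
#' acceptor-only sub-population (uncorrected stoichiometry below
#' `s_acceptor`): median of `n_da / n_aa`.
#'
#' @param bursts burst table (uncorrected).
#' @param s_donor,s_acceptor stoichiometry cuts defining the sub-populations.
#' @return a [correction_factors()].
#' @export
estimate_burst_corrections <- function(bursts, s_donor = 0.9,
                                       s_acceptor = 0.1) {
  b0 <- burst_es(bursts, correction_factors())
  don <- b0[!is.na(b0$S) & b0$S > s_donor & b0$n_dd > 0, , drop = FALSE]
  acc <- b0[!is.na(b0$S) & b0$S < s_acceptor & b0$n_aa > 0, , drop = FALSE]
  lk <- if (nrow(don) > 0) stats::median(don$n_da / don$n_dd) else 0
  dir <- if (nrow(acc) > 0) stats::median(acc$n_da / acc$n_aa) else 0
  correction_factors(lk = max(lk, 0), dir = max(dir, 0))
}

#' Stoichiometry-selected burst FRET histogram
#'
#' Applies the corrections, drops bursts with fewer than `min_photons` total
#' photons (acceptor-excitation photons included) or stoichiometry outside
#' `s_range`, and histograms the corrected efficiencies with a fixed 0.04
#' bin width.
#'
#' @param bursts burst table from [burst_search()].
#' @param cf a [correction_factors()].
#' @param min_photons minimal total photons per burst.
#' @param s_range stoichiometry selection interval.
#' @param bin bin width.
#' @param range histogram range.
#' @return object of class `efficiency_histogram` (see
#'   [efficiency_histogram()]) with `n_traces` = number of selected bursts;
#'   empty selection gives zero counts.
#' @export
es_select_and_histogram <- function(bursts, cf = correction_factors(),
                                    min_photons = 40L,
                                    s_range = c(0.25, 0.85), bin = 0.04,
                                    range = c(-0.2, 1.2)) {
  b <- burst_es(bursts, cf)
  sel <- b$n_photons >= min_photons & !is.na(b$S) &
    b$S >= s_range[1] & b$S <= s_range[2] & !is.na(b$E)
  e <- pmin(pmax(b$E[sel], range[1]), range[2] - bin / 1e6)
  breaks <- round(seq(range[1], range[2], by = bin), 8)
  counts <- tabulate(findInterval(e, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, mids = breaks[-length(breaks)] + bin / 2,
                 counts = counts, n_traces = sum(sel), n_frames = sum(counts),
                 condition = "burst"),
            class = "efficiency_histogram")
}

#' Write / read a photon stream as 3-column delimited text
#'
#' Columns: `timestamp_s`, `detector`, `excitation`; the acquisition
#' duration is stored in a `# duration:` header line.
#'
#' @param stream a `photon_stream`.
#' @param path file path.
#' @return `read_photon_stream` returns a `photon_stream`.
#' @export
write_photon_stream <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration: %.9g", stream$duration), con)
  utils::write.table(
    data.frame(timestamp_s = stream$timestamps, detector = stream$detector,
               excitation = stream$excitation),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_photon_stream
#' @export
read_photon_stream <- function(path) {
  hdr <- readLines(path, n = 1)
  dur <- as.numeric(sub("# duration: *", "", hdr))
  d <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                         stringsAsFactors = FALSE)
  o <- order(d$timestamp_s)
  structure(list(timestamps = d$timestamp_s[o], detector = d$detector[o],
                 excitation = d$excitation[o], duration = dur),
            class = "photon_stream")
}
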