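#' Correction factors for crosstalk, direct excitation and detection balance
#'
#' @param lk donor-to-acceptor channel crosstalk (leakage) fraction.
#' @param dir acceptor direct-excitation fraction under the donor laser,
#'   expressed relative to the acceptor-excitation intensity `I_AA`.
#' @param gamma detection-correction factor (1 = balanced detection; the
#'   reported efficiencies are then proximity-ratio style).
#' @return object of class `correction_factors`.
#' @export
correction_factors <- function(lk = 0, dir = 0, gamma = 1) {
  if (lk < 0 || dir < 0) stop("lk and dir must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(list(lk = lk, dir = dir, gamma = gamma),
            class = "correction_factors")
}

# running median with shrinking windows at the edges
run_median <- function(x, k) {
  n <- length(x)
  if (n == 0 || k <= 1) return(x)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - h):min(n, i + h)], na.rm = TRUE)
  }, numeric(1))
}

#' Median prefilter of a raw trace
#'
#' A 3-frame running median is applied to the signal channels and a 7-frame
#' running median to the background series; window edges shrink. `I_D`/`I_A`
#' are filtered within the green segment and `I_AA` within each red segment,
#' so segment boundaries never mix.
#'
#' @param trace a `fret_trace`.
#' @param k_signal,k_background odd window sizes (frames).
#' @return the filtered `fret_trace`.
#' @export
median_prefilter <- function(trace, k_signal = 3L, k_background = 7L) {
  g <- trace$segment == "green"
  trace$I_D[g] <- run_median(trace$I_D[g], k_signal)
  trace$I_A[g] <- run_median(trace$I_A[g], k_signal)
  for (seg in c("red_head", "red_tail")) {
    s <- trace$segment == seg
    trace$I_AA[s] <- run_median(trace$I_AA[s], k_signal)
  }
  trace$bg_D <- run_median(trace$bg_D, k_background)
  trace$bg_A <- run_median(trace$bg_A, k_background)
  trace
}

#' Estimate crosstalk and direct-excitation factors from single-dye samples
#'
#' Leakage is the median over donor-only traces of the ratio of
#' background-subtracted mean acceptor to donor signal on green frames;
#' direct excitation is the median over acceptor-only traces of the
#' background-subtracted mean green-segment acceptor signal to the mean
#' red-segment `I_AA`.
#'
#' @param donor_only,acceptor_only lists of `fret_trace` from samples
#'   carrying only one dye species.
#' @param gamma detection factor passed through to [correction_factors()].
#' @return a `correction_factors` object.
#' @export
estimate_corrections <- function(donor_only, acceptor_only, gamma = 1) {
  if (length(donor_only) == 0 || length(acceptor_only) == 0)
    stop("both calibration sets must be non-empty")
  lk <- stats::median(vapply(donor_only, function(tr) {
    g <- tr$segment == "green"
    mean(tr$I_A[g] - tr$bg_A[g]) / mean(tr$I_D[g] - tr$bg_D[g])
  }, numeric(1)))
  dir <- stats::median(vapply(acceptor_only, function(tr) {
    g <- tr$segment == "green"
    r <- tr$segment != "green"
    mean(tr$I_A[g] - tr$bg_A[g]) / mean(tr$I_AA[r] - tr$bg_A[r])
  }, numeric(1)))
  correction_factors(lk = max(lk, 0), dir = max(dir, 0), gamma = gamma)
}

#' Background subtraction, crosstalk and direct-excitation correction
#'
#' On green frames: `I_D' = I_D - bg_D`;
#' `I_A' = (I_A - bg_A) - lk * I_D' - dir * mean(I_AA - bg_A)` where the
#' direct-excitation term uses the trace's own mean background-subtracted
#' red-segment `I_AA`; `E_raw = I_A' / (gamma * I_D' + I_A')`, clamped for
#' reporting to `[-0.2, 1.2]`. Frames with (near) zero total corrected
#' intensity get `E_raw = NA`.
#'
#' @param trace a `fret_trace` (normally after [median_prefilter()]).
#' @param cf a [correction_factors()] object.
#' @return list with `I_D_cor`, `I_A_cor`, `E_raw` (green frames only),
#'   `time_s` of the green frames and `undefined` (logical flag per frame).
#' @export
correct_trace <- function(trace, cf) {
  g <- trace$segment == "green"
  r <- trace$segment != "green"
  if (!any(g)) stop("trace has no green frames")
  I_Dp <- trace$I_D[g] - trace$bg_D[g]
  aa <- mean(trace$I_AA[r] - trace$bg_A[r], na.rm = TRUE)
  if (!is.finite(aa)) aa <- 0
  I_Ap <- (trace$I_A[g] - trace$bg_A[g]) - cf$lk * I_Dp - cf$dir * aa
  tot <- cf$gamma * I_Dp + I_Ap
  undef <- !is.finite(tot) | abs(tot) < 1e-9
  E <- ifelse(undef, NA_real_, I_Ap / tot)
  E <- pmin(pmax(E, -0.2), 1.2)
  list(time_s = trace$time_s[g], I_D_cor = I_Dp, I_A_cor = I_Ap,
       E_raw = E, undefined = undef)
}

#' Chung-Kennedy edge-preserving filter
#'
#' Two-predictor form: each point is replaced by a blend of the mean of the
#' preceding `K` points (forward predictor) and the mean of the following
#' `K` points (backward predictor), with weights proportional to the inverse
#' `p`-th power of each predictor's recent squared prediction error summed
#' over a comparison window of `M` points (past errors for the forward
#' predictor, future errors for the backward one). Edges use truncated
#' windows; output length equals input length. A variance floor `eps`
#' avoids division by zero on noiseless segments.
#'
#' On a noiseless step the predictor on the "wrong" side of the edge has a
#' large prediction error and loses all weight, so edges are preserved
#' instead of smeared as with a moving average.
#'
#' @param x numeric series.
#' @param K predictor window (frames).
#' @param M comparison window for the predictor errors (frames).
#' @param p weighting exponent.
#' @param eps variance floor.
#' @return filtered series, same length as `x`.
#' @export
chung_kennedy <- function(x, K = 10L, M = 10L, p = 1, eps = 1e-12) {
  n <- length(x)
  if (n <= 2L * K) stop("series length must exceed 2 * K")
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  # forward predictor: mean of up to K previous points (none at t = 1)
  lo_f <- pmax(idx - K, 1L)
  nf <- idx - lo_f
  f <- ifelse(nf > 0, (cs[idx] - cs[lo_f]) / pmax(nf, 1L), NA_real_)
  # backward predictor: mean of up to K following points (none at t = n)
  hi_b <- pmin(idx + K, n)
  nb <- hi_b - idx
  b <- ifelse(nb > 0, (cs[hi_b + 1L] - cs[idx + 1L]) / pmax(nb, 1L), NA_real_)

  ef <- (x - f)^2   # NA at t = 1
  eb <- (x - b)^2   # NA at t = n
  ef0 <- ifelse(is.na(ef), 0, ef)
  eb0 <- ifelse(is.na(eb), 0, eb)
  cef <- c(0, cumsum(ef0))
  ceb <- c(0, cumsum(eb0))
  # forward error summed over the past M points, backward over the next M
  lo_e <- pmax(idx - M + 1L, 1L)
  sf <- cef[idx + 1L] - cef[lo_e]
  hi_e <- pmin(idx + M - 1L, n)
  sb <- ceb[hi_e + 1L] - ceb[idx]
  wf <- (sf + eps)^(-p)
  wb <- (sb + eps)^(-p)
  wf[is.na(f)] <- 0
  wb[is.na(b)] <- 0
  f0 <- ifelse(is.na(f), 0, f)
  b0 <- ifelse(is.na(b), 0, b)
  (wf * f0 + wb * b0) / (wf + wb)
}

#' Intensity-based selection criteria for single donor/acceptor pairs
#'
#' @param acceptor_window length-2 numeric: admissible window (counts) for the
#'   mean background-subtracted `I_AA` in each red segment (acceptor present,
#'   unbleached, single).
#' @param total_window length-2 numeric: admissible window (counts) for the
#'   mean background-subtracted total green-segment intensity inside the
#'   evaluation windows (single donor, no bleaching).
#' @param eval_window_s evaluation windows = first and last `eval_window_s`
#'   seconds of the recording (default 10 s).
#' @return object of class `selection_criteria`.
#' @export
selection_criteria <- function(acceptor_window, total_window,
                               eval_window_s = 10) {
  stopifnot(length(acceptor_window) == 2, length(total_window) == 2,
            diff(acceptor_window) > 0, diff(total_window) > 0,
            eval_window_s > 0)
  structure(list(acceptor_window = acceptor_window,
                 total_window = total_window,
                 eval_window_s = eval_window_s),
            class = "selection_criteria")
}

#' Derive selection windows from a calibration population
#'
#' Windows default to mean +/- `n_sd` standard deviations of the calibration
#' population of clean single-pair traces (the numeric constraints used on
#' real data are instrument-specific, so they are estimated from the data).
#'
#' @param pair_traces list of `fret_trace` known to carry one donor and one
#'   acceptor without bleaching.
#' @param n_sd half-width of the windows in population SDs.
#' @param eval_window_s passed to [selection_criteria()].
#' @return a `selection_criteria` object.
#' @export
estimate_selection_criteria <- function(pair_traces, n_sd = 2.5,
                                        eval_window_s = 10) {
  # the spread must be measured on the same statistic the verdicts use:
  # short-window means, not whole-trace means (which average away the
  # camera noise the evaluation windows still carry)
  aa <- unlist(lapply(pair_traces, function(tr) {
    c(head = {
      s <- tr$segment == "red_head"
      mean(tr$I_AA[s] - tr$bg_A[s], na.rm = TRUE)
    }, tail = {
      s <- tr$segment == "red_tail"
      mean(tr$I_AA[s] - tr$bg_A[s], na.rm = TRUE)
    })
  }))
  tot <- unlist(lapply(pair_traces, function(tr) {
    g <- tr$segment == "green"
    t_end <- tr$time_s[length(tr$time_s)] + (tr$time_s[2] - tr$time_s[1])
    w1 <- g & tr$time_s < eval_window_s
    w2 <- g & tr$time_s >= t_end - eval_window_s
    v <- tr$I_D - tr$bg_D + tr$I_A - tr$bg_A
    c(mean(v[w1]), mean(v[w2]))
  }))
  selection_criteria(
    acceptor_window = mean(aa) + c(-1, 1) * n_sd * stats::sd(aa),
    total_window = mean(tot) + c(-1, 1) * n_sd * stats::sd(tot),
    eval_window_s = eval_window_s
  )
}

#' Single-pair / no-photobleaching selection verdict
#'
#' A trace is accepted iff (i) the mean background-subtracted `I_AA` in the
#' red head and red tail both fall inside the acceptor single-dye window
#' (acceptor present at start and end, so unbleached, and not multiple), and
#' (ii) the mean background-subtracted total green intensity within the first
#' and last evaluation windows of the recording falls inside the single-pair
#' window (single donor, no donor bleaching). Every rejection carries reason
#' codes rather than an exception.
#'
#' @param trace a `fret_trace` spanning the full ALEX layout.
#' @param criteria a [selection_criteria()] object.
#' @return list with `accepted` (logical) and `reasons` (character vector,
#'   empty when accepted).
#' @export
select_single_pair <- function(trace, criteria) {
  reasons <- character(0)
  head_idx <- trace$segment == "red_head"
  tail_idx <- trace$segment == "red_tail"
  aa_head <- mean(trace$I_AA[head_idx] - trace$bg_A[head_idx], na.rm = TRUE)
  aa_tail <- mean(trace$I_AA[tail_idx] - trace$bg_A[tail_idx], na.rm = TRUE)
  w <- criteria$acceptor_window
  if (!is.finite(aa_head) || aa_head < w[1]) reasons <- c(reasons, "acceptor_start_low")
  if (is.finite(aa_head) && aa_head > w[2]) reasons <- c(reasons, "acceptor_start_high")
  if (!is.finite(aa_tail) || aa_tail < w[1]) reasons <- c(reasons, "acceptor_end_low")
  if (is.finite(aa_tail) && aa_tail > w[2]) reasons <- c(reasons, "acceptor_end_high")
  g <- trace$segment == "green"
  t_all <- trace$time_s
  t_end <- t_all[length(t_all)] + attr(trace, "frame_time")
  first_w <- g & t_all < criteria$eval_window_s
  last_w <- g & t_all >= t_end - criteria$eval_window_s
  tot <- trace$I_D - trace$bg_D + trace$I_A - trace$bg_A
  m_first <- mean(tot[first_w]); m_last <- mean(tot[last_w])
  tw <- criteria$total_window
  if (!is.finite(m_first) || m_first < tw[1] || m_first > tw[2])
    reasons <- c(reasons, "intensity_window_start")
  if (!is.finite(m_last) || m_last < tw[1] || m_last > tw[2])
    reasons <- c(reasons, "intensity_window_end")
  list(accepted = length(reasons) == 0, reasons = reasons)
}

#' Full trace-processing chain
#'
#' Median prefilter, background/crosstalk/direct-excitation correction,
#' optional single-pair selection, Chung-Kennedy filtering of the corrected
#' channels and FRET-efficiency computation before (`E_raw`) and after
#' (`E_ck`) filtering. `E_ck` is computed from the filtered channels,
#' mirroring how filtering precedes efficiency calculation in the analysis
#' of recorded traces.
#'
#' @param trace a `fret_trace`.
#' @param cf a [correction_factors()] object.
#' @param criteria optional [selection_criteria()]; when `NULL` the trace is
#'   marked accepted with no checks.
#' @param K,M,p,eps Chung-Kennedy parameters, see [chung_kennedy()].
#' @return object of class `processed_trace`: list with `time_s`, `I_D_cor`,
#'   `I_A_cor`, `I_D_ck`, `I_A_ck`, `E_raw`, `E_ck`, `selected`, `reasons`,
#'   `trace_id`, `condition`, `frame_time`.
#' @export
process_trace <- function(trace, cf, criteria = NULL,
                          K = 10L, M = 10L, p = 1, eps = 1e-12) {
  filt <- median_prefilter(trace)
  cor <- correct_trace(filt, cf)
  sel <- if (is.null(criteria)) list(accepted = TRUE, reasons = character(0))
         else select_single_pair(filt, criteria)
  id_ck <- chung_kennedy(cor$I_D_cor, K = K, M = M, p = p, eps = eps)
  ia_ck <- chung_kennedy(cor$I_A_cor, K = K, M = M, p = p, eps = eps)
  tot <- cf$gamma * id_ck + ia_ck
  e_ck <- ifelse(abs(tot) < 1e-9, NA_real_, ia_ck / tot)
  e_ck <- pmin(pmax(e_ck, -0.2), 1.2)
  structure(list(time_s = cor$time_s, I_D_cor = cor$I_D_cor,
                 I_A_cor = cor$I_A_cor, I_D_ck = id_ck, I_A_ck = ia_ck,
                 E_raw = cor$E_raw, E_ck = e_ck,
                 selected = sel$accepted, reasons = sel$reasons,
                 trace_id = attr(trace, "trace_id"),
                 condition = attr(trace, "condition"),
                 frame_time = attr(trace, "frame_time")),
            class = "processed_trace")
}

#' Process a list of traces
#'
#' @param traces list of `fret_trace`.
#' @inheritParams process_trace
#' @return list of `processed_trace`.
#' @export
process_traces <- function(traces, cf, criteria = NULL,
                           K = 10L, M = 10L, p = 1, eps = 1e-12) {
  lapply(traces, process_trace, cf = cf, criteria = criteria,
         K = K, M = M, p = p, eps = eps)
}
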