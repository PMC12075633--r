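#' Anticorrelation statistic of a processed trace
#'
#' Dynamic traces show anticorrelated donor and acceptor intensity steps.
#' The statistic is the donor-acceptor covariance normalized by the squared
#' mean total intensity,
#' `c = mean((I_D - <I_D>) * (I_A - <I_A>)) / <I_D + I_A>^2`,
#' computed on the corrected, Chung-Kennedy-filtered green-segment
#' intensities. It is dimensionless and sign-preserving; the covariance in
#' the numerator is invariant under additive offsets, and the statistic as a
#' whole is invariant under a common multiplicative rescaling of both
#' channels (numerator and denominator both scale with the square), which is
#' what makes a fixed threshold transferable across traces of different
#' brightness.
#'
#' @param proc a `processed_trace`.
#' @param use_filtered compute on the Chung-Kennedy filtered channels
#'   (default) or on the corrected unfiltered channels.
#' @return the statistic `c`, or `NA` with attribute `flag = "zero_total"`
#'   when the mean total intensity vanishes.
#' @export
anticorrelation_statistic <- function(proc, use_filtered = TRUE) {
  id <- if (use_filtered) proc$I_D_ck else proc$I_D_cor
  ia <- if (use_filtered) proc$I_A_ck else proc$I_A_cor
  ok <- is.finite(id) & is.finite(ia)
  id <- id[ok]; ia <- ia[ok]
  n <- length(id)
  if (n < 50) stop("at least 50 green frames are required")
  mt <- mean(id + ia)
  if (abs(mt) < 1e-9) {
    return(structure(NA_real_, flag = "zero_total"))
  }
  mean((id - mean(id)) * (ia - mean(ia))) / mt^2
}

#' Classify one trace as dynamic, static-high or static-low
#'
#' A trace is `dynamic` when its anticorrelation statistic is strictly below
#' `threshold` (default -0.01); otherwise it is `static_high` when the median
#' FRET efficiency over the donor-excitation period exceeds `split`
#' (default 0.4) and `static_low` otherwise. Ties at exactly the threshold
#' are static.
#'
#' @param proc a `processed_trace`.
#' @param threshold classifier threshold on the statistic.
#' @param split median-efficiency split between the static classes.
#' @param use_filtered see [anticorrelation_statistic()].
#' @return a one-row data frame with `trace_id`, `statistic`, `label`,
#'   `median_E`.
#' @export
classify_trace <- function(proc, threshold = -0.01, split = 0.4,
                           use_filtered = TRUE) {
  c_stat <- anticorrelation_statistic(proc, use_filtered = use_filtered)
  med_e <- stats::median(proc$E_ck, na.rm = TRUE)
  label <- if (is.finite(c_stat) && c_stat < threshold) "dynamic"
           else if (med_e > split) "static_high" else "static_low"
  data.frame(trace_id = proc$trace_id %||% NA_character_,
             statistic = as.numeric(c_stat), label = label,
             median_E = med_e, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a list of processed traces
#'
#' Unselected traces are retained in the table with `selected = FALSE` so
#' selection tallies can be reported; classification labels are computed for
#' every trace.
#'
#' @param procs list of `processed_trace`.
#' @inheritParams classify_trace
#' @return data frame with one row per trace.
#' @export
classify_traces <- function(procs, threshold = -0.01, split = 0.4,
                            use_filtered = TRUE) {
  out <- do.call(rbind, lapply(procs, classify_trace, threshold = threshold,
                               split = split, use_filtered = use_filtered))
  out$selected <- vapply(procs, function(p) isTRUE(p$selected), logical(1))
  out$condition <- vapply(procs, function(p) p$condition %||% NA_character_,
                          character(1))
  out
}

#' Weighted dynamic-trace fraction across experiments
#'
#' Per-experiment percentages are combined with weights equal to the number
#' of traces per experiment; the weighted standard deviation uses the same
#' frequency-weight convention (denominator `sum(n) - 1`). Experiments with
#' zero traces are excluded with a message.
#'
#' @param n_dynamic,n_total integer vectors, one entry per experiment.
#' @return list with `percent` (weighted mean, %), `sd` (weighted SD, %, `NA`
#'   for a single experiment), `n_experiments`, `n_traces`.
#' @export
dynamic_fraction <- function(n_dynamic, n_total) {
  stopifnot(length(n_dynamic) == length(n_total))
  drop <- n_total == 0
  if (any(drop)) {
    message(sum(drop), " experiment(s) with zero traces excluded")
    n_dynamic <- n_dynamic[!drop]; n_total <- n_total[!drop]
  }
  if (length(n_total) == 0) stop("no experiments with traces")
  p <- 100 * n_dynamic / n_total
  w <- n_total
  m <- sum(w * p) / sum(w)
  s <- if (length(p) < 2) NA_real_
       else sqrt(sum(w * (p - m)^2) / (sum(w) - 1))
  list(percent = m, sd = s, n_experiments = length(p), n_traces = sum(w))
}

#' FRET-efficiency frequency histogram
#'
#' Frame-level Chung-Kennedy-filtered efficiencies of the selected traces are
#' pooled and binned with a fixed bin width of 0.04 spanning `[-0.2, 1.2]`
#' (so corrected-efficiency excursions are visible rather than clipped).
#'
#' @param procs list of `processed_trace` (only `selected` ones contribute).
#' @param condition condition label stored with the histogram.
#' @param bin bin width (0.04 by default).
#' @param range histogram range.
#' @return object of class `efficiency_histogram`: list with `breaks`,
#'   `mids`, `counts`, `n_traces`, `n_frames`, `condition`.
#' @export
efficiency_histogram <- function(procs, condition = NA_character_,
                                 bin = 0.04, range = c(-0.2, 1.2)) {
  sel <- Filter(function(p) isTRUE(p$selected), procs)
  if (length(sel) == 0) stop("at least one selected trace is required")
  e <- unlist(lapply(sel, function(p) p$E_ck), use.names = FALSE)
  e <- e[is.finite(e)]
  breaks <- round(seq(range[1], range[2], by = bin), 8)
  e <- pmin(pmax(e, range[1]), range[2] - bin / 1e6)
  counts <- tabulate(findInterval(e, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, mids = breaks[-length(breaks)] + bin / 2,
                 counts = counts, n_traces = length(sel),
                 n_frames = sum(counts), condition = condition),
            class = "efficiency_histogram")
}

#' Dissociated/associated peak ratio of an efficiency histogram
#'
#' Fits a two-Gaussian mixture to the histogram counts with centers
#' initialized at the dissociated (0.08) and associated (0.60) efficiencies
#' and bounded to within 0.1 of the initialization, and returns the ratio of
#' the fitted peak amplitudes (dissociated over associated). If one
#' population is absent the ratio is 0 or `Inf` with a flag rather than an
#' error.
#'
#' @param hist an [efficiency_histogram()].
#' @param centers initial peak centers `(dissociated, associated)`.
#' @param center_bound maximal shift of each center during the fit.
#' @param use_area return the ratio of Gaussian areas instead of amplitudes.
#' @param shared_width constrain both peaks to one common width. The two
#'   states share the same camera noise, so their widths are physically
#'   equal; sharing the width removes a noisy degree of freedom and makes
#'   the amplitude ratio track the occupancy ratio more tightly.
#' @return list with `ratio`, `flag` (`"ok"`, `"no_dissociated_peak"`,
#'   `"no_associated_peak"`), `fit` (named coefficients or `NULL`),
#'   `converged`.
#' @export
peak_ratio <- function(hist, centers = c(0.08, 0.60), center_bound = 0.1,
                       use_area = FALSE, shared_width = FALSE) {
  if (sum(hist$counts) == 0) stop("histogram is empty")
  x <- hist$mids; y <- hist$counts
  near <- function(m) max(y[abs(x - m) <= 0.08], 0)
  a1_0 <- near(centers[1]); a2_0 <- near(centers[2])
  df <- data.frame(x = x, y = y)
  if (shared_width) {
    start <- list(a1 = max(a1_0, 1e-3), m1 = centers[1],
                  a2 = max(a2_0, 1e-3), m2 = centers[2], s1 = 0.05)
    lower <- c(0, centers[1] - center_bound, 0, centers[2] - center_bound, 0.01)
    upper <- c(Inf, centers[1] + center_bound, Inf, centers[2] + center_bound, 0.3)
    form <- y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
      a2 * exp(-(x - m2)^2 / (2 * s1^2))
  } else {
    start <- list(a1 = max(a1_0, 1e-3), m1 = centers[1], s1 = 0.05,
                  a2 = max(a2_0, 1e-3), m2 = centers[2], s2 = 0.05)
    lower <- c(0, centers[1] - center_bound, 0.01, 0, centers[2] - center_bound, 0.01)
    upper <- c(Inf, centers[1] + center_bound, 0.3, Inf, centers[2] + center_bound, 0.3)
    form <- y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
      a2 * exp(-(x - m2)^2 / (2 * s2^2))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate histogram (e.g. a single occupied bin): fall back to the
    # raw amplitudes near the two centers
    a1 <- a1_0; a2 <- a2_0; cf <- NULL; conv <- FALSE
    v1 <- a1; v2 <- a2
  } else {
    cf <- stats::coef(fit); conv <- TRUE
    a1 <- cf[["a1"]]; a2 <- cf[["a2"]]
    s1 <- cf[["s1"]]; s2 <- if (shared_width) cf[["s1"]] else cf[["s2"]]
    v1 <- if (use_area) a1 * s1 else a1
    v2 <- if (use_area) a2 * s2 else a2
  }
  tot <- max(a1 + a2, 1e-12)
  flag <- "ok"
  if (a1 / tot < 0.01) flag <- "no_dissociated_peak"
  if (a2 / tot < 0.01) flag <- "no_associated_peak"
  ratio <- if (v2 <= 0) {
    if (v1 <= 0) NA_real_ else Inf
  } else v1 / v2
  list(ratio = ratio, flag = flag, fit = cf, converged = conv)
}

#' Dissociated/associated occupancy ratio of an efficiency histogram
#'
#' Ratio of pooled frames on either side of the state midpoint. For
#' two-state data this estimates the dissociated:associated occupancy ratio
#' directly and is considerably less noisy than the two-Gaussian amplitude
#' ratio when one population is small, which makes it the readout of choice
#' for dose-response fitting; under ATP-hyperbolic dissociation the
#' occupancy ratio is exactly hyperbolic in ATP with EC50 equal to the
#' kinetic half-saturation constant.
#'
#' @param hist an [efficiency_histogram()].
#' @param split efficiency separating the dissociated and associated states
#'   (midpoint of the two state efficiencies by default).
#' @return ratio (low-E counts over high-E counts); `Inf` when the
#'   associated side is empty.
#' @export
occupancy_ratio <- function(hist, split = 0.34) {
  lo <- sum(hist$counts[hist$mids < split])
  hi <- sum(hist$counts[hist$mids >= split])
  if (hi == 0) return(Inf)
  lo / hi
}
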