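#' Change-point detection by recursive binary segmentation with two-state merge
#'
#' Deterministic replacement for step-finding in piecewise-constant smFRET
#' series: at each segment the split maximizing the two-sample t statistic is
#' accepted when its p-value is below `alpha` and both halves contain at
#' least `min_dwell` frames; the recursion continues on both halves. The
#' resulting segment means are then collapsed onto two states: segments are
#' split at the mid-range of the segment means, and the two clusters are kept
#' only if their centers are at least `min_gap` efficiency units apart
#' (otherwise the whole trace is a single state); adjacent same-state
#' segments are merged. Transitions are the boundaries between states after
#' merging. Over-segmentation by the t-test on serially correlated
#' (filtered) noise is therefore harmless: spurious splits within one state
#' are merged away.
#'
#' @param x numeric series (normally `E_ck` over the green segment).
#' @param alpha significance level for accepting a split.
#' @param min_dwell minimal segment length (frames).
#' @param min_gap minimal distance between the two state means; segments
#'   closer than this collapse to a single state.
#' @param split_threshold optional fixed threshold separating the two states
#'   (e.g. the midpoint of a global two-population fit); overrides the
#'   mid-range rule.
#' @return list with `changepoints` (indices of the first frame of each new
#'   state, empty when static), `segments` (data frame `start`, `end`,
#'   `mean`, `state` in `{"high","low"}` after merging) and `states`
#'   (per-frame state labels).
#' @export
detect_transitions <- function(x, alpha = 0.001, min_dwell = 3L,
                               min_gap = 0.2, split_threshold = NULL) {
  n <- length(x)
  if (n < 2L * min_dwell) stop("series shorter than 2 * min_dwell")
  bounds <- binseg_(x, 1L, n, alpha, min_dwell)
  starts <- sort(unique(c(1L, bounds)))
  ends <- c(starts[-1] - 1L, n)
  # segment means for state assignment drop the first and last frame of each
  # segment (>= 3 frames): boundary frames carry filter/camera averaging
  # across the transition and would pull short segments towards their
  # neighbours
  means <- vapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- ends[i]
    if (e - s >= 2L) { s <- s + 1L; e <- e - 1L }
    mean(x[s:e])
  }, numeric(1))
  if (!is.null(split_threshold)) {
    high <- means > split_threshold
    if (all(high) || !any(high)) high <- rep(all(high), length(means))
  } else if (length(means) == 1L) {
    high <- TRUE
  } else {
    ctr <- mean(range(means))
    high <- means > ctr
    if (any(high) && any(!high)) {
      gap <- mean(means[high]) - mean(means[!high])
      if (gap < min_gap) high <- rep(TRUE, length(means))
    } else high <- rep(TRUE, length(means))
  }
  state <- ifelse(high, "high", "low")
  # merge adjacent same-state segments
  keep <- c(TRUE, state[-1] != state[-length(state)])
  m_start <- starts[keep]
  m_end <- c(m_start[-1] - 1L, n)
  m_state <- state[keep]
  m_mean <- vapply(seq_along(m_start),
                   function(i) mean(x[m_start[i]:m_end[i]]), numeric(1))
  seg <- data.frame(start = m_start, end = m_end, mean = m_mean,
                    state = m_state, stringsAsFactors = FALSE)
  states <- rep(m_state, m_end - m_start + 1L)
  list(changepoints = if (nrow(seg) > 1) seg$start[-1] else integer(0),
       segments = seg, states = states)
}

# recursive binary segmentation; returns start indices of right halves
binseg_ <- function(x, lo, hi, alpha, min_dwell) {
  n <- hi - lo + 1L
  if (n < 2L * min_dwell) return(integer(0))
  y <- x[lo:hi]
  s <- cumsum(y); s2 <- cumsum(y^2)
  k <- min_dwell:(n - min_dwell)
  m1 <- s[k] / k
  m2 <- (s[n] - s[k]) / (n - k)
  ss1 <- s2[k] - s[k]^2 / k
  ss2 <- (s2[n] - s2[k]) - (s[n] - s[k])^2 / (n - k)
  sp2 <- pmax((ss1 + ss2) / (n - 2L), 1e-12)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / k + 1 / (n - k)))
  best <- which.max(abs(tstat))
  pval <- 2 * stats::pt(-abs(tstat[best]), df = n - 2L)
  if (pval >= alpha) return(integer(0))
  cut <- lo + k[best]  # first index of the right half (absolute)
  c(binseg_(x, lo, cut - 1L, alpha, min_dwell),
    cut,
    binseg_(x, cut, hi, alpha, min_dwell))
}

#' Harvest dwell durations from a segmented trace
#'
#' Only interior dwells (bounded by a detected transition on both sides)
#' have known durations; the first and last dwell of every trace are
#' censored by the observation window and are retained with flags for
#' diagnostics but excluded from fitting. A trace with fewer than two
#' transitions contributes no complete dwell.
#'
#' @param det result of [detect_transitions()], or a list of such results.
#' @param frame_time frame duration (s).
#' @param trace_id id(s) recorded with the dwells.
#' @return a `dwell_set` data frame with columns `trace_id`, `state`
#'   (`"high"`/`"low"`), `duration_s`, `censoring`
#'   (`"first"`/`"last"`/`"complete"`).
#' @export
harvest_dwells <- function(det, frame_time, trace_id = NULL) {
  if (!is.null(det$segments)) det <- list(det)
  if (is.null(trace_id)) trace_id <- sprintf("trace_%04d", seq_along(det))
  out <- lapply(seq_along(det), function(i) {
    seg <- det[[i]]$segments
    k <- nrow(seg)
    if (k == 0) return(NULL)
    cens <- rep("complete", k)
    cens[1] <- "first"; cens[k] <- "last"
    data.frame(trace_id = trace_id[i], state = seg$state,
               duration_s = (seg$end - seg$start + 1L) * frame_time,
               censoring = cens, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(trace_id = character(0), state = character(0),
                      duration_s = numeric(0), censoring = character(0))
  class(res) <- c("dwell_set", "data.frame")
  attr(res, "frame_time") <- frame_time
  res
}

#' Exponential fit of dwell durations with censoring-aware truncation
#'
#' Maximum-likelihood fit of the mean dwell time from complete (interior)
#' dwells. The default `"window"` method maximizes the likelihood of the
#' observation model for interior dwells in a recording of length
#' `window_s`: a dwell of length `x` is observable only if it starts early
#' enough to finish, giving density proportional to
#' `(window_s - x) * exp(-x/tau)` on `[min_dwell_s, window_s]`. This corrects
#' both the hard truncation and the length-biased sampling that make the
#' naive mean underestimate long dwells. `"truncated"` drops the window
#' weight (plain doubly truncated exponential) and `"naive"` is the sample
#' mean, mirroring an uncorrected histogram fit.
#'
#' @param dwells numeric vector of complete dwell durations (s), or a
#'   `dwell_set` (in which case `state` selects the state and only complete
#'   dwells are used).
#' @param window_s observation-window length (s).
#' @param min_dwell_s smallest resolvable dwell (left truncation, s).
#' @param method `"window"`, `"truncated"` or `"naive"`.
#' @param state when `dwells` is a `dwell_set`: `"high"` or `"low"`.
#' @param min_n minimal number of complete dwells (fit refused below).
#' @return object of class `exp_fit`: list with `tau`, `rate`, `se_tau`,
#'   `se_rate`, `ci` (95% on tau), `n`, `method`, `flag`.
#' @export
fit_exponential_dwells <- function(dwells, window_s, min_dwell_s = 0,
                                   method = c("window", "truncated", "naive"),
                                   state = NULL, min_n = 20L) {
  method <- match.arg(method)
  if (inherits(dwells, "dwell_set")) {
    d <- dwells[dwells$censoring == "complete", , drop = FALSE]
    if (!is.null(state)) d <- d[d$state == state, , drop = FALSE]
    x <- d$duration_s
  } else x <- as.numeric(dwells)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < min_n)
    stop(sprintf("fit refused: %d complete dwells < required %d", n, min_n))
  if (stats::sd(x) < 1e-9 * max(mean(x), 1)) {
    return(structure(list(tau = NA_real_, rate = NA_real_, se_tau = NA_real_,
                          se_rate = NA_real_, ci = c(NA_real_, NA_real_),
                          n = n, method = method, flag = "non_exponential"),
                     class = "exp_fit"))
  }
  a <- min_dwell_s; b <- window_s
  if (any(x > b)) stop("dwells exceed the observation window")
  ll <- switch(method,
    naive = NULL,
    truncated = function(tau)
      -sum(x) / tau - n * log(tau * (exp(-a / tau) - exp(-b / tau))),
    window = function(tau) {
      z <- tau * ((b - a) * exp(-a / tau)) +
        tau^2 * (exp(-b / tau) - exp(-a / tau))
      -sum(x) / tau - n * log(z)
    })
  if (method == "naive") {
    tau <- mean(x); se <- stats::sd(x) / sqrt(n)
  } else {
    opt <- stats::optimize(ll, interval = c(max(min(x) / 10, 1e-3), 10 * b),
                           maximum = TRUE, tol = 1e-8)
    tau <- opt$maximum
    h <- tau * 1e-4
    d2 <- (ll(tau + h) - 2 * ll(tau) + ll(tau - h)) / h^2
    se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  }
  ci <- tau + c(-1.96, 1.96) * se
  structure(list(tau = tau, rate = 1 / tau, se_tau = se,
                 se_rate = if (is.finite(se)) se / tau^2 else NA_real_,
                 ci = ci, n = n, method = method, flag = "ok"),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential dwell fit (%s): tau = %.3g s (se %.2g), n = %d%s\n",
              x$method, x$tau, x$se_tau, x$n,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Time of the first dissociation event of a segmented trace
#'
#' @param det result of [detect_transitions()].
#' @param frame_time frame duration (s).
#' @return time (s, from segment start) of the first high-to-low state
#'   change, or `NA` when none occurs.
#' @export
first_dissociation_time <- function(det, frame_time) {
  seg <- det$segments
  if (nrow(seg) < 2) return(NA_real_)
  drop <- which(seg$state[-nrow(seg)] == "high" &
                  seg$state[-1] == "low")
  if (length(drop) == 0) return(NA_real_)
  (seg$start[drop[1] + 1L] - 1L) * frame_time
}

#' Survival-of-first-event analysis
#'
#' Builds the fraction-without-event curve (starting at 1, non-increasing)
#' from per-trace times of the first dissociation event after activation,
#' and fits a one-phase exponential decay. Traces without an event inside
#' the observation window enter the fit as right-censored, via the censored
#' exponential maximum-likelihood estimate
#' `rate = n_events / (sum of event times + n_censored * window)`;
#' the half-life is `log(2) / rate`.
#'
#' @param event_times numeric vector of first-event times (s since
#'   activation); `NA` marks traces without an event (right-censored at
#'   `window_s`).
#' @param window_s observation window (s).
#' @return object of class `first_event_fit`: list with `curve` (data frame
#'   `time`, `surv`), `rate`, `se_rate`, `half_life`, `n_events`,
#'   `n_censored`. When no events occurred, `rate` is `NA` and only the
#'   curve is returned.
#' @export
first_event_analysis <- function(event_times, window_s) {
  cens <- !is.finite(event_times)
  ev <- sort(event_times[!cens])
  n <- length(event_times)
  curve <- data.frame(time = c(0, ev),
                      surv = c(1, 1 - seq_along(ev) / n))
  if (length(ev) == 0) {
    return(structure(list(curve = curve, rate = NA_real_, se_rate = NA_real_,
                          half_life = NA_real_, n_events = 0L,
                          n_censored = sum(cens)),
                     class = "first_event_fit"))
  }
  rate <- length(ev) / (sum(ev) + sum(cens) * window_s)
  se <- rate / sqrt(length(ev))
  structure(list(curve = curve, rate = rate, se_rate = se,
                 half_life = log(2) / rate, n_events = length(ev),
                 n_censored = sum(cens)),
            class = "first_event_fit")
}

#' Two-tailed unpaired comparison of two fitted decay rates
#'
#' Unpaired t test on two rate estimates using their fit standard errors,
#' with Welch-Satterthwaite degrees of freedom built from the per-fit sample
#' sizes.
#'
#' @param rate_a,rate_b fitted rates (s^-1).
#' @param se_a,se_b standard errors of the rates.
#' @param n_a,n_b number of observations behind each fit.
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
compare_decay_rates <- function(rate_a, se_a, n_a, rate_b, se_b, n_b) {
  if (!is.finite(se_a) || !is.finite(se_b) || se_a <= 0 || se_b <= 0)
    stop("both fits must carry positive standard errors")
  v <- se_a^2 + se_b^2
  tt <- (rate_a - rate_b) / sqrt(v)
  df <- v^2 / (se_a^4 / (n_a - 1) + se_b^4 / (n_b - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Hyperbolic dose-response (EC50) fit
#'
#' Least-squares fit of `y = floor + (ceiling - floor) * x / (EC50 + x)`
#' (Hill coefficient fixed at 1). Because the model is linear in floor and
#' ceiling given EC50, EC50 is profiled on a log grid with an exact linear
#' sub-fit at each candidate, which makes the fit deterministic and immune
#' to starting values, and yields a profile-likelihood confidence interval
#' from the F threshold. The estimate is equivariant under rescaling the
#' dose units.
#'
#' @param dose non-negative dose values (>= 4 levels including 0 and a
#'   near-saturating level recommended).
#' @param response response at each dose.
#' @param conf confidence level of the profile interval.
#' @return object of class `ec50_fit`: list with `ec50`, `floor`, `ceiling`,
#'   `ci` (profile interval, may be infinite), `sse`, `flag` (`"ok"`,
#'   `"no_dose_dependence"`, `"decreasing_response"`), `n`.
#' @export
fit_ec50 <- function(dose, response, conf = 0.95) {
  stopifnot(length(dose) == length(response))
  ok <- is.finite(dose) & is.finite(response)
  dose <- dose[ok]; response <- response[ok]
  if (length(unique(dose)) < 4) stop("at least 4 dose levels are required")
  if (any(dose < 0)) stop("doses must be >= 0")
  sub_fit <- function(l10) {
    ec <- 10^l10
    w <- dose / (ec + dose)
    fit <- stats::lm(response ~ w)
    list(sse = sum(stats::resid(fit)^2), coef = stats::coef(fit))
  }
  pos <- dose[dose > 0]
  lo <- log10(min(pos)) - 3; hi <- log10(max(pos)) + 3
  grid <- seq(lo, hi, length.out = 200)
  sse_g <- vapply(grid, function(g) sub_fit(g)$sse, numeric(1))
  i0 <- which.min(sse_g)
  br <- c(grid[max(i0 - 1L, 1L)], grid[min(i0 + 1L, length(grid))])
  opt <- stats::optimize(function(g) sub_fit(g)$sse, interval = br,
                         tol = 1e-10)
  l10_hat <- opt$minimum
  best <- sub_fit(l10_hat)
  cf <- best$coef
  fl <- unname(cf[1]); ce <- unname(cf[1] + cf[2])
  n <- length(dose); dfree <- n - 3
  flag <- "ok"
  if (ce < fl) flag <- "decreasing_response"
  sse0 <- sum((response - mean(response))^2)
  if (dfree > 0) {
    fstat <- ((sse0 - best$sse) / 2) / max(best$sse / dfree, 1e-300)
    p_dep <- stats::pf(fstat, 2, dfree, lower.tail = FALSE)
    if (!is.finite(p_dep) || p_dep > 0.05) flag <- "no_dose_dependence"
  }
  # profile interval on log10(EC50)
  ci <- c(NA_real_, NA_real_)
  if (dfree > 0) {
    thr <- best$sse * (1 + stats::qf(conf, 1, dfree) / dfree)
    fine <- seq(lo, hi, length.out = 600)
    inside <- vapply(fine, function(g) sub_fit(g)$sse, numeric(1)) <= thr
    if (any(inside)) {
      ci <- 10^range(fine[inside])
      if (fine[which(inside)[1]] <= lo + 1e-9) ci[1] <- 0
      if (fine[rev(which(inside))[1]] >= hi - 1e-9) ci[2] <- Inf
    }
  }
  if (flag == "no_dose_dependence") ci <- c(0, Inf)
  structure(list(ec50 = 10^l10_hat, floor = fl, ceiling = ce, ci = ci,
                 sse = best$sse, flag = flag, n = n),
            class = "ec50_fit")
}

#' @export
print.ec50_fit <- function(x, ...) {
  cat(sprintf("EC50 = %.4g (CI %.4g - %.4g), floor %.3g, ceiling %.3g%s\n",
              x$ec50, x$ci[1], x$ci[2], x$floor, x$ceiling,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Welch's ANOVA and Games-Howell/Tukey pairwise tests from group summaries
#'
#' Operates on per-group summary statistics (weighted mean, weighted SD and
#' number of experiments per condition), as needed when each condition is
#' summarized by a weighted average across experiments. The omnibus test is
#' Welch's heteroscedastic F (right-tailed); pairwise comparisons use the
#' studentized-range (Tukey HSD) distribution with Welch-style per-pair
#' error terms and degrees of freedom (Games-Howell), two-tailed.
#'
#' @param means group means.
#' @param sds group standard deviations (must be positive).
#' @param ns group sizes (>= 2 each).
#' @param labels optional group labels.
#' @return list with `F`, `df1`, `df2`, `p` (omnibus, right-tailed) and
#'   `pairwise` (data frame `group1`, `group2`, `diff`, `q`, `df`, `p`).
#' @export
welch_anova_tukey <- function(means, sds, ns, labels = NULL) {
  k <- length(means)
  stopifnot(length(sds) == k, length(ns) == k)
  if (k < 2) stop("at least 2 groups are required")
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (any(sds <= 0)) stop("zero within-group variance")
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  w <- ns / sds^2
  mw <- sum(w * means) / sum(w)
  A <- sum(w * (means - mw)^2) / (k - 1)
  hv <- sum((1 - w / sum(w))^2 / (ns - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * hv
  Fstat <- A / B
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * hv)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  pw <- do.call(rbind, lapply(utils::combn(k, 2, simplify = FALSE),
    function(ij) {
      i <- ij[1]; j <- ij[2]
      vi <- sds[i]^2 / ns[i]; vj <- sds[j]^2 / ns[j]
      se <- sqrt((vi + vj) / 2)
      q <- abs(means[i] - means[j]) / se
      dfij <- (vi + vj)^2 / (vi^2 / (ns[i] - 1) + vj^2 / (ns[j] - 1))
      data.frame(group1 = labels[i], group2 = labels[j],
                 diff = means[i] - means[j], q = q, df = dfij,
                 p = stats::ptukey(q, k, dfij, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  list(F = Fstat, df1 = df1, df2 = df2, p = p, pairwise = pw)
}

#' End-to-end rate estimation from a trace set
#'
#' Runs the full chain: correction and filtering, anticorrelation
#' classification, change-point detection on the dynamic traces, interior
#' dwell harvesting, and censoring-aware exponential fits of both states.
#' The associated-state mean dwell estimates `1/k_diss` and the
#' dissociated-state mean dwell estimates `1/k_assoc`.
#'
#' Binary segmentation misses short central excursions at stringent split
#' thresholds (a brief dwell inside a long segment barely moves the single
#' best split's t statistic), and every missed dwell merges its two
#' neighbours into one spuriously long dwell. The dwell pipeline therefore
#' over-segments at a permissive `alpha` and relies on the deterministic
#' two-state merge in [detect_transitions()] for false-positive control, and
#' it detects on the median-prefiltered corrected efficiency rather than the
#' Chung-Kennedy-filtered series, whose window averaging attenuates dwells
#' shorter than its window. The filtered series remains the classifier
#' input and is available via `detect_on = "filtered"`.
#'
#' @param traces list of `fret_trace`.
#' @param cf [correction_factors()] used for the correction step.
#' @param threshold,split classifier parameters, see [classify_trace()].
#' @param alpha,min_dwell,min_gap detection parameters, see
#'   [detect_transitions()].
#' @param detect_on series used for change-point detection.
#' @param method dwell-fit method, see [fit_exponential_dwells()].
#' @param min_n minimal number of complete dwells per state.
#' @return list with `k_assoc`, `k_diss` (point estimates, s^-1), `fits`
#'   (per-state `exp_fit`), `dwells` (`dwell_set`), `classification`
#'   (data frame), `n_dynamic`.
#' @export
estimate_rates <- function(traces, cf, threshold = -0.01, split = 0.4,
                           alpha = 0.05, min_dwell = 3L, min_gap = 0.2,
                           detect_on = c("raw", "filtered"),
                           method = "window", min_n = 20L) {
  detect_on <- match.arg(detect_on)
  procs <- process_traces(traces, cf)
  cls <- classify_traces(procs, threshold = threshold, split = split)
  ft <- procs[[1]]$frame_time
  window_s <- length(procs[[1]]$E_ck) * ft
  dyn <- which(cls$label == "dynamic")
  dets <- lapply(procs[dyn], function(p)
    detect_transitions(if (detect_on == "raw") p$E_raw else p$E_ck,
                       alpha = alpha, min_dwell = min_dwell,
                       min_gap = min_gap))
  dw <- harvest_dwells(dets, frame_time = ft, trace_id = cls$trace_id[dyn])
  fit_hi <- fit_exponential_dwells(dw, window_s = window_s,
                                   min_dwell_s = min_dwell * ft,
                                   method = method, state = "high",
                                   min_n = min_n)
  fit_lo <- fit_exponential_dwells(dw, window_s = window_s,
                                   min_dwell_s = min_dwell * ft,
                                   method = method, state = "low",
                                   min_n = min_n)
  list(k_assoc = fit_lo$rate, k_diss = fit_hi$rate,
       fits = list(associated = fit_hi, dissociated = fit_lo),
       dwells = dw, classification = cls, n_dynamic = length(dyn))
}
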