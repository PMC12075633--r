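#' Simulate a hidden two-state association/dissociation path
#'
#' Draws a continuous-time two-state Markov path over `[0, duration]`.
#' Waiting times are exponential with rate `k_assoc` out of the dissociated
#' state and `k_diss(atp)` (rectangular hyperbola in ATP, see [k_diss_at()])
#' out of the associated state. Non-responsive and inactive complexes stay
#' associated for the whole duration. The initial state is associated unless
#' the scenario is flagged `pre_equilibrated`, in which case it is drawn from
#' the stationary distribution `k_assoc/(k_assoc + k_diss)` vs
#' `k_diss/(k_assoc + k_diss)`.
#'
#' Single-step irreversible photobleaching times for both dyes are drawn here
#' as part of the ground truth (infinite when the bleach rate is zero).
#'
#' @param scenario a [kinetic_scenario()].
#' @param duration path duration (s), normally the green-segment duration.
#' @param seed integer seed; every public simulation entry point takes an
#'   explicit seed and no global random state is relied upon.
#' @param responsive logical; `FALSE` models a complex whose ATPase subunits
#'   face away from the added ATP (stays associated).
#' @param spot_class one of `"pair"`, `"donor_only"`, `"acceptor_only"`.
#' @return A `ground_truth` list with elements `duration`, `initial_state`
#'   (`"associated"`/`"dissociated"`), `trans_times` (strictly increasing, s),
#'   `bleach_d`, `bleach_a` (s, `Inf` = no bleach), `spot_class`.
#' @export
simulate_state_path <- function(scenario, duration, seed,
                                responsive = TRUE, spot_class = "pair") {
  set.seed(seed)
  sim_path_(scenario, duration, responsive = responsive,
            spot_class = spot_class)
}

# unseeded workhorse so batch generators can share one RNG stream
sim_path_ <- function(scenario, duration, responsive = TRUE,
                      spot_class = "pair", inactive = FALSE) {
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0")
  kd <- if (responsive && !inactive) k_diss_at(scenario) else 0
  ka <- scenario$k_assoc
  if (kd == 0 || inactive || !responsive) {
    # absorbing at zero dissociation rate: stationary state is associated
    init <- "associated"
    trans <- numeric(0)
  } else {
    if (scenario$pre_equilibrated) {
      p_assoc <- ka / (ka + kd)
      init <- if (stats::runif(1) < p_assoc) "associated" else "dissociated"
    } else {
      init <- "associated"
    }
    trans <- numeric(0)
    t <- 0
    state_assoc <- identical(init, "associated")
    repeat {
      rate <- if (state_assoc) kd else ka
      if (rate == 0) break
      t <- t + stats::rexp(1, rate)
      if (t >= duration) break
      trans <- c(trans, t)
      state_assoc <- !state_assoc
    }
  }
  bl_d <- if (scenario$bleach_rate_d > 0)
    stats::rexp(1, scenario$bleach_rate_d) else Inf
  bl_a <- if (scenario$bleach_rate_a > 0)
    stats::rexp(1, scenario$bleach_rate_a) else Inf
  structure(list(duration = duration, initial_state = init,
                 trans_times = trans, bleach_d = bl_d, bleach_a = bl_a,
                 spot_class = spot_class),
            class = "ground_truth")
}

#' Fraction of each interval spent in the associated state
#'
#' Occupancy-weighted averaging over frame intervals: a frame containing a
#' transition gets the time-weighted mean of the two state efficiencies
#' (models sub-frame averaging at the camera integration time).
#'
#' @param truth a `ground_truth` object.
#' @param breaks increasing vector of interval boundaries (s).
#' @return numeric vector of length `length(breaks) - 1` in `[0, 1]`.
#' @export
assoc_occupancy <- function(truth, breaks) {
  ev <- c(0, truth$trans_times, max(breaks[length(breaks)], truth$duration))
  n_int <- length(ev) - 1L
  assoc0 <- identical(truth$initial_state, "associated")
  assoc_state <- rep(c(assoc0, !assoc0), length.out = n_int)
  # cumulative associated time at event boundaries -> piecewise-linear in t
  seg_assoc <- diff(ev) * as.numeric(assoc_state)
  cumA <- c(0, cumsum(seg_assoc))
  a_at <- stats::approx(ev, cumA, xout = pmin(breaks, ev[length(ev)]),
                        rule = 2)$y
  diff(a_at) / diff(breaks)
}

#' Ground-truth per-frame state labels over the green segment
#'
#' @param truth a `ground_truth` object.
#' @param frame_time frame duration (s).
#' @param n_frames number of frames.
#' @return character vector `"associated"`/`"dissociated"` (majority state of
#'   each frame).
#' @export
truth_states <- function(truth, frame_time, n_frames) {
  occ <- assoc_occupancy(truth, seq(0, n_frames * frame_time, by = frame_time))
  ifelse(occ >= 0.5, "associated", "dissociated")
}

#' Render a camera trace from a hidden state path
#'
#' Forward model of the dual-view TIRF recording: per green frame the ideal
#' donor/acceptor counts follow the frame-averaged FRET efficiency of the
#' hidden state; crosstalk adds `leakage * I_D_ideal` to the acceptor channel
#' and direct excitation adds `direct_exc * total` while the acceptor is
#' alive; red head/tail segments carry the acceptor-excitation intensity
#' `I_AA`; photobleaching truncates the relevant dye's emission; the realized
#' background series and Gaussian camera noise are added. Donor-only spots
#' emit no FRET acceptor signal; acceptor-only spots emit only `I_AA` plus
#' the direct-excitation term.
#'
#' Columns `I_D` and `I_A` are defined on green frames, `I_AA` on red frames
#' (`NA` elsewhere). The background series added to the signals is the same
#' series reported in `bg_D`/`bg_A`, so a noiseless render is exactly
#' invertible by [correct_trace()].
#'
#' @param truth a `ground_truth` (must cover the green segment).
#' @param scenario the generating [kinetic_scenario()].
#' @param seed integer seed for noise and background realizations.
#' @param trace_id,condition metadata stored as attributes.
#' @return A `fret_trace` data frame with columns `time_s`, `I_D`, `I_A`,
#'   `I_AA`, `segment`, `bg_D`, `bg_A` and attributes `trace_id`,
#'   `condition`, `atp`, `frame_time`, `truth`.
#' @export
render_trace <- function(truth, scenario, seed, trace_id = "trace_1",
                         condition = "sim") {
  set.seed(seed)
  render_trace_(truth, scenario, trace_id = trace_id, condition = condition)
}

render_trace_ <- function(truth, scenario, trace_id = "trace_1",
                          condition = "sim") {
  sc <- scenario
  n_head <- sc$n_frames_red_head
  n_green <- sc$n_frames_green
  n_tail <- sc$n_frames_red_tail
  ft <- sc$frame_time
  green_dur <- n_green * ft
  if (truth$duration < green_dur - 1e-9)
    stop("ground-truth path does not cover the green segment")
  n <- n_head + n_green + n_tail
  segment <- rep(c("red_head", "green", "red_tail"),
                 times = c(n_head, n_green, n_tail))
  time_s <- (seq_len(n) - 1L) * ft

  # realized background series (same values reported and added)
  bg_D <- sc$bg_d + stats::rnorm(n, 0, sc$bg_sd)
  bg_A <- sc$bg_a + stats::rnorm(n, 0, sc$bg_sd)

  # dye survival per frame; bleach times are on the movie clock
  green_idx <- which(segment == "green")
  red_idx <- which(segment != "green")
  t_green <- (seq_len(n_green) - 1L) * ft        # time within green segment
  donor_alive <- time_s[green_idx] < truth$bleach_d
  # acceptor illumination: direct in red segments, via FRET/direct in green;
  # one clock over the whole movie keeps the model single-step irreversible
  acc_alive_full <- time_s < truth$bleach_a
  acc_alive_green <- acc_alive_full[green_idx]
  acc_alive_red <- acc_alive_full[red_idx]

  tot <- sc$total_intensity
  I_D_id <- numeric(n_green); I_A_id <- numeric(n_green)
  direct <- numeric(n_green)
  if (truth$spot_class == "pair") {
    occ <- assoc_occupancy(truth, c(t_green, n_green * ft))
    E_frame <- occ * sc$E_assoc + (1 - occ) * sc$E_diss
    both <- donor_alive & acc_alive_green
    I_D_id <- ifelse(both, (1 - E_frame) * tot,
                     ifelse(donor_alive, tot, 0))
    I_A_id <- ifelse(both, E_frame * tot, 0)
    direct <- sc$direct_exc * tot * as.numeric(acc_alive_green)
    I_AA_id <- tot * as.numeric(acc_alive_red)
  } else if (truth$spot_class == "donor_only") {
    I_D_id <- tot * as.numeric(donor_alive)
    direct <- 0
    I_AA_id <- numeric(length(red_idx))
  } else if (truth$spot_class == "acceptor_only") {
    direct <- sc$direct_exc * tot * as.numeric(acc_alive_green)
    I_AA_id <- tot * as.numeric(acc_alive_red)
  } else stop("unknown spot_class: ", truth$spot_class)

  noise <- function(k) if (sc$noise_sd > 0) stats::rnorm(k, 0, sc$noise_sd)
                       else numeric(k)

  I_D <- rep(NA_real_, n); I_A <- rep(NA_real_, n); I_AA <- rep(NA_real_, n)
  I_D[green_idx] <- I_D_id + bg_D[green_idx] + noise(n_green)
  I_A[green_idx] <- I_A_id + sc$leakage * I_D_id + direct +
    bg_A[green_idx] + noise(n_green)
  I_AA[red_idx] <- I_AA_id + bg_A[red_idx] + noise(length(red_idx))

  out <- data.frame(time_s = time_s, I_D = I_D, I_A = I_A, I_AA = I_AA,
                    segment = segment, bg_D = bg_D, bg_A = bg_A,
                    stringsAsFactors = FALSE)
  attr(out, "trace_id") <- trace_id
  attr(out, "condition") <- condition
  attr(out, "atp") <- sc$atp
  attr(out, "frame_time") <- ft
  attr(out, "truth") <- truth
  class(out) <- c("fret_trace", "data.frame")
  out
}

#' Simulate a population of traces with known ground truth
#'
#' Spot classes are assigned by the scenario fractions
#' (`frac_donor_only`, `frac_acceptor_only`, rest doubly labeled pairs);
#' pairs are further split into inactive (`frac_inactive`, never switching),
#' non-responsive (`1 - frac_responsive`, stay associated) and responsive
#' complexes that follow the two-state kinetics.
#'
#' @param scenario a [kinetic_scenario()].
#' @param n number of traces.
#' @param seed integer seed.
#' @param condition condition label stored in the metadata.
#' @return list with elements `traces` (list of `fret_trace`), `truth`
#'   (list of `ground_truth`) and `info` (data frame with `trace_id`,
#'   `spot_class`, `label` where `label` is the ground-truth
#'   dynamic/static_high/static_low/donor_only/acceptor_only annotation).
#' @export
simulate_traces <- function(scenario, n, seed, condition = "sim") {
  set.seed(seed)
  green_dur <- scenario$n_frames_green * scenario$frame_time
  traces <- vector("list", n)
  truths <- vector("list", n)
  info <- data.frame(trace_id = sprintf("trace_%04d", seq_len(n)),
                     spot_class = character(n), label = character(n),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    u <- stats::runif(1)
    cls <- if (u < scenario$frac_donor_only) "donor_only"
           else if (u < scenario$frac_donor_only + scenario$frac_acceptor_only)
             "acceptor_only" else "pair"
    inactive <- cls == "pair" && stats::runif(1) < scenario$frac_inactive
    responsive <- cls == "pair" && !inactive &&
      stats::runif(1) < scenario$frac_responsive
    tr <- sim_path_(scenario, green_dur, responsive = responsive,
                    spot_class = cls, inactive = inactive)
    truths[[i]] <- tr
    traces[[i]] <- render_trace_(tr, scenario,
                                 trace_id = info$trace_id[i],
                                 condition = condition)
    info$spot_class[i] <- cls
    info$label[i] <- truth_label(tr, scenario)
  }
  list(traces = traces, truth = truths, info = info)
}

#' Ground-truth classification label of a simulated path
#'
#' `dynamic` if at least one transition falls inside the green window,
#' otherwise `static_high`/`static_low` by the (constant) state FRET
#' efficiency relative to 0.4; single-dye spots keep their spot class.
#'
#' @param truth a `ground_truth`.
#' @param scenario the generating scenario (for the state efficiencies).
#' @return character label.
#' @export
truth_label <- function(truth, scenario) {
  if (truth$spot_class != "pair") return(truth$spot_class)
  if (length(truth$trans_times) > 0) return("dynamic")
  E <- if (identical(truth$initial_state, "associated")) scenario$E_assoc
       else scenario$E_diss
  if (E > 0.4) "static_high" else "static_low"
}

#' Synthetic classifier benchmark with fixed class proportions
#'
#' Generates a labeled mixture of static-high, static-low and dynamic traces
#' (dynamic traces carry 1-5 transitions at uniformly drawn times separated
#' by at least `min_gap_s`), rendered at a per-channel signal-to-noise ratio
#' of roughly `total_intensity / (2 * noise_sd)`. This is the benchmark used
#' to measure concordance of the anticorrelation classifier with ground
#' truth.
#'
#' @param n number of traces.
#' @param seed integer seed.
#' @param scenario rendering scenario; defaults to [kinetic_scenario()] with
#'   all spots doubly labeled and no bleaching.
#' @param prop named proportions for `static_high`, `static_low`, `dynamic`.
#' @param n_trans_range integer range of transition counts for dynamic traces.
#' @param min_gap_s minimal spacing between transitions (s).
#' @return same structure as [simulate_traces()].
#' @export
simulate_benchmark <- function(n = 500, seed = 1,
                               scenario = kinetic_scenario(
                                 frac_donor_only = 0, frac_acceptor_only = 0,
                                 bleach_rate_d = 0, bleach_rate_a = 0),
                               prop = c(static_high = 0.3, static_low = 0.2,
                                        dynamic = 0.5),
                               n_trans_range = 1:5, min_gap_s = 1) {
  set.seed(seed)
  stopifnot(abs(sum(prop) - 1) < 1e-8)
  green_dur <- scenario$n_frames_green * scenario$frame_time
  counts <- round(prop * n)
  counts[1] <- n - sum(counts[-1])
  labels <- rep(names(counts), counts)
  labels <- sample(labels)  # shuffle so trace order carries no information
  traces <- vector("list", n); truths <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (lab == "dynamic") {
      k <- sample(n_trans_range, 1)
      repeat {
        tt <- sort(stats::runif(k, 0, green_dur))
        if (k == 1 || min(diff(tt)) >= min_gap_s) break
      }
      init <- if (stats::runif(1) < 0.5) "associated" else "dissociated"
      tr <- structure(list(duration = green_dur, initial_state = init,
                           trans_times = tt, bleach_d = Inf, bleach_a = Inf,
                           spot_class = "pair"), class = "ground_truth")
    } else {
      init <- if (lab == "static_high") "associated" else "dissociated"
      tr <- structure(list(duration = green_dur, initial_state = init,
                           trans_times = numeric(0), bleach_d = Inf,
                           bleach_a = Inf, spot_class = "pair"),
                      class = "ground_truth")
    }
    truths[[i]] <- tr
    traces[[i]] <- render_trace_(tr, scenario,
                                 trace_id = sprintf("bench_%04d", i),
                                 condition = "benchmark")
  }
  info <- data.frame(trace_id = vapply(traces, function(x) attr(x, "trace_id"),
                                       character(1)),
                     spot_class = "pair", label = labels,
                     stringsAsFactors = FALSE)
  list(traces = traces, truth = truths, info = info)
}

#' Simulate a dose-response panel over a grid of ATP concentrations
#'
#' One trace set per ATP level; all non-ATP parameters are shared.
#'
#' @param scenario base [kinetic_scenario()].
#' @param atp_grid non-negative ATP concentrations (uM), at least 4 levels.
#' @param n_traces traces per level.
#' @param seed integer seed.
#' @return list of per-level results (each as [simulate_traces()]) with the
#'   grid stored in attribute `atp_grid`.
#' @export
simulate_dose_response <- function(scenario, atp_grid, n_traces, seed) {
  if (length(atp_grid) < 4 || any(atp_grid < 0))
    stop("atp_grid must be non-negative with at least 4 levels")
  out <- vector("list", length(atp_grid))
  for (j in seq_along(atp_grid)) {
    scj <- scenario
    scj$atp <- atp_grid[j]
    out[[j]] <- simulate_traces(scj, n_traces, seed = seed + j - 1L,
                                condition = sprintf("atp_%g", atp_grid[j]))
  }
  attr(out, "atp_grid") <- atp_grid
  out
}
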