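#' Generative scenario for the two-state association/dissociation experiment
#'
#' A `kinetic_scenario` bundles every parameter of the forward model: the
#' continuous-time two-state Markov kinetics (association rate `k_assoc`,
#' maximal ATP-driven dissociation rate `k_diss_max` with half-saturation
#' constant `K_atp`), the FRET efficiencies of the associated and dissociated
#' states, the composition of the spot population (responsive/inactive
#' fractions, single-dye fractions), and the camera/photophysics model
#' (intensities, Gaussian noise, crosstalk, direct excitation, background,
#' photobleaching) together with the alternating-excitation frame layout
#' (red head / green / red tail).
#'
#' The effective dissociation rate at ATP concentration `atp` is the
#' single-site rectangular hyperbola
#' `k_diss = k_diss_max * atp / (K_atp + atp)` (Hill coefficient 1);
#' association is ATP-independent.
#'
#' @param k_assoc association rate (s^-1) out of the dissociated state.
#' @param k_diss_max maximal ATP-driven dissociation rate (s^-1).
#' @param K_atp half-saturation ATP concentration (uM).
#' @param atp ATP concentration (uM).
#' @param E_assoc,E_diss FRET efficiency of the associated / dissociated state.
#' @param frac_responsive fraction of complexes able to respond to external
#'   ATP (models membrane orientation of the reconstituted transporter).
#' @param frac_inactive fraction of complexes that never switch.
#' @param frac_donor_only,frac_acceptor_only fractions of single-dye spots.
#' @param total_intensity mean total photon counts per frame for one molecule.
#' @param noise_sd additive per-channel Gaussian camera noise (counts).
#' @param leakage donor-to-acceptor channel crosstalk fraction.
#' @param direct_exc acceptor direct-excitation fraction under the donor laser.
#' @param bg_d,bg_a mean background level per channel (counts/frame).
#' @param bg_sd standard deviation of the reported background series (counts).
#' @param bleach_rate_d,bleach_rate_a per-second photobleaching rates.
#' @param frame_time frame integration time (s).
#' @param n_frames_red_head,n_frames_green,n_frames_red_tail ALEX layout in
#'   frames; defaults 25/450/25 give 5 s + 90 s + 5 s at 200 ms frames.
#' @param pre_equilibrated logical; if `TRUE` the hidden state at the start of
#'   the recording is drawn from the stationary distribution of the two-state
#'   chain (ATP present before the movie), otherwise every molecule starts
#'   associated.
#'
#' @return An object of class `kinetic_scenario` (a validated list).
#' @seealso [simulate_state_path()], [render_trace()], [simulate_traces()]
#' @export
kinetic_scenario <- function(k_assoc = 0.05, k_diss_max = 0.125, K_atp = 380,
                             atp = 10000, E_assoc = 0.60, E_diss = 0.08,
                             frac_responsive = 0.5, frac_inactive = 0.2,
                             frac_donor_only = 0, frac_acceptor_only = 0,
                             total_intensity = 1000, noise_sd = 100,
                             leakage = 0.08, direct_exc = 0.05,
                             bg_d = 100, bg_a = 100, bg_sd = 2,
                             bleach_rate_d = 0, bleach_rate_a = 0,
                             frame_time = 0.2,
                             n_frames_red_head = 25L, n_frames_green = 450L,
                             n_frames_red_tail = 25L,
                             pre_equilibrated = TRUE) {
  sc <- list(
    k_assoc = k_assoc, k_diss_max = k_diss_max, K_atp = K_atp, atp = atp,
    E_assoc = E_assoc, E_diss = E_diss,
    frac_responsive = frac_responsive, frac_inactive = frac_inactive,
    frac_donor_only = frac_donor_only, frac_acceptor_only = frac_acceptor_only,
    total_intensity = total_intensity, noise_sd = noise_sd,
    leakage = leakage, direct_exc = direct_exc,
    bg_d = bg_d, bg_a = bg_a, bg_sd = bg_sd,
    bleach_rate_d = bleach_rate_d, bleach_rate_a = bleach_rate_a,
    frame_time = frame_time,
    n_frames_red_head = as.integer(n_frames_red_head),
    n_frames_green = as.integer(n_frames_green),
    n_frames_red_tail = as.integer(n_frames_red_tail),
    pre_equilibrated = isTRUE(pre_equilibrated)
  )
  class(sc) <- "kinetic_scenario"
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  rates <- c(sc$k_assoc, sc$k_diss_max, sc$K_atp, sc$atp,
             sc$bleach_rate_d, sc$bleach_rate_a)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates and concentrations must be finite and >= 0")
  if (sc$E_assoc < 0 || sc$E_assoc > 1 || sc$E_diss < 0 || sc$E_diss > 1)
    stop("FRET efficiencies must lie in [0, 1]")
  fr <- c(sc$frac_responsive, sc$frac_inactive,
          sc$frac_donor_only, sc$frac_acceptor_only)
  if (any(fr < 0) || any(fr > 1))
    stop("fractions must lie in [0, 1]")
  if (sc$frac_donor_only + sc$frac_acceptor_only > 1)
    stop("frac_donor_only + frac_acceptor_only must be <= 1")
  if (sc$noise_sd < 0 || sc$bg_sd < 0 || sc$total_intensity <= 0)
    stop("intensities must be positive, noise SDs non-negative")
  if (sc$leakage < 0 || sc$direct_exc < 0)
    stop("leakage and direct_exc must be >= 0")
  if (sc$frame_time <= 0) stop("frame_time must be > 0")
  nf <- c(sc$n_frames_red_head, sc$n_frames_green, sc$n_frames_red_tail)
  if (any(nf <= 0)) stop("frame counts must be > 0")
  sc
}

#' Effective ATP-dependent dissociation rate
#'
#' `k_diss = k_diss_max * atp / (K_atp + atp)`; zero at zero ATP and half the
#' maximal rate at `atp = K_atp`.
#'
#' @param scenario a [kinetic_scenario()].
#' @param atp optional ATP concentration (uM) overriding the scenario's.
#' @return dissociation rate (s^-1).
#' @export
k_diss_at <- function(scenario, atp = scenario$atp) {
  if (atp < 0) stop("atp must be >= 0")
  if (atp == 0) return(0)
  scenario$k_diss_max * atp / (scenario$K_atp + atp)
}

#' @export
print.kinetic_scenario <- function(x, ...) {
  cat("Two-state smFRET kinetic scenario\n")
  cat(sprintf("  k_assoc = %g /s, k_diss(ATP = %g uM) = %g /s (max %g, K_atp %g uM)\n",
              x$k_assoc, x$atp, k_diss_at(x), x$k_diss_max, x$K_atp))
  cat(sprintf("  E: associated %.2f / dissociated %.2f\n", x$E_assoc, x$E_diss))
  cat(sprintf("  layout: %d + %d + %d frames at %g s\n",
              x$n_frames_red_head, x$n_frames_green, x$n_frames_red_tail,
              x$frame_time))
  invisible(x)
}
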