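#' Förster relation between FRET efficiency and fluorophore distance
#'
#' `E = 1 / (1 + (r / R0)^6)` where `R0` is the Förster radius (the
#' distance giving 0.5 efficiency; 51 Å for the Alexa Fluor 555/647 pair).
#' The inversion is exact: `r = R0 * ((1 - E) / E)^(1/6)`.
#'
#' @param r inter-fluorophore distance (Å).
#' @param R0 Förster radius (Å).
#' @return `fret_from_distance`: efficiency in (0, 1);
#'   `distance_from_fret`: distance in Å.
#' @export
fret_from_distance <- function(r, R0 = 51) {
  if (any(R0 <= 0) || any(r < 0)) stop("R0 must be > 0 and r >= 0")
  1 / (1 + (r / R0)^6)
}

#' @rdname fret_from_distance
#' @param E FRET efficiency, strictly inside (0, 1).
#' @export
distance_from_fret <- function(E, R0 = 51) {
  if (any(E <= 0) || any(E >= 1)) stop("E must lie strictly in (0, 1)")
  if (any(R0 <= 0)) stop("R0 must be > 0")
  R0 * ((1 - E) / E)^(1 / 6)
}

#' C-alpha distance between two residues of a PDB structure
#'
#' Euclidean distance between the C-alpha atoms of two residues given as
#' `"chain:resno"`. The first model is used and, when alternate locations
#' are present, altloc `A` is preferred. Missing residues or atoms give an
#' explicit error naming the selection.
#'
#' @param pdb_file path to a PDB-format file.
#' @param sel_a,sel_b residue selections, e.g. `"A:77"`.
#' @return distance in Å.
#' @export
calpha_distance <- function(pdb_file, sel_a, sel_b) {
  pdb <- bio3d::read.pdb(pdb_file, verbose = FALSE)
  get_ca <- function(sel) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("selection must be 'chain:resno': ", sel)
    ch <- parts[1]; resno <- as.integer(parts[2])
    a <- pdb$atom
    hit <- a$chain == ch & a$resno == resno & a$elety == "CA" &
      (is.na(a$alt) | a$alt %in% c("", "A"))
    if (!any(hit))
      stop(sprintf("no C-alpha atom for %s:%d in %s", ch, resno, pdb_file))
    as.numeric(a[which(hit)[1], c("x", "y", "z")])
  }
  xa <- get_ca(sel_a); xb <- get_ca(sel_b)
  sqrt(sum((xa - xb)^2))
}

#' Modified Gompertz growth-curve fit
#'
#' Least-squares fit of the Zwietering reparameterization
#' `y = A * exp(-exp(mu_m * e / A * (lambda - t) + 1))` with asymptote `A`,
#' maximum specific growth rate `mu_m` (per hour) and lag time `lambda`
#' (hours). Starting values are taken from the data (asymptote from the
#' plateau, `mu_m` from the steepest finite-difference slope, `lambda` from
#' its intercept) with a small multi-start grid on `lambda` for robustness.
#' Flat or monotonically decreasing curves return a `"no_growth"` flag
#' instead of a fit.
#'
#' @param time time points (h), strictly increasing.
#' @param y growth readout (e.g. baseline-subtracted OD600).
#' @return object of class `gompertz_fit`: list with `A`, `mu_m`, `lambda`,
#'   `se` (named vector), `sse`, `flag` (`"ok"`/`"no_growth"`), `fitted`.
#' @export
fit_gompertz <- function(time, y) {
  stopifnot(length(time) == length(y), length(y) >= 10)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  rng <- max(y) - min(y)
  slopes <- diff(y) / diff(time)
  if (rng <= 0 || max(slopes) <= 0 || stats::cor(time, y) <= 0) {
    return(structure(list(A = NA_real_, mu_m = NA_real_, lambda = NA_real_,
                          se = NULL, sse = NA_real_, flag = "no_growth",
                          fitted = NULL), class = "gompertz_fit"))
  }
  A0 <- max(y)
  i_max <- which.max(slopes)
  mu0 <- max(slopes)
  t_mid <- (time[i_max] + time[i_max + 1]) / 2
  lam0 <- max(t_mid - y[i_max] / mu0, 0)
  span <- max(time) - min(time)
  best <- NULL
  for (lam_try in unique(c(lam0, 0, span * c(0.25, 0.5)))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-exp(mu_m * exp(1) / A * (lambda - time) + 1)),
        data = data.frame(time = time, y = y),
        start = list(A = A0, mu_m = mu0, lambda = lam_try),
        lower = c(1e-9, 1e-9, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    return(structure(list(A = NA_real_, mu_m = NA_real_, lambda = NA_real_,
                          se = NULL, sse = NA_real_, flag = "no_growth",
                          fitted = NULL), class = "gompertz_fit"))
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  structure(list(A = cf[["A"]], mu_m = cf[["mu_m"]], lambda = cf[["lambda"]],
                 se = se, sse = best$sse, flag = "ok",
                 fitted = stats::fitted(best$fit)),
            class = "gompertz_fit")
}

#' Optical pathlength of a microplate well from near-infrared absorbance
#'
#' Water absorbs at 977 nm but not at 900 nm; the pathlength in cm is
#' `(A977 - A900) / 0.18`.
#'
#' @param A977,A900 absorbance readings of the well.
#' @return pathlength (cm).
#' @export
pathlength_from_absorbance <- function(A977, A900) {
  (A977 - A900) / 0.18
}

#' ATPase turnover from a coupled-enzyme NADH absorbance assay
#'
#' NADH oxidation (one NADH per ATP regenerated) is monitored as the
#' decrease of A340. The NADH consumption rate is
#' `-slope / (epsilon * pathlength)` in µM/s with the NADH extinction
#' coefficient `epsilon = 6.22e-3` per µM per cm (i.e. 6.22 per mM per cm);
#' multiplied by the assay volume this gives pmol ATP/s, and division by the
#' protein amount and the fraction of active (correctly oriented) protein
#' gives the per-complex turnover.
#'
#' @param time_s time points (s) of the A340 series.
#' @param a340 absorbance values.
#' @param pathlength_cm optical pathlength (cm), e.g. from
#'   [pathlength_from_absorbance()].
#' @param protein_pmol amount of transporter in the well (pmol).
#' @param volume_ul assay volume (µL).
#' @param orientation fraction of protein oriented with accessible ATPase
#'   sites (0.5 for a random membrane reconstitution).
#' @param window optional length-2 time window (s) restricting the linear
#'   regime used for the slope.
#' @param epsilon extinction coefficient (per µM per cm).
#' @return list with `turnover` (ATP/s per complex), `rate_um_s` (µM NADH/s),
#'   `slope` (A/s), `flag` (`"ok"`/`"no_activity"`).
#' @export
atpase_turnover <- function(time_s, a340, pathlength_cm, protein_pmol,
                            volume_ul, orientation = 0.5, window = NULL,
                            epsilon = 6.22e-3) {
  stopifnot(length(time_s) == length(a340), pathlength_cm > 0,
            protein_pmol > 0, volume_ul > 0, orientation > 0)
  if (!is.null(window)) {
    keep <- time_s >= window[1] & time_s <= window[2]
    time_s <- time_s[keep]; a340 <- a340[keep]
  }
  slope <- unname(stats::coef(stats::lm(a340 ~ time_s))[2])
  if (slope >= 0) {
    return(list(turnover = 0, rate_um_s = 0, slope = slope,
                flag = "no_activity"))
  }
  rate_um_s <- -slope / (epsilon * pathlength_cm)
  rate_pmol_s <- rate_um_s * volume_ul  # µM * µL = pmol
  list(turnover = rate_pmol_s / (protein_pmol * orientation),
       rate_um_s = rate_um_s, slope = slope, flag = "ok")
}
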