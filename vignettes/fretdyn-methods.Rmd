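---
title: "Models and methods behind fretdyn"
author: "fretdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretdyn)
```

# The experiment this package models

Energy-coupling factor (ECF) transporters import vitamins into bacteria
with an unusual mechanism: the substrate-binding membrane subunit
(S-component) is thought to dissociate from the ATPase-containing ECF
module and re-associate with it during the transport cycle. A
single-molecule FRET sensor reports on this directly: one fluorophore on
the ECF module and one on the S-component give high FRET efficiency
(about 0.60 for the C-terminal sensor) while the complex is assembled, and
an efficiency close to zero (about 0.08) once the S-component has diffused
away in the liposomal membrane. Surface-immobilized proteoliposomes are
imaged on a dual-view TIRF microscope at 200 ms frames for 100 s, with the
first and last 5 s under direct acceptor excitation (red segments) so that
traces with exactly one live donor and one live acceptor can be selected.
In solution, the same sensors are screened by confocal microscopy with
pulsed interleaved excitation and burst analysis.

`fretdyn` implements the full analysis chain for such experiments — and a
forward simulator with known ground truth, so that every stage of the
chain can be validated by parameter recovery rather than by eye.

# The generative model

`kinetic_scenario()` collects the parameters. The hidden dynamics is a
two-state continuous-time Markov chain: dissociation (high-to-low FRET)
at rate $k_\mathrm{diss}$, association at rate $k_\mathrm{assoc}$.
ATP drives dissociation through a single-site rectangular hyperbola,

$$k_\mathrm{diss}([\mathrm{ATP}]) = k_\mathrm{diss}^{\max}
  \frac{[\mathrm{ATP}]}{K_\mathrm{ATP} + [\mathrm{ATP}]},$$

with Hill coefficient fixed at 1; association is ATP-independent. This is
the simplest generative form consistent with strictly ATP-hydrolysis-
dependent dissociation. At zero ATP the associated state is absorbing.

Default rates are $k_\mathrm{assoc} = 0.05\,\mathrm{s^{-1}}$ and
$k_\mathrm{diss}^{\max} = 0.125\,\mathrm{s^{-1}}$, i.e. mean dwells of
20 s dissociated and 8 s associated at saturating ATP, the scale of the
dwell times the TIRF experiment resolves; $K_\mathrm{ATP}$ defaults to
380 µM, the scale of the apparent ATP half-saturation seen both in
single-molecule dose-response readouts and in bulk transport. Only a
`frac_responsive` fraction of complexes (default 0.5) responds to
externally added ATP, modeling the two membrane orientations of a
reconstituted transporter; a `frac_inactive` fraction (default 0.2) never
switches.

Rendering (`render_trace()`) converts a hidden path into camera counts.
A frame containing a transition gets the occupancy-weighted mean of the
two state efficiencies (sub-frame averaging). Crosstalk adds
`leakage * I_D` to the acceptor channel, direct excitation adds a
constant proportional to the acceptor-excitation intensity, backgrounds
are constant-mean Gaussian series, and camera noise is additive Gaussian
per channel — an EMCCD abstraction chosen deliberately, because no stage
of the analysis uses photon-counting statistics of TIRF frames. The
default total intensity of 1000 counts/frame with `noise_sd = 100` gives
a per-channel signal-to-noise ratio of about 5. Photobleaching is
single-step and irreversible per dye; blinking is not modeled (the
recording buffer of the experiment contains an anti-blinking agent; this
remains a documented simplification). Every simulation entry point takes
an explicit seed and leaves no global random state behind.

What the simulator does *not* emulate — slow focus or intensity drift,
liposome geometry, spectral bleed-through beyond a single leakage
coefficient, anisotropy effects, fast (sub-frame) dynamics — bounds what
green tests mean: they validate the estimators against the stated model,
not against every pathology of real recordings.

# The trace-processing chain

Processing follows the order: 3-frame running median on the signal
channels and 7-frame on the background series (edges shrink); background
subtraction; crosstalk correction; direct-excitation correction using the
trace's own mean red-segment acceptor intensity (the red segments exist
precisely to quantify the acceptor); efficiency computation
$E = I_A' / (\gamma I_D' + I_A')$ with $\gamma = 1$ throughout, so
reported efficiencies are proximity-ratio style. Correction factors are
estimated from donor-only and acceptor-only calibration populations
(medians of per-trace ratios). On noiseless synthetic input the
render-correct round trip reproduces the state efficiency to better than
$10^{-10}$, which is the package's guard against sign or ordering
mistakes in the corrections.

Single-pair selection uses the first and last 10 s of the recording: the
red-segment acceptor level must sit inside a single-dye window at both
ends (acceptor present, unbleached, not multiple) and the
background-subtracted total green intensity must sit inside a single-pair
window at both ends (single donor, no donor bleach). The numeric windows
of the original instrument are not transferable, so
`estimate_selection_criteria()` derives them as mean ± 2.5 SD of a clean
calibration population, computed on the *same short-window statistic* the
verdicts use — a window estimated from whole-trace means would be
systematically too narrow, because short windows retain camera noise that
whole-trace averages suppress.

## Chung-Kennedy filtering

`chung_kennedy()` implements the two-predictor edge-preserving filter
with the experiment's parameters $K = M = 10$, $p = 1$: each point is a
blend of the mean of the preceding $K$ points and the mean of the
following $K$ points, weighted by the inverse $p$-th power of each
predictor's summed squared prediction error over a comparison window of
$M$ points (past errors for the forward predictor, future errors for the
backward one). At a step edge the predictor straddling the edge
accumulates a large error and loses essentially all weight, so noiseless
steps pass through unchanged while stationary noise is averaged down more
than 2.5-fold. A variance floor of $10^{-12}$ keeps the weights finite on
noiseless segments. The filter is the identity on constants and
idempotent on noiseless piecewise-constant input; the suite verifies it
against an independent loop re-implementation.

# Classifying dynamic and static traces

The classifier statistic is the donor-acceptor covariance normalized by
the squared mean total intensity,

$$c = \frac{\tfrac1N \sum_t (I_D(t) - \langle I_D\rangle)
  (I_A(t) - \langle I_A\rangle)}{\langle I_D + I_A\rangle^2},$$

computed on corrected, Chung-Kennedy-filtered green-segment intensities.
Among the normalizations compatible with the idea of "correlation
normalized by the squared average total intensity", this one was chosen
because it is invariant under a common rescaling of both channels, which
is what makes one fixed threshold transferable across traces of different
brightness. A trace is dynamic when $c < -0.01$ strictly (ties are
static); non-dynamic traces split into static-high and static-low at a
median filtered efficiency of 0.4. For a trace spending a fraction $f$ in
one state, $c \approx -f(1-f)\,\Delta E^2$, so with $\Delta E = 0.52$ the
$-0.01$ threshold resolves transitions that keep at least about 4% of the
trace on each side — single transitions very close to either end of the
recording are the intrinsic false negatives of this statistic, and noise
anti-correlation its rare false positives. On the labeled benchmark
(30% static-high, 20% static-low, 50% dynamic with 1-5 transitions,
per-channel SNR 5) the classifier agrees with ground truth for about 98%
of traces, comfortably above the 90% concordance reported for manual
annotation of such data.

Pooled, frame-level filtered efficiencies form frequency histograms with
a fixed 0.04 bin width on $[-0.2, 1.2]$ — wider than $[0,1]$ so corrected
excursions remain visible. Two readouts summarize the dissociated vs
associated balance: `peak_ratio()` fits a two-Gaussian mixture (centers
initialized at 0.08 and 0.60, bounded to ±0.1) and returns the amplitude
ratio, matching the "peak-to-peak" convention; `occupancy_ratio()` simply
counts frames on either side of the state midpoint. The latter is the
readout used for dose-response fitting here, for two reasons: its
sampling noise is far smaller when one population is weak, and under the
generative model the dissociated:associated occupancy ratio is *exactly*
hyperbolic in ATP with half-saturation at $K_\mathrm{ATP}$, whereas the
fraction-of-dynamic-traces readout saturates once
$k_\mathrm{diss} T \gg 1$ (nearly every responsive trace shows at least
one transition) and therefore carries no usable dose scale at these
rates. Parameter-recovery benchmarks for the EC50 machinery accordingly
simulate with responsive fraction 1 and inactive fraction 0, isolating
the kinetics from the composition nuisance parameters.

# Dwell times and kinetics

## Change-point detection

Step finding uses recursive binary segmentation: within each segment the
split maximizing the two-sample $t$ statistic is accepted if its p-value
is below `alpha` and both halves span at least `min_dwell = 3` frames.
Segment means are then collapsed onto two states (split at the mid-range
of the segment means, with the two clusters kept only if their centers
are at least 0.2 efficiency units apart) and adjacent same-state segments
are merged; transitions are the surviving state boundaries. The merge
step is the false-positive control: over-segmentation of noise produces
same-state fragments that vanish on merging, so the measured false
transition rate on static traces is below 1% even at permissive `alpha`.

Two deliberate choices depart from a naive reading of "detect transitions
on the filtered trace with a stringent test", both driven by parameter
recovery on synthetic ground truth:

* **Detection runs on the median-prefiltered, corrected efficiency, not
  the Chung-Kennedy-filtered series.** The CK filter's 10-frame windows
  attenuate dwells shorter than the window; detecting on the filtered
  series loses a substantial fraction of 3-8-frame dwells, and each
  missed dwell merges its two neighbours into one spuriously long dwell,
  biasing rate estimates by 20-40%. The filtered series remains the
  classifier input and display trace.
* **The dwell pipeline over-segments at `alpha = 0.05`.** Binary
  segmentation is insensitive to short excursions in the middle of long
  segments (a brief dwell barely moves any single split's $t$
  statistic); a permissive threshold recovers those splits and the
  two-state merge removes the spurious ones. `detect_transitions()`
  itself defaults to the stringent `alpha = 0.001` for generic use.

Segment means used for state assignment drop one boundary frame per side
(when a segment has at least three frames), because camera integration
and the median prefilter smear transition frames toward intermediate
values and would pull short segments toward their neighbours.

## Censoring-aware dwell fitting

Only interior dwells — bounded by detected transitions on both sides —
have known durations; the first and last dwell of each trace are
censored and enter diagnostics only. Even interior dwells are biased:
a dwell of length $x$ is observable only if it starts early enough to
finish inside the recording of length $T$, so the observed density is
proportional to $(T - x)\,e^{-x/\tau}$ on
$[t_\mathrm{min}, T]$, with $t_\mathrm{min}$ the shortest resolvable
dwell (`min_dwell` frames). `fit_exponential_dwells(method = "window")`
maximizes exactly this likelihood; the plain doubly-truncated exponential
and the naive sample mean are retained as `"truncated"` and `"naive"`.
At $\tau = 20$ s in a 90 s window the naive mean underestimates $\tau$ by
roughly 25% while the window-corrected MLE is unbiased to within a few
percent — this ordering (correction strictly reduces bias at
$\tau = 4, 8, 20$ s) is an acceptance property of the package. The
residual few-percent bias of the full pipeline comes from genuinely
unresolvable dwells (shorter than 3 frames) whose loss concatenates their
neighbours; this floor is documented rather than corrected.

A subtlety worth recording: excluding the censored first and last dwells
is a robustness measure, not a bias fix, in the Markov world. By
memorylessness, the age and residual-life dwells at the window edges are
themselves exponential samples, so at short $\tau$ their inclusion would
not bias a mean dwell estimate; exclusion genuinely matters once window
truncation dominates (dwells comparable to the 90 s window) and whenever
real dwells deviate from exponentiality.

End to end, `estimate_rates()` (600 traces, 90 s green window) recovers
generating rate pairs in the range 0.05-0.125 s$^{-1}$ within 15%
relative error in the large majority of runs.

## First-event survival and rate comparison

`first_event_analysis()` takes per-trace times of the first dissociation
after ATP arrival, builds the fraction-without-event curve, and fits a
one-phase exponential decay by the censored maximum-likelihood estimator
$\hat\lambda = d / (\sum_i t_i + n_\mathrm{cens} T)$ — traces without an
event are right-censored at the window end rather than discarded, which
the suite cross-checks against an exponential survival regression.
`compare_decay_rates()` compares two fitted rates with a two-tailed
unpaired $t$ statistic on the fit standard errors and Welch-Satterthwaite
degrees of freedom.

## Dose-response

`fit_ec50()` fits $y = \mathrm{floor} + (\mathrm{ceiling} -
\mathrm{floor})\,x / (EC_{50} + x)$. Given $EC_{50}$ the model is linear
in floor and ceiling, so the fit profiles $EC_{50}$ on a log grid with an
exact linear sub-fit at each candidate — deterministic, free of starting
values, exact on noiseless hyperbolas, and equivariant under rescaling
the dose units — and returns a profile-likelihood interval from the F
threshold. The Hill coefficient is fixed at 1 to match the generative
model; flat readouts are flagged `no_dose_dependence` with an unbounded
interval.

## Between-condition statistics

Replicate experiments are summarized by `dynamic_fraction()`: percentages
weighted by traces per experiment, with the frequency-weight convention
(denominator $\sum n_i - 1$) for the weighted SD; a single experiment
reports an undefined SD rather than zero. `welch_anova_tukey()` computes
Welch's heteroscedastic F (right-tailed) from group summaries — verified
to machine precision against `oneway.test()` — and Games-Howell pairwise
comparisons on the studentized-range distribution with Welch per-pair
error terms (for two groups this reduces exactly to Welch's $t$ test).
Its empirical size under equal-means simulation is close to the nominal
5%.

# Confocal burst analysis

Background rates are estimated per 30 s window and detection stream from
inter-photon delays above the mean delay (a shifted-exponential MLE;
sparse windows carry the previous rate with a flag). The all-photon
sliding-window search marks a photon as in-burst when $m = 10$
consecutive photons arrive at more than $F = 6$ times the local
background rate; maximal runs form bursts. Burst efficiency and
stoichiometry use the standard additive corrections
($E = (n_{DA} - lk\,n_{DD} - dir\,n_{AA}) / (\cdot + n_{DD})$), with $lk$
and $dir$ estimated from the donor-only ($S > 0.9$) and acceptor-only
($S < 0.1$) sub-populations of the same acquisition; $\gamma$ and $\beta$
corrections are intentionally omitted, so burst efficiencies are
corrected proximity ratios. Bursts need at least 40 photons (acceptor-
excitation photons included) and stoichiometry in $[0.25, 0.85]$ to enter
the 0.04-bin efficiency histogram. A long pure-background stream yields
zero bursts after the 40-photon selection; the raw sliding-window search
has a small per-window false-positive probability (about $3\times10^{-5}$
per photon at the defaults), which is why the size selection, not the
search, defines "no bursts". Photon streams are exchanged as 3-column
delimited text (timestamp, detector, excitation period).

# Auxiliary calculations

The Förster relation $E = 1/(1 + (r/R_0)^6)$ and its exact inversion use
$R_0 = 51$ Å for the Alexa Fluor 555/647 pair; with the H-sensor marker
residues 34 Å apart in the assembled complex, the predicted efficiency is
comfortably above 0.5, consistent with the high-FRET assembled state.
`calpha_distance()` reads PDB text (first model, altloc A preferred) and
names the offending selection on errors. Growth lags use the Zwietering
modified-Gompertz parameterization
$y = A \exp(-\exp(\mu_m e / A\,(\lambda - t) + 1))$ with data-driven
starts and a small multi-start grid on $\lambda$. ATPase turnover inverts
the coupled-assay arithmetic: NADH consumption from the A340 slope via
Beer-Lambert (extinction 6.22 per mM per cm, i.e. $6.22\times10^{-3}$
per µM per cm), microplate pathlength from $(A_{977} - A_{900})/0.18$,
and a 50% orientation correction for randomly reconstituted protein.

# Numerical conventions and problem sizes

Seeds are explicit everywhere; identical scenario and seed give
bit-identical output. Efficiencies are clamped to $[-0.2, 1.2]$ for
reporting; zero-total frames give `NA` with a flag rather than an error;
degenerate dwell sets (all equal) are flagged non-exponential; absent
histogram populations give ratio 0 or `Inf` with a flag. The validation
suite runs at deliberately modest scales — 500-trace classifier
benchmarks, 600-trace rate-recovery runs, 150 traces per dose level,
a few hundred bursts per stream — chosen so each property is tested with
enough statistics to be meaningful while the whole suite stays quick to
run on a laptop.

# Known limitations

* Two states only; no intermediate-FRET species, no multi-exponential
  dwell mixtures, no hidden-Markov inference.
* No blinking, spectral drift, or frame-level photon statistics in the
  simulator; $\gamma$ is fixed at 1 (exposed in the correction factors
  for generality).
* Binary segmentation resolves dwells of 3 frames and longer; faster
  dynamics alias into apparent static traces or longer dwells, exactly
  as in the real experiment at a 200 ms frame time.
* Channel registration, flat-field and camera-offset corrections are
  upstream of this package: image stacks are assumed aligned with a known
  integer channel offset.
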