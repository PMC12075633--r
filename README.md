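# fretdyn

Single-molecule FRET analysis of ATP-driven association/dissociation
dynamics in membrane transporter complexes.

Energy-coupling factor (ECF) transporters are bacterial ABC importers in
which the substrate-binding membrane subunit (the S-component) is thought
to dissociate from the ATPase-containing ECF module and re-associate with
it during each transport cycle. With one fluorophore on the module and one
on the S-component, an assembled complex shows high FRET efficiency
(E ≈ 0.60) and a dissociated one shows E ≈ 0.08, so TIRF recordings of
single liposome-reconstituted complexes (200 ms frames, 90 s under donor
excitation flanked by 5 s of direct acceptor excitation) turn the
mechanistic question into a trace-analysis problem. `fretdyn` is written
for researchers analyzing such recordings — and for anyone who wants to
validate each stage of that analysis against simulations with known
ground truth.

The package covers, as composable functions:

* **Forward simulation** — two-state continuous-time Markov switching with
  ATP-dependent dissociation `k_diss = k_max·[ATP]/(K_ATP + [ATP])`,
  membrane-orientation and inactive fractions, single-dye spots,
  crosstalk, direct excitation, background, camera noise, photobleaching,
  and the alternating-excitation frame layout; plus dual-view image
  stacks and confocal photon streams with burst ground truth.
* **Trace processing** — 3/7-frame median prefilters, background
  subtraction, crosstalk and direct-excitation correction, single-pair
  selection from the red segments and intensity windows, and
  Chung–Kennedy edge-preserving filtering (K = M = 10, p = 1).
* **Classification** — the anticorrelation statistic
  `c = cov(I_D, I_A)/⟨I_D+I_A⟩²` with the −0.01 dynamic threshold and the
  0.4 median-E static split; 0.04-bin efficiency histograms, two-Gaussian
  peak ratios, occupancy ratios, and weighted dynamic-trace fractions.
* **Kinetics** — change-point detection (binary segmentation with a
  deterministic two-state merge), interior-dwell harvesting with
  first/last-dwell censoring, window-corrected truncated-exponential
  maximum-likelihood dwell fits, time-to-first-dissociation survival
  analysis with right censoring, hyperbolic EC50 dose–response fits with
  profile-likelihood intervals, and Welch ANOVA + Games–Howell pairwise
  tests from weighted group summaries.
* **Confocal bursts** — 30 s-windowed background estimation, the
  all-photon m = 10 / F = 6 sliding-window burst search, ALEX corrections,
  the ≥ 40-photon and stoichiometry 0.25–0.85 selection, and burst-E
  histograms.
* **Auxiliary calculations** — Förster relation (R₀ = 51 Å),
  Cα–Cα distances from PDB files, modified-Gompertz growth-lag fits, and
  coupled-assay ATPase turnover with the (A977−A900)/0.18 pathlength and
  50 % orientation corrections.

## Worked example

Simulate one recording condition (10 mM ATP outside), run the full chain,
and estimate the kinetics:

```r
library(fretdyn)

sc <- kinetic_scenario(atp = 10000)   # 10 mM ATP
sc
#> Two-state smFRET kinetic scenario
#>   k_assoc = 0.05 /s, k_diss(ATP = 10000 uM) = 0.120424 /s (max 0.125, K_atp 380 uM)
#>   E: associated 0.60 / dissociated 0.08
#>   layout: 25 + 450 + 25 frames at 0.2 s

sim   <- simulate_traces(sc, n = 300, seed = 42, condition = "ATP_out")
cf    <- correction_factors(lk = 0.08, dir = 0.05)
procs <- process_traces(sim$traces, cf)
cls   <- classify_traces(procs)
table(cls$label)
#>     dynamic static_high  static_low
#>         129         165           6

res <- estimate_rates(sim$traces, cf)
res$fits$associated
#> Exponential dwell fit (window): tau = 8.73 s (se 0.52), n = 360
res$fits$dissociated
#> Exponential dwell fit (window): tau = 21.6 s (se 1.9), n = 301
```

43 % of traces are dynamic: with half of the complexes oriented away from
the added ATP and a fifth inactive, the simulation's responsive, active
complexes essentially all switch during 90 s at saturating ATP. The mean
associated dwell of 8.7 ± 0.5 s corresponds to an estimated dissociation
rate of 0.115 s⁻¹ against a generating rate of 0.120 s⁻¹, and the
dissociated dwell of 21.6 ± 1.9 s to an association rate of 0.046 s⁻¹
against 0.050 s⁻¹ — interior dwells only, with the fit correcting for the
finite 90 s observation window (a naive dwell mean would underestimate
the 20 s dwell by roughly a quarter). The pooled efficiency histogram of
the same run has its dissociated and associated peaks at 0.08 and 0.60
with an amplitude ratio of 0.38:

```r
h <- efficiency_histogram(procs, condition = "ATP_out")
peak_ratio(h)$ratio
#> [1] 0.38
```

The methods vignette (`vignettes/fretdyn-methods.Rmd`) explains the
models, the estimators, every tunable default, and the design decisions.

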