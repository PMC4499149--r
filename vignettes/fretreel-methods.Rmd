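---
title: "Models and methods behind fretreel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretreel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretreel)
```

# The system and the measurement

A partial-duplex DNA construct is immobilized with a donor/acceptor FRET
pair reporting the end-to-end compaction of a 5' single-stranded overhang.
A RecQ-family helicase (the package's presets are modeled on core BLM
acting on human telomeric G-quadruplex, GQ, constructs) binds near the
ss/dsDNA junction and, with ATP, *reels in* the overhang: the apparent FRET
efficiency `E = I_A / (I_A + I_D)` rises from a construct-specific baseline
to a high plateau. If the overhang carries a GQ behind a poly-T spacer, the
enzyme arriving at the folded GQ either unfolds it — seen as a dip from the
high level and a recovery when the GQ refolds or the freed strand is reeled
in — or fails, releasing the DNA or dissociating. Dip-and-rise cycles
repeat a few times per binding event before the enzyme lets go.

The analysis pipeline turns two-channel intensity traces into:

* **event rates** — events counted per second of total observation time,
  including traces with no events — as a function of the titrated
  co-factor (helicase or ATP), fitted with a Langmuir binding isotherm
  `y = A c / (c + K_eq)`;
* **dwell times** — reeling time (rise), waiting time (high plateau), and
  the unfolding transition time Δt_uf (top-to-bottom drop of a dip) — read
  from Gaussian fits to dwell histograms;
* **success fractions** — the ratio of fitted saturation amplitudes of a
  GQ construct and a GQ-free reference, which estimates the probability
  that a reeling attempt unfolds the GQ;
* **spot-count survival** — for the duplex-capped construct, the fraction
  of donor spots remaining over time after unwinding releases the labeled
  strand.

# The stochastic state model

`simulate_state_path()` draws a continuous-time path through

```
UNBOUND -> BOUND -> REELING -> WAITING_AT_JUNCTION
                                  |--(p_unfold)--> UNFOLDING_COLLAPSE ->
                                  |        UNFOLDED -> POST_UNFOLD_REELING
                                  |                      -> WAITING ...
                                  '--(otherwise)--> RELEASED
```

with dissociation checked after every unfold/refold cycle
(`dissociation_prob_per_cycle`, geometric cycle counts).

**Event initiation.** Arrivals follow a Poisson process *in wall time* at
the Langmuir rate `A c / (c + K_eq)`; an arrival landing while the DNA is
occupied binds as soon as the molecule is free. This phenomenological
choice — rather than explicit on/off binding kinetics — makes the realized
event count per unit observation time equal the isotherm value, which is
exactly the quantity the event-rate estimator measures; explicit binding
kinetics would add parameters the event-rate data cannot identify.

**Dwell-time defaults** (chosen once; all overridable through
`kinetic_params()`):

| parameter | default | why |
|---|---|---|
| `bind_dwell_mean` | 0.15 s | brief pre-rise bound state, matching the short binding dip visible before rises |
| `reel_velocity_max`, `reel_K_ATP` | 100 nt/s, 10 uM | gives sub-second reeling of 30-50 nt spacers at tens of uM ATP, the published reeling-time scale |
| `release_rate` | 3 /s | waiting times of a few tenths of a second |
| `unfold_collapse_time` | 0.18 s | center of the published 0.17-0.19 s transition-time range; the collapse is rendered as a single linear drop (no step-wise unfolding) |
| `refold_rate` | 4 /s | sub-second unfolded dwell before refolding |
| `dissociation_prob_per_cycle` | 0.3 | "a few" unfold/refold cycles per event |
| `release_relax_time` | 0.6 s | fixed dead time at baseline after release, keeping consecutive events visually separated as in published traces |

**Emission layer.** `render_trace()` maps states to mean FRET levels
(`fret_state_map()`): constant levels for baseline, bound dip, plateau and
unfolded dip; linear ramps for reeling (fraction of spacer reeled maps
linearly to FRET — monotone rises are observed, but no distance-to-FRET
calibration exists, so linearity is the minimal assumption), the collapse,
and post-unfold reeling. Mean FRET is sampled at frame midpoints, split
into donor/acceptor intensities, and given Gaussian channel noise
`sd = noise_sd_floor + shot_noise_scale * sqrt(mean)`.
`noise_floor_for_sigma()` inverts first-order error propagation so that the
rendered baseline reproduces the construct's printed histogram width.
Donor photobleaching (default 5e-4 /s) silences both channels; acceptor
bleaching is off by default because molecules without an active FRET pair
are excluded at trace selection in real pipelines and thus never reach the
analysis.

**What the generator does not emulate:** diffusing background molecules,
baseline drift and flicker, partial-reel releases mid-ramp, the slower
conformer exchange of the two folded GQ states of short-spacer constructs
(the dominant 0.62 conformer is used), or camera digitization. Passing
recovery tests therefore demonstrates correctness of the analysis under
the stated noise model, not robustness to every artifact of real data.

# Event detection

Detection reads a running-median-smoothed trace (window 3) against
construct-specific levels (`detection_config()`); dwell measurements are
refined on raw frames, honoring the two-frame timing convention
(`timing_uncertainty()`: 2 x 0.032 s = 0.064 s, reported as 0.07 s).

* **Excursions.** Candidate events are maximal runs above the baseline
  band (mean + 2 sigma of the construct's histogram peak) that persist at
  least `min_dwell_frames` (noise blips are not events); runs separated by
  less than `cluster_gap_max` are merged into one cluster. The default gap
  is 0.5 s: within-event dips rarely leave the baseline band, so the gap
  only needs to bridge few-frame dropouts, while at saturating event rates
  (0.3+/s) inter-event gaps shorter than 2 s are common and a larger
  tolerance would merge distinct events and bias rates down. Excursions
  touching the trace start, the trace end or the photobleach point are
  discarded rather than censored.
* **Completion.** An excursion qualifies as a completed reeling only if
  the smoothed trace reaches `high_threshold` (E = 0.60); lower rises that
  return to baseline are unsuccessful attempts.
* **Plateau.** The local high level is the 0.9 quantile of the smoothed
  excursion — robust to in-event dips and deliberately independent of
  `high_threshold`, which keeps the detected GQ-event count monotone in
  that threshold. Reeling time runs from the last frame at or below the
  baseline mean to entry into the plateau band (plateau - high_sigma);
  waiting time from plateau entry to the last frame in the band, i.e. the
  onset of the systematic final drop.
* **Significant dips** (GQ events): a departure below the plateau band
  lasting at least `min_dwell_frames` whose minimum reaches at least
  `dip_depth` (0.25) below the plateau, *bracketed by the high level on
  both sides* — the bracket excludes the initial reeling ramp and the
  final release from the cycle count. At least one such dip-and-rise makes
  the cluster a GQ event; its count estimates the unfold/refold cycles.
* **Unfolding dips** (short-spacer constructs): the smoothed trace must
  stay at or below the 0.35 cut-off for at least `min_dwell_frames` and
  recover above the folded band; dips bottoming in the 0.40-0.50 band are
  recorded as non-unfolding binding events and excluded from statistics.

**Transition time Δt_uf.** Measured on raw frames between the last frame
still at the folded level and the first frame at the unfolded level, where
"at a level" means within `level_tol` state standard deviations of the
state mean. `level_tol` is an estimator calibration: wide bands trigger on
mid-ramp noise and read short, while crossing the bare means waits for
half-sigma noise excursions and reads long. The default 0.25 was fixed by
simulating linear collapses of known duration (0.18 s) and choosing the
value for which the Gaussian-fitted mean of the measured times is
unbiased; the residual asymmetry of the dwell histogram keeps the Gaussian
readout about 0.005 s below the raw mean.

# Rates and fits

* `event_rate()` divides counted events by the *total* valid observation
  time — zero-event traces contribute time, never dropped. Valid time ends
  at the photobleach point found by `truncate_at_bleach()` (sustained drop
  of total intensity below half its initial median).
* `split_error()` partitions traces into three random near-equal groups
  and reports the standard deviation of the group rates.
* `fit_langmuir()` is unweighted nonlinear least squares in log-parameter
  space (positivity by construction), initialized at the maximum observed
  rate and the concentration nearest half of it; errors come from the
  Gauss-Newton curvature, mapped back by the delta method. Unweighted is
  the default because published fits state no weighting; with per-point
  counting errors the weighted option is the calibrated choice (its 3-SE
  intervals cover the truth in >= 95% of Poisson replicates). A fit is
  flagged unidentifiable when the K_eq error exceeds K_eq or K_eq escapes
  the concentration range of the design.
* `fit_gaussians()` fits one or two Gaussians to binned data by least
  squares — dwell histograms are fitted with Gaussians to follow the
  published convention, although exponential mixtures are the more usual
  kinetic model; for lattice-valued dwell samples the first bin is
  centered on the sample minimum so values sit on bin centers.
* `unfold_success_fraction()` is the amplitude ratio A_GQ / A_ref. For GQ
  constructs the simulator's amplitude parameter is the *initiation*
  (attempt) rate; the measured GQ-event amplitude is `p_unfold` times it,
  mirroring the published arithmetic 0.7 x 0.17 ≈ 0.12 /s.

# Spot-count assay

`simulate_movie()` renders immobilized Gaussian spots that disappear at an
exponential time with rate unwind + bleach (indistinguishable in one
channel; the no-ATP control isolates bleaching by subtraction).
`count_spots()` band-passes each frame (difference of Gaussians), takes
8-neighborhood local maxima above a robust MAD threshold, and deduplicates
within two PSF sigmas; `fraction_remaining()` matches first-frame
reference spots within a 2-pixel radius (spots are immobilized, so no
tracking). `fit_spot_decay()` summarizes the series with a
single-exponential-plus-floor fit; fix `floor = 0` when the generating
model has none.

# Problem sizes, reproducibility, degenerate inputs

Recovery experiments in the package's validation use 7 log-spaced
concentrations with 300 traces of 200 s per point for titrations, 600+
dips for transition times, and 300 traces for histogram peaks — matching
the scale of the published data sets (several hundred molecules per
condition). All simulation entry points take integer seeds and derive
per-concentration sub-seeds, so runs are bit-reproducible; written
artifacts (`run_titration(out_dir = ...)`) are byte-identical for a fixed
config and seed.

Degenerate inputs are handled without exceptions where a value is still
defined: zero total intensity gives an undefined FRET frame (`NA`), an
empty trace file reads as an empty collection with a warning, a flat
titration fits but is flagged unidentifiable, a delta-like histogram
reports the occupied bin directly, and a dip without a measurable
top-to-bottom bridge is excluded from transition statistics rather than
invented. A zero reeling velocity with a nonzero spacer is a parameter
error, as is a rate computed over zero observation time.

# Known limitations

* Waiting and reeling times are ATP-dependent in the data; the simulator
  makes reeling speed ATP-dependent but keeps the junction-waiting rate
  constant, so ATP trends in waiting times are not emulated.
* Unsuccessful attempts always occur at the junction (release after a
  complete rise); mid-ramp releases are not generated, though the
  detectors would classify them correctly as unsuccessful.
* The threshold detectors are deliberately not hidden-Markov inference;
  they reproduce a threshold-based analysis, and their dwell estimates
  inherit its frame-quantization floor.
* Consecutive clusters are attributed to different enzyme molecules by
  construction; no attempt is made to track molecular identity.
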