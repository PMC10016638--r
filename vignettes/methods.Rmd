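---
title: "Methods: hourly RR-segment risk classification and the POAF evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hourly RR-segment risk classification and the POAF evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hrvaf)
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which assumptions, which
constants are standards of the field, which are stand-ins for
undisclosed commercial parameters, and what a green test does and does
not establish.

## 1. The screening problem

Postoperative atrial fibrillation after bypass surgery arises in
roughly 25–40% of patients, mostly on postoperative days 1–5 with a
peak around day 2, and is preceded — often by less than a few hours —
by rising atrial ectopy and a shift of autonomic balance toward vagal
(high-frequency) modulation. Commercial Holter analyzers exploit this:
they score each one-hour RR-interval stretch into sinus rhythm
(Risk 0), elevated paroxysmal-AF risk (Risk 1), or AF present
(Risk 2), where "AF present" requires at least 30 s of sustained
fibrillatory irregularity. `hrvaf` reimplements that pipeline with an
explicit decision matrix, because the commercial coefficients are
proprietary: our thresholds are *documented stand-ins*, not a
replication.

## 2. Ingestion and preprocessing

RR series are one beat per row (`t_s`, `rr_ms`, `label`); labels follow
Holter-annotation practice (`N` sinus, `A` atrial premature, `V`
ventricular, `X` artifact, `U` unlabeled). Design choices the source
protocol leaves open:

* **Hour bins** are half-open `[3600k, 3600(k+1))` anchored at
  recording start — reproducible and overlap-free; a beat at exactly
  3600 s belongs to hour 1.
* **Artifact removal** (no rule is published; ours follows common
  Holter QC): drop `X` beats, RR outside 300–2200 ms, and RR deviating
  from the running 11-beat median of plausible neighbours by more than
  50%. An hour losing over 20% of beats is flagged unanalyzable rather
  than silently passed.
* **Analyzable hour**: at least 1800 beats. At sinus rates this is
  ~40 min of coverage; sparser hours yield unstable statistics and are
  excluded, never imputed.
* **PAC labeling** for unannotated series: a beat shorter than 0.80×
  the local 11-beat median whose successor exceeds 1.15× that median
  (premature beat plus post-extrasystolic pause). The thresholds are
  configurable; their operating characteristics are pinned by the
  generator-recovery tests (≥ 90% of injected PACs recovered, ≤ 2
  false labels per hour).

## 3. HRV descriptors

**Time domain** (linear indices) are computed over normal-to-normal
intervals only: mean NN, SDNN, RMSSD, pNN50, CV. Two conventions are
fixed so oracles match bit for bit: variances are *population*
variances, and the first interval of a series counts as NN when its
closing beat is normal (its opening beat predates the recording and is
presumed normal). Successive differences are taken only between
index-adjacent NN intervals, so an excluded ectopic beat never
manufactures a spurious jump.

**Poincaré descriptors** are computed over *all* usable pairs,
including PAC-adjacent ones — rhythm irregularity is the signal here,
whereas the time-domain block isolates sinus variability; this mirrors
the dual use of the two families in the original system. With
population variances,

* SD1² = Var(ΔRR)/2, SD2² = 2·Var(RR) − Var(ΔRR)/2 (floored at 0),
  which enforces SD1² + SD2² = 2·SDNN² identically and gives
  SD1 = RMSSD/√2 whenever the successive differences have zero mean;
* the plotted quantity is the normalized successive difference
  nᵢ = (Rᵢ − Rᵢ₊₁)/(Rᵢ + Rᵢ₊₁), strictly inside (−1, 1), antisymmetric
  under pair reversal. Its standard deviation is the **dispersion**;
  points more than 3 dispersions from the mean are **outliers**;
* **cluster count** uses one-dimensional density grouping of the
  sorted nᵢ (split at gaps > 0.025, count groups of ≥ 15 points).
  A full 2-D density clustering (DBSCAN-style) was considered and
  rejected: the Poincaré arms of ectopy are essentially
  one-dimensional in the normalized-difference coordinate, and the 1-D
  grouping is O(n log n), deterministic and dependency-free.

The visual classes are made quantitative with precedence DISPERSED →
SCATTERED → COMET: DISPERSED when dispersion ≥ 0.08 *and* lag-1
autocorrelation ≤ 0.2 (fibrillatory dispersion is serially
uncorrelated); SCATTERED when (≥ 2 clusters or ≥ 2% outliers) *and*
autocorrelation > 0.2 (ectopic arms on a correlated sinus baseline);
COMET otherwise. Note one deliberate consequence: very dense ectopy
depresses the lag-1 autocorrelation below 0.2 and such segments fall
through to COMET — they are still caught by the density and dispersion
thresholds of the risk matrix, so the pattern rule is kept as designed
rather than widened.

**Spectral powers** use the Lomb–Scargle least-squares periodogram
evaluated directly on the irregular beat times; ectopic and artifact
beats are excluded *without interpolation*, avoiding the resampling
bias of evenly-gridded estimators. Bands are the conventional
short-term HRV bands (LF 0.04–0.15 Hz, HF 0.15–0.40 Hz). Normalization
is variance-preserving: a pure modulation tone of amplitude *a* yields
band power ≈ a²/2 ms² (verified to 15% in tests, the residual being
spectral leakage at finite record length). The estimator behind the
published autonomic sub-analysis is unspecified; Lomb–Scargle on the
NN tachogram is our documented choice.

## 4. AF detection and the decision matrix

Sliding 60 s windows (10 s step) are flagged AF-like when four
conditions hold simultaneously: CV > 0.10, lag-1 autocorrelation
< 0.2, normalized-ΔRR dispersion > 0.08, and more than half of the
deltas exceed 0.04 in magnitude. The fourth condition is ours, added
after testing: a chance cluster of 2–3 PACs inside one minute can pass
the first three screens, but fibrillatory conduction makes *nearly
every* interval differ from its neighbour, which the density-of-
irregularity condition captures and ectopy does not. A beat is inside
an AF stretch when at least half the windows covering it are flagged —
this per-beat vote localizes the stretch to the irregular beats
instead of the union of 60 s windows, which is what lets a 20 s insert
fail the 30 s minimum while a 10-minute episode is recovered with
> 90% overlap. Maximal runs shorter than 30 s are discarded.

Classification precedence (the published system implies but never
states one): any reportable AF stretch ⇒ Risk 2; else SCATTERED
pattern, or PAC density ≥ 30/h, or dispersion ≥ 0.03 ⇒ Risk 1; else
Risk 0. All constants sit in `classifier_config()` with units in the
documentation. They were tuned once against the default synthetic
cohort and then frozen; they are not estimates of the commercial
coefficients.

## 5. The evaluation protocol

Cases contribute their analyzable hours from the 24 h window ending at
AF onset; the hour containing onset is excluded, so no AF contaminates
a "prediction" segment. Controls contribute postoperative day 2 (the
peak-incidence day). Open points resolved here: "first three hours"
means the first three *analyzable* hours; the group-II closing window
is the last three analyzable day-2 hours; patients with AF onset
within 6 h of monitoring start are excluded at cohort assembly;
patients with fewer than three analyzable hours in a window get an
undefined call and are excluded from that analysis — all exclusions
are enumerated in the run report. Window positivity rates pool
segments across patients (the source tables are segment-pooled); the
per-patient mean is reported alongside for transparency.

Diagnostic statistics keep full precision internally and round
half-up only at rendering. Wilson intervals (proportions) and
log-method intervals (likelihood ratios) are provided although the
reference study reports none. The reference-table verification accepts
agreement within one unit in the last printed digit: the published
tables demonstrably mix round-half-up and truncated renderings (e.g.
66/81 = 81.48% printed as 81.4, but 85/112 = 75.89% printed as 75.9),
so exact final-digit reproduction is not well-defined.

Group comparisons follow the published analysis plan: Shapiro–Wilk
normality screen at 0.05, then Welch t (both groups normal) or
Mann–Whitney; Fisher's exact when any expected cell < 5, else
chi-squared with continuity correction.

## 6. The synthetic cohort: what it emulates and what it does not

No recordings are deposited with the reference study, so the generator
*is* the data source, and its defaults are the stated world:

* **Cohort**: 114 patients, POAF prevalence 0.28 (Bernoulli), onset
  day weighted (0.20, 0.35, 0.25, 0.12, 0.08) over days 1–5 — peaked
  on day 2 — onset hour uniform; recordings span days 1–5 from 00:00
  of day 1; master seed 20230315, per-patient seeds derived as
  `(master + 7919·i) mod (2³¹−19)`.
* **Sinus rhythm**: RR generated beat-by-beat as a mean (650–950 ms
  across patients) plus LF (0.10 Hz, 15–30 ms) and HF (0.25 Hz,
  8–16 ms) modulation tones and white noise (6–12 ms), floored at
  300 ms, clock advanced by each interval. The ranges are ordinary
  resting adult HRV magnitudes, narrowed during the single calibration
  pass (below).
* **Ectopy**: PAC events as a Poisson process; each event shortens an
  interval to 0.5–0.7× the local median and stretches the next to
  1.2× (premature beat + compensatory pause). Baseline density is
  log-normal: median 23/h (σ_log = 0.5) in the POAF arm vs 8.5/h
  (σ_log = 0.6) in controls — patients who go on to fibrillate carry a
  denser ectopic substrate throughout, which is what makes hours far
  from onset informative at all (the reference data show 57% positive
  case-hours even ~1 day before onset).
* **Pre-onset ramp**: over the final 3 h before onset (matching the
  3-hour evaluation windows), PAC density rises linearly to 4× and HF
  amplitude to 2× baseline, in 15-minute piecewise-linear steps. The
  published sub-analysis reports the *direction* (HF up, LF/HF down)
  but no effect sizes; the multipliers are free parameters chosen once.
* **AF**: i.i.d. Gamma intervals, mean 600 ms, CV 0.20 — the simplest
  process with the fully dispersed, serially uncorrelated signature;
  no atrioventricular-node model. Episode durations are log-normal
  around 1 h (capped at 4 h). PAC insertions advance the clock, so the
  realized onset (first fibrillatory beat) is taken as the
  authoritative onset time in the truth object.

**Calibration, once.** The free generator parameters (noise and HF
amplitude ranges, the two ectopy medians) were tuned in a single
calibration exercise against the classifier's frozen spec-default
thresholds so that the default cohort lands near the published
operating point, then frozen: segment-level sensitivity 65.6% and
specificity 84.4% at the default seed (published: 69%/84%), first-3-h
group-I positivity 65.7% vs pre-onset 86.7% (published pattern:
57% → 83%). These numbers are *constructed to be comparable*, not
estimated from data; the acceptance criterion therefore tests a band
(sens 0.60–0.85, spec 0.75–0.92), and a green test establishes that
the pipeline's rules interlock as designed on data with the assumed
statistical structure — not that the classifier would achieve this on
real Holter recordings.

Not emulated: respiratory coupling and baroreflex dynamics (modulation
tones are fixed-frequency sinusoids), ventricular ectopy, signal
dropout, heart-rate turbulence, ECG waveforms, and any clinical
covariate structure.

## 7. Numerical conventions and degenerate inputs

* Population variance throughout the HRV block; SD2² floored at 0.
* Zero-variance windows define lag-1 autocorrelation as 1 ("perfectly
  regular"), so a metronomic series can never look AF-like.
* Undefined is explicit: fewer than 2 NN intervals, fewer than 100
  Poincaré pairs, fewer than 300 NN intervals or < 5 min span
  (spectral), zero denominators in 2×2 ratios — all return
  undefined-flagged results, never silent zeros, and unanalyzable
  segments are excluded from contingency counts with a log entry.
* Generators are pure functions of (parameters, seed); classification
  is a pure function of (segment, configuration); rerunning any
  protocol on identical inputs is bit-identical.

## 8. Known limitations

The decision matrix is a stand-in: agreement of its operating point
with the published one is constructed, and class-2 behaviour before
onset (the reference study observed none in its selected windows)
depends on our AF-detector specifics. The Lomb normalization is exact
only for isolated tones; broadband leakage between LF and HF of order
a few percent is expected at one-hour records. The 1-D cluster count
can merge ectopic arms into the main cloud at very high dispersion,
which is harmless here because those segments are classified by the
dispersion rules. Sample-size reconstruction for the reference study
is out of scope (its stated inputs underdetermine the printed 94).
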