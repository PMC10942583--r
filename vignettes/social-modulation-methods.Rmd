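---
title: "Methods: social-bout modulation and cross-region correlation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social-bout modulation and cross-region correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socroc)
library(dplyr)
```

## The problem

Joint recordings of cerebellar spike trains (Purkinje-cell simple spikes,
dentate-nucleus units) and ~30 Hz calcium imaging of anterior cingulate
cortex (ACC) during free social interaction pose three linked analysis
problems:

1. **When is the animal interacting?** Interaction bouts must be derived
   from position tracking by a proximity rule.
2. **Which units care?** Each unit or neuron must be classified as
   positively modulated, negatively modulated, or unmodulated by
   interaction, with a null that respects the strong autocorrelation of
   both firing rates and calcium signals.
3. **Do the regions co-fluctuate, and is that co-fluctuation behavioral?**
   Pairwise cerebellum–ACC correlations must be assessed against
   autocorrelation-preserving surrogates, both over the whole session and
   restricted to non-social epochs.

`socroc` implements this pipeline end to end, together with a seeded
synthetic-session generator so that every stage can be validated against
known ground truth without any recorded data.

## Bout detection

A frame is an interaction frame when the distance from the subject's nose
to any of the target's nose, body centroid, or tail base is at or below
the proximity threshold (default 20 mm — the 2 cm criterion standard for
this assay). The contact tag (nose-nose / nose-body / nose-rear) is the
nearest part. We use point distances between tracked landmarks; traced
body outlines carry more shape information, but the 2 cm landmark rule is
what the point abstraction realizes, and it makes the detector exactly
testable.

Runs of flagged frames become bouts after two post-processing steps whose
values the protocol itself does not fix: gaps shorter than `merge_gap`
(default 0.5 s) are bridged, and bouts shorter than `min_duration`
(default 0.2 s) are dropped. Both defaults exist to suppress single-frame
tracking jitter and are exposed in `analysis_params()`. Bout intervals are
half-open `[onset_frame, offset_frame)` with frame 0 at the first
timestamp.

Head kinematics come from the head-mounted LED. A single LED carries no
orientation, so heading is taken as the direction of LED displacement,
gated below 20 mm/s where direction is numerically meaningless (angular
speed is reported as 0 there, with a mask). This displacement-heading
proxy is a package decision, not a claim about how any particular lab
computed it. Movement events (locomotion onset/offset, head-rotation
onset) use a hysteresis detector: onset fires when speed crosses the high
threshold after at least `refractory` seconds below the low threshold;
offsets are symmetric.

## Rate series and traces

Spike trains are binned at the imaging frame times themselves — nominally
33 ms bins at ~30 Hz — so spike rates and calcium traces share one frame
clock by construction rather than by resampling. Rates are smoothed with a
unit-area Gaussian kernel (sigma 100 ms, truncated at ±4σ) and z-scored
per unit over the whole session using the population SD. Calcium traces
are z-scored the same way. Zero-variance series are flagged degenerate and
excluded from every downstream test rather than propagating NaNs.

Edge handling matters for the shuffle tests: display smoothing uses
reflect padding, but circular padding is available and is what makes
smoothing-then-z-scoring commute *exactly* with circular shifts — the
property the shuffle-validity tests rely on.

Z-scoring is computed once on the full session and reused in both epoch
modes of the correlation analysis. Restricting the z-score to the off-bout
epoch would change each pair's r only through an affine rescaling, to
which Pearson correlation is invariant; full-session normalization keeps
the two epoch modes directly comparable.

As a recording-quality utility, `cs_ss_crosscorrelogram()` builds the
simple-spike/complex-spike lag histogram in which a genuine Purkinje cell
shows the characteristic simple-spike pause (tens of ms) after each
complex spike.

## Modulation classification

The statistic is the ROC area (AUC) between a unit's per-frame activity
and the binary interaction indicator, computed through the tie-corrected
midrank Mann–Whitney identity `AUC = U/(n1*n0)`. AUC is a rank statistic,
so any strictly monotone transform of activity leaves the classification
unchanged; z-scoring is therefore immaterial to the AUC itself, while
smoothing is not (it reshapes ranks across neighboring frames). The
activity fed to the classifier is the smoothed z-scored rate (ephys) or
z-scored trace (calcium), configurable.

The null distribution is built from 1000 circular shifts of the activity,
drawn uniformly from `[min_shift, L - min_shift]` frames. The minimum
shift (default 10 s) keeps surrogates from nearly reproducing the observed
alignment despite slow autocorrelation. Shifting rotates the activity
rather than the indicator; the two are equivalent under rotation, and
fixing one convention makes runs reproducible. P-values use the add-one
permutation rule, `p = (1 + #{null >= obs}) / (1 + n_shuffles)`, which is
permutation-valid and never exactly zero. A unit is labeled positive when
the upper-tail p falls below 0.025, negative on the lower tail — the
per-tail criterion corresponding to a two-tailed 0.05. (Group-level tests
in this literature often quote a 0.01 level; that applies to cohort
comparisons, not to this per-unit criterion.)

Implementation note: rotating the activity permutes its fixed midranks, so
every null AUC is a sum of ranks falling on indicator frames — a circular
cross-correlation of the indicator with the rank vector. One FFT evaluates
the null at every admissible shift; results are rounded back onto the
half-integer midrank grid, so tie comparisons against the observed AUC
remain exact. The test suite asserts bit-level agreement with the naive
shift-and-recompute oracle.

Peri-event time histograms extract activity around bout onsets (or
movement events) at frame resolution, with events whose window leaves the
session excluded and counted, optional per-event baseline normalization,
and SEM across events (reported as zeros, flagged, when only one event
survives). The movement-confound check compares each unit's post-minus-pre
event difference against redraws of the event times, so a bout-driven unit
with independently timed movement events stays non-significant at roughly
the nominal rate while a speed-driven unit is caught.

## Cross-region correlation

Each cerebellar unit × ACC neuron pair gets a Pearson r over the usable
frames of the chosen epoch: all frames (`full`) or all frames outside
every bout dilated by `pad` seconds (`offbout`, default pad 1 s — chosen
to absorb the 1–4 s response tails that outlast a bout). Significance
comes from circular shifts of the *intact, full-length* calcium trace —
shift first, then mask — so each surrogate keeps the within-epoch
autocorrelation of a real trace. Whether the shift is applied to the trace
only or to both series is a free choice; the trace-only construction is
followed. Two-sided add-one p at `corr_alpha = 0.05` (a conventional
level; it is exposed in `analysis_params()` because the underlying
protocol does not pin it down). The surrogate r at every shift is computed
exactly with three FFT cross-correlations (mask-aware), validated in the
tests against a direct shift-then-mask loop.

Class summaries key the r distributions and the percentage of
significantly positive/negative pairs by (cerebellar label × ACC label ×
epoch mode). Empty class cells are reported as missing, never as zero.

## The synthetic generator

`synth_config()` defaults describe the session the analysis expects:

* 48 × 48 cm arena (coordinates in mm), ~30 Hz frame clock, 8 min total
  with a 1 min baseline before the target appears;
* subject and target move as Ornstein–Uhlenbeck smoothed random walks with
  reflecting walls (the simplest model with realistic free-running mouse
  speeds); during each scheduled approach episode the tagged target part
  is held at contact distance and the subject slows down, matching the
  observed speed drop at interaction onset;
* 35 approach episodes of 1–3 s in the interaction period (~15% of frames
  interacting) — bout counts are not published as generative parameters
  anywhere we know of, so this is a package choice recorded here once;
* Purkinje-cell simple-spike trains at 40–100 Hz baseline, dentate units
  at 20–60 Hz, ACC calcium event rates 0.15–0.6 Hz;
* bout-locked modulation: negative units multiply their baseline by
  (1 − amplitude) inside a window of 1–3 s drawn per bout onset
  (suppression convention), positive units by (1 + amplitude) for 2–4 s
  (excitation convention), amplitude 0.5 by default;
* optional complex-spike trains with an enforced simple-spike pause
  (default 40 ms) after each complex spike;
* calcium transients as Poisson events convolved with a causal
  double-exponential kernel (rise 50 ms, decay 400 ms — GCaMP6f-like; the
  forward model is a package choice), plus additive Gaussian noise;
* optional planted coupling: designated cerebellar-unit/ACC-neuron pairs
  share a standardized OU latent applied on the log-rate scale with gain
  `coupling_strength`, optionally gated to bouts. Keeping the shared
  signal in the latent rates (rather than mixing traces) preserves
  modality-specific noise.

One master seed fans out into named substreams (behavior / spikes /
calcium / coupling / shuffles), so each stage can be regenerated
independently and every run is bit-reproducible.

What the generator does *not* emulate: real pose geometry and tracking
noise, non-Poisson spike-train structure (bursting, refractoriness beyond
the CS pause), calcium indicator nonlinearity and drift, session-level
nonstationarity, and realistic bout-count asymmetries between social and
object targets. Passing recovery tests therefore demonstrate that the
*analysis* is correct and calibrated under its stated assumptions — not
that those assumptions exhaust real recordings.

## Numerical and design choices

* Bin edges are the frame timestamps (last bin closed), so "33 ms" is
  nominal and alignment is exact by construction.
* Population-SD z-scores (divide by N), constant documented choice.
* Half-open frame intervals everywhere; frame 0 at the first timestamp.
* Degenerate inputs (constant series, all-masked positions, empty epochs,
  single events) are flagged or error loudly — never silently dropped.
* Calcium deconvolution is out of scope; correlations use the traces
  themselves, and spike-to-deconvolved-event cross-correlograms are
  deliberately not offered.
* The pipeline entry points are the exported functions
  (`run_pipeline()` / `render_report()` driven by a YAML config); run
  configuration uses YAML and trace matrices use wide CSV.

## Validation scale

The statistical validation in the test suite runs at desk scale, chosen so
the full suite completes in about two minutes: classifier calibration on
1000 simulated unmodulated units (20 Hz, 480 s, 1000 shuffles each),
planted-effect recovery on 100 units per class, correlation calibration on
1000 independent pairs and power on 40 strongly coupled pairs, and an
epoch-ablation scenario with 12 × 40 labeled pairs. Exact-oracle checks
(brute-force AUC with ties, hand-expanded Pearson formula, loop-computed
surrogates) are exhaustive at small n. Stochastic rate checks are asserted
within three binomial standard errors of their nominal levels; point
checks (sensitivity, power, epoch-ablation shrinkage) are asserted
directly.
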