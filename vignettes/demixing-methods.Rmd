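---
title: "Demixing dendritic voltage-imaging traces: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demixing dendritic voltage-imaging traces: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltdemix)
```

## The problem

Epifluorescence voltage imaging of the olfactory bulb at ~1 kHz yields
fluorescence traces for on the order of a hundred dendritic regions of
interest (ROIs), but the scientific units of interest are glomeruli and
single mitral/tufted cells. Two anatomical facts make demixing possible
without source-extraction machinery:

* every mitral/tufted cell sends one apical dendrite into exactly one
  glomerulus, and "sister" cells of a glomerulus share synaptic input —
  so traces from the same glomerulus are correlated (subthreshold
  co-fluctuations, partially shared spiking);
* every somatic action potential backpropagates into all dendrites of
  that neuron — so ROIs of one neuron carry near-identical spike trains,
  offset by a sub-millisecond-to-millisecond latency gradient.

`voltdemix` implements the corresponding two-level pipeline:
correlation + k-means at the glomerulus level, then a spike
synchronicity index + hierarchical clustering inside each glomerulus.
Around it sit the supporting analyses: ΔF/F₀ baselines, SD-threshold
spike detection, spike-triggered averages with half-rise latency maps,
odor-response amplitudes, orientation-tuning fits for V1 calcium data,
and theta-phase spike statistics.

## Signal model and generator

`simulate_voltage_dataset()` draws a recording as follows. Raw
fluorescence is negative-going (Voltron-like):

```
F(t) = F_b * (1 + drift(t) - dff(t)) + F_b * e(t),     e ~ N(0, sd_noise)
dff(t) = spikes(t) + subthreshold_g(t)
```

* **Spikes.** Each neuron fires an inhomogeneous Poisson train (mean
  rate 8 Hz) with an absolute refractory period of 5 ms, rate-modulated
  by theta phase (depth 0.6, peaking at the theta peak; during an
  optional odor window the preferred phase shifts by a configurable
  amount). Each glomerulus owns a shared "master" train carrying a
  fraction `sister_coupling` (default 0.3) of the rate; its spikes are
  copied into every sister with ±0.5 ms jitter, and each sister adds an
  independent train for the remainder. Pairwise, sisters therefore share
  ≈30% of their spikes — a single knob reproducing the qualitative
  finding that sister cells synchronise above chance. Every spike
  reaches each of the neuron's ROIs at that ROI's backpropagation
  latency (0 at the soma-like ROI up to 1.5 ms at the tip) plus N(0,
  0.3 ms) jitter, rendered as a difference-of-exponentials kernel (rise
  0.5 ms, decay 3 ms) of amplitude 2.5% −ΔF/F₀.
* **Subthreshold.** One realisation per glomerulus, shared by all its
  ROIs: a slow Ornstein–Uhlenbeck process (τ = 50 ms), a theta sinusoid
  (5 Hz, global phase), and a fast gamma-band OU component (τ = 3 ms).
  Total SD defaults to 0.3% ΔF/F₀ (components A/2, A/2, A/3). The
  gamma-band term deserves comment: a 25-frame median baseline at 1 kHz
  acts as a ~40 Hz high-pass, so slow shared signals are removed from
  ΔF/F₀ before the correlation stage ever sees them. Glomerular
  micro-circuits famously generate gamma-band (40–100 Hz) population
  activity, and it is exactly this fast shared component that survives
  the baseline and gives the correlation matrix its within-glomerulus
  block structure even when spike sharing is absent.
* **Noise and drift.** White Gaussian noise, default SD 0.15% ΔF/F₀
  (spike SNR ≈ 17), plus a slow polynomial drift (default −1% linear).
  The noise default is deliberately at the clean end of what the
  indicator supports: the pipeline's clustering threshold sits at
  mean + 1.5 SD of the *total* trace, and for that threshold to separate
  spikes from the noise-peak distribution — as its routine use in vivo
  implies it does — the noise floor must sit ≈4σ below it. At a 0.4%
  noise floor the 1.5 SD trains are dominated by noise peaks and no
  correct implementation can subcluster on them.
* **Rate co-modulation knob.** `subthreshold_rate_mod` couples each
  neuron's firing rate to its glomerulus's slow subthreshold signal. It
  defaults to 0: any non-zero value elevates within-glomerulus chance
  coincidence, so a "no coupling" configuration would no longer be a
  synchrony null. Users who want rate co-modulation can turn it on
  explicitly.

What the generator deliberately does **not** model: biophysical
conductances, optics/PSF and depth-dependent blur, hemodynamics,
movement artifacts, neuropil contamination, and spatially overlapping
sources. Passing recovery tests on these data therefore demonstrates
that the pipeline's statistics are implemented correctly and behave as
designed under the stated signal model — not that the pipeline is robust
to every artifact of real recordings.

## Baselines and preprocessing

* `compute_f0_temporal_median()` — centred rolling median. Windows
  shrink symmetrically at the trace edges; no data are fabricated. An
  even window is bumped to the next odd value with a warning (a
  "25-frame" window is 12 + 1 + 12). Whether the original analyses used
  centred or causal windows is not stated anywhere we know of; centred
  is the common choice and is what the shrink rule assumes.
* `compute_f0_sliding_percentile()` — causal window (default the 30 s up
  to and including the current sample), 25th percentile, linear
  interpolation between order statistics (one convention had to be
  fixed; it is oracle-tested).
* `compute_dff()` — (F − F₀)/F₀, stored sign-flipped for
  negative-polarity indicators so spikes are positive-going. Baselines
  below 10⁻⁶ of the per-ROI median fluorescence raise an error rather
  than clip: a near-zero F₀ means the recording, not the formula, is
  broken.
* `smooth_savitzky_golay()` — window 5, order 2. The source convention
  this follows was printed with an impossible parameter pair ("32
  points" for a 5-frame window); 5 frames is the only value stated in
  frame units, and order 2 is the standard choice at that width. Both
  are exposed.
* Spike thresholds are computed on the smoothed signal; whether the
  original pipeline thresholded raw or smoothed traces is unstated, and
  smoothing first is the choice that makes the stated thresholds
  workable at 1 kHz.

## Spike detection

`detect_spikes()` finds interior local maxima above mean + k·SD, both
moments taken over the whole trace, spikes included — the literal
`findpeaks`-plus-threshold rule. Consequences users should know:

* detection is invariant to gain but **not** robust to gross artifacts
  (a robust median/MAD variant is available, off by default);
* spike count is monotonically nonincreasing in `k_sd`;
* the minimum peak distance defaults to 5 ms. The spike kernel is
  ~5–6 ms wide, so a smaller separation lets noise on the decay shoulder
  re-trigger a detection of the same spike; 5 ms also equals the
  generator's refractory period, so no genuine spikes are merged.
  Equal-height peaks inside the window keep the earlier peak.

## The demixing stages

**Glomeruli.** Rows of the ROI × ROI Pearson correlation matrix are the
feature vectors; k-means with k set to the anatomical glomerulus count,
k-means++ seeding, best of 50 restarts by within-cluster sum of squares.
Plain random restarts were measurably unreliable here (with 88 ROIs and
k = 11 roughly a quarter of runs stalled in local optima that split one
glomerulus and merged two others); k-means++ removed every such failure
in our recovery experiments. Labels are arbitrary up to permutation —
always compare partitions with the adjusted Rand index.

**Synchronicity index.** Coincidences within ±7 ms (inclusive; a 21 ms
window) are counted by greedy one-to-one nearest-time matching, so no
spike is counted twice and SI ≤ 1 by construction, with
SI = matches / ((n_A + n_B)/2). Greedy matching can drop at most one
match per pair relative to the exhaustive bipartite optimum in chain
configurations (verified against an exhaustive oracle for trains of ≤8
spikes); at physiological densities discrepancies are essentially
absent. Two empty trains define SI = 0, flagged.

**Subclusters.** Within each glomerulus independently (subclusters never
span glomeruli), average-linkage hierarchical clustering on d = 1 − SI,
cut at 10% of the maximum dendrogram distance. The maximum is taken
**dataset-wide** by default (`threshold_scope = "dataset"`): if the
fraction is applied to each glomerulus's own maximum, the rule
degenerates whenever a cluster contains a single neuron — its largest
within-cluster distance is then just detection noise, 10% of it is
≈0, and the neuron shatters into singleton subclusters that are nearly
perfectly synchronous with each other. The dataset-wide maximum keeps
the cut at a meaningful absolute height (≈0.09 in d units on typical
data) while preserving the "10% of the maximum distance in the
dendrogram" reading. The per-glomerulus variant is available as
`threshold_scope = "glomerulus"`.

**Sister synchrony.** Subcluster-level trains are formed by merging
member-ROI trains and collapsing events within the ±7 ms window (they
are one spike seen on several branches); whether to merge or pick a
representative ROI is unstated in the source convention, and merging
uses all the data. Same-glomerulus versus different-glomerulus SI is
compared by a two-sided Wilcoxon rank-sum test. The clustering-stage
trains (1.5 SD) drive the subclustering; the final trains (3 SD) are
used for reported synchrony comparisons.

## Latency mapping

`spike_triggered_average()` aligns snippets on reference (soma) spike
times, dropping events whose lag window leaves the recording.
`half_rise_time()` finds the first crossing of 50% of (peak − baseline)
by linear interpolation between samples, giving sub-frame resolution;
`backprop_latency_map()` subtracts the reference ROI so the soma is 0 ms
by definition. The optional inclusion rule (peak > baseline mean + 5 SD)
flags unreliable waveforms as excluded rather than returning a number.
With 65 averaged events at 0.5 ms/frame the simulated 1.5 ms tip latency
is recovered to within ±0.05 ms in typical runs.

## Orientation tuning

The wrapped two-Gaussian model shares one width σ between the two lobes
and allows independent nonnegative amplitudes (direction selectivity);
R_p ≥ R_o is enforced by relabelling (θ_p ↦ θ_p + 180°). Fitting is
Levenberg–Marquardt, multi-started from each of the eight sampled
directions, best residual sum of squares wins; flat profiles are flagged
rather than fitted, and σ is bounded to [1°, 180°]. For the OSI the
fitted responses are baseline-subtracted and the orthogonal response
(mean of θ_p ± 90°) is rectified at zero — the source equation does not
state baseline or rectification conventions, so both choices are made
explicit here and flagged in the output. The blank condition enters only
the Kruskal–Wallis responsiveness screen, never the tuning fit. When all
responses are identical the Kruskal–Wallis statistic is undefined and
both p-values are reported as 1.

## Theta phase

The reference is the average of glomerular ΔF/F₀ traces, band-passed
1–12 Hz with a zero-phase Butterworth filter; the instantaneous phase is
the angle of the FFT analytic signal, with phase 0 at the oscillation
peak (the −ΔF/F₀ maximum — sign conventions differ between papers, so
this one is stated). Inside `run_pipeline()` the reference is built from
ΔF/F₀ computed with a long (~1 s) median window: the 25-frame baseline
of the spike pipeline would remove the theta band itself. Spike phases
are linearly interpolated on the unwrapped phase; per-condition circular
means and resultant lengths, and the circular difference between two
condition means (e.g. odor-evoked phase shift), are reported.

## Sizes, tolerances and numerical choices

* Default study conditions: 11 glomeruli × 2 neurons × 4 ROIs, 60 s at
  1 kHz. A full recovery run (simulate → preprocess → detect → demix →
  phase) takes ~7 s on one core; the test suite uses 10-seed batteries
  for the recovery properties and smaller configurations elsewhere, and
  the acceptance script uses 5-seed medians.
* Determinism is bitwise: one seed controls the generator
  (`withr::with_seed`), and k-means restarts take their own seed
  argument. Pipeline outputs are hashed (MD5) into a manifest;
  rerunning a configuration reproduces the hashes exactly.
* Ties: equal-height peaks keep the earlier; nearest-direction ties in
  `max_response()` keep the smaller angle; coincidence candidates at
  equal distance match in time order.
* Degenerate inputs have defined behaviour rather than errors where a
  value is meaningful (SD = 0 trace → empty train; flat tuning profile →
  flagged; empty train pair → SI 0 flagged) and errors where none is
  (zero-variance ROI in the correlation matrix, all ROIs filtered out,
  baseline at zero).

## Known limitations

* The correlation stage needs *some* shared within-glomerulus signal
  that survives the baseline window; in recordings where the baseline
  window is much longer than at 1 kHz (e.g. 7 ms frames) slow
  subthreshold correlations contribute too, but the pipeline does not
  model or exploit cross-frequency structure beyond that.
* k is fixed by the anatomical glomerulus count; there is deliberately
  no automatic model selection.
* The SI treats trains symmetrically and ignores rate differences beyond
  the normalisation; strongly rate-mismatched pairs have SI bounded by
  2·min(n_A, n_B)/(n_A + n_B) regardless of timing.
* Greedy coincidence matching is not globally optimal (bounded one match
  per pair from optimum); exact optimal matching would cost O(n²) per
  pair with no practical benefit at these densities.
* No motion correction, neuropil subtraction, or source overlap
  handling: ROIs are taken as given (the upstream segmentation is
  external), and the movie renderer enforces non-overlapping footprints.
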