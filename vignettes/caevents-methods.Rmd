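---
title: "Methods: calcium-event analysis with caevents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-event analysis with caevents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caevents)
```

# The problem

Wide-field calcium imaging of an invertebrate high-order neuropil yields a
slow (20 Hz), low-amplitude fluorescence signal in which two kinds of
structure matter for memory experiments: the *rate* of spontaneous calcium
transients in stimulus-free periods, and the *magnitude* of
stimulus-evoked transients. The experimental design compares these
quantities before and after the presentation of a training context,
between trained (TR), naive (NAIVE) and protein-synthesis-blocked
(TR_CHX) animals. `caevents` implements the full analysis chain -- trace
normalization, event detection, evoked-response quantification, spatial
activity-pattern clustering and the group statistics -- together with a
synthetic-data generator that carries known ground truth, so every stage
can be verified end to end without animal data.

# Trace model and %ΔF/F

The ROI-mean fluorescence per frame, $F(t)$, is modelled by the generator
as

$$F(t) = B\,e^{-t/\tau_b}\left(1 + \frac{s(t)}{100}\right) + \varepsilon(t),$$

where $B$ is the baseline intensity (16-bit camera units), $\tau_b$ a
mono-exponential bleaching constant, $s(t)$ the summed transient signal in
percent, and $\varepsilon$ i.i.d. Gaussian noise. Transients multiply the
bleached baseline rather than adding raw counts so that a planted
amplitude of $a$ percent survives the normalization below as an $a$
%ΔF/F excursion.

Processing follows the standard two steps:

1. **Band-pass filter, 0.025--5 Hz.** Realized as a 2nd-order Butterworth
   band-pass applied forward-backward (`signal::filtfilt`), i.e. zero
   phase: the event rules depend on onset and peak *timing*, which causal
   filtering would shift. Segments are reflect-padded (three periods of
   the low corner, capped at the segment length); segments shorter than
   three startup lengths are processed but flagged with a warning. The
   high-pass corner removes the mean, which would drive the percentile
   baseline to zero, so the pre-filter segment mean is added back after
   filtering (*DC restoration*). The filter is applied per analyzed
   segment, the unit over which the baseline is defined.
2. **Percentile baseline.** $F_0$ is the 8th percentile (linear
   interpolation between order statistics, R's `quantile` type 7) of the
   filtered segment, and $\%\Delta F/F = (F - F_0)/F_0 \times 100$. By
   construction at most 8% of frames fall below zero, and the result is
   invariant under multiplicative rescaling of the raw intensities.

Whether the baseline is taken before or after filtering is a genuinely
open choice; this implementation computes it after, on the filtered
profile, which is the order the processing sequence implies.

# Calcium-event detection

A calcium event is a fast rise to a peak followed by an exponential-like
decay. The printed acceptance rules are applied verbatim:

* the rise must take at least `minRiseFrames = 2` frames (100 ms at
  20 Hz);
* the relative amplitude, $\%\Delta F/F(\mathrm{peak}) -
  \%\Delta F/F(\mathrm{onset})$, must reach both `minAmpPct = 0.02` %ΔF/F
  and `sdFactor = 0.3` times the animal's pooled SD (the *population* SD
  of all of that animal's analyzed segments concatenated);
* the peak is the *first* strict local maximum within `peakWindowS = 2` s
  of the onset; plateaus take their first frame.

Candidate onsets are frames where a rise starts (a local minimum, or the
last frame of a flat valley, followed by an increase). A new event
superimposed on a decay is split at the interior local minimum, matching
the "short decay followed by a superimposed new event" candidate shape.
Events whose 2 s peak window crosses the segment end are dropped with a
warning.

**Why candidate proposal is unsmoothed by default.** The original
candidates were identified by eye, so any automated proposal rule is a
surrogate. An earlier design smoothed the trace (3-frame moving average)
before proposing onsets; we found that this erases the one-frame interior
minima that separate superimposed events, so the detector no longer
agrees with an exhaustive scan that applies the three printed criteria
directly. The package therefore proposes candidates on the raw %ΔF/F
trace by default (`smoothWindow = 1`); the amplitude thresholds are the
noise control, exactly as printed. For recordings whose noise SD
approaches the 0.02% floor, `smoothWindow = 3` restores the
noise-suppressing proposal at the cost of that exact correspondence.
The test suite verifies exact equivalence with the brute-force scan on
random kernel-train traces, and F1 ≥ 0.9 against planted ground truth on
noisy traces whose amplitudes are at least five noise SDs. Detected
onsets lead the planted frames by up to ~5 frames because the zero-phase
filter smears the 100 ms rise symmetrically; recovery is therefore scored
with a 250 ms onset-matching tolerance.

Event rate is simply `n events / segment duration` (Hz).

# Stimulus-evoked responses

Evoked activity is the plain sum of %ΔF/F over the stimulus window minus
the sum over the immediately preceding equal-length window: 9 s for the
visual danger stimulus (vds, presented during the last nine seconds of a
27 s context, two movement cycles separated by 2 s), and 1 s for the
mechanical control (mec). Sums are over frames (units %·frame) at the
fixed 20 Hz frame rate; integrating over time would only rescale both
windows by 1/20 and change no comparison. Windows are annotation-driven:
the vds window starts at the first movement-cycle onset.

# Spatial activity patterns

Movies are 2×2 pixel-binned (block means; a binned ROI pixel is in-ROI
when any pixel of its block is), then normalized pixelwise as %ΔF/F
against a *centred* 400-frame (20 s) rolling mean with shrinking windows
at the edges, and the video-wide minimum is subtracted so all values are
non-negative while intensity relations are preserved. The pattern at an
event peak is the average of the peak frame ±1, cropped to the ROI
bounding box, normalized to the in-ROI maximum, Gaussian-filtered
(σ = 1 px; skippable per animal via `gaussian = FALSE`), re-normalized,
and thresholded at 0.5 (sub-threshold and out-of-ROI pixels set to 0).
Re-normalizing after the filter keeps the map's in-ROI maximum at exactly
1, so the 0.5 threshold always means "half of the peak". The Gaussian
filter is a small separable kernel (truncated at 3σ) with reflecting
boundaries -- wrap-around boundaries would blend opposite ROI edges --
and its exact behaviour is pinned by a golden-file test.

Patterns are vectorized over in-ROI pixels (row-major) and clustered with
K-means (`stats::kmeans`, ≥ 10 restarts under a fixed seed). When k is
not given it is chosen from 2--8 by maximum mean silhouette score
(`cluster::silhouette`); there is no canonical way to fix k per animal,
so a deterministic, standard selector is used and can be overridden.
Stimulus-evoked patterns are not part of the clustering fit; they are
assigned post hoc to the nearest centroid, and flagged as "matching a
spontaneous configuration" when their distance does not exceed the 95th
percentile of member-to-own-centroid distances in that cluster. That
match rule is this package's convention; no standard quantitative
criterion exists for such a correspondence.

# Group statistics

The statistical battery mirrors the experimental design:

* **Omnibus:** 2 (group) × 2 (period) mixed-design ANOVA -- between-
  subjects SS split into group and subjects-within-groups, within-subjects
  SS into period, group×period and period×subjects error, F against the
  matching error term. It is fitted through `stats::aov` with an
  `Error(animal)` stratum, which realizes exactly this decomposition for
  unequal group sizes; the test suite checks it against an independent
  definitional sums-of-squares oracle to 1e-8 and verifies the exact
  decomposition identity.
* **Post hoc:** paired t-tests per group (two-tailed for rates;
  one-tailed for stimulus-evoked sums, where an increase is the expected
  direction), Holm--Bonferroni corrected. The Holm family is the set of
  pairwise tests following one omnibus, and is recorded verbatim in the
  report, since the source does not enumerate its families.
* **Between groups:** a Welch independent t-test on pos−pre difference
  scores (Welch whenever sample sizes differ).
* **Association:** Pearson correlation between each animal's post-context
  rate change and its vds-evoked delta, with the exact t-transform
  p-value.

Degenerate inputs are handled explicitly: identical paired samples return
t = 0, p = 1 (no effect, no variability); constant data with equal means
raise an undefined-statistic error.

# The synthetic generator and what passing tests mean

Generator defaults define the simulated study conditions: 20 Hz frames,
139 s spontaneous segments (a typical mid-length recording; durations
stay within a 60--188 s range), a 27 s context whose last 9 s carry
the two vds transients, 1 s mec pulses, and cohorts of 6 NAIVE / 5 TR
animals (between-subjects df = 9). Spontaneous event rates and
amplitudes are free parameters of the generator, chosen once at
physiologically sensible values:

| parameter | default | rationale |
|---|---|---|
| spontaneous rate | 0.06 Hz | a few events per minute, low-frequency regime |
| spontaneous amplitude | 0.2 %ΔF/F (±20% jitter) | small transients, an order above the 0.02% floor |
| kernel | 2-frame rise, τ = 0.8 s | fastest admissible rise; sub-second decay |
| trace noise SD | 0.005% of baseline | ROI averaging over ~10⁴ pixels leaves sub-0.01% noise |
| TR rate delta (pos−pre) | +0.10 Hz | roughly doubles the rate; power ≈ 0.9 at n = 6/5 |
| vds amplitude | 1.0% (NAIVE, TR_CHX); 0 (TR) | full suppression in trained animals |
| mec amplitude | 1.0% (all groups) | control stimulus, no group effect |
| bleaching τ | 2000 s | mild drift, removed by the high-pass |

The vds trial is embedded in a 139 s segment (context onset at 60 s):
the 0.025 Hz high-pass needs tens of seconds of context on both sides of
the 9 s windows, exactly as the trials sit inside continuous recordings.
Movie simulations place 3 Gaussian motifs (σ = 2.5 px) about 10 blob-SDs
apart inside a circular ROI; motif identities cycle round-robin, and
events are thinned to ≥ 3 s separation so each peak yields an
uncontaminated pattern -- both properties of the generator, stated here
because the end-to-end recovery test relies on them.

What the generator does *not* emulate: photon-shot (Poisson) noise,
motion artifacts, dye diffusion, optical blur between neighbouring
structures, and amplitude/rate non-stationarity within a segment.
Passing tests therefore demonstrate that the implementation applies the
printed rules correctly and recovers effects under idealized recordings;
they do not certify performance on motion-contaminated or
photon-limited data.

Problem sizes used by the verification suite -- 100 traces for oracle
equivalence, 50 seeds for detection F1, 100 segments for rate recovery,
one movie for motif recovery, 200 datasets for the ANOVA oracle, 500
null and 50 planted cohorts for calibration and power -- were chosen as
the smallest sets whose Monte-Carlo error is comfortably below each
criterion's margin.

# Numerical choices and known limitations

* Frame indexing is 0-based with half-open intervals throughout the file
  formats; times are frame / frame rate. CSV files always use "." as the
  decimal separator (pinned by a byte-level golden test).
* 16-bit TIFF i/o is exact for integer intensities; frame rate travels in
  a YAML sidecar because plain TIFF tags do not carry it.
* K-means inertia is only empirically non-increasing in k (10 restarts);
  a pathological restart set could break monotonicity.
* The type-I calibration of the rate ANOVA sits slightly above 0.05
  (≈ 0.06 over 500 null cohorts): event rates are scaled Poisson counts,
  so the normality assumption is only approximate at λT ≈ 8. This is a
  property of the design being reproduced, not of the implementation.
* The gross-motion QC check only warns; stabilization belongs upstream,
  and segments with unfixable motion should be discarded rather than
  corrected here.
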