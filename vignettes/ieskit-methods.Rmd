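---
title: "Methods: burst-suppression segmentation, spike detection and the jitter synchrony test"
author: "ieskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst-suppression segmentation, spike detection and the jitter synchrony test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieskit)
```

# Scope and assumptions

`ieskit` analyses local field potential (LFP) recordings from rodents under
general anesthesia (GA), where the cortex and hippocampus alternate between
high-amplitude *bursts* and near-isoelectric *suppression* epochs.  Against
that background, brief high-voltage transients — interictal epileptiform
spikes (IES) — are the phenomenon of interest: their per-minute rate, and
whether IES trains recorded simultaneously in two regions (e.g. hippocampal
CA1 and medial prefrontal cortex) are coupled at millisecond timescales.

Every stage assumes: a fixed sampling rate; samples in microvolts; 0-based
time in seconds; half-open intervals `[start, end)` (this makes bin
partitioning exact, with no double-counted boundary samples).  Loaders
refuse NaN samples by default because every detector here is
amplitude-threshold based and a dropout distorts both the baseline SD and
the rectified bin means; an opt-in flag permits linear interpolation of
gaps up to 10 ms.

# Burst-suppression segmentation and BSR

The segmentation pipeline (`segment_bs`) is:

1. **Band-pass 1–1000 Hz**, zero-phase.  The filter is realized as a
   2nd-order Butterworth high-pass and a 2nd-order low-pass, each applied
   forward and backward (`signal::filtfilt`), i.e. 4th-order zero-phase
   overall.  Zero phase matters because bin means must not be shifted in
   time relative to the state boundaries; a cascade of two short sections
   is numerically better conditioned than a single wide band-pass section
   when the band spans three decades.
2. **Rectified 700-ms bins**: the mean of `|x|` per bin; the trailing
   partial bin is dropped.
3. **Bimodal valley threshold**: the bin histogram of a burst-suppression
   recording is bimodal (a suppression mode and a burst mode).  The phrase
   "negative peak of the histogram" is ambiguous; the only reading that
   yields a separator is the *valley* — the deepest local minimum of a
   Gaussian-kernel density (Silverman bandwidth, 512-point grid) between
   the two largest modes.  If no interior valley exists the function
   raises a named `no-bimodality` error; a quantile fallback is available
   by configuration but never silently applied.  Because the kernel
   bandwidth and grid scale linearly with the data, the threshold is
   exactly equivariant under gain: segmentation labels are gain-invariant.
4. **Merge, then accept**: bins at or above threshold are burst
   candidates (ties count as burst — a measure-zero choice fixed for
   determinism); candidate bursts separated by less than 2 s are merged;
   merged bursts are accepted only if longer than 2 s, otherwise
   relabelled suppression.  Merging precedes the duration filter — the
   opposite order would first delete short fragments that together form a
   legitimate burst.  Bursts truncated by the recording edge are still
   subject to the duration rule.
5. **BSR**: fraction of time in suppression per 1-min bin, reported for
   full bins only, so that `sum(BSR * 60 s)` equals total suppression
   time over those bins.

## The synthetic model behind the accuracy claim

`simulate_bs_lfp` draws alternating epochs (starting with a burst) with
log-normal durations and fills them with pink (1/f) Gaussian noise whose
SD switches per epoch.  Pink rather than white noise matters: the
amplitude histogram of real LFP owes its shape to strong low-frequency
structure, and a white-noise simulation would make the bimodality test
trivially easy.

Defaults, chosen once as a realistic regime and not revisited: burst
median 8 s and suppression median 4 s (both log-sigma 0.4), which give an
analytic mean suppression fraction of 1/3 — inside the 0.2–0.5 BSR band
that defines stable surgical-plane anesthesia in this preparation;
suppression SD 5 µV and burst SD 25 µV (5:1); sampling rate 2500 Hz so
that the standard 1–1000 Hz band sits below Nyquist.  No distributional
model for epoch durations is implied by the source workflow; log-normal
is a declared convention of this package.

On 20 seeded 10-min recordings from this model, mean bin-wise accuracy of
the default pipeline against the generative labels exceeds the 92%
benchmark (the tests compute ≈ 98%).  Synthetic recordings do not
reproduce oscillatory burst morphology, movement or electrode artifacts,
or slow drift; passing these tests demonstrates the segmentation rules
and their parameters are implemented correctly, not that the accuracy
figure transfers to any particular real recording.

# IES detection

Detection (`detect_ies`) operates on a z-scored signal.  The baseline is
the *suppression* state: `z = (x - mean_supp) / sd_supp`, both moments
taken over the segmentation's suppression intervals (at least 5 s
required).  Using the suppression SD alongside the mean keeps the
statistic self-consistent and gain-invariant.  For awake recordings,
where no suppression state exists, a robust whole-trace baseline
(median / 1.4826·MAD) is provided as a declared extension.

The rule: samples with `|z| >= 10` (both polarities, one bipolar
detector on a single statistic) seed candidates at the local extremum of
`|z|` in each supra-threshold run; a candidate is accepted only if some
30-ms window containing its peak has peak-to-peak range above 10 z (the
window *slides* — the strictest local reading); accepted candidates are
scanned in time order with a 50-ms dead-time so one spike is never
counted twice.  Event times are stamped at the absolute-value peak, the
fiducial needed for millisecond synchrony analysis.  Rates are reported
per minute.

Two honest caveats, handled by design rather than hidden:

* In the source workflow every detected spike was manually inspected.
  This package replaces that step with a scored harness:
  `detection_score` matches detections to ground truth greedily
  one-to-one within 25 ms and reports precision/recall, and every event
  row carries its features for human review; nothing is silently
  dropped.
* A fixed 10-z threshold referenced to suppression necessarily fires on
  burst background whenever burst amplitude approaches 5 suppression-SD
  (10 z is then only ~2 burst-SD).  Detection-oriented simulations in
  the test suite therefore use a burst SD of 2× suppression SD — a
  regime where the background stays below threshold over a 10-min
  recording while the bin histogram remains clearly bimodal — and inject
  15-z spikes.  Under those conditions mean precision and recall across
  20 seeds exceed 0.95 and the injected-versus-detected rate slope over
  0.2–3.2 events/min lies in [0.95, 1.05].  The reference rates for the
  two phenotypes this emulates (≈ 3.22/min vs ≈ 0.216/min) are exposed
  as generator settings and checked only as a stochastic ordering.

# Jitter-surrogate synchrony test

`window_synchrony` defines synchrony as the rate of target-train events
inside `±h` windows centred on each reference event.  Overlapping
windows are merged before both the count and the denominator time;
without merging, a cluster of reference events double-counts the same
target spikes and the "rate" loses its units.  The unmerged
per-reference-event mean rate is available behind a switch for
sensitivity analysis.

`jitter_test` evaluates half-widths `h ∈ {10, 50, 100, 500, 1000}` ms.
For each `h`, 1000 surrogate target trains are built by displacing every
spike independently, uniform on `±2h`; displaced spikes are folded back
into `[0, duration)` by reflection, which preserves the spike count and
local rate (the boundary policy is not dictated by the procedure's
definition; reflection is this package's declared choice).  Jittering
destroys coupling at timescales below `2h` while preserving slow
co-modulation, which is exactly the confound the test must reject.

Significance at the stated 99.999th percentile of 1000 surrogate values
is implemented as *observed strictly greater than every surrogate*: the
percentile exceeds 1 − 1/1000, so exceeding all surrogates is the only
satisfying event, and the attained p reported by the standard resampling
formula `(1 + #{surrogate ≥ observed}) / (N + 1)` equals 1/1001 ≈ 0.001
in that case.  The p-value can never be zero.  No correction is applied
across half-widths; each is reported per-bin, and users combining them
should correct externally.

Because the synchrony numerator is an integer count over windows whose
total time is fixed by the reference train, surrogate ties with the
observed value are common for sparse trains; ties count against
rejection, so the test is *conservative*: over 5000 replicate pairs of
independent 3/min Poisson trains (30 min each) the empirical rejection
fraction computed by `jitter_null_study` sits at or below the nominal
0.001, within the 3-SE binomial band around it.  Power is checked
separately: for coupling probability ≥ 0.85 at 5-ms lags and ≥ 100
reference events, rejection at `h = 50` ms exceeds 0.9.

`peri_event_histogram` and `fraction_within` provide the descriptive
companions (lag histogram in ±100 ms; fraction of reference events with
a target event within ±100 ms).

# Calcium-activity summaries

The calcium module consumes *deconvolved* activity (cells × frames event
weights, as produced by constrained-NMF source extraction at 10-Hz
imaging), never raw video.  ROI quality filters mirror the standard
criteria: PNR ≥ 8, 30 < size < 300 px, circularity ≥ 0.5 — size bounds
strict, PNR/circularity inclusive, matching the mixed "<" / "minimum"
phrasing of the criteria they implement.  When only spatial footprints
are available, circularity is the standard `4πA/P²` on the footprint
binarized at half its maximum.  Each exclusion is reported with its
reason; the report is the package's substitute for the manual
inspection pass (which removed ~5–10% of cells and cannot be
reproduced algorithmically).

Definitions: a cell's **event rate** is its summed inferred activity
divided by recording time (deconvolved weights are unitless, so rates
are weight/s); a session's **total activity** is the median per-cell
rate times the number of participating cells; **state modulation** is GA
total activity divided by same-day awake total activity.  The simulator
draws per-cell base rates from a log-normal (median 0.1/s, log-sigma
0.8) tied to the seed only, so awake/GA pairs share cells and the
modulation factor is recoverable to within 10% across seeds (Poisson
counting noise only).

# Paired-pulse facilitation

`fepsp_amplitude` measures baseline-to-peak magnitude (the reported
fiducial for these experiments) after subtracting the pre-stimulus
baseline, blanking 2 ms after each stimulus against the artifact.
At the standard 40-ms inter-stimulus interval (25-Hz pairs) the first
response's tail contaminates the second, so `paired_pulse_ratio` by
default fits a single exponential to the first response's tail between
its peak and the second stimulus and subtracts its extrapolation before
measuring the second amplitude; the uncorrected ratio is available.
Whether the source analyses decay-corrected their second responses is
not stated; both are provided, corrected is the default, and the
correction is validated against non-overlapping constructions (200-ms
ISI), recovering generator ratios of 1.24–2.01 within 5% — including
the facilitation regimes of interest (≈ 1.9 intact, ≈ 1.24 impaired).
The ratio is invariant to gain and baseline offset.

# Behaviour and association

`success_rate` is percent correct alternations per delayed-alternation
session.  `spearman_assoc` computes rho on mid-ranks and reports a
two-sided permutation p: full enumeration of all n! permutations for
n ≤ 8, 10⁵ Monte-Carlo permutations for 9 ≤ n ≤ 12, asymptotic t
otherwise — the group sizes typical of these experiments (8–16 mice)
are exactly where asymptotic p-values are unreliable.  The exact
permutation convention here need not match any particular commercial
package, so printed p-values from other software are not reproduction
targets; rho is.

# Determinism, seeds and problem sizes

Every stochastic function takes an explicit seed and restores the
caller's RNG state; identical seeds give identical outputs.  Composite
studies fan one master seed out through a fixed affine derivation
(`seed × 1000 + k mod 2³¹−1`), so module-level streams are reproducible
and decoupled.  The validation studies use 20 recordings × 10 min at
2500 Hz for segmentation accuracy and 5000 replicate pairs × 1000
surrogates for the null-rejection study — sizes at which the binomial
3-SE band around 0.001 is ±0.00134 and each study completes in about a
minute on one CPU; `run_acceptance_suite(scale =)` scales both down
proportionally for quick checks.

# Known limitations

* Synthetic LFP lacks oscillatory burst structure, artifacts and
  nonstationary anesthetic depth; accuracy/precision figures are
  statements about the implementation under the declared model.
* The EDF writer quantizes to the format's 16 bits over each channel's
  observed range; round trips are exact only to that resolution.
* The detector is a single bipolar rule; it does not classify spike
  morphologies or detect ictal (seizure) activity.
* The jitter test's conservativeness under sparse trains means attained
  rejection rates below nominal; this is a property of the exceed-all
  criterion with discrete counts, not an implementation artifact.
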