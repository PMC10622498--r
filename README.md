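# ieskit

Analysis of local field potential (LFP) recordings from anesthetized
rodents, centred on three bespoke computations and their validation on
synthetic ground truth:

* **Burst-suppression segmentation and BSR.** Under general anesthesia the
  LFP alternates between high-amplitude bursts and near-isoelectric
  suppressions.  The signal is band-passed 1–1000 Hz (zero phase), the
  rectified amplitude is averaged in 700-ms bins, and the valley of the
  bimodal bin histogram separates the two states; candidate bursts are
  merged across gaps < 2 s and accepted only if longer than 2 s.  The
  burst-suppression ratio (BSR) is the fraction of time in suppression per
  1-min bin — the depth-of-anesthesia index.
* **Interictal epileptiform spike (IES) detection.** Spikes are detected
  on the z-scored signal, *z* = (*x* − μ<sub>supp</sub>)/σ<sub>supp</sub>
  with both moments taken over the suppression epochs: bipolar threshold
  at |*z*| ≥ 10, acceptance only if the peak-to-peak range within a
  sliding 30-ms window exceeds 10 z, and a 50-ms dead-time.  Rates are
  reported per minute.
* **Jitter-surrogate synchrony test.** Coupling between two regions' IES
  trains (e.g. CA1 and mPFC) is measured as the target-train event rate
  inside merged ±*h* windows around each reference event
  (*h* ∈ {10, 50, 100, 500, 1000} ms).  Each of 1000 surrogates jitters
  every target spike uniformly within ±2*h*; the observed synchrony is
  significant when it exceeds all surrogates (the 99.999th percentile),
  with attained *p* = (1 + #{surrogate ≥ observed})/(*N* + 1) = 1/1001.

Around these sit the supporting assays of the same experimental design:
deconvolved calcium-activity summaries with ROI quality filters
(PNR ≥ 8, 30 < size < 300 px, circularity ≥ 0.5; event rate = summed
activity / time; total activity = median rate × n cells; GA/awake state
modulation), paired-pulse facilitation of evoked fEPSPs with
exponential tail correction at 40-ms ISI, delayed-alternation success
rates, and Spearman rank correlation with exact permutation p-values at
small n.  A seed-deterministic generator
(`simulate_bs_lfp`, `inject_ies`, `simulate_coupled_trains`,
`simulate_ca_matrix`, `simulate_paired_pulse`) emits every input with
full ground truth, so the whole pipeline is testable without any
experimental data.  I/O covers EDF and delimited text for signals, CSV
for events/intervals/behaviour, JSON for parameter sets (see
`FORMATS.md`).

## Worked example

```r
library(ieskit)

# a 10-min synthetic anesthetized recording with spikes injected at 3/min
sim <- simulate_bs_lfp(bs_model(burst_amplitude_sd = 10,
                                suppression_amplitude_sd = 5),
                       duration_s = 600, fs = 2500, seed = 1)
sim <- inject_ies(sim, rate_per_min = 3, amplitude_z = 15, seed = 2)

seg <- segment_bs(sim$recording)
seg
#> <segmentation> 43 bursts, 42 suppressions; suppression fraction 0.298; threshold 4.16 uV

ev <- detect_ies_pipeline(sim$recording, segmentation = seg)
ies_rate(ev, duration(sim$recording) / 60)
#>   channel  n duration_min rate_per_min
#> 1     CA1 25           10          2.5

detection_score(ev$time, sim$truth$ies_times$CA1)[c("precision", "recall")]
#> $precision [1] 1    $recall [1] 1
```

The suppression fraction (≈ 0.30) sits in the 0.2–0.5 BSR band of stable
anesthesia; all 25 injected spikes surviving the 50-ms spacing rule are
recovered with no false positives, so the detected rate equals the
realized injection rate.

Synchrony between two coupled spike trains (90% of target events locked
to a reference event with 5-ms Gaussian lags):

```r
tr <- simulate_coupled_trains(3, 3, coupling_prob = 0.9,
                              lag_jitter_sd_ms = 5,
                              duration_s = 1800, seed = 3)
jitter_test(tr$ref, tr$target, 1800, seed = 4)
#>  half_width_ms observed surrogate_mean surrogate_max significant  p_value
#>             10  35.0000        18.3700       26.8750        TRUE 0.000999
#>             50   7.3925         3.7514        5.2624        TRUE 0.000999
#>            100   3.7386         1.8987        2.5980        TRUE 0.000999
#>            500   0.7593         0.3893        0.5277        TRUE 0.000999
#>           1000   0.3851         0.2168        0.2872        TRUE 0.000999
```

Observed synchrony (events/s inside the merged windows) exceeds every
one of the 1000 surrogates at all half-widths, so the coupling is
significant with the minimal attainable *p* = 1/1001 ≈ 0.001.

`run_ga_session()` chains segment → z-score → detect → rate → synchrony
for a multi-channel recording and returns a reproducible report with a
config-hash provenance block.

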