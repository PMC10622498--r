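# File formats

All delimited files are comma-separated, "." decimal, UTF-8, with a
mandatory header row.  Units are microvolts (µV) and seconds throughout;
time is 0-based from recording start and intervals are half-open
`[start, end)`.  Loaders never resample or rescale, and reject NaN
samples unless interpolation of gaps ≤ 10 ms is explicitly enabled.

## Continuous signals

* **EDF** (`read_edf` / `write_edf`): standard European Data Format,
  16-bit samples with per-channel physical scaling; the sampling rate
  comes from the header and all requested channels must share it.
  Round trips are exact to the 16-bit quantization step
  (channel range / 65535).
* **CSV** (`read_delimited_signal` / `write_delimited_signal`): one
  column per channel; header = channel names; column order = channel
  order; the sampling rate is supplied by the caller.

## Event tables (`read_events_csv` / `write_events_csv`)

Columns: `channel`, `time` (s), then any numeric property columns
(e.g. `peak_z`, `ptp_z`, `polarity`).  Times must be non-negative and
strictly increasing within a channel.  Round trips preserve times to at
least 9 significant digits.

## Interval files (`read_intervals_csv` / `write_intervals_csv`)

Columns: `label` (`burst` or `suppression`), `start`, `end` (s).
Intervals of one label must not overlap; `start < end`.

## Behaviour tables

CSV with columns `mouse`, `day`, `delay`, `trials`, `correct`; consumed
via `success_rate(correct, trials)` per row.  Correlation inputs are
two-column CSVs passed to `spearman_assoc`.

## Parameter sets (`write_run_config` / `read_run_config`)

JSON with blocks `seg` (`segmentation_params`), `det`
(`detection_params`), `jit` (`jitter_params`) and `seed`; every field
has the pipeline default and serialization is lossless.
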