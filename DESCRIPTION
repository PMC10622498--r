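Package: ieskit
Title: Burst-Suppression Segmentation, Interictal Spike Detection and
    Jitter-Surrogate Synchrony Analysis for LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing local field potential (LFP) recordings
    from anesthetized rodents: segmentation of burst-suppression states
    and the burst-suppression ratio (BSR); detection of interictal
    epileptiform spikes (IES) by a suppression-referenced z-score rule
    with a peak-to-peak criterion and dead-time; a jitter-surrogate
    resampling test for millisecond-scale synchrony between two spike
    trains; summaries of deconvolved calcium-imaging activity (ROI
    quality filters, event rate, total activity, state modulation);
    paired-pulse facilitation quantification for evoked field
    potentials; and behavioural alternation and rank-correlation
    statistics.  A seed-deterministic synthetic-data generator emits
    recordings with full ground truth so every stage of the pipeline is
    testable without any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
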