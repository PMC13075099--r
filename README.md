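# fecgeemd

Single-channel fetal ECG extraction by CNN-guided two-stage ensemble
empirical mode decomposition.

## The problem

The fetal electrocardiogram (FECG) carries beat-by-beat timing and QRS
morphology that clinicians use to detect fetal distress and arrhythmias.
Recorded from a single electrode on the maternal abdomen, it is buried under
the maternal ECG (typically 5–10 times larger), electromyographic noise,
baseline wander and power-line interference — and with only one channel
there is no spatial information to separate the sources. This package is for
researchers in biomedical signal processing who need a fully automatic,
reproducible single-channel extraction pipeline together with the synthetic
benchmark data to validate it.

## The method

The pipeline chains five stages:

1. **Preprocessing** — 50 Hz IIR notch (Q = 30) and a fourth-order 0.1–100 Hz
   Butterworth bandpass applied forward–backward (zero phase), realized as
   numerically stable second-order sections.
2. **Maternal template subtraction** — maternal R-peaks are found by an
   integrate-and-threshold QRS detector (amplitude-threshold fallback with a
   500 ms RR floor); a coherent-average template
   `T_m(t) = (1/N_m) Σ_k x(t − t_{m,k})` is placed at every detected peak and
   subtracted.
3. **First EEMD** — the residual is decomposed per 10 s window into at most
   8 intrinsic mode functions (IMFs) by ensemble empirical mode
   decomposition (ensemble size 30, added-noise level 0.2 × sd, from-scratch
   cubic-spline sifting with the Cauchy stop criterion). A 1-D CNN
   (`IMFClassifier1D`-style: five conv–BN–ReLU–pool blocks, kernels
   [31, 21, 15, 11, 7], channels [32, 64, 128, 256, 512], hybrid
   max/adaptive pooling, three fully connected layers; 5.91 M trainable
   parameters) scores each IMF with a fetal-relatedness probability; the two
   top-scoring IMFs form the initial estimate.
4. **Second EEMD** — what stage one left behind is decomposed again and the
   single top-scoring IMF is added back, recovering low-amplitude fetal
   energy.
5. **Output** — a zero-phase 10–60 Hz bandpass and fetal R-peak detection.

Training labels for the CNN come from a scale-invariant rule on each IMF:
label 1 iff the peak-to-peak amplitude near the reference fetal R-peaks
exceeds both `1.4 σ` of the IMF and `0.75 ×` its global peak-to-peak range.
The classifier is trained per held-out subject (leave-one-subject-out) with
Adam (lr 1e-4, weight decay 5e-4), binary cross-entropy on logits, and 2:1
negative resampling. Heuristic (band-energy × correlation) and oracle
(correlation with ground truth) IMF rankings are built in as baselines. The
synthetic generator reproduces a 15-case maternal/fetal simulator grid
(maternal 65–92 bpm, fetal 118–162 bpm, amplitude ratios 1:1.17 to 1:16)
with five-Gaussian PQRST beats, RR/amplitude jitter, and EMG + baseline-wander
augmentation whose overall SNR is held at exactly 10 dB.

The CNN itself (forward pass, backpropagation, batch normalization, Adam) is
implemented in C++ over BLAS inside the package — no external deep-learning
framework is required.

## Worked example

```r
library(fecgeemd)

rec <- synth_clean_aecg(table1_cases()[1, ], duration_s = 20, fs = 250, seed = 101)
rec <- add_noise(rec, noise_spec(seed = 201))   # exact 10 dB augmentation
rec
#> <aecg> case1: 5000 samples @ 250 Hz (20.0 s), 46 fetal / 27 maternal R-peaks, clean components kept

res <- extract_fecg(rec, cfg = extraction_config(selection_mode = "oracle",
                                                 eemd = eemd_config(seed = 3)))
res
#> <extraction_result> 5000 samples @ 250 Hz, 46 fetal R-peaks detected

ref <- butter_bandpass_zerophase(rec$fetal_clean, rec$fs, 10, 60)
cc  <- correlation_cc(ref, res$fecg, rec$fs)
m   <- match_rpeaks(res$fetal_rpeaks, rec$fetal_rpeaks, rec$fs)
sprintf("CC = %.3f, precision = %.3f, recall = %.3f, F1 = %.3f",
        abs(as.numeric(cc)), m$precision, m$recall, m$f1)
#> "CC = 0.924, precision = 1.000, recall = 1.000, F1 = 1.000"
```

`CC` is the lag-tolerant correlation between the extracted waveform and the
10–60 Hz-filtered clean fetal component (0.92: the waveform shape is well
preserved); precision/recall/F1 score detected fetal R-peaks against ground
truth within ±50 ms (here every one of the 46 true beats is found with no
false detections). For CNN-guided selection, build a labeled dataset with
`build_labeled_dataset()`, train with `loso_cv()`, and pass a fold's model as
`model =` with `selection_mode = "cnn"`; `selection_grid_report()` compares
(n1, n2) IMF-selection strategies across cases.

A thin command-line front end is installed at
`system.file("cli", "fecg.R", package = "fecgeemd")` with subcommands
`simulate`, `decompose`, `extract`, `evaluate` and `grid`.

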