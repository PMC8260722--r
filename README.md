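# skewsort

Automatic spike sorting for single-channel extracellular recordings:
adaptive spike detection plus clustering by a finite mixture of
multivariate skew-t distributions.

Sorting extracellular data means recovering *which neuron fired when*
from a continuous voltage trace. The classic recipe — band-pass filter,
threshold, align each waveform on its extremum, cluster a PCA embedding
with a symmetric mixture model — struggles when electrodes drift and
wave-shapes distort: detections become misaligned, noise gets detected as
spikes, and clusters in feature space turn skewed and heavy-tailed.
`skewsort` implements a pipeline built around those failure modes:

* **detection**: zero-phase fourth-order Butterworth band-pass
  (300–3000 Hz), robust noise estimate `sigma_n = median(|r_f|)/0.6745`,
  detection when `m_d + 1` consecutive samples fall below
  `-c_t * sigma_n`, events snapped to the first local minimum within
  1 ms;
* **adaptive cleanup**: statistical filtering (windows whose normalized
  `|mean| > 1` or `sd > 3` are rejected as artifacts/noise) and
  multi-point alignment (waveforms shift by at most `m_shift` samples
  onto data-driven aligning points found as peaks of the spline-smoothed
  histogram of extremum indices);
* **features**: PCA with the dimension chosen adaptively — the smallest
  `n_c` explaining 95% of variance, capped at 15;
* **clustering**: an EM-fitted mixture of multivariate skew-t
  distributions (`ST_p(y) = 2 t_p(y|mu,Sigma,v) T(sqrt((v+p)/(v+d))
  lambda' Sigma^{-1/2}(y-mu) | v+p)`, shared degrees of freedom), with
  the number of units selected automatically by backward pruning of the
  smallest component from `g_max` down to `g_min` and a penalized
  likelihood score;
* **evaluation**: precision/recall under one-to-one 1 ms matching,
  dominant-unit accuracy and purity, a normalized-mutual-information
  spike sorting index (SSI) that folds misses and false alarms into one
  number, a Bayes-optimal reference classifier, and a CA–CA robustness
  regression;
* **simulation**: ground-truthed sessions (four Poisson units, 1 ms
  refractory dead time, 200 s at 40 kHz by default, white Gaussian noise
  at a controlled peak SNR) so the whole pipeline is testable end to end.

The baseline everything is compared against (`mode = "mtd"`) is the
traditional sorter: plain threshold crossing, single-point extremum
alignment, no statistical filtering, and a symmetric t-mixture
(skewness clamped to zero).

## A worked example

```r
library(skewsort)

# simulate 60 s of ground-truthed recording at 15 dB peak SNR
ses <- generate_session(session_config(duration_s = 60, snr_db = 15,
                                       seed = 8))
ses
#> <synthetic_session> 4 units, 60 s @ 40000 Hz, 8823 spikes, SNR 15.0 dB

# run the full pipeline
res <- run_pipeline(ses, pipeline_config(mode = "mstd", seed = 8))
res
#> <sorting_result> mode mstd: 7538 events, g_opt = 3

# score against the ground truth
score_session(res, ses)[, c("precision", "recall", "accuracy", "purity",
                            "g_opt", "ssi")]
#>   precision   recall  accuracy    purity g_opt       ssi
#> 1 0.9812948 0.838377 0.6405299 0.6405299     3 0.2654779
```

Read the columns as: 98.1% of reported events sit within 1 ms of a true
spike (precision); 84% of true spikes were recovered (recall — the
weakest of the four simulated units hovers near the detection threshold
even at this SNR); the mixture search resolved three clusters (the two
most similar units merge at this separation, a known behavior of the
penalized order score discussed in the vignette), so 64% of matched
spikes land in the cluster mapped to their true unit; and the SSI of
0.27 compresses detection and clustering quality into one number
(1 is perfect, 0 unrelated — misses weigh heavily in it).

Recordings on disk are flat binary (int16/float32, little-endian) with a
JSON sidecar, or single-column CSV; see `read_recording()`. A thin
command line lives at `inst/cli/skewsort.R`
(`simulate` / `sort` / `eval` / `reproduce`).

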