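---
title: "Soundscape component analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soundscape component analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(soundclust)
```

This vignette documents the models behind `soundclust`, the parameters
that matter, what the synthetic generator does and does not emulate, and
the choices made where the design was genuinely open.

## The pipeline model

A passive-monitoring campaign produces scheduled 5-minute WAV recordings
per site. The analysis treats each recorded *minute* as the unit of
observation and describes it by a 128-dimensional embedding:

1. **Frontend.** Audio is resampled to 16 kHz and converted to a magnitude
   STFT with a 25 ms periodic Hann window and 10 ms hop (FFT length 512,
   the next power of two above the 400-sample window). A 64-band
   triangular mel filterbank spanning 125–7,500 Hz pools the spectrum, and
   `log(mel + 0.01)` compresses it; the 0.01 offset bounds the log at
   silence. Consecutive non-overlapping runs of 96 frames form one
   0.96 s patch; a trailing partial patch is dropped. These constants are
   the reference configuration of the VGG-style audio embedding family and
   are all exposed through `frontend_params()`. With them, a 300 s
   recording yields `floor((1 + floor((4,800,000 − 400)/160))/96)` = 312
   patches exactly. No amplitude normalization is applied before feature
   extraction; gain therefore shifts log-mel values monotonically.

2. **Embedding.** Each patch maps to 128 numbers. Two backends share one
   interface. The *surrogate* backend standardizes the flattened
   96 × 64 patch and applies a fixed, seeded random 6,144 → 128 projection
   with orthonormalized directions. Random projections approximately
   preserve pairwise distances (Johnson–Lindenstrauss), up to the known
   `sqrt(128/6144)` scale, so cluster structure present in the log-mel
   domain survives; a constant patch maps to the zero vector. The
   *weights-file* backend runs a VGG-style convolutional stack from a JSON
   manifest plus float32 binary; it is optional, and nothing downstream
   depends on which backend produced the vectors. Pre-trained embedding
   releases sometimes post-process vectors (PCA + 8-bit quantization); the
   package defaults to raw float embeddings and exposes a quantize flag,
   off by default.

3. **Aggregation.** Embeddings are averaged over consecutive blocks of 62
   patches (59.52 s ≈ 1 min), which suppresses the high variance of
   sub-second audio. A 312-patch recording gives 5 minute-vectors with 2
   patches unused; dropping the remainder is the only reading consistent
   with "consecutive 1-minute periods". Missing recordings are absent
   rows — proportions downstream are computed over available data, never
   imputed.

4. **Clustering.** Minute vectors are modelled as a K-component Gaussian
   mixture fitted by EM (own implementation; k-means initialization,
   `n_init = 3` seeded restarts keeping the best log-likelihood,
   tolerance 1e-4 on the mean per-sample log-likelihood change, at most
   500 iterations, and a 1e-4 ridge added to every covariance diagonal).
   K is chosen by `BIC = −2·logL + p·ln(n)` over a grid, default 5–200 in
   steps of 5. "Relative minimum" is ambiguous between the global minimum
   and the first dip, so both strategies are implemented
   (`select_k(strategy = "global_min" | "first_local_min")`, global
   minimum by default, ties toward smaller K). Covariances default to
   full (with the ridge) because the projected model draws covariance
   ellipses; a diagonal structure is exposed and is the right choice in
   128 dimensions with few hundred points per cluster — there a full
   covariance costs p ≈ 8,384 parameters per component, so the `p·ln(n)`
   penalty provably exceeds any attainable likelihood gain and BIC
   degenerates to preferring too few clusters, besides the fits being
   singular-prone. The package therefore uses `cov_type = "diag"` in its
   high-dimensional recovery tests and pipeline defaults, and `full` for
   low-dimensional work where ellipses are wanted. One mixture is fitted
   on all sites pooled (clusters are shared across sites); per-site
   fitting is available by filtering the table.

5. **Exemplars and labelling.** For each cluster the 10 assigned minutes
   with the smallest Euclidean distance to the cluster mean are exported
   for human listening (Euclidean, not Mahalanobis — the plain reading of
   "closest to the centre"). Component identity is a human product: the
   cluster → component mapping enters as a CSV validated against the
   closed seven-way taxonomy and the fitted cluster ids, with all
   violations reported at once. For synthetic data only,
   `majority_component_map()` builds the ground-truth mapping by majority
   vote of true source labels within each cluster; it exists for testing
   and is never a substitute for listening on real data.

6. **Summaries.** All four summaries are pure aggregations of the labelled
   minute table. The counting unit is the minute-row (5 per full slot);
   the per-slot heatmap display is recovered by taking the modal component
   within a slot, ties broken by the fixed taxonomy order. Diel
   proportions are normalized per (site, hour) — components sum to 1
   within an hour — because that is the reading consistent with "the
   proportion of components in different hours"; normalization per
   component total is exposed as a flag. Observed strata with zero counts
   of some component report proportion 0; strata with no data at all are
   omitted.

7. **Networks.** For one (site, month), each cluster becomes a daily count
   series (days are the natural sampling unit for month-scale
   co-occurrence; at least 3 days are required). Edges connect cluster
   pairs whose Spearman correlation (average ranks on ties) passes a
   threshold, τ = 0.5 by default and positive-only by default — the
   co-occurrence reading; both are configurable because no canonical
   threshold exists. Zero-variance series produce no edges rather than
   NaNs. Node degree identifies hub clusters.

## The synthetic generator

`make_schedule()` reproduces the campaign design: per site, the first
`slot_s = 300` seconds of every half hour (48 slots/day). Source events
are Poisson: the count for (site, day, hour, source) has rate
`events_per_day × diel_curve[hour]/Σdiel × month_curve[month]/max(month)`,
and each event is placed uniformly inside one of the hour's slots (so
every event is recorded; events that would fall between slots are not
modelled, since they would be invisible to the pipeline anyway).

Default sources (chosen once, as plausible field magnitudes, and not
revisited):

| source | band (Hz) | texture | diel peak | season peak | SNR | events/day |
|---|---|---|---|---|---|---|
| bird | 2,000–8,000 | upward FM bursts 0.1–1 s | 06:00 dawn + dusk bump | Apr–Jun | +20 dB | 200 |
| insect | 3,000–6,000 | AM tone, 60–240 s | night | Aug max | +15 dB | 80 |
| rain | 100–11,000 | band-limited noise, 120–300 s | flat | flat | +10 dB | 12 |
| anthro | 60–1,500 | harmonic stack, 5–30 s | daytime | flat | +10 dB | 15 |

The bird and insect bands are disjoint enough to separate but overlap
enough (3–6 within 2–8 kHz) to be non-trivial. The noise floor is
Gaussian at −50 dBFS; 200 bird events/day concentrates roughly 17 songs
into the peak dawn hour, a modest dawn chorus. Rendering is a pure
function of (schedule, site, slot, sr, seed); peak amplitude is clipped
to ≤ 1 and no source is synthesized above its band, hence never above
Nyquist for any admissible rate (the renderer refuses rates below twice
the highest band edge). Event textures are stationary, so events are
rendered only over their slot overlap.

What the generator does **not** emulate: species-specific call structure,
reverberation and propagation loss, overlapping-source masking
psychoacoustics, recorder self-noise spectra, or clock drift. Passing
recovery tests therefore shows that the pipeline recovers planted
spectro-temporal structure — not that it resolves every mixture a real
forest produces (mixed clusters were a stated limitation of manual
identification too).

`synth_embedding_dataset()` bypasses audio entirely: cluster means have
coordinates i.i.d. N(0, separation²/2), giving expected pairwise centre
distance `separation·√dim`, with unit spherical covariance around them —
so `separation` reads as a per-coordinate displacement scale, separation 0
collapses all clusters, and the warning at `n_per_cluster < dim + 1`
flags singular-covariance risk for full-covariance fits.

## Numerical choices

* Resampling is band-limited spectral truncation by default (exact for
  band-limited signals, fast for long clips), with the `signal` package's
  polyphase FIR resampler selectable; the two differ at the 1e-3 level
  and the choice is a config key. FFT lengths are padded to 2-3-5-smooth
  sizes so arbitrary clip lengths cannot hit slow mixed-radix cases.
* PCA for the 2-D projection is fitted on the full minute table (not the
  K centres — 95 points would be an unstable basis), centred but not
  variance-scaled (embedding dimensions share a scale; a standardize flag
  exists). Loadings fix their sign by making the largest-magnitude
  coordinate positive, so results are reproducible across BLAS builds.
  Projected covariances are the congruence `W Σ Wᵀ`; ellipse axes are
  `2·sqrt(eigenvalues)` (two standard deviations).
* The surrogate projection fixes QR signs (positive R diagonal) for the
  same reproducibility reason.
* EM covariance singularities escalate the ridge by 100× once before
  failing with advice to switch to diagonal covariances.
* All randomness flows from explicit integer seeds; child seeds are
  derived per (restart, slot) with a fixed linear-congruential map kept
  inside the signed 32-bit range.

## Problem sizes used in the shipped tests

The test-suite runs the full audio pipeline at reduced scale, chosen as
the smallest sizes at which every recovery property is still
comfortably detectable: 60 s recording slots (one minute-vector per
slot), one site, 1–3 days (48–144 recordings), BIC grids of 3–7 values
of K, and 16–128 feature dimensions depending on the property. The
sweep default (5–200 by 5) is the campaign-scale setting.

## Known limitations

* The weights-file backend expects a converted checkpoint (JSON manifest +
  float32 binary); converting a published checkpoint is a one-off step
  outside the package, and no shipped test depends on real weights.
* BIC with full covariances is unreliable in high dimensions at desk-scale
  sample sizes (see above); use `diag` there.
* The Spearman networks report degree only; community structure and edge
  significance testing are out of scope.
* Site percentages and cluster inventories from a real campaign depend on
  the recordings themselves; the package reproduces the pipeline's
  arithmetic and its behaviour on synthetic ground truth, not any specific
  field inventory.
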