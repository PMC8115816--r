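---
title: "Measuring behavioural change as prediction error: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring behavioural change as prediction error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormpred)
```

## The problem and the model

Modern pose tracking reduces a crawling *C. elegans* to a short vector of
eigenworm coefficients per video frame: the body's 100 segment tangent
angles are projected onto an orthonormal basis of principal components, and
five coefficients `a1..a5` capture essentially all postural variation.
Forward and backward crawling trace an approximately circular orbit in the
(a1, a2) plane; tight turns appear as large transient excursions of a3.

`wormpred` asks a dynamical question of these series: *is the worm still
moving the way it used to?* The package answers it with one-step prediction
error against a reference attractor:

1. **Delay embedding.** Each time point of a reference *library* interval is
   represented by the concatenation of `E` successive poses spaced `tau`
   samples apart — a `K*E`-dimensional point (25 dimensions with the default
   `E = 5`, `K = 5`). The temporally ordered embedded points trace a
   trajectory; with an adequate `E` this trajectory is an empirical
   attractor of the behaviour in the library.
2. **S-Map prediction.** For an out-of-sample query point, every library
   point is weighted by `w_i = exp(-theta * d_i / dbar)`, where `d_i` is the
   Euclidean distance in embedding space and `dbar` is the query's mean
   distance to admissible library points. One weighted linear map per
   coefficient, fitted jointly by SVD on a shared design matrix, is
   evaluated at the query to predict the pose one step ahead.
   `theta = 0` collapses to a single global linear (autoregressive) model;
   larger `theta` lets the fitted map follow local attractor structure, so
   nonlinearity in the dynamics is exploited rather than assumed.
3. **Error metric.** Predicted and observed coefficients are mapped through
   the eigenworm basis to 100 body-section angles, and the per-sample RMS
   angle error (radians) quantifies how far the observed dynamics have
   departed from the dynamics encoded in the library. The same error over
   five contiguous 20-angle regions localises the departure along the body
   (region 1 = head, region 5 = tail). The *constant predictor* — "the next
   pose equals the current pose" — provides the baseline any informative
   predictor must beat.

Both the embedding and the prediction horizon default to one sampling
interval (`tau_steps = Tp_steps = 1`), maximising temporal resolution:
an error value is attached to the lag-0 time of its query point and
describes the pose predicted one step later. For very high frame rates,
where persistence becomes nearly exact, both can be doubled at a cost in
time resolution.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `E` | 5 | poses | embedding dimension; the scan utilities show error is flat over a wide range, with `E > 1` clearly better than none |
| `theta` | 2 | — | S-Map locality; 0 = global linear; mid-range values tolerate transient nonlinearity without overfitting |
| `tau_steps`, `Tp_steps` | 1 | samples | lag spacing and prediction horizon |
| `svd_rcond` | 1e-8 | — | relative singular-value cutoff of the least-squares solve |
| `exclusion_steps` | 0 | samples | Theiler window for same-source prediction |
| `a3_threshold` | 10 | — | tight-turn gate (15 flags only extreme delta-turn excursions) |
| `epsilon` | 0.1 | rad/s | minimum \|phase velocity\| for a motion label |
| `delta` | 3 | — | minimum (a1, a2) amplitude for a motion label |

`E = 5` and `theta = 2` are deliberately mid-range: large enough to resolve
hidden state and transient nonlinearity, small enough that the scan curves
produced by `robustness_scan()` remain flat around them.

## The behavioural classifier

The classifier is an *approximate, independent* context signal, not part of
the error metric. The phase velocity in the (a1, a2) plane is estimated by
a central difference of the two-quadrant arctangent
`arctan(a2/a1)`; because that arctangent advances by pi (not 2 pi) per half
rotation, the raw difference `alpha` jumps at branch crossings. The rule
`|omega| = min(|alpha|, pi - |alpha|) / (2 dt)`, with the sign flipped
whenever the second branch is the smaller one, undoes those jumps exactly as
long as the true rotation per `2 dt` is below half a turn. Two reading
choices deserve note:

* The min rule is applied to `|alpha|`. As a difference of principal values,
  `alpha` lies in (-pi, pi) and can be negative, so the rule is only
  well-formed after taking magnitudes; the sign is carried separately.
* `omega` is reported with positive = counterclockwise (phase increasing),
  and the default `forward_positive = TRUE` labels positive `omega` as
  forward — the same convention the synthetic generator uses for its
  ground truth. Recordings in which forward crawling rotates clockwise in
  their (a1, a2) coordinates should set `forward_positive = FALSE`.

Samples where `a1` is exactly zero at a stencil point, or where a stencil
pose is missing, get an undefined `omega`; the first and last samples are
always unclassified. The tight-turn rule `|a3| > a3_threshold` needs no
phase velocity and takes precedence everywhere.

## What the synthetic generator emulates — and what it does not

`generate_series()` produces the structural features the method needs to be
tested against, with exact ground truth:

* a limit cycle `a1 = A cos(phi)`, `a2 = A sin(phi)` with piecewise-constant
  signed phase velocity (forward/backward crawling and reversals);
* Gaussian a3 bumps (tight turns), with configurable centre, width and peak;
* missing-sample gaps (`NA` rows, never deleted rows), as pose trackers
  produce during self-occlusion;
* localized dynamic anomalies: inside a chosen window, a1 and a2 are blended
  toward their swap, `a1' = (1-m) a1 + m a2` and symmetrically. This changes
  the *direction* of motion through pose space — precisely the kind of
  change a prediction-error detector must flag — without changing the pose
  amplitude distribution, which additive noise would.
* independent additive Gaussian noise per coefficient per sample (default
  `noise_sd = 0.25`, about 5% of the default cycle amplitude `A = 5`,
  chosen as a realistic tracker-jitter scale).

What it does **not** emulate: pose-dependent (multiplicative) tracking
noise, the broadband variability of real crawling, rate-shape coupling,
self-intersecting postures, or any strain-specific statistics. A green test
suite on this generator shows the machinery is correct and sensitive under
controlled dynamics; it does not certify effect sizes on real recordings.

For chaotic-dynamics benchmarks the package uses a partially observed
Lorenz flow (`make_lorenz_series()`): observing only x leaves the state
ambiguous at `E = 1`, so prediction error falls steeply with embedding
dimension — the cleanest demonstration that the delay embedding, not the
regression, carries the method. A Hénon-map generator is included for fast
shape/determinism tests; note that at `theta = 2` the Hénon map's strong
curvature dominates its partial-observability gain, which is why the
Lorenz series is the benchmark of record here.

## Numerical choices

* **Least squares by SVD.** Each local fit solves the weighted system
  through an SVD with relative cutoff `svd_rcond = 1e-8`. On synthetic
  limit cycles the 25-dimensional embedding is rank-deficient (the cycle is
  planar), and the cutoff makes the minimum-norm solution well-defined and
  reproducible. Tests pin the implementation to an independent brute-force
  pseudo-inverse oracle at 1e-8.
* **Weight normalisation.** `dbar` is the mean distance from the query to
  its admissible library points, recomputed per query. If `dbar = 0` or
  `theta = 0`, all weights are 1 (degenerate neighbourhoods fall back to a
  global fit rather than erroring).
* **Temporal exclusion.** When library and query share a source series,
  library points within `exclusion_steps` samples of the query's time index
  are inadmissible; at the default 0 this still excludes the query's own
  time point. The reference analyses always predict from disjoint
  intervals, so the default matters only for self-prediction diagnostics.
* **Indexing.** Sample indices are 1-based throughout, matching both R and
  the 1-based frame ranges in which tracking intervals are conventionally
  quoted: a file's frames 10001–11000 are `interval = c(10001, 11000)`.
* **Master embeddings for E scans.** Scanning E naively changes which
  samples yield valid points. `robustness_scan()` therefore embeds once at
  the largest E and evaluates smaller E on lag-block subsets
  (`subset_embedding()`), so every grid cell uses the identical point set.
* **Byte-stable outputs.** Workflow tables are written with fixed
  12-significant-digit formatting, making reruns byte-identical and fit
  for regression testing.
* **Robustness grids use coefficient-space RMS** (not angle-space), so
  series recorded under different coordinate conventions can be scanned
  side by side; everything else reports angle-space radians.

## Problem sizes in the shipped tests

The test-suite and acceptance analyses use 1000-point libraries with
500-point prediction sets for the limit-cycle and anomaly studies (the same
library size as the reference foraging analyses), 100 seeded anomaly trials,
500/500 splits of a 1200-sample Lorenz series for the embedding-dimension
scan, and a 30 s, 20 Hz synthetic escape series (stimulus at 10 s, so the
80% pre-stimulus library is exactly 160 samples, i.e. 8 s). These sizes were
chosen so the full suite exercises every code path at realistic scale while
remaining quick to run on a laptop.

## Known limitations

* Rate and shape are coupled: the same pose sequence executed at a
  different speed embeds elsewhere, and will read as elevated error. This
  is inherent to fixed-interval delay embeddings; a rate-normalised
  embedding is out of scope here.
* The error is only meaningful relative to its library. A library that
  under-samples a behaviour makes that behaviour "anomalous" by
  construction — which is why the workflows always emit the classifier
  output and the constant baseline alongside the error.
* The classifier is a coarse guide: no smoothing, no hysteresis, and a
  hard amplitude gate. It is intended to annotate error traces, not to
  serve as an ethogram.
* Real-data validation requires the eigenworm basis shipped with the
  recordings; the synthetic basis is a stand-in with the right structure
  (orthonormal, increasing spatial frequency), not an estimate of any
  real basis.
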