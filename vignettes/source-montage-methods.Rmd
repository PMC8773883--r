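---
title: "Regional source montages for MEG review: model, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional source montages for MEG review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megmontage)
```

## The problem

Whole-head MEG systems record hundreds of channels (306 in the triple-sensor
layout this package emulates: 102 magnetometers and 204 planar
gradiometers), and reviewing continuous recordings for epileptiform
discharges means paging through many channel selections. A *source montage*
replaces the sensor channels with a small, fixed set of virtual source-space
channels: a stored linear inverse operator is applied sample by sample to
the raw data, yielding the waveforms of 29 regional sources distributed
over the cortex. This package builds that operator, simulates test data
with known ground truth, and quantifies when simulated activity is
detectable from the montage channels.

## The model

At one time sample the sensor vector $b_t \in \mathbb{R}^M$ relates to the
source component vector $s_t \in \mathbb{R}^P$ through the lead field
$L$ ($M \times P$) plus noise:

$$b_t = L\, s_t + n_t.$$

Each regional source contributes two columns to $L$: in a spherical
conductor only tangential current dipoles produce external magnetic
fields, so a location's source space is spanned by the spherical tangential
unit vectors $(e_\theta, e_\phi)$ and $P = 2 \times 29 = 58$. The forward
kernel is the closed-form field of a current dipole in a homogeneous
conducting sphere (Sarvas form); planar gradiometers are modeled as
two-point finite differences of the radial field component at the physical
16.8 mm baseline, which is how the physical sensors are constructed.

The stored inverse whitens channels by their noise, compensates the depth
bias, and regularizes. With the diagonal whitener
$W_b = \mathrm{diag}(1/\sigma_i)$ (defaults $\sigma = 200$ fT for
magnetometers, $50$ fT/cm $= 5\times10^{-12}$ T/m for gradiometers) and
depth weights $W_s$ holding the column norms of $W_b L$, the normalized
lead field $L_n = W_b L W_s^{-1}$ has $\mathrm{diag}(L_n^T L_n) = I$, and

$$\hat s_t = W_s^{-1} \left(L_n^T L_n + \lambda I\right)^{-1} L_n^T W_b\, b_t
  = W_s^{-1} G^{-1} L_n^T W_b\, b_t .$$

Because the Gram matrix $G$ has a unit diagonal before regularization,
$\lambda$ reads directly as a percentage (2% $= 0.02$). The
de-normalization by $W_s^{-1}$ makes the outputs physical source
amplitudes in A·m. The condition number of $G$ (eigenvalue ratio) is the
stability diagnostic; it decreases strictly as $\lambda$ grows.

Three display modes reduce the 58 component waveforms: raw components, the
per-location RMS, and the principal orientation: per location the $2\times2$
second-moment matrix of the component pair over an analysis window is
eigendecomposed, and the leading eigenvector — the maximum-variance dipole
orientation for that window — projects the pair to a single trace. The
orientation must be re-estimated per analysis window; ties between
near-degenerate eigenvalues (ratio below $1+10^{-9}$) resolve to the
$e_\theta$ axis, and the sign is fixed so the in-window peak is positive.

## Synthetic geometry

No proprietary geometry ships with the package:

* **Helmet** — 102 sites on a Fibonacci lattice over a spherical cap
  (half-angle 2.2 rad, radius 120 mm), each site carrying a radial
  magnetometer and two orthogonal tangential planar gradiometers. The
  layout is deterministic.
* **29-region layout** — the montage's published coordinates are not in
  the public domain, so a documented canonical stand-in is used: 5 midline
  and 12 left/right paired regions on a 70 mm shell, labels in the style
  of the field's montage figures (`FpM`, `FC6R`, `TPL`, ...). Real
  coordinates can be substituted from JSON (`read_source_set_json()`).
* **Cortical grids** — per hemisphere, a subdivided octahedron sphere
  (level 5: 4098 vertices) of radius 60 mm shifted 6 mm laterally. A
  smooth sphere's normals are nearly radial with respect to the head
  center, and radial dipoles are silent, so a plain sphere cannot stand in
  for folded cortex. The grid therefore carries a synthetic folding
  orientation field: each vertex normal is tilted from radial by
  $\psi = f\,\theta$ about the rotating tangential azimuth
  $\chi = f\,\phi$, with $f = 10$ obliquity cycles pole-to-pole
  (fold wavelength ~19 mm on the 60 mm sphere, gyral scale). Patch normals
  thus sweep every obliquity, like gyral crowns and sulcal walls.

What the synthetic data do *not* emulate: real resting-state background
(rhythms, 1/f structure, artifacts — the background is white noise at the
nominal channel level, band-limited by the shared 2–70 Hz filter), real
cortical folding statistics, subject-specific head position, or sensor
calibration errors. Passing tests therefore demonstrate the correctness
and qualitative behavior of the operator and the evaluation chain, not
clinical performance on recorded data.

## Simulated signals

Each simulated source emits 4 cycles of a 20 Hz sinusoid (200 ms) once per
second, peak amplitude 100 nAm, placed in the last 200 ms of each 1 s
epoch so the preceding 800 ms is a clean baseline. Sampling is 1000 Hz
(typical MEG; 200-ms bursts = 200 samples) for 10 s = 10 epochs. All data
are band-passed 2–70 Hz with a zero-phase (forwards–backwards) order-4
Butterworth — the band is part of the protocol, the filter shape a
package choice. Three scenarios:

1. **Montage locations** — one tangential dipole per montage location,
   moment $100\ \mathrm{nAm} \cdot (e_\theta + e_\phi)/\sqrt{2}$ (the
   stated direction normalized to unit length so the source magnitude is
   100 nAm, consistent with the 100-nAm recovery at $\lambda = 0$).
2. **Fifty tangential dipoles** — the original 50 cortical test positions
   are unpublished; 25 seeded positions per left hemisphere at radii
   30–72 mm (a depth spread driving the distance analysis) are mirrored to
   the right, each with a random tangential moment.
3. **Cortical grid** — per grid vertex, a patch of the vertex plus its
   1-ring neighbors, each dipole along its local (folded) normal, total
   moment 100 nAm split equally. At level 5 that is 4098 patches per
   hemisphere; the package's scaled-down studies use level 3
   (258 per hemisphere), where patches are coarser (~26 mm across) than
   the 1–2 cm² patches of a dense surface.

## SNR and detectability

Per epoch, with the baseline mean $\mathrm{ave}_k$ of channel $k$,

$$\mathrm{SNR}_k = 20 \log_{10}
  \frac{\tfrac{1}{s_2 - s_1}\sum_{t=s_1}^{s_2} (b_k(t) - \mathrm{ave}_k)^2}
       {\tfrac{1}{r_2 - r_1}\sum_{t=r_1}^{r_2} (b_k(t) - \mathrm{ave}_k)^2},$$

averaged over the 10 epochs. The prefactor 20 on a *power* ratio is
implemented exactly as the statistic is printed in the field's usage,
although the conventional dB form of a power ratio uses 10; switching
would change every dB number, so the printed convention is kept
throughout. A zero-power baseline yields an `Inf` sentinel so noiseless
fixtures remain expressible. Source-level SNR (`SNR2`) and the
detectability count `Ndt` (channels at or above the 15 dB visual
threshold, inclusive) are computed on the 29 principal-orientation
waveforms, orientation re-estimated per epoch from its signal window.

The **amplitude readout** at the best-SNR montage channel is the peak
absolute value, within the signal window, of the *epoch-averaged*
principal waveform (orientation from the pooled signal-window covariance).
Averaging time-locked epochs before peak-picking matters: taking the peak
of each noisy epoch and averaging the peaks is upward-biased by the
montage background noise (about +14 nAm at $\lambda = 0$ under the default
study conditions), whereas the averaged-epoch peak reads ~104–106 nAm for
a 100 nAm source — the residual few percent being the peak bias of the
10-fold-averaged noise.

## Numerical choices

* $G$ is solved with the standard dense symmetric solver; $\lambda = 0$ is
  allowed and warns when the condition number exceeds $10^{12}$. A source
  component with a zero-norm lead-field column (magnetically silent) is a
  named error.
* The study driver filters the background and the burst waveform once and
  recombines them per source; because the filter is linear and
  time-invariant and a fixed source's contribution is rank-1 in time, this
  equals the direct simulate-superpose-filter-apply path to rounding
  error (asserted in the tests).
* Epoch segmentation starts at $t = 0$; partial trailing epochs are
  dropped. Ties in best-channel selection resolve to the larger amplitude
  (relevant only for the noiseless `Inf` sentinel), then the lowest index.
* The tangential basis uses standard spherical coordinates about the
  sphere center with the $+z$ pole; on the polar axis it falls back to
  $(\hat x, \hat y)$. Any fixed orthonormal tangent pair is equivalent for
  the montage.

## Worked example

A minimal end-to-end run (the quantities printed here are computed by this
code, at reduced duration so the vignette stays light):

```{r example}
sphere <- sphere_model()
helmet <- make_synthetic_helmet()
regions <- make_br29_locations(sphere)
L <- build_leadfield(regions, helmet, sphere)
op <- build_montage(L, default_noise_model(helmet), lambda_frac = 0.02)
op
condition_number(op)

scn <- run_scenario(scenario_spec("montage_locations", duration = 4,
                                  seed = 2), helmet, regions, sphere)
rec <- scenario_recording(scn, 5)                  # 5th montage location
wf <- apply_montage(op, rec)
readout <- amplitude_readout(wf, snr_windows())
c(best = readout$label, truth = scn$sources[[5]]$label,
  amp_nAm = round(readout$amp * 1e9, 1), snr2_dB = round(readout$snr2, 1))
```

## Known limitations

* The spherical conductor ignores skull anisotropy and realistic head
  shape; only MEG (not EEG, which needs three orientations per region and
  a layered conductor) is covered.
* The canonical 29-region coordinates are a stand-in, not a reproduction
  of the published montage; absolute SNR values depend on the geometry and
  should be compared across conditions, not across implementations.
* The background noise model is spatially white; real interference is
  correlated across channels. A full noise covariance is supported in the
  whitener, but no estimator for one is included.
* Only scalar regularization $\lambda I$ is implemented; the general
  diagonal regularizer is not exercised.
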