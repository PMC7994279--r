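---
title: "Methods: NCC speckle tracking for diaphragm deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NCC speckle tracking for diaphragm deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckletrack)
```

## The problem

The diaphragm is the principal muscle of respiration, yet bedside tools for
quantifying its contractile function are limited: M-mode ultrasound measures
motion along a single beam line only, and B-mode shows structure but not
mechanics. Speckle tracking treats the granular interference pattern of
ultrasound images as a material fingerprint: by following speckle patches
from frame to frame, one recovers the two-dimensional motion of the tissue
itself, from which displacement curves and strain — the relative change in
length of the muscle — can be derived.

`speckletrack` implements this pipeline for B-mode cine loops of the
diaphragm: normalized cross-correlation (NCC) block matching for interframe
displacement, Lagrangian accumulation of those fields into material-point
trajectories, drift correction of the cumulative curves over the breathing
period, and global strain over a manually traced region-of-interest (ROI)
polyline. A synthetic speckle phantom with analytically known motion
provides ground truth for every stage.

## Interframe displacement by block matching

For each node of a regular grid, a kernel-sized template centred on the node
in frame $N$ is compared against every placement inside a search region in
frame $N+1$ using the zero-normalized cross-correlation coefficient

$$\rho(\Delta x, \Delta y) \;=\;
\frac{\sum_{i,j} (a_{ij} - \bar a)(b_{ij} - \bar b)}
     {\sqrt{\sum_{i,j}(a_{ij}-\bar a)^2\;\sum_{i,j}(b_{ij}-\bar b)^2}},$$

which lies in $[-1, 1]$ and is invariant to local gain and offset — the
right similarity measure for ultrasound, where overall brightness varies
with depth and gain settings. The displacement at the node is the lag of the
correlation maximum. Flat (zero-variance) windows make the coefficient
undefined; such nodes are flagged invalid rather than propagating NaNs.

Subpixel accuracy comes from interpolating *both* the image lines and the
correlation surface:

* both frames are upsampled along the lateral (column) axis by a small
  integer factor (default 5) with cubic splines, because lateral line
  density of clinical loops is low and factors of 3–5 are the best
  accuracy/cost trade-off;
* the correlation surface is upsampled around its integer peak (default
  factor 5, separable cubic) and a parabolic vertex fit through the refined
  maximum gives the final real-valued lag.

Two further measures proved necessary on 8-bit envelope data and are part
of the default configuration:

* **axial image interpolation** (`axial_interp_factor`, default 3). The
  axial speckle grain of log-compressed B-mode data is only marginally
  sampled; with correlation-surface refinement alone, subpixel *vertical*
  motion is systematically pulled toward integer lags (pixel locking).
  Upsampling the image lines along depth — exactly the treatment the
  lateral axis already receives — removes most of that bias.
* **pre-smoothing** (`presmooth_sigma_px`, default 0.8 px). Gray-level
  quantization of 8-bit data correlates with the pixel grid and locks
  refined peaks toward integer lags, whereas the raw (unquantized)
  envelope does not show the effect. A sub-pixel Gaussian blur is the
  standard countermeasure, at negligible resolution cost. The subpixel
  accuracy the defaults achieve is what the half-pixel-shift and
  breathing-amplitude checks in the test suite measure.

Both measures can be disabled (`axial_interp_factor = 1`,
`presmooth_sigma_px = 0`) to recover the plain estimator.

Ties between equal correlation maxima are broken toward the smallest
Euclidean lag norm, then smallest row, then smallest column — the
least-motion candidate — so results are deterministic. A peak on the border
of the search region cannot be refined and flags the node; a perfect match
(coefficient exactly 1) is returned unrefined, since interpolation around
an exact-1 peak could only move it off the true lag.

### Defaults

| Parameter | Default | Meaning |
|---|---|---|
| `kernel_size_px` | 17 × 17 | template around each grid node, px |
| `search_margin_px` | 10 × 10 | detectable displacement range, px |
| `lateral_interp_factor` | 5 | lateral image upsampling |
| `axial_interp_factor` | 3 | axial image upsampling |
| `corr_surface_interp_factor` | 5 | correlation-surface upsampling |
| `presmooth_sigma_px` | 0.8 | anti-pixel-locking blur, px |
| `min_correlation` | 0.5 | peak-quality gate |
| `grid_spacing_px` | 8 × 8 | node spacing |

Kernel and search sizes are sized to the phantom's speckle scale (the
clinical source never states the values it used); everything is
configurable. Coordinates are origin top-left, $x$ = column (lateral,
+right), $y$ = row (axial, +down); displacements stay in px and convert to
mm only at reporting time via the pixel spacing.

## Continuous (Lagrangian) tracking

Displacement fields live on the fixed grid, but tissue moves. A tracked
point that sits at $(x, y)$ at frame $N-1$ has moved to
$(x' , y') = (x + U_1, y + V_1)$ by frame $N$; its next increment must
therefore be the frame-$N$ field evaluated *at the moved position*, which
is obtained by bilinear interpolation from the four surrounding grid nodes
(invalid nodes are excluded with renormalized weights). The cumulative
displacement is the prefix sum of these increments, so the position at any
frame is exactly the initial position plus the cumulative displacement. A
point whose trajectory leaves the image is frozen and flagged from that
frame onward — extrapolated fields would be meaningless and failures must
stay visible.

## Drift correction

Estimation errors accumulate along the cumulative curves. Over one
breathing period $T$ the diaphragm returns to its initial state, so any
cumulative displacement or strain curve should close: $S(T) = 0$. The
correction subtracts a ramp inside the first period and a constant after
it:

$$S_{\mathrm{corr}}(t) = \begin{cases}
S(t) - \dfrac{S(T)}{T}\,t, & 0 \le t \le T\\[4pt]
S(t) - S(T), & t \ge T.
\end{cases}$$

$S(T)$ is obtained by linear interpolation between the two frames
bracketing $T$; both branches agree at $t = T$, where the corrected curve
is zero by construction. When $T$ falls between frames, the ramp branch is
applied through the first frame at or beyond $T$, which makes the linearly
interpolated corrected curve vanish at $T$ exactly; the two expressions
differ at that single frame by $O(\Delta t \cdot \text{drift})$. Records
longer than one period keep the constant-subtraction branch (re-anchoring
subsequent cycles is deliberately not done — the formula defines a single
$T$).

Clinically the period is read off M-mode imaging and passed as
`period_T_s`; that value always wins. When it is absent,
`estimate_period()` first-differences the curve (differencing removes
linear drift without distorting the periodic component, unlike fitting and
subtracting a least-squares line over a finite record), takes the first
prominent maximum of the unbiased autocorrelation as a coarse lag, and
refines it by minimizing the residual of a harmonic regression
(fundamental + second harmonic + linear drift). On sampled sinusoids the
refined period is accurate to well under one frame; the estimator refuses
curves without a prominent periodicity instead of guessing. It needs at
least about 1.5 cycles of data — on a record of exactly one cycle the
period must be supplied.

## ROI and global strain

The diaphragm ROI is traced manually as a dense ordered point list (the
package reads CSV or JSON traces). The working polyline keeps every
$k$-th point ($k \in \{1, 3, 5, 10\}$ are the clinically examined
spacings) *and always the last point*, so the polyline spans the same
anatomy at every spacing — otherwise coarser sampling would shorten the
measured length and bias the strain comparison. Global strain at frame $t$
is

$$GS = \frac{L_t - L_0}{L_0} \times 100\,\%$$

with $L$ the sum of Euclidean distances between consecutive tracked ROI
points. Shortening (contraction) is negative by this definition; reports
quote the signed curve plus its peak-to-peak magnitude. Lengths are
measured in px when the pixel spacing is isotropic and converted to mm per
axis first when it is not, since the length ratio is unit-free only under
isotropy.

Interframe displacement scales inversely with the frame rate, so loops
acquired at different rates are made comparable by
$D_{\mathrm{norm}} = (FR / FR_{\max})\, D$, with $FR_{\max}$ the highest
acquisition rate among the loops being compared. Per-point curves are
aggregated frame-wise across the ROI by the median (default; robust to
stray points) or the mean, and each curve is summarized by its
peak-to-peak value over one breathing cycle.

## The synthetic phantom

Real diaphragm loops with ground-truth motion do not exist, so validation
uses a speckle phantom in which the motion is known in closed form:

* Scatterers are placed uniformly at random over the image padded by the
  maximum motion amplitude plus three PSF sigmas (motion never imports
  empty space), at a density of 10 per resolution cell
  ($2\pi\sigma_{ax}\sigma_{lat}$) — enough for fully developed speckle.
* Each scatterer carries a unit-mean Rayleigh amplitude and a uniform
  random phase. The complex amplitudes are splatted bilinearly onto the
  grid, convolved (FFT) with an anisotropic Gaussian PSF
  ($\sigma_{ax} = 1.5$, $\sigma_{lat} = 2$ px), and the modulus is taken:
  the sum of many independent phasors per resolution cell gives a circular
  complex Gaussian field, hence a Rayleigh envelope with the
  fully-developed-speckle SNR $\sqrt{\pi/(4-\pi)} \approx 1.91$, which the
  tests check.
* The envelope is log-compressed over a 45 dB dynamic range (the clinical
  acquisition range) about a fixed rest-frame reference and quantized to
  8-bit gray levels, mimicking B-mode DICOM output.

Three motion models cover the validation needs: rigid translation
(strain-free by construction), uniform lateral stretch with a linear ramp
($GS = 100\,\varepsilon(t)$ exactly for a horizontal ROI), and a breathing
sinusoid with independent horizontal and vertical amplitudes. Defaults are
256 × 256 px frames at 30 Hz, a 3 s breathing period with $A_u = 6$ px
horizontal and $A_v = 3$ px vertical — horizontal-dominant motion, as
observed for the diaphragm in vivo, over roughly one ~3 s respiratory
cycle. Displacement is evaluated at each scatterer's rest position, so the
rendered motion matches the analytic displacement field exactly; identical
spec and seed reproduce a sequence bit for bit.

What the phantom does **not** emulate: RF-domain effects (beamforming,
phase cancellation under compression), attenuation and shadowing,
out-of-plane motion, anatomical structure around the diaphragm, probe or
breathing irregularity. Passing the phantom tests therefore demonstrates
the correctness and subpixel accuracy of the algorithms under clean
fully-developed speckle, not clinical-grade robustness on patient loops.

## Numerical choices

* Cubic splines (`stats::spline`, FMM end conditions) for all image-line
  interpolation; values at original samples are preserved exactly and
  linear data are reproduced.
* NCC is computed in compiled code with integral-image window sums; it
  matches a textbook double-loop implementation to $10^{-10}$ on random
  instances (this equivalence is part of the test suite).
* Degenerate inputs fail loudly and early: flat templates, empty grids,
  zero-length polylines, periods outside the record, frame rates above
  $FR_{\max}$, missing DICOM metadata without an override.
* Problem sizes in the validation runs — 256 × 256 phantoms, one 91-frame
  breathing cycle, 21-frame stretch ramps, grids of a few hundred nodes —
  were chosen as the smallest instances on which subpixel accuracy and
  cycle closure are meaningfully exercised.

## Known limitations

* Tracking quality on clinical loops depends on burnt-in annotations
  (crop them via `run_config(crop = ...)`), probe motion, and the low
  frame rates of abdominal presets; none of these are modelled by the
  phantom.
* The DICOM reader handles uncompressed little-endian transfer syntaxes
  (explicit and implicit VR), multi-frame files and single-frame
  directories; compressed (encapsulated) pixel data is rejected with a
  clear error.
* Strain is global over the ROI polyline; regional strain and strain rate
  are out of scope.
* The period estimator assumes a quasi-periodic curve and at least ~1.5
  cycles of record; irregular breathing should use an externally measured
  period per cycle.
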