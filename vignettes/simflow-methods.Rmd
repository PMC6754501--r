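---
title: "simflow: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{simflow: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(simflow)
```

simflow is a self-contained software model of a video-rate two-beam
structured illumination microscope (SIM) with immediate, streaming
reconstruction. This vignette documents the forward model, the
estimation and reconstruction algorithms, every tunable that matters,
what the synthetic data generator does and does not emulate, and the
design decisions that were genuinely open. It states no empirical
number that the test suite or `scripts/acceptance.R` does not itself
compute.

## The imaging model

Fluorescence is incoherent, so the sinusoidal excitation pattern
multiplies the object in sample space before diffraction blurs the
emission:

$$D_j(\mathbf r) = \mathrm{PSF} * \left[s(\mathbf r)\,
  \bigl(1 + m\cos(2\pi\,\mathbf p_a\!\cdot\!\mathbf r + \phi_{a,j})\bigr)\right],
  \qquad \phi_{a,j} = \phi_a + j\,\tfrac{2\pi}{3},\; j = 0,1,2 .$$

Per reconstructed frame and channel the instrument records nine raw
images (3 pattern orientations $a$, ~60° apart, × 3 phases), ordered
angle-major. In frequency space each raw spectrum mixes three copies
of the object spectrum,

$$\tilde D_j(\mathbf k) = O(k)\left[\tilde S(\mathbf k)
 + \tfrac m2 e^{i\phi_{a,j}}\tilde S(\mathbf k-\mathbf p_a)
 + \tfrac m2 e^{-i\phi_{a,j}}\tilde S(\mathbf k+\mathbf p_a)\right],$$

where $O$ is the detection OTF. The side bands carry object
frequencies up to $k_c + |\mathbf p_a|$ — the resolution gain. The
package uses the ideal incoherent 2D OTF
$O(k) = (2/\pi)(\arccos\rho - \rho\sqrt{1-\rho^2})$, $\rho = k/k_c$,
$k_c = 2\,\mathrm{NA}/\lambda$, for simulation, estimation and
reconstruction alike. A real instrument's measured OTF differs
(aberrations, apodization by the detection path); using the analytic
form keeps every stage checkable against closed forms. Numerical
aperture is a free parameter; the headline demonstrations use the
effective NA 1.33 of the modeled instrument with a pattern frequency
of $0.8\,k_c$, giving a support extension of exactly 1.8.

Conventions: spatial frequencies are in cycles/µm everywhere, pixel
coordinates are 0-based, transforms keep DC at the array corner
(`stats::fft` layout); centred views exist only for display.

## Virtual microscope

`make_phantom()` renders deterministic scenes (seeded): sub-pixel point
emitters, clusters of closely packed 0.2 µm beads (the standard
calibration sample; truth centres and diameters are returned for
truth-based tests), smooth line networks, and a Siemens star.
`simulate_raw_set()` applies illumination, blurs with the OTF, then
models an sCMOS camera: Poisson shot noise at `photons_scale` photons
per unit phantom intensity, Gaussian read noise (default 1.2
counts), a digital baseline of 100 counts (configurable; the
instrument class this emulates has such an offset, and the estimator
must be robust to it), clipping at 0 and 16-bit quantization. With
`photons_scale = Inf` the camera is bypassed and exact
floating-point frames support 1e-9-level oracle tests.
`simulate_multichannel_sequence()` emits individual timestamped frames
for 1–3 channels in the interleaved order of the timing planner, with
per-channel affine mis-registration and optional drift.

Defaults state the modeled world: 512×512 frames at 80 nm projected
pixels, three orientations 60° apart (first at 13°, chosen off-axis so
no pattern aligns with the pixel grid), $|\mathbf p| = 0.8\,k_c$,
modulation 1 for noiseless demonstrations and 0.8 for estimation
tests, 500 photons/pixel peak for "realistic noise" cases (a typical
live-cell SIM exposure). What the generator does **not** emulate:
vectorial/3D PSFs, aberrations, TIRF geometry, photobleaching,
rolling-shutter effects, or elastic (non-affine) channel distortion. A
green test therefore establishes algorithmic correctness under the
stated forward model, not instrument-grade performance on real data.

## Parameter estimation

Reconstruction needs, per angle: the pattern wave vector
$\mathbf p_a$, the starting phase $\phi_a$, and the modulation depth
$m$. `fit_channel_params()` proceeds per angle:

1. **Band separation** (`separate_bands()`): the 3×3 mixing system is
   inverted exactly per frequency. Separation uses a provisional
   $m = 1$; the side bands then carry a factor $m e^{\pm i\phi_a}$
   that the later fit recovers. This avoids a circular dependence of
   separation on the quantity being estimated; the real $m$ enters the
   reconstruction weights instead. Frame means are subtracted first —
   the camera baseline otherwise dominates the DC bin and biases the
   modulation estimate severely.
2. **Coarse search** (`estimate_k_coarse()`): both bands are
   compensated by the OTF over its support (`otf_min = 0.15`) and the
   cross-correlation over all integer-bin shifts is computed at once
   from the product field of the two compensated band images. Its
   magnitude peaks at $\mathbf p_a$ because the aligned side band
   differs from the zero band only by the ramp
   $e^{2\pi i\,\mathbf p\cdot\mathbf r}$. The search is restricted to
   an annulus of 0.2–1.0 $k_c$ (the pattern can sit neither at DC nor
   beyond the cutoff). The normalized score flags pattern-free data;
   the threshold (default 0.2) is a package choice, not validated
   against any instrument. Sparse scenes leave a speckle background of
   relative height $\sim 1/\sqrt{N_\text{emitters}}$ in this
   correlation, so estimation fixtures use dense scenes — exactly why
   densely packed bead layers are the calibration sample of choice.
3. **Sub-bin refinement** (`refine_k_subpixel()`): the correlation at
   a continuous shift $\mathbf q$ is a single fractional-frequency
   Fourier sum over the product field (a phase-ramp multiplication in
   real space, O(N) per evaluation). $|C(\mathbf q)|$ is maximized on
   a shrinking 5×5 grid bracket (span halves per iteration, tolerance
   1e-3 bins, max 30 iterations — non-convergence is an error).
4. **Phase and modulation**: at the optimum, numerator and denominator
   are weighted by the OTF *product* (no division), so the ratio is
   exactly $m e^{i\phi_a}$ for noiseless data and noise at the edge of
   the support is not amplified. The denominator subtracts the
   per-bin noise power measured outside the OTF support, removing the
   upward bias under the weights. $m$ is clipped to (0, 1.5] with a
   warning above 1.

Accuracy, measured by the suite on noiseless 512² data: wave vector to
better than 0.05 bins, phase to 0.02 rad, modulation to 0.02; at 500
photons/pixel over 10 seeds: 0.2 bins / 0.05 on $m$. The phase error
couples the residual wave-vector error to the scene centroid
($\delta\phi \approx 2\pi\,\delta p\, \bar r/N$) and so scales with
grid size; the 0.02 rad figure holds at the native 512 geometry.

## Reconstruction

`reconstruct_set()` separates bands with the estimated phases, places
each band on a twice-finer frequency grid (the output contract is
fixed 2×: 512² raw → 1024² SIM), shifts side bands by
$\pm\mathbf p_a$ as real-space phase ramps (sub-bin exact), and
combines with a generalized Wiener filter

$$\hat S(\mathbf k) = A(\mathbf k)\,
  \frac{\sum_{a,b} O_{ab}(\mathbf k)\, D_{ab}(\mathbf k)}
       {\sum_{a,b} O_{ab}(\mathbf k)^2 + w^2},$$

with $O_{ab}$ the analytic OTF displaced by $b\,\mathbf p_a$ and
weighted by $m^{|b|}$. Weighting by $m$ in numerator and denominator
(rather than dividing bands by $m$) down-weights low-confidence side
bands and is numerically safe as $m \to 0$, where the estimate
degrades gracefully to a Wiener-filtered wide-field image. Tunables:

- `wiener_w` (default 0.05, dimensionless): single global
  regularization, common practice for this reconstruction family; the
  source instrument publishes no value.
- `attenuation_on/strength/fwhm` (default off, 0.99, 1.2 cycles/µm):
  multiplies each band's OTF by $1 - a\,e^{-k^2/2\sigma^2}$ around the
  band's own origin, suppressing the out-of-focus background carried
  by the overlapping low-frequency region of the side bands. Off by
  default because it trades in-focus low-frequency content; strength
  and width are package assumptions.
- **Apodization** $A(\mathbf k)$: the ideal incoherent OTF of a
  fictitious system with cutoff $k_c + \max_a |\mathbf p_a|$. This was
  a genuinely open design point. A half-cosine bell
  $\cos(\pi k/2K)$ leaves the near-inverse Wiener passband almost
  flat, and the measured point-image FWHM gain then overshoots the
  support ratio (~2.0 at $0.8\,k_c$); the idealized-OTF shape makes
  the reconstructed PSF a scaled replica of a diffraction-limited PSF,
  so the FWHM gain tracks the support ratio (the suite measures 1.76
  against the 1.8 bound). The half-cosine remains available by
  editing `precompute_filters`.
- `clip_negative` (default on): Wiener ringing produces small negative
  intensities; clipping is cosmetic and disabled for linearity tests.
- `camera_offset` (default 0): known baseline subtracted before
  separation; the scene's own DC is preserved.

`reconstruct_batch()` shares all precomputed filters (displaced OTFs,
denominator, ramps, apodization) across many sets — the software
analogue of the instrument's concurrent multi-frame processing.

Degenerate inputs: all-zero frames reconstruct to zero; a pattern at
or beyond the cutoff, mismatched geometry, or coincident phases are
errors, not warnings.

## SLM pattern design

The binary ferroelectric SLM acts as an electronically defined phase
grating; spurious diffraction orders must be blocked by a stationary
Fourier-plane mask. Gratings are parameterized by a coprime integer
normal $(u, v)$ and a (possibly fractional) period in SLM pixels;
pixel-grid translations project onto the normal in steps of
$1/\sqrt{u^2+v^2}$, which is what makes 3-phase stepping (period/3)
realizable on exotic slopes and unrealizable on plain ones (period 6
on-axis works; period 2 does not — a 2/3 px shift has no pixel
realization). Spot positions are $n\lambda/P$ along the normal
(normalized units, nm/px; the mapping to mask millimetres is a single
relay calibration factor outside the model's scope); intensities come
from the DFT of the *realized, rounded* bitmap, so rounding-induced
spurious orders are exactly what the mask-transmission check sees. An
ideal 50% duty grating has vanishing even orders.

`multicolor_pattern_search()` enumerates rational normals within ±8°
of 0/60/120° and periods near $\lambda/r_\text{target}$ per
wavelength, requiring: every color's ±1 spots within the hole
tolerance of the shared holes, all phase steps realizable, and all
spurious orders clear of every hole; among feasible sets it maximizes
spurious-order clearance and reports a structured infeasibility
(naming the tightest constraint) otherwise. Equal spot radius across
colors forces $P_{\lambda_2}/P_{\lambda_1} = \lambda_2/\lambda_1$ and
hence the same relative resolution improvement for every channel.

## Acquisition timing

The planner (`plan_acquisition()`) uses an additive model with the
instrument's printed component times: 0.44 ms SLM switch; camera
readout delays of 0.85 ms (256 lines) and 2.1 ms (512 lines),
interpolated linearly in lines between the anchors and clamped at zero
below ~80 lines (where readout hides inside the SLM switch).
Single-channel raw-frame period = exposure + switch + readout
(9 frames per SIM frame). Multi-channel acquisition interleaves
channels round-robin in slots of exposure + switch; a wait is added
only if a camera's readout cannot finish before its next slot. This
reproduces the modeled instrument's printed 31 fps (one color, 1 ms,
512 lines) and 25 fps (three colors) exactly. It deliberately does
not capture every per-sequence overhead of the real hardware; an
`overhead_ms` term (default 0) lets users calibrate against a
measured instrument. Rates are kept exact internally and floored to
integers only for presentation. Invariants enforced by tests: at most
one laser on at any instant; consecutive exposures of a camera
separated by at least its readout delay.

## Streaming pipeline

Frames cross the wire as little-endian messages: magic/version header,
geometry, channel/sequence/angle/phase indices, a nanosecond
timestamp, and the payload at 2 bytes/pixel — bit-exact round trips
are asserted, corrupted magic or truncated payloads are errors.
Grouping emits a set only when nine consecutive sequence indices
complete a 3×3 cycle; any gap discards the partial set (counted).
Ring buffers (overwrite-oldest, never blocking the producer) decouple
acquisition from reconstruction; drops are whole sets, never partial
frames. Channel registration is an affine fit to matched bead
centroids (iterative Gaussian-weighted centroiding, nearest-neighbour
matching after phase-correlation coarse shift); the instrument this
models uses an elastic method for the same purpose — affine is
sufficient for the camera-alignment errors modeled here and keeps the
fit linear. The live loop (decode → group → ring → reconstruct →
register → sink) is deterministic under an injected clock, archives
raw frames to TIFF, and is bit-identical to offline batch
reconstruction of that archive — the property that makes "instant"
reconstruction trustworthy. Wall-clock latency is reported, never
asserted: it is hardware-bound.

## Known limitations

- 2D (two-beam) SIM only; no 3D stacks, TIRF or nonlinear variants.
- The ideal OTF ignores aberrations and vendor apodization; measured
  gains on a real instrument would be lower.
- The estimator assumes exact 2π/3 phase steps (a global phase per
  angle); per-frame free phases are out of scope.
- The timing model is additive and calibrated to two printed anchor
  points; sub-millisecond hardware overheads are not modeled.
- Registration is affine; elastic sample-induced distortions are not.
- TIFF support covers the baseline subset the package writes
  (validated against an independent reader in the suite), not the
  full format zoo.
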