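---
title: "Holographic pixel super-resolution: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holographic pixel super-resolution: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holopsr)
```

## The imaging problem

In lensless digital in-line holography (DIH) a quasi-coherent source — here
an ultraviolet LED at 385 nm behind a pinhole — illuminates a thin sample
resting almost directly on a monochrome CMOS sensor (1.67 µm pixels). No
lens forms an image; the sensor records the interference pattern between
the unscattered background wave and the light scattered by the specimen.
Scalar diffraction theory then lets us refocus that hologram numerically to
any object plane. The resolution of this arrangement is limited less by
diffraction than by the detector pitch: fringes finer than two pixels alias
and are lost to a single exposure.

Multi-frame pixel super-resolution restores part of that information. The
source is displaced laterally by small, irregular amounts between
exposures, shifting the hologram across the sensor by sub-pixel distances.
Each low-resolution (LR) frame then carries a different aliasing phase, and
the set of frames jointly determines the hologram on a finer grid. `holopsr`
implements the full computational chain: frame registration, sub-pixel
refinement by continuous ant colony optimization, shift-and-add fusion,
angular-spectrum reconstruction, and a synthetic acquisition model that
provides ground truth for every stage.

## Angular-spectrum propagation

`propagate()` transports a complex field `U` over a signed distance `z` by
multiplying its spatial-frequency spectrum with the free-space transfer
function

$$H(f_x, f_y) = \exp\!\Big( i \tfrac{2\pi}{\lambda} z
  \sqrt{1 - (\lambda f_x)^2 - (\lambda f_y)^2} \Big),$$

zeroed on the evanescent band $(\lambda f_x)^2 + (\lambda f_y)^2 > 1$.
Numerical choices:

* **Padding.** By default the field is zero-padded to twice each dimension
  and cropped after propagation, which suppresses the wrap-around replicas
  of the periodic DFT. Because holograms have a background near one, naive
  zero-padding would diffract at the pad edge; `propagate()` therefore
  carries the mean field analytically (a constant is an eigenfunction of
  free-space propagation with eigenvalue $e^{i 2\pi z/\lambda}$) and pads
  only the zero-mean part. With `pad = FALSE` the operator is strictly
  unitary on the grid: round trips are exact to machine precision and
  energy is conserved, which is how the package's correctness checks are
  phrased.
* **Validity.** The discretized transfer function is alias-free only up to
  $z_{max} = N\,\Delta^2/\lambda$ for an $N$-pixel grid of pitch $\Delta$.
  `propagate()` warns (and proceeds) beyond that. This is why the bundled
  desk-scale scenes (256² HR grids at 0.4175 µm pitch) use
  object-to-detector distances of 120–300 µm rather than the platform's
  nominal working distances; the physics is identical, only the scale is
  reduced to what a 256² grid supports.
* **Reconstruction input.** Holograms are embedded as the square root of
  the recorded intensity (amplitude-hologram assumption), the standard DIH
  practice that preserves linear fringe contrast; `from_sqrt = FALSE`
  switches to raw intensity.

Correctness is established two ways: the unitary invariants above, and
agreement with an independent brute-force Rayleigh–Sommerfeld summation.
The comparison regime matters: the discrete point-to-point sum itself
aliases when the chirped kernel is under-sampled, so the cross-check uses a
band-limited Gaussian field on a 32² grid with a central comparison window
(relative RMS below 1%). A single-pixel impulse would make the *oracle*,
not the method, fail.

Reconstruction output is a set of planes per distance — real part,
imaginary part, amplitude, phase and the composition (real + imaginary) —
plus an RGB composition (`compose_rgb()`: R = real, G = imaginary,
B = real + imaginary, each min–max normalized; the mapping is a
visualization convention). Morphologically distinct structures diffract
differently into the two quadratures, so e.g. a dense absorbing sperm head
and its thin phase-shifting tail attain different dominant channels, which
is what makes the composition useful for counting and segmentation.

### Autofocus

`focus_scan()` scores back-propagations over a z-scan. Its default score is
the Tamura coefficient (sd/mean) of the amplitude, optionally inside a
window around the object. The sum-modified Laplacian (LAPM) is *not* the
default for this purpose although it is the package's sharpness measure
elsewhere: on coherent amplitude reconstructions of absorbing objects, LAPM
keeps increasing with defocus, because out-of-focus fringes add
second-difference content faster than the focused edge loses it. We
verified this empirically over z-scans; the Tamura score peaks at the true
distance (within one scan step at z = 300 µm in the validation suite).
LAPM's proper role is in the hologram domain, where sharper fringes mean
better-propagated holographic signal — exactly where the energy functional
uses it.

## Registration

Frames are pre-aligned by a classical feature pipeline
(`prealign_stack()`):

1. **Detection** — a determinant-of-Hessian blob detector over a small
   Gaussian scale bank, with 2-D quadratic sub-pixel refinement of each
   response peak. Descriptors are 8×8 patches sampled at the keypoint's
   scale from the smoothed image, normalized to zero mean and unit
   variance (upright by default; hologram stacks are not rotated between
   frames, and an orientation estimate can be switched on).
2. **Matching** — exact nearest-neighbour search in descriptor space with a
   Lowe ratio test (default 0.75).
3. **Geometric filtering** — `filter_matches()` fits the robust common
   displacement and rejects matches whose vector length or angle deviates
   by more than 3 median absolute deviations. An optional `max_shift` prior
   discards matches longer than the acquisition protocol allows. This
   prior is load-bearing for sparse scenes: the concentric diffraction
   rings of two different cells look locally identical, and without the
   prior the matcher can lock whole frames onto the wrong cell.
4. **Robust estimation** — RANSAC (reprojection threshold 1 px, up to 2000
   iterations with adaptive early termination, fixed seed) around a
   normalized-DLT homography fit, with affine and translation-only models
   for constrained acquisitions. On noiseless correspondences with 30%
   gross outliers the homography is recovered to machine precision.

On synthetic hologram stacks with known shifts the pre-alignment residual
is well below half a pixel — sufficient as an initial guess, not as a final
answer, which is precisely the division of labour the two-step design
assumes.

## The super-resolution energy and its optimizer

Given m aligned frames $L_i$ and a candidate HR image $I$ at upsampling
factor $s$, the energy is

$$E(I, L) \;=\; \alpha \sum_{i=1}^{m} \mathrm{MSE}\!\big(L_i,\; I\!\downarrow_i\big)
\;-\; \beta\, \mathrm{LAPM}(I)/N_{px},$$

where $I\!\downarrow_i$ re-samples $I$ on frame i's grid through that
frame's transform and sub-pixel offset. The fidelity term ties the fused
image to every observation; the sharpness term rewards recovered fringe
contrast (the sign is configurable via `sharpness_sign`; the default makes
minimization reward sharpness). Defaults are $\alpha = 1$ and
$\beta = 0.1$ with the per-pixel LAPM normalization, which puts both terms
on comparable scales for unit-background holograms; parameter-recovery
studies run with $\beta = 0$ since fidelity alone identifies the offsets on
clean data.

Two re-sampling conventions exist for $I\!\downarrow_i$. The default,
`sampling = "point"`, samples the fused HR image bilinearly at each LR
pixel's mapped splat centre; it makes the single-frame self-consistency
case exactly zero and reduces to the plain per-pixel difference at factor
1. A box-filtered variant (`sampling = "box"`) models the detector's area
integration explicitly.

**Fusion** (`fuse()`) is shift-and-add: every LR pixel is splatted onto the
HR grid at its mapped position with bilinear weights; the image is the
weighted mean per cell, and zero-weight cells are filled by iterated
neighbourhood interpolation so the output is everywhere defined. Fusion is
linear in the frame intensities and, at the true offsets, suppresses
i.i.d. frame noise by roughly the frame count. Its benefit over
single-frame interpolation is *de-aliasing*: for scenes band-limited below
the single-frame Nyquist rate, bicubic upsampling of one frame can match
fusion's RMS, but content between the single-frame and the HR Nyquist
rates — fine fringes, close point pairs — is recoverable only from the
multi-frame set.

**The optimizer** (`acor_minimize()`) is ant colony optimization for
continuous domains: an archive of k solutions sorted by objective value;
each ant picks a guide solution with rank-based Gaussian weights
(locality q) and samples every coordinate from a normal centred on the
guide whose deviation is the mean absolute archive spread times the
convergence speed ξ; the pooled set is truncated back to the k best.
Defaults (k = 30, q = 0.1, ξ = 0.85, 2 ants per iteration) follow the
standard recommendations for this algorithm family. It is deterministic
under a fixed seed, and on benchmarks it reaches 1e-25 on the 4-D sphere
within 2000 evaluations and localizes the 2-D Rosenbrock minimum to ~1e-7
in 5000 — orders of magnitude beyond an equal-budget random search.

**Search strategy.** `super_resolve()` refines one 2-D offset per
non-reference frame, bounded to ±2 LR px around the pre-alignment, which
stays an additive correction (the pre-alignment transform is never
replaced). The default strategy is a block-coordinate sweep: each frame's
offset is optimized by a small ACO run against the leave-one-out fused
estimate of all other frames, maintained incrementally; after each block
the full energy is evaluated, the best configuration seen is kept, and the
reported trace is the non-increasing best-so-far energy. A joint mode
optimizing all 2(m−1) variables in a single ACO run is available and is
practical for small m; for 49 frames the joint space has 96 dimensions, and
no evaluation budget that fits in minutes explores it to 0.1 px, whereas
the energy is nearly separable per frame once a consensus HR estimate
exists — the sweep converges in 2–3 passes. Two design facts matter for
convergence: the pre-alignment initial guess is genuinely needed (from
identity transforms the first fused estimate can be too blurred for blocks
to escape 0.1–0.4 px biases), and the HR grid should be no finer than the
frame set can support (m frames fill about m/s² of the HR cells; 9-frame
stacks are refined at factor 2, the 49-frame acquisitions at factor 4).

## The synthetic acquisition model

The generator emulates the full physical chain with known ground truth:

* **Scene** — a planar complex transmittance on the HR grid: background 1,
  objects (disks, ellipses, sperm-like shapes with an elliptical head and
  a thin wavy tail of independent optical properties) multiply in soft-edged
  complex factors $a e^{i\varphi}$. Sizes are micrometres; the bundled
  scenes use 1.5–2.5 µm cells, matching few-micron specimens.
* **Forward hologram** — plane-wave illumination, angular-spectrum
  propagation over z, recorded intensity normalized to unit background.
* **Displacements** — a 7×7 lattice of shifts with lattice constant 0.5 LR
  px plus i.i.d. uniform jitter of ±0.3 LR px per axis (deterministic per
  seed). The lattice constant and jitter are the package's fixed study
  conditions: together they scatter the aliasing phases irregularly over
  the unit cell — the operating principle of the irregular-displacement
  acquisition — while keeping every shift within the optimizer's ±2 px
  search box after pre-alignment. Shifts are expressed directly in
  detector pixels; the physical source-displacement-to-hologram-shift
  demagnification of a real rig is folded into them, since the
  reconstruction chain only ever observes detector-plane motion.
* **Detector** — Fourier-shift of the HR hologram (exact for band-limited
  signals; replicate-padded 2× guard against wrap-around), box-average by
  the factor, scaling to digital numbers (background ≈ 180 DN), Poisson
  shot noise (default 4 photons per DN), Gaussian read noise (default
  σ = 1 DN), clipping and 8-bit quantization. `bit_depth = NA` yields
  noiseless float frames for noise-free ground-truth studies.

Frames and their true shifts round-trip through numbered TIFFs plus a
plain-text manifest. The recorded shift of a frame is the translation
mapping its coordinates onto the reference scene — the same convention the
registration and fusion modules use, so recovered alignments compare
directly against the manifest.

What the generator deliberately does **not** model: partial coherence of
the LED/pinhole source, sensor fill-factor and pixel PSF, twin-image
suppression, and dense/confluent samples whose scattering distorts the
reference wave. Passing the synthetic validation therefore demonstrates the
correctness of the computational chain under ideal coherent imaging with
known noise — not the full behaviour of the physical instrument.

## What the validation suite establishes

* Unitary propagation invariants to machine precision and sub-percent
  agreement with the independent diffraction-sum oracle.
* Pre-alignment residual ≤ 0.5 px RMS on stacks with known shifts;
  homography recovery exact under 30% outlier contamination.
* On the full 49-frame, factor-4, 64×64-LR study: sub-pixel offset
  recovery to ≈ 0.03 px RMS noiseless and well within 0.3 px under 8-bit
  quantization with σ = 2 DN read noise; non-increasing best-energy
  traces.
* A two-point target at 1.2 LR px separation (2.0 µm at the platform
  pitch) shows no 20% intensity dip in any of the 49 single-frame
  reconstructions but a ≥ 20% dip in the fused HR reconstruction — the
  synthetic analogue of the platform's LR→HR fringe-recovery demonstration.
* Fused-image noise variance, re-sampled on the LR grid, is an order of
  magnitude below a single frame's.
* Optimizer benchmarks and metric oracles (LAPM, Prewitt compass against
  direct convolution, prominence-based cycle counting at 5% noise) hold at
  their stated tolerances.

All of these are recomputed from scratch by `scripts/acceptance.R` and by
the test suite; the problem sizes quoted above (256² HR grids, 49-frame
stacks, 2000–5000-evaluation benchmarks) are the package's chosen study
scale.

## Known limitations

* Twin-image artifacts are not suppressed; the conjugate focus overlays
  every reconstruction, and the two-point dip criterion operates on top of
  that background.
* The displacement model is translational per frame. The full-homography
  registration path exists (and is the estimation default), but the
  generator does not emulate perspective distortion from large source
  excursions.
* Offsets beyond ±2 LR px after pre-alignment are clipped by the search
  bounds; acquisitions with larger drift need the feature stage to absorb
  it first.
* Block-coordinate refinement inherits the usual caveat of coordinate
  descent: with a severely under-determined grid (too few frames for the
  chosen factor) blocks can settle a fringe period away from the truth.
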