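---
title: "Source-localized MTPM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-localized MTPM: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the science implemented in `slmtpm`: the photon
transport model behind the scattering kernel, the streak-deconvolution
reconstruction, the synthetic forward model used for its validation studies,
and the analysis metrics — together with the parameter defaults, the
numerical choices, and the places where a genuinely open design decision had
to be made.

## 1. The scattering kernel

### Physical model

A fluorophore at the focal plane of a multifocal two-photon microscope emits
photons isotropically; the tissue between the focal plane and the surface
scatters them before they reach the camera. We model this with a Monte Carlo
random walk through a homogeneous slab:

* the emitter sits at the origin of the focal plane, `z = 0`;
* the slab occupies `0 <= z <= z_h`, with the tissue surface at `z = z_h`
  (so `z_h` *is* the imaging depth);
* photons are launched toward the surface with azimuth uniform on
  `[0, 2*pi)` and elevation uniform on `[0, theta_max]`, where
  `theta_max = asin(na / n_medium)` is the half-angle of the objective's
  collection cone. Photons outside the cone are taken to contribute
  negligibly and are not simulated;
* free paths between scattering events are exponential with rate `mu`
  (accepted in mm^-1 and converted to um once, at the configuration
  boundary; all positions are um internally);
* each scattering event deflects the direction by a Henyey–Greenstein (HG)
  polar angle — inverse-CDF sampled, anisotropy `g` — with a uniform
  azimuthal spin;
* a step that would cross a slab boundary is truncated at the boundary
  plane. A photon crossing the surface is *collected*: it is traced
  backwards along its final straight-line direction to the plane `z = 0`,
  because a camera focused on the source plane images the photon at that
  apparent origin. A photon crossing `z = 0` downward can never reach the
  epi-collection optics and is dropped.

The unit-sum histogram of apparent origins, binned on a square grid centred
on the true source, is the scattering PSF used for deconvolution. Ballistic
photons land in the centre bin, which is why the kernel keeps a sharp peak
on top of a broad scattered halo; the kernel is approximately radially
symmetric, and broadens monotonically with depth.

Defaults follow scattering cortical grey matter: `mu = 20` mm^-1, `g = 0.9`,
`z_h = 190` um (the reconstruction kernel depth that worked best across
acquisitions), `na = 1`. Absorption, refractive-index mismatch at the
surface, polarization, time of flight and the microscope's own
diffraction-limited PSF are deliberately not modelled.

### Decisions the physics left open

* **NA-to-angle mapping.** Only the numerical aperture is given; we use
  `theta_max = asin(na / n_medium)` with `n_medium = 1.33` (water
  immersion). Setting `n_medium = na` reproduces the vacuum convention of a
  full hemisphere.
* **"Uniform in elevation".** The launch elevation is uniform in the *angle*
  itself by default; `elevation = "solid-angle"` switches to uniform on the
  spherical cap (uniform in `cos(theta)`). The kernel differs only mildly
  between the two.
* **Kernel grid.** The kernel is square with an odd side
  (`2 * kernel_halfwidth + 1`), so the source occupies the exact centre bin;
  the default halfwidth of 16 gives a 33 x 33 kernel, matching the
  ~32-pixel crop used for deconvolution in the depth modelling. The bin
  pitch defaults to the image pixel pitch (1.5625 um: a 12.5 um beamlet
  pitch rastered with 8 lines).
* **Safety cap.** A walk is abandoned after 10^6 scattering events; the
  probability of reaching this is negligible, it only guards against
  non-termination.

The walk is implemented twice: once in C++ for throughput (10^7 photons in a
few seconds) and once in plain R (`propagate_photon()`); the test suite
checks that both agree on collection fractions and mean event counts.

## 2. Streak reconstruction

Each streak sub-frame `d` is deconvolved with `iterations = 100` (the value
used for all reconstructions) of the multiplicative Richardson–Lucy update
initialized with a *flat prior* — a constant image. Numerical choices:

* the flat prior's value is the mean of the observed sub-frame, making the
  initialization scale-consistent;
* the adjoint kernel defaults to the PSF mirrored along the `x = y` axis
  (the matrix transpose); conventional Richardson–Lucy uses the 180-degree
  rotation, and `adjoint = "rotate180"` selects it. For near-radially-symmetric scattering kernels the two nearly
  coincide, and the tests verify they agree on kernels symmetrised under
  both;
* boundaries are reflectively padded by half the kernel side before the
  iteration (removed afterwards), which suppresses edge artefacts;
* the ratio's denominator is floored at `1e-12`; negative input pixels are
  clipped to zero with a warning; dark subtraction happens before
  deconvolution because the update requires nonnegative data;
* convolutions are FFT-based on the padded image, with the kernel embedded
  with wrap-around so a delta kernel is an exact identity.

An optional 1-D median filter (window 3, along the streak axis — matrix
columns for the default vertical-line scan) can be applied to each
deconvolved streak image *before* the maximum projection; it is off by
default and intended for deep, low-contrast data. A frame is recovered as
the pixelwise maximum over the `m` deconvolved streak images; the pixelwise
mean of the raw streak images is the standard-MTPM comparator. A trailing
group of fewer than `m` sub-frames is an incomplete scan and is dropped with
a warning rather than padded.

## 3. The synthetic forward model

The generator emulates the features of the real acquisitions that the
reconstruction and analyses depend on:

* **Scenes.** Non-overlapping soma-like discs (radius 5–8 um) with a bright
  membrane rim (rim at the cell's brightness, interior at 90% of it) on
  either a diffuse neuropil background (multi-cell labelling, bath-applied
  dye) or a near-zero background (single-cell intracellular loading).
* **Streak structure.** Streaks are ideal 1-pixel-wide vertical lines:
  line image `k` keeps columns congruent to `k` modulo `m` (0-based), so the
  `m` line images partition the scene exactly. Real streaks have a finite
  Gaussian profile; the 1-pixel convention matches the modelling use and
  keeps the partition property exact.
* **Blur and noise.** Line images are convolved with a Monte Carlo kernel
  for the condition's `(mu, z_h)` and every pixel `I0` is replaced by a draw
  from `Normal(I0, I0/10)`, clipped at zero (camera counts are nonnegative;
  zero pixels stay exactly zero).
* **Dynamics.** Each cell's brightness at frame time `t` is scaled by
  `1 + f(t)`, where `f` is the double-exponential calcium transient with
  decay `alpha = 3.18` s^-1 and rise `gamma = 34.39` s^-1 (constants of a
  fast synthetic calcium indicator of the Cal-520 family) and
  closed-form peak normalization `c = 1 / (exp(-alpha*t*) - exp(-gamma*t*))`
  at `t* = log(gamma/alpha) / (gamma - alpha)`, so a single pulse peaks
  exactly at the amplitude `A`. All `m` sub-frames of a frame share that
  frame's time — transients are slow relative to one scan.

What the generator does *not* emulate: diffraction-limited excitation,
photobleaching, sample motion, Poisson photon statistics (the noise model is
the Gaussian one above), axial sectioning, or inhomogeneous scattering. A
passing study therefore demonstrates the reconstruction's behaviour under
idealized streak structure and the stated noise model, not performance on
real tissue; the real-tissue numbers depend on raw recordings that no
synthetic scene reproduces.

## 4. Contrast at depth

`segment_for_contrast()` implements the published rule: threshold, then 4
binary erosions followed by 4 dilations (3 x 3 cross element — the smallest
standard element; the source does not specify one). The phrase defining the
threshold ("80% cutoff of the maximum of the image histogram") is ambiguous;
both readings are implemented, and the default is 0.8 x the maximum pixel
intensity, because the histogram-mode reading degenerates on dim images
(the mode is the background, so nearly every pixel passes). Michelson
contrast uses the 99.9th percentile of cell-mask intensities and the 10th
percentile of background intensities; it is set to 0 when all or no pixels
are segmented, and is invariant under multiplicative rescaling.

For the *simulation* depth study, `depth_series()` measures contrast over
the scene's known ground-truth cell/background masks by default. Two reasons:
(i) the generated scenes' somata span only 3–5 pixels at the study's pixel
pitch, so the published 4-iteration erosion — designed for finely sampled
camera images — removes every cell and the metric degenerates; and (ii) with
ground truth available, fixed masks isolate the effect under study
(scattering and its reversal) from segmentation noise. Re-segmentation per
image remains available (`contrast_masks = "segmentation"`).

The 50% cutoff depth fits a 3rd-order polynomial to relative contrast
(normalized to the shallowest sampled depth) against depth by least squares
and reports the smallest in-range crossing of 0.5, located by a dense 0.1 um
scan refined with bisection — robust to cubic wiggles. Profiles that never
cross within the sampled range are flagged; `depth_cutoff_summary()`
right-censors them at the deepest sampled depth.

### Study conditions

The depth study shipped in the acceptance tests uses a 5-cell multi-cell
scene of 64 x 64 pixels at 3.125 um/pixel (a 200 um field), line separations
{6.25, 12.5, 25, 50} um (oversampling factors 2–16), scattering coefficients
{10, 20, 40} mm^-1, 10^6-photon kernels, a forward-blur kernel of halfwidth
31 (the largest fitting the scene, +-97 um of halo) and a deconvolution
kernel cropped to 33 x 33 and renormalised — mirroring the original
modelling, where the forward kernel was effectively camera-sized and only
the deconvolution kernel was cropped. Depth grids are optical-depth matched:
the base grid {25, 75, 150, 250, 375, 500} um refers to `mu = 20` mm^-1 and
is rescaled by `20/mu` per condition, so every coefficient is sampled over
comparable optical depths `mu * z` and both arms' cutoffs fall inside the
sampled range. These sizes keep the full 12-condition study at around three
minutes on one core; they are stated here as the package's chosen study
scale.

## 5. Functional analysis

* **ROI segmentation.** The local correlation map averages each pixel's
  Pearson correlation with its 8-connected neighbours (edge pixels use the
  neighbours that exist; constant time courses contribute 0 — the
  conservative convention for 0/0). The map (or, for single-cell data, a
  temporal variance map) is thresholded with Otsu's method — the original
  description cites an unnamed automatic threshold, and Otsu is the
  ecosystem default — then binary closing, two rounds of opening (3 x 3
  box), and the largest connected component is kept.
* **Consensus across trials** includes a pixel only when it appears in
  strictly more than a quarter of the per-trial masks.
* **Extracellular ROI.** Full surround (everything outside the cellular
  masks) for multi-cell data; for single-cell data, a box extending 5 pixels
  beyond the cell's bounding box (clipped at the image edge) minus the cell,
  which avoids counting deconvolution ringing far from a solitary bright
  cell while still treating near-cell ringing as unreassigned signal.
* **Traces.** dF/F0 divides the dark-subtracted ROI-mean time course by the
  mean of its baseline window (default: all frames before the first
  stimulus). The signal localization ratio (SLR) is the ratio of peak
  intracellular to peak extracellular dF/F0 inside a stimulus-locked window
  (default 0.5 s after the stimulus); a nonpositive extracellular peak is
  floored at a small epsilon and flagged rather than producing an undefined
  ratio.
* **Amplitude and noise.** With known spike times the transient amplitude is
  the closed-form single-coefficient least-squares solution
  `A = <w, y> / <w, w>` against the unit-amplitude waveform `w`; the noise
  level is the n-1 standard deviation of the final quiescent 0.2 s of the
  trace (0.3 s for multi-cell data, where stimulus timing is less certain);
  PSNR is `A^2 / sigma^2`.

The crosstalk fixture used in the acceptance tests places one active and one
silent cell 23 um apart in a 62.5 um field, renders 10 frames at 10 Hz with
a 100 um-depth kernel (`mu = 20` mm^-1), a spike at 0.3 s with `A = 1`, a
dark level of 100 counts and the standard noise model, and compares the SLR
of the source-localized and raw-mean reconstructions of the *same* streak
data across ten noise seeds.

## 6. Known limitations

* The slab is homogeneous; real cortex is not, and measured cutoff depths in
  tissue are shallower than homogeneous-slab models predict.
* The kernel is sampled on a finite grid: halo photons landing outside the
  grid are discarded before normalization, which biases very deep kernels
  slightly sharp. The depth study counters this with the widest blur kernel
  that fits the scene, but an unbounded-support kernel would decay faster.
* Richardson–Lucy amplifies noise; the package implements the plain
  multiplicative update (damped and blind variants are out of scope), so
  low-frame-rate, sparsely labelled traces can lose PSNR after
  reconstruction even while gaining localization.
* TIFF output stores 32-bit fixed-point samples with the scale in the YAML
  sidecar (round-trip error below 2^-32 of full scale); readers that ignore
  the sidecar see values scaled to [0, 1].
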