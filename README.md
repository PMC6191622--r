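# slmtpm — source-localized multifocal two-photon microscopy

Multifocal two-photon microscopy (MTPM) parallelizes two-photon excitation by
raster-scanning an array of beamlets and imaging the fluorescence onto a
camera. The parallelization buys speed and signal, but in scattering tissue
such as mammalian brain the camera can no longer tell which beamlet a
detected photon came from: scattered emission lands between the excitation
lines, degrading contrast at depth and mixing functional signals between
neighbouring neurons.

`slmtpm` implements a *source-localization* reconstruction for this problem,
together with the simulation and analysis stack around it:

- **Scattering-kernel Monte Carlo** (`scatter_config()`, `sample_kernel()`).
  Photons from a point emitter at the focal plane are propagated through a
  homogeneous slab of thickness *z<sub>h</sub>* with exponential free paths
  (scattering coefficient *μ*, mm⁻¹) and Henyey–Greenstein deflections
  (anisotropy *g*, the mean cosine of the single-scattering angle). Photons
  crossing the tissue surface are traced back along their final direction to
  their apparent origin on the focal plane; the binned, unit-sum histogram of
  apparent origins is the scattering PSF *p*. The compiled walk does 10⁷
  photons in seconds; a pure-R reference walk (`propagate_photon()`) serves
  as an independent cross-check.
- **Streak reconstruction** (`richardson_lucy()`, `reconstruct_series()`).
  The scan is temporally oversampled so that each camera sub-frame (a
  "streak" image *d*) contains one raster line per beamlet — any off-line
  light is known to be scattered. Each streak image is deconvolved by
  100 iterations of the Richardson–Lucy update

  &nbsp;&nbsp;&nbsp;&nbsp;*u*<sub>t+1</sub> = *u*<sub>t</sub> · ( ( *d* / (*u*<sub>t</sub> ⊗ *p*) ) ⊗ *p̂* ),

  from a flat prior with reflective boundary padding, where *p̂* is the PSF
  mirrored along the *x = y* axis (the conventional 180°-rotated adjoint is
  available as an option). A maximum-intensity projection through the *m*
  deconvolved streak images recovers one source-localized frame; the mean of
  the raw streak images is the standard-MTPM comparator
  (`mean_frame_series()`).
- **Synthetic forward model** (`generate_cell_scene()`, `split_streaks()`,
  `apply_scattering()`, `add_noise()`, `render_dynamic_stack()`). Labelled
  cell scenes, exact column-wise streak splitting (image *k* keeps columns
  ≡ *k* mod *m*), depth-dependent scattering blur, the multiplicative camera
  noise model *I* ~ Normal(*I₀*, *I₀*/10), and per-cell calcium dynamics.
- **Contrast at depth** (`michelson_contrast()`, `depth_series()`,
  `cutoff_depth()`). Michelson contrast
  *C* = (*I*<sub>max</sub> − *I*<sub>min</sub>)/(*I*<sub>max</sub> + *I*<sub>min</sub>)
  from the 99.9th percentile of cellular and 10th percentile of background
  intensities, contrast–depth profiles for grids of foci separations and
  scattering coefficients, and 50%-cutoff depths from a cubic fit.
- **Functional analysis** (`local_correlation_map()`,
  `segment_functional_roi()`, `dff()`, `slr()`, `transient_model()`,
  `fit_amplitude()`, `psnr()`). Correlation/variance-map ROI segmentation,
  ΔF/F₀ traces, the signal localization ratio (peak intracellular over peak
  extracellular ΔF/F₀ — higher means less crosstalk), the double-exponential
  calcium transient *f(t) = Σₖ A·c<sub>α,γ</sub>(e^{−α(t−tₖ)} − e^{−γ(t−tₖ)})·u(t−tₖ)*
  with closed-form peak normalization, linear least-squares amplitude
  fitting, and PSNR = *A*²/*σ*².

TIFF/YAML I/O is provided by `read_stack()`/`write_stack()`, and
`inst/cli/slmtpm` is a thin command-line dispatcher over the same functions
(`simulate-kernel`, `simulate-data`, `reconstruct`, `analyze-contrast`,
`analyze-functional`, `model-depth`).

## Worked example: crosstalk between two neurons

One active and one silent cell, 25 µm apart, imaged at 100 µm depth in
tissue with μ = 20 mm⁻¹, g = 0.9. Eight streak sub-frames per frame at 10
reconstructed frames/s; the active cell fires once at t = 0.3 s with a peak
ΔF/F₀ of 1.

```r
library(slmtpm)

kern <- sample_kernel(scatter_config(mu = 20, g = 0.9, z_h = 100,
                                     n_photons = 1e6, seed = 3))
print(kern)
#> <scatter_kernel> 33 x 33 bins, pitch 1.5625 um, width 12.93 um
#>   922494 photons collected (607693 binned), 2.60 scattering events/photon

scene <- generate_cell_scene(2, shape = c(40, 40), pixel_size = 1.5625,
                             seed = 2, centers = rbind(c(20, 13), c(20, 28)))
dyn <- dynamic_scene(scene, spike_times = list(0.3, numeric(0)),
                     frame_rate = 10, duration = 1, amplitudes = 1)
stack <- render_dynamic_stack(dyn, geom = 8, kernel = kern, seed = 8,
                              dark_level = 100)
out <- reconstruct_series(stack, recon_config(kern, iterations = 100))

win <- stimulus_window(0.3, frame_rate = 10, n_frames = 10)
surround <- !(scene$masks[[1]] | scene$masks[[2]])
slr_of <- function(fs) {
  intra <- dff(fs, scene$masks[[1]], baseline_window = 1:3, frame_rate = 10)
  extra <- dff(fs, surround, baseline_window = 1:3, frame_rate = 10)
  as.numeric(slr(intra, extra, win))
}
slr_of(out$raw_mean)          # 8.7
slr_of(out$source_localized)  # 79.6
```

The raw-mean movie leaks the transient into the surround (signal
localization ratio 8.7: the extracellular trace shows roughly an eighth of
the intracellular response). After Richardson–Lucy reassignment the ratio
rises to 79.6 — the scattered photons have been returned to the active cell,
so a silent neighbour's trace is no longer contaminated.

The same machinery runs the foci-separation depth study:

```r
scene <- generate_cell_scene(5, shape = c(64, 64), pixel_size = 3.125, seed = 11)
tbl  <- depth_series(scene, n_photons = 1e6, depth_reference_mu = 20, seed = 20260101)
depth_cutoff_summary(tbl)
```

which reports, per scattering coefficient and line separation, the depth at
which relative contrast falls to 50% for standard and source-localized MTPM
(for μ = 20 mm⁻¹ at 12.5 µm separation: 151 µm raw vs 309 µm
source-localized), with the source-localization advantage growing with line
separation.

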