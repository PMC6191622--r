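#' Generate a synthetic labelled-cell scene
#'
#' Places non-overlapping soma-like discs (radius 5-8 um) with bright
#' membrane rims on a background, emulating fluorophore-labelled neurons.
#' `"multi-cell"` labelling adds a diffuse neuropil background (bath-applied
#' dye); `"single-cell"` labelling puts one bright cell on a near-zero
#' background (intracellular loading).
#'
#' @param n_cells number of cells to place.
#' @param shape image dimensions `c(rows, cols)` in pixels.
#' @param pixel_size sample-space pixel size, um.
#' @param labeling `"multi-cell"` or `"single-cell"`.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param centers optional `n_cells x 2` matrix of (row, col) centres in
#'   pixels, overriding random placement.
#' @return a `scene`: list with `truth` (nonnegative matrix), `pixel_size`
#'   and `masks` (list of per-cell logical matrices).
#' @export
generate_cell_scene <- function(n_cells = 5, shape = c(64, 64),
                                pixel_size = 1.5625,
                                labeling = c("multi-cell", "single-cell"),
                                seed = NULL, centers = NULL) {
  labeling <- match.arg(labeling)
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  if (labeling == "single-cell" && is.null(centers)) n_cells <- max(n_cells, 1L)
  with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    radii_um <- runif(n_cells, 5, 8)
    radii <- radii_um / pixel_size
    if (is.null(centers)) {
      centers <- matrix(NA_real_, n_cells, 2)
      for (i in seq_len(n_cells)) {
        placed <- FALSE
        for (try in seq_len(500L)) {
          cand <- c(runif(1, radii[i] + 2, nr - radii[i] - 1),
                    runif(1, radii[i] + 2, nc - radii[i] - 1))
          ok <- TRUE
          if (i > 1L) {
            d <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                                 matrix(cand, i - 1L, 2, byrow = TRUE))^2))
            ok <- all(d > radii[i] + radii[seq_len(i - 1L)] + 2)
          }
          if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
        }
        if (!placed) {
          stop("could not place ", n_cells,
               " non-overlapping cells in the given shape", call. = FALSE)
        }
      }
    }
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    truth <- if (labeling == "multi-cell") {
      # diffuse neuropil: smoothed uniform texture around 0.1 of soma level
      bg <- matrix(runif(nr * nc), nr, nc)
      box <- matrix(1 / 25, 5, 5)
      0.05 + 0.1 * conv2d(bg, box, "reflect")
    } else {
      matrix(0, nr, nc)
    }
    masks <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      r <- sqrt((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2)
      mask <- r <= radii[i]
      bright <- runif(1, 0.95, 1.05)
      body <- 0.9 * bright * (r <= 0.7 * radii[i])
      rim <- bright * (r > 0.7 * radii[i] & mask)
      truth <- truth * (!mask) + body + rim
      masks[[i]] <- mask
    }
    structure(list(truth = pmax(truth, 0), pixel_size = pixel_size,
                   masks = masks, labeling = labeling),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d x %d px (%.3g um/px), %d cell(s), %s labeling\n",
              nrow(x$truth), ncol(x$truth), x$pixel_size, length(x$masks),
              x$labeling))
  invisible(x)
}

#' Multifocal scan geometry
#'
#' @param line_separation streak (beamlet) spacing in um; 12.5 um default.
#' @param pixel_size sample-space pixel size, um. The oversampling factor is
#'   `m = line_separation / pixel_size` and must be an exact integer.
#' @param streak_axis `"y"` for vertical streaks (matrix columns).
#' @return a `scan_geometry` with fields `line_separation`, `m`,
#'   `pixel_size`, `streak_axis`.
#' @export
scan_geometry <- function(line_separation = 12.5, pixel_size = 1.5625,
                          streak_axis = c("y", "x")) {
  streak_axis <- match.arg(streak_axis)
  if (line_separation <= 0) stop("`line_separation` must be > 0", call. = FALSE)
  m <- line_separation / pixel_size
  if (abs(m - round(m)) > 1e-9) {
    stop("`line_separation` must be an integer multiple of `pixel_size`",
         call. = FALSE)
  }
  structure(list(line_separation = line_separation, m = as.integer(round(m)),
                 pixel_size = pixel_size, streak_axis = streak_axis),
            class = "scan_geometry")
}

#' Split a scene into streak line images
#'
#' Partitions an image into `m` line images: image `k` (`k = 0..m-1`,
#' 0-based) retains the columns whose 0-based index is congruent to `k`
#' modulo `m` and is zero elsewhere. The outputs sum exactly to the input;
#' they emulate the temporally oversampled streak sub-frames of an `m`-line
#' scan.
#'
#' @param x a `scene`, or a 2-D numeric matrix.
#' @param m oversampling factor (lines per beamlet pitch), or a
#'   [scan_geometry()].
#' @return list of `m` matrices.
#' @export
split_streaks <- function(x, m) {
  img <- if (inherits(x, "scene")) x$truth else x
  check_image(img, "x")
  axis <- "y"
  if (inherits(m, "scan_geometry")) {
    geom <- m
    axis <- geom$streak_axis
    if (inherits(x, "scene") &&
        abs(geom$pixel_size - x$pixel_size) > 1e-9) {
      stop("scan geometry pixel size does not match the scene", call. = FALSE)
    }
    m <- geom$m
  }
  m <- as.integer(m)
  n_across <- if (axis == "y") ncol(img) else nrow(img)
  if (m < 1L || m > n_across) {
    stop("incompatible pitch: `m` must be in [1, image width]", call. = FALSE)
  }
  lapply(seq_len(m) - 1L, function(k) {
    out <- matrix(0, nrow(img), ncol(img))
    idx <- which((seq_len(n_across) - 1L) %% m == k)
    if (axis == "y") out[, idx] <- img[, idx] else out[idx, ] <- img[idx, ]
    out
  })
}

#' Apply depth-dependent scattering blur to line images
#'
#' Convolves each line image with the unit-sum scattering kernel.
#'
#' @param line_images list of matrices (or one matrix).
#' @param kernel a `scatter_kernel`.
#' @param boundary `"reflect"` (default) or `"periodic"`; with a periodic
#'   boundary total flux is conserved exactly.
#' @return blurred images (same structure as input).
#' @export
apply_scattering <- function(line_images, kernel,
                             boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(kernel, "scatter_kernel"))
  k <- kernel$values / sum(kernel$values)
  blur <- function(img) pmax(conv2d(img, k, boundary), 0)  # clip FFT round-off
  if (is.matrix(line_images)) return(blur(line_images))
  check_image_list(line_images, "line_images")
  lapply(line_images, blur)
}

#' Add the camera noise model
#'
#' Replaces every pixel value `I0` with a draw from `Normal(I0, I0 / 10)`
#' (standard deviation proportional to intensity), clipped at zero. Pixels
#' with `I0 = 0` stay exactly zero.
#'
#' @param images list of matrices (or one matrix), values `>= 0`.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param sd_frac noise standard deviation as a fraction of intensity.
#' @return noisy images (same structure as input).
#' @export
add_noise <- function(images, seed = NULL, sd_frac = 0.1) {
  noisify <- function(img) {
    if (any(img < 0)) stop("`images` must be nonnegative", call. = FALSE)
    out <- matrix(rnorm(length(img), mean = img, sd = sd_frac * img),
                  nrow(img), ncol(img))
    pmax(out, 0)
  }
  with_seed(seed, {
    if (is.matrix(images)) noisify(images) else {
      check_image_list(images, "images")
      lapply(images, noisify)
    }
  })
}

#' Dynamic (time-resolved) scene
#'
#' Attaches per-cell spiking activity and calcium-transient dynamics to a
#' [generate_cell_scene()] scene; cell `i`'s brightness at frame time `t` is
#' scaled by `1 + f_i(t)` where `f_i` is the double-exponential transient of
#' [transient_waveform()] driven by `spike_times[[i]]`.
#'
#' @param scene a `scene`.
#' @param spike_times list (one numeric vector of spike times in seconds per
#'   cell, within `[0, duration]`).
#' @param frame_rate reconstructed frames per second.
#' @param duration recording length, seconds.
#' @param amplitudes peak dF/F0 amplitude `A` per cell (recycled).
#' @param alpha,gamma transient decay/rise rates, s^-1.
#' @return a `dynamic_scene`.
#' @export
dynamic_scene <- function(scene, spike_times, frame_rate, duration,
                          amplitudes = 1, alpha = 3.18, gamma = 34.39) {
  stopifnot(inherits(scene, "scene"))
  n_cells <- length(scene$masks)
  if (!is.list(spike_times) || length(spike_times) != n_cells) {
    stop("`spike_times` must be a list with one vector per cell", call. = FALSE)
  }
  if (any(unlist(spike_times) < 0) || any(unlist(spike_times) > duration)) {
    stop("spike times must lie within [0, duration]", call. = FALSE)
  }
  amplitudes <- rep_len(amplitudes, n_cells)
  models <- lapply(seq_len(n_cells), function(i) {
    transient_model(A = amplitudes[i], alpha = alpha, gamma = gamma,
                    spike_times = spike_times[[i]])
  })
  structure(list(scene = scene, models = models, frame_rate = frame_rate,
                 duration = duration),
            class = "dynamic_scene")
}

#' Render a dynamic scene into a streak stack
#'
#' The forward model for functional-imaging fixtures: for each reconstructed
#' frame time, each cell's pixels are scaled by `1 + dF/F0(t)`, the frame is
#' split into `m` streak sub-frames, each sub-frame is blurred by the
#' scattering kernel, offset by the dark level, and corrupted by the
#' multiplicative Gaussian noise model.
#'
#' @param dyn a [dynamic_scene()].
#' @param geom oversampling factor `m` or a [scan_geometry()].
#' @param kernel a `scatter_kernel`.
#' @param noise apply [add_noise()]?
#' @param seed RNG seed for the noise; `NULL` uses the current stream.
#' @param dark_level camera offset added to every sub-frame, counts.
#' @param intensity_scale counts per unit of scene brightness.
#' @return a [streak_stack()] with `m * n_frames` sub-frames.
#' @export
render_dynamic_stack <- function(dyn, geom, kernel, noise = TRUE, seed = NULL,
                                 dark_level = 0, intensity_scale = 100) {
  stopifnot(inherits(dyn, "dynamic_scene"))
  m <- if (inherits(geom, "scan_geometry")) geom$m else as.integer(geom)
  n_frames <- round(dyn$duration * dyn$frame_rate)
  times <- (seq_len(n_frames) - 1L) / dyn$frame_rate
  scene <- dyn$scene
  with_seed(seed, {
    subs <- vector("list", m * n_frames)
    for (i in seq_len(n_frames)) {
      truth_t <- scene$truth
      for (ci in seq_along(scene$masks)) {
        f <- transient_waveform(times[i], dyn$models[[ci]])
        if (f != 0) {
          msk <- scene$masks[[ci]]
          truth_t[msk] <- truth_t[msk] * (1 + f)
        }
      }
      lines <- split_streaks(truth_t * intensity_scale, m)
      blurred <- apply_scattering(lines, kernel)
      for (k in seq_len(m)) {
        sf <- blurred[[k]] + dark_level
        if (noise) sf <- add_noise(sf)
        subs[[(i - 1L) * m + k]] <- sf
      }
    }
    streak_stack(subs, m = m, frame_rate = dyn$frame_rate,
                 dark_level = dark_level)
  })
}

#' Model contrast against depth for foci separations and scattering levels
#'
#' The foci-separation depth study: for every combination of scattering
#' coefficient, streak separation and slab depth, the ground-truth scene is
#' split into line images, blurred with a Monte Carlo scattering kernel for
#' that `(mu, depth)`, and corrupted with the Gaussian noise model. Standard
#' MTPM is emulated by a sum projection through the noisy line images;
#' source-localized MTPM deconvolves each line image with the centred
#' `(2 * crop_halfwidth + 1)`-square crop of the kernel and takes a maximum
#' intensity projection. Michelson contrast of both images is recorded.
#'
#' @param scene a `scene`.
#' @param separations streak separations, um (each an integer multiple of the
#'   scene pixel size).
#' @param mu_values scattering coefficients, mm^-1.
#' @param depths slab depths, um.
#' @param g Henyey-Greenstein anisotropy.
#' @param n_photons photons per kernel.
#' @param iterations Richardson-Lucy iterations.
#' @param crop_halfwidth halfwidth of the deconvolution kernel crop.
#' @param blur_halfwidth halfwidth of the forward-blur kernel; default the
#'   largest that fits the scene.
#' @param depth_reference_mu when non-`NULL`, the `depths` grid is taken to
#'   refer to this scattering coefficient and is rescaled per condition as
#'   `depths * depth_reference_mu / mu`, sampling every `mu` over comparable
#'   optical depths `mu * z`.
#' @param contrast_masks `"truth"` measures Michelson contrast over the
#'   scene's known cell/background masks (recommended for simulation studies,
#'   where ground truth exists); `"segmentation"` re-segments every modeled
#'   image with [segment_for_contrast()].
#' @param seed RNG seed covering kernel sampling and noise.
#' @return a data.frame with columns `mu`, `line_separation`, `depth`,
#'   `contrast_raw`, `contrast_sl`.
#' @seealso [cutoff_depth()], [depth_cutoff_summary()]
#' @export
depth_series <- function(scene, separations = c(6.25, 12.5, 25, 50),
                         mu_values = c(10, 20, 40),
                         depths = c(25, 75, 150, 250, 375, 500),
                         g = 0.9, n_photons = 1e6, iterations = 100,
                         crop_halfwidth = 16, blur_halfwidth = NULL,
                         depth_reference_mu = NULL,
                         contrast_masks = c("truth", "segmentation"),
                         seed = NULL) {
  stopifnot(inherits(scene, "scene"))
  contrast_masks <- match.arg(contrast_masks)
  truth <- scene$truth
  px <- scene$pixel_size
  gt_masks <- if (contrast_masks == "truth") {
    cell <- Reduce(`|`, scene$masks)
    list(cell_mask = cell, background_mask = !cell, degenerate = FALSE)
  } else NULL
  ms <- separations / px
  if (any(abs(ms - round(ms)) > 1e-9)) {
    stop("`separations` must be integer multiples of the scene pixel size",
         call. = FALSE)
  }
  ms <- as.integer(round(ms))
  blur_halfwidth <- as.integer(blur_halfwidth %||%
                                 min((min(dim(truth)) - 1L) %/% 2L,
                                     2L * crop_halfwidth))
  rows <- list()
  with_seed(seed, {
    for (mu in mu_values) {
      mu_depths <- if (is.null(depth_reference_mu)) depths else {
        depths * depth_reference_mu / mu
      }
      for (depth in mu_depths) {
        kern_full <- sample_kernel(scatter_config(
          mu = mu, g = g, z_h = depth, n_photons = n_photons,
          pixel_pitch = px, kernel_halfwidth = blur_halfwidth))
        kern_crop <- crop_kernel(kern_full, crop_halfwidth)
        rc <- recon_config(kern_crop, iterations = iterations)
        for (si in seq_along(ms)) {
          lines <- split_streaks(truth, ms[si])
          noisy <- add_noise(apply_scattering(lines, kern_full))
          raw <- Reduce(`+`, noisy)
          sl <- Reduce(pmax, lapply(noisy, richardson_lucy, cfg = rc))
          rows[[length(rows) + 1L]] <- data.frame(
            mu = mu, line_separation = separations[si], depth = depth,
            contrast_raw = michelson_contrast(raw, gt_masks)$contrast,
            contrast_sl = michelson_contrast(sl, gt_masks)$contrast)
        }
      }
    }
  })
  do.call(rbind, rows)
}

#' Summarise a depth study into 50% cutoff depths
#'
#' For each `(mu, line_separation)` condition, normalises the contrast-depth
#' profiles of both arms to their shallowest-depth value and estimates the
#' 50% contrast cutoff depth by [cutoff_depth()]. A profile that never falls
#' below half its shallow value within the sampled range is right-censored at
#' the deepest sampled depth.
#'
#' @param tbl output of [depth_series()].
#' @return a data.frame with `mu`, `line_separation`, `cutoff_raw`,
#'   `cutoff_sl` and `advantage` (their difference, um).
#' @export
depth_cutoff_summary <- function(tbl) {
  conds <- unique(tbl[, c("mu", "line_separation")])
  out <- lapply(seq_len(nrow(conds)), function(i) {
    sub <- tbl[tbl$mu == conds$mu[i] &
                 tbl$line_separation == conds$line_separation[i], ]
    sub <- sub[order(sub$depth), ]
    cut_of <- function(contrasts) {
      prof <- contrast_profile(sub$depth, contrasts)
      if (is.na(prof$cutoff_depth)) max(sub$depth) else prof$cutoff_depth
    }
    data.frame(mu = conds$mu[i], line_separation = conds$line_separation[i],
               cutoff_raw = cut_of(sub$contrast_raw),
               cutoff_sl = cut_of(sub$contrast_sl))
  })
  out <- do.call(rbind, out)
  out$advantage <- out$cutoff_sl - out$cutoff_raw
  out
}
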