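#' Sample a scattering point-spread kernel by Monte Carlo
#'
#' Runs `cfg$n_photons` independent photon walks through the slab (compiled
#' code; see [propagate_photon()] for the reference walk), backprojects each
#' collected photon along its final direction to the focal plane, bins the
#' apparent origins on a square grid centred on the true source, and
#' normalises the histogram to unit sum. Photons exiting backwards through
#' the source plane, or landing outside the grid, are discarded. Runs are
#' bit-identical for a fixed `cfg$seed`.
#'
#' @param cfg a [scatter_config()].
#' @return a `scatter_kernel`: list with `values` (odd-sided, nonnegative,
#'   unit-sum matrix), `pixel_pitch` (um), `meta` (the configuration) and
#'   `stats` (collected/lost/binned counts and the mean number of scattering
#'   events per collected photon).
#' @examples
#' k <- sample_kernel(scatter_config(n_photons = 2e4, z_h = 50, seed = 1))
#' sum(k$values)
#' @export
sample_kernel <- function(cfg) {
  stopifnot(inherits(cfg, "scatter_config"))
  res <- with_seed(cfg$seed, .mc_sample_kernel(
    n_photons = cfg$n_photons,
    mu_um = cfg$mu / 1000,
    g = cfg$g,
    z_h = cfg$z_h,
    theta_max = asin(cfg$na / cfg$n_medium),
    elevation_solid_angle = as.integer(cfg$elevation == "solid-angle"),
    pixel_pitch = cfg$pixel_pitch,
    halfwidth = cfg$kernel_halfwidth,
    max_events = cfg$max_events
  ))
  if (res$n_binned <= 0) {
    stop("empty kernel: no collected photons fell on the kernel grid",
         call. = FALSE)
  }
  structure(
    list(values = res$counts / sum(res$counts),
         pixel_pitch = cfg$pixel_pitch,
         meta = cfg,
         stats = list(n_collected = res$n_collected, n_lost = res$n_lost,
                      n_binned = res$n_binned,
                      mean_events = res$mean_events)),
    class = "scatter_kernel"
  )
}

#' Construct a delta (identity) kernel
#'
#' @param halfwidth bins from centre to edge.
#' @param pixel_pitch bin size, um.
#' @return a `scatter_kernel` with all mass in the centre bin.
#' @export
delta_kernel <- function(halfwidth = 16, pixel_pitch = 1.5625) {
  side <- 2L * as.integer(halfwidth) + 1L
  v <- matrix(0, side, side)
  v[halfwidth + 1L, halfwidth + 1L] <- 1
  structure(list(values = v, pixel_pitch = pixel_pitch, meta = NULL,
                 stats = NULL),
            class = "scatter_kernel")
}

#' Centred crop of a scattering kernel
#'
#' Extracts the central `(2 * halfwidth + 1)` square of a wider kernel and
#' renormalises it to unit sum. Used to mimic deconvolving with a small
#' cropped kernel while the forward blur uses the full one.
#'
#' @param kernel a `scatter_kernel`.
#' @param halfwidth target halfwidth; must not exceed the kernel's.
#' @return a `scatter_kernel`.
#' @export
crop_kernel <- function(kernel, halfwidth) {
  stopifnot(inherits(kernel, "scatter_kernel"))
  h_in <- (nrow(kernel$values) - 1L) %/% 2L
  halfwidth <- as.integer(halfwidth)
  if (halfwidth > h_in) stop("crop halfwidth exceeds kernel size", call. = FALSE)
  idx <- h_in + 1L + seq.int(-halfwidth, halfwidth)
  v <- kernel$values[idx, idx, drop = FALSE]
  s <- sum(v)
  if (s <= 0) stop("empty kernel after crop", call. = FALSE)
  kernel$values <- v / s
  kernel
}

#' Radial width of a kernel
#'
#' Root of the second moment of radius about the kernel centre, in um:
#' `sqrt(sum(k * r^2))` over the unit-sum kernel. Grows with slab depth as
#' scattering broadens the apparent source.
#'
#' @param kernel a `scatter_kernel`.
#' @return width in um.
#' @export
kernel_radial_moment <- function(kernel) {
  stopifnot(inherits(kernel, "scatter_kernel"))
  v <- kernel$values / sum(kernel$values)
  h <- (nrow(v) - 1L) %/% 2L
  ax <- seq.int(-h, h) * kernel$pixel_pitch
  r2 <- outer(ax^2, ax^2, `+`)
  sqrt(sum(v * r2))
}

#' Relative L2 asymmetry of a kernel under 90-degree rotation
#'
#' `||K - rot90(K)|| / ||K||`; small values indicate an approximately
#' radially symmetric kernel.
#'
#' @param kernel a `scatter_kernel` or matrix.
#' @return a nonnegative scalar.
#' @export
kernel_rotational_asymmetry <- function(kernel) {
  v <- if (inherits(kernel, "scatter_kernel")) kernel$values else kernel
  rot <- t(v[nrow(v):1, , drop = FALSE])
  sqrt(sum((v - rot)^2)) / sqrt(sum(v^2))
}

#' @export
print.scatter_kernel <- function(x, ...) {
  side <- nrow(x$values)
  cat(sprintf("<scatter_kernel> %d x %d bins, pitch %g um, width %.2f um\n",
              side, side, x$pixel_pitch, kernel_radial_moment(x)))
  if (!is.null(x$stats)) {
    cat(sprintf("  %g photons collected (%g binned), %.2f scattering events/photon\n",
                x$stats$n_collected, x$stats$n_binned, x$stats$mean_events))
  }
  invisible(x)
}
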