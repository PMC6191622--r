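#' Configuration for the scattering-kernel Monte Carlo
#'
#' Bundles the optical and sampling parameters of the photon-transport
#' simulation used to derive the deconvolution kernel. The model is an
#' isotropically labelled point emitter at the focal plane (`z = 0`) under a
#' homogeneous scattering slab of thickness `z_h`; photons launched within the
#' objective's collection cone propagate with exponential free paths and
#' Henyey-Greenstein deflections until they leave the slab.
#'
#' @param mu scattering coefficient, mm^-1 (reciprocal mean free path).
#'   Cortical grey matter is typically 10-40 mm^-1; default 20.
#' @param g Henyey-Greenstein anisotropy in `[0, 1)`; `g` is the mean cosine
#'   of the single-scattering deflection angle. Default 0.9 (forward-biased,
#'   typical of brain tissue).
#' @param z_h slab thickness, i.e. imaging depth below the tissue surface, um.
#' @param na numerical aperture of the collection objective.
#' @param n_medium refractive index of the immersion/tissue medium used to
#'   convert `na` to the half-angle of the launch cone,
#'   `theta_max = asin(na / n_medium)`. Default 1.33 (water immersion); set
#'   `n_medium = na` for a full hemisphere.
#' @param n_photons number of photon walks used to sample the kernel.
#' @param pixel_pitch kernel bin size in sample space, um. Defaults to
#'   1.5625 um, the raster-line spacing of an 8-line scan over a 12.5 um
#'   beamlet pitch.
#' @param kernel_halfwidth bins from the kernel centre to its edge; the kernel
#'   is square with odd side `2 * kernel_halfwidth + 1`.
#' @param seed RNG seed used by [sample_kernel()]; `NULL` uses the current
#'   RNG stream.
#' @param elevation `"angle"` draws the launch elevation uniformly in the
#'   polar angle on `[0, theta_max]`; `"solid-angle"` draws it uniformly over
#'   the spherical cap (uniform in `cos(theta)`).
#' @param max_events iteration cap per photon walk (plumbing safeguard).
#'
#' @return An object of class `scatter_config`.
#' @seealso [sample_kernel()], [propagate_photon()]
#' @export
scatter_config <- function(mu = 20, g = 0.9, z_h = 190, na = 1,
                           n_medium = 1.33, n_photons = 1e6,
                           pixel_pitch = 1.5625, kernel_halfwidth = 16,
                           seed = NULL, elevation = c("angle", "solid-angle"),
                           max_events = 1e6) {
  elevation <- match.arg(elevation)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("`mu` must be a single positive scattering coefficient (mm^-1)",
         call. = FALSE)
  }
  if (!is.numeric(g) || length(g) != 1L || g < 0 || g >= 1) {
    stop("`g` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(z_h) || length(z_h) != 1L || z_h < 0) {
    stop("`z_h` must be a nonnegative depth (um)", call. = FALSE)
  }
  if (!is.numeric(na) || length(na) != 1L || na <= 0 || na > n_medium) {
    stop("invalid configuration: need 0 < na <= n_medium", call. = FALSE)
  }
  if (!is.numeric(n_photons) || length(n_photons) != 1L || n_photons < 1) {
    stop("`n_photons` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L ||
      pixel_pitch <= 0) {
    stop("`pixel_pitch` must be positive (um)", call. = FALSE)
  }
  if (!is.numeric(kernel_halfwidth) || length(kernel_halfwidth) != 1L ||
      kernel_halfwidth < 0 || kernel_halfwidth != round(kernel_halfwidth)) {
    stop("`kernel_halfwidth` must be a nonnegative integer", call. = FALSE)
  }
  structure(
    list(mu = mu, g = g, z_h = z_h, na = na, n_medium = n_medium,
         n_photons = n_photons, pixel_pitch = pixel_pitch,
         kernel_halfwidth = as.integer(kernel_halfwidth), seed = seed,
         elevation = elevation, max_events = max_events),
    class = "scatter_config"
  )
}

#' @export
print.scatter_config <- function(x, ...) {
  cat("<scatter_config>\n",
      sprintf("  mu = %g mm^-1, g = %g, z_h = %g um\n", x$mu, x$g, x$z_h),
      sprintf("  NA = %g (n = %g, theta_max = %.4f rad, %s elevation)\n",
              x$na, x$n_medium, asin(x$na / x$n_medium), x$elevation),
      sprintf("  %g photons, pitch %g um, kernel %d x %d\n",
              x$n_photons, x$pixel_pitch,
              2L * x$kernel_halfwidth + 1L, 2L * x$kernel_halfwidth + 1L),
      sep = "")
  invisible(x)
}

#' Sample initial photon launch directions
#'
#' Draws unit direction vectors for photons leaving the source toward the
#' tissue surface: azimuth uniform on `[0, 2*pi)`, elevation (polar angle
#' from the optical axis) uniform on `[0, theta_max]` with
#' `theta_max = asin(na / n_medium)` (or uniform on the spherical cap when
#' `cfg$elevation == "solid-angle"`).
#'
#' @param cfg a [scatter_config()].
#' @param n number of directions.
#' @return an `n x 3` matrix of unit vectors; the third component (along the
#'   optical axis, into the slab toward the surface) is positive.
#' @export
sample_initial_direction <- function(cfg, n = 1L) {
  stopifnot(inherits(cfg, "scatter_config"))
  theta_max <- asin(cfg$na / cfg$n_medium)
  ct <- if (cfg$elevation == "angle") {
    cos(runif(n, 0, theta_max))
  } else {
    runif(n, cos(theta_max), 1)
  }
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- runif(n, 0, 2 * pi)
  cbind(x = st * cos(phi), y = st * sin(phi), z = ct)
}

#' Sample photon free-path lengths
#'
#' Free paths between scattering events are exponential with mean `1 / mu`.
#'
#' @param n number of draws.
#' @param mu scattering coefficient, mm^-1.
#' @return path lengths in mm.
#' @export
sample_free_path <- function(n, mu) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("`mu` must be a single positive scattering coefficient (mm^-1)",
         call. = FALSE)
  }
  rexp(n, rate = mu)
}

#' Sample Henyey-Greenstein deflection angles
#'
#' Draws polar deflection angles whose cosine follows the Henyey-Greenstein
#' phase function with anisotropy `g`, via the standard inverse CDF
#' `cos(theta) = (1 + g^2 - ((1 - g^2) / (1 - g + 2 g U))^2) / (2 g)`
#' (`cos(theta) = 2U - 1` in the isotropic limit `g = 0`).
#'
#' @param n number of draws.
#' @param g anisotropy in `[0, 1)`; equals the mean cosine of the deflection.
#' @return deflection angles in radians, in `[0, pi]`.
#' @export
sample_hg_deflection <- function(n, g) {
  if (!is.numeric(g) || length(g) != 1L || g < 0 || g >= 1) {
    stop("`g` must lie in [0, 1)", call. = FALSE)
  }
  u <- runif(n)
  ct <- if (g == 0) {
    2 * u - 1
  } else {
    f <- (1 - g^2) / (1 - g + 2 * g * u)
    (1 + g^2 - f^2) / (2 * g)
  }
  acos(pmin(1, pmax(-1, ct)))
}

#' Henyey-Greenstein density of the deflection cosine
#'
#' `p(cos theta) = (1 - g^2) / (2 * (1 + g^2 - 2 g cos theta)^(3/2))`,
#' normalised over `cos(theta)` in `[-1, 1]`.
#'
#' @param cos_theta cosine(s) of the deflection angle.
#' @param g anisotropy in `[0, 1)`.
#' @return density values.
#' @export
hg_density <- function(cos_theta, g) {
  0.5 * (1 - g^2) / (1 + g^2 - 2 * g * cos_theta)^1.5
}

#' Rotate propagation directions by a scattering deflection
#'
#' Rotates each input unit vector by the polar `deflection` about a local
#' frame aligned with it, with azimuthal spin `azimuth`; the dot product of
#' input and output equals `cos(deflection)`.
#'
#' @param direction a length-3 unit vector or an `n x 3` matrix of them.
#' @param deflection polar deflection angle(s), rad.
#' @param azimuth azimuthal spin angle(s), rad.
#' @return same shape as `direction`, unit-norm rows.
#' @export
scatter_direction <- function(direction, deflection, azimuth) {
  vec <- is.null(dim(direction))
  d <- if (vec) matrix(direction, nrow = 1L) else as.matrix(direction)
  if (ncol(d) != 3L) stop("`direction` must have 3 components", call. = FALSE)
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm < 1e-12)) stop("invalid state: zero-norm direction", call. = FALSE)
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("`direction` rows must be unit vectors", call. = FALSE)
  }
  ct <- cos(deflection); st <- sin(deflection)
  cp <- cos(azimuth);    sp <- sin(azimuth)
  ux <- d[, 1]; uy <- d[, 2]; uz <- d[, 3]
  vertical <- abs(uz) > 0.99999
  denom <- sqrt(pmax(1 - uz^2, 0))
  nx <- ifelse(vertical, st * cp,
               st * (ux * uz * cp - uy * sp) / denom + ux * ct)
  ny <- ifelse(vertical, st * sp,
               st * (uy * uz * cp + ux * sp) / denom + uy * ct)
  nz <- ifelse(vertical, sign(uz) * ct,
               -st * cp * denom + uz * ct)
  out <- cbind(x = nx, y = ny, z = nz)
  out <- out / sqrt(rowSums(out^2))
  if (vec) drop(out) else out
}

#' Propagate a single photon through the scattering slab
#'
#' Pure-R reference implementation of one photon walk: launch from the origin
#' toward the surface, alternate exponential free paths and Henyey-Greenstein
#' deflections while inside the slab `0 <= z < z_h`, truncate the crossing
#' step at the boundary plane. The photon is `"collected"` when it crosses
#' the tissue surface `z = z_h` and `"lost"` when it crosses `z = 0`
#' backwards (such photons never reach the epi-collection optics).
#'
#' [sample_kernel()] runs the same walk in compiled code; this function is
#' retained as an independent cross-check and for inspecting single paths.
#'
#' @param cfg a [scatter_config()].
#' @return a list with `position` (exit point, um), `direction` (exit unit
#'   vector), `n_events` (scattering events) and `status`
#'   (`"collected"`/`"lost"`).
#' @export
propagate_photon <- function(cfg) {
  stopifnot(inherits(cfg, "scatter_config"))
  mu_um <- cfg$mu / 1000              # mm^-1 -> um^-1
  dir <- drop(sample_initial_direction(cfg, 1L))
  pos <- c(0, 0, 0)
  n_events <- 0L
  if (cfg$z_h <= 0) {
    return(list(position = pos, direction = dir, n_events = 0L,
                status = "collected"))
  }
  repeat {
    step <- rexp(1L, rate = mu_um)    # um
    zn <- pos[3] + dir[3] * step
    if (dir[3] > 0 && zn >= cfg$z_h) {
      t <- (cfg$z_h - pos[3]) / dir[3]
      pos <- pos + dir * t
      return(list(position = pos, direction = dir, n_events = n_events,
                  status = "collected"))
    }
    if (dir[3] < 0 && zn < 0) {
      t <- -pos[3] / dir[3]
      pos <- pos + dir * t
      return(list(position = pos, direction = dir, n_events = n_events,
                  status = "lost"))
    }
    pos <- pos + dir * step
    dir <- scatter_direction(dir, sample_hg_deflection(1L, cfg$g),
                             runif(1L, 0, 2 * pi))
    n_events <- n_events + 1L
    if (n_events >= cfg$max_events) {
      return(list(position = pos, direction = dir, n_events = n_events,
                  status = "lost"))
    }
  }
}

#' Backproject an exiting photon to its apparent source-plane origin
#'
#' Traces the exiting photon backwards along its final propagation direction
#' to the focal plane `z = 0`; the intersection is the position at which the
#' camera, focused on the source plane, images the photon. A photon exiting
#' exactly at `z = 0` maps to its exit `(x, y)`.
#'
#' @param position exit position, length-3, um.
#' @param direction exit unit direction vector.
#' @return `c(x, y)` apparent origin in um, or `NULL` when the exit direction
#'   is parallel to the surface (such photons are excluded from the kernel).
#' @export
backproject <- function(position, direction) {
  if (abs(position[3]) < 1e-12) return(position[1:2])
  if (abs(direction[3]) < 1e-12) return(NULL)
  t <- position[3] / direction[3]
  c(position[1] - t * direction[1], position[2] - t * direction[2])
}
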