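#' Temporally oversampled streak-image stack
#'
#' Container for a series of 'streak' sub-frames: each sub-frame captures one
#' raster line per beamlet, so `m` consecutive sub-frames cover one full scan
#' and reconstruct one frame.
#'
#' @param sub_frames list of 2-D nonnegative numeric matrices in time order.
#' @param m oversampling factor: sub-frames per reconstructed frame.
#' @param frame_rate reconstructed frames per second (the sub-frame rate is
#'   `m * frame_rate`).
#' @param dark_level camera offset in counts, subtracted before processing.
#' @return a `streak_stack`.
#' @export
streak_stack <- function(sub_frames, m, frame_rate = NA_real_,
                         dark_level = 0) {
  check_image_list(sub_frames, "sub_frames")
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  structure(list(sub_frames = sub_frames, m = m, frame_rate = frame_rate,
                 dark_level = dark_level),
            class = "streak_stack")
}

#' @export
print.streak_stack <- function(x, ...) {
  d <- dim(x$sub_frames[[1]])
  cat(sprintf("<streak_stack> %d sub-frames of %d x %d (m = %d, %g frames/s, dark %g)\n",
              length(x$sub_frames), d[1], d[2], x$m, x$frame_rate,
              x$dark_level))
  invisible(x)
}

#' Reconstructed or raw movie with frame-rate metadata
#'
#' @param frames list of 2-D numeric matrices in time order.
#' @param frame_rate frames per second.
#' @param provenance `"source-localized"` or `"raw-mean"`.
#' @return a `frame_series`.
#' @export
frame_series <- function(frames, frame_rate = NA_real_,
                         provenance = c("source-localized", "raw-mean")) {
  provenance <- match.arg(provenance)
  check_image_list(frames, "frames")
  structure(list(frames = frames, frame_rate = frame_rate,
                 provenance = provenance),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_series> %d frames of %d x %d (%s, %g Hz)\n",
              length(x$frames), d[1], d[2], x$provenance, x$frame_rate))
  invisible(x)
}

#' Reconstruction configuration
#'
#' @param kernel a `scatter_kernel` used as the deconvolution PSF.
#' @param iterations Richardson-Lucy iterations (default 100).
#' @param adjoint adjoint kernel convention for the correction step:
#'   `"transpose"` mirrors the PSF along the `x = y` axis; `"rotate180"` uses
#'   the conventional flipped kernel. For near-radially-symmetric scattering
#'   kernels the two nearly coincide.
#' @param median_filter apply a 1-D median filter to each deconvolved streak
#'   image (useful on deep, low-contrast data).
#' @param median_window odd window length of the median filter, pixels.
#' @param streak_axis axis along which the streaks run: `"y"` (vertical
#'   lines, i.e. matrix columns; the default scan geometry) or `"x"`.
#' @param dark_level camera offset override; `NULL` takes the stack's value.
#' @param pad_width reflective padding width on each edge; default half the
#'   kernel side.
#' @return a `recon_config`.
#' @export
recon_config <- function(kernel, iterations = 100,
                         adjoint = c("transpose", "rotate180"),
                         median_filter = FALSE, median_window = 3,
                         streak_axis = c("y", "x"), dark_level = NULL,
                         pad_width = NULL) {
  stopifnot(inherits(kernel, "scatter_kernel"))
  adjoint <- match.arg(adjoint)
  streak_axis <- match.arg(streak_axis)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  median_window <- as.integer(median_window)
  if (median_filter && median_window %% 2L == 0L) {
    stop("`median_window` must be odd", call. = FALSE)
  }
  structure(list(kernel = kernel, iterations = iterations, adjoint = adjoint,
                 median_filter = median_filter, median_window = median_window,
                 streak_axis = streak_axis, dark_level = dark_level,
                 pad_width = pad_width),
            class = "recon_config")
}

adjoint_kernel <- function(p, adjoint) {
  if (adjoint == "transpose") t(p) else p[nrow(p):1, ncol(p):1, drop = FALSE]
}

#' Richardson-Lucy deconvolution of a streak image
#'
#' Iterates the multiplicative update
#' `u <- u * conv(d / conv(u, p), p_adj)` from a flat prior (a constant image
#' at the mean of the observed data), where `p` is the unit-sum scattering
#' PSF and `p_adj` its adjoint (see [recon_config()]). Boundaries are
#' reflectively padded before the iteration and the padding is removed from
#' the returned image; the ratio's denominator is floored at `1e-12`.
#' Nonnegativity is preserved at every iteration.
#'
#' @param d 2-D nonnegative image (negative pixels are clipped to zero with
#'   a warning).
#' @param cfg a [recon_config()], or a `scatter_kernel` (default options).
#' @param iterations optional override of `cfg$iterations`.
#' @return the deconvolved image, same shape as `d`.
#' @export
richardson_lucy <- function(d, cfg, iterations = NULL) {
  if (inherits(cfg, "scatter_kernel")) cfg <- recon_config(cfg)
  stopifnot(inherits(cfg, "recon_config"))
  check_image(d, "d")
  p <- cfg$kernel$values
  if (all(p == 0)) stop("invalid kernel: all entries are zero", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) p <- p / sum(p)
  if (any(d < 0)) {
    warning("negative input pixels clipped to 0")
    d[d < 0] <- 0
  }
  iterations <- as.integer(iterations %||% cfg$iterations)
  pad <- as.integer(cfg$pad_width %||% ((nrow(p) + 1L) %/% 2L))
  nr <- nrow(d); nc <- ncol(d)
  dp <- pad_reflect(d, pad)
  u0 <- mean(dp)
  if (u0 <= 0) return(matrix(0, nr, nc))
  otf_p <- kernel_otf(p, nrow(dp), ncol(dp))
  otf_a <- kernel_otf(adjoint_kernel(p, cfg$adjoint), nrow(dp), ncol(dp))
  u <- matrix(u0, nrow(dp), ncol(dp))
  for (i in seq_len(iterations)) {
    est <- conv_otf(u, otf_p)
    ratio <- dp / pmax(est, 1e-12)
    u <- u * conv_otf(ratio, otf_a)
    u[u < 0] <- 0   # guard against FFT round-off
  }
  u[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE]
}

median_filter_streaks <- function(img, window, streak_axis) {
  if (window < 2L || (streak_axis == "y" && nrow(img) < window) ||
      (streak_axis == "x" && ncol(img) < window)) {
    return(img)
  }
  if (streak_axis == "y") {
    apply(img, 2L, function(col) runmed(col, window, endrule = "median"))
  } else {
    t(apply(img, 1L, function(row) runmed(row, window, endrule = "median")))
  }
}

#' Reconstruct one frame from a group of streak sub-frames
#'
#' Dark-subtracts each of the `m` sub-frames, deconvolves each with
#' [richardson_lucy()], optionally median-filters along the streak axis, and
#' takes the pixelwise maximum over the group: the source-localized frame.
#'
#' @param group list of `m` streak sub-frames (matrices of one shape).
#' @param cfg a [recon_config()].
#' @param dark_level camera offset, counts.
#' @return the reconstructed 2-D frame.
#' @export
reconstruct_frame <- function(group, cfg, dark_level = 0) {
  stopifnot(inherits(cfg, "recon_config"))
  check_image_list(group, "group")
  dark <- cfg$dark_level %||% dark_level
  dec <- lapply(group, function(sf) {
    sf <- pmax(sf - dark, 0)
    out <- richardson_lucy(sf, cfg)
    if (cfg$median_filter) {
      out <- median_filter_streaks(out, cfg$median_window, cfg$streak_axis)
    }
    out
  })
  Reduce(pmax, dec)
}

#' Full-exposure comparator frame from a streak group
#'
#' The pixelwise mean of the dark-subtracted sub-frames; equivalent to
#' exposing the camera for the whole scan, i.e. standard (non-source-
#' localized) MTPM.
#'
#' @param group list of `m` streak sub-frames.
#' @param dark_level camera offset, counts.
#' @return the mean 2-D frame.
#' @export
mean_frame <- function(group, dark_level = 0) {
  check_image_list(group, "group")
  Reduce(`+`, lapply(group, function(sf) pmax(sf - dark_level, 0))) /
    length(group)
}

#' Raw-mean movie from a streak stack
#'
#' Groups the sub-frames and applies [mean_frame()] only: the standard-MTPM
#' comparator series, without any deconvolution.
#'
#' @param stack a [streak_stack()].
#' @param dark_level camera offset override; default the stack's value.
#' @return a raw-mean [frame_series()].
#' @export
mean_frame_series <- function(stack, dark_level = NULL) {
  stopifnot(inherits(stack, "streak_stack"))
  m <- stack$m
  n_frames <- length(stack$sub_frames) %/% m
  if (n_frames == 0L) stop("fewer sub-frames than the oversampling factor",
                           call. = FALSE)
  dark <- dark_level %||% stack$dark_level
  frames <- lapply(seq_len(n_frames), function(i) {
    mean_frame(stack$sub_frames[(i - 1L) * m + seq_len(m)], dark_level = dark)
  })
  frame_series(frames, stack$frame_rate, "raw-mean")
}

#' Reconstruct a streak stack into source-localized and raw-mean movies
#'
#' Partitions the sub-frames into consecutive groups of `m` and applies
#' [reconstruct_frame()] and [mean_frame()] to each group. A trailing partial
#' group (sub-frame count not divisible by `m`) is dropped with a warning.
#'
#' @param stack a [streak_stack()].
#' @param cfg a [recon_config()].
#' @return a list with `source_localized` and `raw_mean` [frame_series()],
#'   both at the reconstructed frame rate.
#' @export
reconstruct_series <- function(stack, cfg) {
  stopifnot(inherits(stack, "streak_stack"), inherits(cfg, "recon_config"))
  m <- stack$m
  n <- length(stack$sub_frames)
  n_frames <- n %/% m
  if (n_frames == 0L) stop("fewer sub-frames than the oversampling factor",
                           call. = FALSE)
  if (n %% m != 0L) {
    warning(sprintf("dropping %d trailing sub-frame(s) not forming a full group",
                    n %% m))
  }
  dark <- cfg$dark_level %||% stack$dark_level
  sl <- vector("list", n_frames)
  rw <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    group <- stack$sub_frames[(i - 1L) * m + seq_len(m)]
    sl[[i]] <- reconstruct_frame(group, cfg, dark_level = dark)
    rw[[i]] <- mean_frame(group, dark_level = dark)
  }
  list(source_localized = frame_series(sl, stack$frame_rate,
                                       "source-localized"),
       raw_mean = frame_series(rw, stack$frame_rate, "raw-mean"))
}
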