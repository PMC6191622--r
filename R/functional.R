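# Functional-trace analysis: ROI segmentation from correlation/variance maps,
# dF/F0 extraction, signal localization ratio, calcium-transient model.

as_movie_array <- function(movie) {
  if (inherits(movie, "frame_series")) {
    frames <- movie$frames
    arr <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
    return(arr)
  }
  if (is.array(movie) && length(dim(movie)) == 3L) return(movie)
  if (is.list(movie)) {
    check_image_list(movie, "movie")
    return(array(unlist(movie), dim = c(dim(movie[[1]]), length(movie))))
  }
  stop("`movie` must be a frame_series, a list of frames, or an H x W x T array",
       call. = FALSE)
}

shift_matrix <- function(x, dr, dc, fill = NA_real_) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
  out
}

#' Local correlation map of a movie
#'
#' For every pixel, the mean Pearson correlation between its time course and
#' the time courses of its 8-connected neighbours (edge pixels use the
#' neighbours available). Active structures whose pixels co-fluctuate stand
#' out against temporally independent noise. A constant time course
#' contributes correlation 0.
#'
#' @param movie a [frame_series()], list of frames, or `H x W x T` array with
#'   at least 3 frames.
#' @return a 2-D correlation image.
#' @export
local_correlation_map <- function(movie) {
  arr <- as_movie_array(movie)
  nt <- dim(arr)[3]
  if (nt < 3L) stop("need at least 3 frames", call. = FALSE)
  nr <- dim(arr)[1]; nc <- dim(arr)[2]
  mu <- apply(arr, c(1, 2), mean)
  ctr <- sweep(arr, c(1, 2), mu)
  nrm <- sqrt(apply(ctr^2, c(1, 2), sum))
  z <- array(0, dim(arr))
  pos <- nrm > 0
  for (t in seq_len(nt)) {
    zt <- matrix(0, nr, nc)
    zt[pos] <- ctr[, , t][pos] / nrm[pos]
    z[, , t] <- zt
  }
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  ones <- matrix(1, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    avail <- shift_matrix(ones, dr, dc, fill = 0)
    corr <- matrix(0, nr, nc)
    for (t in seq_len(nt)) {
      corr <- corr + z[, , t] * shift_matrix(z[, , t], dr, dc, fill = 0)
    }
    acc <- acc + corr
    cnt <- cnt + avail
  }
  acc / cnt
}

#' Per-pixel temporal variance map
#'
#' @param movie a [frame_series()], list of frames, or `H x W x T` array.
#' @return a 2-D variance image (n-1 denominator).
#' @export
variance_map <- function(movie) {
  arr <- as_movie_array(movie)
  apply(arr, c(1, 2), stats::var)
}

#' Segment a functional ROI from a correlation or variance map
#'
#' Applies an automatic global threshold (Otsu's method on the map rescaled
#' to `[0, 1]`), binary closing, two rounds of binary opening (3x3 box), and
#' keeps the largest connected component as the intracellular ROI.
#'
#' @param map 2-D image: a [local_correlation_map()] (`mode =
#'   "correlation"`) or a [variance_map()] (`mode = "variance"`).
#' @param mode provenance of the map (recorded on the result).
#' @return a logical mask with attributes `empty` (flag) and `mode`; all
#'   `FALSE` with `empty = TRUE` when nothing survives the morphology.
#' @export
segment_functional_roi <- function(map, mode = c("correlation", "variance")) {
  mode <- match.arg(mode)
  check_image(map, "map")
  rng <- range(map)
  empty_mask <- function() {
    structure(matrix(FALSE, nrow(map), ncol(map)), empty = TRUE, mode = mode)
  }
  if (!all(is.finite(rng)) || rng[1] == rng[2]) return(empty_mask())
  norm <- (map - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(norm, range = c(0, 1))
  m <- (norm > thr) * 1
  brush <- EBImage::makeBrush(3, shape = "box")
  m <- EBImage::closing(m, brush)
  m <- EBImage::opening(EBImage::opening(m, brush), brush)
  if (!any(m > 0.5)) return(empty_mask())
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  structure(lab == keep, empty = FALSE, mode = mode)
}

#' Consensus ROI across trials
#'
#' A pixel is included when it appears in strictly more than a quarter of the
#' per-trial masks.
#'
#' @param masks list of logical masks of one shape.
#' @return a logical mask.
#' @export
consensus_roi <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L) {
    stop("`masks` must be a non-empty list", call. = FALSE)
  }
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1)))) {
    stop("all masks must share one shape", call. = FALSE)
  }
  frac <- Reduce(`+`, lapply(masks, function(m) m * 1)) / length(masks)
  frac > 0.25
}

#' Extracellular ROI around a segmented cell
#'
#' `"ring"` mode takes the intracellular bounding box extended by `extent`
#' pixels per axis (clipped to the image), minus the intracellular mask —
#' used for single-cell labelled data to avoid deconvolution ringing
#' artefacts further out. `"full-surround"` mode takes the whole field minus
#' the intracellular mask — used for multi-cell ROI boxes.
#'
#' @param intracellular nonempty logical mask.
#' @param mode `"ring"` or `"full-surround"`.
#' @param extent ring extension in pixels (default 5).
#' @return a logical mask, disjoint from `intracellular`.
#' @export
extracellular_ring <- function(intracellular, mode = c("ring", "full-surround"),
                               extent = 5) {
  mode <- match.arg(mode)
  if (!any(intracellular)) stop("empty intracellular mask", call. = FALSE)
  nr <- nrow(intracellular); nc <- ncol(intracellular)
  if (mode == "full-surround") return(!intracellular)
  idx <- which(intracellular, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - extent); r1 <- min(nr, max(idx[, 1]) + extent)
  c0 <- max(1L, min(idx[, 2]) - extent); c1 <- min(nc, max(idx[, 2]) + extent)
  out <- matrix(FALSE, nr, nc)
  out[r0:r1, c0:c1] <- TRUE
  out & !intracellular
}

#' Extract a dF/F0 trace from a movie
#'
#' The raw trace is the per-frame mean over the mask minus the dark level;
#' the baseline `F0` is the mean of the raw trace over `baseline_window`,
#' and the returned trace is `(raw - F0) / F0`.
#'
#' @param movie a [frame_series()], list of frames, or `H x W x T` array.
#' @param mask nonempty logical pixel mask.
#' @param dark_level average dark-frame value, counts.
#' @param baseline_window integer frame indices defining the baseline;
#'   default all frames.
#' @param frame_rate frames per second (taken from a `frame_series` input
#'   when omitted).
#' @return a `dff_trace`: list with `values`, `frame_rate`,
#'   `baseline_window`, `f0`.
#' @export
dff <- function(movie, mask, dark_level = 0, baseline_window = NULL,
                frame_rate = NULL) {
  if (inherits(movie, "frame_series") && is.null(frame_rate)) {
    frame_rate <- movie$frame_rate
  }
  arr <- as_movie_array(movie)
  if (!any(mask)) stop("`mask` must be nonempty", call. = FALSE)
  nt <- dim(arr)[3]
  raw <- vapply(seq_len(nt), function(t) mean(arr[, , t][mask]), numeric(1)) -
    dark_level
  baseline_window <- baseline_window %||% seq_len(nt)
  f0 <- mean(raw[baseline_window])
  if (!is.finite(f0) || f0 <= 0) {
    stop("invalid baseline: F0 must be positive", call. = FALSE)
  }
  structure(list(values = (raw - f0) / f0,
                 frame_rate = frame_rate %||% NA_real_,
                 baseline_window = baseline_window, f0 = f0),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d frames at %g Hz, F0 = %.4g, peak = %.4g\n",
              length(x$values), x$frame_rate, x$f0, max(x$values)))
  invisible(x)
}

trace_values <- function(x) if (inherits(x, "dff_trace")) x$values else x

#' Signal localization ratio
#'
#' The ratio of the peak intracellular dF/F0 to the peak extracellular dF/F0
#' within a common window; larger values mean less functional crosstalk from
#' scattered light.
#'
#' @param intra,extra `dff_trace`s (or numeric vectors) of equal length and
#'   frame rate.
#' @param window integer frame indices to search for the peaks; default the
#'   whole trace.
#' @param eps floor applied to a nonpositive extracellular peak (flagged).
#' @return the SLR (scalar) with attribute `floored` when the extracellular
#'   peak was nonpositive.
#' @export
slr <- function(intra, extra, window = NULL, eps = 1e-6) {
  vi <- trace_values(intra); ve <- trace_values(extra)
  if (length(vi) != length(ve)) stop("trace lengths differ", call. = FALSE)
  if (inherits(intra, "dff_trace") && inherits(extra, "dff_trace") &&
      !isTRUE(all.equal(intra$frame_rate, extra$frame_rate))) {
    stop("trace frame rates differ", call. = FALSE)
  }
  window <- window %||% seq_along(vi)
  pi_ <- max(vi[window])
  pe <- max(ve[window])
  floored <- pe <= 0
  if (floored) {
    warning("nonpositive extracellular peak floored at eps")
    pe <- eps
  }
  structure(pi_ / pe, floored = floored)
}

#' Stimulus-locked peak-search window
#'
#' Frame indices covering `[stimulus, stimulus + length_s]`, the short window
#' after the stimulus in which the transient peaks.
#'
#' @param stimulus_time stimulus onset, s.
#' @param frame_rate frames per second.
#' @param n_frames trace length.
#' @param length_s window length, s (default 0.5).
#' @return integer frame indices.
#' @export
stimulus_window <- function(stimulus_time, frame_rate, n_frames,
                            length_s = 0.5) {
  t <- (seq_len(n_frames) - 1L) / frame_rate
  which(t >= stimulus_time & t <= stimulus_time + length_s)
}

#' Calcium-transient pulse model
#'
#' Parameters of the double-exponential fluorescence transient
#' `f(t) = sum_k A * c * (exp(-alpha (t - t_k)) - exp(-gamma (t - t_k)))`
#' for `t >= t_k`. The normalisation `c` is computed in closed form from the
#' analytic peak time `log(gamma / alpha) / (gamma - alpha)` so that a single
#' pulse peaks exactly at `A`.
#'
#' @param A peak amplitude in dF/F0 units.
#' @param alpha decay rate, s^-1 (default 3.18, a fast synthetic calcium
#'   indicator).
#' @param gamma rise rate, s^-1 (default 34.39); must exceed `alpha`.
#' @param spike_times spike (pulse onset) times, s.
#' @param sigma additive trace noise standard deviation.
#' @return a `transient_model` with the derived `c_norm` and `peak_time`.
#' @export
transient_model <- function(A = 1, alpha = 3.18, gamma = 34.39,
                            spike_times = numeric(0), sigma = 0) {
  if (!(gamma > alpha && alpha > 0)) {
    stop("invalid parameters: need gamma > alpha > 0", call. = FALSE)
  }
  t_peak <- log(gamma / alpha) / (gamma - alpha)
  peak <- exp(-alpha * t_peak) - exp(-gamma * t_peak)
  structure(list(A = A, alpha = alpha, gamma = gamma, c_norm = 1 / peak,
                 peak_time = t_peak, spike_times = spike_times, sigma = sigma),
            class = "transient_model")
}

#' Evaluate the calcium-transient waveform
#'
#' Sum over spikes of the normalised double-exponential pulse (see
#' [transient_model()]); zero before the first spike, linear in `A`, exact
#' superposition over spikes.
#'
#' @param t time(s), s.
#' @param model a [transient_model()], or the amplitude `A` when the
#'   remaining parameters are given explicitly.
#' @param spike_times,alpha,gamma used when `model` is a bare amplitude.
#' @return dF/F0 value(s) at `t`.
#' @export
transient_waveform <- function(t, model, spike_times = NULL, alpha = 3.18,
                               gamma = 34.39) {
  if (!inherits(model, "transient_model")) {
    model <- transient_model(A = model, alpha = alpha, gamma = gamma,
                             spike_times = spike_times %||% numeric(0))
  }
  out <- numeric(length(t))
  for (tk in model$spike_times) {
    dt <- t - tk
    on <- dt >= 0
    out[on] <- out[on] + model$A * model$c_norm *
      (exp(-model$alpha * dt[on]) - exp(-model$gamma * dt[on]))
  }
  out
}

#' Fit the transient amplitude by linear least squares
#'
#' Given known spike times, regresses the trace on the unit-amplitude
#' waveform sampled at the frame times: the closed-form solution
#' `A = <w, y> / <w, w>` of the single-coefficient least-squares problem.
#'
#' @param trace a `dff_trace` or numeric vector of samples.
#' @param spike_times spike times, s; at least one must fall inside the trace.
#' @param frame_rate frames per second (taken from a `dff_trace` input when
#'   omitted).
#' @param alpha,gamma transient rates, s^-1.
#' @return the amplitude estimate (scalar).
#' @export
fit_amplitude <- function(trace, spike_times, frame_rate = NULL,
                          alpha = 3.18, gamma = 34.39) {
  y <- trace_values(trace)
  if (inherits(trace, "dff_trace") && is.null(frame_rate)) {
    frame_rate <- trace$frame_rate
  }
  if (is.null(frame_rate) || !is.finite(frame_rate)) {
    stop("`frame_rate` is required", call. = FALSE)
  }
  t <- (seq_along(y) - 1L) / frame_rate
  w <- transient_waveform(t, transient_model(A = 1, alpha = alpha,
                                             gamma = gamma,
                                             spike_times = spike_times))
  ss <- sum(w^2)
  if (ss == 0) stop("degenerate fit: regressor is identically zero",
                    call. = FALSE)
  sum(w * y) / ss
}

#' Trace noise level from the quiescent tail
#'
#' Sample standard deviation (n-1 denominator) of the final
#' `window_seconds` of the trace, assumed free of spiking activity
#' (0.2 s for single-cell data, 0.3 s for multi-cell data).
#'
#' @param trace a `dff_trace` or numeric vector.
#' @param window_seconds tail length, s.
#' @param frame_rate frames per second (taken from a `dff_trace` input).
#' @return the noise standard deviation `sigma`.
#' @export
estimate_noise <- function(trace, window_seconds = 0.2, frame_rate = NULL) {
  y <- trace_values(trace)
  if (inherits(trace, "dff_trace") && is.null(frame_rate)) {
    frame_rate <- trace$frame_rate
  }
  if (is.null(frame_rate) || !is.finite(frame_rate)) {
    stop("`frame_rate` is required", call. = FALSE)
  }
  n_tail <- round(window_seconds * frame_rate)
  if (n_tail < 2L || n_tail > length(y)) {
    stop("tail window must contain at least 2 samples within the trace",
         call. = FALSE)
  }
  sd(tail(y, n_tail))
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = A^2 / sigma^2` with `A` the (fitted or peak-measured) transient
#' amplitude and `sigma` the quiescent-tail noise standard deviation.
#'
#' @param A transient amplitude.
#' @param sigma noise standard deviation; `sigma = 0` yields `Inf` with a
#'   warning.
#' @return the PSNR (dimensionless power ratio).
#' @seealso [psnr_db()]
#' @export
psnr <- function(A, sigma) {
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  if (sigma == 0) {
    warning("sigma = 0: PSNR is infinite")
    return(Inf)
  }
  A^2 / sigma^2
}

#' PSNR in decibels
#'
#' @param p a power-ratio PSNR from [psnr()].
#' @return `10 * log10(p)`.
#' @export
psnr_db <- function(p) 10 * log10(p)
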