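#' Segment cells and background for contrast measurement
#'
#' Thresholds the image to isolate bright (cellular) pixels and removes
#' small objects with 4 binary erosion iterations followed by 4 dilation
#' iterations (3x3 cross structuring element). The background mask is the
#' complement of the dilated cell mask.
#'
#' The threshold is `frac` times either the maximum pixel intensity
#' (`threshold = "max"`, default) or the upper edge of the image histogram's
#' modal bin (`threshold = "mode"`, 256 equal-width bins).
#'
#' @param image 2-D numeric matrix.
#' @param threshold `"max"` or `"mode"` (see Details).
#' @param frac threshold fraction (default 0.8).
#' @param erosions,dilations morphology iteration counts.
#' @return list with logical `cell_mask` and `background_mask` and a
#'   `degenerate` flag (`TRUE` when all or no pixels were segmented).
#' @export
segment_for_contrast <- function(image, threshold = c("max", "mode"),
                                 frac = 0.8, erosions = 4, dilations = 4) {
  threshold <- match.arg(threshold)
  check_image(image, "image")
  ref <- if (threshold == "max") {
    max(image)
  } else {
    breaks <- seq(min(image), max(image), length.out = 257L)
    if (breaks[1] == breaks[257]) {
      max(image)
    } else {
      h <- graphics::hist(image, breaks = breaks, plot = FALSE)
      breaks[which.max(h$counts) + 1L]   # upper edge of the modal bin
    }
  }
  mask <- image > frac * ref
  degenerate_pre <- all(mask) || !any(mask)
  brush <- EBImage::makeBrush(3, shape = "diamond")
  m <- mask * 1
  for (i in seq_len(erosions))  m <- EBImage::erode(m, brush)
  for (i in seq_len(dilations)) m <- EBImage::dilate(m, brush)
  cell <- m > 0.5
  degenerate <- degenerate_pre || all(cell) || !any(cell)
  list(cell_mask = cell, background_mask = !cell, degenerate = degenerate)
}

#' Michelson contrast of an image
#'
#' `C = (I_max - I_min) / (I_max + I_min)` where `I_max` is the 99.9th
#' percentile of the segmented cellular intensities and `I_min` the 10th
#' percentile of the background intensities. The contrast is set to zero
#' when the segmentation is degenerate (all or no pixels segmented) or when
#' `I_max + I_min = 0`.
#'
#' @param image 2-D numeric matrix.
#' @param masks output of [segment_for_contrast()]; computed from `image`
#'   with default settings when `NULL`.
#' @param p_cell,p_bg percentiles (fractions) used for `I_max` and `I_min`.
#' @return a `contrast_result`: list with `contrast`, `i_max`, `i_min`,
#'   `cell_mask`, `background_mask`, `degenerate`.
#' @export
michelson_contrast <- function(image, masks = NULL, p_cell = 0.999,
                               p_bg = 0.10) {
  check_image(image, "image")
  if (is.null(masks)) masks <- segment_for_contrast(image)
  if (isTRUE(masks$degenerate)) {
    return(structure(list(contrast = 0, i_max = NA_real_, i_min = NA_real_,
                          cell_mask = masks$cell_mask,
                          background_mask = masks$background_mask,
                          degenerate = TRUE),
                     class = "contrast_result"))
  }
  i_max <- unname(quantile(image[masks$cell_mask], p_cell))
  i_min <- unname(quantile(image[masks$background_mask], p_bg))
  contrast <- if (i_max + i_min == 0) 0 else (i_max - i_min) / (i_max + i_min)
  structure(list(contrast = contrast, i_max = i_max, i_min = i_min,
                 cell_mask = masks$cell_mask,
                 background_mask = masks$background_mask,
                 degenerate = FALSE),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> C = %.4f (I_max = %.4g, I_min = %.4g%s)\n",
              x$contrast, x$i_max, x$i_min,
              if (x$degenerate) ", degenerate segmentation" else ""))
  invisible(x)
}

#' Relative contrast-depth profile
#'
#' Normalises per-depth contrasts to the shallowest depth's value and
#' estimates the 50% cutoff depth with [cutoff_depth()].
#'
#' @param depths strictly increasing depths, um.
#' @param contrasts Michelson contrasts at those depths.
#' @param level relative-contrast level defining the cutoff (default 0.5).
#' @return a `contrast_profile`: list with `depths`, `contrasts` (relative),
#'   `cutoff_depth` (um; `NA` with a `no_crossing` flag when the fitted
#'   profile never reaches `level` within the sampled range).
#' @export
contrast_profile <- function(depths, contrasts, level = 0.5) {
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("`depths` must be strictly increasing", call. = FALSE)
  }
  if (contrasts[1] <= 0) {
    stop("contrast at the shallowest depth must be positive to normalise",
         call. = FALSE)
  }
  rel <- contrasts / contrasts[1]
  cut <- cutoff_depth(depths, rel, level = level)
  structure(list(depths = depths, contrasts = rel, cutoff_depth = cut,
                 no_crossing = is.na(cut), level = level),
            class = "contrast_profile")
}

#' 50% contrast cutoff depth from a contrast-depth profile
#'
#' Fits a 3rd-order polynomial to relative contrast against depth by least
#' squares and returns the smallest depth within the sampled range at which
#' the fitted polynomial crosses `level`, located by a dense scan (0.1 um)
#' refined by root bisection.
#'
#' @param depths at least 4 depths, um.
#' @param contrasts relative contrasts (1 at the shallowest depth).
#' @param level crossing level (default 0.5).
#' @return cutoff depth in um, or `NA` when the fit never crosses `level`
#'   within the sampled range.
#' @export
cutoff_depth <- function(depths, contrasts, level = 0.5) {
  if (length(depths) < 4L) {
    stop("need at least 4 depth points for the cubic fit", call. = FALSE)
  }
  if (length(contrasts) != length(depths)) {
    stop("`depths` and `contrasts` lengths differ", call. = FALSE)
  }
  fit <- lm(contrasts ~ poly(depths, 3, raw = TRUE))
  f <- function(z) {
    cf <- coef(fit)
    cf[1] + cf[2] * z + cf[3] * z^2 + cf[4] * z^3 - level
  }
  grid <- seq(min(depths), max(depths), by = 0.1)
  vals <- f(grid)
  if (vals[1] <= 0) return(grid[1])   # profile starts at or below the level
  below <- which(vals <= 0)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1]
  uniroot(f, lower = grid[i - 1L], upper = grid[i], tol = 1e-8)$root
}
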