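# TIFF stack I/O with a YAML provenance sidecar.
#
# The `tiff` writer stores integer sample formats scaled from [0, 1], so
# arbitrary-range float frames are stored as 32-bit samples of
# (value - offset) / scale with offset/scale recorded in the sidecar;
# read_stack() restores the original values (round-trip error below
# 2^-32 of full scale). Plain 8/16-bit integer TIFFs from other sources are
# read as their integer values.

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write an image series as a multi-page 32-bit TIFF with a YAML sidecar
#'
#' @param path output TIFF path; the sidecar is written to `paste0(path,
#'   ".yaml")`.
#' @param series a [frame_series()], [streak_stack()], list of matrices, or a
#'   single matrix.
#' @param meta named list of provenance entries (e.g. `seed`, configuration)
#'   stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(path, series, meta = list()) {
  frames <- if (inherits(series, "frame_series")) {
    series$frames
  } else if (inherits(series, "streak_stack")) {
    series$sub_frames
  } else if (is.matrix(series)) {
    list(series)
  } else {
    series
  }
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`series` must contain at least one frame", call. = FALSE)
  }
  check_image_list(frames, "series")
  vals <- range(unlist(lapply(frames, range)))
  offset <- min(vals[1], 0)
  scale <- max(vals[2] - offset, 0)
  if (scale <= 0) scale <- 1
  stored <- lapply(frames, function(f) (f - offset) / scale)
  tiff::writeTIFF(stored, path, bits.per.sample = 32L,
                  compression = "deflate", reduce = FALSE)
  side <- c(list(pages = length(frames),
                 shape = as.integer(dim(frames[[1]])),
                 offset = offset, scale = scale,
                 package = "slmtpm",
                 version = as.character(utils::packageVersion("slmtpm"))),
            meta)
  if (inherits(series, "frame_series")) {
    side$frame_rate <- series$frame_rate
    side$provenance <- series$provenance
  }
  if (inherits(series, "streak_stack")) {
    side$m <- series$m
    side$frame_rate <- series$frame_rate
    side$dark_level <- series$dark_level
  }
  yaml::write_yaml(side, sidecar_path(path))
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Stacks written by [write_stack()] are restored to their original values
#' using the YAML sidecar. TIFFs without a sidecar are returned at their
#' native integer values (8/16-bit) or native floats.
#'
#' @param path TIFF path.
#' @return list with `frames` (list of numeric matrices, page order) and
#'   `meta` (page count, shape, plus any sidecar entries).
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  side <- if (file.exists(sidecar_path(path))) {
    yaml::read_yaml(sidecar_path(path))
  } else NULL
  frames <- if (is.null(side)) {
    tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  } else {
    raw <- tiff::readTIFF(path, all = TRUE)
    lapply(raw, function(f) f * side$scale + side$offset)
  }
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]   # collapse extra channels
    storage.mode(f) <- "double"
    f
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("format error: pages have mixed shapes", call. = FALSE)
  }
  meta <- c(list(pages = length(frames), shape = dim(frames[[1]])),
            side[setdiff(names(side), c("pages", "shape"))])
  list(frames = frames, meta = meta)
}
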