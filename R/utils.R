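# shared internal helpers: seed scoping, image checks, FFT convolution

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

check_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`", arg, "` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(x)) stop("`", arg, "` contains missing values", call. = FALSE)
  invisible(x)
}

check_image_list <- function(xs, arg = "images") {
  if (!is.list(xs) || length(xs) == 0L) {
    stop("`", arg, "` must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(xs, function(m) {
    check_image(m, arg)
    dim(m)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all `", arg, "` must share one shape", call. = FALSE)
  }
  invisible(xs)
}

# Reflection (symmetric, edge-repeating) index map covering any pad width.
reflect_index <- function(n, pad) {
  i <- seq.int(1L - pad, n + pad)
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

pad_reflect <- function(x, pad_r, pad_c = pad_r) {
  x[reflect_index(nrow(x), pad_r), reflect_index(ncol(x), pad_c), drop = FALSE]
}

# Embed a (2h+1)x(2h+1) kernel, centre at its middle bin, into an nr x nc
# matrix with wrap-around so that fft() of the result is the OTF of a
# convolution centred at pixel (1, 1).
kernel_otf <- function(kernel, nr, nc) {
  side_r <- nrow(kernel)
  side_c <- ncol(kernel)
  if (side_r > nr || side_c > nc) {
    stop("kernel larger than the (padded) image", call. = FALSE)
  }
  hr <- (side_r - 1L) %/% 2L
  hc <- (side_c - 1L) %/% 2L
  k <- matrix(0, nr, nc)
  ri <- ((seq_len(side_r) - 1L - hr) %% nr) + 1L
  ci <- ((seq_len(side_c) - 1L - hc) %% nc) + 1L
  k[ri, ci] <- kernel
  stats::fft(k)
}

# circular convolution given a precomputed OTF
conv_otf <- function(x, otf) {
  Re(stats::fft(stats::fft(x) * otf, inverse = TRUE)) / length(x)
}

# 2-D convolution with boundary handling; kernel must fit inside the image.
conv2d <- function(x, kernel, boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  check_image(x, "x")
  if (nrow(kernel) > nrow(x) || ncol(kernel) > ncol(x)) {
    stop("kernel larger than image", call. = FALSE)
  }
  if (boundary == "periodic") {
    return(conv_otf(x, kernel_otf(kernel, nrow(x), ncol(x))))
  }
  pr <- (nrow(kernel) - 1L) %/% 2L + 1L
  pc <- (ncol(kernel) - 1L) %/% 2L + 1L
  xp <- pad_reflect(x, pr, pc)
  out <- conv_otf(xp, kernel_otf(kernel, nrow(xp), ncol(xp)))
  out[pr + seq_len(nrow(x)), pc + seq_len(ncol(x)), drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
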