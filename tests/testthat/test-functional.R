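# functional analysis: correlation maps, ROIs, dF/F0, SLR, transient model

test_that("local correlation map separates co-fluctuating structure from noise", {
  set.seed(31)
  # shared time course everywhere -> map near 1
  tc <- rnorm(60, 100, 10)
  shared <- array(rep(tc, each = 15 * 15), c(15, 15, 60))
  expect_gt(min(local_correlation_map(shared)), 0.999)

  # independent white noise -> map near 0
  noise <- array(rnorm(20 * 20 * 200), c(20, 20, 200))
  m <- local_correlation_map(noise)
  expect_lt(max(abs(mean(m))), 0.05)

  # flickering disc on a static (constant) background
  img <- matrix(0, 24, 24)
  rows <- matrix(seq_len(24), 24, 24); cols <- t(rows)
  disc <- sqrt((rows - 12)^2 + (cols - 12)^2) <= 5
  mov <- array(1, c(24, 24, 80))
  flick <- runif(80, 0.5, 2)
  for (t in 1:80) {
    fr <- mov[, , t]
    fr[disc] <- 1 + flick[t]
    mov[, , t] <- fr + matrix(rnorm(24 * 24, 0, 0.01), 24, 24)
  }
  cm <- local_correlation_map(mov)
  inner <- disc & !EBImage::dilate(!disc * 1, EBImage::makeBrush(3, "box"))
  expect_gt(mean(cm[sqrt((rows - 12)^2 + (cols - 12)^2) <= 3]), 0.8)
  far <- sqrt((rows - 12)^2 + (cols - 12)^2) > 8
  expect_lt(mean(abs(cm[far])), 0.15)
  expect_error(local_correlation_map(mov[, , 1:2]), "at least 3")
})

test_that("functional ROI segmentation keeps the largest component", {
  img <- matrix(0, 40, 40)
  rows <- matrix(seq_len(40), 40, 40); cols <- t(rows)
  big <- sqrt((rows - 14)^2 + (cols - 14)^2) <= 8
  small <- sqrt((rows - 32)^2 + (cols - 32)^2) <= 4
  img[big] <- 1; img[small] <- 1
  roi <- segment_functional_roi(img)
  expect_false(attr(roi, "empty"))
  expect_true(all(which(roi) %in% which(big)))
  expect_gt(sum(roi), 0.6 * sum(big))

  # uniform map cannot be segmented
  expect_true(attr(segment_functional_roi(matrix(1, 20, 20)), "empty"))
})

test_that("variance-map segmentation recovers the active cell (Dice > 0.8)", {
  scene <- generate_cell_scene(1, shape = c(40, 40), labeling = "single-cell",
                               seed = 32)
  active <- scene$masks[[1]]
  set.seed(33)
  mov <- array(0, c(40, 40, 60))
  amp <- runif(60, 0.8, 1.6)
  for (t in 1:60) {
    mov[, , t] <- scene$truth * amp[t] * 100 +
      matrix(rnorm(1600, 0, 1), 40, 40)^2
  }
  roi <- segment_functional_roi(variance_map(mov), mode = "variance")
  dice <- 2 * sum(roi & active) / (sum(roi) + sum(active))
  expect_gt(dice, 0.8)
})

test_that("consensus ROI uses a strict quarter rule", {
  m <- matrix(FALSE, 4, 4)
  one <- m; one[1, 1] <- TRUE
  two <- m; two[1, 1] <- TRUE; two[2, 2] <- TRUE
  # pixel (1,1) in 2/4 masks -> included; (2,2) in 1/4 -> excluded
  cons <- consensus_roi(list(one, two, m, m))
  expect_true(cons[1, 1]); expect_false(cons[2, 2])
  # a single trial returns that mask
  expect_identical(consensus_roi(list(two)), two)
})

test_that("extracellular ROIs have the expected extents", {
  intra <- matrix(FALSE, 20, 20); intra[9:11, 9:11] <- TRUE
  ring <- extracellular_ring(intra, "ring", extent = 5)
  expect_identical(sum(ring), 13L * 13L - 9L)       # 160 pixels
  expect_false(any(ring & intra))
  full <- extracellular_ring(intra, "full-surround")
  expect_identical(sum(full), 400L - 9L)
  # corner cell: ring clipped at the image bounds
  corner <- matrix(FALSE, 20, 20); corner[1:2, 1:2] <- TRUE
  rc <- extracellular_ring(corner, "ring", extent = 5)
  expect_identical(sum(rc), 7L * 7L - 4L)
  expect_error(extracellular_ring(matrix(FALSE, 5, 5)), "empty")
})

test_that("dF/F0 follows the baseline arithmetic", {
  mask <- matrix(TRUE, 4, 4)
  flat <- replicate(10, matrix(100, 4, 4), simplify = FALSE)
  tr <- dff(flat, mask, dark_level = 0, baseline_window = 1:5, frame_rate = 10)
  expect_equal(tr$values, rep(0, 10))
  step <- c(replicate(5, matrix(100, 4, 4), simplify = FALSE),
            replicate(5, matrix(110, 4, 4), simplify = FALSE))
  tr1 <- dff(step, mask, dark_level = 0, baseline_window = 1:5)
  expect_equal(tr1$values[10], 0.10)
  tr2 <- dff(step, mask, dark_level = 50, baseline_window = 1:5)
  expect_equal(tr2$values[10], 0.20)
  # gain invariance when movie and dark level scale together
  step2x <- lapply(step, `*`, 2)
  tr3 <- dff(step2x, mask, dark_level = 100, baseline_window = 1:5)
  expect_equal(tr3$values, tr2$values, tolerance = 1e-12)
  expect_error(dff(step, mask, dark_level = 200, baseline_window = 1:5),
               "baseline")
})

test_that("SLR is the ratio of in-window peaks", {
  a <- c(0, 0.1, 0.4, 0.2); b <- c(0, 0.05, 0.1, 0.02)
  expect_equal(as.numeric(slr(a, b)), 4)
  expect_equal(as.numeric(slr(a, a)), 1)
  expect_warning(v <- slr(a, c(-1, -1, -1, -1)), "floored")
  expect_true(attr(v, "floored"))
})

test_that("transient pulses peak exactly at A and superpose linearly", {
  tm <- transient_model(A = 1, alpha = 3.18, gamma = 34.39,
                        spike_times = 0)
  t <- seq(0, 2, by = 1e-5)
  f <- transient_waveform(t, tm)
  expect_equal(max(f), 1, tolerance = 1e-6)
  expect_equal(t[which.max(f)], tm$peak_time, tolerance = 1e-4)
  # zero before the first spike; exactly zero with no spikes
  tm2 <- transient_model(A = 2, spike_times = 0.5)
  expect_identical(transient_waveform(c(0, 0.25, 0.49), tm2), c(0, 0, 0))
  expect_identical(transient_waveform(t, transient_model(spike_times = numeric(0))),
                   numeric(length(t)))
  # linearity in A and superposition over spikes
  ts <- seq(0, 3, by = 0.01)
  two <- transient_model(A = 1.3, spike_times = c(0.2, 1.1))
  s1 <- transient_model(A = 1.3, spike_times = 0.2)
  s2 <- transient_model(A = 1.3, spike_times = 1.1)
  expect_equal(transient_waveform(ts, two),
               transient_waveform(ts, s1) + transient_waveform(ts, s2),
               tolerance = 1e-12)
  expect_equal(transient_waveform(ts, two),
               2 * transient_waveform(ts, transient_model(A = 0.65,
                                                          spike_times = c(0.2, 1.1))),
               tolerance = 1e-12)
  expect_error(transient_model(alpha = 5, gamma = 2), "gamma > alpha")
})

test_that("amplitude fitting is exact on clean data and matches LS variance", {
  rate <- 50; dur <- 2
  tt <- (seq_len(rate * dur) - 1) / rate
  spikes <- c(0.3, 0.9)
  clean <- transient_waveform(tt, transient_model(A = 2, spike_times = spikes))
  expect_equal(fit_amplitude(clean, spikes, frame_rate = rate), 2,
               tolerance = 1e-9)
  expect_equal(fit_amplitude(numeric(100), spikes, frame_rate = rate), 0)
  expect_error(fit_amplitude(clean, spike_times = 10, frame_rate = rate),
               "degenerate")

  # Monte Carlo estimator spread vs the closed-form least-squares variance
  w <- transient_waveform(tt, transient_model(A = 1, spike_times = spikes))
  sigma <- 0.2
  set.seed(34)
  est <- replicate(100, fit_amplitude(w + rnorm(length(w), 0, sigma), spikes,
                                      frame_rate = rate))
  se_mean <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1), 3 * se_mean)
  analytic_sd <- sigma / sqrt(sum(w^2))
  expect_lt(abs(sd(est) - analytic_sd) / analytic_sd, 0.2)
})

test_that("noise estimation uses the n-1 tail standard deviation", {
  rate <- 50
  tr <- c(numeric(90), rep(c(1, -1), 5))     # final 0.2 s = 10 samples of +-1
  expect_equal(estimate_noise(tr, 0.2, frame_rate = rate),
               sd(rep(c(1, -1), 5)))
  expect_equal(sd(rep(c(1, -1), 5)), sqrt(10 / 9), tolerance = 1e-12)
  expect_identical(estimate_noise(c(numeric(90), rep(2, 10)), 0.2,
                                  frame_rate = rate), 0)
  set.seed(35)
  big <- rnorm(1e4, 0, 0.5)
  expect_lt(abs(estimate_noise(big, 1e4 / rate, frame_rate = rate) - 0.5),
            3 * 0.5 / sqrt(2 * 1e4))
  expect_error(estimate_noise(c(1, 2, 3), 0.02, frame_rate = rate),
               "at least 2")
})

test_that("PSNR follows the power-ratio and dB conventions", {
  expect_equal(psnr(10, 2), 25)
  expect_equal(psnr(0, 1), 0)
  expect_warning(p <- psnr(1, 0), "infinite")
  expect_identical(p, Inf)
  expect_equal(psnr_db(126), 21.0, tolerance = 0.05)
  expect_equal(psnr_db(psnr(2, 0.2)), 20, tolerance = 1e-9)
})
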