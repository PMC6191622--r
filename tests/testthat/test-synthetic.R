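# forward model: scenes, streak splitting, blur, noise, dynamic rendering

test_that("cell scenes are deterministic with disjoint in-bounds masks", {
  s1 <- generate_cell_scene(5, shape = c(64, 64), seed = 3)
  s2 <- generate_cell_scene(5, shape = c(64, 64), seed = 3)
  expect_identical(s1$truth, s2$truth)
  expect_length(s1$masks, 5L)
  overlap <- Reduce(`+`, lapply(s1$masks, `*`, 1))
  expect_lte(max(overlap), 1)
  expect_true(all(s1$truth >= 0))

  single <- generate_cell_scene(1, shape = c(40, 40), labeling = "single-cell",
                                seed = 4)
  expect_identical(max(EBImage::bwlabel(single$truth > 0.1)), 1L)  # one component
  expect_error(generate_cell_scene(80, shape = c(32, 32), seed = 5),
               "non-overlapping")
})

test_that("split_streaks partitions the scene exactly", {
  scene <- generate_cell_scene(3, shape = c(32, 32), seed = 6)
  expect_equal(split_streaks(scene, 1)[[1]], scene$truth)
  for (m in c(4, 8)) {
    lines <- split_streaks(scene, m)
    expect_length(lines, m)
    expect_identical(Reduce(`+`, lines), scene$truth)
    # each line image holds every m-th column
    nz <- which(colSums(lines[[1]]) != 0)
    expect_true(all((nz - 1L) %% m == 0L))
  }
  # m = 8 on a 16-column image: two nonzero columns per line image
  img <- matrix(1, 8, 16)
  expect_true(all(vapply(split_streaks(img, 8),
                         function(l) sum(colSums(l) != 0), numeric(1)) == 2))
  expect_error(split_streaks(img, 20), "incompatible")
})

test_that("scan_geometry enforces integer line separation", {
  g <- scan_geometry(12.5, 1.5625)
  expect_identical(g$m, 8L)
  expect_error(scan_geometry(12.5, 3), "integer multiple")
  scene <- generate_cell_scene(2, shape = c(32, 32), pixel_size = 1.5625,
                               seed = 7)
  expect_length(split_streaks(scene, g), 8L)
})

test_that("scattering blur preserves flux and is a delta-kernel identity", {
  scene <- generate_cell_scene(2, shape = c(32, 32), seed = 8)
  expect_equal(apply_scattering(scene$truth, delta_kernel(4, 1)), scene$truth,
               tolerance = 1e-12)
  k <- test_kernel()
  # DC preservation: constant image unchanged under periodic boundary
  cc <- matrix(2.5, 24, 24)
  expect_equal(apply_scattering(cc, k, boundary = "periodic"), cc,
               tolerance = 1e-10)
  # flux conservation on a periodic fixture
  b <- apply_scattering(scene$truth, k, boundary = "periodic")
  expect_equal(sum(b), sum(scene$truth), tolerance = 1e-10)
  # single bright column spreads symmetrically
  img <- matrix(0, 33, 33); img[, 17] <- 1
  bb <- apply_scattering(img, k, boundary = "periodic")
  expect_gt(sum(bb[, -17]), 0)
  expect_equal(colSums(bb)[16], colSums(bb)[18], tolerance = 0.15 * colSums(bb)[16])
  expect_error(apply_scattering(matrix(1, 4, 4), test_kernel()), "larger")
})

test_that("the camera noise model has the stated moments and fixes zeros", {
  set.seed(9)
  draws <- add_noise(matrix(100, 400, 250))
  expect_lt(abs(mean(draws) - 100), 3 * sd(draws) / sqrt(length(draws)))
  expect_lt(abs(sd(draws) - 10), 3 * sd(draws) / sqrt(2 * length(draws)))
  img <- matrix(c(0, 0, 5, 10), 2, 2)
  n1 <- add_noise(img, seed = 10)
  expect_identical(n1[1:2], c(0, 0))          # zero pixels stay zero
  expect_identical(n1, add_noise(img, seed = 10))  # determinism
  expect_true(all(add_noise(matrix(0.01, 50, 50), seed = 11) >= 0))
  expect_error(add_noise(matrix(-1, 2, 2)), "nonnegative")
})

test_that("dynamic rendering reproduces the transient on the clean path", {
  scene <- crosstalk_scene(seed = 12)
  dyn <- dynamic_scene(scene, list(0.3, numeric(0)), frame_rate = 20,
                       duration = 1, amplitudes = 1.5)
  stack <- render_dynamic_stack(dyn, 8, delta_kernel(4, scene$pixel_size),
                                noise = FALSE)
  expect_length(stack$sub_frames, 8L * 20L)
  out <- reconstruct_series(stack, recon_config(delta_kernel(4, 1),
                                                iterations = 5))
  tr <- dff(out$raw_mean, scene$masks[[1]], baseline_window = 1:6,
            frame_rate = 20)
  # forward-model identity: recovered peak equals the waveform peak at the
  # frame times
  t_frames <- (0:19) / 20
  expected_peak <- max(transient_waveform(t_frames, dyn$models[[1]]))
  expect_equal(max(tr$values), expected_peak, tolerance = 1e-6)
  # silent neighbour stays flat without scattering
  tr2 <- dff(out$raw_mean, scene$masks[[2]], baseline_window = 1:6,
             frame_rate = 20)
  expect_lt(max(abs(tr2$values)), 1e-9)
})

test_that("no spikes gives a statistically flat baseline", {
  scene <- crosstalk_scene(seed = 13)
  dyn <- dynamic_scene(scene, list(numeric(0), numeric(0)), frame_rate = 10,
                       duration = 0.5)
  stack <- render_dynamic_stack(dyn, 4, delta_kernel(4, scene$pixel_size),
                                seed = 14)
  means <- vapply(stack$sub_frames, mean, numeric(1))
  grp <- matrix(means, nrow = 4)        # per-frame means of each sub-frame
  expect_lt(max(apply(grp, 1, sd) / apply(grp, 1, mean)), 0.05)
})

test_that("scattering injects a transient into the silent neighbour", {
  scene <- crosstalk_scene(seed = 15)
  k <- test_kernel(halfwidth = 8, z_h = 100)
  dyn <- dynamic_scene(scene, list(0.2, numeric(0)), frame_rate = 10,
                       duration = 0.8, amplitudes = 2)
  stack <- render_dynamic_stack(dyn, 8, k, seed = 16, dark_level = 50)
  out <- mean_frame_series(stack)
  tr_silent <- dff(out, scene$masks[[2]], baseline_window = 1:2,
                   frame_rate = 10)
  win <- stimulus_window(0.2, 10, length(tr_silent$values))
  expect_gt(max(tr_silent$values[win]), 0.02)
})

test_that("forward model plus reconstruction round-trips the clean scene", {
  scene <- generate_cell_scene(2, shape = c(32, 32), seed = 17)
  lines <- split_streaks(scene, 8)
  cfg <- recon_config(delta_kernel(4, scene$pixel_size), iterations = 10)
  rec <- reconstruct_frame(lines, cfg)
  # max projection of delta-deconvolved disjoint lines rebuilds the scene
  expect_equal(rec, scene$truth, tolerance = 1e-5)
})
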