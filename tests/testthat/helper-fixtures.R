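# shared fixtures built in code

# a small scattering kernel cached across tests (depth 100 um)
test_kernel <- local({
  cache <- NULL
  function(halfwidth = 8, z_h = 100, n_photons = 1e5) {
    key <- paste(halfwidth, z_h, n_photons)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- sample_kernel(scatter_config(
        z_h = z_h, n_photons = n_photons, kernel_halfwidth = halfwidth,
        seed = 101))
    }
    cache[[key]]
  }
})

# ground-truth masks wrapped for michelson_contrast()
truth_masks <- function(scene) {
  cell <- Reduce(`|`, scene$masks)
  list(cell_mask = cell, background_mask = !cell, degenerate = FALSE)
}

# deterministic two-cell scene for crosstalk fixtures: one active cell and
# one silent neighbour at a fixed separation
crosstalk_scene <- function(seed = 1, shape = c(40, 40)) {
  generate_cell_scene(2, shape = shape, pixel_size = 1.5625,
                      labeling = "multi-cell", seed = seed,
                      centers = rbind(c(20, 13), c(20, 28)))
}
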