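# Overlap series used by the trend checks: 4 degrees x 12 images, 6 cells
# per 128 x 128 image, all parameters except the overlap held constant
# (identical cells across degrees by construction).  Built once per run.
shared_overlap_series <- local({
  series <- NULL
  function() {
    if (is.null(series)) {
      patches <- generate_patches(fixture_spec("blob", c(9, 13), "radial",
                                               c(50, 110), n_patches = 10,
                                               rng_seed = 8, n_points = 64))
      model <- train_shape_model(lapply(patches, `[[`, "mask"),
                                 n_points = 64, r_min = 6)
      cfg <- scene_config(layout_spec(6, 1, image_size = c(128, 128)),
                          noise_sigma = 3, rng_seed = 41, n_images = 12)
      series <<- simulate_overlap_series(model, patches, cfg)
    }
    series
  }
})
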