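# Shared fixtures, built in code at test time.

# Small noise-free phantom parameter sets.
tiny_params <- function(n_habitats = 3, seed = 1, ...) {
  phantom_params(grid_shape = c(20, 20, 16), n_habitats_true = n_habitats,
                 seed = seed, ...)
}

# Strong-separation parameters for planted-recovery checks: habitats differ
# in mean intensity (non-collinear offsets) and in texture amplitude and
# correlation length. Mean offsets are kept moderate relative to the texture
# SDs so that each habitat still spans a good share of the 32-level
# discretization range — texture features then carry habitat identity too,
# instead of being flattened into 2-3 occupied levels by a huge
# between-habitat intensity range.
separated_params <- function(seed = 1, n_habitats = 3) {
  base <- c(120, 100, 140, 160)
  offs <- rbind(c(0, 0, 0, 0), c(40, -40, 40, -40), c(-40, 40, 40, 40),
                c(40, 40, -40, -40))[seq_len(n_habitats), , drop = FALSE]
  phantom_params(grid_shape = c(22, 22, 18), n_habitats_true = n_habitats,
                 habitat_intensity_means = sweep(offs, 2, base, "+"),
                 habitat_texture_sd = c(14, 12, 16, 13)[seq_len(n_habitats)],
                 habitat_texture_scale = c(1.2, 2.5, 4, 1.8)[seq_len(n_habitats)],
                 habitat_volume_weights = rep(1, n_habitats),  # equal shares
                 noise_sd = 2, patient_effect_sd = 0, seed = seed)
}

# Deterministic preprocessed volumes for feature tests.
make_preprocessed <- function(params = tiny_params(), msi = 0,
                              bias_correction = FALSE) {
  ph <- generate_phantom(params, msi)
  list(pre = preprocess_volumes(ph$volumes,
                                preprocess_config(bias_correction = bias_correction)),
       truth = ph$truth)
}

# A small in-region random "image" as cropped discretized array.
random_disc_region <- function(dims = c(8, 8, 6), n_levels = 8, seed = 1) {
  withr::with_seed(seed, {
    a <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
    a[1, 1, 1] <- 0L  # keep one background voxel so the region is non-trivial
    a
  })
}

expect_named_length <- function(x, n) {
  expect_length(x, n)
  expect_true(all(nzchar(names(x))))
  expect_false(any(duplicated(names(x))))
}
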