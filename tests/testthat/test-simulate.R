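test_that("phantoms are deterministic with clean air corners at zero noise", {
  sp <- phantom_spec(background_noise_sd = 0, seed = 9)
  ph <- make_phantom(sp)
  g <- build_roi_geometry(ph)
  expect_true(all(ph$data[g$cuboid_idx] == 0))
  expect_identical(make_phantom(sp)$data, ph$data)
  # baseline condition: tissue 50 over noise SD 5 is ~20 dB
  noisy <- make_phantom(phantom_spec(tissue_intensity = 50,
                                     background_noise_sd = 5, seed = 10))
  expect_equal(as.numeric(snr_standard(noisy)), 20, tolerance = 0.5)
  expect_error(phantom_spec(dims = c(8, 16, 16)), ">= 16")
})

test_that("zero-magnitude injections are the identity map", {
  ph <- make_phantom(phantom_spec(seed = 12))
  expect_identical(inject_noise(ph, artifact_spec("gaussian",
                                                  gaussian_variance = 0))$data,
                   ph$data)
  expect_identical(inject_noise(ph, artifact_spec("salt_pepper",
                                                  sp_amount = 0))$data, ph$data)
  expect_identical(inject_noise(ph, artifact_spec("speckle",
                                                  speckle_variance = 0))$data,
                   ph$data)
  expect_identical(inject_noise(ph, artifact_spec("gamma",
                                                  gamma_value = 1))$data, ph$data)
  expect_identical(inject_ghost(ph, artifact_spec("ghost",
                                                  ghost_fraction = 0))$data,
                   ph$data)
  ph4 <- make_phantom(phantom_spec(n_volumes = 6, seed = 12))
  expect_identical(inject_motion(ph4, artifact_spec("motion",
                                                    motion_amplitude_vox = 0))$data,
                   ph4$data)
  expect_error(artifact_spec("ghost", ghost_fraction = 1.2), "out of range")
})

test_that("injections are deterministic under a fixed seed", {
  ph <- make_phantom(phantom_spec(seed = 13))
  for (kind in c("gaussian", "salt_pepper", "speckle")) {
    a <- inject_noise(ph, artifact_spec(kind, seed = 4))
    b <- inject_noise(ph, artifact_spec(kind, seed = 4))
    expect_identical(a$data, b$data)
  }
  ph4 <- make_phantom(phantom_spec(n_volumes = 6, seed = 13))
  expect_identical(inject_motion(ph4, artifact_spec("motion", seed = 4))$data,
                   inject_motion(ph4, artifact_spec("motion", seed = 4))$data)
})

test_that("salt-and-pepper alters the prescribed voxel count", {
  ph <- make_phantom(phantom_spec(seed = 14))
  out <- inject_noise(ph, artifact_spec("salt_pepper", sp_amount = 0.05,
                                        seed = 5))
  n_target <- floor(0.05 * length(ph$data))
  n_changed <- sum(out$data != ph$data)
  # selected positions already at min/max stay equal, hence the lower bound
  expect_lte(n_changed, n_target)
  expect_gte(n_changed, floor(0.9 * n_target))
})

test_that("noise plus gamma shading lowers both SNR estimators", {
  ph <- make_phantom(phantom_spec(seed = 15))
  deg <- inject_noise(ph, artifact_spec("gaussian", gaussian_variance = 0.2,
                                        seed = 6))
  deg <- inject_noise(deg, artifact_spec("gamma", gamma_value = 0.6, seed = 7))
  expect_lt(as.numeric(snr_standard(deg)), as.numeric(snr_standard(ph)))
  expect_lt(as.numeric(snr_chang(deg)), as.numeric(snr_chang(ph)))
})

test_that("ghost peak prominence is non-decreasing in the ghost fraction", {
  ph <- make_phantom(phantom_spec(seed = 16))
  prom <- vapply(c(0.1, 0.2, 0.4), function(f) {
    ev <- ghost_curve(inject_ghost(ph, artifact_spec("ghost",
                                                     ghost_fraction = f)))
    if (length(ev$peak_prominences)) max(ev$peak_prominences) else 0
  }, numeric(1))
  expect_true(all(diff(prom) >= 0))
  expect_gt(prom[3], 0)
})

test_that("validation cohorts are complete, labelled and reproducible", {
  dir1 <- file.path(withr::local_tempdir(), "c1")
  labels <- build_validation_cohort(dir1, n_clean = 10, contaminate_index = 2,
                                    seed = 31, classes = "anatomical",
                                    phantom = phantom_spec(dims = c(32, 32, 16)))
  expect_equal(nrow(labels), 11L)
  expect_equal(sum(labels$contaminated), 1L)
  expect_true(all(file.exists(labels$path)))
  man <- scan_input_tree(dir1)
  expect_equal(nrow(man$records), 11L)
  expect_true(all(man$records$sequence_class == "anatomical"))
  # same seeds give byte-identical trees
  dir2 <- file.path(withr::local_tempdir(), "c2")
  build_validation_cohort(dir2, n_clean = 10, contaminate_index = 2,
                          seed = 31, classes = "anatomical",
                          phantom = phantom_spec(dims = c(32, 32, 16)))
  f1 <- list.files(dir1, pattern = "nii.gz$", recursive = TRUE, full.names = TRUE)
  f2 <- list.files(dir2, pattern = "nii.gz$", recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_true(all(mapply(function(a, b)
    identical(readBin(a, "raw", file.size(a)), readBin(b, "raw", file.size(b))),
    f1, f2)))
  expect_error(build_validation_cohort(tempfile(), n_clean = 3), "at least 10")
})
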