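test_that("centre of intensity is the rounded intensity-weighted centroid", {
  a <- array(0, c(16, 16, 16)); a[3, 4, 5] <- 7
  expect_equal(center_of_intensity(voxel_image(a)), c(3L, 4L, 5L))
  # uniform volume: exact geometric centre
  expect_equal(center_of_intensity(voxel_image(array(2, c(11, 11, 11)))),
               c(6L, 6L, 6L))
  # two equal point masses: midpoint
  b <- array(0, c(21, 9, 9)); b[1, 1, 1] <- 5; b[11, 1, 1] <- 5
  expect_equal(center_of_intensity(voxel_image(b)), c(6L, 1L, 1L))
  expect_error(center_of_intensity(voxel_image(array(0, c(9, 9, 9)))),
               "no signal mass")
})

test_that("ROI geometry follows the relative-size rules and stays disjoint", {
  img <- voxel_image(array(1, c(64, 64, 32)))
  g <- build_roi_geometry(img)
  expect_equal(g$sphere_radius_vox, 3L)          # floor(0.1 * min(dims))
  expect_equal(unname(g$cuboid_edges), c(9L, 9L, 4L))  # floor(0.15 * dim)
  expect_length(intersect(g$sphere_idx, g$cuboid_idx), 0L)
  expect_equal(g$n_cuboid, 8L * 9L * 9L * 4L)
  # boundary case: smallest admissible volume still yields a valid geometry
  g8 <- build_roi_geometry(voxel_image(array(1, c(8, 8, 8))))
  expect_gte(g8$sphere_radius_vox, 1L)
  expect_length(intersect(g8$sphere_idx, g8$cuboid_idx), 0L)
  expect_error(build_roi_geometry(voxel_image(array(1, c(6, 8, 8)))), ">= 8")
})

test_that("standard SNR reproduces closed-form decibel values", {
  for (mu in c(1, 10, 100)) {
    fx <- exact_ratio_image(mu, 1)
    expect_equal(as.numeric(snr_standard(fx$image, fx$geometry)),
                 20 * log10(mu), tolerance = 1e-12)
  }
  # zero noise -> +Inf sentinel with a degeneracy note, not an error
  flat <- voxel_image(array(5, c(32, 32, 16)))
  v <- snr_standard(flat)
  expect_true(is.infinite(v))
  expect_match(attr(v, "notes"), "zero-noise")
})

test_that("standard SNR matches a brute-force oracle on a noisy phantom", {
  ph <- make_phantom(phantom_spec(dims = c(64, 64, 32), tissue_intensity = 50,
                                  background_noise_sd = 5, seed = 11))
  g <- build_roi_geometry(ph)
  # oracle: direct mean/SD over the generated voxels
  oracle <- 20 * log10(mean(ph$data[g$sphere_idx]) /
                         sqrt(mean((ph$data[g$cuboid_idx] -
                                      mean(ph$data[g$cuboid_idx]))^2)))
  expect_equal(as.numeric(snr_standard(ph, g)), oracle, tolerance = 1e-12)
  expect_equal(as.numeric(snr_standard(ph, g)), 20, tolerance = 0.5)
  # scale invariance: signal and noise scale together
  scaled <- voxel_image(ph$data * 3.7, ph$voxel_size_mm)
  expect_equal(as.numeric(snr_standard(scaled, g)),
               as.numeric(snr_standard(ph, g)), tolerance = 1e-9)
})

test_that("histogram noise estimator recovers sigma and scales linearly", {
  set.seed(10)
  sl <- matrix(rnorm(128 * 128, 0, 3), 128)
  est <- estimate_noise_chang(sl)
  expect_equal(as.numeric(est), 3, tolerance = 0.15 * 3)
  # exact scale-equivariance
  expect_equal(as.numeric(estimate_noise_chang(sl * 4)), 4 * as.numeric(est),
               tolerance = 1e-9)
  # constant slice: flagged zero noise
  z <- estimate_noise_chang(matrix(2, 32, 32))
  expect_identical(as.numeric(z), 0)
  expect_match(attr(z, "notes"), "constant")
  expect_error(estimate_noise_chang(matrix(1, 4, 4)), "64")
})

test_that("Chang SNR approximates the closed form and averages directions", {
  set.seed(21)
  a <- array(100 + rnorm(64 * 64 * 16), c(64, 64, 16))
  a[a < 0] <- 0
  img <- voxel_image(a)
  v <- as.numeric(snr_chang(img))
  expect_equal(v, 40, tolerance = 2)   # estimator bias bounded by ~15% in sigma
  # 4D with the same volume as both non-b0 directions: identical to 3D value
  a4 <- array(c(a, a, a), c(64, 64, 16, 3))
  img4 <- voxel_image(a4, bvalues = c(0, 1000, 1000))
  expect_equal(as.numeric(snr_chang(img4)), v, tolerance = 1e-9)
})

test_that("temporal SNR matches its closed form and dB arithmetic", {
  ph <- make_phantom(phantom_spec(dims = c(64, 64, 24), tissue_intensity = 100,
                                  background_noise_sd = 10, n_volumes = 200,
                                  seed = 3))
  ts <- compute_tsnr(ph)
  expect_equal(as.numeric(ts$tsnr_db), 20, tolerance = 0.5)
  expect_equal(dim(ts$tsnr_map), c(64L, 64L, 24L))
  # doubling all intensities leaves tSNR unchanged
  dbl <- voxel_image(ph$data * 2, ph$voxel_size_mm)
  expect_equal(as.numeric(compute_tsnr(dbl)$tsnr_db),
               as.numeric(ts$tsnr_db), tolerance = 1e-9)
  # halving the temporal noise raises tSNR by 20*log10(2) dB
  half <- make_phantom(phantom_spec(dims = c(64, 64, 24), tissue_intensity = 100,
                                    background_noise_sd = 5, n_volumes = 200,
                                    seed = 3))
  expect_equal(as.numeric(compute_tsnr(half)$tsnr_db) - as.numeric(ts$tsnr_db),
               20 * log10(2), tolerance = 0.5)
  expect_error(compute_tsnr(make_phantom(phantom_spec())), "4D")
})

test_that("temporally constant voxels are excluded with a note, not averaged", {
  a <- array(50, c(16, 16, 16, 4))
  set.seed(5)
  a[, , , ] <- a + abs(rnorm(length(a)))
  # freeze one voxel known to sit in the sphere (centre of a uniform volume)
  a[8, 8, 8, ] <- 42
  img <- voxel_image(a)
  ts <- compute_tsnr(img)
  expect_true(is.finite(as.numeric(ts$tsnr_db)))
  expect_match(attr(ts$tsnr_db, "notes"), "constant")
})
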