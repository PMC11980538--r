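test_that("normalized mutual information behaves like an information metric", {
  ph <- make_phantom(phantom_spec(seed = 4))
  x <- ph$data[, , 12]
  expect_equal(as.numeric(mutual_information(x, x)), 1)
  # independent noise: near zero
  set.seed(11); a <- matrix(runif(128 * 128), 128)
  set.seed(12); b <- matrix(runif(128 * 128), 128)
  expect_lt(as.numeric(mutual_information(a, b)), 0.05)
  # mismatch lowers dependence
  shifted <- x[, c(2:ncol(x), 1)]
  expect_lt(as.numeric(mutual_information(x, shifted)),
            as.numeric(mutual_information(x, x)))
  # symmetry on random pairs
  set.seed(13)
  for (i in 1:5) {
    p <- matrix(runif(32 * 32), 32); q <- matrix(rnorm(32 * 32)^2, 32)
    expect_equal(as.numeric(mutual_information(p, q)),
                 as.numeric(mutual_information(q, p)), tolerance = 1e-12)
  }
  # zero-entropy degenerate cases are defined, flagged values
  c1 <- matrix(3, 16, 16)
  expect_equal(as.numeric(mutual_information(c1, c1)), 1)
  expect_equal(as.numeric(mutual_information(c1, matrix(5, 16, 16))), 0)
  expect_match(attr(mutual_information(c1, c1), "notes"), "zero-entropy")
  expect_error(mutual_information(matrix(1, 4, 4), matrix(1, 5, 5)), "dimensions")
})

test_that("representative slice selection follows the middle/brightest rules", {
  odd <- voxel_image(array(runif(32 * 32 * 9), c(32, 32, 9)))
  expect_equal(representative_slice(odd, "ghost")$slice_index, 5L)   # 0-based 4
  even <- voxel_image(array(runif(32 * 32 * 8), c(32, 32, 8)))
  expect_equal(representative_slice(even, "ghost")$slice_index, 5L)  # floor(8/2) 0-based
  # trace mode: slice with highest mean intensity over time
  a <- array(1, c(16, 16, 8, 4)); a[, , 7, ] <- 10
  sel <- representative_slice(voxel_image(a), "trace")
  expect_equal(sel$slice_index, 7L)
  expect_equal(dim(sel$slice), c(16L, 16L, 4L))
})

test_that("reference repetition switches at the steady-state threshold", {
  expect_equal(reference_repetition(10), 1L)
  expect_equal(reference_repetition(300), 10L)
  expect_equal(reference_repetition(2), 1L)
  expect_equal(reference_repetition(20), 10L)
  expect_equal(reference_repetition(19), 1L)
})

test_that("motion traces self-score 1 and dip where frames are displaced", {
  base <- make_phantom(phantom_spec(dims = c(32, 32, 16), background_noise_sd = 0,
                                    seed = 6))
  a <- array(rep(base$data, 40), c(32, 32, 16, 40))
  static <- voxel_image(a)
  tr <- motion_trace(static)
  expect_true(all(abs(tr$values - 1) < 1e-12))
  expect_equal(tr$values[tr$reference_index], 1)
  expect_equal(motion_severity(tr), 0)
  # translate frames 20..30 by 3 voxels: the trace dips exactly there
  b <- a
  for (t in 20:30) b[, , , t] <- b[c(4:32, 1:3), , , t]
  moved <- motion_trace(voxel_image(b))
  expect_lt(max(moved$values[20:30]), min(moved$values[c(1:19, 31:40)]))
  expect_error(motion_trace(base), "4D|repetitions|at least 2")
})

test_that("motion severity is the population SD and grows with amplitude", {
  expect_equal(motion_severity(c(1, 1, 0.8, 0.8)), 0.1, tolerance = 1e-12)
  ph <- make_phantom(phantom_spec(n_volumes = 40, seed = 5))
  sev <- vapply(c(0, 1, 3, 5), function(amp) {
    img <- if (amp == 0) ph else
      inject_motion(ph, artifact_spec("motion", motion_amplitude_vox = amp,
                                      seed = 9))
    motion_severity(motion_trace(img))
  }, numeric(1))
  expect_true(all(diff(sev) > 0))
})

test_that("ghost curves are bowls for clean scans and peak at the injected shift", {
  ph <- make_phantom(phantom_spec(seed = 7))
  clean <- ghost_curve(ph)
  expect_false(clean$is_ghost)
  n <- length(clean$curve$values) + 1L
  # bowl shape: both ends above the middle of the curve
  mid <- clean$curve$values[floor(n / 2)]
  expect_gt(clean$curve$values[1], mid)
  expect_gt(clean$curve$values[n - 1L], mid)
  # cyclicity: a full-cycle shift restores the self-comparison exactly
  sl <- representative_slice(ph, "ghost")$slice
  cycled <- niqc:::circ_shift_cols(sl, ncol(sl))
  expect_identical(cycled, sl)
  expect_equal(as.numeric(mutual_information(sl, cycled)), 1)

  ghosted <- inject_ghost(ph, artifact_spec("ghost", ghost_fraction = 0.3))
  ev <- ghost_curve(ghosted)
  expect_true(ev$is_ghost)
  expect_true(any(abs(ev$peak_shifts - 32) <= 2))
  # pure noise: no structured peak
  set.seed(8)
  noise <- voxel_image(array(abs(rnorm(64 * 64 * 9)), c(64, 64, 9)))
  expect_false(ghost_curve(noise)$is_ghost)
  expect_error(ghost_curve(voxel_image(array(1, c(16, 6, 8)))), "too small")
})
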