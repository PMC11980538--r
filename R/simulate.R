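#' Specify a synthetic brain-like phantom
#'
#' Conditions for [make_phantom()]: an ellipsoidal "brain" of
#' `tissue_intensity` with mild sinusoidal internal texture, centred in an
#' air background carrying Gaussian noise of `background_noise_sd` on a
#' small positive pedestal (magnitude data never goes negative). 4D
#' phantoms repeat the 3D frame with independent noise per frame.
#'
#' @param dims length-3 extents, each at least 16.
#' @param tissue_intensity positive scalar (default 50).
#' @param background_noise_sd non-negative scalar (default 5, i.e. a
#'   baseline standard SNR of about 20 dB).
#' @param n_volumes frame count (1 = 3D).
#' @param seed integer; the same spec always produces the identical phantom.
#' @param voxel_size_mm voxel spacing.
#' @param bvalues optional b-value table for diffusion phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64, 64, 24), tissue_intensity = 50,
                         background_noise_sd = 5, n_volumes = 1L, seed = 1L,
                         voxel_size_mm = c(0.15, 0.15, 0.5), bvalues = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 16L)) stop("dims must be 3 extents, each >= 16")
  if (tissue_intensity <= 0) stop("tissue_intensity must be positive")
  if (background_noise_sd < 0) stop("background_noise_sd must be non-negative")
  structure(list(dims = dims, tissue_intensity = tissue_intensity,
                 background_noise_sd = background_noise_sd,
                 n_volumes = as.integer(n_volumes), seed = as.integer(seed),
                 voxel_size_mm = voxel_size_mm, bvalues = bvalues),
            class = "phantom_spec")
}

#' Generate a synthetic phantom
#'
#' Deterministic given its spec. The ellipsoid has semi-axes of 35% of the
#' x/y extents and 35% of the z extent, so the corner noise cuboids always
#' sit in air; the background pedestal is `4 * background_noise_sd` so
#' additive noise stays non-negative without clipping bias.
#'
#' @param spec a [phantom_spec()].
#' @return A [voxel_image()].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  set.seed(spec$seed)
  cx <- (d + 1) / 2
  ax <- 0.35 * d
  xs <- (seq_len(d[1]) - cx[1]) / ax[1]
  ys <- (seq_len(d[2]) - cx[2]) / ax[2]
  zs <- (seq_len(d[3]) - cx[3]) / ax[3]
  r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  brain <- r2 <= 1
  # mild internal texture: +-5% smooth modulation, breaks the symmetry so
  # mutual information responds sharply to displaced copies
  tex <- outer(outer(sin(2 * pi * seq_len(d[1]) / d[1]),
                     cos(2 * pi * seq_len(d[2]) / d[2]), `*`),
               rep(1, d[3]), `*`)
  base <- array(0, d)
  base[brain] <- spec$tissue_intensity * (1 + 0.05 * tex[brain])

  sd <- spec$background_noise_sd
  pedestal <- 4 * sd
  base[!brain] <- pedestal

  one_frame <- function() {
    fr <- base
    if (sd > 0) fr <- fr + stats::rnorm(length(fr), 0, sd)
    fr[fr < 0] <- 0
    fr
  }
  if (spec$n_volumes <= 1L) {
    return(voxel_image(array(one_frame(), d), spec$voxel_size_mm))
  }
  frames <- vapply(seq_len(spec$n_volumes), function(t) one_frame(),
                   numeric(prod(d)))
  voxel_image(array(frames, c(d, spec$n_volumes)), spec$voxel_size_mm,
              bvalues = spec$bvalues)
}

#' Specify an artifact injection
#'
#' Parameters of the artifact families used for validation: additive
#' Gaussian noise, salt-and-pepper, multiplicative speckle, gamma shading,
#' frame-wise translational motion and half-FOV ghost copies. Defaults are
#' the validation conditions: Gaussian variance 0.2 and gamma 0.6 on
#' intensities normalised to `[0, 1]`.
#'
#' @param kind one of `"gaussian"`, `"salt_pepper"`, `"speckle"`,
#'   `"gamma"`, `"motion"`, `"ghost"`.
#' @param gaussian_variance,gamma_value,sp_amount,speckle_variance numeric
#'   family parameters.
#' @param motion_amplitude_vox maximum absolute in-plane translation.
#' @param ghost_fraction weight of the displaced copy, in `[0, 1)`.
#' @param ghost_shift offset of the copy; `NULL` = half the shift-axis FOV.
#' @param seed integer seed for the stochastic families.
#' @return A list of class `artifact_spec`.
#' @export
artifact_spec <- function(kind = c("gaussian", "salt_pepper", "speckle",
                                   "gamma", "motion", "ghost"),
                          gaussian_variance = 0.2, gamma_value = 0.6,
                          sp_amount = 0.05, speckle_variance = 0.2,
                          motion_amplitude_vox = 3, ghost_fraction = 0.3,
                          ghost_shift = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (gaussian_variance < 0 || sp_amount < 0 || sp_amount > 1 ||
      speckle_variance < 0 || gamma_value <= 0 ||
      motion_amplitude_vox < 0 || ghost_fraction < 0 || ghost_fraction >= 1) {
    stop("artifact parameter out of range for kind '", kind, "'")
  }
  structure(list(kind = kind, gaussian_variance = gaussian_variance,
                 gamma_value = gamma_value, sp_amount = sp_amount,
                 speckle_variance = speckle_variance,
                 motion_amplitude_vox = motion_amplitude_vox,
                 ghost_fraction = ghost_fraction, ghost_shift = ghost_shift,
                 seed = as.integer(seed)),
            class = "artifact_spec")
}

# run f on intensities normalised to [0,1]; restore scale and clip after
with_normalized <- function(image, f) {
  a <- image$data
  mx <- max(a)
  if (mx == 0) return(image)
  x <- f(a / mx)
  x[x < 0] <- 0
  x[x > 1] <- 1
  voxel_image(array(x * mx, dim(a)), image$voxel_size_mm, image$bvalues)
}

#' Inject intensity noise or shading
#'
#' Applies the spec's noise family on intensities normalised to `[0, 1]`
#' (so the variance parameters are unitless), then restores the original
#' scale, clipping into the valid range. Zero-magnitude parameters are the
#' identity map.
#'
#' @param image a [voxel_image()].
#' @param spec an [artifact_spec()] of kind `"gaussian"`, `"salt_pepper"`,
#'   `"speckle"` or `"gamma"`.
#' @return The degraded [voxel_image()].
#' @export
inject_noise <- function(image, spec) {
  stopifnot(inherits(image, "voxel_image"), inherits(spec, "artifact_spec"))
  set.seed(spec$seed)
  switch(spec$kind,
    gaussian = {
      if (spec$gaussian_variance == 0) return(image)
      with_normalized(image, function(x)
        x + stats::rnorm(length(x), 0, sqrt(spec$gaussian_variance)))
    },
    salt_pepper = {
      if (spec$sp_amount == 0) return(image)
      # applied on the original scale: untouched voxels must stay identical
      a <- image$data
      n_alter <- floor(spec$sp_amount * length(a))
      idx <- sample(length(a), n_alter)
      salt <- idx[seq_len(ceiling(n_alter / 2))]
      pepper <- setdiff(idx, salt)
      a[salt] <- max(a)
      a[pepper] <- min(a)
      voxel_image(a, image$voxel_size_mm, image$bvalues)
    },
    speckle = {
      if (spec$speckle_variance == 0) return(image)
      with_normalized(image, function(x)
        x * (1 + stats::rnorm(length(x), 0, sqrt(spec$speckle_variance))))
    },
    gamma = {
      if (spec$gamma_value == 1) return(image)
      with_normalized(image, function(x) x^spec$gamma_value)
    },
    stop("inject_noise handles gaussian/salt_pepper/speckle/gamma, not ", spec$kind))
}

#' Inject frame-wise translational motion
#'
#' Every frame after the first is translated in-plane by integer offsets
#' drawn uniformly from `[-amplitude, amplitude]` per axis (circular
#' shifts), emulating random subject motion over the time course.
#'
#' @param image a 4D [voxel_image()].
#' @param spec an [artifact_spec()] with `motion_amplitude_vox`.
#' @return The motion-corrupted [voxel_image()].
#' @export
inject_motion <- function(image, spec) {
  stopifnot(inherits(image, "voxel_image"), inherits(spec, "artifact_spec"))
  if (!is_4d(image)) stop("motion injection needs a 4D image")
  amp <- spec$motion_amplitude_vox
  if (amp == 0) return(image)
  set.seed(spec$seed)
  a <- image$data
  d <- dim(a)
  for (t in 2:d[4]) {
    dx <- sample(-amp:amp, 1L)
    dy <- sample(-amp:amp, 1L)
    for (z in seq_len(d[3])) {
      sl <- a[, , z, t]
      sl <- circ_shift_rows(sl, dx)
      sl <- circ_shift_cols(sl, dy)
      a[, , z, t] <- sl
    }
  }
  voxel_image(a, image$voxel_size_mm, image$bvalues)
}

circ_shift_rows <- function(m, n) t(circ_shift_cols(t(m), n))

#' Inject a displaced ghost copy
#'
#' Adds `ghost_fraction` times a circularly shifted copy of each slice (and
#' frame) along the second in-plane axis, then renormalises by
#' `1 + fraction` to preserve the intensity range — the mechanism behind a
#' Nyquist ghost, which sits half the field of view away from the object.
#'
#' @param image a [voxel_image()].
#' @param spec an [artifact_spec()]; `ghost_shift = NULL` uses half the
#'   shift-axis extent.
#' @return The ghosted [voxel_image()].
#' @export
inject_ghost <- function(image, spec) {
  stopifnot(inherits(image, "voxel_image"), inherits(spec, "artifact_spec"))
  frac <- spec$ghost_fraction
  if (frac == 0) return(image)
  a <- image$data
  d <- dim(a)
  shift <- spec$ghost_shift %||% (d[2] %/% 2L)
  apply_slice <- function(sl) (sl + frac * circ_shift_cols(sl, shift)) / (1 + frac)
  if (length(d) == 3L) {
    for (z in seq_len(d[3])) a[, , z] <- apply_slice(a[, , z])
  } else {
    for (t in seq_len(d[4])) for (z in seq_len(d[3])) {
      a[, , z, t] <- apply_slice(a[, , z, t])
    }
  }
  voxel_image(a, image$voxel_size_mm, image$bvalues)
}

#' Write a validation cohort of NIfTI fixtures
#'
#' Builds a BIDS-like tree of `n_clean` clean phantoms plus one
#' artifact-contaminated phantom per sequence class (anatomical 3D with
#' Gaussian noise + gamma shading; functional 4D with injected motion;
#' diffusion 4D with Gaussian noise + gamma on every direction), the
#' single-scan contamination protocol used to probe outlier recovery.
#'
#' @param outdir target directory (created if needed).
#' @param n_clean number of clean subjects per class, at least 10.
#' @param contaminate_index which subject (1-based) receives the artifact.
#' @param seed integer master seed.
#' @param classes subset of `c("anatomical", "functional", "diffusion")`.
#' @param phantom base [phantom_spec()] (its seed is re-derived per scan).
#' @param config a [qc_config()] supplying the artifact defaults.
#' @return Data frame of ground-truth labels: `path`, `subject_id`,
#'   `sequence_class`, `contaminated`.
#' @export
build_validation_cohort <- function(outdir, n_clean = 30L,
                                    contaminate_index = 1L, seed = 1L,
                                    classes = c("anatomical", "functional",
                                                "diffusion"),
                                    phantom = phantom_spec(),
                                    config = qc_config()) {
  config <- as_qc_config(config)
  if (n_clean < 10L) stop("n_clean must be at least 10")
  if (contaminate_index < 1L || contaminate_index > n_clean + 1L) {
    stop("contaminate_index out of range")
  }
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)

  rows <- list()
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    for (i in seq_len(n_clean + 1L)) {
      sub <- sprintf("sub-%02d", i)
      scan_seed <- (seed * 1000L + ci * 101L + i) %% .Machine$integer.max
      sp <- phantom
      sp$seed <- scan_seed
      if (cls == "anatomical") {
        sp$n_volumes <- 1L
        img <- make_phantom(sp)
        fname <- sprintf("%s_T2w.nii.gz", sub)
        subdir <- file.path(outdir, sub, "anat")
      } else if (cls == "functional") {
        sp$n_volumes <- 40L
        img <- make_phantom(sp)
        fname <- sprintf("%s_task-rest_bold.nii.gz", sub)
        subdir <- file.path(outdir, sub, "func")
      } else {
        sp$n_volumes <- 12L
        sp$bvalues <- c(0, rep(1000, 11))
        img <- make_phantom(sp)
        fname <- sprintf("%s_dwi.nii.gz", sub)
        subdir <- file.path(outdir, sub, "dwi")
      }
      contaminated <- i == contaminate_index
      if (contaminated) {
        if (cls == "functional") {
          img <- inject_motion(img, artifact_spec(
            "motion", motion_amplitude_vox = config$sim_motion_amplitude,
            seed = scan_seed + 7L))
        } else {
          img <- inject_noise(img, artifact_spec(
            "gaussian", gaussian_variance = config$sim_gaussian_variance,
            seed = scan_seed + 7L))
          img <- inject_noise(img, artifact_spec(
            "gamma", gamma_value = config$sim_gamma_value,
            seed = scan_seed + 8L))
        }
      }
      dir.create(subdir, recursive = TRUE, showWarnings = FALSE)
      path <- file.path(subdir, fname)
      write_voxel_image(img, path)
      if (cls == "diffusion") {
        writeLines(paste(sp$bvalues, collapse = " "),
                   sub("\\.nii\\.gz$", ".bval", path))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, subject_id = sub, sequence_class = cls,
        contaminated = contaminated, stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, rows)
  utils::write.csv(labels, file.path(outdir, "ground_truth.csv"),
                   row.names = FALSE)
  labels
}

#' Write a voxel image to a NIfTI file
#'
#' @param image a [voxel_image()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_voxel_image <- function(image, path) {
  stopifnot(inherits(image, "voxel_image"))
  nif <- RNifti::asNifti(image$data)
  nd <- length(dim(image$data))
  RNifti::pixdim(nif) <- c(image$voxel_size_mm, rep(1, nd - 3L))
  RNifti::writeNifti(nif, path)
  invisible(path)
}
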