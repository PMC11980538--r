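#' Centre of intensity of a volume
#'
#' The intensity-weighted mean coordinate of a 3D volume, rounded to the
#' nearest lattice point. Anchors the automatic signal sphere so no manual
#' region of interest is needed. 4D callers average over the fourth axis
#' first (see [time_average()]).
#'
#' @param image a 3D [voxel_image()] with at least one positive voxel.
#' @return Integer triple of 1-based voxel indices.
#' @export
center_of_intensity <- function(image) {
  stopifnot(inherits(image, "voxel_image"))
  if (is_4d(image)) stop("center_of_intensity expects a 3D image; average 4D data first")
  a <- image$data
  total <- sum(a)
  if (total <= 0) stop("no signal mass: image is all zero")
  d <- dim(a)
  coi <- vapply(1:3, function(ax) {
    w <- apply(a, ax, sum)
    sum(w * seq_len(d[ax])) / total
  }, numeric(1))
  as.integer(round(coi))
}

#' Build the automatic signal/noise geometry
#'
#' Places a sphere at the centre of intensity as the signal reference and
#' eight cuboids in the volume corners as the noise reference. The sphere
#' radius is `floor(sphere_radius_frac * min(dims))`, at least 2, shrunk if
#' needed so the sphere stays inside the lattice; each cuboid edge is
#' `floor(cuboid_edge_frac * dim)`, at least 2, per axis.
#'
#' @param image a 3D [voxel_image()] with every extent at least 8.
#' @param config a [qc_config()] (fractions above).
#' @return A list of class `roi_geometry`: `coi`, `sphere_radius_vox`,
#'   `sphere_idx` / `cuboid_idx` (linear voxel indices), `n_sphere`,
#'   `n_cuboid`, `cuboid_edges`.
#' @export
build_roi_geometry <- function(image, config = qc_config()) {
  config <- as_qc_config(config)
  stopifnot(inherits(image, "voxel_image"))
  if (is_4d(image)) image <- time_average(image)
  d <- dim(image$data)
  if (any(d < 8L)) {
    stop("volume too small for the sphere/cuboid geometry; every extent must be >= 8 voxels")
  }
  coi <- center_of_intensity(image)

  radius <- max(2L, floor(config$sphere_radius_frac * min(d)))
  # never let the sphere poke out of the lattice
  radius <- min(radius, coi - 1L, d - coi)
  if (radius < 1L) {
    stop("centre of intensity too close to the volume edge for a signal sphere; ",
         "minimum usable extent is 8 voxels with an interior object")
  }

  rng <- lapply(1:3, function(ax) (coi[ax] - radius):(coi[ax] + radius))
  grid <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  inside <- (grid$x - coi[1])^2 + (grid$y - coi[2])^2 + (grid$z - coi[3])^2 <=
    radius^2
  sphere_idx <- grid$x[inside] + d[1] * (grid$y[inside] - 1L) +
    d[1] * d[2] * (grid$z[inside] - 1L)

  edges <- pmax(2L, floor(config$cuboid_edge_frac * d))
  cuboid_idx <- integer(0)
  axis_rng <- function(ax, lo) if (lo) 1:edges[ax] else (d[ax] - edges[ax] + 1L):d[ax]
  for (cx in c(TRUE, FALSE)) for (cy in c(TRUE, FALSE)) for (cz in c(TRUE, FALSE)) {
    g <- expand.grid(x = axis_rng(1, cx), y = axis_rng(2, cy), z = axis_rng(3, cz))
    cuboid_idx <- c(cuboid_idx,
                    g$x + d[1] * (g$y - 1L) + d[1] * d[2] * (g$z - 1L))
  }
  if (length(intersect(sphere_idx, cuboid_idx))) {
    stop("signal sphere overlaps the corner noise cuboids; volume too small ",
         "or object off-centre - a larger matrix is needed")
  }
  structure(list(coi = coi, sphere_radius_vox = radius,
                 sphere_idx = sphere_idx, cuboid_idx = cuboid_idx,
                 n_sphere = length(sphere_idx), n_cuboid = length(cuboid_idx),
                 cuboid_edges = edges, dims = d),
            class = "roi_geometry")
}

# population standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standard (COI sphere / corner cuboid) SNR in decibels
#'
#' The mean intensity inside the automatically placed signal sphere divided
#' by the standard deviation of the eight pooled corner cuboids, reported as
#' `20*log10(ratio)` dB. For 4D diffusion data the first b0 volume
#' represents the image.
#'
#' @param image a 3D or 4D diffusion [voxel_image()].
#' @param geometry optional precomputed [build_roi_geometry()] result.
#' @param config a [qc_config()].
#' @return Numeric dB value; `Inf` with a `"zero-noise"` entry in
#'   `attr(, "notes")` when the cuboid standard deviation is 0.
#' @export
snr_standard <- function(image, geometry = NULL, config = qc_config()) {
  config <- as_qc_config(config)
  if (is_4d(image)) image <- get_volume(image, b0_indices(image, config$b0_threshold)[1L])
  if (is.null(geometry)) geometry <- build_roi_geometry(image, config)
  mu_s <- mean(image$data[geometry$sphere_idx])
  sigma_c <- pop_sd(image$data[geometry$cuboid_idx])
  if (sigma_c == 0) {
    return(structure(Inf, notes = "zero-noise: cuboid standard deviation is 0"))
  }
  structure(to_db(mu_s / sigma_c), notes = character())
}

#' Histogram-based noise estimate for one slice
#'
#' ROI-free noise estimation from the statistical distribution of local
#' intensity variability: sample standard deviations over sliding
#' `chang_window`-square neighbourhoods are histogrammed with
#' `ceiling(sqrt(n))` bins, the counts smoothed with a
#' `chang_smooth_bins`-wide moving average, and the mode taken as the noise
#' standard deviation. Air regions dominate the mode, so no region selection
#' is needed.
#'
#' @param slice numeric matrix with at least 64 entries.
#' @param config a [qc_config()].
#' @return Non-negative noise SD in intensity units; 0 with a
#'   `"constant-slice"` note for a constant slice.
#' @export
estimate_noise_chang <- function(slice, config = qc_config()) {
  config <- as_qc_config(config)
  if (!is.matrix(slice)) slice <- as.matrix(slice)
  if (length(slice) < 64L) stop("slice too small for histogram noise estimation (need >= 64 voxels)")
  w <- as.integer(config$chang_window)
  nr <- nrow(slice); nc <- ncol(slice)
  if (nr < w || nc < w) stop("slice smaller than the sliding window")
  if (max(slice) == min(slice)) {
    return(structure(0, notes = "constant-slice: no intensity variation"))
  }
  # sliding-window sums over the w*w shifted copies (valid windows only)
  s1 <- matrix(0, nr - w + 1L, nc - w + 1L)
  s2 <- matrix(0, nr - w + 1L, nc - w + 1L)
  for (i in seq_len(w)) for (j in seq_len(w)) {
    block <- slice[i:(nr - w + i), j:(nc - w + j), drop = FALSE]
    s1 <- s1 + block
    s2 <- s2 + block^2
  }
  nwin <- w * w
  v <- (s2 - s1^2 / nwin) / (nwin - 1)     # sample variance per window
  sds <- sqrt(pmax(v, 0))
  if (max(sds) == 0) {
    return(structure(0, notes = "constant-slice: zero local variability"))
  }
  nbins <- ceiling(sqrt(length(sds)))
  h <- graphics::hist(sds, breaks = seq(0, max(sds), length.out = nbins + 1L),
                      plot = FALSE)
  counts <- as.numeric(h$counts)
  k <- as.integer(config$chang_smooth_bins)
  sm <- stats::filter(counts, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  mode_bin <- which.max(sm)
  structure(h$mids[mode_bin], notes = character())
}

#' Chang-style histogram SNR in decibels
#'
#' Per slice, the mean signal inside the COI sphere's cross-section divided
#' by the histogram noise estimate of that slice, in dB; the scalar result
#' averages over all slices intersecting the sphere. For 4D diffusion
#' images, the per-volume values of every non-b0 direction are averaged.
#'
#' @param image a 3D image or a 4D diffusion [voxel_image()].
#' @param geometry optional [build_roi_geometry()] result (3D input only).
#' @param config a [qc_config()].
#' @return Numeric dB value with a `notes` attribute listing degenerate
#'   slices.
#' @export
snr_chang <- function(image, geometry = NULL, config = qc_config()) {
  config <- as_qc_config(config)
  stopifnot(inherits(image, "voxel_image"))
  if (is_4d(image)) {
    nt <- n_volumes(image)
    b0 <- b0_indices(image, config$b0_threshold)
    use <- setdiff(seq_len(nt), b0)
    if (!length(use)) use <- seq_len(nt)   # nothing but b0: fall back to all
    vals <- lapply(use, function(t) snr_chang(get_volume(image, t), NULL, config))
    notes <- unique(unlist(lapply(vals, attr, "notes")))
    return(structure(mean(unlist(vals)), notes = notes))
  }
  if (is.null(geometry)) geometry <- build_roi_geometry(image, config)
  d <- dim(image$data)
  # slice membership of each sphere voxel
  z_of <- ((geometry$sphere_idx - 1L) %/% (d[1] * d[2])) + 1L
  notes <- character()
  e_z <- c()
  for (z in sort(unique(z_of))) {
    mu <- mean(image$data[geometry$sphere_idx[z_of == z]])
    sigma <- estimate_noise_chang(image$data[, , z], config)
    if (sigma == 0) {
      notes <- c(notes, sprintf("slice %d: zero noise estimate, skipped", z))
      next
    }
    if (mu <= 0) {
      notes <- c(notes, sprintf("slice %d: no signal in sphere cross-section, skipped", z))
      next
    }
    e_z <- c(e_z, to_db(mu / sigma))
  }
  if (!length(e_z)) stop("all slices degenerate: no usable noise estimate")
  structure(mean(e_z), notes = notes)
}

#' Temporal SNR of a 4D series
#'
#' Builds the signal sphere on the time-averaged volume, computes the
#' per-voxel temporal mean over temporal standard deviation as a dB map, and
#' summarises it as the mean over the sphere. Temporally constant voxels are
#' undefined (infinite) in the map; they are excluded from the sphere mean
#' and counted in the notes.
#'
#' @param image a 4D [voxel_image()] with at least 2 frames.
#' @param config a [qc_config()].
#' @return List with `tsnr_map` (3D array, dB; `Inf` where the voxel is
#'   temporally constant) and `tsnr_db` (scalar sphere mean, with `notes`).
#' @export
compute_tsnr <- function(image, config = qc_config()) {
  config <- as_qc_config(config)
  stopifnot(inherits(image, "voxel_image"))
  if (!is_4d(image) || n_volumes(image) < 2L) {
    stop("temporal SNR needs a 4D series with at least 2 frames")
  }
  d <- dim(image$data)
  mat <- matrix(image$data, ncol = d[4L])
  mu_t <- rowMeans(mat)
  sigma_t <- sqrt(pmax(rowMeans((mat - mu_t)^2), 0))
  map <- ifelse(sigma_t > 0 & mu_t > 0, to_db(mu_t / sigma_t),
                ifelse(sigma_t == 0, Inf, NA_real_))
  dim(map) <- d[1:3]

  geometry <- build_roi_geometry(time_average(image), config)
  vals <- map[geometry$sphere_idx]
  n_const <- sum(is.infinite(vals))
  usable <- vals[is.finite(vals)]
  notes <- if (n_const > 0) {
    sprintf("%d temporally constant voxels excluded from sphere mean", n_const)
  } else character()
  if (!length(usable)) stop("all sphere voxels temporally constant: tSNR undefined")
  list(tsnr_map = map,
       tsnr_db = structure(mean(usable), notes = notes),
       geometry = geometry)
}
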