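#' Normalized mutual information between two slices
#'
#' Mutual information from a joint intensity histogram (`mi_bins` bins per
#' axis over each image's own min-max range), normalised as
#' `2*I(a;b) / (H(a) + H(b))` so identical images score 1 and independent
#' ones score near 0. Symmetric in its arguments.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param config a [qc_config()].
#' @return Score in `[0, 1]`. A constant (zero-entropy) input is degenerate:
#'   the score is 1 if both are constant and equal, otherwise 0, with a
#'   `"zero-entropy"` note attached.
#' @export
mutual_information <- function(a, b, config = qc_config()) {
  config <- as_qc_config(config)
  if (!all(dim(a) == dim(b))) stop("images must have identical dimensions")
  nb <- as.integer(config$mi_bins)
  const_a <- max(a) == min(a)
  const_b <- max(b) == min(b)
  if (const_a || const_b) {
    val <- if (const_a && const_b && a[1] == b[1]) 1 else 0
    return(structure(val, notes = "zero-entropy: constant input image"))
  }
  bin <- function(x) {
    i <- floor((x - min(x)) / (max(x) - min(x)) * nb) + 1L
    pmin(i, nb)
  }
  ia <- bin(a); ib <- bin(b)
  joint <- tabulate(ia + nb * (ib - 1L), nbins = nb * nb) / length(a)
  pa <- tabulate(ia, nbins = nb) / length(a)
  pb <- tabulate(ib, nbins = nb) / length(b)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h_a <- ent(pa); h_b <- ent(pb); h_ab <- ent(joint)
  mi <- h_a + h_b - h_ab
  structure(min(1, max(0, 2 * mi / (h_a + h_b))), notes = character())
}

#' Select the representative slice of a volume
#'
#' For the ghost shift curve the middle axial slice is used (of the
#' fourth-axis average for 4D data); for motion traces, the slice with the
#' highest mean intensity over the fourth axis, which keeps the trace on
#' tissue and the processing time low.
#'
#' @param image a [voxel_image()].
#' @param mode `"ghost"` (middle slice) or `"trace"` (brightest slice).
#' @return List with `slice` (2D matrix; for `"trace"` on 4D data a
#'   `n_x x n_y x T` array of that slice over frames) and 1-based
#'   `slice_index`. Even slice counts take index `floor(N/2)` (0-based
#'   convention), i.e. `floor(N/2) + 1` in R indexing.
#' @export
representative_slice <- function(image, mode = c("ghost", "trace")) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "voxel_image"))
  d <- dim(image$data)
  if (mode == "ghost") {
    avg <- time_average(image)
    zi <- floor(d[3] / 2) + 1L
    return(list(slice = avg$data[, , zi], slice_index = zi))
  }
  if (!is_4d(image)) {
    zi <- floor(d[3] / 2) + 1L
    return(list(slice = image$data[, , zi], slice_index = zi))
  }
  z_means <- apply(image$data, 3, mean)
  zi <- which.max(z_means)
  list(slice = image$data[, , zi, ], slice_index = zi)
}

#' Reference repetition for motion traces
#'
#' Short series use the first repetition as the mutual-information
#' reference; longer series use the tenth, by which point the signal has
#' reached steady state and is free of initial transient effects.
#'
#' @param n_volumes number of repetitions (>= 2).
#' @param config a [qc_config()] (`reference_volume_threshold`, default 20).
#' @return 1-based reference index (1 or 10).
#' @export
reference_repetition <- function(n_volumes, config = qc_config()) {
  config <- as_qc_config(config)
  stopifnot(n_volumes >= 2L)
  if (n_volumes >= config$reference_volume_threshold) 10L else 1L
}

#' Mutual-information trace across repetitions
#'
#' On the brightest slice, normalized mutual information between the
#' reference repetition and every repetition in acquisition order. Motion
#' shows up as characteristic drops in the trace.
#'
#' @param image a 4D [voxel_image()] (functional: time axis; diffusion:
#'   direction axis).
#' @param config a [qc_config()].
#' @return An object of class `mi_trace`: list with `values` (in `[0,1]`,
#'   `values[reference_index] == 1`), `reference_index`, `axis` (`"time"`
#'   or `"direction"`) and `slice_index`.
#' @export
motion_trace <- function(image, config = qc_config()) {
  config <- as_qc_config(config)
  stopifnot(inherits(image, "voxel_image"))
  nt <- n_volumes(image)
  if (nt < 2L) stop("motion trace needs at least 2 repetitions")
  rep_sl <- representative_slice(image, "trace")
  frames <- rep_sl$slice                      # n_x x n_y x T
  ref <- reference_repetition(nt, config)
  ref_img <- frames[, , ref]
  values <- vapply(seq_len(nt), function(t)
    as.numeric(mutual_information(ref_img, frames[, , t], config)), numeric(1))
  axis <- if (!is.null(image$bvalues)) "direction" else "time"
  structure(list(values = values, reference_index = ref, axis = axis,
                 slice_index = rep_sl$slice_index),
            class = "mi_trace")
}

#' Motion severity of a trace
#'
#' A single per-scan motion value: the population standard deviation of the
#' mutual-information trace. 0 for a perfectly static series; grows with
#' the amplitude and frequency of inter-repetition displacement.
#'
#' @param trace an `mi_trace` (or bare numeric vector of MI values).
#' @return Non-negative scalar.
#' @export
motion_severity <- function(trace) {
  v <- if (inherits(trace, "mi_trace")) trace$values else as.numeric(trace)
  if (length(v) < 2L) stop("trace needs at least 2 values")
  pop_sd(v)
}

# circular shift of matrix columns (axis 2, the displayed row direction)
circ_shift_cols <- function(m, n) {
  nc <- ncol(m)
  n <- ((n %% nc) + nc) %% nc
  if (n == 0) return(m)
  m[, c((nc - n + 1L):nc, 1L:(nc - n))]
}

# peak prominence: height above the higher of the two minima separating the
# peak from taller terrain (or the series ends)
peak_prominence <- function(x, i) {
  lmin <- x[i]; j <- i - 1L
  while (j >= 1L && x[j] < x[i]) { lmin <- min(lmin, x[j]); j <- j - 1L }
  if (j < 1L) lmin <- min(x[1:i])
  rmin <- x[i]; j <- i + 1L
  while (j <= length(x) && x[j] < x[i]) { rmin <- min(rmin, x[j]); j <- j + 1L }
  if (j > length(x)) rmin <- min(x[i:length(x)])
  x[i] - max(lmin, rmin)
}

#' Ghost evidence from the mutual-information shift curve
#'
#' The representative slice is compared against circularly shifted copies of
#' itself over every offset `1 .. N-1` along the second in-plane axis. A
#' clean image yields a smooth bowl-shaped curve (mismatch grows, then the
#' shifted image wraps back towards the reference); a ghosted image produces
#' peaks where the displaced copy re-aligns with the object — a Nyquist
#' ghost peaks half the field of view away. Interior local maxima with
#' prominence of at least `ghost_prominence_frac` of the curve range count
#' as ghost evidence.
#'
#' @param image a [voxel_image()] with shift-axis extent of at least 8.
#' @param config a [qc_config()].
#' @return An object of class `ghost_evidence`: `curve` (`mi_trace` with
#'   axis `"shift"`, values for offsets `1..N-1`), `peak_shifts` (offsets,
#'   excluding 0 and N), `peak_prominences`, `is_ghost`.
#' @export
ghost_curve <- function(image, config = qc_config()) {
  config <- as_qc_config(config)
  rep_sl <- representative_slice(image, "ghost")
  ref <- rep_sl$slice
  n_shift <- ncol(ref)
  if (n_shift < 8L) stop("image too small for shift analysis (shift axis < 8 voxels)")
  values <- vapply(seq_len(n_shift - 1L), function(n)
    as.numeric(mutual_information(ref, circ_shift_cols(ref, n), config)),
    numeric(1))
  rng <- max(values) - min(values)
  # relative prominence keeps the rule scale-free; the absolute floor (in
  # normalized-MI units) stops flat, all-noise curves from firing
  min_prom <- max(config$ghost_prominence_frac * rng,
                  config$ghost_prominence_min)
  peaks <- integer(0); proms <- numeric(0)
  if (rng > 0) {
    for (i in 2:(length(values) - 1L)) {
      if (values[i] > values[i - 1L] && values[i] >= values[i + 1L]) {
        pr <- peak_prominence(values, i)
        if (pr >= min_prom) {
          peaks <- c(peaks, i)      # offset i corresponds to shift i
          proms <- c(proms, pr)
        }
      }
    }
  }
  curve <- structure(list(values = values, reference_index = NA_integer_,
                          axis = "shift", slice_index = rep_sl$slice_index),
                     class = "mi_trace")
  structure(list(curve = curve, peak_shifts = peaks,
                 peak_prominences = proms, is_ghost = length(peaks) > 0L),
            class = "ghost_evidence")
}
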