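#' Construct a voxel image
#'
#' A `voxel_image` is the package's in-memory container for magnitude MR data:
#' a 3D `(x, y, z)` or 4D `(x, y, z, t/direction)` array of finite,
#' non-negative intensities together with the voxel spacing in millimetres
#' and, for diffusion acquisitions, the b-value table aligned with the fourth
#' axis.
#'
#' @param data numeric array with 3 or 4 dimensions; all values must be
#'   finite and `>= 0` (magnitude-reconstructed data).
#' @param voxel_size_mm positive length-3 numeric, voxel edge lengths in mm.
#' @param bvalues optional numeric vector of non-negative diffusion
#'   weightings (s/mm^2); its length must equal the fourth-axis extent.
#' @return An object of class `voxel_image` with elements `data`,
#'   `voxel_size_mm` and `bvalues`.
#' @export
voxel_image <- function(data, voxel_size_mm = c(1, 1, 1), bvalues = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L))) {
    stop("`data` must be a 3D or 4D array")
  }
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) {
    stop("image intensities must all be finite")
  }
  if (any(data < 0)) {
    stop("image intensities must be non-negative (magnitude data)")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be three positive lengths")
  }
  if (!is.null(bvalues)) {
    bvalues <- as.numeric(bvalues)
    if (any(bvalues < 0) || anyNA(bvalues)) {
      stop("b-values must be non-negative")
    }
    if (length(bvalues) != n_volumes_of(data)) {
      stop(sprintf("b-value table length (%d) does not match 4th-axis extent (%d)",
                   length(bvalues), n_volumes_of(data)))
    }
  }
  structure(list(data = data, voxel_size_mm = voxel_size_mm, bvalues = bvalues),
            class = "voxel_image")
}

n_volumes_of <- function(data) {
  d <- dim(data)
  if (length(d) == 4L) d[4L] else 1L
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %s voxels, %s mm%s\n",
              paste(d, collapse = " x "),
              paste(signif(x$voxel_size_mm, 4), collapse = " x "),
              if (is.null(x$bvalues)) "" else
                sprintf(", %d b-values", length(x$bvalues))))
  invisible(x)
}

#' Number of volumes along the fourth axis
#' @param image a `voxel_image`.
#' @return Integer count (1 for a 3D image).
#' @export
n_volumes <- function(image) {
  stopifnot(inherits(image, "voxel_image"))
  n_volumes_of(image$data)
}

is_4d <- function(image) length(dim(image$data)) == 4L

#' Average a 4D image over the fourth axis
#'
#' Returns the image unchanged when it is already 3D. Used to obtain the
#' representative 3D volume on which the centre of intensity, signal sphere
#' and middle slice are defined for time series and diffusion acquisitions.
#'
#' @param image a `voxel_image`.
#' @return A 3D `voxel_image`.
#' @export
time_average <- function(image) {
  stopifnot(inherits(image, "voxel_image"))
  if (!is_4d(image)) return(image)
  d <- dim(image$data)
  m <- rowMeans(matrix(image$data, ncol = d[4L]), na.rm = FALSE)
  voxel_image(array(m, d[1:3]), image$voxel_size_mm)
}

# Extract one 3D frame of a 4D image (or the image itself when 3D).
get_volume <- function(image, t) {
  if (!is_4d(image)) return(image)
  voxel_image(image$data[, , , t, drop = FALSE][, , , 1L],
              image$voxel_size_mm)
}

# Indices of b0 volumes: b-value below `threshold` when a table exists,
# otherwise the first volume is assumed to be b0.
b0_indices <- function(image, threshold = 50) {
  nt <- n_volumes(image)
  if (is.null(image$bvalues)) return(1L)
  idx <- which(image$bvalues < threshold)
  if (length(idx) == 0L) idx <- 1L
  idx
}

# 20 * log10(ratio), the decibel convention used for every SNR-type feature.
to_db <- function(ratio) 20 * log10(ratio)
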