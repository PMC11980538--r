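# Fixture builders shared across the test files. Everything is generated in
# code at test time; nothing binary ships with the package.

# A volume with an exactly known sphere-mean / cuboid-SD ratio: constant mu
# inside the precomputed sphere, corner cuboids alternating sigma*2 / 0
# (pooled mean sigma, population SD exactly sigma when the voxel count is
# even). Returns the image plus the geometry to evaluate it with.
exact_ratio_image <- function(mu, sigma, dims = c(64, 64, 32)) {
  base <- voxel_image(array(mu, dims))
  geom <- build_roi_geometry(base)
  stopifnot(geom$n_cuboid %% 2L == 0L)
  a <- array(mu, dims)
  vals <- rep(c(2 * sigma, 0), geom$n_cuboid / 2L)
  a[geom$cuboid_idx] <- vals
  list(image = voxel_image(a, base$voxel_size_mm), geometry = geom)
}

# Minimal BIDS-like tree: one anatomical + one functional scan for sub-01.
write_bids_fixture <- function(dir) {
  anat <- make_phantom(phantom_spec(dims = c(24, 24, 16), seed = 1))
  func <- make_phantom(phantom_spec(dims = c(24, 24, 16), n_volumes = 12,
                                    seed = 2))
  dir.create(file.path(dir, "sub-01", "anat"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "sub-01", "func"), recursive = TRUE,
             showWarnings = FALSE)
  write_voxel_image(anat, file.path(dir, "sub-01", "anat", "sub-01_T2w.nii.gz"))
  write_voxel_image(func,
                    file.path(dir, "sub-01", "func", "sub-01_task-rest_bold.nii.gz"))
  invisible(dir)
}

# Minimal synthetic Bruker study folder: method + visu_pars parameter files
# and a little-endian int16 2dseq payload.
write_bruker_fixture <- function(dir, dims = c(32, 32, 8), n_dirs = 30,
                                 slope = 0.5, seed = 3) {
  scan_dir <- file.path(dir, "subj1", "3")
  pdata <- file.path(scan_dir, "pdata", "1")
  dir.create(pdata, recursive = TRUE, showWarnings = FALSE)
  bvals <- c(0, rep(1000, n_dirs - 1))
  writeLines(c("##$Method=<Bruker:DtiEpi>",
               "##$PVM_Matrix=( 2 )", paste(dims[1], dims[2]),
               "##$PVM_SpatResol=( 2 )", "0.15 0.15",
               "##$PVM_SliceThick=0.5",
               sprintf("##$PVM_SPackArrNSlices=( 1 )"), as.character(dims[3]),
               sprintf("##$PVM_DwEffBval=( %d )", n_dirs),
               paste(bvals, collapse = " "),
               "##$PVM_NRepetitions=1"),
             file.path(scan_dir, "method"))
  writeLines(c("##$VisuCoreWordType=_16BIT_SGN_INT",
               "##$VisuCoreDataSlope=( 1 )", as.character(slope)),
             file.path(pdata, "visu_pars"))
  set.seed(seed)
  vals <- sample(0:1000, prod(dims) * n_dirs, replace = TRUE)
  writeBin(as.integer(vals), file.path(pdata, "2dseq"), size = 2L,
           endian = "little")
  list(root = dir, seq2d = file.path(pdata, "2dseq"), bvals = bvals,
       dims = dims, slope = slope, raw = vals)
}

# Independent brute-force linear-interpolation quantile (the oracle the IQR
# rule is checked against); mirrors the standard order-statistic definition
# without calling stats::quantile.
brute_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Anatomical feature pair used by the recovery experiments.
anat_features <- function(img) {
  g <- build_roi_geometry(img)
  c(snr_standard_db = as.numeric(snr_standard(img, g)),
    snr_chang_db = as.numeric(snr_chang(img, g)))
}
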