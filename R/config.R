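#' Default pipeline configuration
#'
#' Every tunable used by the feature extractors, detectors and simulator,
#' collected in one list so a whole run can be reproduced from its config
#' snapshot. Values can be overridden by name; unknown names are an error.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A named list of class `qc_config`.
#' @details Main entries:
#' \describe{
#'   \item{sphere_radius_frac / cuboid_edge_frac}{Relative size of the COI
#'     signal sphere (fraction of the smallest spatial extent, floor, min 2)
#'     and the corner noise cuboids (fraction of each extent, floor, min 2).}
#'   \item{b0_threshold}{b-values below this (s/mm^2) count as b0.}
#'   \item{chang_window / chang_smooth_bins}{Sliding-window edge and
#'     moving-average width of the histogram noise estimator.}
#'   \item{mi_bins}{Joint-histogram bins per axis for mutual information.}
#'   \item{ghost_prominence_frac}{Peak prominence threshold as a fraction of
#'     the MI shift-curve range.}
#'   \item{reference_volume_threshold}{Series with at least this many
#'     repetitions use repetition 10 as MI reference, shorter ones use 1.}
#'   \item{min_functional_volumes}{4D series with at least this many frames
#'     and no b-table classify as functional even without a keyword.}
#'   \item{contamination, ocsvm_nu, iforest_trees, lof_neighbors_max}{Outlier
#'     detector settings shared across the four multivariate methods.}
#'   \item{vote_threshold}{Majority votes at or above this mark a scan for
#'     review (1-5).}
#'   \item{ghost_in_feature_matrix}{If TRUE the ghost boolean joins the
#'     outlier feature matrix; default keeps it report-only.}
#' }
#' @export
qc_config <- function(...) {
  cfg <- list(
    # ingest
    keywords_anatomical = c("turbo", "rare", "anat", "struc", "t1", "t2"),
    keywords_diffusion  = c("diff", "dwi", "dti"),
    keywords_functional = c("rest", "rs-", "func", "bold"),
    keywords_excluded   = c("localizer", "localiser", "scout", "tripilot"),
    min_functional_volumes = 10L,
    b0_threshold = 50,
    # snr geometry + Chang estimator
    sphere_radius_frac = 0.1,
    cuboid_edge_frac = 0.15,
    chang_window = 3L,
    chang_smooth_bins = 3L,
    # mutual information
    mi_bins = 64L,
    ghost_prominence_frac = 0.1,
    ghost_prominence_min = 0.05,
    reference_volume_threshold = 20L,
    # outlier stage
    contamination = 0.05,
    ocsvm_nu = 0.1,
    iforest_trees = 100L,
    iforest_sample = 256L,
    lof_neighbors_max = 20L,
    vote_threshold = 3L,
    ghost_in_feature_matrix = FALSE,
    # simulator defaults (study conditions)
    sim_gaussian_variance = 0.2,
    sim_gamma_value = 0.6,
    sim_sp_amount = 0.05,
    sim_speckle_variance = 0.2,
    sim_motion_amplitude = 3,
    sim_ghost_fraction = 0.3,
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "qc_config")
}

# Merge a user-supplied partial config (list or qc_config) over the defaults.
as_qc_config <- function(config) {
  if (is.null(config)) return(qc_config())
  if (inherits(config, "qc_config")) return(config)
  do.call(qc_config, as.list(config))
}
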