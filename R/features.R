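#' Compute the quality features of one scan
#'
#' Dispatches on the sequence class: anatomical scans get the two spatial
#' SNR estimators; diffusion scans additionally get motion severity over
#' the direction axis; functional scans get temporal SNR and motion
#' severity. Ghost evidence is computed for every scan and reported
#' alongside (it joins the outlier feature matrix only when
#' `ghost_in_feature_matrix` is enabled).
#'
#' @param image a [voxel_image()].
#' @param sequence_class `"anatomical"`, `"diffusion"` or `"functional"`.
#' @param config a [qc_config()].
#' @return Named list: `snr_standard_db`, `snr_chang_db`, `tsnr_db`,
#'   `motion_severity` (NA where not applicable), `ghost` (0/1), `notes`
#'   (character vector of degeneracy flags).
#' @export
compute_qc_features <- function(image, sequence_class, config = qc_config()) {
  config <- as_qc_config(config)
  notes <- character()
  grab <- function(expr) {
    v <- tryCatch(expr, error = function(e) {
      notes <<- c(notes, conditionMessage(e))
      NA_real_
    })
    notes <<- c(notes, attr(v, "notes"))
    as.numeric(v)
  }
  snr_std <- NA_real_; snr_ch <- NA_real_; tsnr <- NA_real_; mot <- NA_real_

  if (sequence_class %in% c("anatomical", "diffusion")) {
    snr_std <- grab(snr_standard(image, config = config))
    snr_ch <- grab(snr_chang(image, config = config))
  }
  if (sequence_class == "functional") {
    tsnr <- grab(compute_tsnr(image, config = config)$tsnr_db)
  }
  if (sequence_class %in% c("diffusion", "functional") && n_volumes(image) >= 2L) {
    mot <- grab(motion_severity(motion_trace(image, config = config)))
  }
  ghost <- tryCatch(ghost_curve(image, config = config)$is_ghost,
                    error = function(e) {
                      notes <<- c(notes, conditionMessage(e))
                      NA
                    })
  list(snr_standard_db = snr_std, snr_chang_db = snr_ch, tsnr_db = tsnr,
       motion_severity = mot, ghost = as.integer(ghost),
       notes = notes)
}

# columns that enter the outlier matrix, by class
class_feature_set <- function(cls, config) {
  base <- switch(cls,
    anatomical = c("snr_standard_db", "snr_chang_db"),
    diffusion  = c("snr_standard_db", "snr_chang_db", "motion_severity"),
    functional = c("tsnr_db", "motion_severity"),
    character())
  if (isTRUE(config$ghost_in_feature_matrix)) c(base, "ghost") else base
}

#' Compute features for every scan in a manifest
#'
#' Stage II of the pipeline: reads each record, computes its class-specific
#' features, and assembles one feature table per sequence class. Scans
#' whose image cannot be read or whose features all fail are logged and
#' excluded from detection, never silently dropped.
#'
#' @param manifest a `qc_manifest` from [scan_input_tree()].
#' @param config a [qc_config()].
#' @param progress function called with a status string per scan (or NULL).
#' @return List with `tables` (named list of per-class data frames:
#'   identifying columns + feature columns + `notes`), and `log`.
#' @export
compute_features_stage <- function(manifest, config = qc_config(),
                                   progress = NULL) {
  config <- as_qc_config(config)
  recs <- manifest$records
  log <- character()
  rows <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    rec <- recs[i, ]
    if (!is.null(progress)) progress(sprintf("features %d/%d: %s",
                                             i, nrow(recs), rec$path))
    feats <- tryCatch({
      img <- read_image(rec)
      compute_qc_features(img, rec$sequence_class, config)
    }, error = function(e) {
      list(snr_standard_db = NA_real_, snr_chang_db = NA_real_,
           tsnr_db = NA_real_, motion_severity = NA_real_, ghost = NA_integer_,
           notes = paste("feature stage failed:", conditionMessage(e)))
    })
    if (length(feats$notes)) {
      log <- c(log, sprintf("%s: %s", rec$path,
                            paste(feats$notes, collapse = "; ")))
    }
    rows[[i]] <- data.frame(
      path = rec$path, subject_id = rec$subject_id,
      sequence_class = rec$sequence_class, sequence_name = rec$sequence_name,
      scan_index = rec$scan_index,
      snr_standard_db = feats$snr_standard_db,
      snr_chang_db = feats$snr_chang_db, tsnr_db = feats$tsnr_db,
      motion_severity = feats$motion_severity, ghost = feats$ghost,
      notes = paste(feats$notes, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  all_rows <- if (length(rows)) do.call(rbind, rows) else NULL
  tables <- list()
  if (!is.null(all_rows)) {
    for (cls in unique(all_rows$sequence_class)) {
      sub <- all_rows[all_rows$sequence_class == cls, , drop = FALSE]
      fset <- class_feature_set(cls, config)
      keep_cols <- c("path", "subject_id", "sequence_class", "sequence_name",
                     "scan_index", fset, "notes")
      tab <- sub[, keep_cols, drop = FALSE]
      all_missing <- apply(tab[, fset, drop = FALSE], 1,
                           function(r) all(is.na(as.numeric(r))))
      if (any(all_missing)) {
        log <- c(log, sprintf("%s: all features missing, excluded from detection",
                              tab$path[all_missing]))
        tab <- tab[!all_missing, , drop = FALSE]
      }
      rownames(tab) <- NULL
      tables[[cls]] <- tab
    }
  }
  list(tables = tables, log = log)
}
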