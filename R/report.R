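#' Write per-class feature tables
#'
#' One CSV per sequence class (`features_<class>.csv`): file path, sequence
#' name, the class's feature values, degeneracy notes and the exported
#' middle-slice image name, so table rows and gallery images cross-reference.
#'
#' @param report a `qc_report` from [run_pipeline()] (or a list with
#'   `feature_tables`).
#' @param outdir output directory.
#' @return Character vector of written file paths.
#' @export
write_feature_tables <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot write to ", outdir)
  paths <- character()
  for (cls in names(report$feature_tables)) {
    tab <- report$feature_tables[[cls]]
    tab$image_file <- slice_image_name(cls, tab$scan_index, tab$subject_id)
    p <- file.path(outdir, sprintf("features_%s.csv", cls))
    utils::write.csv(tab, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  paths
}

slice_image_name <- function(cls, index, subject) {
  sprintf("%s_%d_%s.png", cls, index, gsub("[^A-Za-z0-9-]", "", subject))
}

#' Write the voting table
#'
#' `voting.csv`: one row per scan with its path and metadata, the five 0/1
#' detector columns (`iqr`, `ocsvm`, `iforest`, `lof`, `ee`), the 0-5
#' majority vote and the review flag — so the user can see which algorithm
#' was decisive for each scan.
#'
#' @param report a `qc_report` (or list with `voting_table`).
#' @param outdir output directory.
#' @return Path of the written file.
#' @export
write_voting_table <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot write to ", outdir)
  p <- file.path(outdir, "voting.csv")
  utils::write.csv(report$voting_table, p, row.names = FALSE,
                   fileEncoding = "UTF-8")
  p
}

#' Export middle-slice inspection images
#'
#' Saves one grayscale PNG per scan (4D scans: middle slice of the
#' fourth-axis average), named `<class>_<index>_<subject>.png` with the
#' index incrementing per class in manifest order — a quick visual gallery
#' for spotting mis-oriented or obviously noisy scans.
#'
#' @param manifest a `qc_manifest`.
#' @param outdir output directory (a `manual_slice_inspection` subfolder is
#'   created).
#' @param progress optional function called per exported file.
#' @return Character vector of written paths; per-file failures are logged
#'   in `attr(, "log")` and do not abort the run.
#' @export
export_middle_slices <- function(manifest, outdir, progress = NULL) {
  gallery <- file.path(outdir, "manual_slice_inspection")
  dir.create(gallery, recursive = TRUE, showWarnings = FALSE)
  recs <- manifest$records
  out <- character()
  log <- character()
  for (i in seq_len(nrow(recs))) {
    rec <- recs[i, ]
    fname <- slice_image_name(rec$sequence_class, rec$scan_index, rec$subject_id)
    res <- tryCatch({
      img <- read_image(rec)
      sl <- representative_slice(img, "ghost")$slice
      rng <- range(sl)
      norm <- if (diff(rng) > 0) (sl - rng[1]) / diff(rng) else sl * 0
      # transpose so x runs left-right in the PNG
      png::writePNG(t(norm)[rev(seq_len(ncol(norm))), , drop = FALSE],
                    file.path(gallery, fname))
      file.path(gallery, fname)
    }, error = function(e) {
      log <<- c(log, sprintf("slice export failed for %s: %s", rec$path,
                             conditionMessage(e)))
      NA_character_
    })
    if (!is.na(res)) {
      out <- c(out, res)
      if (!is.null(progress)) progress(res)
    }
  }
  structure(out, log = log)
}

#' Render summary figures
#'
#' Static raster figures: a pie chart of the voxel sizes per axis (to spot
#' scans acquired with the wrong sequence parameters) and, per class and
#' feature, a histogram with IQR-flagged scans drawn in red and the review
#' threshold annotated. Renders headlessly via the `png()` device.
#'
#' @param report a `qc_report` (uses `feature_tables`, `voting_table`,
#'   `manifest`).
#' @param outdir output directory (a `figures` subfolder is created).
#' @return Character vector of figure paths; empty classes are skipped with
#'   a note in `attr(, "log")`.
#' @export
render_summary_figures <- function(report, outdir) {
  figdir <- file.path(outdir, "figures")
  dir.create(figdir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  log <- character()

  # voxel-size pie charts, one per axis
  vox <- report$manifest$records$voxel_size_mm
  if (length(vox)) {
    p <- file.path(figdir, "voxel_sizes.png")
    grDevices::png(p, width = 900, height = 320)
    graphics::par(mfrow = c(1, 3))
    for (ax in 1:3) {
      sizes <- vapply(vox, function(v) round(v[ax], 4), numeric(1))
      tab <- table(sizes)
      graphics::pie(tab, labels = sprintf("%s mm (n=%d)", names(tab), tab),
                    main = c("x", "y", "z")[ax])
    }
    grDevices::dev.off()
    out <- c(out, p)
  }

  for (cls in names(report$feature_tables)) {
    tab <- report$feature_tables[[cls]]
    if (!nrow(tab)) { log <- c(log, sprintf("class %s empty, figure skipped", cls)); next }
    flags <- iqr_flags(tab)
    for (f in feature_columns(tab)) {
      x <- tab[[f]]
      ok <- is.finite(x)
      if (sum(ok) < 2L) { log <- c(log, sprintf("%s/%s: too few values", cls, f)); next }
      p <- file.path(figdir, sprintf("dist_%s_%s.png", cls, f))
      grDevices::png(p, width = 540, height = 400)
      h <- graphics::hist(x[ok], breaks = "FD", plot = FALSE)
      cols <- rep("grey70", length(h$mids))
      if (any(flags & ok)) {
        bad <- x[flags & ok]
        for (b in bad) cols[findInterval(b, h$breaks, all.inside = TRUE)] <- "red"
      }
      graphics::plot(h, col = cols, main = sprintf("%s: %s", cls, f),
                     xlab = f)
      graphics::mtext(sprintf("red = IQR outlier; review threshold = %d votes",
                              attr(report$voting_table, "threshold") %||% NA),
                      side = 3, line = 0.2, cex = 0.75)
      grDevices::dev.off()
      out <- c(out, p)
    }
  }
  structure(out, log = log)
}

#' Run the full quality-control pipeline
#'
#' The three consecutive stages — parsing, feature calculation, outlier
#' detection — followed by report writing: per-class feature tables,
#' `voting.csv`, the middle-slice gallery, summary figures, a config
#' snapshot and a timestamped run log, all under `outdir`.
#'
#' @param root input directory of scans.
#' @param outdir output directory.
#' @param config a [qc_config()].
#' @param format_hint optional `"nifti"`, `"bids"` or `"bruker"`.
#' @param mode `"per_dataset"` or `"collective"` outlier pooling.
#' @param threshold review threshold 1-5 (default from config).
#' @param seed integer seed recorded in the report and forwarded to the
#'   stochastic detectors.
#' @param quiet suppress console progress.
#' @return A `qc_report`: `manifest`, `feature_tables`, `voting_table`,
#'   `files` (everything written), `config`, `seed`, `log`.
#' @export
run_pipeline <- function(root, outdir, config = qc_config(),
                         format_hint = NULL, mode = "per_dataset",
                         threshold = NULL, seed = 1L, quiet = FALSE) {
  config <- as_qc_config(config)
  t0 <- Sys.time()
  log <- character()
  say <- function(msg) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg)
    log <<- c(log, line)
    if (!quiet) message(line)
  }

  say(sprintf("stage I: parsing %s", root))
  manifest <- scan_input_tree(root, format_hint, config)
  say(sprintf("found %d scans, %d excluded", nrow(manifest$records),
              nrow(manifest$excluded)))

  say("stage II: feature calculation")
  feat <- compute_features_stage(manifest, config,
                                 progress = if (quiet) NULL else function(m) say(m))
  log <- c(log, feat$log)

  say("stage III: outlier detection")
  if (!length(feat$tables)) {
    say("no feature tables; outlier stage skipped")
    voting <- data.frame()
  } else {
    voting <- run_outlier_stage(feat$tables, mode = mode,
                                threshold = threshold, seed = seed,
                                config = config)
    log <- c(log, attr(voting, "log"))
  }

  say("writing reports")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  report <- structure(list(manifest = manifest, feature_tables = feat$tables,
                           voting_table = voting, config = config,
                           seed = seed, log = log),
                      class = "qc_report")
  files <- c(write_feature_tables(report, outdir),
             if (nrow(voting)) write_voting_table(report, outdir))
  gallery <- export_middle_slices(manifest, outdir)
  log <- c(log, attr(gallery, "log"))
  figs <- tryCatch(render_summary_figures(report, outdir),
                   error = function(e) {
                     log <<- c(log, paste("figure rendering failed:",
                                          conditionMessage(e)))
                     character()
                   })
  log <- c(log, attr(figs, "log"))

  cfg_snapshot <- file.path(outdir, "run_config.yaml")
  yaml::write_yaml(c(list(root = root, outdir = outdir, mode = mode,
                          seed = seed,
                          threshold = attr(voting, "threshold")),
                     unclass(config)), cfg_snapshot)
  say(sprintf("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  report$log <- log
  writeLines(log, file.path(outdir, "run_log.txt"))
  report$files <- c(files, gallery, figs, cfg_snapshot,
                    file.path(outdir, "run_log.txt"))
  if (nrow(manifest$excluded)) {
    excl_path <- file.path(outdir, "excluded.csv")
    utils::write.csv(manifest$excluded, excl_path, row.names = FALSE)
    report$files <- c(report$files, excl_path)
  }
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d scans in %d class tables; %d flagged at threshold %s\n",
              sum(vapply(x$feature_tables, nrow, integer(1))),
              length(x$feature_tables),
              if (nrow(x$voting_table)) sum(x$voting_table$flagged) else 0L,
              attr(x$voting_table, "threshold") %||% "-"))
  invisible(x)
}
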