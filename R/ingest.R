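#' Classify an acquisition into a sequence class
#'
#' Assigns one of `"anatomical"`, `"diffusion"`, `"functional"` or
#' `"excluded"` from the acquisition name, the b-value table and the number
#' of volumes. A multi-entry b-value table always forces `"diffusion"`;
#' otherwise case-insensitive substring matching against the keyword lists in
#' [qc_config()] decides; a 4D series without b-table classifies as
#' functional when it carries a functional keyword or has at least
#' `min_functional_volumes` repetitions. Anything unresolved is `"excluded"`.
#'
#' @param sequence_name acquisition name (free text, may be `""`).
#' @param bvalues optional numeric b-value table.
#' @param n_volumes number of volumes along the fourth axis (1 for 3D).
#' @param config a [qc_config()] list.
#' @return A single string: the sequence class.
#' @export
classify_sequence <- function(sequence_name, bvalues = NULL, n_volumes = 1L,
                              config = qc_config()) {
  config <- as_qc_config(config)
  name <- tolower(sequence_name %||% "")
  has_kw <- function(kws) any(vapply(kws, grepl, logical(1), x = name,
                                     fixed = TRUE))
  if (has_kw(config$keywords_excluded)) return("excluded")
  if (!is.null(bvalues) && length(bvalues) > 1L) return("diffusion")
  if (has_kw(config$keywords_diffusion)) return("diffusion")
  if (has_kw(config$keywords_functional)) return("functional")
  if (has_kw(config$keywords_anatomical)) return("anatomical")
  if (n_volumes >= config$min_functional_volumes) return("functional")
  "excluded"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discover scans under an input tree
#'
#' Recursively searches `root` for NIfTI files (optionally BIDS-organised
#' with JSON sidecars) and raw Bruker study folders (directories containing a
#' `2dseq` reconstruction), reads the minimal metadata needed for quality
#' control, and classifies every candidate. Localizers, unreadable files and
#' scans without class evidence go to the `excluded` list with a reason;
#' everything else becomes a record. Ordering is deterministic
#' (lexicographic by path).
#'
#' @param root input directory.
#' @param format_hint optional `"nifti"`, `"bids"` or `"bruker"`; restricts
#'   the search to that layout. `NULL` searches for both NIfTI and Bruker.
#' @param config a [qc_config()] list.
#' @return A `qc_manifest`: list with `records` (data frame, one row per
#'   scan: `path`, `subject_id`, `session_id`, `sequence_class`,
#'   `source_format`, `sequence_name`, `n_volumes`, `voxel_size_mm`
#'   (list-column), `bvalues` (list-column)), `excluded` (data frame of
#'   `path`, `reason`) and `root`.
#' @export
scan_input_tree <- function(root, format_hint = NULL, config = qc_config()) {
  config <- as_qc_config(config)
  if (!dir.exists(root)) stop("input root does not exist or is unreadable: ", root)
  if (!is.null(format_hint) &&
      !format_hint %in% c("nifti", "bids", "bruker")) {
    stop("format_hint must be one of nifti, bids, bruker")
  }

  candidates <- list()
  if (is.null(format_hint) || format_hint %in% c("nifti", "bids")) {
    nii <- list.files(root, pattern = "\\.nii(\\.gz)?$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
    for (p in nii) candidates[[p]] <- "nifti"
  }
  if (is.null(format_hint) || format_hint == "bruker") {
    seq2d <- list.files(root, pattern = "^2dseq$", recursive = TRUE,
                        full.names = TRUE)
    for (p in seq2d) candidates[[p]] <- "bruker"
  }
  paths <- sort(names(candidates))

  records <- list()
  excluded <- list()
  drop <- function(path, reason) {
    excluded[[length(excluded) + 1L]] <<- list(path = path, reason = reason)
  }

  for (p in paths) {
    fmt <- candidates[[p]]
    meta <- tryCatch(
      if (fmt == "bruker") bruker_metadata(p) else nifti_metadata(p, config),
      error = function(e) e)
    if (inherits(meta, "error")) {
      drop(p, paste("unreadable:", conditionMessage(meta)))
      next
    }
    cls <- classify_sequence(meta$sequence_name, meta$bvalues,
                             meta$n_volumes, config)
    if (cls == "excluded") {
      drop(p, sprintf("no sequence-class evidence for '%s'", meta$sequence_name))
      next
    }
    records[[length(records) + 1L]] <- list(
      path = p,
      subject_id = meta$subject_id,
      session_id = meta$session_id,
      sequence_class = cls,
      source_format = if (fmt == "nifti" && isTRUE(meta$bids)) "bids" else fmt,
      sequence_name = meta$sequence_name,
      n_volumes = meta$n_volumes,
      voxel_size_mm = list(meta$voxel_size_mm),
      bvalues = list(meta$bvalues))
  }

  rec_df <- if (length(records)) {
    do.call(rbind, lapply(records, function(r)
      data.frame(path = r$path, subject_id = r$subject_id,
                 session_id = r$session_id, sequence_class = r$sequence_class,
                 source_format = r$source_format,
                 sequence_name = r$sequence_name, n_volumes = r$n_volumes,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(path = character(), subject_id = character(),
               session_id = character(), sequence_class = character(),
               source_format = character(), sequence_name = character(),
               n_volumes = integer(), stringsAsFactors = FALSE)
  }
  if (nrow(rec_df)) {
    rec_df$voxel_size_mm <- lapply(records, function(r) r$voxel_size_mm[[1]])
    rec_df$bvalues <- lapply(records, function(r) r$bvalues[[1]])
    # duplicate subject/class collisions get a running scan index for joins
    key <- paste(rec_df$subject_id, rec_df$sequence_class)
    rec_df$scan_index <- stats::ave(seq_along(key), key,
                                    FUN = seq_along)
  } else {
    rec_df$voxel_size_mm <- list()
    rec_df$bvalues <- list()
    rec_df$scan_index <- integer()
  }
  exc_df <- if (length(excluded)) {
    data.frame(path = vapply(excluded, `[[`, "", "path"),
               reason = vapply(excluded, `[[`, "", "reason"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(path = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(records = rec_df, excluded = exc_df, root = root),
            class = "qc_manifest")
}

#' @export
print.qc_manifest <- function(x, ...) {
  cat(sprintf("<qc_manifest> %d scans (%s), %d excluded, root: %s\n",
              nrow(x$records),
              paste(sprintf("%d %s", table(x$records$sequence_class),
                            names(table(x$records$sequence_class))),
                    collapse = ", "),
              nrow(x$excluded), x$root))
  invisible(x)
}

# --- NIfTI / BIDS metadata -------------------------------------------------

nifti_metadata <- function(path, config) {
  # corrupt files raise here and land in `excluded`; the reader's own
  # partial-read warnings would just duplicate that reason
  hdr <- suppressWarnings(RNifti::niftiHeader(path))
  ndim <- hdr$dim[1L]
  if (ndim < 3L) stop("image has fewer than 3 dimensions")
  dims <- hdr$dim[2:(1L + ndim)]
  nvol <- if (ndim >= 4L) as.integer(hdr$dim[5L]) else 1L
  if (nvol < 1L) nvol <- 1L
  vox <- abs(hdr$pixdim[2:4])
  if (any(!is.finite(vox)) || any(vox <= 0)) stop("non-positive voxel sizes in header")

  base <- sub("\\.nii(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  sidecar <- file.path(dirname(path), paste0(base, ".json"))
  bids <- FALSE
  seq_name <- base
  if (file.exists(sidecar)) {
    js <- tryCatch(jsonlite::read_json(sidecar), error = function(e) NULL)
    if (!is.null(js)) {
      bids <- TRUE
      nm <- js$SeriesDescription %||% js$ProtocolName
      if (!is.null(nm)) seq_name <- paste(base, nm)
    }
  }
  bval_file <- file.path(dirname(path), paste0(base, ".bval"))
  bvalues <- NULL
  if (file.exists(bval_file)) {
    bvalues <- suppressWarnings(as.numeric(scan(bval_file, quiet = TRUE)))
    bvalues <- bvalues[is.finite(bvalues)]
    if (!length(bvalues)) bvalues <- NULL
  }

  sub_id <- bids_entity(path, "sub") %||% basename(dirname(path))
  if (grepl("^sub-", basename(path))) bids <- TRUE
  list(subject_id = sub_id,
       session_id = bids_entity(path, "ses") %||% NA_character_,
       sequence_name = seq_name, n_volumes = nvol,
       voxel_size_mm = as.numeric(vox), bvalues = bvalues, bids = bids)
}

# Pull a BIDS entity (sub-XX / ses-XX) from the filename or any path part.
bids_entity <- function(path, key) {
  parts <- c(basename(path), strsplit(dirname(path), "/")[[1]])
  pat <- paste0("(^|[/_])", key, "-([A-Za-z0-9]+)")
  for (p in parts) {
    m <- regmatches(p, regexec(pat, p))[[1]]
    if (length(m) == 3L) return(paste0(key, "-", m[3L]))
  }
  NULL
}

# --- Bruker (minimal ParaVision subset) ------------------------------------

# Parse the line-oriented "##$Key=value" parameter dialect; array parameters
# ("##$Key=( n )" followed by values) are flattened to numeric/character
# vectors. Only the handful of fields needed for QC is interpreted.
parse_bruker_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "##$")) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- substring(ln, 4L, eq - 1L)
      val <- substring(ln, eq + 1L)
      if (grepl("^\\(", val)) {           # array parameter: values follow
        vals <- character()
        j <- i + 1L
        while (j <= length(lines) && !startsWith(lines[j], "##") &&
               !startsWith(lines[j], "$$")) {
          vals <- c(vals, lines[j])
          j <- j + 1L
        }
        txt <- paste(vals, collapse = " ")
        num <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1]]))
        out[[key]] <- if (all(is.finite(num)) && length(num)) num else trimws(txt)
        i <- j
        next
      }
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (is.finite(num)) num else trimws(val)
    }
    i <- i + 1L
  }
  out
}

bruker_metadata <- function(seq2d_path, read_data = FALSE) {
  d <- dirname(seq2d_path)
  # 2dseq lives in <scan>/pdata/<recon>/2dseq; method sits at the scan level
  scan_dir <- dirname(dirname(d))
  method_file <- file.path(scan_dir, "method")
  visu_file <- file.path(d, "visu_pars")
  if (!file.exists(method_file)) stop("missing Bruker 'method' file for ", seq2d_path)
  m <- parse_bruker_params(method_file)
  v <- if (file.exists(visu_file)) parse_bruker_params(visu_file) else list()

  mat <- m$PVM_Matrix
  if (is.null(mat) || length(mat) < 2L) stop("missing PVM_Matrix")
  res <- m$PVM_SpatResol
  if (is.null(res)) stop("missing PVM_SpatResol")
  nslices <- if (length(mat) >= 3L) mat[3L] else (m$PVM_SPackArrNSlices %||% 1)
  slice_thk <- m$PVM_SliceThick %||% res[min(3L, length(res))]
  vox <- c(res[1L], res[2L], if (length(res) >= 3L) res[3L] else slice_thk)
  dims <- c(mat[1L], mat[2L], nslices)
  bvalues <- m$PVM_DwEffBval
  nrep <- as.integer(m$PVM_NRepetitions %||% 1)
  nvol <- if (!is.null(bvalues)) length(bvalues) else nrep
  seq_name <- as.character(m$Method %||% basename(scan_dir))
  seq_name <- gsub("[<>]", "", seq_name)

  meta <- list(subject_id = basename(dirname(scan_dir)),
               session_id = NA_character_,
               sequence_name = seq_name, n_volumes = max(1L, nvol),
               voxel_size_mm = as.numeric(vox), bvalues = bvalues,
               bids = FALSE)
  if (!read_data) return(meta)

  word_type <- as.character(v$VisuCoreWordType %||% "_16BIT_SGN_INT")
  slope <- v$VisuCoreDataSlope %||% 1
  n <- prod(dims) * max(1L, nvol)
  con <- file(seq2d_path, "rb")
  on.exit(close(con))
  raw_vals <- switch(word_type,
    "_16BIT_SGN_INT" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                               endian = "little"),
    "_32BIT_SGN_INT" = readBin(con, "integer", n = n, size = 4L,
                               endian = "little"),
    "_32BIT_FLOAT" = readBin(con, "double", n = n, size = 4L,
                             endian = "little"),
    stop("unsupported Bruker word type: ", word_type))
  if (length(raw_vals) != n) {
    stop(sprintf("2dseq size mismatch at %s: expected %d values, read %d; ",
                 seq2d_path, n, length(raw_vals)),
         "check the matrix/slice parameters and correct the study manually")
  }
  vals <- as.numeric(raw_vals) * slope[1L]
  vals[vals < 0] <- 0   # magnitude data; negative quantisation residue clipped
  arr <- if (nvol > 1L) array(vals, c(dims, nvol)) else array(vals, dims)
  meta$image <- voxel_image(arr, vox, bvalues = bvalues)
  meta
}

#' Read the image payload of a manifest record
#'
#' Loads a `voxel_image` from a NIfTI file or a Bruker `2dseq`
#' reconstruction, carrying voxel sizes from the header/parameter files and
#' the b-value table when one accompanies the scan.
#'
#' @param record one row of a manifest's `records` data frame (or any list
#'   with `path` and `source_format`), or a bare path to a NIfTI file.
#' @return A [voxel_image()].
#' @export
read_image <- function(record) {
  if (is.character(record)) record <- list(path = record, source_format = "nifti")
  path <- record$path
  fmt <- record$source_format %||% "nifti"
  if (!file.exists(path)) stop("image payload not found: ", path)

  if (fmt == "bruker") {
    meta <- bruker_metadata(path, read_data = TRUE)
    return(meta$image)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI at ", path,
                                           ": ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) > 4L) {
    dd <- dim(arr)
    if (all(dd[-(1:4)] == 1L)) dim(arr) <- dd[1:4]
    else stop("more than 4 non-singleton dimensions at ", path)
  }
  if (length(dim(arr)) < 3L) stop("image at ", path, " has fewer than 3 dimensions")
  arr[arr < 0] <- 0
  arr[!is.finite(arr)] <- 0
  vox <- abs(RNifti::pixdim(img))[1:3]
  bvalues <- record$bvalues
  if (is.list(bvalues)) bvalues <- bvalues[[1]]
  if (!is.null(bvalues) && length(bvalues) != n_volumes_of(arr)) {
    stop(sprintf(
      "b-value table length (%d) does not match the %d volumes at %s; correct the metadata manually",
      length(bvalues), n_volumes_of(arr), path))
  }
  voxel_image(arr, vox, bvalues = bvalues)
}
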