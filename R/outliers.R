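#' Univariate IQR outlier flags
#'
#' Per feature, quartiles are computed with linear-interpolation quantiles
#' and a scan is flagged when any feature violates its quality polarity:
#' SNR-type features below `Q1 - 1.5*IQR`, motion severity above
#' `Q3 + 1.5*IQR`. The rule is one-sided — an unusually *good* value is
#' never an outlier.
#'
#' @param table data frame of features (rows = scans); feature columns are
#'   numeric, `motion_severity` is treated as "high is bad", all others as
#'   "low is bad". Non-numeric columns are ignored.
#' @return Logical vector, one flag per row. With fewer than 4 usable rows
#'   per feature the flag is `FALSE` for everyone (noted via attribute
#'   `"log"`).
#' @export
iqr_flags <- function(table) {
  feats <- feature_columns(table)
  n <- nrow(table)
  flags <- rep(FALSE, n)
  log <- character()
  for (f in feats) {
    x <- table[[f]]
    ok <- is.finite(x)
    if (sum(ok) < 4L) {
      log <- c(log, sprintf("feature %s: <4 finite values, IQR rule skipped", f))
      next
    }
    q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    # +-Inf sentinels are legitimate violations of the one-sided band
    viol <- if (f == "motion_severity") x > q[2] + 1.5 * iqr else x < q[1] - 1.5 * iqr
    flags <- flags | (!is.na(x) & viol)
  }
  structure(flags, log = log)
}

feature_columns <- function(table) {
  cand <- c("snr_standard_db", "snr_chang_db", "tsnr_db", "motion_severity",
            "ghost")
  intersect(cand, names(table)[vapply(table, is.numeric, logical(1))])
}

# ---- multivariate detectors -----------------------------------------------

# z-score columns; zero-variance columns are dropped (degenerate)
standardize_features <- function(X) {
  sds <- apply(X, 2, stats::sd)
  keep <- which(is.finite(sds) & sds > 0)
  if (!length(keep)) return(NULL)
  scale(X[, keep, drop = FALSE])
}

# Isolation forest (Liu, Ting & Zhou 2008): random axis-parallel splits,
# anomaly score 2^(-E[h(x)]/c(psi)). No CRAN/Bioc implementation is
# pre-installed, so the forest is grown here directly.
iforest_scores <- function(X, ntrees = 100L, sample_size = 256L) {
  n <- nrow(X)
  psi <- min(sample_size, n)
  hlim <- ceiling(log2(psi))
  avg_path <- function(m) {
    if (m <= 1L) return(0)
    2 * (log(m - 1) + 0.5772156649) - 2 * (m - 1) / m
  }
  grow <- function(idx, depth) {
    if (depth >= hlim || length(idx) <= 1L) {
      return(list(leaf = TRUE, size = length(idx)))
    }
    spreads <- apply(X[idx, , drop = FALSE], 2, function(v) diff(range(v)))
    usable <- which(spreads > 0)
    if (!length(usable)) return(list(leaf = TRUE, size = length(idx)))
    q <- if (length(usable) == 1L) usable else sample(usable, 1L)
    rng <- range(X[idx, q])
    p <- stats::runif(1, rng[1], rng[2])
    left <- idx[X[idx, q] < p]
    right <- idx[X[idx, q] >= p]
    if (!length(left) || !length(right)) return(list(leaf = TRUE, size = length(idx)))
    list(leaf = FALSE, q = q, p = p,
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }
  path_len <- function(tree, x, depth = 0L) {
    if (tree$leaf) return(depth + avg_path(tree$size))
    if (x[tree$q] < tree$p) path_len(tree$left, x, depth + 1L)
    else path_len(tree$right, x, depth + 1L)
  }
  depths <- matrix(0, n, ntrees)
  for (t in seq_len(ntrees)) {
    idx <- sample(n, psi, replace = FALSE)
    tree <- grow(idx, 0L)
    depths[, t] <- vapply(seq_len(n), function(i) path_len(tree, X[i, ]),
                          numeric(1))
  }
  2^(-rowMeans(depths) / avg_path(psi))
}

# Local outlier factor (Breunig et al. 2000) with k neighbours.
lof_scores <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  ord <- apply(D, 1, order)                 # n x n, columns are neighbour order
  kdist <- vapply(seq_len(n), function(i) D[i, ord[k, i]], numeric(1))
  neigh <- lapply(seq_len(n), function(i) which(D[i, ] <= kdist[i]))
  lrd <- vapply(seq_len(n), function(i) {
    reach <- pmax(kdist[neigh[[i]]], D[i, neigh[[i]]])
    1 / (mean(reach) + 1e-12)
  }, numeric(1))
  vapply(seq_len(n), function(i) mean(lrd[neigh[[i]]]) / lrd[i], numeric(1))
}

#' Multivariate outlier flags for one detector
#'
#' Runs one of the four multivariate detectors on the z-scored feature
#' matrix of a cohort and returns its per-scan outlier decision. Scores are
#' thresholded at the `(1 - contamination)` quantile of the in-cohort
#' scores, so each method flags roughly a `contamination` fraction of the
#' cohort — its most anomalous scans.
#'
#' @param table feature data frame (rows = scans).
#' @param method `"ocsvm"` (one-class SVM, RBF kernel, `nu`),
#'   `"iforest"` (isolation forest), `"lof"` (local outlier factor,
#'   `k = min(lof_neighbors_max, n-1)`), or `"ee"` (elliptic envelope:
#'   robust MCD covariance + Mahalanobis distance).
#' @param seed integer; the detector is deterministic given seed and input.
#' @param config a [qc_config()].
#' @return Logical vector of flags, one per row. Rows with missing features
#'   and degenerate cohorts (no feature variance, singular covariance) give
#'   `FALSE`, with an explanation in `attr(, "log")`.
#' @export
multivariate_flags <- function(table, method = c("ocsvm", "iforest", "lof", "ee"),
                               seed = 1L, config = qc_config()) {
  method <- match.arg(method)
  config <- as_qc_config(config)
  n <- nrow(table)
  flags <- rep(FALSE, n)
  feats <- feature_columns(table)
  X0 <- as.matrix(table[, feats, drop = FALSE])
  log <- character()
  # +-Inf sentinels (degenerate-but-informative features) are clamped just
  # beyond the finite cohort range so the row stays in detection as an
  # extreme value; rows where a feature failed outright (NA) are imputed
  # with the column median and logged.
  for (j in seq_len(ncol(X0))) {
    x <- X0[, j]
    fin <- x[is.finite(x)]
    if (!length(fin)) next
    pad <- 2 * max(stats::sd(fin), 1e-8)
    if (any(x == -Inf, na.rm = TRUE)) X0[x == -Inf & !is.na(x), j] <- min(fin) - pad
    if (any(x == Inf, na.rm = TRUE)) X0[x == Inf & !is.na(x), j] <- max(fin) + pad
    if (anyNA(x)) {
      log <- c(log, sprintf("%d missing values in %s imputed with the median for %s",
                            sum(is.na(x)), feats[j], method))
      X0[is.na(x), j] <- stats::median(fin)
    }
  }
  complete <- apply(X0, 1, function(r) all(is.finite(r)))
  if (sum(!complete)) {
    log <- c(log, sprintf("%d rows with no usable features excluded from %s",
                          sum(!complete), method))
  }
  if (sum(complete) < 4L) {
    return(structure(flags, log = c(log, sprintf(
      "%s skipped: only %d complete rows", method, sum(complete)))))
  }
  if (sum(complete) < 10L) {
    log <- c(log, sprintf("%s: fewer than 10 rows, decisions may be unstable", method))
  }
  X <- standardize_features(X0[complete, , drop = FALSE])
  if (is.null(X)) {
    return(structure(flags, log = c(log, sprintf(
      "%s skipped: no feature variance in cohort", method))))
  }
  m <- nrow(X)
  # canonical row order: detectors whose fit depends on data order (libsvm
  # working-set selection, subsampled trees) see the same sequence no matter
  # how the cohort rows were supplied, making flags permutation-equivariant
  ord <- do.call(order, as.data.frame(X))
  X <- X[ord, , drop = FALSE]
  res <- tryCatch({
    set.seed(seed)
    if (method == "ocsvm") {
      # the one-class SVM carries its own decision boundary (nu bounds the
      # outlier fraction); margin points count as inliers
      fit <- e1071::svm(X, type = "one-classification",
                        kernel = "radial", nu = config$ocsvm_nu,
                        scale = FALSE)
      dv <- as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                            "decision.values"))
      dv < 0
    } else {
      scores <- switch(method,
        iforest = iforest_scores(X, ntrees = config$iforest_trees,
                                 sample_size = config$iforest_sample),
        lof = lof_scores(X, k = min(config$lof_neighbors_max, m - 1L)),
        ee = {
          rob <- MASS::cov.rob(X, method = "mcd")
          stats::mahalanobis(X, rob$center, rob$cov)
        })
      # score-based detectors flag the top `contamination` fraction
      thr <- stats::quantile(scores, 1 - config$contamination, type = 7,
                             names = FALSE)
      scores > thr
    }
  }, error = function(e) e)
  if (inherits(res, "error")) {
    return(structure(flags, log = c(log, sprintf(
      "%s failed (%s): all flags false", method, conditionMessage(res)))))
  }
  res[ord] <- res                      # undo the canonical ordering
  flags[complete] <- res
  structure(flags, log = log)
}

#' Majority vote over the five detector flags
#'
#' @param flags named logical vector (or list) with entries `iqr`, `ocsvm`,
#'   `iforest`, `lof`, `ee`.
#' @return Integer 0-5: the count of detectors that flagged the scan.
#' @export
majority_vote <- function(flags) {
  flags <- unlist(flags)
  need <- c("iqr", "ocsvm", "iforest", "lof", "ee")
  if (!setequal(names(flags), need)) {
    stop("flags must be exactly the five named detectors: ",
         paste(need, collapse = ", "))
  }
  as.integer(sum(flags[need]))
}

#' Run the full outlier-detection stage
#'
#' Applies the five detectors (IQR, one-class SVM, isolation forest, local
#' outlier factor, elliptic envelope) to each sequence class's feature
#' table and aggregates them into a 0-5 majority vote per scan; scans at or
#' above the review threshold are marked. In `"collective"` mode the tables
#' of the same class from multiple datasets are pooled before detection.
#'
#' @param tables a single feature data frame, or a named list of them (one
#'   per sequence class; in collective mode each entry may itself be a list
#'   of per-dataset tables that get pooled).
#' @param mode `"per_dataset"` or `"collective"`.
#' @param threshold review threshold on the vote, 1-5 (default from config).
#' @param seed integer seed forwarded to the stochastic detectors.
#' @param config a [qc_config()].
#' @return A data frame with one row per scan: the five 0/1 detector
#'   columns, `majority_vote`, and logical `flagged`; identifying columns of
#'   the input tables are carried through. Attribute `"log"` collects
#'   detector notes.
#' @export
run_outlier_stage <- function(tables, mode = c("per_dataset", "collective"),
                              threshold = NULL, seed = 1L,
                              config = qc_config()) {
  mode <- match.arg(mode)
  config <- as_qc_config(config)
  threshold <- as.integer(threshold %||% config$vote_threshold)
  if (threshold < 1L || threshold > 5L) stop("threshold must be in 1..5")
  if (is.data.frame(tables)) tables <- list(all = tables)

  out <- list()
  log <- character()
  for (cls in names(tables)) {
    tab <- tables[[cls]]
    if (is.list(tab) && !is.data.frame(tab)) {   # collective pooling
      tab <- do.call(rbind, tab)
    }
    if (is.null(tab) || !nrow(tab)) {
      log <- c(log, sprintf("class %s: empty feature table, skipped", cls))
      next
    }
    fl_iqr <- iqr_flags(tab)
    methods <- c("ocsvm", "iforest", "lof", "ee")
    fl_multi <- lapply(seq_along(methods), function(i)
      multivariate_flags(tab, methods[i], seed = seed + i, config = config))
    names(fl_multi) <- methods
    log <- c(log, attr(fl_iqr, "log"),
             unlist(lapply(fl_multi, attr, "log")))

    votes <- tab
    votes$iqr <- as.integer(fl_iqr)
    for (mth in methods) votes[[mth]] <- as.integer(fl_multi[[mth]])
    votes$majority_vote <- votes$iqr + votes$ocsvm + votes$iforest +
      votes$lof + votes$ee
    votes$flagged <- votes$majority_vote >= threshold
    votes$sequence_class <- votes$sequence_class %||% cls
    out[[cls]] <- votes
  }
  if (!length(out)) {
    return(structure(data.frame(), log = log, threshold = threshold))
  }
  common <- Reduce(intersect, lapply(out, names))
  res <- do.call(rbind, lapply(out, function(v) v[, common, drop = FALSE]))
  rownames(res) <- NULL
  structure(res, log = unique(log), threshold = threshold)
}
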