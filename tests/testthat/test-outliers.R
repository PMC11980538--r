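test_that("IQR flags violate only in the bad-quality direction", {
  tab <- data.frame(snr_standard_db = c(30, 31, 32, 33, 34, 10))
  expect_equal(which(iqr_flags(tab)), 6L)
  # identical values: degenerate band, nobody flagged
  expect_false(any(iqr_flags(data.frame(snr_standard_db = rep(30, 6)))))
  # unusually HIGH SNR is good, not an outlier
  expect_false(any(iqr_flags(data.frame(snr_standard_db = c(30, 31, 32, 33, 60)))))
  # high motion severity IS an outlier
  expect_equal(which(iqr_flags(data.frame(motion_severity = c(0.01, 0.012, 0.011,
                                                              0.013, 0.3)))), 5L)
  # -Inf sentinel counts as a low-SNR violation
  expect_true(iqr_flags(data.frame(snr_standard_db = c(30, 31, 32, 33, -Inf)))[5])
})

test_that("IQR flags agree with a brute-force quantile oracle", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 30, sample(c(0.5, 2, 8), 1))
    got <- iqr_flags(data.frame(snr_standard_db = x))
    q1 <- brute_quantile(x, 0.25); q3 <- brute_quantile(x, 0.75)
    expect_identical(as.logical(got), x < q1 - 1.5 * (q3 - q1))
    got_m <- iqr_flags(data.frame(motion_severity = x))
    expect_identical(as.logical(got_m), x > q3 + 1.5 * (q3 - q1))
  }
})

test_that("majority vote equals the flag sum over all 32 combinations", {
  for (code in 0:31) {
    fl <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L, 16L)) > 0)
    names(fl) <- c("iqr", "ocsvm", "iforest", "lof", "ee")
    expect_identical(majority_vote(fl), as.integer(sum(fl)))
  }
  expect_error(majority_vote(c(iqr = TRUE)), "five")
})

test_that("each multivariate detector isolates a planted far outlier", {
  set.seed(1)
  tab <- data.frame(snr_standard_db = c(rnorm(30, 30, 1), 30 - 10),
                    snr_chang_db = c(rnorm(30, 28, 1), 28 - 10))
  for (m in c("ocsvm", "iforest", "lof", "ee")) {
    fl <- multivariate_flags(tab, m, seed = 7)
    expect_true(fl[31], label = paste(m, "flags the planted outlier"))
  }
})

test_that("multivariate detectors are deterministic and permutation-equivariant", {
  set.seed(2)
  tab <- data.frame(snr_standard_db = rnorm(25, 30, 2),
                    snr_chang_db = rnorm(25, 28, 2))
  perm <- sample(25)
  for (m in c("ocsvm", "iforest", "lof", "ee")) {
    a <- multivariate_flags(tab, m, seed = 3)
    b <- multivariate_flags(tab, m, seed = 3)
    expect_identical(as.logical(a), as.logical(b))
    p <- multivariate_flags(tab[perm, , drop = FALSE], m, seed = 3)
    expect_identical(as.logical(p), as.logical(a)[perm],
                     label = paste(m, "permutation equivariance"))
  }
})

test_that("degenerate feature tables never crash the detectors", {
  same <- data.frame(snr_standard_db = rep(30, 12), snr_chang_db = rep(28, 12))
  for (m in c("ocsvm", "iforest", "lof", "ee")) {
    fl <- multivariate_flags(same, m, seed = 1)
    expect_false(any(fl), label = paste(m, "on identical rows"))
    expect_true(length(attr(fl, "log")) >= 1)
  }
  tiny <- data.frame(snr_standard_db = c(1, 2))
  expect_false(any(multivariate_flags(tiny, "lof", seed = 1)))
})

test_that("the outlier stage votes, thresholds and pools deterministically", {
  set.seed(3)
  tab <- data.frame(path = sprintf("scan%02d", 1:31),
                    sequence_class = "anatomical",
                    snr_standard_db = c(rnorm(30, 30, 0.5), 12),
                    snr_chang_db = c(rnorm(30, 28, 0.5), 10))
  v <- run_outlier_stage(list(anatomical = tab), seed = 5)
  expect_equal(v$majority_vote, v$iqr + v$ocsvm + v$iforest + v$lof + v$ee)
  expect_equal(which.max(v$majority_vote), 31L)
  expect_gte(v$majority_vote[31], 3)
  expect_true(v$flagged[31])
  # vote below a stricter threshold empties the review list
  v5 <- run_outlier_stage(list(anatomical = tab), threshold = 5, seed = 5)
  expect_identical(v5$flagged, v5$majority_vote >= 5)
  # per-dataset and collective agree on a single dataset
  vc <- run_outlier_stage(list(anatomical = list(tab)), mode = "collective",
                          seed = 5)
  expect_equal(vc$majority_vote, v$majority_vote)
  # determinism end to end
  v2 <- run_outlier_stage(list(anatomical = tab), seed = 5)
  expect_identical(v$majority_vote, v2$majority_vote)
  # empty class table is skipped with a log entry, not an error
  ve <- run_outlier_stage(list(anatomical = tab, functional = data.frame()),
                          seed = 5)
  expect_true(any(grepl("empty", attr(ve, "log"))))
})
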