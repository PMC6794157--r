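test_that("well delta-Cq is a plain difference", {
  expect_equal(well_delta_cq(25, 25), 0)
  expect_equal(well_delta_cq(26, 25), 1)
  expect_equal(well_delta_cq(24, 25), -1)
})

test_that("replicate aggregation is a dropout-aware median", {
  expect_equal(aggregate_replicates(c(1, 1, 1, 1)),
               list(delta_cq = 1, n_used = 4L, dispersion = 0))
  r <- aggregate_replicates(c(0.9, 1.0, 1.1, 9.0))
  expect_equal(r$delta_cq, 1.05)
  expect_equal(r$n_used, 4L)
  expect_lt(r$dispersion, 0.2)
  expect_true(is.na(aggregate_replicates(rep(NA_real_, 4))$delta_cq))
  # half dropout already counts as dropout
  expect_true(is.na(aggregate_replicates(c(1, 1, NA, NA))$delta_cq))
  expect_false(is.na(aggregate_replicates(c(1, 1, 1, NA))$delta_cq))
  expect_error(aggregate_replicates(numeric(0)),
               class = "qkatr_validation_error")
})

test_that("calibration anchors behave in both modes", {
  a <- calibrate(mode = "calibrator_sample", calibrator_delta_cq = 0.7,
                 calibrator_cn = 2)
  expect_equal(a, list(delta_cq0 = 0.7, cn0 = 2))
  expect_error(calibrate(mode = "calibrator_sample",
                         calibrator_delta_cq = NA, calibrator_cn = 2),
               class = "qkatr_calibration_error")
  expect_error(calibrate(c(1, 2, 3), mode = "most_frequent_cn",
                         default_cn = 2),
               class = "qkatr_calibration_error") # too few samples
  # modal class wins even at 45/55 imbalance straddling the median
  set.seed(7)
  x <- c(rnorm(45, 1, 0.05), rnorm(55, 0, 0.05))
  b <- calibrate(x, mode = "most_frequent_cn", default_cn = 2)
  expect_equal(b$delta_cq0, 0, tolerance = 0.05)
  expect_equal(b$cn0, 2)
})

test_that("delta-delta-Cq calls follow the doubling rule and tie-break", {
  r <- call_copy_number(0.5, 0.5, 2)
  expect_equal(r$cn_estimate, 2)
  expect_equal(r$cn_called, 2L)
  expect_equal(r$confidence, 1)
  expect_equal(call_copy_number(-0.5, 0.5, 2)$cn_estimate, 4)
  expect_equal(call_copy_number(-0.5, 0.5, 2)$cn_called, 4L)
  # estimate 0.5 ties away from zero: one copy, low confidence
  r2 <- call_copy_number(1, 0, 1)
  expect_equal(r2$cn_estimate, 0.5)
  expect_equal(r2$cn_called, 1L)
  expect_equal(r2$confidence, 0, tolerance = 1e-12)
  # dropout is a qualitative zero
  r3 <- call_copy_number(NA, 0, 2)
  expect_equal(r3$cn_called, 0L)
  expect_equal(r3$cn_estimate, 0)
})

test_that("cn_estimate is strictly decreasing in sample delta-Cq", {
  dcqs <- seq(-2, 2, by = 0.25)
  ests <- vapply(dcqs, function(d) call_copy_number(d, 0, 2)$cn_estimate,
                 numeric(1))
  expect_true(all(diff(ests) < 0))
})

test_that("noise-free cohorts are called exactly in both modes, with drift", {
  res <- called_cohort(40, seed = 31, cq_noise_sd = 0, drift_sd = 0.8,
                       fixed_pairs = list(CAL = c("A_2DS4del", "A_2DS4del")))
  expect_equal(profile_matrix(res$profiles),
               truth_matrix(res$truth, res$profiles$sample_id),
               ignore_attr = TRUE)
  res2 <- called_cohort(40, seed = 31, cq_noise_sd = 0, drift_sd = 0.8,
                        mode = "calibrator_sample",
                        fixed_pairs = list(CAL = c("A_2DS4del", "A_2DS4del")),
                        calibrator_sample = "CAL")
  expect_equal(profile_matrix(res2$profiles),
               truth_matrix(res2$truth, res2$profiles$sample_id),
               ignore_attr = TRUE)
  # the two calibration paths agree call-for-call
  expect_equal(res$calls$cn_called, res2$calls$cn_called)
})

test_that("reference failure invalidates wells instead of calling zero", {
  res <- called_cohort(24, seed = 41, cq_noise_sd = 0)
  cq <- res$cq
  # knock out STAT6 in all four wells of one sample on reaction 1
  sid <- cq$sample_id[1]
  hit <- cq$locus == "STAT6" & cq$sample_id == sid & cq$reaction_number == 1
  cq$cq[hit] <- NA
  calls <- call_copy_numbers(cq, .panel)
  bad <- calls[calls$sample_id == sid &
                 calls$locus %in% c("3DP1", "2DL2"), ]
  expect_true(all(grepl("ref_failure", bad$flags)))
  expect_equal(bad$n_replicates_used, c(0L, 0L))
})

test_that("profiles flag missing reactions, conflicts and concordant duplicates", {
  res <- called_cohort(24, seed = 51, cq_noise_sd = 0)
  calls <- res$calls
  sid <- calls$sample_id[1]

  # sample missing reaction 5 -> 3DS1 and 2DL4 flagged missing
  drop5 <- calls[!(calls$sample_id == sid & calls$reaction_number == 5), ]
  prof <- build_profiles(drop5, .panel)
  row <- prof[prof$sample_id == sid, ]
  expect_true(is.na(row[["3DS1"]]) && is.na(row[["2DL4"]]))
  expect_match(row$flags, "3DS1=missing")
  expect_match(row$flags, "2DL4=missing")

  # concordant duplicate plates collapse to one clean call
  dup <- dplyr::bind_rows(calls, dplyr::mutate(calls, plate_id = "other"))
  prof2 <- build_profiles(dup, .panel)
  expect_equal(profile_matrix(prof2),
               truth_matrix(res$truth, prof2$sample_id), ignore_attr = TRUE)

  # discordant duplicates become conflicts, not silent overwrites
  disc <- calls[calls$sample_id == sid & calls$locus == "3DL3", ]
  disc$plate_id <- "other"
  disc$cn_called <- disc$cn_called + 1L
  prof3 <- build_profiles(dplyr::bind_rows(calls, disc), .panel)
  row3 <- prof3[prof3$sample_id == sid, ]
  expect_true(is.na(row3[["3DL3"]]))
  expect_match(row3$flags, "3DL3=.*conflict")
})

test_that("copy numbers above the cap are flagged implausible", {
  r <- call_copy_number(-3, 0, 2) # estimate 16
  expect_equal(r$cn_called, 16L)
  cq <- tibble::tibble(
    plate_id = "R01-P01", reaction_number = 1,
    well = rep(c("A1", "A2", "B1", "B2"), each = 3, times = 6),
    source_well = "A1",
    sample_id = rep(sprintf("S%02d", 1:6), each = 12),
    replicate = rep(rep(1:4, each = 3), times = 6),
    channel = rep(c("465-510", "618-660", "533-580"), 24),
    locus = rep(c("3DP1", "2DL2", "STAT6"), 24),
    cq = rep(c(27, 27, 24), 24))
  cq$well <- paste0(cq$well, rep(1:6, each = 12)) # make wells unique
  cq$cq[cq$sample_id == "S01" & cq$locus == "2DL2"] <- 22 # ~2^5 copies
  calls <- call_copy_numbers(cq, .panel, min_samples = 5)
  odd <- calls[calls$sample_id == "S01" & calls$locus == "2DL2", ]
  expect_true(is.na(odd$cn_called))
  expect_match(odd$flags, "implausible_cn")
})
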