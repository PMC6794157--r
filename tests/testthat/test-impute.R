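profiles_from <- function(mats, ids = names(mats)) {
  dplyr::bind_cols(tibble::tibble(sample_id = ids),
                   tibble::as_tibble(do.call(rbind, unname(mats))))
}

test_that("enumeration agrees with an independent brute-force oracle", {
  # random profiles: a mix of true pair sums and perturbed (often invalid)
  set.seed(42)
  m <- as.matrix(.haps[, .loci])
  cases <- lapply(1:100, function(i) {
    p <- m[sample(nrow(m), 1), ] + m[sample(nrow(m), 1), ]
    if (i %% 3 == 0) {
      l <- sample(length(p), 1)
      p[l] <- max(0, p[l] + sample(c(-1, 1), 1))
    }
    p
  })
  prof <- profiles_from(cases, sprintf("P%03d", 1:100))
  got <- impute_all_pairs(prof, .haps)
  for (i in 1:100) {
    want <- oracle_enumerate_pairs(prof[i, ], .haps)
    rows <- got[got$sample_id == prof$sample_id[i], ]
    if (length(want) == 0) {
      expect_equal(rows$status, "unassigned")
    } else {
      expect_setequal(pair_key(rows$hap1, rows$hap2),
                      vapply(want, function(w) pair_key(w$hap1, w$hap2),
                             character(1)))
      wf <- setNames(vapply(want, `[[`, numeric(1), "freq"),
                     vapply(want, function(w) pair_key(w$hap1, w$hap2),
                            character(1)))
      expect_equal(unname(wf[pair_key(rows$hap1, rows$hap2)]),
                   unname(rows$combined_frequency))
    }
  }
})

test_that("an A/A profile imputes uniquely; impossible profiles do not", {
  m <- as.matrix(.haps[, .loci])
  rownames(m) <- .haps$haplotype
  aa <- profiles_from(list(s = m["A_2DS4del", ] + m["A_2DS4del", ]), "s")
  got <- impute_all_pairs(aa, .haps)
  expect_equal(nrow(got), 1)
  expect_equal(got$hap1, "A_2DS4del")
  expect_equal(got$hap2, "A_2DS4del")
  expect_equal(got$combined_frequency,
               .haps$frequency[.haps$haplotype == "A_2DS4del"]^2)

  # an odd framework count can never be a pair sum
  odd <- aa
  odd[["2DL4"]] <- 1
  expect_equal(impute_all_pairs(odd, .haps)$status, "unassigned")

  # empty reference table assigns nothing
  expect_equal(impute_all_pairs(aa, .haps[0, ])$status, "unassigned")
})

test_that("heterozygous pairs carry the Hardy-Weinberg factor two", {
  m <- as.matrix(.haps[, .loci])
  rownames(m) <- .haps$haplotype
  het <- profiles_from(list(s = m["A_2DS4del", ] + m["B_cA01_tB01", ]), "s")
  got <- impute_all_pairs(het, .haps)
  f <- .haps$frequency
  names(f) <- .haps$haplotype
  expect_true(pair_key("A_2DS4del", "B_cA01_tB01") %in%
                pair_key(got$hap1, got$hap2))
  i <- which(pair_key(got$hap1, got$hap2) ==
               pair_key("A_2DS4del", "B_cA01_tB01"))
  expect_equal(got$combined_frequency[i],
               2 * f[["A_2DS4del"]] * f[["B_cA01_tB01"]])
})

test_that("trim_best keeps exactly the argmax set", {
  x <- tibble::tibble(sample_id = c("a", "a", "b", "b", "c", "d"),
                      hap1 = "h", hap2 = "h",
                      combined_frequency = c(0.04, 0.01, 0.02, 0.02, 0.5, NA),
                      status = c(rep("assigned", 5), "unassigned"))
  expect_warning(out <- trim_best(x), "unassigned")
  expect_equal(out$combined_frequency[out$sample_id == "a"], 0.04)
  expect_equal(nrow(out[out$sample_id == "b", ]), 2) # exact tie kept
  expect_equal(out$status[out$sample_id == "c"], "trimmed_best")
  expect_equal(out$status[out$sample_id == "d"], "unassigned")
})

test_that("imputation is invariant to locus column order", {
  set.seed(9)
  truth <- simulate_cohort(15, .haps, seed = 61)
  prof <- truth[, c("sample_id", .loci)]
  got <- impute_all_pairs(prof, .haps)
  shuffled <- prof[, c("sample_id", sample(.loci))]
  got2 <- impute_all_pairs(shuffled, .haps)
  expect_equal(as.data.frame(got), as.data.frame(got2))
})

test_that("noise-free cohorts always contain the true pair; best pairs track the Bayes rate", {
  res <- called_cohort(192, seed = 71, cq_noise_sd = 0)
  truth <- res$truth
  got <- impute_all_pairs(res$profiles, .haps)
  best <- suppressWarnings(trim_best(got))
  hit_all <- hit_best <- logical(nrow(truth))
  bayes <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    key <- pair_key(truth$hap1[i], truth$hap2[i])
    rows <- got[got$sample_id == truth$sample_id[i], ]
    hit_all[i] <- key %in% pair_key(rows$hap1, rows$hap2)
    b <- best[best$sample_id == truth$sample_id[i], ]
    hit_best[i] <- key %in% pair_key(b$hap1, b$hap2)
    # oracle posterior mass of the trimmed set, given the profile
    bayes[i] <- sum(b$combined_frequency) / sum(rows$combined_frequency)
  }
  expect_true(all(hit_all))
  rate <- mean(bayes)
  se <- sqrt(rate * (1 - rate) / length(bayes))
  expect_gte(mean(hit_best), rate - 3 * se)
})

test_that("the three output files are written with the documented content", {
  dir <- withr::local_tempdir()
  m <- as.matrix(.haps[, .loci])
  rownames(m) <- .haps$haplotype
  prof <- profiles_from(list(
    ok = m["A_2DS4del", ] + m["B_cB01_tA01", ],
    odd = m["A_2DS4del", ] + m["A_2DS4del", ]), c("ok", "odd"))
  prof[["3DL3"]][2] <- 3 # make sample "odd" unassignable
  got <- impute_all_pairs(prof, .haps)
  paths <- write_imputation_outputs(got, dir, prefix = "hap")
  expect_true(all(file.exists(paths)))
  all_f <- readr::read_csv(paths[["all"]], show_col_types = FALSE)
  una <- readr::read_csv(paths[["unassigned"]], show_col_types = FALSE)
  best <- readr::read_csv(paths[["best"]], show_col_types = FALSE)
  expect_equal(unique(all_f$sample_id), "ok")
  expect_equal(una$sample_id, "odd")
  expect_gte(nrow(best), 1)
  expect_true(all(best$sample_id == "ok"))

  # fully assignable cohort: unassigned file empty but present
  got2 <- impute_all_pairs(prof[1, ], .haps)
  paths2 <- write_imputation_outputs(got2, dir, prefix = "hap2")
  una2 <- readr::read_csv(paths2[["unassigned"]], show_col_types = FALSE)
  expect_equal(nrow(una2), 0)
})
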