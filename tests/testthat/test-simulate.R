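test_that("cohort truth is the per-locus sum of the sampled pair", {
  truth <- simulate_cohort(30, .haps, seed = 5)
  m <- as.matrix(.haps[, .loci])
  rownames(m) <- .haps$haplotype
  for (i in seq_len(nrow(truth))) {
    expect_equal(unlist(truth[i, .loci]),
                 (m[truth$hap1[i], ] + m[truth$hap2[i], ]),
                 ignore_attr = TRUE)
  }
  expect_true(all(truth$hap1 <= truth$hap2)) # unordered, stored sorted
})

test_that("a degenerate one-haplotype table yields only self-pairs", {
  one <- .haps[.haps$haplotype == "A_2DS4del", ]
  one$frequency <- 1
  truth <- simulate_cohort(10, one, seed = 1)
  expect_true(all(truth$hap1 == "A_2DS4del" & truth$hap2 == "A_2DS4del"))
})

test_that("simulation is deterministic under a fixed seed", {
  t1 <- simulate_cohort(20, .haps, seed = 9)
  t2 <- simulate_cohort(20, .haps, seed = 9)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  c1 <- synthesize_cq(t1, .panel, seed = 3)
  c2 <- synthesize_cq(t2, .panel, seed = 3)
  expect_equal(as.data.frame(c1), as.data.frame(c2))
  c3 <- synthesize_cq(t1, .panel, seed = 4)
  expect_false(isTRUE(all.equal(c1$cq, c3$cq)))
})

test_that("every simulated profile satisfies the LD rules by construction", {
  truth <- simulate_cohort(60, .haps, seed = 21)
  rep <- check_ld(truth)
  expect_true(all(attr(rep, "conformity")$conforms))
})

test_that("fixed pairs are honoured and validated", {
  truth <- simulate_cohort(5, .haps, seed = 2,
                           fixed_pairs = list(CTRL = c("A_2DS4del",
                                                       "B_cA01_tB01")))
  ctrl <- truth[truth$sample_id == "CTRL", ]
  expect_equal(nrow(truth), 6)
  expect_equal(ctrl$hap1, "A_2DS4del")
  expect_equal(unname(unlist(ctrl[, "2DS5"])), 1)
  expect_error(simulate_cohort(2, .haps, seed = 1,
                               fixed_pairs = list(X = c("nope", "nope"))),
               class = "qkatr_config_error")
})

test_that("Cq synthesis encodes copy number as log2 shifts with dropout at zero", {
  truth <- simulate_cohort(0, .haps,
                           fixed_pairs = list(
                             AA = c("A_2DS4del", "A_2DS4del"),
                             BB = c("B_cB01_tB01", "B_cB01_tB01")))
  cq <- synthesize_cq(truth, .panel, cq_noise_sd = 0, drift_sd = 0, seed = 1)
  # k = 0: all four replicate wells dropout (AA has no 3DS1)
  dss <- cq[cq$sample_id == "AA" & cq$locus == "3DS1", ]
  expect_equal(nrow(dss), 4)
  expect_true(all(is.na(dss$cq)))
  # one- vs two-copy targets differ by exactly one cycle
  one_copy <- cq$cq[cq$sample_id == "BB" & cq$locus == "2DS3"][1] # CN 2
  framework <- cq$cq[cq$sample_id == "BB" & cq$locus == "3DL3"][1] # CN 2
  expect_equal(one_copy, framework) # same CN, same baseline
  dl5 <- cq$cq[cq$sample_id == "BB" & cq$locus == "2DL5"][1] # CN 4
  expect_equal(framework - dl5, 1) # doubling -> one cycle earlier
  # STAT6 present in every well
  wells <- unique(cq[, c("plate_id", "well")])
  stat6 <- cq[cq$locus == "STAT6", c("plate_id", "well")]
  expect_equal(nrow(dplyr::anti_join(wells, stat6,
                                     by = c("plate_id", "well"))), 0)
})

test_that("shared-drift wells move together; delta-Cq is drift-invariant", {
  truth <- simulate_cohort(6, .haps, seed = 3)
  cq <- synthesize_cq(truth, .panel, cq_noise_sd = 0, drift_sd = 1.5,
                      seed = 4)
  ref <- cq[cq$locus == "STAT6", c("plate_id", "well", "cq")]
  names(ref)[3] <- "stat6"
  kir <- merge(cq[cq$locus != "STAT6" & !is.na(cq$cq), ], ref)
  dcq <- kir$cq - kir$stat6
  truth_m <- truth_matrix(truth, truth$sample_id)
  k <- truth_m[cbind(match(kir$sample_id, truth$sample_id),
                     match(kir$locus, colnames(truth_m)))]
  # delta-Cq equals the noise-free closed form exactly: drift cancels
  expect_equal(dcq, (28 - log2(k)) - 24, tolerance = 1e-9)
})

test_that("the quadruplicate layout maps 96 sources to a 384-well bijection", {
  truth <- simulate_cohort(96, .haps, seed = 7)
  cq <- synthesize_cq(truth, .panel, seed = 8)
  p1 <- cq[cq$plate_id == "R01-P01", ]
  blocks <- split(p1$well, p1$source_well)
  expect_equal(length(blocks), 96)
  for (b in blocks) expect_equal(length(unique(b)), 4)
  expect_equal(sort(unique(p1$well)),
               sort(paste0(rep(LETTERS[1:16], each = 24), 1:24)))
})

test_that("synthesized curves recover their target Cq under both methods", {
  truth <- simulate_cohort(1, .haps, seed = 12)
  cq <- synthesize_cq(truth, .panel, cq_noise_sd = 0, drift_sd = 0, seed = 13)
  sub <- utils::head(cq[!is.na(cq$cq), ], 6)
  cur <- synthesize_curves(sub, k = 0.8)
  res <- call_cq(cur)
  m <- match(paste(sub$well, sub$channel), paste(res$well, res$channel))
  expect_true(all(abs(res$cq[m] - sub$cq) < 0.05))

  curf <- synthesize_curves(sub, method = "fit_points", noise_band = 1)
  resf <- call_cq(curf, method = "fit_points", noise_band = 1)
  m <- match(paste(sub$well, sub$channel), paste(resf$well, resf$channel))
  expect_true(all(abs(resf$cq[m] - sub$cq) < 0.01))

  # dropout wells yield flat curves and no Cq
  drop <- utils::head(cq[is.na(cq$cq), ], 2)
  curd <- synthesize_curves(drop, noise_sd = 0.005, seed = 14)
  resd <- call_cq(curd)
  expect_true(all(is.na(resd$cq)))
})
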