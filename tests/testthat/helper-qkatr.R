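# Shared fixtures and independent oracles, built in code at test time.

.panel <- load_assay_panel()
.haps <- builtin_reference_haplotypes()
.loci <- kir_loci()

# truth/profile matrices aligned on sample id, for accuracy comparisons
truth_matrix <- function(truth, ids) {
  as.matrix(as.data.frame(truth)[match(ids, truth$sample_id), .loci])
}
profile_matrix <- function(profiles) {
  as.matrix(as.data.frame(profiles)[, .loci])
}

# noise-free cohort plus its called profiles in one go
called_cohort <- function(n, seed, cq_noise_sd = 0, drift_sd = 0,
                          mode = "most_frequent_cn", fixed_pairs = NULL,
                          calibrator_sample = NULL, sim_seed_offset = 1000L) {
  truth <- simulate_cohort(n, .haps, seed = seed, fixed_pairs = fixed_pairs)
  cq <- synthesize_cq(truth, .panel, cq_noise_sd = cq_noise_sd,
                      drift_sd = drift_sd, seed = seed + sim_seed_offset)
  cal_cn <- if (!is.null(calibrator_sample)) {
    truth[truth$sample_id == calibrator_sample, ]
  } else NULL
  calls <- call_copy_numbers(cq, .panel, calibration = mode,
                             calibrator_sample = calibrator_sample,
                             calibrator_cn = cal_cn,
                             min_samples = min(5, max(3, n %/% 8)))
  profiles <- build_profiles(calls, .panel)
  list(truth = truth, cq = cq, calls = calls, profiles = profiles)
}

# all distinct profiles reachable as sums of two built-in haplotypes
builtin_pair_profiles <- function() {
  m <- as.matrix(.haps[, .loci])
  rownames(m) <- .haps$haplotype
  n <- nrow(m)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      out[[paste(rownames(m)[i], rownames(m)[j], sep = "/")]] <- m[i, ] + m[j, ]
    }
  }
  out
}

# Independent brute-force pair enumerator: deliberately written as a plain
# double loop with element-wise comparison, unlike the vectorised
# implementation it checks.
oracle_enumerate_pairs <- function(profile, haplotypes) {
  hits <- list()
  for (i in seq_len(nrow(haplotypes))) {
    for (j in i:nrow(haplotypes)) {
      ok <- TRUE
      for (l in kir_loci()) {
        s <- haplotypes[[l]][i] + haplotypes[[l]][j]
        if (is.na(profile[[l]]) || s != profile[[l]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        h1 <- haplotypes$haplotype[i]
        h2 <- haplotypes$haplotype[j]
        f <- haplotypes$frequency[i] * haplotypes$frequency[j] *
          (if (i == j) 1 else 2)
        hits[[length(hits) + 1]] <- list(hap1 = min(h1, h2),
                                         hap2 = max(h1, h2), freq = f)
      }
    }
  }
  hits
}

# canonical string form of a pair set, for set comparisons
pair_key <- function(h1, h2) paste(pmin(h1, h2), pmax(h1, h2), sep = "|")
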