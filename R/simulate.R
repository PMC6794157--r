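# Synthetic qPCR cohorts: haplotype-pair sampling, plate layout, per-well Cq
# values and (optionally) amplification curves. The generative model is the
# inverse of the delta-delta-Cq quantification: a well with k template copies
# amplifies log2(k) cycles earlier than a one-copy well.

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate cohort ground truth by Hardy-Weinberg haplotype pairing
#'
#' Draws two haplotypes independently per sample with probability
#' proportional to the reference frequencies (random mating, no inbreeding),
#' and derives each sample's true copy-number profile as the per-locus sum of
#' the pair's gene content.
#'
#' @param n_samples Number of samples (>= 1).
#' @param haplotypes Reference table, e.g. [builtin_reference_haplotypes()].
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @param fixed_pairs Optional named list `sample_id = c(hap1, hap2)` of
#'   samples whose pair is fixed rather than drawn — e.g. a control sample of
#'   known copy number placed on every plate. These are appended after the
#'   `n_samples` random samples.
#' @return A `kir_truth` tibble: `sample_id`, `hap1`, `hap2` (unordered,
#'   stored sorted) and one truth column per locus.
#' @export
#' @examples
#' truth <- simulate_cohort(8, seed = 1)
#' truth
simulate_cohort <- function(n_samples, haplotypes = builtin_reference_haplotypes(),
                            seed = NULL, fixed_pairs = NULL) {
  validate_haplotype_table(haplotypes)
  if (n_samples < 0 || (n_samples == 0 && is.null(fixed_pairs))) {
    abort("n_samples must be >= 1 (or fixed_pairs supplied)",
          class = "qkatr_config_error")
  }
  f <- haplotypes$frequency / sum(haplotypes$frequency)
  draws <- with_seed(seed, {
    if (n_samples > 0) {
      matrix(sample(haplotypes$haplotype, 2 * n_samples, replace = TRUE,
                    prob = f), ncol = 2)
    } else {
      matrix(character(0), ncol = 2)
    }
  })
  ids <- if (n_samples > 0) sprintf("S%03d", seq_len(n_samples)) else character(0)
  h1 <- draws[, 1]; h2 <- draws[, 2]
  if (!is.null(fixed_pairs)) {
    bad <- setdiff(unlist(fixed_pairs), haplotypes$haplotype)
    if (length(bad) > 0) {
      abort(paste0("fixed_pairs references unknown haplotype: ", bad[1]),
            class = "qkatr_config_error")
    }
    ids <- c(ids, names(fixed_pairs))
    h1 <- c(h1, unname(vapply(fixed_pairs, `[`, character(1), 1)))
    h2 <- c(h2, unname(vapply(fixed_pairs, `[`, character(1), 2)))
  }
  # store pairs unordered
  lo <- pmin(h1, h2); hi <- pmax(h1, h2)
  m <- as.matrix(haplotypes[, kir_loci()])
  rownames(m) <- haplotypes$haplotype
  prof <- m[lo, , drop = FALSE] + m[hi, , drop = FALSE]
  out <- tibble(sample_id = ids, hap1 = lo, hap2 = hi) %>%
    dplyr::bind_cols(as_tibble(prof))
  structure(out, class = c("kir_truth", class(out)))
}

# 96-well source position (1..96, row-major A1..H12) for the i-th sample of
# a plate set
well96_name <- function(pos) {
  r <- (pos - 1) %/% 12 + 1
  c <- (pos - 1) %% 12 + 1
  paste0(LETTERS[r], c)
}

# 2x2 block of 384-well positions fed from one 96-well source position;
# replicate order: top-left, top-right, bottom-left, bottom-right
well384_block <- function(pos) {
  r <- (pos - 1) %/% 12 + 1
  c <- (pos - 1) %% 12 + 1
  rows <- c(2 * r - 1, 2 * r - 1, 2 * r, 2 * r)
  cols <- c(2 * c - 1, 2 * c, 2 * c - 1, 2 * c)
  paste0(LETTERS[rows], cols)
}

#' Synthesize per-well Cq values for a cohort
#'
#' Emulates the wet-lab design: each sample is dispensed in quadruplicate
#' onto one 384-well plate per reaction (a 2x2 block per 96-well source
#' position), and each well reports three channels — the two KIR targets and
#' STAT6. A well with `k` copies of a KIR locus has
#' `Cq = kir_baseline_cq - log2(k) + drift + noise`; `k = 0` yields no
#' amplification (Cq `NA`). STAT6 always amplifies at
#' `stat6_baseline_cq + drift + noise`.
#'
#' DNA-concentration drift emulates uneven template amounts across the
#' source plate: one offset per sample, shared by all channels and wells of
#' that sample (`drift_mode = "shared"`, the physical situation — the same
#' aliquot feeds every well), so it cancels exactly in the within-well
#' delta-Cq. `drift_mode = "per_channel"` draws the offset independently per
#' well and channel, reproducing the concentration artefact that breaks
#' relative quantification.
#'
#' @param truth A `kir_truth` cohort from [simulate_cohort()].
#' @param panel A `kir_panel`.
#' @param cq_noise_sd Gaussian Cq noise per well and channel, cycles.
#' @param drift_sd DNA-concentration drift SD, cycles.
#' @param drift_mode `"shared"` (default) or `"per_channel"`.
#' @param replicates Wells per sample (default 4, the quadruplicate design).
#' @param seed Optional integer seed.
#' @param kir_baseline_cq Cq of a one-copy KIR target (default 28).
#' @param stat6_baseline_cq Cq of the two-copy STAT6 reference (default 24).
#' @return A `kir_cq` tibble with `plate_id`, `reaction_number`, `well`,
#'   `source_well`, `sample_id`, `replicate`, `channel`, `locus`, `cq`.
#' @export
synthesize_cq <- function(truth, panel = load_assay_panel(), cq_noise_sd = 0.1,
                          drift_sd = 0.3, drift_mode = c("shared", "per_channel"),
                          replicates = 4, seed = NULL,
                          kir_baseline_cq = 28, stat6_baseline_cq = 24) {
  drift_mode <- match.arg(drift_mode)
  stopifnot(cq_noise_sd >= 0, drift_sd >= 0, replicates >= 1)
  if (!all(kir_loci() %in% names(truth))) {
    abort("truth table does not carry the panel loci",
          class = "qkatr_config_error")
  }
  if (replicates > 4) {
    abort("the 2x2 quadruplicate layout supports at most 4 replicates",
          class = "qkatr_config_error")
  }
  n <- nrow(truth)
  map <- panel_channel_map(panel)

  # long skeleton: sample x reaction x replicate x channel
  pos_in_set <- (seq_len(n) - 1) %% 96 + 1
  set <- (seq_len(n) - 1) %/% 96 + 1
  blocks <- t(vapply(pos_in_set, well384_block, character(4)))

  skel <- tidyr::expand_grid(
    si = seq_len(n),
    reaction_number = 1:10,
    replicate = seq_len(replicates)
  ) %>%
    mutate(sample_id = truth$sample_id[.data$si],
           plate_set = set[.data$si],
           source_well = well96_name(pos_in_set[.data$si]),
           well = blocks[cbind(.data$si, .data$replicate)],
           plate_id = sprintf("R%02d-P%02d", .data$reaction_number,
                              .data$plate_set)) %>%
    inner_join(map, by = "reaction_number", relationship = "many-to-many")

  truth_long <- truth %>%
    as_tibble() %>%
    select("sample_id", dplyr::all_of(kir_loci())) %>%
    tidyr::pivot_longer(-"sample_id", names_to = "locus", values_to = "k")

  out <- with_seed(seed, {
    drift_sample <- rnorm(n, 0, drift_sd)
    x <- skel %>%
      left_join(truth_long, by = c("sample_id", "locus")) %>%
      mutate(k = ifelse(.data$locus == reference_locus(), 2L, .data$k))
    drift <- if (drift_mode == "shared") {
      drift_sample[x$si]
    } else {
      rnorm(nrow(x), 0, drift_sd)
    }
    noise <- rnorm(nrow(x), 0, cq_noise_sd)
    base <- ifelse(x$locus == reference_locus(),
                   stat6_baseline_cq,
                   kir_baseline_cq - log2(pmax(x$k, 1)))
    x %>%
      mutate(cq = ifelse(.data$locus != reference_locus() & .data$k == 0,
                         NA_real_, base + drift + noise))
  })
  out <- out %>%
    select("plate_id", "reaction_number", "well", "source_well", "sample_id",
           "replicate", "channel", "locus", "cq") %>%
    arrange(.data$reaction_number, .data$sample_id, .data$replicate)
  structure(out, class = c("kir_cq", class(out)))
}

#' Synthesize amplification curves for a Cq table
#'
#' Generates one 40-cycle logistic fluorescence curve per well and channel:
#' `F(c) = baseline + plateau / (1 + exp(-k (c - m))) + noise`, with the
#' midpoint `m` positioned so that the chosen Cq-calling method recovers the
#' target Cq (`m = cq + ln(2 + sqrt(3)) / k` for the second-derivative
#' maximum; solved numerically for the fit-points method). Dropout wells
#' (Cq `NA`) produce flat baseline-plus-noise traces.
#'
#' @param cq_tbl A `kir_cq` table (or any tibble with `well`, `channel`,
#'   `cq`, and optionally `plate_id`).
#' @param k Logistic slope per cycle.
#' @param plateau,baseline Fluorescence levels.
#' @param noise_sd Fluorescence noise SD.
#' @param n_cycles Cycles run (default 40).
#' @param method Cq-calling method the curves are positioned for.
#' @param noise_band Band used when positioning for the fit-points method.
#' @param seed Optional integer seed for the fluorescence noise.
#' @return Long tibble: identity columns of `cq_tbl` plus `cycle` and
#'   `fluorescence`.
#' @export
synthesize_curves <- function(cq_tbl, k = 0.8, plateau = 10, baseline = 0.1,
                              noise_sd = 0, n_cycles = 40,
                              method = c("second_derivative_max", "fit_points"),
                              noise_band = 1, seed = NULL) {
  method <- match.arg(method)
  cycles <- seq_len(n_cycles)
  id_cols <- intersect(c("plate_id", "reaction_number", "well", "source_well",
                         "sample_id", "replicate", "channel", "locus", "cq"),
                       names(cq_tbl))
  place_m <- function(cq) {
    if (method == "second_derivative_max") {
      cq + log(2 + sqrt(3)) / k
    } else {
      f <- function(m) {
        fl <- baseline + plateau / (1 + exp(-k * (cycles - m)))
        r <- fit_points_cq(cycles, fl, noise_band = noise_band)
        (if (is.na(r)) Inf else r) - cq
      }
      stats::uniroot(f, lower = cq - 6 / k, upper = cq + 12 / k,
                     tol = 1e-6)$root
    }
  }
  out <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(cq_tbl)), function(i) {
      cq <- cq_tbl$cq[i]
      fl <- if (is.na(cq)) {
        rep(baseline, n_cycles)
      } else {
        m <- place_m(cq)
        baseline + plateau / (1 + exp(-k * (cycles - m)))
      }
      fl <- fl + rnorm(n_cycles, 0, noise_sd)
      dplyr::bind_cols(cq_tbl[i, id_cols],
                       tibble(cycle = cycles, fluorescence = fl))
    })
  })
  as_tibble(out)
}
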