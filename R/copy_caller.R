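# Relative quantification: per-well delta-Cq against STAT6, replicate
# aggregation, per-plate calibration, and integer copy-number calls by the
# delta-delta-Cq method.

#' Within-well delta-Cq
#'
#' `Cq(KIR) - Cq(STAT6)` for a well. The two channels are read from the same
#' well, so DNA-amount variation cancels. A missing STAT6 Cq invalidates the
#' well (reference failure) rather than indicating copy number zero.
#'
#' @param kir_cq,stat6_cq Numeric vectors of Cq values (NA = no
#'   amplification).
#' @return Numeric vector of delta-Cq values; NA where the KIR channel
#'   dropped out. Errors if all STAT6 values are absent are left to the
#'   caller, which flags such wells invalid.
#' @export
#' @examples
#' well_delta_cq(26, 25) # 1
well_delta_cq <- function(kir_cq, stat6_cq) {
  kir_cq - stat6_cq
}

#' Aggregate replicate delta-Cq values
#'
#' Quadruplicate wells are combined per sample and locus: when at least half
#' of the valid replicates show no KIR amplification the aggregate is
#' dropout (copy number zero signature); otherwise the robust centre is the
#' median of the non-dropout values, with the raw median absolute deviation
#' as dispersion.
#'
#' @param delta_cqs Numeric vector of per-well delta-Cq values, NA for
#'   dropout wells.
#' @return List with `delta_cq` (NA when dropout wins), `n_used`, and
#'   `dispersion`.
#' @export
#' @examples
#' aggregate_replicates(c(0.9, 1.0, 1.1, 9.0)) # median robust to outlier
aggregate_replicates <- function(delta_cqs) {
  n <- length(delta_cqs)
  if (n < 1) {
    abort("need at least one replicate", class = "qkatr_validation_error")
  }
  n_drop <- sum(is.na(delta_cqs))
  if (n_drop >= n / 2) {
    return(list(delta_cq = NA_real_, n_used = as.integer(n - n_drop),
                dispersion = NA_real_))
  }
  x <- delta_cqs[!is.na(delta_cqs)]
  med <- median(x)
  list(delta_cq = med, n_used = length(x),
       dispersion = median(abs(x - med)))
}

#' Calibration anchor for one locus
#'
#' Relative quantification needs an anchor (delta-Cq0, CN0) per plate and
#' locus. `calibrator_sample` mode anchors on a sample of known copy number;
#' `most_frequent_cn` mode anchors the plate's delta-Cq ladder at the
#' default copy number typically observed in European-origin cohorts.
#' Because copy-number classes sit on a rigid log2 ladder, the anchor is
#' chosen as the candidate (every observed delta-Cq is one) that maps all
#' plate samples closest to integer copy estimates, with ties resolved by
#' parsimony (smallest implied maximum copy number) and then by the size of
#' the implied default class; the returned anchor is the median of that
#' class. This is exact on noise-free plates and, unlike a bare plate
#' median, stays on the correct rung when the modal class holds under half
#' of the amplified samples (e.g. 2DL3) or when adjacent classes — only
#' 0.585 cycles apart — are nearly balanced (e.g. 2DS4Del).
#'
#' @param delta_cqs Aggregated per-sample delta-Cq values for the locus on
#'   one plate (NA = dropout samples, excluded).
#' @param mode `"most_frequent_cn"` or `"calibrator_sample"`.
#' @param default_cn Default copy number for the locus (mode 2).
#' @param calibrator_delta_cq,calibrator_cn The calibrator's aggregated
#'   delta-Cq and its known copy number (mode 1).
#' @param min_samples Minimum non-dropout samples required in mode 2.
#' @return List `(delta_cq0, cn0)`.
#' @export
calibrate <- function(delta_cqs = NULL,
                      mode = c("most_frequent_cn", "calibrator_sample"),
                      default_cn = NULL, calibrator_delta_cq = NULL,
                      calibrator_cn = NULL, min_samples = 5) {
  mode <- match.arg(mode)
  if (mode == "calibrator_sample") {
    if (is.null(calibrator_delta_cq) || is.na(calibrator_delta_cq)) {
      abort("calibrator sample missing or dropped out",
            class = "qkatr_calibration_error")
    }
    if (is.null(calibrator_cn) || is.na(calibrator_cn) || calibrator_cn < 1) {
      abort("calibrator copy number must be a known positive integer",
            class = "qkatr_calibration_error")
    }
    return(list(delta_cq0 = calibrator_delta_cq, cn0 = calibrator_cn))
  }
  x <- sort(delta_cqs[!is.na(delta_cqs)])
  if (length(x) < min_samples) {
    abort(paste0("most-frequent-CN calibration needs >= ", min_samples,
                 " non-dropout samples"),
          class = "qkatr_calibration_error")
  }
  if (is.null(default_cn) || is.na(default_cn)) {
    abort("most-frequent-CN calibration needs a default copy number",
          class = "qkatr_calibration_error")
  }
  # Every observed delta-Cq is a candidate anchor at the default copy
  # number. The copy-number ladder is log2-rigid, so the right anchor maps
  # every plate sample near an integer estimate: score candidates by total
  # misfit to the integer ladder (amplified samples cannot round to zero),
  # then by parsimony (smallest implied maximum copy number — an anchor one
  # class too high doubles every call), then by the size of the implied
  # default-CN class, then by closeness to the plate median.
  cand <- unique(x)
  est <- default_cn * 2^(-outer(x, cand, "-"))
  r <- round_half_away(est, 0)
  dist <- ifelse(r < 1, 0.5, pmin(abs(est - r), 0.5))
  misfit <- round(colSums(dist), 6)
  maxcn <- apply(r, 2, max)
  size <- colSums(r == default_cn)
  best <- order(misfit, maxcn, -size, abs(cand - median(x)))[1]
  in_class <- r[, best] == default_cn
  anchor <- if (any(in_class)) median(x[in_class]) else cand[best]
  list(delta_cq0 = anchor, cn0 = default_cn)
}

#' Copy-number call from an anchored delta-Cq
#'
#' `ddcq = delta_cq - delta_cq0`; estimate `cn0 * 2^(-ddcq)`; the integer
#' call rounds half away from zero, so an estimate of exactly 0.5 calls one
#' copy — a zero call requires the qualitative dropout signature, not a
#' quantitative rounding. Confidence is
#' `max(0, 1 - 2 |estimate - call| / max(call, 1))`.
#'
#' @param delta_cq Aggregated sample delta-Cq (NA = dropout).
#' @param delta_cq0,cn0 Calibration anchor, e.g. from [calibrate()].
#' @return List `(ddcq, cn_estimate, cn_called, confidence)`.
#' @export
#' @examples
#' call_copy_number(-1, 0, 2) # estimate 4
call_copy_number <- function(delta_cq, delta_cq0, cn0) {
  if (is.na(delta_cq)) {
    return(list(ddcq = NA_real_, cn_estimate = 0, cn_called = 0L,
                confidence = 1))
  }
  ddcq <- delta_cq - delta_cq0
  est <- cn0 * 2^(-ddcq)
  called <- as.integer(round_half_away(est, 0))
  conf <- max(0, 1 - 2 * abs(est - called) / max(called, 1))
  list(ddcq = ddcq, cn_estimate = est, cn_called = called, confidence = conf)
}

#' Call copy numbers for a whole Cq table
#'
#' Runs the full relative-quantification chain on a per-well Cq table:
#' within-well delta-Cq against STAT6, replicate aggregation, per-plate
#' calibration and delta-delta-Cq copy-number calls for every sample and
#' locus.
#'
#' Wells whose STAT6 channel failed are invalid (flag `ref_failure`) and are
#' excluded from aggregation. In `calibrator_sample` mode, loci at which the
#' calibrator's known copy number is zero (so it cannot amplify) fall back
#' to the most-frequent-CN anchor for that locus; a calibrator that should
#' amplify but dropped out is an error.
#'
#' @param cq_tbl A `kir_cq` tibble (see [synthesize_cq()] or
#'   [split_by_reaction()]).
#' @param panel A `kir_panel`.
#' @param calibration `"most_frequent_cn"` (default) or
#'   `"calibrator_sample"`.
#' @param calibrator_sample Sample id of the calibrator (mode 1).
#' @param calibrator_cn Named vector (locus -> known copies) for the
#'   calibrator, e.g. a row of a `kir_truth` cohort (mode 1).
#' @param min_samples Passed to [calibrate()].
#' @param cn_cap Calls above this are flagged implausible and set NA
#'   (default 8).
#' @return A `kir_calls` tibble: `sample_id`, `locus`, `plate_id`,
#'   `reaction_number`, `delta_cq`, `n_replicates_used`, `dispersion`,
#'   `ddcq`, `cn_estimate`, `cn_called`, `confidence`, `flags`.
#' @export
call_copy_numbers <- function(cq_tbl, panel = load_assay_panel(),
                              calibration = c("most_frequent_cn",
                                              "calibrator_sample"),
                              calibrator_sample = NULL, calibrator_cn = NULL,
                              min_samples = 5, cn_cap = 8) {
  calibration <- match.arg(calibration)
  if (calibration == "calibrator_sample") {
    if (is.null(calibrator_sample)) {
      abort("calibrator_sample mode needs a calibrator sample id",
            class = "qkatr_calibration_error")
    }
    if (is.null(calibrator_cn)) {
      abort("calibrator_sample mode needs the calibrator's known copy numbers",
            class = "qkatr_calibration_error")
    }
    if (is.data.frame(calibrator_cn)) {
      calibrator_cn <- unlist(calibrator_cn[1, intersect(kir_loci(),
                                                         names(calibrator_cn))])
    }
  }
  defaults <- panel_default_cn(panel)

  ref <- cq_tbl %>%
    filter(.data$locus == reference_locus()) %>%
    select("plate_id", "well", stat6_cq = "cq")
  kir <- cq_tbl %>% filter(.data$locus != reference_locus())
  wells <- kir %>%
    left_join(ref, by = c("plate_id", "well")) %>%
    mutate(ref_failure = is.na(.data$stat6_cq),
           dcq = well_delta_cq(.data$cq, .data$stat6_cq))

  agg <- wells %>%
    group_by(.data$plate_id, .data$reaction_number, .data$sample_id,
             .data$locus) %>%
    summarise(
      n_ref_failure = sum(.data$ref_failure),
      agg = list(if (all(.data$ref_failure)) {
        # every well of the group lost its reference: invalid, not copy 0
        list(delta_cq = NA_real_, n_used = 0L, dispersion = NA_real_)
      } else {
        aggregate_replicates(.data$dcq[!.data$ref_failure])
      }),
      .groups = "drop") %>%
    mutate(delta_cq = purrr::map_dbl(.data$agg, "delta_cq"),
           n_replicates_used = purrr::map_int(.data$agg, "n_used"),
           dispersion = purrr::map_dbl(.data$agg, "dispersion")) %>%
    select(-"agg")

  anchors <- agg %>%
    group_by(.data$plate_id, .data$locus) %>%
    summarise(anchor = list({
      loc <- .data$locus[1]
      if (calibration == "calibrator_sample" &&
          (loc %in% names(calibrator_cn)) && calibrator_cn[[loc]] >= 1) {
        i <- which(.data$sample_id == calibrator_sample)
        if (length(i) == 0) {
          abort(paste0("calibrator sample ", calibrator_sample,
                       " not present on plate ", .data$plate_id[1]),
                class = "qkatr_calibration_error")
        }
        calibrate(mode = "calibrator_sample",
                  calibrator_delta_cq = .data$delta_cq[i[1]],
                  calibrator_cn = calibrator_cn[[loc]])
      } else {
        calibrate(.data$delta_cq, mode = "most_frequent_cn",
                  default_cn = defaults[[loc]], min_samples = min_samples)
      }
    }), .groups = "drop") %>%
    mutate(delta_cq0 = purrr::map_dbl(.data$anchor, "delta_cq0"),
           cn0 = purrr::map_dbl(.data$anchor, "cn0")) %>%
    select(-"anchor")

  calls <- agg %>%
    left_join(anchors, by = c("plate_id", "locus")) %>%
    mutate(
      invalid = .data$n_replicates_used == 0 & .data$n_ref_failure > 0,
      ddcq = .data$delta_cq - .data$delta_cq0,
      cn_estimate = ifelse(is.na(.data$delta_cq), 0,
                           .data$cn0 * 2^(-.data$ddcq)),
      cn_called = as.integer(round_half_away(.data$cn_estimate, 0)),
      confidence = pmax(0, 1 - 2 * abs(.data$cn_estimate - .data$cn_called) /
                          pmax(.data$cn_called, 1)),
      cn_estimate = ifelse(.data$invalid, NA_real_, .data$cn_estimate),
      cn_called = ifelse(.data$invalid, NA_integer_, .data$cn_called),
      confidence = ifelse(.data$invalid, 0, .data$confidence),
      flags = paste0(
        ifelse(.data$n_ref_failure > 0, "ref_failure;", ""),
        ifelse(!is.na(.data$dispersion) & .data$dispersion > 0.5,
               "high_dispersion;", ""),
        ifelse(.data$confidence < 0.5, "low_confidence;", ""),
        ifelse(!is.na(.data$cn_called) & .data$cn_called > cn_cap,
               "implausible_cn;", "")),
      flags = sub(";$", "", .data$flags),
      cn_called = ifelse(!is.na(.data$cn_called) & .data$cn_called > cn_cap,
                         NA_integer_, .data$cn_called)
    ) %>%
    select("sample_id", "locus", "plate_id", "reaction_number", "delta_cq",
           "n_replicates_used", "dispersion", "ddcq", "cn_estimate",
           "cn_called", "confidence", "flags") %>%
    arrange(.data$sample_id, .data$locus)
  structure(calls, class = c("kir_calls", class(calls)))
}

#' Combine per-reaction calls into per-sample copy-number profiles
#'
#' Mirrors the combine-all-plates spreadsheet step: one row per sample with
#' a called copy number for each of the 20 loci, plus a per-sample `flags`
#' column (`locus=flag` entries, semicolon-separated). Samples missing a
#' reaction get NA at the affected loci with a `missing` flag; duplicate
#' calls for the same (sample, locus) from different plates are kept if
#' concordant and flagged `conflict` (value NA) if discordant.
#'
#' @param calls A `kir_calls` tibble from [call_copy_numbers()].
#' @param panel A `kir_panel`.
#' @return A `kir_profiles` tibble: `sample_id`, one integer column per
#'   locus, `flags`.
#' @export
build_profiles <- function(calls, panel = load_assay_panel()) {
  loci <- panel$loci
  per <- calls %>%
    group_by(.data$sample_id, .data$locus) %>%
    summarise(
      cn = if (dplyr::n_distinct(.data$cn_called) == 1) .data$cn_called[1]
           else NA_integer_,
      flag = {
        f <- unique(unlist(strsplit(.data$flags[.data$flags != ""], ";")))
        if (dplyr::n_distinct(.data$cn_called) > 1) f <- c(f, "conflict")
        paste(f, collapse = "+")
      },
      .groups = "drop")

  full <- tidyr::expand_grid(sample_id = unique(calls$sample_id),
                             locus = loci) %>%
    left_join(per, by = c("sample_id", "locus")) %>%
    mutate(flag = dplyr::case_when(
      is.na(.data$flag) ~ "missing",
      TRUE ~ .data$flag))

  flags <- full %>%
    filter(.data$flag != "") %>%
    group_by(.data$sample_id) %>%
    summarise(flags = paste0(.data$locus, "=", .data$flag, collapse = ";"),
              .groups = "drop")

  wide <- full %>%
    select("sample_id", "locus", "cn") %>%
    tidyr::pivot_wider(names_from = "locus", values_from = "cn") %>%
    select("sample_id", dplyr::all_of(loci)) %>%
    left_join(flags, by = "sample_id") %>%
    mutate(flags = ifelse(is.na(.data$flags), "", .data$flags)) %>%
    arrange(.data$sample_id)
  structure(wide, class = c("kir_profiles", class(wide)))
}
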