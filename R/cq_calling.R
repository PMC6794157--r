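# Quantification-cycle extraction from amplification curves, by the two
# methods offered by instrument software: the second-derivative maximum and
# the fit-points (log-linear threshold crossing) method.

check_curve <- function(cycles, fluorescence, min_cycles = 10) {
  if (length(cycles) != length(fluorescence)) {
    abort("cycles and fluorescence must have equal length",
          class = "qkatr_validation_error")
  }
  if (length(cycles) < min_cycles) {
    abort(paste0("curve too short: need >= ", min_cycles, " cycles"),
          class = "qkatr_validation_error")
  }
  if (any(diff(cycles) <= 0)) {
    abort("cycle vector must be strictly increasing",
          class = "qkatr_validation_error")
  }
  invisible(TRUE)
}

#' Classify an amplification curve as flat (no amplification)
#'
#' A curve is flat when its total signal rise above the baseline level is
#' less than `flat_factor` times the baseline noise (strict inequality).
#' Baseline level and noise are the median and SD of fluorescence over
#' cycles 3-12, a window late enough to avoid early-cycle artefacts and
#' early enough to precede amplification.
#'
#' @param cycles,fluorescence Numeric vectors of equal length.
#' @param flat_factor Rise threshold in baseline-SD units (default 5).
#' @return Logical scalar.
#' @export
classify_flat <- function(cycles, fluorescence, flat_factor = 5) {
  base <- fluorescence[cycles >= 3 & cycles <= 12]
  if (length(base) < 3) base <- head(fluorescence, 5)
  bsd <- stats::sd(base)
  rise <- max(fluorescence) - median(base)
  rise < flat_factor * max(bsd, .Machine$double.eps)
}

#' Cq by the second-derivative-maximum method
#'
#' The quantification cycle is the position of the maximum of the second
#' derivative of the amplification curve — the point of maximal acceleration
#' at the onset of exponential growth. A four-parameter logistic
#' `b + P / (1 + exp(-k (c - m)))` is fitted to the (Savitzky-Golay
#' smoothed) fluorescence and the maximum taken analytically at
#' `m - ln(2 + sqrt(3)) / k`, which gives sub-cycle precision; one-cycle
#' sampling is too coarse to localise the skewed second-derivative peak by
#' finite differences alone, so the difference-based estimate (quadratic
#' interpolation around the discrete maximum of the second differences) is
#' kept only as a fallback when the sigmoid fit fails to converge.
#'
#' @param cycles Strictly increasing cycle numbers (>= 10 cycles).
#' @param fluorescence Fluorescence readings, same length.
#' @param flat_factor Passed to [classify_flat()]; flat curves give `NA`.
#' @return Cq in cycles, or `NA` for a flat (non-amplifying) curve.
#' @export
#' @examples
#' cyc <- 1:40
#' fl <- 10 / (1 + exp(-0.8 * (cyc - 25)))
#' second_derivative_max_cq(cyc, fl) # 25 - log(2 + sqrt(3)) / 0.8
second_derivative_max_cq <- function(cycles, fluorescence, flat_factor = 5) {
  check_curve(cycles, fluorescence)
  if (classify_flat(cycles, fluorescence, flat_factor)) return(NA_real_)
  sm <- signal::sgolayfilt(fluorescence, p = 3, n = 5)
  lo <- min(sm); hi <- max(sm)
  m0 <- cycles[which.min(abs(sm - (lo + hi) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      sm ~ b + P / (1 + exp(-k * (cycles - m))),
      start = list(b = lo, P = hi - lo, k = 1, m = m0),
      lower = c(-Inf, 0, 1e-3, min(cycles) - 10),
      upper = c(Inf, Inf, 10, max(cycles) + 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  cq <- if (!is.null(fit)) {
    cf <- stats::coef(fit)
    cf[["m"]] - log(2 + sqrt(3)) / cf[["k"]]
  } else {
    sdm_discrete_cq(cycles, sm)
  }
  min(max(cq, cycles[1]), cycles[length(cycles)])
}

# fallback: quadratic interpolation around the discrete second-difference max
sdm_discrete_cq <- function(cycles, sm) {
  n <- length(sm)
  d2 <- sm[3:n] - 2 * sm[2:(n - 1)] + sm[1:(n - 2)] # centred at 2..n-1
  j <- which.max(d2)
  if (j == 1 || j == length(d2)) return(cycles[j + 1])
  a <- d2[j - 1]; b <- d2[j]; c <- d2[j + 1]
  denom <- a - 2 * b + c
  off <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (a - c) / denom
  cycles[j + 1] + max(min(off, 0.5), -0.5) * (cycles[2] - cycles[1])
}

#' Cq by the fit-points method
#'
#' Fits a log-linear line through the first `n_fit_points` cycles whose
#' fluorescence exceeds the noise band, and reports the cycle at which the
#' fitted line crosses the band — the threshold-crossing point. With perfect
#' doubling per cycle the fit is exact, and doubling the band raises the Cq
#' by exactly one cycle.
#'
#' @param cycles,fluorescence The curve.
#' @param noise_band Fluorescence threshold above background; must be > 0.
#' @param n_fit_points Number of above-band cycles to fit (instrument
#'   default 3).
#' @return Cq in cycles, or `NA` when fewer than `n_fit_points` cycles
#'   exceed the band.
#' @export
#' @examples
#' cyc <- 1:40
#' fit_points_cq(cyc, 2^(cyc - 20), noise_band = 1) # 20
fit_points_cq <- function(cycles, fluorescence, noise_band,
                          n_fit_points = 3) {
  check_curve(cycles, fluorescence)
  if (!is.numeric(noise_band) || noise_band <= 0) {
    abort("noise_band must be positive", class = "qkatr_validation_error")
  }
  above <- which(fluorescence > noise_band)
  if (length(above) < n_fit_points) return(NA_real_)
  idx <- above[seq_len(n_fit_points)]
  if (any(fluorescence[idx] <= 0)) {
    abort("non-positive fluorescence in fit window: log-linear fit undefined",
          class = "qkatr_fit_error")
  }
  x <- cycles[idx]
  y <- log2(fluorescence[idx])
  fit <- stats::lm.fit(cbind(1, x), y)
  b0 <- fit$coefficients[1]; b1 <- fit$coefficients[2]
  if (!is.finite(b1) || b1 <= 0) return(NA_real_)
  unname((log2(noise_band) - b0) / b1)
}

#' Call Cq values for a table of amplification curves
#'
#' Applies one of the two Cq-calling methods to every (well, channel) curve
#' in a long curve table, e.g. from [synthesize_curves()] or
#' [read_curve_table()].
#'
#' @param curves Long tibble with `cycle` and `fluorescence` plus identity
#'   columns (`well`, `channel`, and any of `plate_id`, `sample_id`,
#'   `replicate`, `locus`, `reaction_number`, `source_well`).
#' @param method `"second_derivative_max"` (default) or `"fit_points"`.
#' @param noise_band Threshold for the fit-points method.
#' @param n_fit_points Fit points (default 3).
#' @param flat_factor Passed to [classify_flat()].
#' @return Tibble with one row per curve: identity columns, `cq` and
#'   `method`. Flat curves have `cq = NA`.
#' @export
call_cq <- function(curves, method = c("second_derivative_max", "fit_points"),
                    noise_band = NULL, n_fit_points = 3, flat_factor = 5) {
  method <- match.arg(method)
  if (method == "fit_points" && is.null(noise_band)) {
    abort("fit_points method needs a noise_band",
          class = "qkatr_validation_error")
  }
  id_cols <- intersect(c("plate_id", "reaction_number", "well", "source_well",
                         "sample_id", "replicate", "channel", "locus"),
                       names(curves))
  curves %>%
    group_by(dplyr::across(dplyr::all_of(id_cols))) %>%
    arrange(.data$cycle, .by_group = TRUE) %>%
    summarise(cq = {
      fl <- .data$fluorescence
      cyc <- .data$cycle
      if (classify_flat(cyc, fl, flat_factor)) NA_real_
      else if (method == "second_derivative_max") {
        second_derivative_max_cq(cyc, fl, flat_factor)
      } else {
        fit_points_cq(cyc, fl, noise_band, n_fit_points)
      }
    }, .groups = "drop") %>%
    mutate(method = .env$method)
}
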