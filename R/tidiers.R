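# broom-style tidiers for the pipeline's result objects.

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy copy-number calls
#'
#' @param x A `kir_calls` tibble.
#' @param ... Ignored.
#' @return A plain tibble of per-(sample, locus) calls.
#' @export
tidy.kir_calls <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' One-row summary of a set of copy-number calls
#'
#' @param x A `kir_calls` tibble.
#' @param ... Ignored.
#' @return Tibble with sample/locus counts, mean confidence, dropout and
#'   flagged fractions.
#' @export
glance.kir_calls <- function(x, ...) {
  tibble(
    n_samples = n_distinct(x$sample_id),
    n_loci = n_distinct(x$locus),
    mean_confidence = mean(x$confidence, na.rm = TRUE),
    frac_dropout = mean(is.na(x$delta_cq)),
    frac_flagged = mean(x$flags != "")
  )
}

#' Tidy an LD report down to its violations
#'
#' @param x A `kir_ld_report`.
#' @param ... Ignored.
#' @return Tibble of violated rule evaluations only.
#' @export
tidy.kir_ld_report <- function(x, ...) {
  tibble::as_tibble(unclass_result(x)) %>% filter(.data$violated)
}

#' One-row summary of an LD report
#'
#' @param x A `kir_ld_report`.
#' @param ... Ignored.
#' @return Tibble with sample counts and conformity fraction.
#' @export
glance.kir_ld_report <- function(x, ...) {
  conf <- attr(x, "conformity")
  tibble(
    n_samples = nrow(conf),
    n_conforming = sum(conf$conforms),
    frac_conforming = mean(conf$conforms),
    n_violations = sum(x$violated)
  )
}

#' Tidy a haplotype imputation
#'
#' @param x A `kir_imputation`.
#' @param ... Ignored.
#' @return Plain tibble of pair assignments.
#' @export
tidy.kir_imputation <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' One-row summary of a haplotype imputation
#'
#' @param x A `kir_imputation`.
#' @param ... Ignored.
#' @return Tibble with assignment counts and ambiguity.
#' @export
glance.kir_imputation <- function(x, ...) {
  per <- x %>%
    group_by(.data$sample_id) %>%
    summarise(status = first(.data$status), n_pairs = sum(!is.na(.data$hap1)),
              .groups = "drop")
  tibble(
    n_samples = nrow(per),
    n_assigned = sum(per$status != "unassigned"),
    n_unassigned = sum(per$status == "unassigned"),
    mean_pairs_per_assigned = mean(per$n_pairs[per$status != "unassigned"])
  )
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("kir_calls", "kir_ld_report",
                                  "kir_imputation", "kir_profiles",
                                  "kir_cq", "kir_truth"))
  x
}
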