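# Linkage-disequilibrium consistency rules for European cohorts, applied as
# arithmetic checks on called copy-number profiles. Rules are data (coefficient
# relations over loci), so a different population's rule set can be swapped in.

#' The ten built-in LD consistency rules
#'
#' The fixed arithmetic relations between KIR locus copy numbers observed in
#' European-origin populations. Each rule is one or more equalities of the
#' form `lhs = rhs`, where each side is a `+`-joined list of loci or an
#' integer constant; a rule is violated when any of its equalities fails.
#'
#' @return A `kir_ld_rules` tibble: `rule_id` (1-10), `description`, `lhs`,
#'   `rhs` (one row per equality; rules 1 and 5 span several).
#' @export
#' @examples
#' builtin_rules()
builtin_rules <- function() {
  r <- tibble::tribble(
    ~rule_id, ~description, ~lhs, ~rhs,
    1L, "framework genes 3DL3, 3DP1, 2DL4 and 3DL2 are present on both haplotypes",
        "3DL3", "2",
    1L, "framework genes 3DL3, 3DP1, 2DL4 and 3DL2 are present on both haplotypes",
        "3DP1", "2",
    1L, "framework genes 3DL3, 3DP1, 2DL4 and 3DL2 are present on both haplotypes",
        "2DL4", "2",
    1L, "framework genes 3DL3, 3DP1, 2DL4 and 3DL2 are present on both haplotypes",
        "3DL2ex4", "2",
    1L, "framework genes 3DL3, 3DP1, 2DL4 and 3DL2 are present on both haplotypes",
        "3DL2ex9", "2",
    2L, "2DS2 and 2DL2 are in strong LD", "2DS2", "2DL2",
    3L, "2DL2 and 2DL3 are alleles of one gene", "2DL2+2DL3", "2",
    4L, "2DP1 and 2DL1 are in strong LD", "2DP1", "2DL1",
    5L, "exon-4 and exon-9 measurements of 3DL1 and 3DL2 agree",
        "3DL1ex4", "3DL1ex9",
    5L, "exon-4 and exon-9 measurements of 3DL1 and 3DL2 agree",
        "3DL2ex4", "3DL2ex9",
    6L, "3DL1 and 3DS1 are alleles of one gene", "3DL1ex4+3DS1", "2",
    7L, "2DS3 and 2DS5 are in LD with 2DL5", "2DS3+2DS5", "2DL5",
    8L, "3DS1 and 2DS1 are in strong LD", "3DS1", "2DS1",
    9L, "2DS1 and 2DS4 are mutually exclusive per haplotype",
        "2DS1+2DS4Total", "2",
    10L, "2DS4FL and 2DS4Del are variants of 2DS4",
        "2DS4FL+2DS4Del", "2DS4Total"
  )
  structure(r, class = c("kir_ld_rules", class(r)))
}

#' Read an LD rule set from CSV
#'
#' @param path CSV with columns `rule_id`, `description`, `lhs`, `rhs` in
#'   the format of [builtin_rules()].
#' @return A `kir_ld_rules` tibble.
#' @export
read_ld_rules <- function(path) {
  r <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("rule_id", "description", "lhs", "rhs")
  if (!all(need %in% names(r))) {
    abort("rules CSV needs columns rule_id, description, lhs, rhs",
          class = "qkatr_parse_error")
  }
  structure(as_tibble(r), class = c("kir_ld_rules", class(as_tibble(r))))
}

# evaluate a "+"-joined side against a named copy-number vector;
# returns NA when a referenced locus is NA or missing
eval_side <- function(expr, cn) {
  toks <- trimws(strsplit(expr, "+", fixed = TRUE)[[1]])
  vals <- vapply(toks, function(t) {
    if (grepl("^-?[0-9]+$", t)) as.numeric(t)
    else if (t %in% names(cn)) as.numeric(cn[[t]])
    else NA_real_
  }, numeric(1))
  sum(vals)
}

#' Check copy-number profiles against LD rules
#'
#' Evaluates every rule for every sample. Equalities touching a missing
#' (NA) locus are reported as not evaluable rather than violated.
#'
#' @param profiles A `kir_profiles` tibble (or any data frame with
#'   `sample_id` and locus columns).
#' @param rules A `kir_ld_rules` tibble; defaults to the built-in European
#'   set.
#' @return A `kir_ld_report` tibble: `sample_id`, `rule_id`, `description`,
#'   `constraint`, `lhs_value`, `rhs_value`, `evaluable`, `violated`, plus a
#'   `conforms` logical column repeated per sample (TRUE iff no violated
#'   rule).
#' @export
check_ld <- function(profiles, rules = builtin_rules()) {
  loci <- intersect(kir_loci(), names(profiles))
  if (nrow(rules) == 0) {
    empty <- tibble(sample_id = character(0), rule_id = integer(0),
                    description = character(0), constraint = character(0),
                    lhs_value = numeric(0), rhs_value = numeric(0),
                    evaluable = logical(0), violated = logical(0),
                    conforms = logical(0))
    return(structure(empty, class = c("kir_ld_report", class(empty)),
                     conformity = tibble(sample_id = profiles$sample_id,
                                         conforms = TRUE)))
  }
  out <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    cn <- setNames(as.numeric(unlist(profiles[i, loci])), loci)
    tibble(
      sample_id = profiles$sample_id[i],
      rule_id = rules$rule_id,
      description = rules$description,
      constraint = paste0(rules$lhs, " = ", rules$rhs),
      lhs_value = vapply(rules$lhs, eval_side, numeric(1), cn = cn),
      rhs_value = vapply(rules$rhs, eval_side, numeric(1), cn = cn)
    ) %>%
      mutate(evaluable = !is.na(.data$lhs_value) & !is.na(.data$rhs_value),
             violated = .data$evaluable & .data$lhs_value != .data$rhs_value)
  })
  conf <- out %>%
    group_by(.data$sample_id) %>%
    summarise(conforms = !any(.data$violated), .groups = "drop")
  samples_missing <- setdiff(profiles$sample_id, conf$sample_id)
  if (length(samples_missing) > 0) {
    conf <- bind_rows(conf, tibble(sample_id = samples_missing,
                                   conforms = TRUE))
  }
  out <- out %>% left_join(conf, by = "sample_id")
  structure(out, class = c("kir_ld_report", class(out)),
            conformity = conf)
}

#' Per-sample LD report
#'
#' Convenience wrapper giving one row per sample with its violated rules.
#'
#' @param report A `kir_ld_report` from [check_ld()].
#' @return Tibble: `sample_id`, `conforms`, `n_violations`,
#'   `violated_rules`.
#' @export
ld_conformity <- function(report) {
  base <- attr(report, "conformity")
  viol <- report %>%
    filter(.data$violated) %>%
    group_by(.data$sample_id) %>%
    summarise(n_violations = n(),
              violated_rules = paste(sort(unique(.data$rule_id)),
                                     collapse = ","),
              .groups = "drop")
  base %>%
    left_join(viol, by = "sample_id") %>%
    mutate(n_violations = ifelse(is.na(.data$n_violations), 0L,
                                 .data$n_violations),
           violated_rules = ifelse(is.na(.data$violated_rules), "",
                                   .data$violated_rules)) %>%
    arrange(dplyr::desc(.data$n_violations), .data$sample_id)
}

#' Cohort-level QC summary
#'
#' @param report A `kir_ld_report` from [check_ld()].
#' @return List of two tibbles: `by_rule` (violation counts per rule,
#'   worst-first) and `by_sample` (conformity per sample, worst-first).
#'   With an empty rule set every sample conforms vacuously.
#' @export
cohort_qc_summary <- function(report) {
  if (nrow(report) == 0) {
    by_rule <- tibble(rule_id = integer(0), description = character(0),
                      n_violations = integer(0))
  } else {
    by_rule <- report %>%
      group_by(.data$rule_id) %>%
      summarise(description = first(.data$description),
                n_violations = sum(.data$violated), .groups = "drop") %>%
      arrange(dplyr::desc(.data$n_violations), .data$rule_id)
  }
  list(by_rule = by_rule, by_sample = ld_conformity(report))
}
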