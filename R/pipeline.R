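# End-to-end analysis: parse exports -> split per reaction -> copy-number
# calls -> combined spreadsheet -> LD report -> haplotype imputation.

#' Run the full typing pipeline
#'
#' Executes the analysis arm of the workflow on either raw export files or a
#' typed Cq table, writing the combined copy-number spreadsheet, the LD
#' quality report and the three imputation files into `out_dir`. Each stage
#' is logged with row counts; a failing stage aborts with its name, keeping
#' outputs of earlier stages on disk.
#'
#' @param exports Paths to plate-export files (tab-delimited dialect of
#'   [parse_plate_export()]); alternatively supply `cq_tbl`.
#' @param cq_tbl A ready `kir_cq` table (skips parsing/splitting).
#' @param panel A `kir_panel`.
#' @param manifest Optional plate-to-reaction manifest.
#' @param calibration,calibrator_sample,calibrator_cn,min_samples
#'   Passed to [call_copy_numbers()].
#' @param haplotypes Reference haplotype table, a CSV path, or NULL to skip
#'   imputation with `impute = FALSE`.
#' @param rules LD rule set (default [builtin_rules()]).
#' @param impute Run haplotype imputation (default TRUE).
#' @param wildcard_na Passed to [impute_all_pairs()].
#' @param out_dir Output directory.
#' @param verbose Log stages with [message()] (default TRUE).
#' @return Invisible list: `cq`, `calls`, `profiles`, `ld_report`,
#'   `qc_summary`, `imputation`, `paths`.
#' @export
run_pipeline <- function(exports = NULL, cq_tbl = NULL,
                         panel = load_assay_panel(), manifest = NULL,
                         calibration = c("most_frequent_cn",
                                         "calibrator_sample"),
                         calibrator_sample = NULL, calibrator_cn = NULL,
                         min_samples = 5,
                         haplotypes = builtin_reference_haplotypes(),
                         rules = builtin_rules(), impute = TRUE,
                         wildcard_na = FALSE, out_dir, verbose = TRUE) {
  calibration <- match.arg(calibration)
  say <- function(...) if (verbose) message("[qkat] ", ...)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), class = "qkatr_pipeline_error")
    })
  }
  if (impute) {
    if (is.character(haplotypes)) {
      if (!file.exists(haplotypes)) {
        abort(paste0("haplotype table not found: ", haplotypes),
              class = "qkatr_config_error")
      }
      haplotypes <- read_haplotype_table(haplotypes)
    }
    if (is.null(haplotypes)) {
      abort("imputation requested but no haplotype table supplied",
            class = "qkatr_config_error")
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()

  if (is.null(cq_tbl)) {
    if (is.null(exports)) {
      abort("supply either export files or a Cq table",
            class = "qkatr_config_error")
    }
    parsed <- stage("parse", lapply(exports, parse_plate_export))
    say("parsed ", length(parsed), " plate export(s)")
    cq_tbl <- stage("split", split_by_reaction(parsed, panel, manifest))
  }
  say("Cq table: ", nrow(cq_tbl), " rows, ",
      n_distinct(cq_tbl$sample_id), " samples")

  calls <- stage("call", call_copy_numbers(
    cq_tbl, panel, calibration = calibration,
    calibrator_sample = calibrator_sample, calibrator_cn = calibrator_cn,
    min_samples = min_samples))
  paths$calls <- file.path(out_dir, "calls.csv")
  readr::write_csv(calls, paths$calls)

  profiles <- stage("combine", build_profiles(calls, panel))
  say("profiles: ", nrow(profiles), " samples x ", length(panel$loci),
      " loci")
  paths$profiles <- file.path(out_dir, "profiles.csv")
  readr::write_csv(profiles, paths$profiles)

  ld <- stage("qc", check_ld(profiles, rules))
  qc <- cohort_qc_summary(ld)
  say("LD QC: ", sum(!attr(ld, "conformity")$conforms),
      " non-conforming sample(s)")
  paths$ld_report <- file.path(out_dir, "ld_report.csv")
  readr::write_csv(as_tibble(ld), paths$ld_report)
  paths$qc_summary <- file.path(out_dir, "qc_by_sample.csv")
  readr::write_csv(qc$by_sample, paths$qc_summary)

  imputation <- NULL
  if (impute) {
    imputation <- stage("impute", impute_all_pairs(
      profiles, haplotypes, wildcard_na = wildcard_na))
    ip <- write_imputation_outputs(imputation, out_dir)
    paths <- c(paths, as.list(ip))
    say("imputation: ",
        sum(imputation$status == "unassigned"), " unassigned sample(s)")
  }
  invisible(list(cq = cq_tbl, calls = calls, profiles = profiles,
                 ld_report = ld, qc_summary = qc, imputation = imputation,
                 paths = paths))
}
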