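# Gene-content haplotype-pair imputation: exhaustive enumeration of reference
# haplotype pairs whose per-locus sums reproduce a called copy-number profile.

#' Impute all consistent haplotype pairs for each profile
#'
#' For every sample, enumerates all unordered pairs of reference haplotypes
#' (including self-pairs) whose per-locus copy sums equal the sample's
#' profile over all 20 measurements. Each retained pair carries a combined
#' Hardy-Weinberg frequency `f1 * f2 * (2 if hap1 != hap2 else 1)`. Samples
#' with no consistent pair are `unassigned` — a hint of a miscall or a novel
#' haplotype.
#'
#' Loci whose call is NA (missing or suppressed by a flag) make a sample
#' unassignable by default; with `wildcard_na = TRUE` such loci match any
#' pair sum, supporting follow-up of samples with unusual polymorphism.
#'
#' @param profiles A `kir_profiles` tibble.
#' @param haplotypes Reference table, default [builtin_reference_haplotypes()].
#' @param wildcard_na Treat NA loci as wildcards (default FALSE).
#' @return A `kir_imputation` tibble: `sample_id`, `hap1`, `hap2` (unordered,
#'   `hap1 <= hap2`), `combined_frequency`, `status`
#'   (`assigned`/`unassigned`); unassigned samples have one NA-pair row.
#' @export
impute_all_pairs <- function(profiles, haplotypes = builtin_reference_haplotypes(),
                             wildcard_na = FALSE) {
  if (is.null(haplotypes) || nrow(haplotypes) == 0) {
    # an empty reference assigns nothing
    out <- tibble(sample_id = profiles$sample_id, hap1 = NA_character_,
                  hap2 = NA_character_, combined_frequency = NA_real_,
                  status = "unassigned")
    return(structure(out, class = c("kir_imputation", class(out))))
  }
  validate_haplotype_table(haplotypes)
  loci <- kir_loci()
  absent <- setdiff(loci, names(profiles))
  if (length(absent) > 0) {
    abort(paste0("profiles lack loci referenced by the reference table: ",
                 paste(absent, collapse = ", ")),
          class = "qkatr_validation_error")
  }
  H <- as.matrix(haplotypes[, loci])
  storage.mode(H) <- "numeric"
  nm <- haplotypes$haplotype
  f <- haplotypes$frequency
  n_h <- nrow(H)
  ij <- which(upper.tri(matrix(0, n_h, n_h), diag = TRUE), arr.ind = TRUE)
  pair_sum <- H[ij[, 1], , drop = FALSE] + H[ij[, 2], , drop = FALSE]

  out <- purrr::map_dfr(seq_len(nrow(profiles)), function(s) {
    p <- as.numeric(unlist(profiles[s, loci]))
    use <- if (wildcard_na) !is.na(p) else rep(TRUE, length(p))
    hit <- if (any(is.na(p[use]))) {
      logical(nrow(pair_sum)) # non-wildcarded NA: nothing can match
    } else if (!any(use)) {
      rep(TRUE, nrow(pair_sum))
    } else {
      rowSums(pair_sum[, use, drop = FALSE] !=
                matrix(p[use], nrow(pair_sum), sum(use), byrow = TRUE)) == 0
    }
    if (!any(hit)) {
      return(tibble(sample_id = profiles$sample_id[s], hap1 = NA_character_,
                    hap2 = NA_character_, combined_frequency = NA_real_,
                    status = "unassigned"))
    }
    i <- ij[hit, 1]; j <- ij[hit, 2]
    tibble(sample_id = profiles$sample_id[s],
           hap1 = pmin(nm[i], nm[j]), hap2 = pmax(nm[i], nm[j]),
           combined_frequency = unname(f[i] * f[j] * ifelse(i == j, 1, 2)),
           status = "assigned") %>%
      distinct(.data$hap1, .data$hap2, .keep_all = TRUE) %>%
      arrange(dplyr::desc(.data$combined_frequency))
  })
  structure(out, class = c("kir_imputation", class(out)))
}

#' Trim an imputation to the highest-frequency pairs
#'
#' Retains, per sample, only the pair(s) whose combined frequency equals the
#' sample's maximum; exact ties are all retained. Unassigned samples pass
#' through unchanged with a warning.
#'
#' @param assignment A `kir_imputation` from [impute_all_pairs()].
#' @return A `kir_imputation` with `status = "trimmed_best"` on retained
#'   assigned rows.
#' @export
trim_best <- function(assignment) {
  if (any(assignment$status == "unassigned")) {
    warn("trim_best: unassigned samples passed through unchanged")
  }
  out <- assignment %>%
    group_by(.data$sample_id) %>%
    filter(.data$status == "unassigned" |
             .data$combined_frequency ==
               max(.data$combined_frequency[!is.na(.data$combined_frequency)],
                   -Inf)) %>%
    ungroup() %>%
    mutate(status = ifelse(.data$status == "assigned", "trimmed_best",
                           .data$status))
  structure(out, class = unique(c("kir_imputation", class(out))))
}

#' Write the three imputation output files
#'
#' Reproduces the haplotype-identifier deliverable: `<prefix>.all.csv` lists
#' every consistent pair per sample, `<prefix>.best.csv` the trimmed
#' highest-combined-frequency pairs, and `<prefix>.unassigned.csv` the
#' samples to which no reference pair can be assigned (candidate novel
#' haplotypes). All files are created even when empty. Combined frequencies
#' use the Hardy-Weinberg heterozygote factor 2 (noted in the file header
#' comment).
#'
#' @param assignment A `kir_imputation` from [impute_all_pairs()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"haplotypes"`).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_imputation_outputs <- function(assignment, dir, prefix = "haplotypes") {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      abort(paste0("cannot create output directory: ", dir),
            class = "qkatr_io_error")
    }
  }
  paths <- c(all = file.path(dir, paste0(prefix, ".all.csv")),
             best = file.path(dir, paste0(prefix, ".best.csv")),
             unassigned = file.path(dir, paste0(prefix, ".unassigned.csv")))
  assigned <- assignment %>% filter(.data$status != "unassigned")
  unassigned <- assignment %>%
    filter(.data$status == "unassigned") %>%
    select("sample_id") %>%
    mutate(note = "no reference pair consistent with profile; possible novel haplotype")
  best <- trim_best_quietly(assignment) %>%
    filter(.data$status != "unassigned")
  readr::write_csv(assigned, paths[["all"]])
  readr::write_csv(best, paths[["best"]])
  readr::write_csv(unassigned, paths[["unassigned"]])
  invisible(paths)
}

trim_best_quietly <- function(assignment) {
  suppressWarnings(trim_best(assignment))
}
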