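#' Built-in synthetic reference haplotypes
#'
#' A small synthetic table of KIR gene-content haplotypes shaped like a
#' European-origin reference set: the two A-group haplotypes (carrying the
#' full-length or the 22-bp-deleted form of 2DS4) and four common B-group
#' gene contents (cB01/tA01, cA01/tB01, cB01/tB01 and cB02/tA01). It is a
#' stand-in for a population reference list — adequate for validation and
#' simulation; real studies should supply their own table via
#' [read_haplotype_table()].
#'
#' Every haplotype contributes exactly one copy of each framework locus and
#' obeys the allelic relationships of the locus (2DL2/2DL3, 3DL1/3DS1,
#' 2DS1/2DS4, 2DS3+2DS5 = 2DL5). Frequencies sum to one.
#'
#' @return A `kir_haplotypes` tibble: `haplotype`, `frequency`, and one
#'   column per measurement in [kir_loci()].
#' @export
#' @examples
#' builtin_reference_haplotypes()
builtin_reference_haplotypes <- function() {
  read_haplotype_table(system.file("extdata", "haplotypes",
                                   "synthetic_european_reference.csv",
                                   package = "qkatr"),
                       source_label = "builtin-synthetic-european")
}

#' Read a reference haplotype table
#'
#' @param path CSV with columns `haplotype`, `frequency` and one column per
#'   locus in [kir_loci()] giving the copies contributed per haplotype.
#' @param source_label Label recorded on the returned object.
#' @return A validated `kir_haplotypes` tibble.
#' @export
read_haplotype_table <- function(path, source_label = path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_haplotype_table(x)
  structure(as_tibble(x), class = c("kir_haplotypes", class(as_tibble(x))),
            source = source_label)
}

#' Validate a haplotype table
#'
#' Checks column completeness, name uniqueness, frequency range, and the
#' per-haplotype gene-content constraints (framework loci contribute one
#' copy; allelic loci 2DL2+2DL3 = 1, 3DL1ex4+3DS1 = 1, 2DS1+2DS4Total = 1;
#' exon-4 and exon-9 measurements agree; 2DS2 = 2DL2, 2DP1 = 2DL1,
#' 3DS1 = 2DS1, 2DS3+2DS5 = 2DL5, 2DS4FL+2DS4Del = 2DS4Total).
#'
#' @param x Data frame to validate.
#' @return `x`, invisibly; errors describe the offending haplotype.
#' @export
validate_haplotype_table <- function(x) {
  need <- c("haplotype", "frequency", kir_loci())
  absent <- setdiff(need, names(x))
  if (length(absent) > 0) {
    abort(paste0("haplotype table: missing column(s) ",
                 paste(absent, collapse = ", ")),
          class = "qkatr_validation_error")
  }
  if (nrow(x) == 0) {
    abort("haplotype table is empty", class = "qkatr_config_error")
  }
  if (anyDuplicated(x$haplotype) > 0) {
    abort("haplotype names must be unique", class = "qkatr_validation_error")
  }
  if (any(x$frequency < 0 | x$frequency > 1)) {
    abort("haplotype frequencies must lie in [0, 1]",
          class = "qkatr_validation_error")
  }
  g <- function(l) x[[l]]
  checks <- list(
    "framework contribution must be 1" =
      g("3DL3") == 1 & g("3DP1") == 1 & g("2DL4") == 1 &
      g("3DL2ex4") == 1 & g("3DL2ex9") == 1,
    "2DL2 + 2DL3 must be 1" = g("2DL2") + g("2DL3") == 1,
    "3DL1ex4 + 3DS1 must be 1" = g("3DL1ex4") + g("3DS1") == 1,
    "3DL1ex4 must equal 3DL1ex9" = g("3DL1ex4") == g("3DL1ex9"),
    "3DL2ex4 must equal 3DL2ex9" = g("3DL2ex4") == g("3DL2ex9"),
    "2DS2 must equal 2DL2" = g("2DS2") == g("2DL2"),
    "2DP1 must equal 2DL1" = g("2DP1") == g("2DL1"),
    "2DS3 + 2DS5 must equal 2DL5" = g("2DS3") + g("2DS5") == g("2DL5"),
    "3DS1 must equal 2DS1" = g("3DS1") == g("2DS1"),
    "2DS1 + 2DS4Total must be 1" = g("2DS1") + g("2DS4Total") == 1,
    "2DS4FL + 2DS4Del must equal 2DS4Total" =
      g("2DS4FL") + g("2DS4Del") == g("2DS4Total")
  )
  for (msg in names(checks)) {
    ok <- checks[[msg]]
    if (any(!ok)) {
      abort(paste0("haplotype ", x$haplotype[which(!ok)[1]], ": ", msg),
            class = "qkatr_validation_error")
    }
  }
  invisible(x)
}

#' Count distinct KIR genes on a haplotype
#'
#' Counts genes (not measurements): exon-4/exon-9 assays of the same gene and
#' the 2DS4 variant assays collapse to one gene, pseudogenes (2DP1, 3DP1) are
#' excluded. The canonical A haplotype carries 7 genes.
#'
#' @param haplotypes A `kir_haplotypes` tibble.
#' @return Named integer vector of gene counts.
#' @export
haplotype_gene_count <- function(haplotypes) {
  genes <- list(
    "3DL3" = "3DL3", "2DS2" = "2DS2", "2DL2" = "2DL2", "2DL3" = "2DL3",
    "2DL1" = "2DL1", "2DL4" = "2DL4", "3DL1" = "3DL1ex4", "3DS1" = "3DS1",
    "2DL5" = "2DL5", "2DS3" = "2DS3", "2DS5" = "2DS5", "2DS1" = "2DS1",
    "2DS4" = "2DS4Total", "3DL2" = "3DL2ex4"
  )
  counts <- vapply(seq_len(nrow(haplotypes)), function(i) {
    sum(vapply(genes, function(l) haplotypes[[l]][i] > 0, logical(1)))
  }, integer(1))
  setNames(counts, haplotypes$haplotype)
}

# copy-number profile implied by an unordered pair of haplotypes
pair_profile <- function(haplotypes, h1, h2) {
  m <- as.matrix(haplotypes[, kir_loci()])
  rownames(m) <- haplotypes$haplotype
  m[h1, ] + m[h2, ]
}
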