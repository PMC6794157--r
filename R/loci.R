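#' The 20 KIR measurements typed by the qKAT panel
#'
#' The panel types 16 KIR genes via 20 measurements: 3DL1 and 3DL2 are each
#' measured twice (exon 4 and exon 9 assays), and 2DS4 is resolved into the
#' full-length form, the 22-bp-deleted form and their total. 2DL5 counts
#' 2DL5A and 2DL5B jointly. 2DP1 and 3DP1 are pseudogenes.
#'
#' @return Character vector of the 20 locus (measurement) names, in panel
#'   order.
#' @export
#' @examples
#' kir_loci()
kir_loci <- function() {
  c("3DL3", "2DS2", "2DL2", "2DL3", "2DP1", "2DL1", "3DP1", "2DL4",
    "3DL1ex4", "3DL1ex9", "3DS1", "2DL5", "2DS3", "2DS5", "2DS1",
    "2DS4Total", "2DS4FL", "2DS4Del", "3DL2ex4", "3DL2ex9")
}

#' Framework loci
#'
#' 3DL3, 3DP1, 2DL4 and 3DL2 are present on essentially all haplotypes, so
#' every sample is expected to carry two copies. 3DL2 is measured by both its
#' exon-4 and exon-9 assays.
#'
#' @return Character vector of framework measurement names.
#' @export
kir_framework_loci <- function() {
  c("3DL3", "3DP1", "2DL4", "3DL2ex4", "3DL2ex9")
}

# Fluorescence filter tokens of the three optical channels, as exported by
# the instrument: FAM (green, KIR target a), ATTO550/VIC/HEX (yellow, STAT6),
# ATTO647N/Cy5 (red, KIR target b).
kir_channels <- function() {
  c(green = "465-510", yellow = "533-580", red = "618-660")
}

reference_locus <- function() "STAT6"

# Cq value used to mark wells with no amplification inside numeric vectors;
# user-facing tables carry NA instead.
is_dropout <- function(cq) is.na(cq)
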