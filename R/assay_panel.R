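#' Load the qKAT assay panel
#'
#' Reads the panel definition — primers, hydrolysis probes, the ten multiplex
#' reactions and the most-frequent (default) copy numbers observed in
#' European-origin samples — and validates its structure. Each reaction
#' amplifies two KIR targets and the fixed-copy reference gene STAT6, read on
#' the green (FAM), red (ATTO647N) and yellow (ATTO550) filters respectively.
#'
#' @param path Directory containing `primers.csv`, `probes.csv`,
#'   `reactions.csv` and `defaults.csv`. Defaults to the packaged panel.
#' @return A `kir_panel` object: a list with tibbles `primers`, `probes`,
#'   `reactions` and `defaults`, plus the locus vector `loci`.
#' @export
#' @examples
#' panel <- load_assay_panel()
#' panel
load_assay_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "panel", package = "qkatr")
  }
  files <- c("primers.csv", "probes.csv", "reactions.csv", "defaults.csv")
  missing <- files[!file.exists(file.path(path, files))]
  if (length(missing) > 0) {
    abort(paste0("panel fixture incomplete: missing ", paste(missing, collapse = ", "),
                 " in ", path), class = "qkatr_parse_error")
  }
  read_tbl <- function(f, cols) {
    x <- readr::read_csv(file.path(path, f), show_col_types = FALSE,
                         progress = FALSE)
    absent <- setdiff(cols, names(x))
    if (length(absent) > 0) {
      abort(paste0(f, ": missing column(s) ", paste(absent, collapse = ", ")),
            class = "qkatr_parse_error")
    }
    x
  }
  primers <- read_tbl("primers.csv",
                      c("assay", "locus", "primer", "direction", "sequence",
                        "length_nt", "gc_percent", "start_pos", "end_pos",
                        "amplicon_bp"))
  probes <- read_tbl("probes.csv",
                     c("probe", "sense", "dye_5p", "quencher_3p", "sequence",
                       "length_nt", "gc_percent"))
  reactions <- read_tbl("reactions.csv",
                        c("reaction_number", "role", "locus", "fwd_primer",
                          "rev_primer", "probe", "channel",
                          "fwd_nM", "rev_nM", "probe_nM"))
  defaults <- read_tbl("defaults.csv", c("locus", "default_cn"))
  reactions$reaction_number <- as.integer(reactions$reaction_number)
  defaults$default_cn <- as.integer(defaults$default_cn)

  bad_dir <- primers %>%
    mutate(.row = row_number()) %>%
    filter(!.data$direction %in% c("forward", "reverse"))
  if (nrow(bad_dir) > 0) {
    abort(paste0("primers.csv row ", bad_dir$.row[1], " (", bad_dir$primer[1],
                 "): direction must be forward/reverse"),
          class = "qkatr_parse_error")
  }
  bad_seq <- primers %>%
    mutate(.row = row_number()) %>%
    filter(stringr::str_detect(.data$sequence, "[^ACGT]"))
  if (nrow(bad_seq) > 0) {
    abort(paste0("primers.csv row ", bad_seq$.row[1], " (", bad_seq$primer[1],
                 "): sequence contains non-ACGT characters"),
          class = "qkatr_parse_error")
  }

  panel <- structure(
    list(primers = primers, probes = probes, reactions = reactions,
         defaults = defaults, loci = kir_loci()),
    class = "kir_panel"
  )
  check_panel_structure(panel)
  panel
}

# Structural invariants of the ten-reaction design.
check_panel_structure <- function(panel) {
  rx <- panel$reactions
  nums <- sort(unique(rx$reaction_number))
  if (!identical(nums, 1:10) && !identical(as.numeric(nums), as.numeric(1:10))) {
    abort("panel must contain reactions numbered 1-10, each once",
          class = "qkatr_validation_error")
  }
  by_rx <- rx %>% group_by(.data$reaction_number) %>%
    summarise(n_probes = n(),
              has_ref = any(.data$locus == reference_locus()),
              .groups = "drop")
  if (any(by_rx$n_probes != 3)) {
    abort(paste0("reaction ", by_rx$reaction_number[by_rx$n_probes != 3][1],
                 ": expected exactly three probes"),
          class = "qkatr_validation_error")
  }
  if (any(!by_rx$has_ref)) {
    abort(paste0("reaction ", by_rx$reaction_number[!by_rx$has_ref][1],
                 ": STAT6 reference missing"),
          class = "qkatr_validation_error")
  }
  kir_rows <- rx %>% filter(.data$role != "reference")
  if (anyDuplicated(kir_rows$locus) > 0) {
    abort(paste0("locus targeted by more than one reaction: ",
                 kir_rows$locus[duplicated(kir_rows$locus)][1]),
          class = "qkatr_validation_error")
  }
  if (!setequal(kir_rows$locus, panel$loci)) {
    abort("panel reactions must target the 20 KIR measurements exactly once each",
          class = "qkatr_validation_error")
  }
  if (!setequal(panel$defaults$locus, panel$loci) ||
      anyDuplicated(panel$defaults$locus) > 0) {
    abort("defaults table must list each of the 20 loci exactly once",
          class = "qkatr_validation_error")
  }
  invisible(panel)
}

#' @export
print.kir_panel <- function(x, ...) {
  cat("qKAT assay panel: 10 multiplex reactions, ",
      length(x$loci), " KIR measurements + ", reference_locus(), "\n", sep = "")
  map <- panel_channel_map(x) %>% filter(.data$locus != reference_locus())
  for (r in 1:10) {
    tg <- map$locus[map$reaction_number == r]
    cat(sprintf("  reaction %2d: %s\n", r, paste(tg, collapse = " + ")))
  }
  invisible(x)
}

#' Reaction/channel map of a panel
#'
#' @param panel A `kir_panel`.
#' @return Tibble with `reaction_number`, `channel` (filter token), `role`
#'   and `locus`, one row per optical channel of each reaction.
#' @export
panel_channel_map <- function(panel) {
  panel$reactions %>%
    select("reaction_number", "channel", "role", "locus")
}

#' Default (most frequent) copy number per locus
#'
#' @param panel A `kir_panel`.
#' @return Named integer vector over the 20 loci.
#' @export
panel_default_cn <- function(panel) {
  setNames(as.integer(panel$defaults$default_cn), panel$defaults$locus)
}

#' GC content of a DNA sequence
#'
#' Percentage of G and C bases, rounded half-away-from-zero to one decimal
#' place (the convention used in the printed assay tables).
#'
#' @param sequence Character vector of A/C/G/T strings.
#' @return Numeric vector of percentages with one decimal.
#' @export
#' @examples
#' gc_percent("GCCCCTGCTGAAATCAGG") # 61.1
gc_percent <- function(sequence) {
  if (length(sequence) == 0 || any(is.na(sequence)) || any(nchar(sequence) == 0)) {
    abort("sequence must be non-empty", class = "qkatr_validation_error")
  }
  if (any(stringr::str_detect(sequence, "[^ACGT]"))) {
    abort("sequence must contain only A/C/G/T",
          class = "qkatr_validation_error")
  }
  raw <- 100 * stringr::str_count(sequence, "[GC]") / nchar(sequence)
  round_half_away(raw, 1)
}

# round-half-away-from-zero, the convention reproducing the printed GC% cells
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Amplicon length from primer coordinates
#'
#' Length of the amplified product on the 1-based inclusive coding-sequence
#' coordinates carried by the panel: `rev end - fwd start + 1`.
#'
#' @param fwd,rev Single-row data frames (or named lists) with `start_pos`
#'   and `end_pos`; `fwd` is the forward primer, `rev` the reverse.
#' @return Integer length in nucleotides.
#' @export
#' @examples
#' amplicon_length(list(start_pos = 399, end_pos = 416),
#'                 list(start_pos = 559, end_pos = 577)) # 179
amplicon_length <- function(fwd, rev) {
  s <- fwd[["start_pos"]]
  e <- rev[["end_pos"]]
  if (is.null(s) || is.null(e) || is.na(s) || is.na(e)) {
    abort("amplicon length needs primer positions on a shared coordinate system",
          class = "qkatr_unsupported_error")
  }
  as.integer(e - s + 1)
}

#' Cross-check a panel against its printed columns
#'
#' Recomputes every primer and probe length, GC% and amplicon size from the
#' sequences and coordinates, and compares with the values stored from the
#' published tables. An empty result means the panel is self-consistent.
#' For assays with two forward primers (3DL3) the amplicon is computed from
#' the outermost forward start; STAT6 carries no coordinates, so its printed
#' amplicon size is kept as a literal and not recomputed.
#'
#' @param panel A `kir_panel`.
#' @return Tibble of discrepancies with columns `table`, `name`, `field`,
#'   `printed`, `computed`; zero rows when all cells reproduce.
#' @export
validate_panel <- function(panel) {
  disc <- list()
  add <- function(table, name, field, printed, computed) {
    tibble(table = table, name = name, field = field,
           printed = as.numeric(printed), computed = as.numeric(computed))
  }

  pr <- panel$primers
  len <- nchar(pr$sequence)
  bad <- which(len != pr$length_nt)
  for (i in bad) disc[[length(disc) + 1]] <-
    add("primers", pr$primer[i], "length_nt", pr$length_nt[i], len[i])

  gc <- gc_percent(pr$sequence)
  bad <- which(abs(gc - pr$gc_percent) > 1e-9)
  for (i in bad) disc[[length(disc) + 1]] <-
    add("primers", pr$primer[i], "gc_percent", pr$gc_percent[i], gc[i])

  span <- which(!is.na(pr$start_pos) & !is.na(pr$end_pos))
  slen <- pr$end_pos[span] - pr$start_pos[span] + 1
  bad <- span[slen != pr$length_nt[span]]
  for (i in bad) disc[[length(disc) + 1]] <-
    add("primers", pr$primer[i], "position_span",
        pr$length_nt[i], pr$end_pos[i] - pr$start_pos[i] + 1)

  amp <- pr %>%
    filter(!is.na(.data$start_pos)) %>%
    group_by(.data$assay) %>%
    summarise(
      computed = amplicon_length(
        list(start_pos = min(.data$start_pos[.data$direction == "forward"])),
        list(end_pos = max(.data$end_pos[.data$direction == "reverse"]))),
      printed = .data$amplicon_bp[1], .groups = "drop")
  bad <- which(amp$computed != amp$printed)
  for (i in bad) disc[[length(disc) + 1]] <-
    add("primers", amp$assay[i], "amplicon_bp", amp$printed[i], amp$computed[i])

  pb <- panel$probes
  len <- nchar(pb$sequence)
  bad <- which(len != pb$length_nt)
  for (i in bad) disc[[length(disc) + 1]] <-
    add("probes", pb$probe[i], "length_nt", pb$length_nt[i], len[i])
  gc <- gc_percent(pb$sequence)
  bad <- which(abs(gc - pb$gc_percent) > 1e-9)
  for (i in bad) disc[[length(disc) + 1]] <-
    add("probes", pb$probe[i], "gc_percent", pb$gc_percent[i], gc[i])

  if (length(disc) == 0) {
    tibble(table = character(), name = character(), field = character(),
           printed = numeric(), computed = numeric())
  } else {
    bind_rows(disc)
  }
}
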