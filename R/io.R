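# Plate-export plumbing: the documented tab-delimited export dialect
# (header: plate, well, sample, filter, cq), the 96-to-384 quadruplicate
# geometry, and the per-reaction splitter that turns raw exports into typed
# Cq tables.

valid_wells_384 <- function() {
  paste0(rep(LETTERS[1:16], each = 24), rep(1:24, times = 16))
}

#' Parse an instrument-style plate export
#'
#' Reads one tab-delimited export file with columns `plate`, `well`,
#' `sample`, `filter`, `cq`. Empty `cq` fields are preserved as dropout
#' (`NA`). Rows with an invalid 384-well position or an unknown filter name
#' are collected into a problem report; with `strict = TRUE` (default) any
#' problem is an error naming the offending row, otherwise problem rows are
#' returned in the `problems` attribute. A duplicated (well, filter)
#' combination is always a conflict error.
#'
#' @param path Export file.
#' @param strict Error on malformed rows (default) or collect them.
#' @return A `kir_plate_export` tibble (`plate_id`, `well`, `sample`,
#'   `filter`, `cq`) with attribute `problems`.
#' @export
parse_plate_export <- function(path, strict = TRUE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    plate = readr::col_character(), well = readr::col_character(),
    sample = readr::col_character(), filter = readr::col_character(),
    cq = readr::col_double()), progress = FALSE)
  need <- c("plate", "well", "sample", "filter", "cq")
  if (!all(need %in% names(raw))) {
    abort(paste0(path, ": export must have columns ",
                 paste(need, collapse = ", ")), class = "qkatr_parse_error")
  }
  raw <- raw %>% mutate(.row = row_number() + 1L) # +1: header line
  problems <- bind_rows(
    raw %>% filter(!.data$well %in% valid_wells_384()) %>%
      mutate(problem = "invalid 384-well position"),
    raw %>% filter(!.data$filter %in% kir_channels()) %>%
      mutate(problem = "unknown filter name")
  )
  if (nrow(problems) > 0 && strict) {
    p <- problems[1, ]
    abort(paste0(path, " line ", p$.row, ": ", p$problem, " ('",
                 if (p$problem == "unknown filter name") p$filter else p$well,
                 "')"), class = "qkatr_parse_error")
  }
  ok <- raw %>% dplyr::anti_join(problems, by = ".row")
  dup <- ok %>% count(.data$well, .data$filter) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(path, ": duplicate well/filter ", dup$well[1], "/",
                 dup$filter[1]), class = "qkatr_conflict_error")
  }
  out <- ok %>%
    select(plate_id = "plate", "well", sample_id = "sample",
           "filter", "cq")
  structure(out, class = c("kir_plate_export", class(out)),
            problems = problems %>% select("well", "filter", "problem",
                                           line = ".row"))
}

#' Write Cq tables as plate-export files
#'
#' Inverse of [parse_plate_export()]: writes one tab-delimited export per
#' plate in the documented dialect.
#'
#' @param cq_tbl A `kir_cq` tibble (e.g. from [synthesize_cq()]).
#' @param dir Output directory (created if needed).
#' @return Tibble `plate_id`, `path` of written files, invisibly.
#' @export
write_plate_export <- function(cq_tbl, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plates <- unique(cq_tbl$plate_id)
  paths <- vapply(plates, function(p) {
    out <- cq_tbl %>%
      filter(.data$plate_id == p) %>%
      select(plate = "plate_id", "well", sample = "sample_id",
             filter = "channel", "cq")
    path <- file.path(dir, paste0(p, ".txt"))
    readr::write_tsv(out, path, na = "")
    path
  }, character(1))
  invisible(tibble(plate_id = plates, path = unname(paths)))
}

#' Manifest mapping plates to reactions
#'
#' The default naming convention `R<reaction>-P<set>` is decoded to a
#' manifest; exports named differently need an explicit manifest.
#'
#' @param plate_ids Character vector of plate identifiers.
#' @return Tibble `plate_id`, `reaction_number`.
#' @export
default_manifest <- function(plate_ids) {
  m <- stringr::str_match(plate_ids, "^R(\\d+)")
  tibble(plate_id = plate_ids,
         reaction_number = as.integer(m[, 2]))
}

# 384-well position -> (source 96-well, replicate index within 2x2 block)
well384_to_source <- function(well) {
  r <- match(stringr::str_sub(well, 1, 1), LETTERS)
  c <- as.integer(stringr::str_sub(well, 2))
  sr <- (r + 1) %/% 2
  sc <- (c + 1) %/% 2
  list(source_well = paste0(LETTERS[sr], sc),
       replicate = 1L + 2L * ((r - 1) %% 2) + (c - 1) %% 2)
}

#' Split plate exports into per-reaction Cq tables
#'
#' Maps each export's filters to loci through the panel's channel map for
#' the plate's reaction, reconstructs the quadruplicate groups from the
#' 96-to-384 block geometry, and returns one typed Cq table covering all
#' plates.
#'
#' @param exports A `kir_plate_export` or list of them.
#' @param panel A `kir_panel`.
#' @param manifest Tibble `plate_id`, `reaction_number`; defaults to
#'   decoding the `R<reaction>-P<set>` naming convention.
#' @return A `kir_cq` tibble.
#' @export
split_by_reaction <- function(exports, panel = load_assay_panel(),
                              manifest = NULL) {
  if (inherits(exports, "kir_plate_export")) exports <- list(exports)
  all <- bind_rows(lapply(exports, as_tibble))
  if (is.null(manifest)) manifest <- default_manifest(unique(all$plate_id))
  unmapped <- setdiff(unique(all$plate_id), manifest$plate_id[
    !is.na(manifest$reaction_number)])
  if (length(unmapped) > 0) {
    abort(paste0("no manifest entry for plate ", unmapped[1]),
          class = "qkatr_config_error")
  }
  map <- panel_channel_map(panel)
  out <- all %>%
    inner_join(manifest, by = "plate_id") %>%
    left_join(map, by = c("reaction_number", "filter" = "channel"))
  bad <- out %>% filter(is.na(.data$locus))
  if (nrow(bad) > 0) {
    abort(paste0("reaction ", bad$reaction_number[1],
                 ": filter ", bad$filter[1], " maps to no locus"),
          class = "qkatr_config_error")
  }
  src <- well384_to_source(out$well)
  out <- out %>%
    mutate(source_well = src$source_well, replicate = src$replicate,
           channel = .data$filter) %>%
    filter(!is.na(.data$sample_id) & .data$sample_id != "")
  # the four wells of a block must carry one sample
  mixed <- out %>%
    group_by(.data$plate_id, .data$source_well) %>%
    summarise(n_samples = n_distinct(.data$sample_id), .groups = "drop") %>%
    filter(.data$n_samples > 1)
  if (nrow(mixed) > 0) {
    abort(paste0("plate ", mixed$plate_id[1], " block ",
                 mixed$source_well[1],
                 ": replicate wells carry different samples"),
          class = "qkatr_conflict_error")
  }
  out <- out %>%
    select("plate_id", "reaction_number", "well", "source_well", "sample_id",
           "replicate", "channel", "locus", "cq") %>%
    arrange(.data$reaction_number, .data$sample_id, .data$replicate)
  structure(out, class = c("kir_cq", class(out)))
}

#' Read a long-format amplification-curve table
#'
#' @param path CSV with columns `well`, `channel`, `cycle`, `fluorescence`
#'   (plus optional identity columns, preserved).
#' @return Tibble of curves for [call_cq()].
#' @export
read_curve_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("well", "channel", "cycle", "fluorescence")
  if (!all(need %in% names(x))) {
    abort("curve table needs columns well, channel, cycle, fluorescence",
          class = "qkatr_parse_error")
  }
  as_tibble(x)
}
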