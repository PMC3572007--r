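SPOT_COLS <- c("array_id", "probe_id", "probe_class",
               "ch_sample_fg", "ch_sample_bg", "ch_sample_bg_sd",
               "ch_sample_frac_px2sd",
               "ch_ref_fg", "ch_ref_bg", "ch_ref_bg_sd", "ch_ref_frac_px2sd")

#' Read a spot table
#'
#' Reads the TSV spot-table dialect written by [write_spot_tables()]: one
#' record per spot with two-channel foreground/background statistics.
#'
#' @param path Path to a TSV file.
#' @return Tibble in spot-record form.
#' @export
read_spot_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(SPOT_COLS, names(out))
  if (length(missing)) {
    abort(paste0("spot table misses column(s): ", paste(missing, collapse = ", ")))
  }
  out[SPOT_COLS]
}

#' Write spot tables, one TSV per array
#'
#' @param spots Spot tibble (possibly several arrays; split on `array_id`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the written paths.
#' @export
write_spot_tables <- function(spots, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- map_chr(split(spots[SPOT_COLS], spots$array_id), function(tab) {
    path <- file.path(dir, paste0(tab$array_id[1], ".tsv"))
    readr::write_tsv(tab, path, progress = FALSE)
    path
  })
  invisible(unname(paths))
}

#' Read a GenePix-style GPR table into spot-record form
#'
#' Maps the familiar GenePix column names (`F635 Mean`, `B635 Mean`,
#' `B635 SD`, `% > B635+2SD`, and the 532-channel equivalents) onto the
#' two-channel spot dialect, treating 635 nm as the sample channel and
#' 532 nm as the reference channel.
#'
#' @param path Path to a tab-separated GPR-like file with those columns plus
#'   `ID` and optionally `Flags`.
#' @param array_id Array identifier to stamp on the records.
#' @return Tibble in spot-record form; probe classes guessed from the id
#'   prefix (`CAL`, `POS`, `NEG`), all other spots `mirna`.
#' @export
read_gpr_table <- function(path, array_id) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("ID", "F635 Mean", "B635 Mean", "B635 SD", "% > B635+2SD",
            "F532 Mean", "B532 Mean", "B532 SD", "% > B532+2SD")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("GPR table misses column(s): ", paste(missing, collapse = ", ")))
  }
  tibble(
    array_id = array_id,
    probe_id = raw$ID,
    probe_class = case_when(
      startsWith(raw$ID, "CAL") ~ "calibration",
      startsWith(raw$ID, "POS") ~ "position_control",
      startsWith(raw$ID, "NEG") ~ "negative_control",
      TRUE ~ "mirna"
    ),
    ch_sample_fg = raw[["F635 Mean"]],
    ch_sample_bg = raw[["B635 Mean"]],
    ch_sample_bg_sd = raw[["B635 SD"]],
    ch_sample_frac_px2sd = raw[["% > B635+2SD"]] / 100,
    ch_ref_fg = raw[["F532 Mean"]],
    ch_ref_bg = raw[["B532 Mean"]],
    ch_ref_bg_sd = raw[["B532 SD"]],
    ch_ref_frac_px2sd = raw[["% > B532+2SD"]] / 100
  )
}

#' Write / read an abundance matrix with its detection mask
#'
#' The values table is samples x miRNAs; a parallel mask table of the same
#' shape holds the detected flags.
#'
#' @param abundance Long tibble (`sample_id`, `mirna`, `value`, `detected`).
#' @param path Path of the values TSV; the mask goes to `<path>.mask.tsv`.
#' @return Invisibly, `path`.
#' @export
write_abundance <- function(abundance, path) {
  vals <- abundance %>%
    select("sample_id", "mirna", "value") %>%
    pivot_wider(names_from = "mirna", values_from = "value")
  mask <- abundance %>%
    select("sample_id", "mirna", "detected") %>%
    pivot_wider(names_from = "mirna", values_from = "detected")
  readr::write_tsv(vals, path, progress = FALSE)
  readr::write_tsv(mask, paste0(path, ".mask.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  vals <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) %>%
    pivot_longer(-"sample_id", names_to = "mirna", values_to = "value")
  mask <- readr::read_tsv(paste0(path, ".mask.tsv"),
                          show_col_types = FALSE, progress = FALSE) %>%
    pivot_longer(-"sample_id", names_to = "mirna", values_to = "detected")
  inner_join(vals, mask, by = c("sample_id", "mirna"))
}

#' Write a gene-set collection in GMT format
#'
#' One set per line: name, description (here the set name again), then the
#' member genes, tab-separated.
#'
#' @param pathways Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  lines <- imap(pathways, function(genes, nm) {
    paste(c(nm, nm, genes), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("GMT reading needs the 'fgsea' package")
  }
  fgsea::gmtPathways(path)
}
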