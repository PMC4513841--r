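# Readers/writers for the package's small tabular dialects. All are plain
# text, lossless round trips, and tolerant of CRLF line endings.

well_cols <- c("well_id", "arm", "outcome", "final_cfu")
plating_cols <- c("plate_id", "condition", "dilution_factor", "volume_ml",
                  "colonies")

#' Read and write well-outcome tables
#'
#' CSV with columns `well_id`, `arm` (`selective`/`titer`), `outcome`
#' (`positive`/`negative`, empty for titer wells) and `final_cfu` (titer
#' wells only), as produced by [simulate_fluctuation_experiment()].
#'
#' @param path File path.
#' @return `read_well_csv()` a tibble; `write_well_csv()` `path`
#'   invisibly.
#' @export
read_well_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    well_id = readr::col_character(),
    arm = readr::col_character(),
    outcome = readr::col_character(),
    final_cfu = readr::col_double()))
  missing <- setdiff(well_cols, names(out))
  if (length(missing) > 0L) {
    abort(sprintf("well CSV missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- !out$arm %in% c("selective", "titer")
  if (any(bad)) {
    abort(sprintf("invalid arm at row %d.", which(bad)[[1]]))
  }
  out
}

#' @rdname read_well_csv
#' @param wells Well-outcome tibble.
#' @export
write_well_csv <- function(wells, path) {
  extra <- setdiff(names(wells), c(well_cols, "mutant_count"))
  if (length(extra) > 0L || !all(well_cols %in% names(wells))) {
    abort("`wells` must have the well-outcome columns.")
  }
  readr::write_csv(wells[, well_cols], path, na = "")
  invisible(path)
}

#' Read and write plating tables
#'
#' CSV with columns `plate_id`, `condition`
#' (`restrictive`/`nonrestrictive`), `dilution_factor`, `volume_ml`,
#' `colonies`, as produced by [simulate_dilution_plating()].
#'
#' @param path File path.
#' @return `read_plating_csv()` a tibble; `write_plating_csv()` `path`
#'   invisibly.
#' @export
read_plating_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    plate_id = readr::col_character(),
    condition = readr::col_character(),
    dilution_factor = readr::col_double(),
    volume_ml = readr::col_double(),
    colonies = readr::col_double()))
  missing <- setdiff(plating_cols, names(out))
  if (length(missing) > 0L) {
    abort(sprintf("plating CSV missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out
}

#' @rdname read_plating_csv
#' @param records Plating tibble.
#' @export
write_plating_csv <- function(records, path) {
  if (!all(plating_cols %in% names(records))) {
    abort("`records` must have the plating columns.")
  }
  readr::write_csv(records[, plating_cols], path)
  invisible(path)
}

#' Gene lengths from FASTA or a two-column table
#'
#' Accepts either a (multi-)FASTA of gene sequences, whose record widths
#' give the lengths, or a two-column tab- or comma-separated table
#' `gene,length`.
#'
#' @param path File path (`.fa`/`.fasta`/`.fna` treated as FASTA; anything
#'   else as a table).
#' @return Named numeric vector of lengths in bp.
#' @export
read_gene_lengths <- function(path) {
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    lens <- setNames(as.numeric(Biostrings::width(seqs)),
                     sub("\\s.*$", "", names(seqs)))
  } else {
    tab <- readr::read_delim(
      path, delim = if (grepl("\\.csv$", path)) "," else "\t",
      col_names = c("gene", "length"),
      col_types = readr::cols(.default = readr::col_character()))
    len <- suppressWarnings(as.numeric(tab$length))
    if (nrow(tab) > 0L && is.na(len[[1]])) {
      # a header line was present; drop it
      tab <- tab[-1L, ]
      len <- len[-1L]
    }
    if (anyNA(len)) abort("non-numeric gene length in table.")
    lens <- setNames(len, tab$gene)
  }
  if (length(lens) == 0L || any(lens < 1)) {
    abort("gene lengths must be >= 1 bp.")
  }
  lens
}

#' Write a JSON report with unit labels
#'
#' All numeric outputs carry explicit unit metadata so rates (per
#' division/generation) and frequencies (per plated cell) are never mixed
#' silently.
#'
#' @param x Named list to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("the jsonlite package is required to write JSON reports.")
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
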