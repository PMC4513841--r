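blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")

#' Parse a tabular alignment hit file
#'
#' Reads the standard 12-column tab-separated alignment format (query id,
#' subject id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score). Comment lines
#' beginning `#` are skipped. Reverse-orientation hits (`qstart > qend`)
#' are normalized by swapping so query intervals always run forward.
#'
#' @param path Path to the TSV file, or a character vector of lines.
#' @return A tibble of alignment hits, one per row (0 rows for an empty
#'   file).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("relE\tg1\t95.0\t100\t5\t0\t90\t10\t500\t580\t1e-30\t180", tf)
#' parse_hit_table(tf)
#' @export
parse_hit_table <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
  else as.character(path)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(!!!setNames(
      list(character(), character(), numeric(), integer(), integer(),
           integer(), integer(), integer(), integer(), integer(),
           numeric(), numeric()), blast_cols)))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed hit record at line %d: expected 12 columns, got %d.",
                  idx[bad[[1]]], lengths(fields)[bad[[1]]]))
  }
  m <- do.call(rbind, fields)
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      abort(sprintf("non-numeric value in column %s at line %d.",
                    blast_cols[j], idx[which(is.na(v))[1]]))
    }
    v
  }
  out <- tibble(qseqid = m[, 1L], sseqid = m[, 2L], pident = num(3L),
                length = as.integer(num(4L)), mismatch = as.integer(num(5L)),
                gapopen = as.integer(num(6L)), qstart = as.integer(num(7L)),
                qend = as.integer(num(8L)), sstart = as.integer(num(9L)),
                send = as.integer(num(10L)), evalue = num(11L),
                bitscore = num(12L))
  flip <- out$qstart > out$qend
  if (any(flip)) {
    tmp <- out$qstart[flip]
    out$qstart[flip] <- out$qend[flip]
    out$qend[flip] <- tmp
  }
  if (any(out$qstart < 1L)) abort("query coordinates must be >= 1.")
  if (any(out$pident < 0 | out$pident > 100)) {
    abort("percent identity must be in [0, 100].")
  }
  out
}

#' Write alignment hits in the tabular dialect
#'
#' @param hits Tibble in the 12-column layout of [parse_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  hits <- as_tibble(hits)[, blast_cols]
  readr::write_tsv(hits, path, col_names = FALSE)
  invisible(path)
}

#' Merged-interval coverage of one gene in one genome
#'
#' Clips the query intervals of all hits for a (gene, genome) pair to
#' `[1, gene_length]`, merges overlapping and book-ended (adjacent)
#' intervals, and returns merged length / gene length.
#'
#' @param qstart,qend 1-based inclusive query coordinates of the hits
#'   (either orientation).
#' @param gene_length Gene length in bp (>= 1).
#' @return Covered fraction in [0, 1].
#' @examples
#' gene_coverage(c(1, 140), c(150, 290), 300)  # 290/300
#' @export
gene_coverage <- function(qstart, qend, gene_length) {
  gene_length <- check_count(gene_length, "gene_length", min = 1L)
  if (length(qstart) != length(qend)) {
    abort("`qstart` and `qend` must have equal length.")
  }
  if (length(qstart) == 0L) return(0)
  lo <- pmax(pmin(qstart, qend), 1)
  hi <- pmin(pmax(qstart, qend), gene_length)
  ok <- lo <= hi
  if (!any(ok)) return(0)
  merged <- IRanges::reduce(IRanges::IRanges(start = lo[ok], end = hi[ok]))
  sum(IRanges::width(merged)) / gene_length
}

#' Gene-by-genome coverage and presence calls
#'
#' Computes merged-interval coverage for every (gene, genome) pair in a
#' hit table and calls a gene present in a genome when its coverage is at
#' least `threshold` (default 0.80, the blastn-alignment cutoff that in
#' practice captures orthologues, including full-length genes carrying
#' frameshifts). Pairs with no hits get coverage 0; genomes with no hits
#' at all must be supplied via `genomes` to appear as all-absent columns.
#'
#' @param hits Tibble from [parse_hit_table()] or [simulate_hit_table()].
#' @param gene_lengths Named numeric vector of gene lengths, or a data
#'   frame with columns `gene` and `length` (see [read_gene_lengths()]).
#' @param genomes Complete genome panel; defaults to the genomes seen in
#'   `hits`.
#' @param threshold Covered-fraction cutoff; comparison is `>=`.
#' @return A tibble of class `presence_matrix` with one row per
#'   (gene, genome): `gene`, `genome`, `coverage`, `present`. The
#'   threshold and gene lengths are attached as attributes.
#' @examples
#' p <- panel_spec(genomes = c("g1", "g2"),
#'                 genes = data.frame(gene = "relE", length = 288),
#'                 presence = data.frame(gene = "relE", genome = "g1",
#'                                       coverage = 1))
#' presence_matrix(simulate_hit_table(p, seed = 1),
#'                 gene_lengths = c(relE = 288), genomes = c("g1", "g2"))
#' @export
presence_matrix <- function(hits, gene_lengths, genomes = NULL,
                            threshold = 0.8) {
  hits <- as_tibble(hits)
  if (is.data.frame(gene_lengths)) {
    if (!all(c("gene", "length") %in% names(gene_lengths))) {
      abort("`gene_lengths` data frame needs columns `gene` and `length`.")
    }
    gene_lengths <- setNames(gene_lengths$length, gene_lengths$gene)
  }
  if (is.null(names(gene_lengths))) {
    abort("`gene_lengths` must be named by gene.")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0 ||
      threshold > 1) {
    abort("`threshold` must be in (0, 1].")
  }
  if (nrow(hits) > 0L) {
    unknown <- setdiff(unique(hits$qseqid), names(gene_lengths))
    if (length(unknown) > 0L) {
      abort(sprintf("hit refers to gene(s) with unknown length: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  genomes <- genomes %||% unique(hits$sseqid)
  if (length(genomes) == 0L) abort("no genomes in hits; supply `genomes`.")
  covered <- if (nrow(hits) > 0L) {
    hits |>
      dplyr::group_by(gene = .data$qseqid, genome = .data$sseqid) |>
      dplyr::summarise(
        coverage = gene_coverage(.data$qstart, .data$qend,
                                 gene_lengths[[dplyr::cur_group()$gene]]),
        .groups = "drop")
  } else {
    tibble(gene = character(), genome = character(), coverage = numeric())
  }
  grid <- tidyr::expand_grid(gene = names(gene_lengths),
                             genome = as.character(genomes))
  out <- grid |>
    dplyr::left_join(covered, by = c("gene", "genome")) |>
    dplyr::mutate(coverage = dplyr::coalesce(.data$coverage, 0),
                  present = .data$coverage >= threshold)
  class(out) <- c("presence_matrix", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "gene_lengths") <- gene_lengths
  out
}

#' Rank candidate negative-selection toxins for a target strain
#'
#' A toxin gene is a usable negative-selection marker in a target strain
#' only if the strain lacks it (no resident antitoxin). Step 1 keeps genes
#' absent from `target_genome`; step 2 computes, for each kept gene, the
#' fraction of panel genomes lacking it, flagging genes absent from
#' strictly more than half the panel as broadly usable. Results are sorted
#' by absence fraction (descending), with ties broken by gene length
#' (ascending, shorter cassettes are easier to amplify) then name.
#'
#' @param matrix A [presence_matrix()].
#' @param target_genome Genome the cassette will be used in.
#' @param panel Character vector of panel genome names (e.g. all non-K12
#'   genomes); defaults to every genome in the matrix except the target.
#' @return A tibble: `gene`, `gene_length`, `absence_fraction`,
#'   `majority_absent`.
#' @export
candidate_toxins <- function(matrix, target_genome, panel = NULL) {
  if (!inherits(matrix, "presence_matrix")) {
    abort("`matrix` must come from presence_matrix().")
  }
  genomes <- unique(matrix$genome)
  if (!target_genome %in% genomes) {
    abort(sprintf("unknown target genome '%s'.", target_genome))
  }
  panel <- panel %||% setdiff(genomes, target_genome)
  missing <- setdiff(panel, genomes)
  if (length(missing) > 0L) {
    abort(sprintf("panel genome(s) not in matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  lengths <- attr(matrix, "gene_lengths")
  in_target <- matrix |>
    dplyr::filter(.data$genome == target_genome, !.data$present) |>
    dplyr::pull("gene")
  matrix |>
    dplyr::filter(.data$gene %in% in_target, .data$genome %in% panel) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(absence_fraction = mean(!.data$present),
                     .groups = "drop") |>
    dplyr::mutate(gene_length = as.numeric(lengths[.data$gene]),
                  majority_absent = .data$absence_fraction > 0.5) |>
    dplyr::arrange(dplyr::desc(.data$absence_fraction), .data$gene_length,
                   .data$gene) |>
    dplyr::select("gene", "gene_length", "absence_fraction",
                  "majority_absent")
}
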