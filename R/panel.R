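#' Specify a synthetic gene-by-genome alignment panel
#'
#' Describes the fixture for coverage-based presence/absence screening: a
#' set of genomes, a set of genes with lengths, and the intended alignment
#' coverage of each (gene, genome) pair. [simulate_hit_table()] turns this
#' into a tabular alignment hit file whose merged-interval coverage matches
#' the intent.
#'
#' @param genomes Character vector of genome names.
#' @param genes Data frame with columns `gene` and `length` (bp, >= 1).
#' @param presence Data frame with columns `gene`, `genome`, `coverage`
#'   (intended covered fraction in [0, 1]). Pairs not listed, or with
#'   coverage 0, produce no hits.
#' @param identity Percent identity reported on simulated hits.
#' @param fragmentation Maximum number of HSPs a present gene may be split
#'   into.
#' @return A `panel_spec` list.
#' @examples
#' panel_spec(
#'   genomes = c("g1", "g2"),
#'   genes = data.frame(gene = "relE", length = 288),
#'   presence = data.frame(gene = "relE", genome = "g1", coverage = 1))
#' @export
panel_spec <- function(genomes, genes, presence, identity = 95,
                       fragmentation = 3) {
  if (!is.character(genomes)) abort("`genomes` must be character names.")
  genes <- as_tibble(genes)
  if (!all(c("gene", "length") %in% names(genes))) {
    abort("`genes` needs columns `gene` and `length`.")
  }
  if (any(genes$length < 1)) abort("gene lengths must be >= 1 bp.")
  if (anyDuplicated(genes$gene)) abort("duplicated gene names.")
  presence <- as_tibble(presence)
  if (!all(c("gene", "genome", "coverage") %in% names(presence))) {
    abort("`presence` needs columns `gene`, `genome`, `coverage`.")
  }
  if (any(presence$coverage < 0 | presence$coverage > 1)) {
    abort("intended coverage must be in [0, 1].")
  }
  if (!all(presence$gene %in% genes$gene)) {
    abort("`presence` refers to genes missing from `genes`.")
  }
  if (!all(presence$genome %in% genomes)) {
    abort("`presence` refers to genomes missing from `genomes`.")
  }
  if (!is.numeric(identity) || identity < 0 || identity > 100) {
    abort("`identity` must be a percent in [0, 100].")
  }
  fragmentation <- check_count(fragmentation, "fragmentation", min = 1L)
  structure(list(genomes = genomes, genes = genes, presence = presence,
                 identity = as.numeric(identity),
                 fragmentation = fragmentation),
            class = "panel_spec")
}

# Place `m` covered bases on a gene of length `len` as `k` disjoint,
# non-adjacent segments; returns a two-column matrix of starts/ends
# (1-based inclusive). Segments never overlap so merged length is exactly m.
place_segments <- function(len, m, k) {
  k <- min(k, m, len - m + 1L)  # need k-1 uncovered gaps of >= 1 bp
  k <- max(k, 1L)
  # random composition of m into k parts >= 1
  cuts <- sort(sample.int(m - 1L, k - 1L))
  seg_len <- diff(c(0L, cuts, m))
  # distribute uncovered slack: k-1 internal gaps get 1 + extra
  slack <- len - m - (k - 1L)
  extra <- if (slack > 0L) {
    as.vector(rmultinom(1L, slack, rep(1, k + 1L)))
  } else rep(0L, k + 1L)
  gaps <- c(extra[1L], extra[seq_len(k - 1L) + 1L] + 1L)  # before each segment
  starts <- cumsum(gaps + c(0L, seg_len[-k])) + 1L
  # first segment start: gaps[1]+1; subsequent add previous segment length
  ends <- starts + seg_len - 1L
  cbind(starts, ends)
}

#' Simulate a tabular alignment hit file for a panel
#'
#' Emits BLAST-tabular-style records (12 columns: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore; the
#' query is the gene) such that the merged query-interval coverage of each
#' (gene, genome) pair equals the panel's intended coverage to within
#' rounding (half a base). Present genes are split into 1 to
#' `fragmentation` non-overlapping HSPs; absent pairs emit nothing.
#'
#' @param panel A [panel_spec()].
#' @param seed Integer seed.
#' @return A tibble of alignment hits (possibly 0 rows) in the 12-column
#'   layout accepted by [parse_hit_table()].
#' @examples
#' p <- panel_spec(genomes = "g1",
#'                 genes = data.frame(gene = "relE", length = 288),
#'                 presence = data.frame(gene = "relE", genome = "g1",
#'                                       coverage = 0.9))
#' simulate_hit_table(p, seed = 1)
#' @export
simulate_hit_table <- function(panel, seed) {
  if (!inherits(panel, "panel_spec")) {
    abort("`panel` must be created with panel_spec().")
  }
  set.seed(check_seed(seed))
  lengths <- setNames(panel$genes$length, panel$genes$gene)
  rows <- purrr::pmap(panel$presence, function(gene, genome, coverage) {
    len <- lengths[[gene]]
    m <- round(coverage * len)
    if (m < 1) return(NULL)
    k <- sample.int(panel$fragmentation, 1L)
    seg <- place_segments(len, m, k)
    dimnames(seg) <- NULL
    n <- nrow(seg)
    alen <- seg[, 2L] - seg[, 1L] + 1L
    tibble(qseqid = gene,
           sseqid = genome,
           pident = panel$identity,
           length = alen,
           mismatch = round((1 - panel$identity / 100) * alen),
           gapopen = 0L,
           qstart = as.integer(seg[, 1L]),
           qend = as.integer(seg[, 2L]),
           sstart = as.integer(seg[, 1L] + 1000L),
           send = as.integer(seg[, 2L] + 1000L),
           evalue = 10^(-round(alen / 10)),
           bitscore = round(1.8 * alen, 1))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(qseqid = character(), sseqid = character(),
                  pident = numeric(), length = integer(),
                  mismatch = numeric(), gapopen = integer(),
                  qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer(),
                  evalue = numeric(), bitscore = numeric())
  }
  out
}
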