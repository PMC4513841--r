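test_that("the tabular hit parser handles the 12-column dialect", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), tf)
  expect_equal(nrow(parse_hit_table(tf)), 0)

  writeLines(c("# comment line", hit_line("relE", "g1", 90, 10)), tf)
  hits <- parse_hit_table(tf)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$qstart, 10L)  # reverse orientation normalized
  expect_equal(hits$qend, 90L)

  # CRLF input parses identically
  crlf <- withr::local_tempfile(fileext = ".tsv")
  writeBin(charToRaw(paste0(hit_line("relE", "g1", 90, 10), "\r\n")), crlf)
  expect_equal(parse_hit_table(crlf), hits)

  writeLines(c(hit_line("a", "g", 1, 50), "bad\trow"), tf)
  expect_error(parse_hit_table(tf), "line 2")
})

test_that("hit tables round-trip through write and read", {
  p <- panel_spec(
    genomes = c("g1", "g2"),
    genes = data.frame(gene = c("a", "b"), length = c(300, 450)),
    presence = data.frame(gene = c("a", "b"), genome = c("g1", "g2"),
                          coverage = c(0.9, 1)))
  hits <- simulate_hit_table(p, seed = 4)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, tf)
  back <- parse_hit_table(tf)
  expect_equal(as.data.frame(back[, c("qseqid", "sseqid", "qstart", "qend")]),
               as.data.frame(hits[, c("qseqid", "sseqid", "qstart", "qend")]))
  expect_equal(back$pident, hits$pident)
})

test_that("merged-interval coverage matches hand-worked examples", {
  expect_equal(gene_coverage(integer(), integer(), 300), 0)
  expect_equal(gene_coverage(c(1, 140), c(150, 290), 300), 290 / 300)
  expect_equal(gene_coverage(1, 500, 500), 1)
  # adjacent intervals merge: [1,100] + [101,200]
  expect_equal(gene_coverage(c(1, 101), c(100, 200), 400), 0.5)
  # hits sticking out past the gene end are clipped
  expect_equal(gene_coverage(450, 600, 500), 51 / 500)
})

test_that("coverage equals the per-base oracle on random hit sets", {
  set.seed(7)
  for (i in 1:200) {
    L <- sample.int(1000, 1L)
    h <- random_hits(L)
    expect_equal(gene_coverage(h$qstart, h$qend, L),
                 coverage_oracle(h$qstart, h$qend, L))
  }
})

test_that("coverage is invariant to hit order and to splitting a hit", {
  set.seed(9)
  for (i in 1:50) {
    L <- sample(100:800, 1L)
    h <- random_hits(L, max_hits = 8L)
    base <- gene_coverage(h$qstart, h$qend, L)
    perm <- sample.int(nrow(h))
    expect_equal(gene_coverage(h$qstart[perm], h$qend[perm], L), base)
    # split the first hit into two abutting halves
    lo <- min(h$qstart[1], h$qend[1]); hi <- max(h$qstart[1], h$qend[1])
    if (hi > lo) {
      mid <- lo + (hi - lo) %/% 2
      qs <- c(lo, mid + 1, h$qstart[-1]); qe <- c(mid, hi, h$qend[-1])
      expect_equal(gene_coverage(qs, qe, L), base)
    }
  }
})

test_that("presence calls use an inclusive >= threshold", {
  lines <- c(hit_line("exact", "g1", 1, 240),   # 240/300 = 0.80
             hit_line("under", "g1", 1, 237))   # 237/300 = 0.79
  hits <- parse_hit_table(lines)
  pm <- presence_matrix(hits, c(exact = 300, under = 300), genomes = "g1")
  expect_true(pm$present[pm$gene == "exact"])
  expect_false(pm$present[pm$gene == "under"])
  expect_equal(attr(pm, "threshold"), 0.8)
  expect_error(presence_matrix(hits, c(exact = 300), genomes = "g1"),
               "unknown length")
})

test_that("candidate ranking keeps target-absent genes and flags majority absence", {
  # 56 genomes: the target plus a panel of 55
  genomes <- c("target", sprintf("p%02d", 1:55))
  genes <- c(wide = 300, tied_a = 200, tied_b = 200, resident = 400)
  rows <- list()
  present_in <- list(
    wide = sprintf("p%02d", 1:27),      # absent in 28/55 -> flagged
    tied_a = sprintf("p%02d", 1:30),    # absent in 25/55
    tied_b = sprintf("p%02d", 1:30),
    resident = c("target", sprintf("p%02d", 1:5)))
  for (g in names(present_in)) {
    for (s in present_in[[g]]) {
      rows[[length(rows) + 1L]] <- hit_line(g, s, 1, genes[[g]])
    }
  }
  hits <- parse_hit_table(unlist(rows))
  pm <- presence_matrix(hits, genes, genomes = genomes)
  cand <- candidate_toxins(pm, "target", panel = sprintf("p%02d", 1:55))
  # resident gene excluded despite high panel absence
  expect_false("resident" %in% cand$gene)
  expect_equal(cand$gene[1], "wide")
  expect_equal(cand$absence_fraction[1], 28 / 55)
  expect_true(cand$majority_absent[1])
  expect_false(any(cand$majority_absent[-1]))
  # ties broken by gene length then name
  expect_equal(cand$gene[-1], c("tied_a", "tied_b"))

  expect_error(candidate_toxins(pm, "nope"), "unknown target")
  # a gene set whose only member is present in the target yields no candidates
  resident_hits <- parse_hit_table(
    unlist(lapply(c("target", sprintf("p%02d", 1:5)),
                  function(s) hit_line("resident", s, 1, 400))))
  empty <- candidate_toxins(
    presence_matrix(resident_hits, genes["resident"], genomes = genomes),
    "target")
  expect_equal(nrow(empty), 0)
})

test_that("simulated panels round-trip to exact presence calls off the boundary", {
  set.seed(13)
  genes <- data.frame(gene = sprintf("t%02d", 1:20),
                      length = sample(150:900, 20))
  cov <- runif(20)
  # stay clear of the threshold by the spec'd 2/L guard band
  guard <- abs(cov - 0.8) > 2 / genes$length
  pres <- data.frame(gene = genes$gene, genome = "s1", coverage = cov)
  p <- panel_spec(genomes = "s1", genes = genes, presence = pres,
                  fragmentation = 3)
  pm <- presence_matrix(simulate_hit_table(p, seed = 21),
                        genes, genomes = "s1")
  got <- pm$present[match(genes$gene, pm$gene)]
  expect_equal(got[guard], (cov >= 0.8)[guard])
})
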