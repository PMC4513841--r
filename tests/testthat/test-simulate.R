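test_that("a zero mutation rate never yields a mutant", {
  out <- simulate_culture(culture_model(1e2, 1e8, 0), seed = 1)
  expect_equal(out$mutant_count, 0)
  expect_false(out$is_positive)
  w <- simulate_fluctuation_experiment(
    fluctuation_design(100, 0, culture_model(1e2, 1e8, 0)), seed = 1)
  expect_equal(sum(w$outcome == "negative"), 100)
})

test_that("negative fraction follows the null-class law exp(-mu*d)", {
  # 1e4 wells per condition; binomial 4-sigma tolerance
  for (m in c(0.1, 1, 3)) {
    mu <- 1e-8
    des <- design_for(mu, m, n_wells = 1e4)
    w <- simulate_fluctuation_experiment(des, seed = round(1000 * m) + 7)
    p <- exp(-mu * des$culture_model$divisions)
    tol <- 4 * sqrt(p * (1 - p) / 1e4)
    expect_lt(abs(mean(w$outcome == "negative") - p), tol)
  }
  # closed-form half-and-half design: mu*d = ln 2
  mu <- 1e-8
  des <- design_for(mu, log(2), n_wells = 1e4)
  w <- simulate_fluctuation_experiment(des, seed = 99)
  expect_lt(abs(mean(w$outcome == "negative") - 0.5), 0.015)
})

test_that("jackpot clones skew mutant counts right (mean > median)", {
  for (seed in c(5, 17, 23)) {
    des <- design_for(1e-8, 1, n_wells = 1000)
    w <- simulate_fluctuation_experiment(des, seed = seed)
    expect_gt(mean(w$mutant_count), stats::median(w$mutant_count))
  }
})

test_that("seeds determine outputs completely", {
  des <- fluctuation_design(culture_model = culture_model(1e2, 1e8, 1e-8))
  a <- simulate_fluctuation_experiment(des, seed = 42)
  b <- simulate_fluctuation_experiment(des, seed = 42)
  expect_identical(a, b)
  differing <- vapply(1:20, function(s) {
    !identical(simulate_fluctuation_experiment(des, seed = s)$outcome,
               simulate_fluctuation_experiment(des, seed = s + 1000)$outcome)
  }, NA)
  expect_true(all(differing))
})

test_that("dilution plating counts are Poisson at lambda = cfu*vol/dilution", {
  expect_true(all(
    simulate_dilution_plating(0, 10^(5:8), 0.1, seed = 1)$colonies == 0))
  # mean count 10 at 1e9 CFU/ml, 1e7 dilution, 0.1 ml
  counts <- vapply(1:1000, function(s) {
    simulate_dilution_plating(1e9, 1e7, 0.1, seed = s)$colonies
  }, 0)
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 1000))
  # a 10-fold series has non-increasing expected counts
  series <- rowMeans(vapply(1:200, function(s) {
    simulate_dilution_plating(1e9, 10^(5:9), 0.1, seed = s)$colonies
  }, numeric(5)))
  expect_true(all(diff(series) <= 0))
})

test_that("stringency assay counts are Poisson(frequency * plated)", {
  expect_equal(simulate_stringency_assay(0, 1e10, seed = 1), 0)
  counts <- vapply(1:500, function(s) {
    simulate_stringency_assay(1.1e-8, 1e10, seed = s)
  }, 0)
  expect_lt(abs(mean(counts) - 110), 4 * sqrt(110 / 500))
})

test_that("simulated hit tables honour the intended coverage", {
  empty <- panel_spec(
    genomes = "g1",
    genes = data.frame(gene = "a", length = 300),
    presence = data.frame(gene = character(), genome = character(),
                          coverage = numeric()))
  expect_equal(nrow(simulate_hit_table(empty, seed = 1)), 0)

  one <- panel_spec(
    genomes = "g1",
    genes = data.frame(gene = "a", length = 300),
    presence = data.frame(gene = "a", genome = "g1", coverage = 1),
    fragmentation = 1)
  h <- simulate_hit_table(one, seed = 1)
  expect_equal(nrow(h), 1)
  expect_equal(h$qstart, 1)
  expect_equal(h$qend, 300)

  # intended coverage is recovered within half a base after merging
  set.seed(31)
  cases <- data.frame(
    gene = sprintf("g%02d", 1:30),
    length = sample(60:1000, 30),
    coverage = runif(30))
  panel <- panel_spec(
    genomes = "s1",
    genes = cases[c("gene", "length")],
    presence = data.frame(gene = cases$gene, genome = "s1",
                          coverage = cases$coverage),
    fragmentation = 4)
  hits <- simulate_hit_table(panel, seed = 8)
  for (i in seq_len(nrow(cases))) {
    hi <- hits[hits$qseqid == cases$gene[i], ]
    got <- gene_coverage(hi$qstart, hi$qend, cases$length[i])
    expect_lte(abs(got - cases$coverage[i]), 1 / cases$length[i])
  }
})

test_that("coverage just under the cutoff is called absent downstream", {
  p <- panel_spec(
    genomes = "s1",
    genes = data.frame(gene = c("lo", "hi"), length = c(300, 300)),
    presence = data.frame(gene = c("lo", "hi"), genome = "s1",
                          coverage = c(0.79, 0.80)))
  pm <- presence_matrix(simulate_hit_table(p, seed = 2),
                        c(lo = 300, hi = 300), genomes = "s1")
  expect_false(pm$present[pm$gene == "lo"])
  expect_true(pm$present[pm$gene == "hi"])
})
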