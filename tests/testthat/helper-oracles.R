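# Independent oracles and fixture builders shared across tests.

# Per-base coverage oracle: marks every covered base in a boolean array.
# Deliberately naive and independent of the interval-merging code path.
coverage_oracle <- function(qstart, qend, gene_length) {
  covered <- logical(gene_length)
  for (i in seq_along(qstart)) {
    lo <- max(min(qstart[i], qend[i]), 1L)
    hi <- min(max(qstart[i], qend[i]), gene_length)
    if (lo <= hi) covered[lo:hi] <- TRUE
  }
  mean(covered)
}

# Random hit set on a gene of length L (intervals may overlap, abut, run
# in either orientation, or stick out past the gene end).
random_hits <- function(L, max_hits = 20L) {
  n <- sample.int(max_hits, 1L)
  s <- sample.int(L + 10L, n, replace = TRUE)
  e <- pmin(s + sample.int(max(L %/% 2L, 1L), n, replace = TRUE), L + 15L)
  flip <- runif(n) < 0.5
  data.frame(qstart = ifelse(flip, e, s), qend = ifelse(flip, s, e))
}

# A design with mutation rate mu and divisions chosen to give the target
# expected mutations per culture (m = mu * d).
design_for <- function(mu, m, n_wells = 100, n0 = 100) {
  d <- round(m / mu)
  fluctuation_design(
    n_selective_cultures = n_wells, n_titer_cultures = 0,
    culture_model = culture_model(n0, n0 + d, mu))
}

# Twelve-column hit line in the tabular alignment dialect.
hit_line <- function(gene, genome, qs, qe, pid = 95, len = abs(qe - qs) + 1) {
  sprintf("%s\t%s\t%.1f\t%d\t%d\t0\t%d\t%d\t%d\t%d\t1e-30\t%.1f",
          gene, genome, pid, len, round((1 - pid / 100) * len), qs, qe,
          1000L + qs, 1000L + qe, 1.8 * len)
}
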