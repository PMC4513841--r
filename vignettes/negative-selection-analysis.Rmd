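---
title: "Quantifying negative-selection stringency: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying negative-selection stringency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxsel)
library(dplyr)
```

## The problem

A negative-selection (counterselection) cassette — an inducible toxin gene
integrated into a bacterial chromosome — permits growth only of cells that
have *lost* the cassette. Its practical value is its stringency: the
fraction of plated cells that break through restrictive conditions anyway.
Breakthrough arises from spontaneous mutations that inactivate the toxin or
its expression, so the floor on stringency is set by mutation biology, not
by the cleverness of the construct. This package implements the four
quantitative analyses needed to characterise such a system:

1. **Stringency frequencies** — breakthrough colonies divided by plated
   CFU, with CFU densities computed from serial-dilution counts.
2. **Mutation rates** — the null-class (p0) Luria–Delbrück fluctuation-test
   estimator, which is robust to jackpot clones, with exact confidence
   intervals.
3. **Theoretical mutability bounds** — the maximum attainable stringency of
   a cassette of given length, propagated from published genomic
   mutation-rate intervals.
4. **Candidate toxin screening** — coverage-based presence/absence of toxin
   genes across a genome panel from tabular alignment hits, to find toxins
   a target strain lacks.

A stochastic simulator generates all four input kinds so every estimator is
tested against a generative model with known truth.

## The fluctuation model and the p0 estimator

Each culture grows from $N_0$ to $N_t$ cells by synchronous doubling over
$G = \lceil \log_2(N_t/N_0) \rceil$ generations, undergoing $d = N_t - N_0$
cell divisions. Mutations arise with probability $\mu$ per division, so the
number of mutations per culture is Poisson with mean $m = \mu d$, and

$$P(\text{no mutant in a culture}) = e^{-\mu d}.$$

A mutation in generation $g$ founds a clone of $2^{G-g}$ descendants — the
jackpot effect that makes mutant *counts* wildly overdispersed and mutant
*frequencies* unreliable as rate estimates. The null-class method uses only
the zero class, which the jackpot effect cannot distort: with $k$ of $n$
cultures negative,

$$\hat\mu = \frac{-\ln(k/n)}{d}.$$

`p0_estimate()` implements this with two divisor conventions. The default
`per_culture` divides by the divisions of one culture, which is the
standard null-class method and reproduces the magnitudes such experiments
report; a `summed` convention (divide additionally by $n$) is exposed
behind a flag because the phrase "total number of cell divisions" is
genuinely ambiguous in parts of the literature, and the output records
which convention produced it.

Confidence intervals are exact Clopper–Pearson intervals for the binomial
proportion $p_0 = k/n$ mapped through the decreasing transform
$-\ln(\cdot)/d$. We chose Clopper–Pearson over asymptotic intervals because
well counts are small (tens, not thousands) and boundary outcomes are
routine; exactness costs a little conservatism (true coverage at $n = 100$,
$m = 1$ is 96.2% for a nominal 95%) but never undercovers. Boundary
outcomes return bounds, not infinities: zero negative wells yields only a
finite lower rate bound (from the one-sided upper Clopper–Pearson limit of
$p_0$); all-negative yields a point estimate of 0 with a one-sided upper
bound.

```{r}
wells <- simulate_fluctuation_experiment(
  fluctuation_design(n_selective_cultures = 100, n_titer_cultures = 20,
                     culture_model = culture_model(1e2, 1e8, 1e-8)),
  seed = 7)
fit <- estimate_rate(wells, initial_cells = 1e2)
tidy(fit)
glance(fit)
```

## What the simulator emulates — and what it does not

`simulate_fluctuation_experiment()` reproduces the standard 96-well design:
100 selective wells scored positive/negative plus 20 titer wells, inoculated
at ~1e2 CFU per well. Final well size $N_t$ defaults to 1e8 CFU — a typical
saturated 200 µl well — and is an explicit parameter because published
fluctuation protocols rarely report per-well titers, so no literature value
can anchor it; parameter-recovery tests are therefore run across $\mu d$
from 0.2 to 2, the informative regime of the design.

Deliberate simplifications, matching the assumptions implicit in the p0
formula: no cell death, no mutant fitness cost or phenotypic lag, 100%
plating efficiency, deterministic synchronous doubling. Divisions in
generation $g$ are $N_0 2^{g-1}$ (the last generation truncated so the
total is exactly $d$). Consequently, passing tests demonstrate correctness
*under this model*; on real data, phenotypic delay or differential mutant
growth would bias any p0 analysis, ours included, and are explicitly out of
scope. Dilution-series counts and rare-escape assays are Poisson, which is
exact for well-mixed plating; plate-to-plate volume error is not modelled.

All randomness in a simulation flows from one integer seed with a fixed
vectorized draw order, so a (design, seed) pair fully determines the
output.

## Stringency frequencies

CFU densities come from the pooled ratio estimator over countable plates,
$\sum c_i / \sum (v_i / f_i)$, which is the Poisson maximum-likelihood
estimate. The countable range is 3–300 colonies per plate — standard
microbiological practice; counts above 300 are unreliable to enumerate and
below 3 carry little information. If no plate is countable the least-diluted
plate is used and flagged.

A zero-colony restrictive plate is reported as the 95% rule-of-three upper
bound $3/n_{\text{plated}}$ rather than 0: at the detection limit a
stringency claim is a bound, and reporting 0 would overstate it. Replicates
are aggregated as the mean of log-transformed frequencies (the geometric
mean) with the SD of the log10 values — multiplicative noise dominates
these assays, and this matches how stringency comparisons are conventionally
plotted (`plot_stringency()`).

```{r}
stringency_frequency(110, 1e10)
aggregate_replicates(c(3.31e-8, 2.38e-8, 1.11e-8))
```

## Theoretical maximum stringency

For a cassette of $L$ bp in a genome of $L_g$ bp with genomic mutation-rate
interval $[\mu_1, \mu_2]$ per genome per generation, the chain is:
per-nucleotide rate $[\mu_1, \mu_2]/L_g$; per-cassette rate $\times L$;
inactivation rate $\times$ the interval of mutation fractions assumed to
inactivate the toxin (bracketed by the nonsense fraction of coding
mutations, 5%, and the dominant fraction of *lacI* mutations, 40%); plus
the spontaneous large-deletion rate interval. Defaults in
`mutability_inputs()` are the *E. coli* K-12 values (genomic rate 1e-3 to
3.3e-3, 4,641,652 bp chromosome, an 811 bp promoter–toxin cassette,
deletions at 1.79e-9 to 2.5e-7 per generation).

Each stage rounds to 2 significant figures by default, because published
chains of this kind print rounded intermediates and feed them forward — the
printed endpoints are reproducible only with rounded inputs (e.g.
$0.9\times10^{-8} = 1.8\times10^{-7} \times 0.05$ holds only after
rounding). `sig_figs = Inf` gives the unrounded chain, which the test suite
verifies against a single-expression computation to 1e-12 relative
tolerance. Classification of an observed rate against an interval is
inclusive at both boundaries, since these bounds are order-of-magnitude
statements, not sharp thresholds. The 14% overall fraction of strongly
deleterious *de novo* mutations sometimes quoted alongside the 5%/40%
limits is informational only and is not an input to the chain.

```{r}
escape_rate_chain(mutability_inputs())
classify_observed(1.42e-8, rate_interval(0.9e-8, 2.3e-7))
```

## Coverage-based toxin screening

`parse_hit_table()` reads the 12-column tabular alignment dialect
(1-based inclusive query coordinates; reverse-orientation hits are
normalized by swapping). Coverage of a gene in a genome is the merged
length of its query intervals (clipped to the gene, with book-ended
intervals merged) divided by gene length; a gene is called present at
coverage $\ge$ 0.80. The inclusive comparison operationalises "alignment
over 80% of the gene length" and is exposed as a parameter; the 0.80
default embodies the empirical observation that this cutoff captures
orthologues — including full-length genes carrying frameshifts, which are
deliberately called present because a frameshifted resident copy still
implies a resident antitoxin context. Candidate ranking keeps genes absent
from the target genome and flags those absent from strictly more than half
of the panel ("more than half" is strict), sorting by absence fraction with
ties broken by gene length (shorter cassettes amplify more easily) then
name.

```{r}
panel <- panel_spec(
  genomes = c("target", "p1", "p2"),
  genes = data.frame(gene = c("relE", "mqsR"), length = c(288, 297)),
  presence = data.frame(
    gene = c("relE", "relE", "mqsR"),
    genome = c("p1", "p2", "target"),
    coverage = c(1, 0.6, 1)))
hits <- simulate_hit_table(panel, seed = 1)
pm <- presence_matrix(hits, c(relE = 288, mqsR = 297),
                      genomes = c("target", "p1", "p2"))
candidate_toxins(pm, "target", panel = c("p1", "p2"))
```

## Numerical and testing choices

* **Problem sizes.** Calibration checks use 200 simulated experiments per
  rate magnitude for 2-fold recovery, 1000 for CI coverage, and 1e4
  cultures per condition for the null-class law — sizes at which binomial
  noise is a few tenths of a percent, keeping the whole suite under a
  minute of simulation.
* **CI coverage is asserted on the exact value.** Coverage of the
  transformed Clopper–Pearson interval is computable by enumerating the
  binomial null-class distribution; the suite asserts the 93–97% band on
  that exact value and separately requires Monte Carlo coverage to agree
  with it within binomial 4σ, so a finite simulation cannot mask (or fake)
  a calibration failure.
* **Coverage arithmetic** is verified against a naive per-base boolean
  array oracle on randomized hit sets, plus invariance to hit order and to
  splitting hits into abutting fragments.
* **Degenerate inputs**: zero mutation rate, all-negative and no-negative
  plates, all-zero dilution series, empty hit tables and empty candidate
  sets all return defined values or typed errors, never NaN/Inf surprises.

## Known limitations

* The growth model is deterministic doubling; continuous-time birth–death
  dynamics, mutant fitness effects, phenotypic delay and plating
  efficiency below 1 are not modelled, and the p0 estimator inherits those
  assumptions.
* Only the null-class estimator is provided; maximum-likelihood
  (Ma–Sandri–Sarkar-type) fluctuation estimators that use full mutant
  counts are out of scope.
* The screen consumes nucleotide-level alignment hits; it does not run an
  aligner, and protein-level corroboration is outside its contract.
* Rates (per division/generation) and frequencies (per plated cell) are
  conceptually distinct; the package labels every JSON output with its
  kind and never converts between them.
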