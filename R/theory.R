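#' Rate intervals
#'
#' A `rate_interval` is a closed interval `[low, high]` of per-generation
#' rates. Published genomic mutation rates, inactivating-fraction limits and
#' spontaneous-deletion rates are all reported as intervals, and the
#' theoretical maximum-stringency chain propagates them endpointwise.
#'
#' @param low,high Non-negative rates with `low <= high`.
#' @return A `rate_interval` object (length-2 numeric with class).
#' @examples
#' rate_interval(1e-3, 3.3e-3)
#' @export
rate_interval <- function(low, high = low) {
  if (!is.numeric(low) || !is.numeric(high) ||
      length(low) != 1L || length(high) != 1L ||
      is.na(low) || is.na(high)) {
    abort("`low` and `high` must be single numbers.")
  }
  if (low < 0 || high < low) {
    abort("need 0 <= low <= high.")
  }
  structure(c(low = low, high = high), class = "rate_interval")
}

#' @export
print.rate_interval <- function(x, ...) {
  cat(sprintf("<rate_interval> [%g, %g] per generation\n", x[["low"]],
              x[["high"]]))
  invisible(x)
}

as_rate_interval <- function(x, name = "interval") {
  if (inherits(x, "rate_interval")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(rate_interval(x[[1]], x[[2]]))
  abort(sprintf("`%s` must be a rate_interval or a length-2 numeric.", name))
}

signif_interval <- function(x, sig_figs) {
  if (is.null(sig_figs) || !is.finite(sig_figs)) return(x)
  rate_interval(signif(x[["low"]], sig_figs), signif(x[["high"]], sig_figs))
}

#' Inputs for the theoretical cassette-mutability chain
#'
#' Bundles the published quantities from which the maximum attainable
#' stringency (minimum escape rate) of a chromosomal negative-selection
#' cassette is derived: a genomic mutation-rate interval, the genome and
#' cassette lengths, the interval of mutation fractions assumed to
#' inactivate the cassette, and the spontaneous large-deletion rate
#' interval.
#'
#' Defaults are the values for *E. coli* K-12: genomic rate 1e-3 to 3.3e-3
#' per genome per generation, the 4,641,652 bp MG1655 chromosome, an 811 bp
#' promoter-toxin cassette, inactivating fractions bracketed by the nonsense
#' fraction of coding mutations (5%) and the dominant fraction of lacI
#' mutations (40%), and large deletions at 1.79e-9 to 2.5e-7 per generation.
#'
#' @param genomic_rate Per-genome per-generation mutation-rate interval.
#' @param genome_length Genome size in bp.
#' @param cassette_length Cassette size in bp.
#' @param inactivating_fraction Interval of proportions of cassette
#'   mutations assumed to abolish toxin activity or expression.
#' @param deletion_rate Per-generation spontaneous large-deletion rate
#'   interval.
#' @param sig_figs Significant figures kept after each stage of the chain;
#'   use `Inf` for no rounding. Default 2, matching how such chains are
#'   usually reported (each printed stage feeds the next already rounded).
#' @return A `mutability_inputs` list.
#' @examples
#' mutability_inputs()
#' @export
mutability_inputs <- function(genomic_rate = rate_interval(1e-3, 3.3e-3),
                              genome_length = 4641652,
                              cassette_length = 811,
                              inactivating_fraction = c(0.05, 0.40),
                              deletion_rate = rate_interval(1.79e-9, 2.5e-7),
                              sig_figs = 2) {
  genomic_rate <- as_rate_interval(genomic_rate, "genomic_rate")
  deletion_rate <- as_rate_interval(deletion_rate, "deletion_rate")
  genome_length <- check_count(genome_length, "genome_length", min = 1L)
  cassette_length <- check_count(cassette_length, "cassette_length", min = 1L)
  if (!is.numeric(inactivating_fraction) ||
      length(inactivating_fraction) != 2L ||
      any(inactivating_fraction < 0) || any(inactivating_fraction > 1) ||
      inactivating_fraction[[1]] > inactivating_fraction[[2]]) {
    abort("`inactivating_fraction` must be an ordered pair in [0, 1].")
  }
  if (!is.numeric(sig_figs) || length(sig_figs) != 1L || sig_figs < 1) {
    abort("`sig_figs` must be a single number >= 1 (or Inf).")
  }
  structure(
    list(genomic_rate = genomic_rate,
         genome_length = genome_length,
         cassette_length = cassette_length,
         inactivating_fraction = as.numeric(inactivating_fraction),
         deletion_rate = deletion_rate,
         sig_figs = sig_figs),
    class = "mutability_inputs"
  )
}

#' Per-nucleotide mutation rate from a genomic rate
#'
#' Divides each endpoint of a per-genome per-generation rate interval by
#' the genome length, then rounds to `sig_figs` significant figures.
#'
#' @param genomic_rate A [rate_interval()] per genome per generation.
#' @param genome_length Genome size in bp.
#' @param sig_figs Significant figures (`Inf` = no rounding).
#' @return A [rate_interval()] per nucleotide per generation.
#' @examples
#' per_nucleotide_rate(rate_interval(1e-3, 3.3e-3), 4641652)
#' @export
per_nucleotide_rate <- function(genomic_rate, genome_length, sig_figs = 2) {
  genomic_rate <- as_rate_interval(genomic_rate, "genomic_rate")
  genome_length <- check_count(genome_length, "genome_length", min = 1L)
  out <- rate_interval(genomic_rate[["low"]] / genome_length,
                       genomic_rate[["high"]] / genome_length)
  signif_interval(out, sig_figs)
}

#' Per-cassette mutation rate from a per-nucleotide rate
#'
#' @param per_nt A [rate_interval()] per nucleotide per generation.
#' @param cassette_length Cassette size in bp.
#' @inheritParams per_nucleotide_rate
#' @return A [rate_interval()] per cassette per generation.
#' @examples
#' per_cassette_rate(rate_interval(2.2e-10, 7.1e-10), 811)
#' @export
per_cassette_rate <- function(per_nt, cassette_length, sig_figs = 2) {
  per_nt <- as_rate_interval(per_nt, "per_nt")
  if (!is.numeric(cassette_length) || length(cassette_length) != 1L ||
      cassette_length < 0) {
    abort("`cassette_length` must be a single non-negative length.")
  }
  out <- rate_interval(per_nt[["low"]] * cassette_length,
                       per_nt[["high"]] * cassette_length)
  signif_interval(out, sig_figs)
}

#' Cassette-inactivation rate
#'
#' Scales a per-cassette mutation-rate interval by the interval of mutation
#' fractions assumed to inactivate the cassette: the lower endpoint pairs
#' with the lower fraction and the upper with the upper, giving the widest
#' consistent interval.
#'
#' @param per_cassette A [rate_interval()] per cassette per generation.
#' @param fractions Ordered pair of inactivating proportions in [0, 1].
#' @inheritParams per_nucleotide_rate
#' @return A [rate_interval()].
#' @examples
#' inactivation_rate(rate_interval(1.8e-7, 5.8e-7), c(0.05, 0.40))
#' @export
inactivation_rate <- function(per_cassette, fractions, sig_figs = 2) {
  per_cassette <- as_rate_interval(per_cassette, "per_cassette")
  if (!is.numeric(fractions) || length(fractions) != 2L ||
      any(fractions < 0) || any(fractions > 1) ||
      fractions[[1]] > fractions[[2]]) {
    abort("`fractions` must be an ordered pair in [0, 1].")
  }
  out <- rate_interval(per_cassette[["low"]] * fractions[[1]],
                       per_cassette[["high"]] * fractions[[2]])
  signif_interval(out, sig_figs)
}

#' Total escape rate including spontaneous deletions
#'
#' Point mutation is not the only escape route from a toxin cassette: a
#' spontaneous large deletion removing the cassette also permits growth
#' under restrictive conditions. The total expected escape rate is the
#' endpointwise sum of the two intervals.
#'
#' @param inactivation A [rate_interval()] of inactivating point mutation.
#' @param deletion A [rate_interval()] of spontaneous large deletion.
#' @param sig_figs Significant figures (`Inf` = no rounding; default keeps
#'   3 so the sum of two 2-s.f. inputs is not distorted further).
#' @return A [rate_interval()].
#' @examples
#' total_escape_rate(rate_interval(0.9e-8, 2.3e-7),
#'                   rate_interval(1.79e-9, 2.5e-7))
#' @export
total_escape_rate <- function(inactivation, deletion, sig_figs = 3) {
  inactivation <- as_rate_interval(inactivation, "inactivation")
  deletion <- as_rate_interval(deletion, "deletion")
  out <- rate_interval(inactivation[["low"]] + deletion[["low"]],
                       inactivation[["high"]] + deletion[["high"]])
  signif_interval(out, sig_figs)
}

#' Run the full theoretical maximum-stringency chain
#'
#' Composes [per_nucleotide_rate()], [per_cassette_rate()],
#' [inactivation_rate()] and [total_escape_rate()] over a set of
#' [mutability_inputs()], returning one row per stage. Rounding to
#' `inputs$sig_figs` is applied after every stage, so printed intermediate
#' values feed the next stage (set `sig_figs = Inf` for an unrounded
#' chain).
#'
#' @param inputs A [mutability_inputs()] object.
#' @return A tibble with columns `stage`, `unit`, `low`, `high`, of class
#'   `escape_rate_chain`.
#' @examples
#' escape_rate_chain(mutability_inputs())
#' @export
escape_rate_chain <- function(inputs = mutability_inputs()) {
  if (!inherits(inputs, "mutability_inputs")) {
    abort("`inputs` must be created with mutability_inputs().")
  }
  sf <- inputs$sig_figs
  per_nt <- per_nucleotide_rate(inputs$genomic_rate, inputs$genome_length, sf)
  per_cas <- per_cassette_rate(per_nt, inputs$cassette_length, sf)
  inact <- inactivation_rate(per_cas, inputs$inactivating_fraction, sf)
  total <- total_escape_rate(inact, inputs$deletion_rate,
                             sig_figs = if (is.finite(sf)) sf + 1 else sf)
  out <- tibble(
    stage = c("genomic", "per_nucleotide", "per_cassette", "inactivation",
              "deletion", "total_escape"),
    unit = c("per genome per generation",
             "per nucleotide per generation",
             "per cassette per generation",
             "per cassette per generation",
             "per generation",
             "per generation"),
    low = c(inputs$genomic_rate[["low"]], per_nt[["low"]], per_cas[["low"]],
            inact[["low"]], inputs$deletion_rate[["low"]], total[["low"]]),
    high = c(inputs$genomic_rate[["high"]], per_nt[["high"]],
             per_cas[["high"]], inact[["high"]],
             inputs$deletion_rate[["high"]], total[["high"]])
  )
  class(out) <- c("escape_rate_chain", class(out))
  attr(out, "inputs") <- inputs
  out
}

#' Classify an observed rate against a theoretical interval
#'
#' @param observed Observed per-generation rate (non-negative scalar).
#' @param interval A [rate_interval()]. Boundaries are inclusive: a rate
#'   exactly at an endpoint classifies as `"within"`.
#' @return One of `"below"`, `"within"`, `"above"`.
#' @examples
#' classify_observed(1.42e-8, rate_interval(0.9e-8, 2.3e-7))
#' @export
classify_observed <- function(observed, interval) {
  if (!is.numeric(observed) || length(observed) != 1L || is.na(observed) ||
      observed < 0) {
    abort("`observed` must be a single non-negative rate.")
  }
  interval <- as_rate_interval(interval)
  if (observed < interval[["low"]]) "below"
  else if (observed > interval[["high"]]) "above"
  else "within"
}

#' On-target fraction of randomly sheared donor DNA
#'
#' In generalized allelic exchange, donor genomic DNA is sheared to a fixed
#' fragment length and only fragments spanning the targeted locus can
#' replace the selection cassette. To first order the on-target fraction of
#' input DNA is fragment length / genome length.
#'
#' @param fragment_length Sheared fragment length in bp.
#' @param genome_length Donor genome length in bp.
#' @param percent Return a percentage (default) rather than a fraction.
#' @return A single number.
#' @examples
#' on_target_fraction(10e3, 5e6)  # 0.2 (%)
#' @export
on_target_fraction <- function(fragment_length, genome_length,
                               percent = TRUE) {
  if (!is.numeric(fragment_length) || fragment_length <= 0 ||
      !is.numeric(genome_length) || genome_length <= 0) {
    abort("lengths must be positive.")
  }
  frac <- fragment_length / genome_length
  if (percent) 100 * frac else frac
}
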