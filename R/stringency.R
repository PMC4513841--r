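#' CFU density from serial-dilution plate counts
#'
#' Pools counts over plates in the countable range (3-300 colonies,
#' inclusive) with the ratio estimator
#' `sum(colonies) / sum(volume_ml / dilution_factor)`, the
#' maximum-likelihood estimate under Poisson counting. When no plate is
#' countable the least-diluted plate is used and the result is flagged
#' low-confidence; all-zero counts return density 0 with a flag.
#'
#' @param records Data frame with columns `dilution_factor`, `volume_ml`,
#'   `colonies` (one condition; one or more plates).
#' @param countable Inclusive colony-count range treated as reliable.
#' @return A one-row tibble: `cfu_per_ml`, `n_countable`,
#'   `low_confidence`.
#' @examples
#' cfu_from_dilution_counts(
#'   data.frame(dilution_factor = c(1e7, 1e8), volume_ml = 0.1,
#'              colonies = c(100, 10)))
#' @export
cfu_from_dilution_counts <- function(records, countable = c(3, 300)) {
  records <- as_tibble(records)
  need <- c("dilution_factor", "volume_ml", "colonies")
  if (!all(need %in% names(records))) {
    abort("`records` needs columns dilution_factor, volume_ml, colonies.")
  }
  if (nrow(records) == 0L) abort("`records` has no plates.")
  if (any(records$dilution_factor < 1) || any(records$volume_ml <= 0) ||
      any(records$colonies < 0)) {
    abort("need dilution_factor >= 1, volume_ml > 0, colonies >= 0.")
  }
  ok <- records$colonies >= countable[[1]] & records$colonies <= countable[[2]]
  if (any(ok)) {
    use <- records[ok, ]
    est <- sum(use$colonies) / sum(use$volume_ml / use$dilution_factor)
    return(tibble(cfu_per_ml = est, n_countable = sum(ok),
                  low_confidence = FALSE))
  }
  if (all(records$colonies == 0)) {
    return(tibble(cfu_per_ml = 0, n_countable = 0L, low_confidence = TRUE))
  }
  least <- records[which.min(records$dilution_factor), ]
  est <- least$colonies / (least$volume_ml / least$dilution_factor)
  tibble(cfu_per_ml = est, n_countable = 0L, low_confidence = TRUE)
}

#' Selection-stringency frequency
#'
#' The stringency frequency of a selection cassette is the fraction of
#' plated viable cells that grow under restrictive conditions (smaller =
#' more stringent): breakthrough colonies divided by the calculated CFU
#' spread on the restrictive plate. When no colony grows the frequency is
#' reported as the 95% "rule of three" upper bound `3 / plated_total`
#' rather than 0, since the assay is at its detection limit.
#'
#' @param restrictive_colonies Breakthrough colonies on restrictive plates.
#' @param plated_total Viable cells spread (typically 1e10).
#' @return A one-row tibble of class `stringency_result`: `frequency`,
#'   `is_upper_bound`, `restrictive_cfu`, `plated_total`.
#' @examples
#' stringency_frequency(110, 1e10)   # 1.1e-8
#' stringency_frequency(0, 1e10)     # <= 3e-10 (upper bound)
#' @export
stringency_frequency <- function(restrictive_colonies, plated_total) {
  restrictive_colonies <- check_count(restrictive_colonies,
                                      "restrictive_colonies")
  plated_total <- check_count(plated_total, "plated_total", min = 1L)
  upper <- restrictive_colonies == 0
  freq <- if (upper) 3 / plated_total else
    restrictive_colonies / plated_total
  out <- tibble(frequency = freq, is_upper_bound = upper,
                restrictive_cfu = restrictive_colonies,
                plated_total = plated_total)
  class(out) <- c("stringency_result", class(out))
  out
}

#' Aggregate replicate stringency frequencies in log space
#'
#' Biological replicates of stringency assays are summarized as the
#' average of log-transformed frequencies (the geometric mean), with the
#' standard deviation of the log10 values as the dispersion. Zero-colony
#' upper bounds must not be mixed in; aggregate them separately.
#'
#' @param frequencies Positive frequencies, one per replicate.
#' @return A one-row tibble: `geometric_mean`, `log10_sd`,
#'   `n_replicates`.
#' @examples
#' aggregate_replicates(c(1e-8, 1e-6))  # gmean 1e-7, log10 sd sqrt(2)
#' @export
aggregate_replicates <- function(frequencies) {
  if (!is.numeric(frequencies) || length(frequencies) < 1L) {
    abort("`frequencies` must be a non-empty numeric vector.")
  }
  if (any(frequencies <= 0)) {
    abort(paste("all frequencies must be > 0;",
                "aggregate zero-count upper bounds separately."))
  }
  lg <- log10(frequencies)
  tibble(geometric_mean = 10^mean(lg),
         log10_sd = if (length(lg) > 1L) sd(lg) else 0,
         n_replicates = length(frequencies))
}

#' Stringency from a plating experiment table
#'
#' Convenience wrapper for the full measurement: computes the
#' non-restrictive CFU density from the dilution series via
#' [cfu_from_dilution_counts()], sums breakthrough colonies on restrictive
#' plates, and forms the stringency frequency against `plated_total`.
#'
#' @param records Data frame with columns `condition`
#'   (`"restrictive"`/`"nonrestrictive"`), `dilution_factor`, `volume_ml`,
#'   `colonies`.
#' @param plated_total Viable cells spread on the restrictive plates.
#' @inheritParams cfu_from_dilution_counts
#' @return A one-row `stringency_result` tibble with the reference density
#'   added as `reference_cfu_per_ml`.
#' @export
stringency_from_plating <- function(records, plated_total,
                                    countable = c(3, 300)) {
  records <- as_tibble(records)
  if (!"condition" %in% names(records)) {
    abort("`records` needs a `condition` column.")
  }
  nonres <- dplyr::filter(records, .data$condition == "nonrestrictive")
  res <- dplyr::filter(records, .data$condition == "restrictive")
  if (nrow(res) == 0L) abort("no restrictive records.")
  ref <- if (nrow(nonres) > 0L) {
    cfu_from_dilution_counts(nonres, countable)$cfu_per_ml
  } else NA_real_
  out <- stringency_frequency(sum(res$colonies), plated_total)
  out$reference_cfu_per_ml <- ref
  out
}
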