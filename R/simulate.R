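# Birth-and-mutation simulator for fluctuation tests, dilution plating and
# rare-escape stringency assays. All draws are funnelled through one
# set.seed(seed) call per exported function, with a fixed vectorized draw
# order, so a seed fully determines the output.

# Divisions occurring in each generation g = 1..G under deterministic
# doubling: cells after generation g are min(N0 * 2^g, Nt), so divisions in
# g are the increment. Sums exactly to Nt - N0.
generation_divisions <- function(model) {
  g <- model$generations
  if (g == 0L) return(numeric(0))
  after <- pmin(model$initial_cells * 2^(seq_len(g)), model$final_cells)
  diff(c(model$initial_cells, after))
}

# Vectorized core: mutant counts for n cultures. A culture acquires
# K ~ Poisson(mu * d) mutations; each mutation falls in generation g with
# probability proportional to the divisions in g and founds a clone that
# doubles to size 2^(G - g) by the final generation. The total mutant count
# is capped at Nt. P(K = 0) = exp(-mu * d) exactly.
simulate_mutant_counts <- function(model, n) {
  d <- model$divisions
  m <- model$mutation_rate * d
  counts <- rpois(n, m)
  total <- numeric(n)
  pos <- which(counts > 0L)
  if (length(pos) > 0L) {
    w <- generation_divisions(model)
    gmax <- model$generations
    clone_sizes <- pmin(2^(gmax - seq_len(gmax)), model$final_cells)
    for (i in pos) {
      gens <- sample.int(gmax, counts[i], replace = TRUE, prob = w)
      total[i] <- min(sum(clone_sizes[gens]), model$final_cells)
    }
  }
  total
}

#' Simulate one culture of a fluctuation experiment
#'
#' Realizes the generative process that the null-class (p0) estimator
#' inverts: mutations arise during growth as a Poisson process over cell
#' divisions, and an early ("jackpot") mutation expands into a large
#' resistant clone. The probability that a culture contains no mutant is
#' exactly `exp(-mu * (Nt - N0))`.
#'
#' @param model A [culture_model()].
#' @param seed Integer seed.
#' @return A one-row tibble with `mutant_count`, `total_count`,
#'   `is_positive`.
#' @examples
#' simulate_culture(culture_model(1e2, 1e8, 1e-8), seed = 1)
#' @export
simulate_culture <- function(model, seed) {
  if (!inherits(model, "culture_model")) {
    abort("`model` must be created with culture_model().")
  }
  set.seed(check_seed(seed))
  mc <- simulate_mutant_counts(model, 1L)
  tibble(mutant_count = mc,
         total_count = model$final_cells,
         is_positive = mc > 0)
}

#' Simulate a parallel-culture fluctuation experiment
#'
#' Grows `n_selective_cultures` wells under the design's culture model and
#' scores each positive (any mutant present) or negative, and reports final
#' CFU for the titer wells. Reproducible under a fixed seed.
#'
#' @param design A [fluctuation_design()].
#' @param seed Integer seed.
#' @return A tibble with one row per well: `well_id`, `arm` ("selective" or
#'   "titer"), `outcome` ("positive"/"negative", `NA` for titer wells),
#'   `mutant_count` (`NA` for titer wells) and `final_cfu` (titer wells
#'   only). The design is attached as attribute `"design"`.
#' @examples
#' wells <- simulate_fluctuation_experiment(
#'   fluctuation_design(culture_model = culture_model(1e2, 1e8, 5e-9)),
#'   seed = 1)
#' table(wells$outcome)
#' @export
simulate_fluctuation_experiment <- function(design, seed) {
  if (!inherits(design, "fluctuation_design")) {
    abort("`design` must be created with fluctuation_design().")
  }
  set.seed(check_seed(seed))
  model <- design$culture_model
  ns <- design$n_selective_cultures
  nt <- design$n_titer_cultures
  mc <- simulate_mutant_counts(model, ns)
  titer <- if (nt > 0L) {
    if (design$titer_noise == "poisson") rpois(nt, model$final_cells)
    else rep(model$final_cells, nt)
  } else numeric(0)
  out <- dplyr::bind_rows(
    tibble(well_id = sprintf("S%03d", seq_len(ns)),
           arm = "selective",
           outcome = ifelse(mc > 0, "positive", "negative"),
           mutant_count = mc,
           final_cfu = NA_real_),
    tibble(well_id = sprintf("T%03d", seq_len(nt)),
           arm = "titer",
           outcome = NA_character_,
           mutant_count = NA_real_,
           final_cfu = as.numeric(titer))
  )
  attr(out, "design") <- design
  out
}

#' Simulate serial-dilution plate counts
#'
#' Each plate receives `plated_volume / dilution` ml-equivalents of the
#' original suspension, so its colony count is
#' Poisson(`true_cfu_per_ml * plated_volume / dilution`).
#'
#' @param true_cfu_per_ml True density of the undiluted suspension.
#' @param dilutions Vector of dilution factors (>= 1), e.g.
#'   `10^(5:8)` for a 10-fold series.
#' @param plated_volume Volume plated per plate, in ml.
#' @param seed Integer seed.
#' @param plate_id,condition Labels carried into the output.
#' @return A tibble with `plate_id`, `condition`, `dilution_factor`,
#'   `volume_ml`, `colonies`.
#' @examples
#' simulate_dilution_plating(1e9, 10^(5:8), 0.1, seed = 1)
#' @export
simulate_dilution_plating <- function(true_cfu_per_ml, dilutions,
                                      plated_volume = 0.1, seed,
                                      plate_id = "P1",
                                      condition = "nonrestrictive") {
  if (!is.numeric(true_cfu_per_ml) || length(true_cfu_per_ml) != 1L ||
      true_cfu_per_ml < 0) {
    abort("`true_cfu_per_ml` must be a single non-negative density.")
  }
  if (!is.numeric(dilutions) || length(dilutions) < 1L ||
      any(dilutions <= 0)) {
    abort("`dilutions` must be positive factors.")
  }
  if (!is.numeric(plated_volume) || plated_volume <= 0) {
    abort("`plated_volume` must be positive (ml).")
  }
  set.seed(check_seed(seed))
  lambda <- true_cfu_per_ml * plated_volume / dilutions
  tibble(plate_id = plate_id,
         condition = condition,
         dilution_factor = as.numeric(dilutions),
         volume_ml = plated_volume,
         colonies = rpois(length(dilutions), lambda))
}

#' Simulate a rare-escape stringency assay
#'
#' A large number of cells (default 1e10, a pelleted 10 ml culture at
#' OD600 = 1) is spread on restrictive plates; breakthrough colonies arise
#' at a small true escape frequency, so the observed colony count is
#' Poisson(`escape_frequency * n_plated`).
#'
#' @param escape_frequency True escape frequency in [0, 1].
#' @param n_plated Number of cells spread.
#' @param seed Integer seed.
#' @return A single colony count.
#' @examples
#' simulate_stringency_assay(1.1e-8, 1e10, seed = 1)  # mean 110
#' @export
simulate_stringency_assay <- function(escape_frequency, n_plated = 1e10,
                                      seed) {
  escape_frequency <- check_prob(escape_frequency, "escape_frequency")
  n_plated <- check_count(n_plated, "n_plated", min = 1L)
  set.seed(check_seed(seed))
  rpois(1L, escape_frequency * n_plated)
}
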