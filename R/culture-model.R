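#' Growth model for one fluctuation-test culture
#'
#' Describes a grow-then-select culture by its inoculum `initial_cells`
#' (N0), final size `final_cells` (Nt) and per-division mutation
#' probability `mutation_rate` (mu). Growth is deterministic synchronous
#' doubling: the culture passes through `G = ceiling(log2(Nt / N0))`
#' generations and undergoes `d = Nt - N0` cell divisions in total, the
#' divisor of the null-class estimator.
#'
#' Defaults mirror a 96-well fluctuation design: ~1e2 CFU inoculated per
#' well and grown to 1e8 CFU.
#'
#' @param initial_cells N0, inoculum CFU (>= 1).
#' @param final_cells Nt, final CFU (>= N0).
#' @param mutation_rate mu, mutation probability per cell division.
#' @return A `culture_model` list with derived `generations` and
#'   `divisions`.
#' @examples
#' culture_model(1e2, 1e8, mutation_rate = 1e-8)
#' @export
culture_model <- function(initial_cells = 1e2, final_cells = 1e8,
                          mutation_rate = 0) {
  initial_cells <- check_count(initial_cells, "initial_cells", min = 1L)
  final_cells <- check_count(final_cells, "final_cells", min = 1L)
  if (final_cells < initial_cells) {
    abort("`final_cells` must be >= `initial_cells`.")
  }
  mutation_rate <- check_prob(mutation_rate, "mutation_rate")
  g <- if (final_cells == initial_cells) 0L else
    as.integer(ceiling(log2(final_cells / initial_cells)))
  structure(
    list(initial_cells = initial_cells,
         final_cells = final_cells,
         mutation_rate = mutation_rate,
         generations = g,
         divisions = final_cells - initial_cells),
    class = "culture_model"
  )
}

#' @export
print.culture_model <- function(x, ...) {
  cat(sprintf(
    "<culture_model> N0 = %g, Nt = %g, mu = %g (%d generations, %g divisions)\n",
    x$initial_cells, x$final_cells, x$mutation_rate, x$generations,
    x$divisions))
  invisible(x)
}

#' Design of a parallel-culture fluctuation experiment
#'
#' A fluctuation test grows many small parallel cultures, plates most of
#' them whole under restrictive conditions (scoring each well positive or
#' negative for growth) and titers the rest to measure the final CFU per
#' well. The standard plate layout here is 100 selective wells and 20 titer
#' wells (the central 60 wells of two 96-well plates, 50 + 10 per plate).
#'
#' @param n_selective_cultures Wells plated whole on restrictive medium.
#' @param n_titer_cultures Wells used to titer final CFU per well.
#' @param culture_model A [culture_model()].
#' @param titer_noise `"none"` reports the deterministic Nt per titer well;
#'   `"poisson"` perturbs each titer count as Poisson(Nt).
#' @return A `fluctuation_design` list.
#' @examples
#' fluctuation_design(culture_model = culture_model(1e2, 1e8, 1e-8))
#' @export
fluctuation_design <- function(n_selective_cultures = 100,
                               n_titer_cultures = 20,
                               culture_model = culture_model(),
                               titer_noise = c("none", "poisson")) {
  n_selective_cultures <- check_count(n_selective_cultures,
                                      "n_selective_cultures", min = 1L)
  n_titer_cultures <- check_count(n_titer_cultures, "n_titer_cultures",
                                  min = 0L)
  if (!inherits(culture_model, "culture_model")) {
    abort("`culture_model` must be created with culture_model().")
  }
  titer_noise <- match.arg(titer_noise)
  structure(
    list(n_selective_cultures = n_selective_cultures,
         n_titer_cultures = n_titer_cultures,
         culture_model = culture_model,
         titer_noise = titer_noise),
    class = "fluctuation_design"
  )
}

#' @export
print.fluctuation_design <- function(x, ...) {
  cat(sprintf("<fluctuation_design> %g selective + %g titer wells\n",
              x$n_selective_cultures, x$n_titer_cultures))
  print(x$culture_model)
  invisible(x)
}
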