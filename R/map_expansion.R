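#' Genetic map-expansion factor
#'
#' Multiplier on per-meiosis effective recombination implied by a
#' population design, relative to a single meiosis:
#'
#' * `intermated_inbred`: `j/2 + (2^i - 1)/2^i`, where `j` is the number
#'   of generations of intermating and `i` the number of generations of
#'   inbreeding.
#' * `inbred_only`: `(2^(i+1) - 1)/2^i` for lines inbred without
#'   intermating.
#'
#' `i = Inf` gives the fully-inbred limit (`(2^i - 1)/2^i -> 1`;
#' `(2^(i+1) - 1)/2^i -> 2`).
#'
#' @param i generations of inbreeding (>= 0, `Inf` allowed).
#' @param j generations of intermating (>= 0; used by
#'   `intermated_inbred` only).
#' @param formula `"intermated_inbred"` (default) or `"inbred_only"`.
#' @return the expansion factor.
#' @examples
#' expansion_factor(i = Inf, j = 4)    # 3
#' expansion_factor(i = Inf, j = 14)   # 8
#' expansion_factor(i = 1, formula = "inbred_only")  # 1.5
#' @export
expansion_factor <- function(i = Inf, j = 0,
                             formula = c("intermated_inbred", "inbred_only")) {
  formula <- match.arg(formula)
  if (any(i < 0) || any(j < 0)) stop("i and j must be non-negative")
  inbred_term <- ifelse(is.infinite(i), 1, (2^i - 1) / 2^i)
  switch(formula,
         intermated_inbred = j / 2 + inbred_term,
         inbred_only = ifelse(is.infinite(i), 2, (2^(i + 1) - 1) / 2^i))
}

#' Scale effective recombination events between population designs
#'
#' Given the average effective recombination events per individual in one
#' population, estimates the average in another design sharing the same
#' per-meiosis baseline, by the ratio of their map-expansion factors.
#' For example, recombinant inbred lines intermated for 4 generations
#' (factor 3 in the fully-inbred limit) carrying 57 effective events
#' imply 57 x 8/3 = 152 events in a population intermated for 14
#' generations under the same limit.  The fully-inbred limit `i = Inf` is
#' the default convention even for noninbred intermated populations; pass
#' finite `i` to change it (e.g. `i = 0` for a strictly noninbred
#' population gives 57 x (7/2 + 0)/3 = 133 in the example above — the
#' choice of convention matters and is exposed deliberately).
#'
#' @param known_events effective recombination events per individual in
#'   the known population.
#' @param known,target lists with elements `i`, `j` and optional
#'   `formula`, as for [expansion_factor()].
#' @return estimated effective recombination events in the target design.
#' @examples
#' scale_effective_recombination(57, list(i = Inf, j = 4),
#'                               list(i = Inf, j = 14))  # 152
#' @export
scale_effective_recombination <- function(known_events, known, target) {
  stopifnot(is.numeric(known_events), known_events > 0)
  fk <- do.call(expansion_factor, known)
  ft <- do.call(expansion_factor, target)
  if (fk == 0) stop("known design has zero expansion factor")
  known_events * ft / fk
}
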