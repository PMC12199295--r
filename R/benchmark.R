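# Standard desk-scale benchmark conditions.
#
# The engine's behavioural claims are exercised on a fixed, fully
# reproducible desk-scale setup; see the package vignette for why each
# condition is what it is. Tests and scripts share this construction so the
# conditions cannot drift apart.

#' Desk-scale benchmark conditions
#'
#' Builds the package's standard desk-scale experiment: a three-reaction
#' fixture library (12 synthons per component), a surrogate scorer whose
#' hidden target is the product of the first synthon of each component of
#' the first reaction, a starting molecule chosen as the worst-scoring
#' member of a 100-product random baseline (the production protocol starts
#' from a poorly docked random molecule), and a desk-scaled run
#' configuration: 200 iterations, exploration for the first 150 with the
#' step-size controller on `[0.05, 0.6]` (+0.04 per rejection), refinement
#' at a fixed ratio of 0.08, candidate limit 60, `kT = 0.0025`.
#'
#' @param seed Integer seed controlling the fixture library, the baseline
#'   draw that selects the start, and nothing else.
#' @return List with `lib`, `target` (hidden target [rx_mol]), `scorer`,
#'   `start` (starting molecule SMILES), and `cfg` (an [run_config()]).
#' @export
desk_benchmark <- function(seed = 7L) {
  lib <- make_fixture_library(3L, 12L, seed = seed)
  rxn1 <- lib$reactions[[1L]]
  target <- run_reaction(rxn1, vapply(lib$synthons[[1L]], `[[`,
                                      character(1), 1L))
  scorer <- make_surrogate_scorer(target)
  cfg <- run_config(
    n_iterations = 200L, dynamic_phase_end = 150L,
    dynamic = list(m = 0.05, M = 0.6, s = 0.04),
    refinement_ratio = 0.08, kT = 0.0025,
    proposal = proposal_config(candidate_limit = 60L))
  pool <- suppressMessages(
    random_baseline(lib, 100L, scorer, cfg, seed = seed))
  start <- pool$smiles[which.max(pool$le2)]
  list(lib = lib, target = target, scorer = scorer, start = start,
       cfg = cfg)
}

#' Distinct molecules scored by a route
#'
#' The number of distinct molecules a route submitted to the scorer. With a
#' deterministic, memoised scorer this is the route's evaluation cost, and
#' the budget an equal-cost random baseline receives.
#'
#' @param record An `rx_route`.
#' @return Integer count.
#' @export
n_scored_unique <- function(record) {
  stopifnot(inherits(record, "rx_route"))
  scored <- record$trajectory$proposal[!is.na(record$trajectory$delta)]
  length(unique(scored))
}
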