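# The Monte Carlo Metropolis design loop, two-phase schedule, cascaded
# multi-round workflow, and random baselines.
#
# Each iteration: (1) generate candidates by similarity-guided fragment
# sampling and pick one; (2) ligand filters; (3) if pose tracking is on,
# map atoms to the previous ligand, superpose conformers, keep the closest,
# and apply the pocket-location filter; (4) score; (5) Metropolis accept or
# reject on the design-score difference. Any failure on the way (no
# candidates, filter rejection, empty atom mapping, pocket miss) counts as a
# rejected iteration for the step-size controller. Rejection restores the
# prior state exactly.
#
# No-op proposals: the current molecule is itself a library product and its
# own synthons rank at the top of the similarity ranking, so at small
# sampling ratios the engine frequently re-proposes the current state. Such
# a proposal has delta = 0 and is accepted by the Metropolis rule, but it
# moves nothing; if it also reset the step-size controller, small libraries
# would make the no-op an absorbing state. The controller therefore treats
# an accepted no-op like a rejection (the ratio keeps ramping until the
# search actually moves), which is exactly the trapped-in-a-neighbourhood
# escape behaviour dynamic sampling exists to provide. See the vignette.

#' Run configuration for the design engine
#'
#' Defaults follow the production settings of the method: 2000 iterations
#' with dynamic sampling (ratio range 0.01--0.2, +0.002 per rejection) for
#' the first half, then a refinement phase at a fixed small ratio of 1e-4
#' with the controller off.
#'
#' @param n_iterations Monte Carlo iterations (default 2000).
#' @param dynamic_phase_end 0-based iteration at which exploration ends
#'   (default `n_iterations / 2`).
#' @param dynamic List `list(m, M, s, enabled)` for the step-size controller
#'   (defaults 0.01, 0.2, 0.002, TRUE).
#' @param sampling_ratio Fixed exploration ratio used when the controller is
#'   disabled (default `dynamic$m`).
#' @param refinement_ratio Fixed ratio of the refinement phase (default 1e-4).
#' @param kT Metropolis temperature factor in design-score units (default
#'   0.1; see the package vignette for the calibration rationale).
#' @param proposal A [proposal_config()].
#' @param filters A [filter_set()].
#' @param score_mode `"le2"` (default) or `"raw"` interface energy.
#' @param conformers_k Conformers generated per accepted-candidate alignment
#'   when pose tracking is on (default 20).
#' @param seed Default RNG seed for [run_route()] (optional).
#' @return A list of class `rx_config`.
#' @export
run_config <- function(n_iterations = 2000L, dynamic_phase_end = NULL,
                       dynamic = list(m = 0.01, M = 0.2, s = 0.002,
                                      enabled = TRUE),
                       sampling_ratio = NULL, refinement_ratio = 1e-4,
                       kT = 0.1, proposal = proposal_config(),
                       filters = filter_set(), score_mode = c("le2", "raw"),
                       conformers_k = 20L, seed = NULL) {
  n_iterations <- as.integer(n_iterations)
  if (is.null(dynamic_phase_end)) dynamic_phase_end <- n_iterations %/% 2L
  dynamic_phase_end <- as.integer(dynamic_phase_end)
  stopifnot(n_iterations >= 0L, dynamic_phase_end >= 0L,
            dynamic_phase_end <= n_iterations, kT > 0,
            refinement_ratio > 0, refinement_ratio < 1)
  dyn <- utils::modifyList(list(m = 0.01, M = 0.2, s = 0.002, enabled = TRUE),
                           dynamic)
  if (is.null(sampling_ratio)) sampling_ratio <- dyn$m
  structure(list(n_iterations = n_iterations,
                 dynamic_phase_end = dynamic_phase_end,
                 dynamic = dyn, sampling_ratio = sampling_ratio,
                 refinement_ratio = refinement_ratio, kT = kT,
                 proposal = proposal, filters = filters,
                 score_mode = match.arg(score_mode),
                 conformers_k = as.integer(conformers_k), seed = seed),
            class = "rx_config")
}

#' Optimization phase of an iteration
#'
#' @param iteration 0-based iteration index.
#' @param cfg An [run_config()].
#' @return `"exploration"` if `iteration < dynamic_phase_end`, else
#'   `"refinement"` (fixed small sampling ratio, controller off).
#' @export
phase_of <- function(iteration, cfg) {
  stopifnot(iteration >= 0L, iteration <= cfg$n_iterations)
  if (iteration < cfg$dynamic_phase_end) "exploration" else "refinement"
}

# effective design score of a molecule under a scorer + filters
.design_score <- function(mol, pose, scorer, cfg, penalty = 0) {
  energy <- scorer(mol, pose)
  stopifnot(is.finite(energy))
  base <- if (cfg$score_mode == "le2") le2(energy, mol$n_heavy) else energy
  list(energy = energy, score = base + penalty)
}

#' Run one Monte Carlo design route
#'
#' @param lib An `rx_library`.
#' @param initial Starting molecule ([rx_mol] or SMILES).
#' @param cfg An [run_config()].
#' @param scorer Scorer function (see [register_scorer()]), e.g. from
#'   [make_surrogate_scorer()].
#' @param initial_pose Optional [rx_pose] of the starting molecule; when
#'   given, pose tracking (atom mapping, conformer superposition and the
#'   pocket filter) is active.
#' @param pocket Optional [rx_pocket] (requires `initial_pose`).
#' @param seed RNG seed (default `cfg$seed`); the route is fully
#'   deterministic given the seed.
#' @return An object of class `rx_route`: list with `accepted` (data frame:
#'   iteration, smiles, energy, le2, n_heavy), `trajectory` (one row per
#'   iteration: iteration, proposal, verdict, delta, ratio, accepted),
#'   `best` (row of `accepted` with the lowest design score),
#'   `proposed_count`, `rejected_count`, `provenance`, `seed`, `config`.
#' @export
run_route <- function(lib, initial, cfg = run_config(), scorer,
                      initial_pose = NULL, pocket = NULL, seed = cfg$seed) {
  stopifnot(inherits(lib, "rx_library"), is.function(scorer))
  if (!is.null(pocket) && is.null(initial_pose)) {
    stop("a pocket filter requires an initial pose", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  current <- rx_mol(initial)
  current_pose <- initial_pose
  v0 <- apply_filters(current, cfg$filters)
  sc <- .design_score(current, current_pose, scorer, cfg,
                      if (v0$status == "penalize") v0$penalty else 0)
  ctrl <- sampling_controller(cfg$dynamic$m, cfg$dynamic$M, cfg$dynamic$s,
                              cfg$dynamic$enabled)
  accepted <- data.frame(iteration = 0L, smiles = current$smiles,
                         energy = sc$energy, le2 = sc$score,
                         n_heavy = current$n_heavy, stringsAsFactors = FALSE)
  provenance <- list(list(reaction_id = NA_character_,
                          synthons = character()))
  traj <- vector("list", cfg$n_iterations)
  rejected <- 0L
  for (it in seq_len(cfg$n_iterations)) {
    phase <- phase_of(it - 1L, cfg)
    x <- if (phase == "exploration") {
      if (cfg$dynamic$enabled) ctrl$current else cfg$sampling_ratio
    } else cfg$refinement_ratio
    step <- list(iteration = it, proposal = NA_character_,
                 verdict = "no_candidates", delta = NA_real_, ratio = x,
                 accepted = FALSE)
    cands <- propose_candidates(lib, current, x, cfg$proposal)
    if (length(cands)) {
      cand <- select_candidate(cands, current, x)
      step$proposal <- cand$smiles
      verdict <- apply_filters(cand, cfg$filters)
      if (verdict$status == "reject") {
        step$verdict <- paste0("filter_reject: ", verdict$reason)
      } else {
        cand_pose <- NULL
        pose_ok <- TRUE
        if (!is.null(current_pose)) {
          mapping <- map_atoms(current, cand)
          if (!nrow(mapping)) {
            step$verdict <- "no_atom_mapping"
            pose_ok <- FALSE
          } else {
            confs <- generate_conformers(cand, cfg$conformers_k)
            sel <- select_pose(confs, current_pose, mapping,
                               k = cfg$conformers_k)
            cand_pose <- sel$pose
            if (!is.null(pocket) && !com_in_pocket(cand_pose, pocket)) {
              step$verdict <- "pocket_filter"
              pose_ok <- FALSE
            }
          }
        }
        if (pose_ok) {
          cs <- .design_score(cand, cand_pose, scorer, cfg,
                              if (verdict$status == "penalize")
                                verdict$penalty else 0)
          step$delta <- cs$score - sc$score
          if (metropolis_accept(step$delta, cfg$kT)) {
            step$verdict <- if (cand$smiles == current$smiles)
              "accepted_noop" else "accepted"
            step$accepted <- TRUE
            current <- cand
            current_pose <- cand_pose
            sc <- cs
            accepted <- rbind(accepted, data.frame(
              iteration = it, smiles = current$smiles, energy = sc$energy,
              le2 = sc$score, n_heavy = current$n_heavy,
              stringsAsFactors = FALSE))
            prov <- attr(cand, "provenance")
            provenance[[length(provenance) + 1L]] <-
              if (is.null(prov)) list(reaction_id = NA_character_,
                                      synthons = character()) else prov
          } else {
            step$verdict <- "metropolis_reject"
          }
        }
      }
    }
    if (!step$accepted) rejected <- rejected + 1L
    # an accepted no-op does not reset the step-size ramp (see header note)
    ctrl <- update_controller(ctrl, step$accepted &&
                                      step$verdict != "accepted_noop")
    traj[[it]] <- step
  }
  trajectory <- do.call(rbind, lapply(traj, function(s)
    data.frame(s, stringsAsFactors = FALSE)))
  if (is.null(trajectory)) {
    trajectory <- data.frame(iteration = integer(), proposal = character(),
                             verdict = character(), delta = numeric(),
                             ratio = numeric(), accepted = logical(),
                             stringsAsFactors = FALSE)
  }
  best_i <- which.min(accepted$le2)
  structure(list(accepted = accepted, trajectory = trajectory,
                 best = accepted[best_i, , drop = FALSE],
                 final_pose = current_pose,
                 proposed_count = sum(!is.na(trajectory$proposal)),
                 rejected_count = rejected,
                 provenance = provenance, seed = seed, config = cfg),
            class = "rx_route")
}

#' @export
print.rx_route <- function(x, ...) {
  cat("<rx_route> ", x$config$n_iterations, " iterations, ",
      nrow(x$accepted) - 1L, " accepted moves\n", sep = "")
  cat("  best: ", x$best$smiles, "  design score ",
      signif(x$best$le2, 5), "\n", sep = "")
  invisible(x)
}

#' @export
summary.rx_route <- function(object, ...) {
  acc <- object$accepted
  out <- list(
    n_iterations = object$config$n_iterations,
    n_accepted = nrow(acc) - 1L,
    n_rejected = object$rejected_count,
    n_scored = sum(!is.na(object$trajectory$delta)),
    best_smiles = object$best$smiles,
    best_score = object$best$le2,
    mean_step_size = if (nrow(acc) >= 2L) mean_step_size(object) else NA_real_)
  class(out) <- "summary.rx_route"
  out
}

#' @export
print.summary.rx_route <- function(x, ...) {
  cat("Monte Carlo design route\n")
  cat("  iterations:     ", x$n_iterations, "\n")
  cat("  accepted moves: ", x$n_accepted, "\n")
  cat("  scored props:   ", x$n_scored, "\n")
  cat("  best design:    ", x$best_smiles, "\n")
  cat("  best score:     ", signif(x$best_score, 5), "\n")
  if (!is.na(x$mean_step_size)) {
    cat("  mean step size: ", signif(x$mean_step_size, 4),
        " (Tanimoto between consecutive accepted ligands)\n")
  }
  invisible(x)
}

#' @export
plot.rx_route <- function(x, ...) {
  acc <- x$accepted
  graphics::plot(acc$iteration, acc$le2, type = "s",
                 xlab = "Monte Carlo iteration", ylab = "design score (LE2)",
                 main = "Accepted-state design score", ...)
  graphics::points(acc$iteration, acc$le2, pch = 20)
  if (x$config$dynamic_phase_end > 0 &&
      x$config$dynamic_phase_end < x$config$n_iterations) {
    graphics::abline(v = x$config$dynamic_phase_end, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Random-product baseline
#'
#' Draws `n` random products from the library (reactions
#' with replacement, synthons without) and scores each one -- the
#' equal-budget comparison set for design routes.
#'
#' @param lib An `rx_library`.
#' @param n Number of molecules.
#' @param scorer Scorer function.
#' @param cfg An [run_config()] (supplies score mode and filters; filter
#'   penalties are applied to the score as in the engine, rejected molecules
#'   keep their score but are flagged).
#' @param seed RNG seed.
#' @return Data frame: `smiles`, `energy`, `le2`, `n_heavy`, `filter_status`.
#' @export
random_baseline <- function(lib, n, scorer, cfg = run_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mols <- random_products(lib, n)
  rows <- lapply(mols, function(m) {
    v <- apply_filters(m, cfg$filters)
    s <- .design_score(m, NULL, scorer, cfg,
                       if (v$status == "penalize") v$penalty else 0)
    data.frame(smiles = m$smiles, energy = s$energy, le2 = s$score,
               n_heavy = m$n_heavy, filter_status = v$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select diverse next-round seeds from finished routes
#'
#' Ranks the route-best designs by design score, keeps the `top_k` best, and
#' greedily selects `pick` of them maximising the minimum pairwise Tanimoto
#' distance (the best-scoring design is always selected first, so the best
#' route is always extended). Each seed carries its final pose when the
#' route tracked poses.
#'
#' @param records Non-empty list of `rx_route`.
#' @param top_k Pool size (default 5).
#' @param pick Number of seeds (<= `top_k`).
#' @return List of seeds: each a list with `mol`, `pose` (may be `NULL`) and
#'   `from_best` (the design score of the originating route).
#' @export
cascade_round <- function(records, top_k = 5L, pick = 1L) {
  stopifnot(length(records) >= 1L, pick >= 1L, pick <= top_k)
  if (top_k > length(records)) top_k <- length(records)
  if (pick > top_k) stop("pick > available routes", call. = FALSE)
  bests <- vapply(records, function(r) r$best$le2, numeric(1))
  ord <- order(bests)[seq_len(top_k)]
  pool <- records[ord]
  smi <- vapply(pool, function(r) r$best$smiles, character(1))
  fpm <- fp_matrix(smi)
  dist <- 1 - vapply(seq_along(smi), function(i)
    tanimoto_vec(rx_fingerprint(smi[i]), fpm), numeric(length(smi)))
  sel <- 1L   # always extend the best-scoring route
  while (length(sel) < pick) {
    rem <- setdiff(seq_along(smi), sel)
    mind <- vapply(rem, function(j) min(dist[j, sel]), numeric(1))
    sel <- c(sel, rem[which.max(mind)])   # ties: earliest (= best score)
  }
  lapply(sel, function(i) list(mol = rx_mol(smi[i]),
                               pose = pool[[i]]$final_pose,
                               from_best = pool[[i]]$best$le2))
}

#' Run a cascaded multi-round design campaign
#'
#' Round 1 launches `n_routes` independent routes from the initial molecule;
#' each later round launches `n_routes` from each of the `pick` diverse
#' top-`top_k` seeds of the previous round ([cascade_round()]), with scorer
#' and filter state reset. Route `i` (counted across the whole campaign)
#' uses seed `seed + i`.
#'
#' @param lib An `rx_library`.
#' @param initial Starting molecule.
#' @param cfg An [run_config()].
#' @param scorer Scorer function.
#' @param n_routes Routes per starting entity per round.
#' @param n_rounds Number of rounds (default 3).
#' @param top_k,pick Cascade selection parameters (defaults 5, 1).
#' @param seed Campaign seed.
#' @param initial_pose,pocket Optional pose tracking (as in [run_route()]).
#' @return An object of class `rx_campaign`: list with `rounds` (list of
#'   lists of `rx_route`), `seeds` (cascade seeds used per round), `config`.
#' @export
run_campaign <- function(lib, initial, cfg = run_config(), scorer,
                         n_routes = 10L, n_rounds = 3L, top_k = 5L,
                         pick = 1L, seed = 1L,
                         initial_pose = NULL, pocket = NULL) {
  stopifnot(n_routes >= 1L, n_rounds >= 1L)
  rounds <- list()
  seeds_used <- list()
  starts <- list(list(mol = rx_mol(initial), pose = initial_pose))
  route_counter <- 0L
  for (round in seq_len(n_rounds)) {
    seeds_used[[round]] <- starts
    recs <- list()
    for (st in starts) {
      for (i in seq_len(n_routes)) {
        route_counter <- route_counter + 1L
        recs[[length(recs) + 1L]] <- run_route(
          lib, st$mol, cfg, scorer, initial_pose = st$pose, pocket = pocket,
          seed = seed + route_counter)
      }
    }
    rounds[[round]] <- recs
    if (round < n_rounds) starts <- cascade_round(recs, top_k, pick)
  }
  structure(list(rounds = rounds, seeds = seeds_used, config = cfg,
                 seed = seed), class = "rx_campaign")
}

#' @export
print.rx_campaign <- function(x, ...) {
  cat("<rx_campaign> ", length(x$rounds), " round(s)\n", sep = "")
  for (r in seq_along(x$rounds)) {
    bests <- vapply(x$rounds[[r]], function(rt) rt$best$le2, numeric(1))
    cat("  round ", r, ": ", length(bests), " routes; best ",
        signif(min(bests), 5), ", median ", signif(stats::median(bests), 5),
        "\n", sep = "")
  }
  invisible(x)
}

#' Unique final designs of a campaign round
#'
#' Route-best molecules of one round, deduplicated by canonical SMILES.
#'
#' @param campaign An `rx_campaign`.
#' @param round Round number (default: last).
#' @return Data frame: `route_id`, `smiles`, `le2`, `n_heavy`, `scaffold`.
#' @export
campaign_designs <- function(campaign, round = length(campaign$rounds)) {
  recs <- campaign$rounds[[round]]
  df <- do.call(rbind, lapply(seq_along(recs), function(i) {
    b <- recs[[i]]$best
    data.frame(route_id = i, smiles = b$smiles, le2 = b$le2,
               n_heavy = b$n_heavy, stringsAsFactors = FALSE)
  }))
  df <- df[!duplicated(df$smiles), , drop = FALSE]
  df$scaffold <- vapply(df$smiles, murcko_scaffold, character(1),
                        USE.NAMES = FALSE)
  rownames(df) <- NULL
  df
}
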