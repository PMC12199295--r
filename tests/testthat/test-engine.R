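# The Monte Carlo design loop, phases, cascade, campaign.

engine_fixture <- function() {
  lib <- fixture_lib(3, 6, seed = 7)
  target <- run_reaction(lib$reactions[[1]],
                         vapply(lib$synthons[[1]], `[[`, character(1), 1))
  list(lib = lib, target = target,
       scorer = make_surrogate_scorer(target),
       start = run_reaction(lib$reactions[[2]],
                            vapply(lib$synthons[[2]], `[[`, character(1), 2)))
}

small_cfg <- function(n = 30L, ...) {
  run_config(n_iterations = n, kT = 0.005,
             dynamic = list(m = 0.05, M = 0.5, s = 0.02),
             refinement_ratio = 0.05,
             proposal = proposal_config(candidate_limit = 12), ...)
}

test_that("zero iterations yield a record with only the initial state", {
  fx <- engine_fixture()
  r <- run_route(fx$lib, fx$start, small_cfg(0), fx$scorer, seed = 1)
  expect_equal(nrow(r$accepted), 1L)
  expect_identical(r$accepted$smiles, fx$start$smiles)
  expect_equal(nrow(r$trajectory), 0L)
  expect_identical(r$best$smiles, fx$start$smiles)
})

test_that("routes are byte-identical under a fixed seed", {
  fx <- engine_fixture()
  r1 <- run_route(fx$lib, fx$start, small_cfg(25), fx$scorer, seed = 5)
  r2 <- run_route(fx$lib, fx$start, small_cfg(25), fx$scorer, seed = 5)
  expect_identical(r1$accepted, r2$accepted)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("phase schedule follows the dynamic_phase_end boundary", {
  cfg <- run_config(n_iterations = 2000, dynamic_phase_end = 1000)
  expect_identical(phase_of(999, cfg), "exploration")
  expect_identical(phase_of(1000, cfg), "refinement")
  cfg0 <- run_config(n_iterations = 100, dynamic_phase_end = 0)
  expect_identical(phase_of(0, cfg0), "refinement")
  # defaults: half/half split, production iteration count
  expect_equal(run_config()$n_iterations, 2000L)
  expect_equal(run_config()$dynamic_phase_end, 1000L)
  expect_equal(run_config()$dynamic[c("m", "M", "s")],
               list(m = 0.01, M = 0.2, s = 0.002))
  expect_equal(run_config()$refinement_ratio, 1e-4)
})

test_that("the ratio trace replays from the verdict sequence", {
  fx <- engine_fixture()
  cfg <- small_cfg(40)
  r <- run_route(fx$lib, fx$start, cfg, fx$scorer, seed = 6)
  tr <- r$trajectory
  cur <- cfg$dynamic$m
  for (i in seq_len(nrow(tr))) {
    expected <- if (phase_of(i - 1L, cfg) == "exploration") cur
                else cfg$refinement_ratio
    expect_equal(tr$ratio[i], expected, tolerance = 1e-12)
    moved <- tr$accepted[i] && tr$verdict[i] != "accepted_noop"
    cur <- if (moved) cfg$dynamic$m
           else min(cur + cfg$dynamic$s, cfg$dynamic$M)
  }
})

test_that("the running best design score is monotone non-increasing", {
  fx <- engine_fixture()
  r <- run_route(fx$lib, fx$start, small_cfg(40), fx$scorer, seed = 7)
  expect_true(all(diff(cummin(r$accepted$le2)) <= 0))
  expect_equal(r$best$le2, min(r$accepted$le2))
})

test_that("every accepted molecule is a product of exactly one library reaction", {
  fx <- engine_fixture()
  r <- run_route(fx$lib, fx$start, small_cfg(40), fx$scorer, seed = 8)
  # full enumeration of the library product space per reaction
  space <- lapply(fx$lib$reactions, function(rxn) {
    ps <- enumerate_products(list(reaction = rxn,
                                  sub_containers = fx$lib$synthons[[
                                    rxn$reaction_id]]))
    vapply(ps, `[[`, character(1), "smiles")
  })
  for (smi in r$accepted$smiles[-1]) {
    hits <- vapply(space, function(s) smi %in% s, logical(1))
    expect_identical(sum(hits), 1L)
  }
  # provenance re-derivation agrees
  for (k in seq_along(r$provenance)[-1]) {
    prov <- r$provenance[[k]]
    redo <- run_reaction(fx$lib$reactions[[prov$reaction_id]],
                         as.list(prov$synthons))
    expect_identical(redo$smiles, r$accepted$smiles[k])
  }
})

test_that("strictly better proposals are always accepted; worse ones decay", {
  fx <- engine_fixture()
  r <- run_route(fx$lib, fx$start, small_cfg(60), fx$scorer, seed = 9)
  tr <- r$trajectory[!is.na(r$trajectory$delta), ]
  expect_true(all(tr$accepted[tr$delta < 0]))
  worse <- tr[tr$delta > 0, ]
  if (nrow(worse) >= 10) {
    lo <- worse$accepted[worse$delta <= stats::median(worse$delta)]
    hi <- worse$accepted[worse$delta > stats::median(worse$delta)]
    expect_gte(mean(lo), mean(hi))
  }
})

test_that("cascade_round extends the best route and never repeats a duplicate", {
  fx <- engine_fixture()
  rts <- lapply(1:4, function(i)
    run_route(fx$lib, fx$start, small_cfg(25), fx$scorer, seed = 20 + i))
  seeds <- cascade_round(rts, top_k = 1, pick = 1)
  bests <- vapply(rts, function(r) r$best$le2, numeric(1))
  expect_identical(seeds[[1]]$mol$smiles, rts[[which.min(bests)]]$best$smiles)
  expect_error(cascade_round(rts, top_k = 2, pick = 3), "pick")
})

test_that("cascade_round never forwards a duplicate molecule twice", {
  fake_route <- function(s, score) {
    row <- data.frame(iteration = 0L, smiles = canonical_smiles(s),
                      energy = score, le2 = score, n_heavy = 10L)
    structure(list(accepted = row, best = row, final_pose = NULL),
              class = "rx_route")
  }
  routes <- Map(fake_route,
                c("CC(=O)NC", "CC(=O)NC", "CC(=O)NCC", "CCS(=O)(=O)NC",
                  "CCOC(=O)C"),
                c(-0.5, -0.5, -0.4, -0.35, -0.3))   # best molecule duplicated
  s2 <- cascade_round(routes, top_k = 5, pick = 2)
  expect_false(identical(s2[[1]]$mol$smiles, s2[[2]]$mol$smiles))
  expect_identical(s2[[1]]$mol$smiles, canonical_smiles("CC(=O)NC"))
})

test_that("greedy max-min diversity pick matches exhaustive search", {
  # crafted pool: the most distant pair contains the best-scoring design,
  # so the greedy pick (which always keeps the best) is also the global
  # max-min optimum over all C(5,2) subsets
  smi <- c("CCOc1ccsc1C(=O)NC",        # best score, acid family
           "CCOc1ccsc1C(=O)NCC",       # close analog of 1
           "CCOc1ccsc1C(=O)NCCC",      # close analog of 1
           "CCOc1ccsc1C(=O)NC(C)C",    # close analog of 1
           "CCCCS(=O)(=O)NC1CCCC1")    # structurally remote
  fake_route <- function(s, score) {
    structure(list(
      accepted = data.frame(iteration = 0L, smiles = canonical_smiles(s),
                            energy = score, le2 = score, n_heavy = 10L),
      best = data.frame(iteration = 0L, smiles = canonical_smiles(s),
                        energy = score, le2 = score, n_heavy = 10L),
      final_pose = NULL), class = "rx_route")
  }
  routes <- Map(fake_route, smi, c(-0.5, -0.45, -0.4, -0.35, -0.3))
  picked <- cascade_round(routes, top_k = 5, pick = 2)
  got <- sort(vapply(picked, function(s) s$mol$smiles, character(1)))
  # exhaustive max-min over all pairs
  fpm <- lapply(smi, rx_fingerprint)
  pairs <- utils::combn(5, 2)
  dmin <- apply(pairs, 2, function(ij)
    1 - tanimoto(fpm[[ij[1]]], fpm[[ij[2]]]))
  bestpair <- pairs[, which.max(dmin)]
  expect_identical(got, sort(canonical_smiles(smi[bestpair])))
})

test_that("a one-round campaign equals independent routes with offset seeds", {
  fx <- engine_fixture()
  cfg <- small_cfg(20)
  camp <- run_campaign(fx$lib, fx$start, cfg, fx$scorer, n_routes = 2,
                       n_rounds = 1, seed = 50)
  solo <- lapply(1:2, function(i)
    run_route(fx$lib, fx$start, cfg, fx$scorer, seed = 50 + i))
  expect_identical(lapply(camp$rounds[[1]], `[[`, "accepted"),
                   lapply(solo, `[[`, "accepted"))
})

test_that("campaign rounds start from the cascade seeds", {
  fx <- engine_fixture()
  cfg <- small_cfg(20)
  camp <- run_campaign(fx$lib, fx$start, cfg, fx$scorer, n_routes = 3,
                       n_rounds = 2, top_k = 2, pick = 1, seed = 60)
  expected_seed <- cascade_round(camp$rounds[[1]], top_k = 2, pick = 1)
  expect_identical(camp$seeds[[2]][[1]]$mol$smiles,
                   expected_seed[[1]]$mol$smiles)
  starts2 <- vapply(camp$rounds[[2]], function(r) r$accepted$smiles[1],
                    character(1))
  expect_true(all(starts2 == expected_seed[[1]]$mol$smiles))
  d <- campaign_designs(camp)
  expect_true(all(c("route_id", "smiles", "le2", "n_heavy", "scaffold")
                  %in% names(d)))
  expect_identical(anyDuplicated(d$smiles), 0L)
})

test_that("raw score mode optimises interface energy, not LE2", {
  fx <- engine_fixture()
  cfg <- run_config(n_iterations = 10L, kT = 0.5, score_mode = "raw",
                    dynamic = list(m = 0.05, M = 0.5, s = 0.04),
                    refinement_ratio = 0.08,
                    proposal = proposal_config(candidate_limit = 12L))
  r <- run_route(fx$lib, fx$start, cfg, fx$scorer, seed = 90)
  # unpenalised accepted states carry the raw energy as their design score
  ok <- abs(r$accepted$le2 - r$accepted$energy) < 1e-9 |
        abs(r$accepted$le2 - r$accepted$energy - 0.5) < 1e-9
  expect_true(all(ok))
})

test_that("pose tracking runs the alignment and pocket machinery", {
  fx <- engine_fixture()
  pose0 <- generate_conformers(fx$start, 1)[[1]]
  pocket <- rx_pocket(colMeans(pose0$coords), radius = 7.5)
  cfg <- small_cfg(8, conformers_k = 4L)
  r <- run_route(fx$lib, fx$start, cfg, fx$scorer,
                 initial_pose = pose0, pocket = pocket, seed = 70)
  expect_s3_class(r, "rx_route")
  expect_true(all(r$trajectory$verdict %in%
    c("accepted", "accepted_noop", "metropolis_reject", "no_candidates",
      "no_atom_mapping", "pocket_filter") |
    startsWith(r$trajectory$verdict, "filter_reject")))
  if (nrow(r$accepted) > 1) expect_false(is.null(r$final_pose))
  expect_error(run_route(fx$lib, fx$start, cfg, fx$scorer,
                         pocket = pocket, seed = 1), "initial pose")
})
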