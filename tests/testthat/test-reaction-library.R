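# Reactions, product enumeration, random baselines, fixture libraries.

test_that("amide coupling gives the hand-derived product", {
  # acetic acid + methylamine -> N-methylacetamide
  p <- run_reaction(amide_rxn(), c("CC(=O)O", "CN"))
  expect_identical(p$smiles, canonical_smiles("CNC(C)=O"))
  prov <- attr(p, "provenance")
  expect_identical(prov$reaction_id, "amide")
  expect_identical(prov$synthons,
                   c(canonical_smiles("CC(=O)O"), canonical_smiles("CN")))
})

test_that("swapped component order fails rather than silently misassigning", {
  expect_null(run_reaction(amide_rxn(), c("CN", "CC(=O)O")))
})

test_that("arity and SMARTS validation are enforced", {
  expect_error(run_reaction(amide_rxn(), c("CC(=O)O")), "needs 2 fragments")
  expect_error(rx_reaction("bad", "[C:1][OH]>>"), "bad")
  expect_error(rx_reaction("bad", "[C:1](=[O:2])[OX2H1]>>[C:1](=[O:2])[N:9]"),
               "absent from reactants")
})

test_that("multi-match substrates give one deterministic product", {
  # succinic acid offers two acid sites; product must be reproducible
  p1 <- run_reaction(amide_rxn(), c("OC(=O)CCC(=O)O", "CN"))
  p2 <- run_reaction(amide_rxn(), c("OC(=O)CCC(=O)O", "CN"))
  expect_false(is.null(p1))
  expect_identical(p1$smiles, p2$smiles)
  expect_identical(p1$smiles, canonical_smiles("CNC(=O)CCC(=O)O"))
})

test_that("enumerate_products covers the cross product and truncates", {
  cont <- list(reaction = amide_rxn(),
               sub_containers = list(c("CC(=O)O", "CCC(=O)O"),
                                     c("CN", "CCN", "NC1CCCCC1")))
  prods <- enumerate_products(cont)
  expect_length(prods, 6L)
  expect_length(enumerate_products(cont, limit = 4), 4L)
  # two spellings of one acid yield the same canonical products: deduplicated
  cont2 <- list(reaction = amide_rxn(),
                sub_containers = list(c("CC(=O)O", "OC(C)=O"), "CN"))
  expect_length(enumerate_products(cont2), 1L)
})

test_that("every enumerated product re-derives from its provenance", {
  lib <- fixture_lib()
  cont <- list(reaction = lib$reactions[[1]],
               sub_containers = lapply(lib$synthons[[1]], utils::head, 3))
  for (p in enumerate_products(cont)) {
    prov <- attr(p, "provenance")
    redo <- run_reaction(lib$reactions[[prov$reaction_id]],
                         as.list(prov$synthons))
    expect_identical(redo$smiles, p$smiles)
  }
})

test_that("fixture library is valid, deterministic and sized as requested", {
  lib <- fixture_lib(3, 6, seed = 7)
  expect_length(lib$reactions, 3L)
  arity <- vapply(lib$reactions, `[[`, integer(1), "n_components")
  expect_true(any(arity == 3L))   # a 3-component reaction is present
  for (rid in names(lib$synthons)) {
    for (ci in seq_along(lib$synthons[[rid]])) {
      comp <- lib$synthons[[rid]][[ci]]
      expect_length(comp, 6L)
      tmpl <- lib$reactions[[rid]]$reactants[[ci]]
      for (s in comp) {
        expect_gt(length(rxnmc:::match_smarts(tmpl, rxnmc:::mol_graph(s), 1L)),
                  0L)
      }
    }
  }
  lib2 <- suppressMessages(make_fixture_library(3, 6, seed = 7))
  expect_identical(lib$synthons, lib2$synthons)
  expect_identical(lib$fragments, lib2$fragments)
})

test_that("the fixture's two-component space is densely enumerable", {
  lib <- fixture_lib(3, 6, seed = 7)
  cont <- list(reaction = lib$reactions[[1]],
               sub_containers = lib$synthons[[1]])
  prods <- enumerate_products(cont)
  # 6 x 6 cross product, nearly all combinations must react successfully
  expect_gte(length(prods), 32L)
})

test_that("library round-trips through the TSV files", {
  lib <- fixture_lib(3, 6, seed = 7)
  rp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  save_library(lib, rp, sp)
  lib2 <- suppressWarnings(load_library(rp, sp))
  expect_identical(names(lib2$reactions), names(lib$reactions))
  expect_identical(lapply(lib2$synthons, lapply, sort),
                   lapply(lib$synthons, lapply, canonical_smiles) |>
                     lapply(lapply, sort))
  expect_identical(sort(lib2$fragments), sort(lib$fragments))
})

test_that("non-matching and duplicate synthons are handled at load", {
  rxn <- amide_rxn()
  # hexane matches no component; duplicate amine collapses
  expect_warning(
    lib <- combinatorial_library(
      list(rxn), list(amide = list(c("CC(=O)O", "CCCCCC"),
                                   c("CN", "NC", "CCN")))),
    "not matching")
  expect_length(lib$synthons$amide[[1]], 1L)
  expect_length(lib$synthons$amide[[2]], 2L)   # CN and NC are one synthon
  expect_error(
    suppressWarnings(combinatorial_library(
      list(rxn), list(amide = list("CCCCCC", "CN")))),
    "no valid synthons")
})

test_that("random_products honours n, determinism, and reaction uniformity", {
  lib <- fixture_lib(3, 6, seed = 7)
  expect_length(random_products(lib, 0), 0L)
  set.seed(10)
  a <- suppressMessages(random_products(lib, 25))
  set.seed(10)
  b <- suppressMessages(random_products(lib, 25))
  expect_identical(vapply(a, `[[`, character(1), "smiles"),
                   vapply(b, `[[`, character(1), "smiles"))
  expect_true(all(vapply(a, function(m) !is.na(canonical_smiles(m$smiles)),
                         logical(1))))
  # reactions drawn uniformly with replacement: 3-sigma binomial band
  set.seed(11)
  draws <- suppressMessages(random_products(lib, 240))
  rid <- vapply(draws, function(m) attr(m, "provenance")$reaction_id,
                character(1))
  n <- length(rid); p0 <- 1 / 3
  for (r in names(lib$reactions)) {
    expect_lt(abs(sum(rid == r) / n - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
})
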