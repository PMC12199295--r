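# Atom mapping, rigid superposition, conformer selection, pocket filter.

test_that("identical molecules map completely", {
  m <- "CC(=O)Nc1ccccc1"
  mp <- map_atoms(m, m)
  expect_equal(nrow(mp), rx_mol(m)$n_heavy)
  expect_identical(anyDuplicated(mp[, "new"]), 0L)
})

test_that("toluene/ethylbenzene share the ring plus one carbon", {
  mp <- map_atoms("Cc1ccccc1", "CCc1ccccc1")
  # hand-derived maximum common substructure: 6 ring atoms + 1 carbon
  expect_equal(nrow(mp), 7L)
  g <- rxnmc:::mol_graph("Cc1ccccc1")
  ring_atoms <- which(g$atoms$in_ring)
  expect_gte(sum(mp[, "prev"] %in% ring_atoms), 6L)
})

test_that("molecules with no meaningful common substructure map <= 1 atom", {
  expect_lte(nrow(map_atoms("C", "c1ccccc1")), 1L)
})

test_that("superposition removes rigid motions exactly", {
  set.seed(30)
  m <- rx_mol("CCOC(=O)C")
  coords <- matrix(rnorm(3 * m$n_heavy, sd = 2), ncol = 3)
  ref <- rx_pose(m, coords)
  # random rotation + translation of the same coordinates
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1,0,0, 0,cos(th[1]),-sin(th[1]), 0,sin(th[1]),cos(th[1])),3,3)
  Rz <- matrix(c(cos(th[3]),-sin(th[3]),0, sin(th[3]),cos(th[3]),0, 0,0,1),3,3)
  moved <- rx_pose(m, sweep(coords %*% (Rx %*% Rz), 2, c(4, -2, 7), `+`))
  mapping <- cbind(prev = seq_len(m$n_heavy), new = seq_len(m$n_heavy))
  fit <- superpose(ref, moved, mapping)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$pose$coords, ref$coords, tolerance = 1e-8)
})

test_that("superposition RMSD matches a numerical optimiser oracle", {
  set.seed(31)
  m <- rx_mol("CCCCCO")
  A <- matrix(rnorm(3 * 6, sd = 1.5), ncol = 3)
  B <- A
  B[3, ] <- B[3, ] + c(1, 0, 0)     # displace one atom by 1 Angstrom
  pa <- rx_pose(m, A); pb <- rx_pose(m, B)
  mapping <- cbind(prev = 1:6, new = 1:6)
  fit <- superpose(pa, pb, mapping)
  expect_lte(fit$rmsd, 1 / sqrt(6) + 1e-9)
  # independent oracle: direct minimisation over rotation angles + shift
  obj <- function(par) {
    c1 <- cos(par[1]); s1 <- sin(par[1])
    c2 <- cos(par[2]); s2 <- sin(par[2])
    c3 <- cos(par[3]); s3 <- sin(par[3])
    R <- matrix(c(c2 * c3, -c2 * s3, s2,
                  c1 * s3 + c3 * s1 * s2, c1 * c3 - s1 * s2 * s3, -c2 * s1,
                  s1 * s3 - c1 * c3 * s2, c3 * s1 + c1 * s2 * s3, c1 * c2),
                3, 3, byrow = TRUE)
    Bt <- sweep(B %*% t(R), 2, par[4:6], `+`)
    sqrt(mean(rowSums((A - Bt)^2)))
  }
  oracle <- stats::optim(rep(0, 6), obj, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12))$value
  expect_equal(fit$rmsd, oracle, tolerance = 1e-4)
})

test_that("optimal-RMSD is symmetric on random 5-atom poses", {
  set.seed(32)
  m <- rx_mol("CCCCC")
  mapping <- cbind(prev = 1:5, new = 1:5)
  for (i in 1:5) {
    a <- rx_pose(m, matrix(rnorm(15), ncol = 3))
    b <- rx_pose(m, matrix(rnorm(15), ncol = 3))
    expect_equal(superpose(a, b, mapping)$rmsd,
                 superpose(b, a, mapping)$rmsd, tolerance = 1e-8)
  }
})

test_that("superposition is invariant under rigid pre-transformation", {
  set.seed(33)
  m <- rx_mol("CCOCC")
  a <- rx_pose(m, matrix(rnorm(15), ncol = 3))
  b <- rx_pose(m, matrix(rnorm(15), ncol = 3))
  mapping <- cbind(prev = 1:5, new = 1:5)
  r0 <- superpose(a, b, mapping)$rmsd
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b2 <- rx_pose(m, sweep(b$coords %*% R, 2, c(-3, 1, 2), `+`))
  expect_equal(superpose(a, b2, mapping)$rmsd, r0, tolerance = 1e-8)
})

test_that("degenerate mappings fall back to translation with a warning", {
  m <- rx_mol("CC")
  a <- rx_pose(m, matrix(c(0, 0, 0, 1.5, 0, 0), ncol = 3, byrow = TRUE))
  b <- rx_pose(m, matrix(c(5, 5, 5, 6.5, 5, 5), ncol = 3, byrow = TRUE))
  expect_warning(fit <- superpose(a, b, cbind(1, 1)), "translation-only")
  expect_lt(fit$rmsd, 1e-10)
  expect_error(superpose(a, b, matrix(integer(), ncol = 2)), "empty")
})

test_that("select_pose equals the exhaustive-minimum oracle", {
  set.seed(34)
  m <- "CCCC"   # butane
  confs <- generate_conformers(m, 10)
  expect_length(confs, 10L)
  prev <- confs[[4]]
  mapping <- cbind(prev = 1:4, new = 1:4)
  sel <- select_pose(confs, prev, mapping)
  rmsds <- vapply(confs, function(cf) superpose(prev, cf, mapping)$rmsd,
                  numeric(1))
  expect_equal(sel$rmsd, min(rmsds), tolerance = 1e-10)
  # a conformer identical to the previous geometry wins with RMSD ~ 0
  expect_lt(sel$rmsd, 1e-8)
  expect_error(select_pose(list(), prev, mapping), "empty")
  one <- select_pose(confs[2], prev, mapping)
  expect_equal(one$rmsd, rmsds[2], tolerance = 1e-10)
})

test_that("conformers are seeded and respect the molecule", {
  set.seed(35); c1 <- generate_conformers("CCCCO", 5)
  set.seed(35); c2 <- generate_conformers("CCCCO", 5)
  expect_equal(lapply(c1, `[[`, "coords"), lapply(c2, `[[`, "coords"))
  expect_length(c1, 5L)
})

test_that("pocket filter uses the mass-weighted centre of mass", {
  m <- rx_mol("CC")
  pose0 <- rx_pose(m, matrix(c(0, 0, 0, 1.5, 0, 0), ncol = 3, byrow = TRUE))
  pk <- rx_pocket(c(0.75, 0, 0), radius = 7.5)
  expect_true(com_in_pocket(pose0, pk))
  # COM at exactly the boundary passes; just outside fails
  shift <- function(d) rx_pose(m, sweep(pose0$coords, 2, c(d, 0, 0), `+`))
  expect_true(com_in_pocket(shift(7.5), pk))
  expect_false(com_in_pocket(shift(8.0), pk))
  # mass weighting: carbon vs bromine shifts the COM toward the heavy end
  mb <- rx_mol("CBr")
  poseb <- rx_pose(mb, matrix(c(0, 0, 0, 1.9, 0, 0), ncol = 3, byrow = TRUE))
  pkb <- rx_pocket(c(0, 0, 0), radius = 1.2)
  expect_false(com_in_pocket(poseb, pkb))  # COM pulled to Br, ~1.66 A away
})

test_that("poses round-trip through SDF to 4 decimals", {
  set.seed(36)
  confs <- generate_conformers("CC(=O)NC1CCCCC1", 2)
  path <- tempfile(fileext = ".sdf")
  write_poses(confs, path)
  back <- read_poses(path)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$mol$smiles, confs[[i]]$mol$smiles)
    expect_lt(max(abs(back[[i]]$coords - confs[[i]]$coords)), 1e-4)
  }
})
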