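# Molecule representation, fingerprints, similarity, scaffolds, properties.

test_that("canonicalisation is idempotent and spelling-invariant", {
  m1 <- rx_mol("C1=CC=CC=C1")       # kekulized benzene
  m2 <- rx_mol("c1ccccc1")          # aromatic spelling
  expect_identical(m1$smiles, m2$smiles)
  expect_identical(canonical_smiles(m1$smiles), m1$smiles)
  expect_identical(rx_mol(m1$smiles)$smiles, m1$smiles)
  expect_equal(m1$n_heavy, 6L)
  expect_error(rx_mol("notasmiles(("), "invalid molecule")
})

test_that("fingerprints are deterministic and spelling-invariant", {
  f1 <- rx_fingerprint("CCO")
  f2 <- rx_fingerprint("OCC")
  expect_identical(f1$bits, f2$bits)
  expect_identical(rx_fingerprint("CCO")$bits, f1$bits)
  expect_gt(length(f1$bits), 0L)
  # distinct molecules: ethane vs a larger heteroaromatic differ
  t <- tanimoto(rx_fingerprint("CC"),
                rx_fingerprint("Cc1ccc2nc(N)sc2c1CCCCO"))
  expect_lt(t, 1)
})

test_that("tanimoto matches hand-computed set overlap", {
  expect_equal(tanimoto(fp_of(c(1, 2, 3)), fp_of(c(1, 2, 3))), 1.0)
  expect_equal(tanimoto(fp_of(c(1, 2)), fp_of(c(3, 4))), 0.0)
  expect_equal(tanimoto(fp_of(c(1, 2, 3)), fp_of(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(fp_of(integer()), fp_of(integer())), 1.0)
  expect_error(tanimoto(fp_of(1), fp_of(1, n_bits = 2048L)), "bit spaces")
})

test_that("tversky matches the closed form and its limits", {
  # fragment subset of reference: c = 9, ref-only = 10, alpha = 0.1 -> 0.9
  ref <- fp_of(1:19); frag <- fp_of(1:9)
  expect_equal(tversky(ref, frag, 0.1, 0), 9 / (9 + 0.1 * 10))
  expect_equal(tversky(ref, ref), 1.0)
  expect_equal(tversky(fp_of(integer()), fp_of(integer())), 1.0)
  # symmetry under weight exchange
  a <- fp_of(c(1, 5, 9, 12)); b <- fp_of(c(5, 9, 40, 41, 42))
  expect_equal(tversky(a, b, 0.1, 0.9), tversky(b, a, 0.9, 0.1))
})

test_that("tversky with alpha = beta = 1 equals tanimoto on random pairs", {
  set.seed(1)
  for (i in 1:1000) {
    a <- fp_of(sample.int(1024, sample(0:40, 1)))
    b <- fp_of(sample.int(1024, sample(0:40, 1)))
    expect_identical(tversky(a, b, 1, 1), tanimoto(a, b))
  }
})

test_that("similarities always lie in [0, 1] and tanimoto is symmetric", {
  set.seed(2)
  for (i in 1:200) {
    a <- fp_of(sample.int(1024, sample(0:60, 1)))
    b <- fp_of(sample.int(1024, sample(0:60, 1)))
    t1 <- tanimoto(a, b); tv <- tversky(a, b)
    expect_gte(min(t1, tv), 0); expect_lte(max(t1, tv), 1)
    expect_identical(t1, tanimoto(b, a))
  }
})

test_that("murcko scaffolds collapse side chains and handle acyclic input", {
  expect_identical(murcko_scaffold("Cc1ccccc1"),     # toluene
                   murcko_scaffold("CCc1ccccc1"))    # ethylbenzene
  expect_identical(murcko_scaffold("Cc1ccccc1"), canonical_smiles("c1ccccc1"))
  expect_identical(murcko_scaffold("CCCCCC"), "")
  # para-substituted biphenyl keeps the biphenyl framework
  expect_identical(murcko_scaffold("Cc1ccc(-c2ccc(CC)cc2)cc1"),
                   canonical_smiles("c1ccc(-c2ccccc2)cc1"))
})

test_that("scaffold diversity counts unique scaffolds per molecule", {
  benzenes <- c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1", "OCc1ccccc1")
  expect_equal(scaffold_diversity(benzenes), 25)
  distinct <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1ccsc1C")
  expect_equal(scaffold_diversity(distinct), 100)
  expect_equal(scaffold_diversity(c("Cc1ccccc1", "CCc1ccccc1", "C1CCCCC1")),
               100 * 2 / 3, tolerance = 1e-12)
  expect_error(scaffold_diversity(list()), "empty")
  # duplication changes the value only through the denominator
  set4 <- c("Cc1ccccc1", "C1CCCCC1", "c1ccncc1", "Cc1ccccc1")
  expect_equal(scaffold_diversity(set4), 100 * 3 / 4)
})

test_that("physchem fills the property map with sensible values", {
  hex <- physchem("CCCCCC")
  expect_equal(hex$props$hba, 0L)
  expect_equal(hex$props$hbd, 0L)
  eth <- physchem("CCO")
  expect_equal(eth$props$hba, 1L)
  expect_equal(eth$props$hbd, 1L)
  expect_equal(physchem("C")$props$mol_weight, 16.04, tolerance = 1e-3)
  expect_equal(physchem("CCCC")$props$n_rotatable, 1L)
  expect_equal(physchem("c1ccccc1c1ccccc1")$props$n_rotatable, 1L)
  s <- physchem("CC(=O)Nc1ccccc1")$props$sascore
  expect_gte(s, 1); expect_lte(s, 10)
  # provider override is honoured
  expect_equal(physchem("CCO", logp_fn = function(m) 42)$props$logp, 42)
})
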