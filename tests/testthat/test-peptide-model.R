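test_that("design parsing validates codes, length and is deterministic", {
  s <- parse_design("HYWSENLFQ", "PG", cyclic = TRUE)
  expect_length(s$residues, 11)
  expect_true(s$cyclic)
  expect_identical(paste(s$residues, collapse = ""), "HYWSENLFQPG")
  expect_identical(unname(s$proline_configs), "trans")
  expect_identical(names(s$proline_configs), "10")
  expect_identical(s, parse_design("HYWSENLFQ", "PG", cyclic = TRUE))

  lin <- parse_design("A", "", cyclic = FALSE)
  expect_length(lin$residues, 1)
  expect_false(lin$cyclic)

  expect_error(parse_design("HYWZ", "PG"), "Z")
  expect_error(parse_design("AB", ""), "B")
  expect_error(parse_design("AG", "", cyclic = TRUE), "3")
})

test_that("peptide-bond count law holds for cyclic and linear 3..20-mers", {
  set.seed(7)
  for (n in 3:20) {
    res <- paste(sample(cyclomimic:::AA_ONE, n, replace = TRUE),
                 collapse = "")
    for (cyc in c(TRUE, FALSE)) {
      top <- build_topology(parse_design(res, "", cyclic = cyc))
      expect_length(top$peptide_bond_rows, if (cyc) n else n - 1)
      expect_identical(is.null(top$ring_closure_bond), !cyc)
    }
  }
})

test_that("reduced template follows its residue rules", {
  top <- design_top()
  atoms <- top$atoms
  # glycine (residue 11): no CB, hence no beta pseudo-proton
  gly <- atoms[atoms$res == 11, ]
  expect_false(any(gly$atom %in% c("CB", "HB", "SC")))
  # proline (residue 10): no amide proton
  pro <- atoms[atoms$res == 10, ]
  expect_false("HN" %in% pro$atom)
  expect_true(all(c("N", "CA", "C", "O", "HA", "CB", "HB", "SC") %in%
                    pro$atom))
  # proton set is HN/HA/HB only and within the atom table
  expect_true(all(atoms$atom[top$proton_set] %in% c("HN", "HA", "HB")))
  expect_true(all(top$proton_set <= top$natoms))

  # linear 2-mer: one peptide bond, no closure
  top2 <- build_topology(parse_design("AG", "", cyclic = FALSE))
  expect_length(top2$peptide_bond_rows, 1)
  expect_null(top2$ring_closure_bond)
})

test_that("extended builder realises its own ideal geometry", {
  top <- build_topology(parse_design("HYWSENLFQ", "PG", cyclic = FALSE))
  ext <- build_conformation(top, "extended")
  terms <- total_energy(ext)$terms
  expect_lt(terms[["bond"]], 1)
  expect_lt(terms[["angle"]], 1)
  expect_lt(terms[["torsion"]], 1e-6)
  expect_lt(terms[["chirality"]], 1e-6)
  # determinism without randomness: bitwise identical
  ext2 <- build_conformation(top, "extended")
  expect_identical(ext$xyz, ext2$xyz)
})

test_that("random builds are seeded, distinct across seeds, and close the ring", {
  top <- design_top()
  r1 <- build_conformation(top, "random", seed = 1)
  r1b <- build_conformation(top, "random", seed = 1)
  expect_identical(r1$xyz, r1b$xyz)
  r2 <- build_conformation(top, "random", seed = 2)
  expect_gt(kabsch_superpose(r1$xyz, r2$xyz)$rmsd, 0)
  ideal <- top$bond_r0[top$bond_closure == 1L]
  for (s in c(1, 2, 5, 9)) {
    conf <- build_conformation(top, "random", seed = s)
    cb <- top$ring_closure_bond
    len <- sqrt(sum((conf$xyz[cb[1], ] - conf$xyz[cb[2], ])^2))
    expect_lt(abs(len - ideal), 0.1)
  }
  expect_error(build_conformation(top, "random"), "seed")
})
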