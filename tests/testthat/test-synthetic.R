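test_that("ground truths are seeded, clash-free and ring-closed", {
  t1 <- truth11()
  t2 <- make_ground_truth(design_seq(), seed = 11)
  expect_identical(t1$xyz, t2$xyz)
  top <- t1$topology
  # non-bonded pairs (1-2 and 1-3 excluded) at hard-sphere distance or more
  d <- sqrt(rowSums((t1$xyz[top$nb_i, ] - t1$xyz[top$nb_j, ])^2))
  expect_gte(min(d), 1.8)
  cb <- top$ring_closure_bond
  ideal <- top$bond_r0[top$bond_closure == 1L]
  expect_lt(abs(sqrt(sum((t1$xyz[cb[1], ] - t1$xyz[cb[2], ])^2)) - ideal),
            0.1)
})

test_that("NOESY simulation respects the cutoff and its seed", {
  truth <- truth11()
  sim <- simulate_noesy(truth, cutoff = 5, sigma = 0.1, seed = 3)
  sim2 <- simulate_noesy(truth, cutoff = 5, sigma = 0.1, seed = 3)
  expect_identical(sim$peaks, sim2$peaks)
  # every listed pair really is within the cutoff on the source structure
  top <- truth$topology
  key <- setNames(seq_len(top$natoms), paste(top$atoms$res, top$atoms$atom))
  i <- key[paste(sim$peaks$res_i, sim$peaks$atom_i)]
  j <- key[paste(sim$peaks$res_j, sim$peaks$atom_j)]
  d <- sqrt(rowSums((truth$xyz[i, ] - truth$xyz[j, ])^2))
  expect_true(all(d <= 5))
  # subsampling shrinks the list deterministically
  sub <- simulate_noesy(truth, sigma = 0, seed = 4, subsample = 0.3)
  expect_equal(nrow(sub$peaks), round(0.3 * nrow(
    simulate_noesy(truth, sigma = 0, seed = 4)$peaks)), tolerance = 1)
})

test_that("noise-free forward NOESY then calibration is the identity", {
  truth <- truth11()
  sim <- simulate_noesy(truth, sigma = 0, seed = 1)
  restr <- calibrate_noe(sim$peaks, sim$reference)
  top <- truth$topology
  key <- setNames(seq_len(top$natoms), paste(top$atoms$res, top$atoms$atom))
  i <- key[paste(restr$res_i, restr$atom_i)]
  j <- key[paste(restr$res_j, restr$atom_j)]
  d <- sqrt(rowSums((truth$xyz[i, ] - truth$xyz[j, ])^2))
  expect_lt(max(abs(restr$distance_A - d)), 1e-9)
})

test_that("assay simulation inverts the normalisation exactly at zero noise", {
  doses <- c(10, 30, 120, 400, 1000, 30, 3, 60)
  plate <- simulate_assay(ic50 = 120, hill = 1, doses = doses, noise_sd = 0,
                          seed = 5, a_neg = 1.0, a_baseline = 0.1)
  # the well dosed exactly at the IC50 sits midway between the anchors
  mid <- plate$a620[plate$role == "sample" & plate$conc_uM == 120]
  expect_equal(mid, rep((1.0 + 0.1) / 2, length(mid)))
  expect_identical(plate, simulate_assay(ic50 = 120, hill = 1, doses = doses,
                                         noise_sd = 0, seed = 5))
})

test_that("recovery experiments replay exactly from their seeds", {
  sched <- annealing_schedule(t_start = 1500, t_end = 100, steps = 300)
  r1 <- recovery_experiment(design_seq(), seed = 3, n_structures = 2,
                            schedule = sched)
  r2 <- recovery_experiment(design_seq(), seed = 3, n_structures = 2,
                            schedule = sched)
  expect_identical(r1$best_rmsd, r2$best_rmsd)
  expect_identical(r1$ensemble$energies, r2$ensemble$energies)
  expect_identical(r1$mimicry, r2$mimicry)
  expect_identical(r1$seeds, list(truth = 3, noesy = 4, ensemble_base = 300))
})
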