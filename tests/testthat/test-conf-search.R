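test_that("zero-step search returns only the minimised start", {
  start <- build_conformation(toy_top(), "extended")
  ens <- monte_carlo_search(start, steps = 0, seed = 1)
  expect_length(ens, 1)
  direct <- minimize_conformation(start)
  expect_equal(ens$energies[1], direct$energy, tolerance = 1e-9)
})

test_that("search is deterministic under a fixed seed", {
  start <- build_conformation(toy_top(), "extended")
  e1 <- monte_carlo_search(start, steps = 25, seed = 7)
  e2 <- monte_carlo_search(start, steps = 25, seed = 7)
  expect_identical(e1$energies, e2$energies)
  expect_identical(e1$conformations[[1]]$xyz, e2$conformations[[1]]$xyz)
  expect_false(is.unsorted(e1$energies))
})

test_that("Boltzmann factors follow the closed form", {
  confs <- list(build_conformation(toy_top(), "extended"))
  mk <- function(energies) {
    cyclomimic:::new_conformer_ensemble(rep(confs, length(energies)),
                                        energies)
  }
  R <- 8.314e-3
  # Delta E = R*T at 500 K: ratio is exactly exp(-1)
  bw <- boltzmann_weights(mk(c(0, R * 500)), temperature = 500)
  expect_equal(bw$bf[2], exp(-1), tolerance = 1e-12)
  expect_equal(1 / bw$ratio_vs_highest[1], exp(-1), tolerance = 1e-12)
  # Delta E = 1 kJ/mol at 298.15 K
  bw2 <- boltzmann_weights(mk(c(10, 11)), temperature = 298.15)
  expect_equal(bw2$bf[2], exp(-1 / (R * 298.15)), tolerance = 1e-12)
  # minimum-energy conformer has shifted BF exactly 1
  expect_equal(bw2$bf[1], 1)
  # every ratio vs the highest-energy member is >= 1, BF in (0, 1]
  bw3 <- boltzmann_weights(mk(c(3, 9, 4, 7)), temperature = 500)
  expect_true(all(bw3$ratio_vs_highest >= 1))
  expect_true(all(bw3$bf > 0 & bw3$bf <= 1))
  expect_error(boltzmann_weights(mk(numeric(0))), "empty")
})

test_that("Boltzmann ratios are monotone in energy gap and temperature", {
  R <- 8.314e-3
  ratio <- function(de, temp) exp(-de / (R * temp))
  confs <- list(build_conformation(toy_top(), "extended"))
  des <- seq(0.5, 20, length.out = 8)
  r_fixed_t <- vapply(des, function(de) {
    ens <- cyclomimic:::new_conformer_ensemble(rep(confs, 2), c(0, de))
    boltzmann_weights(ens, 500)$bf[2]
  }, numeric(1))
  expect_true(all(diff(r_fixed_t) < 0))
  temps <- seq(100, 2000, length.out = 8)
  r_fixed_de <- vapply(temps, function(tt) {
    ens <- cyclomimic:::new_conformer_ensemble(rep(confs, 2), c(0, 5))
    boltzmann_weights(ens, tt)$bf[2]
  }, numeric(1))
  expect_true(all(diff(r_fixed_de) > 0))
  expect_equal(r_fixed_t, ratio(des, 500), tolerance = 1e-12)
})

test_that("deduplication merges by all-atom superposed RMSD", {
  base <- minimize_conformation(build_conformation(design_top(), "random",
                                                   seed = 4))
  one <- cyclomimic:::new_conformer_ensemble(list(base), base$energy)
  expect_length(dedup_ensemble(one, 0.5), 1)

  twice <- cyclomimic:::new_conformer_ensemble(list(base, base),
                                               c(base$energy, base$energy))
  expect_length(dedup_ensemble(twice, 0.5), 1)

  far <- perturb_to_rmsd(base, 2.5, seed = 8)
  pair <- cyclomimic:::new_conformer_ensemble(list(base, far),
                                              c(1, 2))
  expect_length(dedup_ensemble(pair, 1.0), 2)
  kept <- dedup_ensemble(pair, 3.0)
  expect_length(kept, 1)
  expect_equal(kept$energies, 1)  # lower-energy member survives
})
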