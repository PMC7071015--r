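test_that("schedules validate and cool strictly from t_start to t_end", {
  for (mode in c("geometric", "linear")) {
    s <- annealing_schedule(3500, 100, 500, cooling = mode)
    expect_equal(s$temps[1], 3500)
    expect_equal(s$temps[length(s$temps)], 100)
    expect_true(all(diff(s$temps) < 0))
    expect_true(all(diff(s$k_noes) >= 0))
    expect_equal(s$k_noes[1], 2)
    expect_equal(s$k_noes[length(s$k_noes)], 50)
  }
  expect_error(annealing_schedule(100, 3500), "t_start")
  expect_error(annealing_schedule(3500, -5), "t_end")
  expect_error(annealing_schedule(3500, 100, 0), "steps")
  expect_error(annealing_schedule(3500, 100, 10, k_noe_start = 50,
                                  k_noe_end = 2), "k_noe")
})

test_that("violation reports implement the signed flat-bottom definition", {
  top <- design_top()
  conf <- build_conformation(top, "extended")
  i <- top$idx$HA[1]
  j <- top$idx$HA[4]
  d <- sqrt(sum((conf$xyz[i, ] - conf$xyz[j, ])^2))
  mk <- function(lo, up) data.frame(res_i = 1, atom_i = "HA", res_j = 4,
                                    atom_j = "HA", lower_A = lo,
                                    upper_A = up)
  inside <- violation_report(conf, mk(d - 1, d + 1))
  expect_equal(inside$fraction_satisfied, 1)
  expect_equal(inside$max_violation, 0)
  above <- violation_report(conf, mk(d - 2, d - 0.7))
  expect_equal(above$violations, 0.7, tolerance = 1e-9)
  expect_equal(above$max_violation, 0.7, tolerance = 1e-9)
  expect_identical(above$n_above_half, 1L)
  below <- violation_report(conf, mk(d + 0.4, d + 2))
  expect_equal(below$violations, -0.4, tolerance = 1e-9)
  # invariance under rigid rotation
  rot <- conf
  set.seed(2)
  rot$xyz <- conf$xyz %*% t(cyclomimic:::random_rotation())
  expect_equal(violation_report(rot, mk(d - 2, d - 0.7))$max_violation,
               above$max_violation, tolerance = 1e-9)
  # restraint referencing an unknown atom fails before any computation
  bad <- data.frame(res_i = 1, atom_i = "HZ", res_j = 4, atom_j = "HA",
                    lower_A = 2, upper_A = 3)
  expect_error(violation_report(conf, bad), "unknown atom")
  expect_error(anneal(conf, bad, annealing_schedule(steps = 10), seed = 1),
               "unknown atom")
})

test_that("annealing is deterministic, energy-reducing and keeps the ring", {
  top <- design_top()
  sched <- annealing_schedule(t_start = 1500, t_end = 100, steps = 800)
  start <- build_conformation(top, "random", seed = 31)
  a1 <- anneal(start, empty_restraints(), sched, seed = 31)
  a2 <- anneal(start, empty_restraints(), sched, seed = 31)
  expect_identical(a1$xyz, a2$xyz)
  # restrained total energy of the result <= that of the minimised start
  m_start <- minimize_conformation(start)
  expect_lte(a1$energy, m_start$energy + 1e-9)
  # closure bond intact after the unrestrained control run
  cb <- top$ring_closure_bond
  ideal <- top$bond_r0[top$bond_closure == 1L]
  expect_lt(abs(sqrt(sum((a1$xyz[cb[1], ] - a1$xyz[cb[2], ])^2)) - ideal),
            0.1)
})

test_that("enforced trans prolines stay planar-trans through annealing", {
  top <- design_top()   # proline at position 10, trans
  sched <- annealing_schedule(t_start = 1500, t_end = 100, steps = 800)
  for (s in c(13, 29)) {
    a <- anneal(build_conformation(top, "random", seed = s),
                empty_restraints(), sched, seed = s)
    omega <- dihedral_angle(a$xyz[top$idx$CA[9], ], a$xyz[top$idx$C[9], ],
                            a$xyz[top$idx$N[10], ], a$xyz[top$idx$CA[10], ])
    dev <- abs(((omega - pi + pi) %% (2 * pi)) - pi)  # distance to 180 deg
    expect_lt(dev, cyclomimic:::deg2rad(20))
  }
})

test_that("ensembles assemble survivors with violation reports, reproducibly", {
  top <- design_top()
  sched <- annealing_schedule(t_start = 1500, t_end = 100, steps = 400)
  truth <- truth11()
  sim <- simulate_noesy(truth, sigma = 0, seed = 2)
  restr <- calibrate_noe(sim$peaks, sim$reference)
  e1 <- generate_ensemble(top, restr, n = 3, schedule = sched, base_seed = 5)
  expect_length(e1, 3)
  expect_false(is.unsorted(e1$energies))
  expect_length(e1$violations, 3)
  expect_setequal(e1$member_seeds, 5L + 1:3)  # stored in energy order
  e2 <- generate_ensemble(top, restr, n = 3, schedule = sched, base_seed = 5)
  expect_identical(e1$energies, e2$energies)
  expect_identical(e1$conformations[[1]]$xyz, e2$conformations[[1]]$xyz)
  single <- generate_ensemble(top, restr, n = 1, schedule = sched,
                              base_seed = 9)
  expect_length(single, 1)
})
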