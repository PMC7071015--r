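test_that("energy is invariant under rigid-body motion", {
  conf <- build_conformation(design_top(), "random", seed = 3)
  e0 <- total_energy(conf)$total
  # the specific worked translation
  shifted <- conf
  shifted$xyz <- sweep(conf$xyz, 2, c(10, -3, 7), "+")
  expect_equal(total_energy(shifted)$total, e0, tolerance = 1e-9)
  # random rotations + translations
  set.seed(21)
  for (q in 1:5) {
    rot <- cyclomimic:::random_rotation()
    moved <- conf
    moved$xyz <- conf$xyz %*% t(rot) +
      matrix(rnorm(3, 0, 5), nrow(conf$xyz), 3, byrow = TRUE)
    expect_equal(total_energy(moved)$total, e0, tolerance = 1e-8)
  }
})

test_that("breakdown terms sum to the total", {
  for (s in 1:3) {
    conf <- build_conformation(design_top(), "random", seed = s)
    e <- total_energy(conf)
    expect_equal(sum(e$terms), e$total, tolerance = 1e-9)
  }
  bad <- build_conformation(design_top(), "extended")
  bad$xyz[1, 1] <- NaN
  expect_error(total_energy(bad), "finite")
})

test_that("analytic gradient matches central finite differences", {
  top <- build_topology(parse_design("AGSVP", "", cyclic = FALSE))
  model <- cyclomimic:::compile_model(top)
  for (s in 1:2) {
    conf <- build_conformation(top, "random", seed = s)
    set.seed(s + 50)
    x <- conf$xyz + matrix(rnorm(length(conf$xyz), 0, 0.1), ncol = 3)
    g <- as.numeric(t(cyclomimic:::cpp_energy(x, model, 1, TRUE)$grad))
    par <- as.numeric(t(x))
    h <- 1e-5
    fd <- vapply(seq_along(par), function(q) {
      p1 <- par; p1[q] <- p1[q] + h
      p2 <- par; p2[q] <- p2[q] - h
      (cyclomimic:::cpp_obj(p1, model, 1) -
         cyclomimic:::cpp_obj(p2, model, 1)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("NOE restraint term is flat-bottom", {
  top <- design_top()
  conf <- build_conformation(top, "extended")
  i <- top$idx$HA[1]
  j <- top$idx$HA[3]
  d <- sqrt(sum((conf$xyz[i, ] - conf$xyz[j, ])^2))
  restr <- function(lo, up) {
    data.frame(res_i = 1, atom_i = "HA", res_j = 3, atom_j = "HA",
               lower_A = lo, upper_A = up)
  }
  # distance exactly at the upper bound: zero
  at_upper <- total_energy(conf, restraints = restr(d - 1, d))$terms
  expect_equal(at_upper[["restraint"]], 0)
  inside <- total_energy(conf, restraints = restr(d - 1, d + 1))$terms
  expect_equal(inside[["restraint"]], 0)
  # 0.3 A outside: k_noe * 0.3^2
  outside <- total_energy(conf, restraints = restr(d - 1, d - 0.3),
                          k_noe = 50)$terms
  expect_equal(outside[["restraint"]], 50 * 0.09, tolerance = 1e-6)
  # no restraints supplied: term zero
  expect_equal(total_energy(conf)$terms[["restraint"]], 0)
})

test_that("minimiser reaches its gradient tolerance and is monotone", {
  top <- toy_top()
  conf <- build_conformation(top, "random", seed = 6)
  e_start <- total_energy(conf)$total
  m1 <- minimize_conformation(conf, tol = 0.01)
  expect_lte(m1$energy, e_start)
  expect_lte(attr(m1, "rms_gradient"), 0.01)
  expect_true(attr(m1, "converged"))
  # fixed point: re-minimising changes the energy by < 1e-6
  m2 <- minimize_conformation(m1, tol = 0.01)
  expect_lt(abs(m2$energy - m1$energy), 1e-6)
})

test_that("a stretched bond relaxes back to its ideal length", {
  top <- build_topology(parse_design("AG", "", cyclic = FALSE))
  conf <- minimize_conformation(build_conformation(top, "extended"))
  i_n <- top$idx$N[1]
  i_h <- top$idx$HN[1]
  ideal <- 1.010
  dir <- conf$xyz[i_h, ] - conf$xyz[i_n, ]
  dir <- dir / sqrt(sum(dir^2))
  stretched <- conf
  stretched$xyz[i_h, ] <- conf$xyz[i_n, ] + 2 * ideal * dir
  m <- minimize_conformation(stretched)
  len <- sqrt(sum((m$xyz[i_h, ] - m$xyz[i_n, ])^2))
  expect_lt(abs(len - ideal), 0.01)
})
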