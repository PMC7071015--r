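test_that("Kabsch superposition handles exact and degenerate cases", {
  set.seed(4)
  pts <- matrix(rnorm(15), 5, 3)
  same <- kabsch_superpose(pts, pts)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)
  # reference = rotated + translated copy: exact rigid match
  rot <- cyclomimic:::random_rotation()
  moved <- pts %*% t(rot) + matrix(c(3, -1, 2), 5, 3, byrow = TRUE)
  sp <- kabsch_superpose(pts, moved)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(t(sp$rotation) %*% sp$rotation, diag(3), tolerance = 1e-9)
  expect_error(kabsch_superpose(pts, pts[1:4, ]), "differ")
  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition agrees with an independent reference route", {
  set.seed(11)
  for (q in 1:5) {
    a <- matrix(rnorm(24), 8, 3)
    b <- matrix(rnorm(24), 8, 3)
    mine <- kabsch_superpose(a, b)$rmsd
    fitted <- suppressWarnings(
      bio3d::fit.xyz(as.numeric(t(b)), as.numeric(t(a))))
    ref <- bio3d::rmsd(as.numeric(t(b)), fitted)  # bio3d rounds to 3 dp
    expect_lt(abs(mine - ref), 1e-3)
  }
})

test_that("backbone RMSD is symmetric, self-zero and rigid-invariant", {
  a <- truth11()
  b <- perturb_to_rmsd(a, 1.7, seed = 3)
  expect_equal(backbone_rmsd(a, a), 0, tolerance = 1e-9)
  expect_equal(backbone_rmsd(a, b), backbone_rmsd(b, a), tolerance = 1e-9)
  set.seed(14)
  moved <- b
  moved$xyz <- b$xyz %*% t(cyclomimic:::random_rotation()) +
    matrix(rnorm(3, 0, 4), nrow(b$xyz), 3, byrow = TRUE)
  expect_equal(backbone_rmsd(a, moved), backbone_rmsd(a, b),
               tolerance = 1e-9)
  # definitional consistency with an explicit Kabsch on backbone atoms
  frame <- function(conf) cyclomimic:::backbone_coords(
    cyclomimic:::coord_frame(conf), 1:11)
  expect_equal(backbone_rmsd(a, b),
               kabsch_superpose(frame(a), frame(b))$rmsd, tolerance = 1e-12)
})

test_that("per-atom Gaussian noise yields the expected RMSD scale", {
  a <- truth11()
  sigma <- 0.4
  set.seed(99)
  rmsds <- replicate(100, {
    noisy <- a
    noisy$xyz <- a$xyz + matrix(rnorm(length(a$xyz), 0, sigma), ncol = 3)
    backbone_rmsd(a, noisy)
  })
  expect_gt(mean(rmsds), 0.8 * sqrt(3) * sigma * 0.9)
  expect_lt(mean(rmsds), 1.2 * sqrt(3) * sigma)
})

test_that("clustering partitions ensembles sensibly", {
  base <- truth11()
  copies <- cyclomimic:::new_conformer_ensemble(rep(list(base), 10), 1:10)
  cs <- cluster_ensemble(copies, 2)
  expect_length(cs$clusters, 1)
  expect_length(cs$clusters[[1]], 10)
  singleton <- cyclomimic:::new_conformer_ensemble(list(base), 5)
  expect_length(cluster_ensemble(singleton, 2)$clusters, 1)
  # cluster count is monotone non-increasing in the cutoff
  ens <- two_group_ensemble()
  counts <- vapply(c(0.2, 1, 2, 5, 10), function(h)
    length(cluster_ensemble(ens, h)$clusters), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mimicry tables rank by backbone RMSD and flag unmappables", {
  ref <- truth11()
  near <- perturb_to_rmsd(ref, 0.8, seed = 5)
  far <- perturb_to_rmsd(ref, 2.4, seed = 6)
  tab <- mimicry_table(list(self = ref, far = far, near = near), ref)
  expect_identical(tab$structure, c("self", "near", "far"))
  expect_equal(tab$rmsd_A[1], 0, tolerance = 1e-9)
  expect_true(all(diff(tab$rmsd_A) > 0))
  # a structure missing a backbone atom is flagged, not dropped
  broken <- cyclomimic:::coord_frame(ref)
  keep <- !(broken$atoms$res == 5 & broken$atoms$atom == "CA")
  broken <- list(atoms = broken$atoms[keep, ], xyz = ref$xyz[keep, ])
  tab2 <- mimicry_table(list(ok = near, broken = broken), ref)
  expect_identical(nrow(tab2), 2L)
  expect_true(is.na(tab2$rmsd_A[tab2$structure == "broken"]))
  expect_match(tab2$note[tab2$structure == "broken"], "missing backbone")
})
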