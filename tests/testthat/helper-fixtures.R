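# Shared fixtures, built in code and memoised so expensive objects are
# constructed once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), .fixture_env)
  }
  get(name, .fixture_env, inherits = FALSE)
}

design_seq <- function() memo("design_seq",
                              parse_design("HYWSENLFQ", "PG", cyclic = TRUE))

design_top <- function() memo("design_top", build_topology(design_seq()))

toy_top <- function() memo("toy_top",
                           build_topology(parse_design("GGGG", "",
                                                       cyclic = TRUE)))

truth11 <- function() memo("truth11", make_ground_truth(design_seq(),
                                                        seed = 11))

ci_schedule <- function(steps = 10000) {
  annealing_schedule(t_start = 3500, t_end = 100, steps = steps)
}

empty_restraints <- function() {
  data.frame(res_i = integer(0), atom_i = character(0),
             res_j = integer(0), atom_j = character(0),
             lower_A = numeric(0), upper_A = numeric(0))
}

# Perturb a conformation so its all-atom superposed RMSD to the original hits
# `target` (A) to within `tol`, by bisection on the perturbation scale.
perturb_to_rmsd <- function(conf, target, seed = 1, tol = 1e-3) {
  set.seed(seed)
  p <- matrix(rnorm(length(conf$xyz)), ncol = 3)
  f <- function(s) kabsch_superpose(conf$xyz + s * p, conf$xyz)$rmsd
  lo <- 0
  hi <- 1
  while (f(hi) < target) hi <- hi * 2
  for (q in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  out <- conf
  out$xyz <- conf$xyz + hi * p
  stopifnot(abs(kabsch_superpose(out$xyz, conf$xyz)$rmsd - target) < tol)
  out
}

# Brute-force rotation-grid RMSD oracle: for fixed rotation the optimal
# translation aligns centroids, and rmsd^2 = (|mc|^2 + |rc|^2 - 2 tr(R A))/n
# with A the cross-covariance, so the search maximises tr(R A) over a
# 10-degree global ZYZ Euler grid followed by an exhaustive 1-degree local
# refinement. Independent of the SVD route used by kabsch_superpose().
grid_rmsd_oracle <- function(mobile, reference) {
  n <- nrow(mobile)
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  a <- t(mc) %*% rc
  base <- sum(mc^2) + sum(rc^2)
  best_tr <- function(alpha, beta, gamma) {
    g <- expand.grid(a = alpha, b = beta, g = gamma)
    ca <- cos(g$a); sa <- sin(g$a)
    cb <- cos(g$b); sb <- sin(g$b)
    cg <- cos(g$g); sg <- sin(g$g)
    # R = Rz(a) Ry(b) Rz(g); tr(R A) = sum_ij R_ij A_ji
    tr <- (ca * cb * cg - sa * sg) * a[1, 1] +
      (-ca * cb * sg - sa * cg) * a[2, 1] +
      (ca * sb) * a[3, 1] +
      (sa * cb * cg + ca * sg) * a[1, 2] +
      (-sa * cb * sg + ca * cg) * a[2, 2] +
      (sa * sb) * a[3, 2] +
      (-sb * cg) * a[1, 3] +
      (sb * sg) * a[2, 3] +
      cb * a[3, 3]
    k <- which.max(tr)
    list(tr = tr[k], ang = c(g$a[k], g$b[k], g$g[k]))
  }
  d2r <- pi / 180
  coarse <- best_tr(seq(0, 350, 10) * d2r, seq(0, 180, 10) * d2r,
                    seq(0, 350, 10) * d2r)
  fine <- best_tr(coarse$ang[1] + seq(-10, 10, 1) * d2r,
                  coarse$ang[2] + seq(-10, 10, 1) * d2r,
                  coarse$ang[3] + seq(-10, 10, 1) * d2r)
  sqrt(max(0, (base - 2 * fine$tr) / n))
}

# 7 + 3 two-centroid ensemble used by the clustering checks: members jittered
# tightly around two centroids a known backbone-RMSD apart.
two_group_ensemble <- function(n_a = 7, n_b = 3, separation = 4,
                               jitter = 0.15, seed = 42) {
  centre_a <- truth11()
  centre_b <- perturb_backbone_rmsd(centre_a, separation, seed = seed)
  make_member <- function(centre, s) {
    set.seed(s)
    out <- centre
    out$xyz <- centre$xyz + matrix(rnorm(length(centre$xyz), 0, jitter),
                                   ncol = 3)
    out
  }
  confs <- c(lapply(seq_len(n_a), function(q) make_member(centre_a, seed + q)),
             lapply(seq_len(n_b), function(q)
               make_member(centre_b, seed + 100 + q)))
  cyclomimic:::new_conformer_ensemble(confs, seq_along(confs),
                                      provenance = "fixture")
}

# Like perturb_to_rmsd but targeting the backbone RMSD used by clustering.
perturb_backbone_rmsd <- function(conf, target, seed = 1) {
  set.seed(seed)
  p <- matrix(rnorm(length(conf$xyz)), ncol = 3)
  f <- function(s) {
    out <- conf
    out$xyz <- conf$xyz + s * p
    backbone_rmsd(out, conf)
  }
  lo <- 0
  hi <- 1
  while (f(hi) < target) hi <- hi * 2
  for (q in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  out <- conf
  out$xyz <- conf$xyz + hi * p
  out
}
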