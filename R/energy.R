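# Simplified geometric potential and minimiser. The potential is authored for
# this package (bonds, angles, soft 3-fold rotors, soft-sphere repulsion,
# peptide-bond planarity, chirality impropers, ring closure, flat-bottom NOE
# restraints, optional radius-of-gyration compaction); absolute energies are
# not comparable to any molecular-mechanics force field and are used only to
# rank and sample conformations.

#' Default force-field parameters
#'
#' Force constants (kJ/mol-based), soft-sphere radii and the ideal-geometry
#' constants the topology builder freezes into each topology. All constants
#' can be overridden by editing the returned list.
#'
#' @return A `forcefield_params` list:
#'   \describe{
#'     \item{k_bond}{bond force constant, kJ mol^-1 A^-2}
#'     \item{k_angle}{angle force constant, kJ mol^-1 rad^-2}
#'     \item{k_torsion3}{3-fold rotor barrier scale, kJ/mol}
#'     \item{k_omega, k_chirality}{peptide-planarity and chirality torsion
#'       constants, kJ/mol}
#'     \item{k_rep}{soft-sphere repulsion constant, kJ mol^-1 A^-2}
#'     \item{radius_heavy, radius_h}{soft-sphere radii, A}
#'     \item{k_noe}{default NOE restraint constant, kJ mol^-1 A^-2}
#'     \item{rg_k, rg0}{optional compaction term (flat-bottom on the radius
#'       of gyration); disabled by default}
#'     \item{geometry}{ideal bond lengths (A) and sp2/sp3 angles (degrees)}
#'   }
#' @export
default_forcefield <- function() {
  p <- list(
    k_bond = 1000, k_angle = 150, k_torsion3 = 2,
    k_omega = 80, k_chirality = 80,
    k_rep = 200, radius_heavy = 1.45, radius_h = 1.0,
    k_noe = 50,
    rg_k = 0, rg0 = Inf,
    geometry = list(
      bond_lengths = c("N-CA" = 1.458, "CA-C" = 1.525, "C-O" = 1.231,
                       "C-N" = 1.329, "N-HN" = 1.010, "CA-HA" = 1.090,
                       "CA-CB" = 1.530, "CB-HB" = 1.000),
      angle_sp3_deg = 109.47, angle_sp2_deg = 120
    )
  )
  class(p) <- "forcefield_params"
  validate_forcefield(p)
  p
}

validate_forcefield <- function(p) {
  ks <- c(p$k_bond, p$k_angle, p$k_torsion3, p$k_omega, p$k_chirality,
          p$k_rep, p$radius_heavy, p$radius_h, p$k_noe)
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    stop("force-field constants must be positive and finite")
  }
  if (any(!is.finite(p$geometry$bond_lengths))) stop("non-finite ideal geometry")
  invisible(p)
}

# Flatten topology + params (+ resolved restraints) into the arrays the C++
# kernel consumes.
compile_model <- function(top, params = default_forcefield(),
                          restraints = NULL) {
  validate_forcefield(params)
  rad <- ifelse(top$atoms$element == "H", params$radius_h, params$radius_heavy)
  nb_rmin <- rad[top$nb_i] + rad[top$nb_j]
  h_k <- c(omega = params$k_omega, chirality = params$k_chirality,
           prochi = params$k_chirality)[top$h_class]
  h_cls <- c(omega = 0L, chirality = 1L, prochi = 2L)[top$h_class]
  if (is.null(restraints) || nrow(restraints) == 0) {
    ri <- rj <- integer(0)
    rlo <- rup <- numeric(0)
  } else {
    idx <- resolve_restraints(top, restraints)
    ri <- idx$i; rj <- idx$j; rlo <- idx$lower; rup <- idx$upper
  }
  list(bond_i = top$bonds[, 1], bond_j = top$bonds[, 2],
       bond_r0 = top$bond_r0, bond_closure = as.integer(top$bond_closure),
       k_bond = params$k_bond,
       ang_i = top$angles[, 1], ang_j = top$angles[, 2],
       ang_k = top$angles[, 3], ang_th0 = top$ang_th0,
       k_angle = params$k_angle,
       t3_a = top$t3[, 1], t3_b = top$t3[, 2], t3_c = top$t3[, 3],
       t3_d = top$t3[, 4], k_torsion3 = params$k_torsion3,
       h_a = top$harm[, 1], h_b = top$harm[, 2], h_c = top$harm[, 3],
       h_d = top$harm[, 4], h_phi0 = top$h_phi0, h_k = unname(h_k),
       h_class = unname(h_cls),
       nb_i = top$nb_i, nb_j = top$nb_j, nb_rmin = nb_rmin,
       k_rep = params$k_rep,
       restr_i = ri, restr_j = rj, restr_lo = rlo, restr_up = rup,
       rg_k = params$rg_k, rg0 = params$rg0)
}

# Map (residue, atom-name) restraint endpoints onto topology atom indices.
resolve_restraints <- function(top, restraints) {
  need <- c("res_i", "atom_i", "res_j", "atom_j", "lower_A", "upper_A")
  miss <- setdiff(need, names(restraints))
  if (length(miss) > 0) stop("restraints lack column(s): ",
                             paste(miss, collapse = ", "))
  keymap <- setNames(seq_len(top$natoms),
                     paste(top$atoms$res, top$atoms$atom))
  i <- keymap[paste(restraints$res_i, restraints$atom_i)]
  j <- keymap[paste(restraints$res_j, restraints$atom_j)]
  if (anyNA(i) || anyNA(j)) {
    bad <- which(is.na(i) | is.na(j))[1]
    stop(sprintf("restraint %d references unknown atom (%s %s / %s %s)",
                 bad, restraints$res_i[bad], restraints$atom_i[bad],
                 restraints$res_j[bad], restraints$atom_j[bad]))
  }
  list(i = unname(i), j = unname(j),
       lower = restraints$lower_A, upper = restraints$upper_A)
}

#' Total potential energy of a conformation
#'
#' Evaluates the package's geometric potential term by term. The restraint
#' term is present only when restraints are supplied and is flat-bottom: zero
#' between the lower and upper bound, harmonic outside.
#'
#' @param conf A `conformation`.
#' @param params Force-field parameters.
#' @param restraints Optional distance-restraint table (see
#'   [calibrate_noe()]).
#' @param k_noe Restraint force constant, kJ mol^-1 A^-2.
#' @return An `energy_breakdown`: list with `terms` (named per-term energies,
#'   kJ/mol) and `total`.
#' @export
total_energy <- function(conf, params = default_forcefield(),
                         restraints = NULL, k_noe = params$k_noe) {
  stopifnot(inherits(conf, "conformation"))
  if (any(!is.finite(conf$xyz))) stop("non-finite coordinates")
  model <- compile_model(conf$topology, params, restraints)
  res <- cpp_energy(conf$xyz, model, k_noe, FALSE)
  structure(list(terms = res$terms, total = res$total),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy breakdown (kJ/mol):\n")
  for (nm in names(x$terms)) cat(sprintf("  %-10s %12.4f\n", nm, x$terms[nm]))
  cat(sprintf("  %-10s %12.4f\n", "total", x$total))
  invisible(x)
}

energy_gradient <- function(conf, params = default_forcefield(),
                            restraints = NULL, k_noe = params$k_noe) {
  model <- compile_model(conf$topology, params, restraints)
  cpp_energy(conf$xyz, model, k_noe, TRUE)$grad
}

#' Minimise a conformation's potential energy
#'
#' L-BFGS minimisation (via [stats::optim()]) with the package's analytic
#' gradient, iterated until the RMS gradient (over all 3N coordinates, in
#' kJ mol^-1 A^-1) falls below `tol` or `max_iter` function evaluations are
#' spent; in the latter case the best-so-far structure is returned flagged as
#' unconverged.
#'
#' @param conf A `conformation`.
#' @param params Force-field parameters.
#' @param restraints Optional restraint table.
#' @param k_noe Restraint force constant.
#' @param tol RMS-gradient convergence tolerance, kJ mol^-1 A^-1.
#' @param max_iter Maximum total function evaluations.
#' @return The minimised `conformation` with `energy` set and attributes
#'   `rms_gradient`, `converged` and `breakdown`.
#' @export
minimize_conformation <- function(conf, params = default_forcefield(),
                                  restraints = NULL, k_noe = params$k_noe,
                                  tol = 0.01, max_iter = 10000) {
  stopifnot(tol > 0)
  if (any(!is.finite(conf$xyz))) stop("non-finite coordinates")
  model <- compile_model(conf$topology, params, restraints)
  par <- as.numeric(t(conf$xyz))
  fn <- function(p) cpp_obj(p, model, k_noe)
  gr <- function(p) cpp_obj_grad(p, model, k_noe)
  used <- 0L
  e_prev <- fn(par)
  if (!is.finite(e_prev)) stop("non-finite energy at start of minimisation")
  repeat {
    chunk <- min(500L, max(1L, max_iter - used))
    res <- optim(par, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = chunk, factr = 10, pgtol = 0))
    par <- res$par
    used <- used + res$counts[["function"]]
    if (!is.finite(res$value)) stop("non-finite energy during minimisation")
    g <- gr(par)
    rmsg <- sqrt(mean(g^2))
    if (rmsg <= tol || used >= max_iter) break
    if (abs(e_prev - res$value) < 1e-12 && res$convergence == 0) break
    e_prev <- res$value
  }
  xyz <- matrix(par, ncol = 3, byrow = TRUE)
  out <- new_conformation(conf$topology, xyz, energy = res$value,
                          label = conf$label)
  br <- cpp_energy(xyz, model, k_noe, FALSE)
  out$energy <- br$total
  attr(out, "rms_gradient") <- rmsg
  attr(out, "converged") <- rmsg <= tol
  attr(out, "breakdown") <- structure(list(terms = br$terms,
                                           total = br$total),
                                      class = "energy_breakdown")
  out
}
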