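# Exhaustive torsion-grid reference search. Enumerates every combination of
# the build torsions (psi_1..psi_{n-1}, phi_2..phi_n) on a fixed angular
# grid, pruning branches whose partial chain provably cannot reach ring
# closure (triangle inequality on the remaining backbone path), then
# minimises the best raw-energy closure-feasible grid points. Exponential in
# the residue count: a reference method for small cycles, used to
# cross-check the Monte-Carlo search.

#' Exhaustive torsion-grid scan of a small cyclic peptide
#'
#' @param top A cyclic `peptide_topology` (practical only for very short
#'   cycles; the grid has `steps^(2n-2)` points).
#' @param step_deg Grid resolution in degrees.
#' @param params Force-field parameters.
#' @param topk Number of best closure-feasible grid points kept for
#'   minimisation.
#' @param gap_tol Closure feasibility: maximum deviation of the C..N closure
#'   distance from its ideal bond length at a raw grid point, A.
#' @param refine Minimise the kept grid points (recommended; raw grid
#'   energies carry the closure-mismatch penalty).
#' @return List with `best_energy` (kJ/mol), `best_conformation`,
#'   `energies` (refined, ascending), `raw_energies`, `n_leaves` (grid
#'   points visited after pruning) and `n_evals` (closure-feasible leaves
#'   evaluated).
#' @export
grid_torsion_scan <- function(top, step_deg = 30,
                              params = default_forcefield(), topk = 300,
                              gap_tol = 1.0, refine = TRUE) {
  stopifnot(inherits(top, "peptide_topology"),
            !is.null(top$ring_closure_bond))
  n <- length(top$sequence$residues)
  grid <- deg2rad(seq(-180, 180 - step_deg, by = step_deg))
  model <- compile_model(top, params)
  closure_r0 <- top$bond_r0[top$bond_closure == 1L]

  # reach bound per backbone atom: remaining backbone path length to C_n
  # plus the closure bond (+ tolerance); sound by the triangle inequality
  bl <- params$geometry$bond_lengths
  prune_atom <- integer(0)
  prune_reach <- numeric(0)
  for (r in 2:n) {
    rem_res <- if (r < n) (r + 1):n else integer(0)
    rem <- length(rem_res) * (bl[["C-N"]] + bl[["N-CA"]] + bl[["CA-C"]])
    for (w in c("N", "CA", "C")) {
      at <- top$idx[[w]][r]
      extra <- switch(w, N = bl[["N-CA"]] + bl[["CA-C"]],
                      CA = bl[["CA-C"]], C = 0)
      prune_atom <- c(prune_atom, at)
      prune_reach <- c(prune_reach, rem + extra + closure_r0 + gap_tol)
    }
  }

  scan <- cpp_grid_scan(top$zmat, top$seed, max(1L, top$nvar), grid, model,
                        prune_atom, prune_reach,
                        top$ring_closure_bond[1], top$ring_closure_bond[2],
                        closure_r0, gap_tol, topk)
  if (length(scan$energies) == 0) {
    stop("no closure-feasible grid point; widen gap_tol or the grid")
  }
  out <- list(raw_energies = scan$energies, n_leaves = scan$n_leaves,
              n_evals = scan$n_evals, vars = scan$vars)
  if (refine) {
    refined <- vapply(seq_len(nrow(scan$vars)), function(q) {
      xyz <- cpp_build_zmat(top$zmat, top$seed, scan$vars[q, ])
      conf <- minimize_conformation(new_conformation(top, xyz), params,
                                    max_iter = 4000)
      conf$energy
    }, numeric(1))
    ord <- order(refined)
    best_xyz <- cpp_build_zmat(top$zmat, top$seed, scan$vars[ord[1], ])
    out$best_conformation <- minimize_conformation(
      new_conformation(top, best_xyz, label = "grid_minimum"), params,
      max_iter = 8000)
    out$energies <- refined[ord]
    out$best_energy <- out$energies[1]
  } else {
    out$best_energy <- scan$energies[1]
  }
  out
}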