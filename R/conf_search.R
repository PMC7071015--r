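# Basin-hopping Monte-Carlo conformational search and Boltzmann ensemble
# analysis. Each step perturbs every atom by an independent uniform vector,
# minimises, and applies Metropolis acceptance on the minimised energies at
# the search temperature; the ensemble collects all distinct accepted minima.

new_conformer_ensemble <- function(conformations, energies,
                                   provenance = "search", seed = NA_integer_,
                                   extras = NULL) {
  stopifnot(length(conformations) == length(energies),
            all(is.finite(energies)))
  ord <- order(energies)
  ens <- structure(list(conformations = conformations[ord],
                        energies = energies[ord],
                        provenance = provenance, seed = seed),
                   class = "conformer_ensemble")
  if (!is.null(extras)) for (nm in names(extras)) ens[[nm]] <- extras[[nm]][ord]
  ens
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer_ensemble: %d conformations (%s, seed %s)\n",
              length(x$energies), x$provenance, x$seed))
  cat(sprintf("  energies (kJ/mol): %s\n",
              paste(sprintf("%.2f", head(x$energies, 8)), collapse = ", ")))
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$energies)

#' Basin-hopping Monte-Carlo conformational search
#'
#' Starting from a minimised structure, each step displaces every atom by an
#' independent uniform random vector of norm at most `max_displacement`,
#' minimises the perturbed structure to `tol`, and accepts or rejects the new
#' minimum by the Metropolis criterion at `temperature`. All distinct accepted
#' minima are collected. Deterministic under `seed`.
#'
#' @param start A `conformation`.
#' @param steps Number of Monte-Carlo steps.
#' @param max_displacement Maximum per-atom Cartesian displacement, A.
#' @param temperature Metropolis temperature, K.
#' @param tol RMS-gradient tolerance of the per-step minimisation.
#' @param seed Integer RNG seed.
#' @param params Force-field parameters.
#' @param max_iter_min Evaluation budget of each per-step minimisation.
#' @return A `conformer_ensemble` sorted by energy.
#' @export
monte_carlo_search <- function(start, steps = 5000, max_displacement = 3,
                               temperature = 500, tol = 0.01, seed = 1,
                               params = default_forcefield(),
                               max_iter_min = 3000) {
  stopifnot(inherits(start, "conformation"), steps >= 0,
            max_displacement > 0, temperature > 0)
  set.seed(as.integer(seed))
  n <- nrow(start$xyz)
  cur <- minimize_conformation(start, params, tol = tol,
                               max_iter = max_iter_min)
  confs <- list(cur)
  energies <- cur$energy
  skipped <- 0L
  rt <- GAS_CONSTANT_KJ * temperature
  for (s in seq_len(steps)) {
    dir <- matrix(rnorm(3 * n), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    disp <- dir * (max_displacement * runif(n)^(1 / 3))
    prop_xyz <- cur$xyz + disp
    prop <- tryCatch(
      minimize_conformation(new_conformation(start$topology, prop_xyz),
                            params, tol = tol, max_iter = max_iter_min),
      error = function(e) NULL)
    if (is.null(prop)) {
      skipped <- skipped + 1L
      warning(sprintf("step %d: minimisation failed, step skipped", s),
              call. = FALSE)
      next
    }
    dE <- prop$energy - cur$energy
    if (dE <= 0 || runif(1) < exp(-dE / rt)) {
      cur <- prop
      dup <- any(vapply(seq_along(energies), function(q) {
        abs(energies[q] - prop$energy) < 1e-6 &&
          kabsch_superpose(prop$xyz, confs[[q]]$xyz)$rmsd < 0.05
      }, logical(1)))
      if (!dup) {
        confs[[length(confs) + 1]] <- prop
        energies <- c(energies, prop$energy)
      }
    }
  }
  ens <- new_conformer_ensemble(confs, energies, provenance = "search",
                                seed = as.integer(seed))
  attr(ens, "skipped_steps") <- skipped
  ens
}

#' Boltzmann factors and ratios of a conformer ensemble
#'
#' Computes per-conformer Boltzmann factors `exp(-(E - E_min)/(R T))` (shifted
#' by the ensemble minimum so the exponential cannot underflow; the shift
#' cancels from every ratio) and the ratio of each conformer's factor to that
#' of the highest-energy member. R = 8.314e-3 kJ mol^-1 K^-1.
#'
#' @param ens A `conformer_ensemble`.
#' @param temperature Temperature in K.
#' @return A data frame with columns `conformer`, `energy`, `delta_e`, `bf`
#'   and `ratio_vs_highest`; the temperature used is carried as an attribute.
#' @export
boltzmann_weights <- function(ens, temperature = 500) {
  stopifnot(inherits(ens, "conformer_ensemble"))
  if (length(ens$energies) == 0) stop("empty ensemble")
  stopifnot(temperature > 0)
  rt <- GAS_CONSTANT_KJ * temperature
  e <- ens$energies
  out <- data.frame(conformer = seq_along(e), energy = e,
                    delta_e = e - min(e),
                    bf = exp(-(e - min(e)) / rt),
                    ratio_vs_highest = exp(-(e - max(e)) / rt))
  attr(out, "temperature") <- temperature
  attr(out, "gas_constant") <- GAS_CONSTANT_KJ
  out
}

#' Remove near-duplicate conformers from an ensemble
#'
#' Greedy pass from the lowest-energy member: a conformer is kept only if its
#' all-atom superposed RMSD to every already-kept conformer exceeds
#' `rmsd_tol`, so each duplicate pair keeps its lower-energy member.
#'
#' @param ens A `conformer_ensemble`.
#' @param rmsd_tol All-atom RMSD merge threshold, A.
#' @return A deduplicated `conformer_ensemble`.
#' @export
dedup_ensemble <- function(ens, rmsd_tol = 0.5) {
  stopifnot(inherits(ens, "conformer_ensemble"), rmsd_tol >= 0)
  keep <- integer(0)
  for (q in seq_along(ens$energies)) {  # already sorted ascending by energy
    dup <- any(vapply(keep, function(k) {
      kabsch_superpose(ens$conformations[[q]]$xyz,
                       ens$conformations[[k]]$xyz)$rmsd <= rmsd_tol
    }, logical(1)))
    if (!dup) keep <- c(keep, q)
  }
  out <- ens
  out$conformations <- ens$conformations[keep]
  out$energies <- ens$energies[keep]
  for (nm in setdiff(names(ens), c("conformations", "energies", "provenance",
                                   "seed"))) {
    if (length(ens[[nm]]) == length(ens$energies)) out[[nm]] <- ens[[nm]][keep]
  }
  out
}
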