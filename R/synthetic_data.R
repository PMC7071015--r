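# Synthetic-data generators: ground-truth conformations, NOESY peak tables
# from the inverse-sixth-power forward model, dose-response plates, and the
# end-to-end recovery experiment that binds the pipeline stages together.
# Every generated dataset is fully determined by its recorded seeds.

#' Generate a ground-truth conformation
#'
#' Unrestrained simulated annealing from a random build, with a weak
#' flat-bottom radius-of-gyration compaction term switched on so the truth is
#' compact enough to show medium/long-range NOE contacts, followed by a final
#' minimisation under the standard (compaction-free) potential. The result is
#' closure-satisfying and clash-free, and deterministic under `seed`.
#'
#' @param seq A `peptide_sequence`.
#' @param seed Integer RNG seed.
#' @param schedule Annealing schedule of the generator.
#' @param params Force-field parameters.
#' @param rg0 Compaction flat-bottom radius, A; default scales with length.
#' @param rg_k Compaction force constant during generation, kJ mol^-1 A^-2.
#' @return A `conformation` labelled `truth_seed<seed>`.
#' @export
make_ground_truth <- function(seq, seed = 1,
                              schedule = annealing_schedule(
                                t_start = 2000, t_end = 100, steps = 4000),
                              params = default_forcefield(),
                              rg0 = max(3.5, 0.40 * length(seq$residues)),
                              rg_k = 5) {
  stopifnot(inherits(seq, "peptide_sequence"))
  top <- build_topology(seq, params)
  gen_params <- params
  gen_params$rg_k <- rg_k
  gen_params$rg0 <- rg0
  start <- build_conformation(top, "random", seed = seed, params = params)
  empty <- data.frame(res_i = integer(0), atom_i = character(0),
                      res_j = integer(0), atom_j = character(0),
                      lower_A = numeric(0), upper_A = numeric(0))
  conf <- anneal(start, empty, schedule, gen_params, seed = seed)
  conf <- minimize_conformation(conf, params, max_iter = 8000)
  conf$label <- sprintf("truth_seed%d", seed)
  conf
}

#' Simulate a NOESY peak table from a conformation
#'
#' Forward model of the volume-distance relation: every proton pair within
#' the observability cutoff yields a cross peak of volume
#' `c_scale * r^-6 * exp(N(0, sigma^2))` (multiplicative log-normal noise).
#' The calibration reference is the closest intra-residue HA..HB pair (a
#' fixed-template geometry, playing the role of a geminal reference) with its
#' noise-free volume.
#'
#' @param conf A `conformation` whose topology has a non-empty proton set.
#' @param c_scale Volume scale, arbitrary units * A^6.
#' @param cutoff Observability cutoff, A.
#' @param sigma Log-normal noise sigma (0.1 is about 10% volume noise).
#' @param seed Integer RNG seed (needed when `sigma > 0` or
#'   `subsample < 1`).
#' @param subsample Fraction of peaks retained (uniformly at random), to
#'   emulate sparser experimental peak lists.
#' @return List with `peaks` (res_i, atom_i, res_j, atom_j, volume) and
#'   `reference` (a [calibration_reference()] carrying its atom pair).
#' @export
simulate_noesy <- function(conf, c_scale = 1e6, cutoff = 5.0, sigma = 0,
                           seed = 1, subsample = 1) {
  stopifnot(inherits(conf, "conformation"), cutoff > 0, sigma >= 0,
            c_scale > 0, subsample > 0, subsample <= 1)
  top <- conf$topology
  pr <- top$proton_set
  if (length(pr) < 2) stop("topology has fewer than two protons")
  pairs <- t(utils::combn(pr, 2))
  d <- sqrt(rowSums((conf$xyz[pairs[, 1], , drop = FALSE] -
                     conf$xyz[pairs[, 2], , drop = FALSE])^2))
  keep <- d <= cutoff
  if (!any(keep)) {
    warning("no proton pair within the observability cutoff; empty peak list")
  }
  pairs <- pairs[keep, , drop = FALSE]
  d <- d[keep]
  set.seed(as.integer(seed))
  if (subsample < 1 && nrow(pairs) > 0) {
    take <- sort(sample(nrow(pairs), max(1, round(subsample * nrow(pairs)))))
    pairs <- pairs[take, , drop = FALSE]
    d <- d[take]
  }
  noise <- if (sigma > 0) exp(rnorm(length(d), 0, sigma)) else rep(1, length(d))
  peaks <- data.frame(res_i = top$atoms$res[pairs[, 1]],
                      atom_i = top$atoms$atom[pairs[, 1]],
                      res_j = top$atoms$res[pairs[, 2]],
                      atom_j = top$atoms$atom[pairs[, 2]],
                      volume = c_scale * d^-6 * noise,
                      stringsAsFactors = FALSE)
  # reference pair: closest intra-residue HA..HB contact, noise-free volume
  ha <- top$idx$HA
  hb <- top$idx$HB
  ok <- which(!is.na(hb))
  if (length(ok) > 0) {
    dref <- sqrt(rowSums((conf$xyz[ha[ok], , drop = FALSE] -
                          conf$xyz[hb[ok], , drop = FALSE])^2))
    i <- ok[which.min(dref)]
    r_ref <- min(dref)
    ref_atoms <- sprintf("res %d HA..HB", i)
  } else {
    i <- which.min(d)
    r_ref <- d[i]
    ref_atoms <- sprintf("res %d %s..res %d %s", peaks$res_i[i],
                         peaks$atom_i[i], peaks$res_j[i], peaks$atom_j[i])
  }
  reference <- calibration_reference(r_ref, c_scale * r_ref^-6)
  reference$atoms <- ref_atoms
  list(peaks = peaks, reference = reference)
}

#' Simulate a dose-response plate
#'
#' Inverts the inhibition normalisation: sample absorbances are generated
#' from the 4PL percent-inhibition curve (bottom 0%, top 100%) between the
#' negative-control and baseline anchors, with additive Gaussian noise of
#' standard deviation `noise_sd` percent of the dynamic range. Negative,
#' positive and blank control wells are included.
#'
#' @param ic50 True IC50, uM.
#' @param hill True Hill slope.
#' @param doses Tested concentrations, uM.
#' @param noise_sd Additive noise, percent of the dynamic range.
#' @param replicates Wells per dose and per control.
#' @param seed Integer RNG seed.
#' @param a_neg,a_baseline Absorbance anchors (negative control and
#'   100%-inhibition baseline).
#' @param compound Compound label.
#' @return A plate-readings data frame (`compound`, `conc_uM`, `a620`,
#'   `role`).
#' @export
simulate_assay <- function(ic50, hill = 1,
                           doses = 10^seq(0.5, 3, length.out = 8),
                           noise_sd = 5, replicates = 2, seed = 1,
                           a_neg = 1.0, a_baseline = 0.1,
                           compound = "cpd") {
  stopifnot(ic50 > 0, length(doses) > 0, all(doses > 0), noise_sd >= 0,
            replicates >= 1, a_neg > a_baseline)
  set.seed(as.integer(seed))
  rng <- a_neg - a_baseline
  noise <- function(k) rnorm(k, 0, noise_sd / 100 * rng)
  inh <- 100 / (1 + (ic50 / rep(doses, each = replicates))^hill)
  smp <- data.frame(compound = compound,
                    conc_uM = rep(doses, each = replicates),
                    a620 = a_neg - inh / 100 * rng +
                      noise(length(doses) * replicates),
                    role = "sample", stringsAsFactors = FALSE)
  ctrl <- data.frame(
    compound = rep(c("TNFa", "anti-TNFa", "vehicle"), each = replicates),
    conc_uM = 0,
    a620 = c(a_neg + noise(replicates), a_baseline + noise(replicates),
             a_baseline + noise(replicates)),
    role = rep(c("negative", "positive", "blank"), each = replicates),
    stringsAsFactors = FALSE)
  rbind(ctrl, smp)
}

#' End-to-end structure-recovery experiment
#'
#' Binds the pipeline together with known ground truth: generate a truth
#' conformation, simulate its NOESY peaks, calibrate them into restraints,
#' fold an annealed ensemble from random starts, cluster it, and rank every
#' member against the truth by backbone RMSD. All seeds are recorded so the
#' report can be replayed exactly.
#'
#' @param seq A `peptide_sequence`.
#' @param seed Master seed; the truth uses `seed`, the NOESY simulation
#'   `seed + 1`, the annealing runs `seed * 100 + i`.
#' @param sigma NOESY volume noise (log-normal sigma).
#' @param n_structures Ensemble size.
#' @param schedule Annealing schedule for the recovery runs.
#' @param params Force-field parameters.
#' @param c_scale,cutoff,subsample Passed to [simulate_noesy()].
#' @param cluster_cutoff Linkage cutoff of the cluster summary, A.
#' @return A `recovery_report`: best backbone RMSD to truth, the full mimicry
#'   table, violation statistics, cluster summary, the ensemble, and the
#'   seeds/configs used.
#' @export
recovery_experiment <- function(seq, seed = 1, sigma = 0, n_structures = 10,
                                schedule = annealing_schedule(),
                                params = default_forcefield(),
                                c_scale = 1e6, cutoff = 5.0, subsample = 1,
                                cluster_cutoff = 2.0) {
  stopifnot(inherits(seq, "peptide_sequence"))
  truth <- make_ground_truth(seq, seed = seed, params = params)
  sim <- simulate_noesy(truth, c_scale = c_scale, cutoff = cutoff,
                        sigma = sigma, seed = seed + 1,
                        subsample = subsample)
  restraints <- calibrate_noe(sim$peaks, sim$reference)
  top <- truth$topology
  ens <- generate_ensemble(top, restraints, n = n_structures,
                           schedule = schedule, params = params,
                           base_seed = seed * 100)
  mim <- mimicry_table(ens, truth)
  clus <- cluster_ensemble(ens, cutoff = cluster_cutoff)
  best_i <- as.integer(sub("conf_", "", mim$structure[1]))
  structure(list(
    truth = truth, restraints = restraints, ensemble = ens,
    mimicry = mim, clusters = clus,
    best_rmsd = mim$rmsd_A[1],
    best_violations = ens$violations[[best_i]],
    seeds = list(truth = seed, noesy = seed + 1, ensemble_base = seed * 100),
    config = list(sigma = sigma, n_structures = n_structures,
                  c_scale = c_scale, cutoff = cutoff, subsample = subsample,
                  schedule = schedule)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "recovery_report: best backbone RMSD to truth %.3f A over %d structures\n",
    x$best_rmsd, length(x$ensemble$energies)))
  cat(sprintf("  restraints: %d; best-structure satisfaction %.0f%% (max |viol| %.3f A)\n",
              nrow(x$restraints), 100 * x$best_violations$fraction_satisfied,
              x$best_violations$max_violation))
  cat(sprintf("  clusters at %.1f A: sizes %s\n", x$clusters$cutoff,
              paste(lengths(x$clusters$clusters), collapse = "/")))
  invisible(x)
}
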