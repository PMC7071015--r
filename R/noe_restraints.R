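# NOESY cross-peak calibration into distance restraints, and proline
# cis/trans classification from 13C shifts.
#
# Calibration uses the inverse-sixth-power relation between cross-peak volume
# and interproton distance: r_ij = r_ref * (alpha_ref / alpha_ij)^(1/6),
# referenced to a peak of known distance. Bounds are flat-bottom,
# r_ij -/+ bound_margin, with the lower bound clamped at hard-sphere contact
# (1.8 A) and a +1.0 A pseudo-atom allowance on upper bounds involving the
# beta pseudo-proton.

#' Calibration reference for NOESY volumes
#'
#' @param r_ref Known distance of the reference proton pair, A.
#' @param a_ref Cross-peak volume of the reference pair (same arbitrary units
#'   as the peak list).
#' @return A `calibration_reference`.
#' @export
calibration_reference <- function(r_ref, a_ref) {
  stopifnot(is.finite(r_ref), r_ref > 0, is.finite(a_ref), a_ref > 0)
  structure(list(r_ref = r_ref, a_ref = a_ref),
            class = "calibration_reference")
}

#' Calibrate NOESY cross-peak volumes into distance restraints
#'
#' @param peaks Data frame with columns `res_i`, `atom_i`, `res_j`, `atom_j`,
#'   `volume` (one NOESY cross peak per row; volumes must be positive).
#' @param reference A [calibration_reference()].
#' @param bound_margin Symmetric flat-bottom half-width, A.
#' @param lower_clamp Hard-sphere lower-bound clamp, A.
#' @param pseudo_atoms Atom names treated as pseudo-atoms; restraints touching
#'   one get `pseudo_correction` added to the upper bound.
#' @param pseudo_correction Pseudo-atom upper-bound allowance, A.
#' @return A restraint data frame with columns `res_i`, `atom_i`, `res_j`,
#'   `atom_j`, `distance_A`, `lower_A`, `upper_A`, `source_peak`, one row per
#'   peak in input order.
#' @export
calibrate_noe <- function(peaks, reference, bound_margin = 0.5,
                          lower_clamp = 1.8, pseudo_atoms = "HB",
                          pseudo_correction = 1.0) {
  stopifnot(inherits(reference, "calibration_reference"))
  need <- c("res_i", "atom_i", "res_j", "atom_j", "volume")
  miss <- setdiff(need, names(peaks))
  if (length(miss) > 0) stop("peaks lack column(s): ",
                             paste(miss, collapse = ", "))
  bad <- which(!is.finite(peaks$volume) | peaks$volume <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive volume in peak %d (%s%s-%s%s)", bad[1],
                 peaks$res_i[bad[1]], peaks$atom_i[bad[1]],
                 peaks$res_j[bad[1]], peaks$atom_j[bad[1]]))
  }
  r <- reference$r_ref * (reference$a_ref / peaks$volume)^(1 / 6)
  lower <- pmax(pmin(lower_clamp, r), r - bound_margin)
  upper <- r + bound_margin +
    ifelse(peaks$atom_i %in% pseudo_atoms | peaks$atom_j %in% pseudo_atoms,
           pseudo_correction, 0)
  data.frame(res_i = peaks$res_i, atom_i = peaks$atom_i,
             res_j = peaks$res_j, atom_j = peaks$atom_j,
             distance_A = r, lower_A = lower, upper_A = upper,
             source_peak = seq_len(nrow(peaks)),
             stringsAsFactors = FALSE)
}

#' Classify proline cis/trans from 13C chemical shifts
#'
#' Uses the difference between the C-beta and C-gamma shifts: a small
#' difference indicates the trans X-Pro configuration, a large one cis
#' (typical values are about 4.5 ppm for trans and 9.15 ppm for cis). The
#' decision bands are this package's rule: trans when the absolute difference
#' is at most `trans_max`, cis when at least `cis_min`, ambiguous between.
#'
#' @param delta_cb,delta_cg C-beta and C-gamma 13C shifts, ppm (vectorised).
#' @param trans_max Upper edge of the trans band, ppm.
#' @param cis_min Lower edge of the cis band, ppm.
#' @return Character vector of `"trans"`, `"cis"` or `"ambiguous"`.
#' @export
classify_proline <- function(delta_cb, delta_cg, trans_max = 6.0,
                             cis_min = 8.0) {
  stopifnot(all(is.finite(delta_cb)), all(is.finite(delta_cg)))
  dd <- abs(delta_cb - delta_cg)
  ifelse(dd <= trans_max, "trans", ifelse(dd >= cis_min, "cis", "ambiguous"))
}
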