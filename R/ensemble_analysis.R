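# Superposition, clustering and mimicry ranking.
#
# Backbone comparisons use N, CA, C (carbonyl O excluded). The cyclic-to-
# linear correspondence against a reference loop maps residues by position
# through an explicit residue mapping; by default the identity mapping over
# the first min(n_mobile, n_reference) residues, which for an
# epitope-first design aligns the grafted epitope onto the loop it mimics.

BACKBONE_ATOMS <- c("N", "CA", "C")

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal rotation and translation of `mobile` onto
#' `reference` via the SVD of the cross-covariance matrix, with the
#' determinant correction that excludes reflections.
#'
#' @param mobile,reference n x 3 coordinate matrices with equal row counts
#'   (n >= 3, not all collinear).
#' @return A `superposition`: `rotation` (3 x 3, det +1), `translation`
#'   (length 3), `rmsd` (A) and `n`. The aligned mobile set is
#'   `mobile %*% t(rotation) + translation` (rowwise).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(reference))
  }
  if (nrow(mobile) < 3) stop("need at least 3 points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  mc <- sweep(mobile, 2, cm)
  rc <- sweep(reference, 2, cr)
  if (svd(mc)$d[2] < 1e-8 && svd(rc)$d[2] < 1e-8) {
    stop("degenerate (collinear) point set")
  }
  a <- t(mc) %*% rc                       # sum over points of m r^T
  s <- svd(a)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- mc %*% t(rot)
  structure(list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
                 rmsd = sqrt(mean(rowSums((aligned - rc)^2))),
                 n = nrow(mobile)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d points, rmsd %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

# Normalise conformations / read_pdb models / raw frames to a common shape.
coord_frame <- function(x) {
  if (inherits(x, "conformation")) {
    list(atoms = x$topology$atoms[, c("res", "atom")], xyz = x$xyz)
  } else if (is.list(x) && !is.null(x$atoms) && !is.null(x$xyz)) {
    list(atoms = x$atoms[, c("res", "atom")], xyz = as.matrix(x$xyz))
  } else {
    stop("cannot interpret object as a coordinate set")
  }
}

backbone_coords <- function(frame, residues, atoms = BACKBONE_ATOMS,
                            who = "structure") {
  keymap <- setNames(seq_len(nrow(frame$atoms)),
                     paste(frame$atoms$res, frame$atoms$atom))
  wanted <- expand.grid(atom = atoms, res = residues,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- keymap[paste(wanted$res, wanted$atom)]
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("%s: missing backbone atom %s of residue %s", who,
                 wanted$atom[bad], wanted$res[bad]))
  }
  frame$xyz[idx, , drop = FALSE]
}

#' Backbone RMSD between two structures
#'
#' Superposes the mapped N, CA, C atoms by [kabsch_superpose()] and reports
#' the RMSD over those same atoms.
#'
#' @param a,b `conformation`s or coordinate sets (lists with `atoms` and
#'   `xyz`, as returned by [read_pdb_models()]).
#' @param mapping Optional data frame with columns `mobile_res`, `ref_res`
#'   (residue indices of `a` mapped onto `b`); defaults to the identity
#'   mapping over the first `min(n_a, n_b)` residues.
#' @param atoms Backbone atom names used.
#' @return RMSD in Angstroms.
#' @export
backbone_rmsd <- function(a, b, mapping = NULL, atoms = BACKBONE_ATOMS) {
  fa <- coord_frame(a)
  fb <- coord_frame(b)
  if (is.null(mapping)) {
    na <- length(unique(fa$atoms$res))
    nb <- length(unique(fb$atoms$res))
    k <- min(na, nb)
    mapping <- data.frame(mobile_res = sort(unique(fa$atoms$res))[seq_len(k)],
                          ref_res = sort(unique(fb$atoms$res))[seq_len(k)])
  }
  if (anyDuplicated(mapping$mobile_res) || anyDuplicated(mapping$ref_res)) {
    stop("residue mapping must be injective")
  }
  xa <- backbone_coords(fa, mapping$mobile_res, atoms, "mobile")
  xb <- backbone_coords(fb, mapping$ref_res, atoms, "reference")
  kabsch_superpose(xa, xb)$rmsd
}

#' Cluster an ensemble on pairwise backbone RMSD
#'
#' Average-linkage hierarchical clustering of the pairwise backbone-RMSD
#' matrix, cut at `cutoff`. Clusters are sorted by size (descending), ties by
#' their lowest member energy.
#'
#' @param ens A `conformer_ensemble`.
#' @param cutoff Linkage cutoff, A.
#' @return A `cluster_set`: list of member-index vectors plus the cutoff.
#' @export
cluster_ensemble <- function(ens, cutoff = 2.0) {
  stopifnot(inherits(ens, "conformer_ensemble"), cutoff > 0)
  n <- length(ens$energies)
  if (n == 0) stop("empty ensemble")
  if (n == 1) {
    return(structure(list(clusters = list(1L), cutoff = cutoff),
                     class = "cluster_set"))
  }
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dm[i, j] <- dm[j, i] <- backbone_rmsd(ens$conformations[[i]],
                                            ens$conformations[[j]])
    }
  }
  hc <- hclust(as.dist(dm), method = "average")
  # guard against numerical-noise height inversions on (near-)degenerate
  # distance matrices (e.g. an ensemble of identical structures)
  hc$height <- cummax(pmax(hc$height, 0))
  memb <- cutree(hc, h = cutoff)
  clusters <- split(seq_len(n), memb)
  sizes <- lengths(clusters)
  emin <- vapply(clusters, function(ix) min(ens$energies[ix]), numeric(1))
  ord <- order(-sizes, emin)
  structure(list(clusters = unname(clusters[ord]), cutoff = cutoff),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters at %.2f A cutoff, sizes %s\n",
              length(x$clusters), x$cutoff,
              paste(lengths(x$clusters), collapse = "/")))
  invisible(x)
}

#' Mimicry ranking against a reference loop
#'
#' Backbone RMSD of every labelled structure against a reference loop,
#' returned sorted ascending (best mimic first). Unmappable structures are
#' flagged with `NA` and a note, never dropped.
#'
#' @param structures Named list of `conformation`s / coordinate sets, or a
#'   `conformer_ensemble` (members are then labelled `conf_1`, `conf_2`, ...
#'   in energy order).
#' @param reference Coordinate set of the reference loop (e.g. one model from
#'   [read_pdb_models()], residue-range selected).
#' @param mapping Optional residue mapping passed to [backbone_rmsd()].
#' @return Data frame with columns `structure`, `rmsd_A`, `note`, sorted by
#'   RMSD.
#' @export
mimicry_table <- function(structures, reference, mapping = NULL) {
  if (inherits(structures, "conformer_ensemble")) {
    structures <- setNames(structures$conformations,
                           paste0("conf_", seq_along(structures$energies)))
  }
  stopifnot(length(structures) > 0)
  if (is.null(names(structures)) || any(!nzchar(names(structures)))) {
    names(structures) <- paste0("structure_", seq_along(structures))
  }
  rows <- lapply(names(structures), function(nm) {
    r <- tryCatch(backbone_rmsd(structures[[nm]], reference, mapping),
                  error = function(e) conditionMessage(e))
    if (is.character(r)) {
      data.frame(structure = nm, rmsd_A = NA_real_, note = r,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(structure = nm, rmsd_A = r, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$rmsd_A), out$rmsd_A), , drop = FALSE]
  rownames(out) <- NULL
  out
}
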