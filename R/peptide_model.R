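# Design parsing and atom-level realisation of head-to-tail cyclic peptides.
#
# The molecular representation is a reduced template: backbone N, CA, C, O per
# residue; side chains as CB plus a single side-chain centroid pseudo-atom SC
# for residues with atoms beyond CB; protons limited to the amide H (HN, absent
# on proline), the alpha H (HA) and one beta pseudo-proton (HB, absent on
# glycine). This is the proton set the NOE machinery uses, so nothing finer is
# carried. Ideal geometry comes from the force-field parameter object and is
# frozen into the topology, which keeps the builder and the energy model
# exactly self-consistent.

AA_ONE <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# CB -> side-chain-centroid distance (Angstrom) of the reduced template;
# rough centroids of the heavy atoms beyond CB. NA = no SC atom.
SC_DIST <- c(A = NA, R = 3.9, N = 1.95, D = 1.95, C = 1.81, E = 2.55,
             Q = 2.55, G = NA, H = 2.3, I = 2.05, L = 2.1, K = 3.2,
             M = 2.7, F = 2.9, P = 1.2, S = 1.43, T = 1.5, W = 3.4,
             Y = 3.2, V = 1.53)

#' Parse a cyclic-peptide design specification
#'
#' A design is an epitope (the loop sequence to be mimicked) followed by a
#' short linker; the concatenated sequence is optionally cyclised head to
#' tail. Prolines default to the trans configuration of their preceding
#' peptide bond.
#'
#' @param epitope One-letter residue string of the grafted epitope.
#' @param linker One-letter residue string of the linker (may be empty only
#'   for linear designs).
#' @param cyclic Logical; head-to-tail cyclisation flag.
#' @param origin_labels Optional vector labelling epitope positions with their
#'   source numbering (e.g. receptor residue numbers), recycled onto the
#'   epitope part only.
#' @return A `peptide_sequence` object.
#' @examples
#' parse_design("HYWSENLFQ", "PG", cyclic = TRUE)
#' @export
parse_design <- function(epitope, linker = "", cyclic = TRUE,
                         origin_labels = NULL) {
  stopifnot(is.character(epitope), length(epitope) == 1L, nzchar(epitope))
  stopifnot(is.character(linker), length(linker) == 1L)
  res <- strsplit(paste0(epitope, linker), "")[[1]]
  bad <- setdiff(unique(res), AA_ONE)
  if (length(bad) > 0) {
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
  }
  if (isTRUE(cyclic) && length(res) < 3) {
    stop("a head-to-tail cycle needs at least 3 residues, got ", length(res))
  }
  pro <- which(res == "P")
  configs <- setNames(rep("trans", length(pro)), pro)
  labels <- NULL
  if (!is.null(origin_labels)) {
    ep <- strsplit(epitope, "")[[1]]
    labels <- setNames(rep_len(origin_labels, length(ep)), seq_along(ep))
  }
  new_peptide_sequence(res, isTRUE(cyclic), configs, labels)
}

new_peptide_sequence <- function(residues, cyclic, proline_configs = NULL,
                                 origin_labels = NULL) {
  stopifnot(all(residues %in% AA_ONE))
  if (cyclic && length(residues) < 3) stop("cyclic sequence shorter than 3")
  if (length(proline_configs) > 0) {
    pos <- as.integer(names(proline_configs))
    if (any(residues[pos] != "P")) {
      stop("proline_configs refers to a non-proline position")
    }
    stopifnot(all(proline_configs %in% c("cis", "trans")))
  }
  structure(list(residues = residues, cyclic = cyclic,
                 proline_configs = proline_configs,
                 origin_labels = origin_labels),
            class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("peptide_sequence: %s (%d residues, %s)\n",
              paste(x$residues, collapse = ""), length(x$residues),
              if (x$cyclic) "cyclic head-to-tail" else "linear"))
  if (length(x$proline_configs) > 0) {
    cat("  proline configs:",
        paste(sprintf("P%s=%s", names(x$proline_configs), x$proline_configs),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# -- topology ----------------------------------------------------------------

#' Build the molecular topology of a peptide design
#'
#' Realises a `peptide_sequence` as atoms, bonds, angles, torsion terms and a
#' buildable internal-coordinate recipe under the package's reduced template.
#' A cyclic design carries a ring-closure bond between the C-terminal carbonyl
#' C and the N-terminal N, so a cyclic N-mer has exactly N peptide bonds and a
#' linear N-mer has N - 1.
#'
#' @param seq A `peptide_sequence`.
#' @param params Force-field parameters supplying the ideal geometry
#'   constants; see [default_forcefield()].
#' @return A `peptide_topology` object.
#' @export
build_topology <- function(seq, params = default_forcefield()) {
  stopifnot(inherits(seq, "peptide_sequence"))
  geo <- params$geometry
  res <- seq$residues
  n <- length(res)
  cyclic <- seq$cyclic
  sp3 <- deg2rad(geo$angle_sp3_deg)
  sp2 <- deg2rad(geo$angle_sp2_deg)
  bl <- geo$bond_lengths

  # omega target entering each residue i (the X -> i peptide bond)
  omega_target <- rep(pi, n)
  if (length(seq$proline_configs) > 0) {
    cis_pos <- as.integer(names(seq$proline_configs)[seq$proline_configs == "cis"])
    omega_target[cis_pos] <- 0
  }

  has_hn <- res != "P"
  has_cb <- res != "G"
  has_sc <- !is.na(SC_DIST[res])

  atoms <- data.frame(res = integer(0), res_name = character(0),
                      atom = character(0), element = character(0),
                      stringsAsFactors = FALSE)
  add_atom <- function(i, name, element) {
    atoms[nrow(atoms) + 1L, ] <<- list(i, AA_THREE[[res[i]]], name, element)
    nrow(atoms)
  }

  nvar <- if (n > 1) 2L * (n - 1L) else 0L
  psi_id <- function(i) i                      # i in 1..n-1
  phi_id <- function(i) (n - 1L) + (i - 1L)    # i in 2..n
  var_names <- character(nvar)
  if (n > 1) {
    var_names[seq_len(n - 1)] <- paste0("psi_", seq_len(n - 1))
    var_names[n:(2L * n - 2L)] <- paste0("phi_", 2:n)
  }

  zm <- list(a = integer(0), b = integer(0), c = integer(0),
             r = numeric(0), theta = numeric(0), phi = numeric(0),
             var = integer(0), offset = numeric(0))
  add_z <- function(a, b, c, r, theta, phi = 0, var = 0L, offset = 0) {
    zm$a <<- c(zm$a, a); zm$b <<- c(zm$b, b); zm$c <<- c(zm$c, c)
    zm$r <<- c(zm$r, r); zm$theta <<- c(zm$theta, theta)
    zm$phi <<- c(zm$phi, phi); zm$var <<- c(zm$var, var)
    zm$offset <<- c(zm$offset, offset)
  }

  # backbone block: N, CA, C per residue, in chain order
  iN <- iCA <- iC <- integer(n)
  for (i in seq_len(n)) {
    iN[i] <- add_atom(i, "N", "N")
    iCA[i] <- add_atom(i, "CA", "C")
    iC[i] <- add_atom(i, "C", "C")
    if (i == 1) {
      add_z(0L, 0L, 0L, 0, 0); add_z(0L, 0L, 0L, 0, 0); add_z(0L, 0L, 0L, 0, 0)
    } else {
      add_z(iN[i - 1], iCA[i - 1], iC[i - 1], bl[["C-N"]], sp2,
            var = psi_id(i - 1))
      add_z(iCA[i - 1], iC[i - 1], iN[i], bl[["N-CA"]], sp2,
            phi = omega_target[i])
      add_z(iC[i - 1], iN[i], iCA[i], bl[["CA-C"]], sp3, var = phi_id(i))
    }
  }

  # decorations: O, HN, HA, CB, HB, SC per residue
  iO <- iHN <- iHA <- iCB <- iHB <- iSC <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    iO[i] <- add_atom(i, "O", "O")
    if (i <= n - 1) {
      add_z(iN[i], iCA[i], iC[i], bl[["C-O"]], sp2, var = psi_id(i),
            offset = pi)
    } else {
      add_z(iN[i], iCA[i], iC[i], bl[["C-O"]], sp2, phi = pi)
    }
    if (has_hn[i]) {
      iHN[i] <- add_atom(i, "HN", "H")
      prev <- if (i > 1) i - 1L else if (cyclic) n else NA_integer_
      if (is.na(prev)) {
        add_z(iC[1], iCA[1], iN[1], bl[["N-HN"]], sp2, phi = pi)
      } else {
        add_z(iCA[prev], iC[prev], iN[i], bl[["N-HN"]], sp2,
              phi = omega_target[i] - pi)
      }
    }
    iHA[i] <- add_atom(i, "HA", "H")
    add_z(iC[i], iN[i], iCA[i], bl[["CA-HA"]], sp3, phi = deg2rad(120))
    if (has_cb[i]) {
      iCB[i] <- add_atom(i, "CB", "C")
      add_z(iC[i], iN[i], iCA[i], bl[["CA-CB"]], sp3, phi = deg2rad(-120))
      chi0 <- if (res[i] == "P") deg2rad(30) else pi
      iHB[i] <- add_atom(i, "HB", "H")
      add_z(iN[i], iCA[i], iCB[i], bl[["CB-HB"]], sp3, phi = chi0 + deg2rad(120))
      if (has_sc[i]) {
        iSC[i] <- add_atom(i, "SC", "C")
        add_z(iN[i], iCA[i], iCB[i], SC_DIST[[res[i]]], sp3, phi = chi0)
      }
    }
  }
  natoms <- nrow(atoms)

  # bonds
  bonds <- matrix(integer(0), ncol = 2)
  bond_r0 <- numeric(0)
  bond_closure <- integer(0)
  bond_label <- character(0)
  add_bond <- function(i, j, r0, label, closure = 0L) {
    bonds <<- rbind(bonds, c(i, j))
    bond_r0 <<- c(bond_r0, r0)
    bond_closure <<- c(bond_closure, closure)
    bond_label <<- c(bond_label, label)
  }
  for (i in seq_len(n)) {
    add_bond(iN[i], iCA[i], bl[["N-CA"]], "N-CA")
    add_bond(iCA[i], iC[i], bl[["CA-C"]], "CA-C")
    add_bond(iC[i], iO[i], bl[["C-O"]], "C-O")
    if (has_hn[i]) add_bond(iN[i], iHN[i], bl[["N-HN"]], "N-HN")
    add_bond(iCA[i], iHA[i], bl[["CA-HA"]], "CA-HA")
    if (has_cb[i]) {
      add_bond(iCA[i], iCB[i], bl[["CA-CB"]], "CA-CB")
      add_bond(iCB[i], iHB[i], bl[["CB-HB"]], "CB-HB")
      if (has_sc[i]) add_bond(iCB[i], iSC[i], SC_DIST[[res[i]]], "CB-SC")
    }
  }
  for (i in seq_len(max(0, n - 1))) {
    add_bond(iC[i], iN[i + 1], bl[["C-N"]], "C-N")
  }
  ring_closure_bond <- NULL
  if (cyclic) {
    add_bond(iC[n], iN[1], bl[["C-N"]], "C-N", closure = 1L)
    ring_closure_bond <- c(iC[n], iN[1])
  }
  peptide_bond_rows <- which(bond_label == "C-N")

  # adjacency, angles (all bonded triples), non-bonded exclusions
  adj <- vector("list", natoms)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds[b, 1]]] <- c(adj[[bonds[b, 1]]], bonds[b, 2])
    adj[[bonds[b, 2]]] <- c(adj[[bonds[b, 2]]], bonds[b, 1])
  }
  ang <- matrix(integer(0), ncol = 3)
  for (j in seq_len(natoms)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      ang <- rbind(ang, t(rbind(cmb[1, ], rep(j, ncol(cmb)), cmb[2, ])))
    }
  }
  sp3_centers <- c("CA", "CB")
  ang_th0 <- ifelse(atoms$atom[ang[, 2]] %in% sp3_centers, sp3, sp2)

  # soft 3-fold rotors: phi, psi, chi (proline chi is harmonic instead)
  t3 <- matrix(integer(0), ncol = 4)
  t3_label <- character(0)
  add_t3 <- function(q, label) {
    t3 <<- rbind(t3, q)
    t3_label <<- c(t3_label, label)
  }
  for (i in seq_len(n)) {
    prev <- if (i > 1) i - 1L else if (cyclic) n else NA_integer_
    nxt <- if (i < n) i + 1L else if (cyclic) 1L else NA_integer_
    if (!is.na(prev)) add_t3(c(iC[prev], iN[i], iCA[i], iC[i]),
                             paste0("phi_", i))
    if (!is.na(nxt)) add_t3(c(iN[i], iCA[i], iC[i], iN[nxt]),
                            paste0("psi_", i))
    if (has_sc[i] && res[i] != "P") {
      add_t3(c(iN[i], iCA[i], iCB[i], iSC[i]), paste0("chi_", i))
    }
  }

  # harmonic torsions: omega planarity, chirality impropers, proline chi
  harm <- matrix(integer(0), ncol = 4)
  h_phi0 <- numeric(0)
  h_class <- character(0)
  add_h <- function(q, phi0, class) {
    harm <<- rbind(harm, q)
    h_phi0 <<- c(h_phi0, phi0)
    h_class <<- c(h_class, class)
  }
  for (i in seq_len(n)) {
    nxt <- if (i < n) i + 1L else if (cyclic) 1L else NA_integer_
    if (!is.na(nxt)) {
      add_h(c(iCA[i], iC[i], iN[nxt], iCA[nxt]), omega_target[nxt], "omega")
    }
    add_h(c(iCA[i], iN[i], iC[i], iHA[i]), 0, "chirality")  # target set below
    if (has_cb[i]) add_h(c(iCA[i], iN[i], iC[i], iCB[i]), 0, "chirality")
    if (has_sc[i] && res[i] == "P") {
      add_h(c(iN[i], iCA[i], iCB[i], iSC[i]), deg2rad(30), "prochi")
    }
  }

  # non-bonded pairs: everything except 1-2 and 1-3
  excl <- new.env(hash = TRUE)
  key <- function(i, j) paste0(min(i, j), ".", max(i, j))
  for (b in seq_len(nrow(bonds))) assign(key(bonds[b, 1], bonds[b, 2]), TRUE, excl)
  for (a in seq_len(nrow(ang))) assign(key(ang[a, 1], ang[a, 3]), TRUE, excl)
  allp <- which(upper.tri(matrix(0, natoms, natoms)), arr.ind = TRUE)
  keep <- !vapply(seq_len(nrow(allp)),
                  function(q) exists(key(allp[q, 1], allp[q, 2]), excl,
                                     inherits = FALSE),
                  logical(1))
  nb_i <- allp[keep, 1]
  nb_j <- allp[keep, 2]

  proton_set <- c(iHN[!is.na(iHN)], iHA, iHB[!is.na(iHB)])
  proton_set <- sort(proton_set)

  seed <- rbind(c(0, 0, 0),
                c(bl[["N-CA"]], 0, 0),
                c(bl[["N-CA"]] + bl[["CA-C"]] * cos(pi - sp3),
                  bl[["CA-C"]] * sin(pi - sp3), 0))

  top <- structure(list(
    sequence = seq, atoms = atoms, natoms = natoms,
    bonds = bonds, bond_r0 = bond_r0, bond_closure = bond_closure,
    bond_label = bond_label, peptide_bond_rows = peptide_bond_rows,
    ring_closure_bond = ring_closure_bond,
    angles = ang, ang_th0 = ang_th0,
    t3 = t3, t3_label = t3_label,
    harm = harm, h_phi0 = h_phi0, h_class = h_class,
    nb_i = nb_i, nb_j = nb_j,
    proton_set = proton_set,
    zmat = zm, seed = seed, nvar = nvar, var_names = var_names,
    idx = list(N = iN, CA = iCA, C = iC, O = iO, HN = iHN, HA = iHA,
               CB = iCB, HB = iHB, SC = iSC)
  ), class = "peptide_topology")

  # chirality improper targets are whatever the ideal template realises;
  # measure them once on the extended build so builder and potential agree
  ext <- cpp_build_zmat(top$zmat, top$seed, rep(pi, max(1, nvar)))
  for (q in which(h_class == "chirality")) {
    at <- harm[q, ]
    top$h_phi0[q] <- dihedral_angle(ext[at[1], ], ext[at[2], ],
                                    ext[at[3], ], ext[at[4], ])
  }

  # torsion-space move set for annealing: phi/psi pivots plus non-proline chi
  top$moves <- build_move_set(top)
  top
}

#' @export
print.peptide_topology <- function(x, ...) {
  cat(sprintf(
    "peptide_topology: %s, %d residues, %d atoms, %d bonds (%d peptide%s)\n",
    paste(x$sequence$residues, collapse = ""), length(x$sequence$residues),
    x$natoms, nrow(x$bonds), length(x$peptide_bond_rows),
    if (!is.null(x$ring_closure_bond)) ", incl. ring closure" else ""))
  invisible(x)
}

# Downstream atom set when rotating about tree edge a -> b (closure bond
# removed so the bond graph is acyclic).
tree_component <- function(top, a, b) {
  keep <- top$bond_closure == 0L
  adj <- vector("list", top$natoms)
  for (q in which(keep)) {
    i <- top$bonds[q, 1]; j <- top$bonds[q, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(top$natoms)
  seen[a] <- TRUE
  stack <- b
  seen[b] <- TRUE
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  out <- which(seen)
  setdiff(out, c(a, b))
}

build_move_set <- function(top) {
  n <- length(top$sequence$residues)
  res <- top$sequence$residues
  moves <- list()
  for (i in seq_len(n)) {
    moves[[length(moves) + 1]] <- list(name = paste0("phi_", i),
                                       a = top$idx$N[i], b = top$idx$CA[i])
    moves[[length(moves) + 1]] <- list(name = paste0("psi_", i),
                                       a = top$idx$CA[i], b = top$idx$C[i])
    if (!is.na(top$idx$SC[i]) && res[i] != "P") {
      moves[[length(moves) + 1]] <- list(name = paste0("chi_", i),
                                         a = top$idx$CA[i], b = top$idx$CB[i])
    }
  }
  lapply(moves, function(m) {
    m$atoms <- tree_component(top, m$a, m$b)
    m
  })
}

# -- conformations -----------------------------------------------------------

new_conformation <- function(topology, xyz, energy = NULL, label = "") {
  stopifnot(nrow(xyz) == topology$natoms, all(is.finite(xyz)))
  structure(list(topology = topology, xyz = xyz, energy = energy,
                 label = label), class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation%s: %d atoms%s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$xyz),
              if (!is.null(x$energy)) sprintf(", E = %.3f kJ/mol", x$energy)
              else ""))
  invisible(x)
}

#' Build an initial conformation for a topology
#'
#' `extended` places all build torsions at 180 degrees; `random` draws the
#' backbone phi/psi torsions uniformly. For cyclic topologies the chain is
#' then refined by energy minimisation until the ring-closure bond is within
#' tolerance of its ideal length; an unattainable closure is an error naming
#' the residual gap.
#'
#' @param top A `peptide_topology`.
#' @param mode `"extended"` or `"random"`.
#' @param seed Integer RNG seed, required for `mode = "random"`.
#' @param params Force-field parameters.
#' @param closure_gap_tol Maximum allowed deviation of the closure bond from
#'   its ideal length after refinement (Angstrom).
#' @return A `conformation`.
#' @export
build_conformation <- function(top, mode = c("extended", "random"),
                               seed = NULL, params = default_forcefield(),
                               closure_gap_tol = 0.3) {
  stopifnot(inherits(top, "peptide_topology"))
  mode <- match.arg(mode)
  if (mode == "random") {
    if (is.null(seed)) stop("mode = 'random' requires a seed")
    set.seed(as.integer(seed))
    vals <- runif(max(1, top$nvar), -pi, pi)
  } else {
    vals <- rep(pi, max(1, top$nvar))
  }
  xyz <- cpp_build_zmat(top$zmat, top$seed, vals)
  conf <- new_conformation(top, xyz, label = mode)
  cyclic <- !is.null(top$ring_closure_bond)
  if (cyclic || mode == "random") {
    conf <- minimize_conformation(conf, params, max_iter = 4000)
  }
  if (cyclic) {
    cb <- top$ring_closure_bond
    ideal <- top$bond_r0[top$bond_closure == 1L]
    gap <- abs(vnorm(conf$xyz[cb[1], ] - conf$xyz[cb[2], ]) - ideal)
    if (gap > closure_gap_tol) {
      conf <- minimize_conformation(conf, params, max_iter = 20000)
      gap <- abs(vnorm(conf$xyz[cb[1], ] - conf$xyz[cb[2], ]) - ideal)
    }
    if (gap > closure_gap_tol) {
      stop(sprintf("ring closure unattainable: residual gap %.3f A", gap))
    }
  }
  conf$label <- mode
  conf
}
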