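# File formats: PDB reading (via bio3d) and writing (own writer, because the
# ensemble writer needs MODEL/ENDMDL blocks plus the ring-closure CONECT
# record), and the pipeline's TSV dialects. All TSVs are tab-delimited with a
# header row and '.' decimal separator.

#' Read structures from a PDB file
#'
#' Parses ATOM records (PDB v3.3 fixed columns, through bio3d) with optional
#' chain and residue-range selection; multi-model files yield one coordinate
#' set per model.
#'
#' @param path PDB file.
#' @param chain Optional chain identifier to select.
#' @param resno Optional integer vector of residue numbers to select.
#' @return List of models; each is a list with `atoms` (data frame `res`,
#'   `res_name`, `atom`, `chain`, `element`) and `xyz` (n x 3 matrix).
#' @export
read_pdb_models <- function(path, chain = NULL, resno = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  at_lines <- grep("^ATOM  |^HETATM", lines)
  if (length(at_lines) == 0) stop("no ATOM records in ", path)
  for (ln in at_lines) {
    coords <- suppressWarnings(as.numeric(c(
      substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
      substr(lines[ln], 47, 54))))
    if (anyNA(coords)) stop("malformed ATOM record at line ", ln)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- rep(TRUE, nrow(pdb$atom))
  if (!is.null(chain)) sel <- sel & pdb$atom$chain %in% chain
  if (!is.null(resno)) sel <- sel & pdb$atom$resno %in% resno
  if (!any(sel)) stop("empty selection (chain/residue filter matched nothing)")
  atoms <- data.frame(res = pdb$atom$resno[sel],
                      res_name = pdb$atom$resid[sel],
                      atom = pdb$atom$elety[sel],
                      chain = pdb$atom$chain[sel],
                      element = pdb$atom$elesy[sel],
                      stringsAsFactors = FALSE)
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[sel, , drop = FALSE]
    list(atoms = atoms, xyz = xyz)
  })
}

pdb_atom_line <- function(serial, name, res_name, res, x, y, z, element) {
  # PDB v3.3 fixed columns: name 13-16 (short names start at 14), resName
  # 18-20, chain 22, resSeq 23-26, x/y/z 31-54, element 77-78
  sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, res_name, res, x, y, z, 1, 0, element)
}

#' Write structures to a PDB file
#'
#' Emits standard ATOM records (atoms grouped by residue), MODEL/ENDMDL
#' blocks for ensembles, and one CONECT record linking the C-terminal
#' carbonyl C to the N-terminal N when the topology is cyclic. Output is
#' deterministic for identical input.
#'
#' @param x A `conformation` or `conformer_ensemble`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "conformation")) {
    confs <- list(x)
  } else if (inherits(x, "conformer_ensemble")) {
    confs <- x$conformations
  } else {
    stop("cannot write object of class ", paste(class(x), collapse = "/"))
  }
  top <- confs[[1]]$topology
  ord <- order(top$atoms$res, seq_len(top$natoms))
  serial_of <- integer(top$natoms)
  serial_of[ord] <- seq_len(top$natoms)
  lines <- character(0)
  multi <- length(confs) > 1
  for (m in seq_along(confs)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    xyz <- confs[[m]]$xyz
    lines <- c(lines, vapply(ord, function(i) {
      pdb_atom_line(serial_of[i], top$atoms$atom[i], top$atoms$res_name[i],
                    top$atoms$res[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
                    top$atoms$element[i])
    }, character(1)))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  if (!is.null(top$ring_closure_bond)) {
    cb <- top$ring_closure_bond
    lines <- c(lines, sprintf("CONECT%5d%5d", serial_of[cb[1]],
                              serial_of[cb[2]]))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) stop(path, " lacks column(s): ",
                             paste(miss, collapse = ", "))
  df
}

#' Read / write NOESY peak tables
#'
#' Tab-delimited with header `res_i, atom_i, res_j, atom_j, volume`.
#' @param path File path.
#' @return `read_noe_peaks`: the peaks data frame.
#' @export
read_noe_peaks <- function(path) {
  read_tsv_file(path, c("res_i", "atom_i", "res_j", "atom_j", "volume"))
}

#' @rdname read_noe_peaks
#' @param peaks Peaks data frame.
#' @export
write_noe_peaks <- function(peaks, path) write_tsv_file(peaks, path)

#' Read / write distance-restraint tables
#'
#' Tab-delimited with header `res_i, atom_i, res_j, atom_j, distance_A,
#' lower_A, upper_A, source_peak`.
#' @param path File path.
#' @return `read_restraints_tsv`: the restraint data frame.
#' @export
read_restraints_tsv <- function(path) {
  read_tsv_file(path, c("res_i", "atom_i", "res_j", "atom_j", "distance_A",
                        "lower_A", "upper_A"))
}

#' @rdname read_restraints_tsv
#' @param restraints Restraint data frame.
#' @export
write_restraints_tsv <- function(restraints, path) {
  write_tsv_file(restraints, path)
}

#' Read / write plate-reading tables
#'
#' Tab-delimited with header `compound, conc_uM, a620, role`.
#' @param path File path.
#' @return `read_plate_tsv`: the readings data frame.
#' @export
read_plate_tsv <- function(path) {
  read_tsv_file(path, c("compound", "conc_uM", "a620", "role"))
}

#' @rdname read_plate_tsv
#' @param readings Readings data frame.
#' @export
write_plate_tsv <- function(readings, path) write_tsv_file(readings, path)

#' Write ensemble summary tables
#'
#' `write_ensemble_tsv` writes `conformer_id, energy_kJ_mol,
#' boltzmann_ratio` (ratio of each conformer's Boltzmann factor to the
#' highest-energy member's, at `temperature`); `write_annealing_tsv` writes
#' `model_id, energy_kJ_mol, max_violation_A, fraction_satisfied` for an
#' annealed ensemble carrying violation reports.
#'
#' @param ens A `conformer_ensemble`.
#' @param path Output file.
#' @param temperature Temperature (K) of the Boltzmann ratios.
#' @return Invisibly, `path`.
#' @export
write_ensemble_tsv <- function(ens, path, temperature = 500) {
  bw <- boltzmann_weights(ens, temperature)
  write_tsv_file(data.frame(conformer_id = bw$conformer,
                            energy_kJ_mol = bw$energy,
                            boltzmann_ratio = bw$ratio_vs_highest), path)
}

#' @rdname write_ensemble_tsv
#' @export
write_annealing_tsv <- function(ens, path) {
  stopifnot(!is.null(ens$violations))
  write_tsv_file(data.frame(
    model_id = seq_along(ens$energies),
    energy_kJ_mol = ens$energies,
    max_violation_A = vapply(ens$violations, `[[`, numeric(1),
                             "max_violation"),
    fraction_satisfied = vapply(ens$violations, `[[`, numeric(1),
                                "fraction_satisfied")), path)
}
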