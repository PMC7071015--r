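# Pipeline configuration: a YAML file with one section per stage. Unknown
# sections or keys are rejected so silent typos cannot change a run; the
# fully resolved configuration (defaults merged with the file) is returned
# and is what a caller should log alongside results.

PIPELINE_SCHEMA <- list(
  design = c("epitope", "linker", "cyclic"),
  forcefield = c("k_bond", "k_angle", "k_torsion3", "k_omega", "k_chirality",
                 "k_rep", "radius_heavy", "radius_h", "k_noe", "rg_k", "rg0"),
  search = c("steps", "max_displacement", "temperature", "tol", "seed"),
  calibration = c("bound_margin", "lower_clamp", "pseudo_correction"),
  annealing = c("t_start", "t_end", "steps", "cooling", "k_noe_start",
                "k_noe_end", "n_structures", "base_seed"),
  clustering = c("cutoff"),
  assay = c("noise_sd", "replicates"),
  synthetic = c("c_scale", "cutoff", "sigma", "subsample", "seed")
)

#' Read and validate a pipeline configuration file
#'
#' @param path YAML file with sections `design`, `forcefield`, `search`,
#'   `calibration`, `annealing`, `clustering`, `assay`, `synthetic` (all
#'   optional); unknown sections or keys are an error.
#' @return Named list of sections with the supplied values; empty sections
#'   are absent.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(list())
  bad_sec <- setdiff(names(cfg), names(PIPELINE_SCHEMA))
  if (length(bad_sec) > 0) {
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), PIPELINE_SCHEMA[[sec]])
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in [%s]: %s", sec,
                   paste(bad, collapse = ", ")))
    }
  }
  cfg
}
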