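#' Pipeline configuration
#'
#' Collects the thresholds that govern identification filtering,
#' quantification filtering and bench QC, together with the reference set
#' used for across-set normalization and the random seed used by any
#' randomized step. Defaults are the values used throughout multiplexed
#' TMT practice: 1% peptide and protein FDR, a summed-reporter ("TMT
#' total") floor of 200, an isolation-specificity floor of 0.7, a 15%
#' missed-cleavage ceiling and a 95% labeling-efficiency floor.
#'
#' @param psm_fdr Peptide-level FDR threshold, in (0, 1).
#' @param protein_fdr Protein-level FDR threshold, in (0, 1).
#' @param tmt_total_min Minimum summed TMT reporter intensity; peptides must
#'   exceed this value (strict inequality) to be quantified.
#' @param isolation_specificity_min Minimum isolation specificity (fraction
#'   of precursor-window signal from the selected peptide); strict
#'   inequality, in [0, 1).
#' @param missed_cleavage_max Maximum tolerated fraction of potential
#'   cleavage sites left uncleaved, in [0, 1].
#' @param labeling_efficiency_min Minimum fraction of labelable sites that
#'   must carry a TMT label, in [0, 1].
#' @param ratio_check_tolerance Maximum tolerated relative deviation of any
#'   channel total from the median channel total.
#' @param reference_set Integer id of the set whose bridge anchors
#'   across-set normalization.
#' @param scale_include_bridge Logical; whether bridge samples enter the
#'   denominator of the 0-100 scaling step.
#' @param bridge_policy How to resolve multiple bridge channels in one set:
#'   `"first"` uses the first-flagged bridge, `"average"` averages them.
#' @param random_seed Integer seed recorded in provenance and used by
#'   randomized operations.
#'
#' @return A `plex_config` object (a named list).
#' @export
#' @examples
#' cfg <- plex_config()
#' cfg$tmt_total_min
plex_config <- function(psm_fdr = 0.01,
                        protein_fdr = 0.01,
                        tmt_total_min = 200,
                        isolation_specificity_min = 0.7,
                        missed_cleavage_max = 0.15,
                        labeling_efficiency_min = 0.95,
                        ratio_check_tolerance = 0.10,
                        reference_set = 4L,
                        scale_include_bridge = TRUE,
                        bridge_policy = c("first", "average"),
                        random_seed = 1L) {
  bridge_policy <- match.arg(bridge_policy)
  cfg <- list(
    psm_fdr = as.numeric(psm_fdr),
    protein_fdr = as.numeric(protein_fdr),
    tmt_total_min = as.numeric(tmt_total_min),
    isolation_specificity_min = as.numeric(isolation_specificity_min),
    missed_cleavage_max = as.numeric(missed_cleavage_max),
    labeling_efficiency_min = as.numeric(labeling_efficiency_min),
    ratio_check_tolerance = as.numeric(ratio_check_tolerance),
    reference_set = as.integer(reference_set),
    scale_include_bridge = isTRUE(scale_include_bridge),
    bridge_policy = bridge_policy,
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "plex_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  in_unit <- function(x) is.finite(x) && x > 0 && x < 1
  if (!in_unit(cfg$psm_fdr)) {
    abort("`psm_fdr` must lie strictly between 0 and 1.", class = "plex_validation_error")
  }
  if (!in_unit(cfg$protein_fdr)) {
    abort("`protein_fdr` must lie strictly between 0 and 1.", class = "plex_validation_error")
  }
  if (!is.finite(cfg$tmt_total_min) || cfg$tmt_total_min < 0) {
    abort("`tmt_total_min` must be a non-negative number.", class = "plex_validation_error")
  }
  if (!is.finite(cfg$isolation_specificity_min) ||
      cfg$isolation_specificity_min < 0 || cfg$isolation_specificity_min >= 1) {
    abort("`isolation_specificity_min` must lie in [0, 1).", class = "plex_validation_error")
  }
  if (!is.finite(cfg$missed_cleavage_max) ||
      cfg$missed_cleavage_max < 0 || cfg$missed_cleavage_max > 1) {
    abort("`missed_cleavage_max` must lie in [0, 1].", class = "plex_validation_error")
  }
  if (!is.finite(cfg$labeling_efficiency_min) ||
      cfg$labeling_efficiency_min < 0 || cfg$labeling_efficiency_min > 1) {
    abort("`labeling_efficiency_min` must lie in [0, 1].", class = "plex_validation_error")
  }
  if (!is.finite(cfg$ratio_check_tolerance) || cfg$ratio_check_tolerance < 0) {
    abort("`ratio_check_tolerance` must be non-negative.", class = "plex_validation_error")
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file fall back to the [plex_config()] defaults;
#' unknown keys raise an error so that typos do not silently revert a
#' threshold to its default.
#'
#' @param path Path to a YAML (key: value) configuration file.
#' @return A `plex_config` object.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "plex_io_error")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(plex_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")),
          class = "plex_format_error")
  }
  do.call(plex_config, vals)
}

#' Write a pipeline configuration to a YAML file
#'
#' @param config A `plex_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "plex_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.plex_config <- function(x, ...) {
  cat("<plex_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Short stable hash of a config, recorded in provenance logs.
config_hash <- function(config) {
  txt <- paste(names(config), vapply(config, format, character(1)),
               sep = "=", collapse = ";")
  # polynomial rolling hash over the serialized key=value string
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
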