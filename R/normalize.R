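#' Within-set bridge normalization
#'
#' Equalizes sample loading inside each TMT set: every peptide intensity
#' of sample j in set k is multiplied by the ratio of the bridge
#' channel's summed intensity to sample j's summed intensity, the sums
#' running over all peptides present in that set. Afterwards every
#' sample total in a set equals the set's bridge total; the bridge
#' channel itself is a fixed point. Exactly removes multiplicative
#' per-sample loading factors.
#'
#' @param peptides Raw-stage peptide tibble.
#' @param design Validated study design.
#' @param bridge_policy `"first"` uses the first-flagged bridge channel of
#'   each set; `"average"` uses the mean total of all bridge channels.
#' @return Peptide tibble at stage `"within_set"`.
#' @export
within_set_normalize <- function(peptides, design,
                                 bridge_policy = c("first", "average")) {
  bridge_policy <- match.arg(bridge_policy)
  totals <- sample_totals(peptides)
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero) > 0) {
    abort(paste0("Zero total intensity for sample(s): ",
                 paste(head(zero, 5), collapse = ", ")),
          class = "plex_validation_error")
  }
  btot <- bridge_totals(totals, design, bridge_policy)
  fac <- dplyr::left_join(totals, btot, by = "set_id")
  fac$factor <- fac$bridge_total / fac$total
  out <- dplyr::left_join(
    peptides, dplyr::select(fac, "set_id", "sample_id", "factor"),
    by = c("set_id", "sample_id"))
  out$intensity <- out$intensity * out$factor
  out$factor <- NULL
  out$stage <- "within_set"
  out
}

#' Across-set bridge normalization
#'
#' Puts all sets on the intensity scale of a designated reference set:
#' every within-set-normalized intensity in set k is multiplied by the
#' ratio of the reference set's bridge total to set k's bridge total,
#' both totals computed from the raw intensities. Afterwards every set's
#' bridge total equals the reference set's raw bridge total; the
#' reference set is a fixed point. Exactly removes multiplicative
#' per-set (batch) intensity factors.
#'
#' @param peptides Peptide tibble at stage `"within_set"`.
#' @param raw The raw-stage peptide tibble the within-set table was
#'   derived from (bridge totals are taken from it).
#' @param design Validated study design.
#' @param reference_set Reference set id; defaults to the design's
#'   `reference_set` attribute.
#' @param bridge_policy As in [within_set_normalize()].
#' @return Peptide tibble at stage `"across_set"`.
#' @export
across_set_normalize <- function(peptides, raw, design, reference_set = NULL,
                                 bridge_policy = c("first", "average")) {
  bridge_policy <- match.arg(bridge_policy)
  reference_set <- reference_set %||% reference_set_of(design)
  btot <- bridge_totals(sample_totals(raw), design, bridge_policy)
  if (any(btot$bridge_total == 0)) {
    abort("A set has zero bridge total intensity.", class = "plex_validation_error")
  }
  if (!reference_set %in% btot$set_id) {
    abort(paste0("Reference set ", reference_set, " has no bridge total."),
          class = "plex_design_error")
  }
  ref_total <- btot$bridge_total[btot$set_id == reference_set]
  out <- dplyr::left_join(peptides, btot, by = "set_id")
  out$intensity <- out$intensity * ref_total / out$bridge_total
  out$bridge_total <- NULL
  out$stage <- "across_set"
  out
}

sample_totals <- function(peptides) {
  dplyr::summarise(dplyr::group_by(peptides, .data$set_id, .data$sample_id),
                   total = sum(.data$intensity), .groups = "drop")
}

bridge_totals <- function(totals, design, bridge_policy) {
  br <- bridge_samples(design,
                       policy = if (bridge_policy == "first") "first" else "all")
  bt <- dplyr::inner_join(totals, br, by = c("set_id", "sample_id"))
  missing_sets <- setdiff(unique(totals$set_id), bt$set_id)
  if (length(missing_sets) > 0) {
    abort(paste0("No bridge intensities in set(s): ",
                 paste(missing_sets, collapse = ", ")),
          class = "plex_design_error")
  }
  dplyr::summarise(dplyr::group_by(bt, .data$set_id),
                   bridge_total = mean(.data$total), .groups = "drop")
}

#' Roll peptide intensities up to protein quantities
#'
#' The quantity of protein l in sample j of set k is the mean of the
#' across-set-normalized intensities of the peptides assigned to l that
#' were reported in set k (the sum over those peptides divided by their
#' number `n_peptides`). Because TMT reporting is complete within a set,
#' `n_peptides` depends on the protein and the set but not on the sample.
#'
#' @param peptides Peptide tibble (normally stage `"across_set"`).
#' @param peptide_map Optional peptide-to-protein assignment: a tibble
#'   with `peptide_id`, `protein_id` (e.g. from [assign_parsimony()]) or
#'   a named character vector. Defaults to the table's own `protein_id`
#'   column.
#' @return Long protein tibble at stage `"rolled"` with columns
#'   `protein_id`, `set_id`, `sample_id`, `quantity`, `n_peptides`.
#' @export
rollup_proteins <- function(peptides, peptide_map = NULL) {
  tab <- peptides
  if (!is.null(peptide_map)) {
    if (is.character(peptide_map)) {
      peptide_map <- tibble::tibble(peptide_id = names(peptide_map),
                                    protein_id = unname(peptide_map))
    }
    unmapped <- setdiff(unique(tab$peptide_id), peptide_map$peptide_id)
    if (length(unmapped) > 0) {
      abort(paste0("Peptide(s) without a protein assignment: ",
                   paste(head(unmapped, 5), collapse = ", ")),
            class = "plex_reference_error")
    }
    tab$protein_id <- NULL
    tab <- dplyr::left_join(tab,
                            dplyr::select(peptide_map, "peptide_id", "protein_id"),
                            by = "peptide_id")
  } else if (!"protein_id" %in% names(tab)) {
    abort("Supply `peptide_map` or a `protein_id` column.",
          class = "plex_reference_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$protein_id, .data$set_id, .data$sample_id),
    quantity = mean(.data$intensity),
    n_peptides = dplyr::n(), .groups = "drop")
  out$stage <- "rolled"
  out
}

#' Scale quantities to a 0-100 range within each set
#'
#' Each feature (peptide or protein) is expressed as its percentage of
#' that feature's total over the samples of its set: value times 100
#' divided by the per-feature per-set sum. Scaled values of one feature
#' in one set sum to 100. Features with a zero set total are passed
#' through as all-zero with a warning.
#'
#' @param x A peptide tibble (`intensity` column) or long protein tibble
#'   (`quantity` column).
#' @param design Optional validated design; required only when
#'   `include_bridge = FALSE` so bridge channels can be dropped before
#'   scaling.
#' @param include_bridge Whether bridge channels enter the denominator
#'   (and the output). Default `TRUE`: the sum runs over all samples of
#'   the set.
#' @return The table with its value column rescaled and stage `"scaled"`.
#' @export
scale_0_100 <- function(x, design = NULL, include_bridge = TRUE) {
  value_col <- if ("intensity" %in% names(x)) "intensity" else "quantity"
  feature_col <- if (value_col == "intensity") "peptide_id" else "protein_id"
  tab <- x
  if (!include_bridge) {
    if (is.null(design)) {
      abort("`design` is required to exclude bridge channels.",
            class = "plex_design_error")
    }
    bridge_ids <- design$sample_id[design$is_bridge]
    tab <- dplyr::filter(tab, !.data$sample_id %in% bridge_ids)
  }
  grp <- dplyr::group_by(tab, .data[[feature_col]], .data$set_id)
  out <- dplyr::mutate(grp, .set_sum = sum(.data[[value_col]]))
  out <- dplyr::ungroup(out)
  zero <- out$.set_sum == 0
  if (any(zero)) {
    warn(sprintf("%d feature-set group(s) have zero total; passed through as zero.",
                 length(unique(out[[feature_col]][zero]))))
  }
  out[[value_col]] <- ifelse(zero, 0, 100 * out[[value_col]] / out$.set_sum)
  out$.set_sum <- NULL
  out$stage <- "scaled"
  out
}

#' Run the full normalization pipeline
#'
#' Composes the stages that turn a raw long-format peptide table into
#' normalized peptide-level and protein-level matrices: optional
#' restriction to quantification-filtered peptides, within-set bridge
#' normalization, across-set bridge normalization, 0-100 scaling of the
#' peptide table, protein rollup and 0-100 scaling of the protein table.
#'
#' @param peptides Raw-stage peptide tibble.
#' @param design Validated study design.
#' @param config A [plex_config()]; supplies the reference set, bridge
#'   policy and whether bridges enter the scaling denominator.
#' @param peptide_map Optional peptide-to-protein assignment (see
#'   [rollup_proteins()]).
#' @param keep_peptides Optional character vector of peptide ids that
#'   passed identification/quantification filtering; other peptides are
#'   dropped before normalization.
#' @return A list: `peptides_within`, `peptides_across`,
#'   `level2_peptides` (scaled peptides), `proteins` (rolled),
#'   `level3_proteins` (scaled proteins), and `counts`, a provenance
#'   tibble of row/feature counts per stage tagged with the config hash.
#' @export
run_pipeline <- function(peptides, design, config = plex_config(),
                         peptide_map = NULL, keep_peptides = NULL) {
  raw <- peptides
  if (!is.null(keep_peptides)) {
    raw <- dplyr::filter(raw, .data$peptide_id %in% keep_peptides)
  }
  w <- within_set_normalize(raw, design, bridge_policy = config$bridge_policy)
  a <- across_set_normalize(w, raw, design,
                            reference_set = config$reference_set,
                            bridge_policy = config$bridge_policy)
  lvl2 <- scale_0_100(a, design, include_bridge = config$scale_include_bridge)
  rolled <- rollup_proteins(a, peptide_map)
  lvl3 <- scale_0_100(rolled, design, include_bridge = config$scale_include_bridge)
  counts <- tibble::tibble(
    stage = c("raw", "within_set", "across_set", "level2_peptides",
              "rolled_proteins", "level3_proteins"),
    n_rows = c(nrow(raw), nrow(w), nrow(a), nrow(lvl2), nrow(rolled), nrow(lvl3)),
    n_features = c(dplyr::n_distinct(raw$peptide_id),
                   dplyr::n_distinct(w$peptide_id),
                   dplyr::n_distinct(a$peptide_id),
                   dplyr::n_distinct(lvl2$peptide_id),
                   dplyr::n_distinct(rolled$protein_id),
                   dplyr::n_distinct(lvl3$protein_id)),
    config_hash = config_hash(config)
  )
  list(peptides_within = w, peptides_across = a, level2_peptides = lvl2,
       proteins = rolled, level3_proteins = lvl3, counts = counts)
}
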