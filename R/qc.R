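#' Missed-cleavage rate of identified peptides
#'
#' Gauges digestion quality from the identified peptide sequences. For
#' each peptide, a missed cleavage is an internal lysine (K) or arginine
#' (R) not immediately followed by proline (trypsin/Lys-C does not cut
#' K-P/R-P bonds); a realized cleavage is counted when the C-terminal
#' residue is K or R. The rate is the summed missed sites divided by the
#' summed potential sites (missed + realized) over all peptides — the
#' fraction of potential cleavage sites left uncleaved.
#'
#' @param peptide_sequences Character vector of peptide sequences.
#' @param threshold Pass ceiling on the rate (default 0.15).
#' @return One-row tibble: `n_missed`, `n_realized`, `n_sites`,
#'   `missed_cleavage_rate`, `pass`.
#' @export
missed_cleavage_rate <- function(peptide_sequences, threshold = 0.15) {
  if (length(peptide_sequences) == 0) {
    abort("No peptide sequences supplied.", class = "plex_validation_error")
  }
  n_missed <- stringr::str_count(peptide_sequences, "[KR](?!P)(?!$)")
  last <- stringr::str_sub(peptide_sequences, -1)
  n_realized <- as.integer(last %in% c("K", "R"))
  denom <- sum(n_missed) + sum(n_realized)
  if (denom == 0) {
    abort("No potential cleavage sites observed; rate undefined.",
          class = "plex_validation_error")
  }
  rate <- sum(n_missed) / denom
  tibble::tibble(n_missed = sum(n_missed), n_realized = sum(n_realized),
                 n_sites = denom, missed_cleavage_rate = rate,
                 pass = rate < threshold)
}

#' TMT labeling efficiency
#'
#' Fraction of labelable sites (peptide N-termini and lysine side chains)
#' that carry a TMT label, summed over all PSMs.
#'
#' @param psms PSM tibble with `n_labelable_sites` and `n_labeled_sites`.
#' @param threshold Pass floor on the efficiency (default 0.95).
#' @return One-row tibble: `n_labeled`, `n_labelable`,
#'   `labeling_efficiency`, `pass`.
#' @export
labeling_efficiency <- function(psms, threshold = 0.95) {
  denom <- sum(psms$n_labelable_sites)
  if (is.na(denom) || denom == 0) {
    abort("No labelable sites; efficiency undefined.",
          class = "plex_validation_error")
  }
  eff <- sum(psms$n_labeled_sites) / denom
  tibble::tibble(n_labeled = sum(psms$n_labeled_sites), n_labelable = denom,
                 labeling_efficiency = eff, pass = eff > threshold)
}

#' Ratio check of pooled channel totals
#'
#' Before pooling, equal peptide amounts of every channel should be
#' combined; the ratio check compares the total peptide intensity of each
#' channel of a set for equivalence. The reference is the median channel
#' total; each channel's correction factor is `median / total`, so
#' multiplying a channel by its factor equalizes it to the median. A set
#' passes when no channel deviates from the median by more than
#' `tolerance` (relative).
#'
#' @param peptides Raw-stage peptide tibble.
#' @param set_id Optional set id(s) to check; all sets by default.
#' @param tolerance Maximum tolerated relative deviation (default 0.10).
#' @return Tibble with one row per channel: `set_id`, `sample_id`,
#'   `channel_total`, `correction_factor`, `deviation`, `pass` (set-level
#'   flag).
#' @export
ratio_check <- function(peptides, set_id = NULL, tolerance = 0.10) {
  tab <- peptides
  if (!is.null(set_id)) tab <- dplyr::filter(tab, .data$set_id %in% !!set_id)
  totals <- dplyr::summarise(
    dplyr::group_by(tab, .data$set_id, .data$sample_id),
    channel_total = sum(.data$intensity), .groups = "drop_last")
  sizes <- dplyr::summarise(totals, n = dplyr::n(), .groups = "drop")
  if (any(sizes$n < 2)) {
    abort("Ratio check needs at least two channels per set.",
          class = "plex_validation_error")
  }
  if (any(totals$channel_total == 0)) {
    abort("A channel has zero total intensity; ratio check undefined.",
          class = "plex_validation_error")
  }
  out <- dplyr::mutate(
    totals,
    correction_factor = median(.data$channel_total) / .data$channel_total,
    deviation = abs(.data$channel_total / median(.data$channel_total) - 1)
  )
  out <- dplyr::mutate(out, pass = max(.data$deviation) <= tolerance)
  dplyr::ungroup(out)
}

#' Per-set QC report
#'
#' Convenience wrapper computing the ratio check per set and, when a PSM
#' table is supplied, the missed-cleavage rate and labeling efficiency,
#' with pass flags against the configured thresholds.
#'
#' @param peptides Raw-stage peptide tibble.
#' @param psms Optional PSM tibble.
#' @param config A [plex_config()].
#' @return A list with elements `ratio_check` (per-channel tibble) and,
#'   if `psms` given, `missed_cleavage` and `labeling`.
#' @export
qc_report <- function(peptides, psms = NULL, config = plex_config()) {
  out <- list(ratio_check = ratio_check(peptides,
                                        tolerance = config$ratio_check_tolerance))
  if (!is.null(psms)) {
    out$missed_cleavage <- missed_cleavage_rate(
      psms$peptide_sequence, threshold = config$missed_cleavage_max)
    out$labeling <- labeling_efficiency(
      psms, threshold = config$labeling_efficiency_min)
  }
  out
}
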