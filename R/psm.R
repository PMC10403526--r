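#' Fit the linear discriminant that rescores peptide-spectrum matches
#'
#' Combines the three search-engine identification scores — cross
#' correlation (`xcorr`), the score gap to the runner-up match
#' (`delta_cn`) and the absolute precursor mass error in ppm — into a
#' single discriminant score separating target from decoy PSMs. The fit
#' is classical two-class linear discriminant analysis with a pooled
#' within-class covariance: the weight vector is
#' `S_pooled^-1 (mean_target - mean_decoy)`, oriented so that higher
#' scores are more target-like. Mass error enters as its absolute value,
#' since error of either sign indicates a mismatch.
#'
#' @param psms PSM tibble with columns `xcorr`, `delta_cn`,
#'   `mass_error_ppm` and `label` (`"target"`/`"decoy"`).
#' @param regularize Ridge added to the pooled covariance if it is
#'   numerically singular (applied automatically with a warning).
#' @return A `plex_lda` model with elements `weights`, `offset`,
#'   `class_means`, `pooled_cov` and per-class counts. Supports
#'   [discriminant_score()], `tidy()` and `glance()`.
#' @export
fit_discriminant <- function(psms, regularize = 1e-8) {
  if (!all(c("target", "decoy") %in% psms$label)) {
    abort("Both target and decoy PSMs are required to fit the discriminant.",
          class = "plex_validation_error")
  }
  x <- discriminant_features(psms)
  grp <- psms$label
  n_t <- sum(grp == "target"); n_d <- sum(grp == "decoy")
  if (n_t < 2 || n_d < 2) {
    abort("At least two PSMs per class are required.", class = "plex_validation_error")
  }
  m_t <- colMeans(x[grp == "target", , drop = FALSE])
  m_d <- colMeans(x[grp == "decoy", , drop = FALSE])
  s_t <- stats::cov(x[grp == "target", , drop = FALSE])
  s_d <- stats::cov(x[grp == "decoy", , drop = FALSE])
  pooled <- ((n_t - 1) * s_t + (n_d - 1) * s_d) / (n_t + n_d - 2)
  w <- tryCatch(solve(pooled, m_t - m_d), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    warn("Pooled covariance is singular; applying a small ridge.")
    lambda <- regularize * mean(diag(pooled))
    if (!is.finite(lambda) || lambda <= 0) lambda <- regularize
    w <- solve(pooled + diag(lambda, ncol(pooled)), m_t - m_d)
  }
  offset <- -sum(w * (m_t + m_d) / 2)
  model <- structure(list(
    weights = w, offset = offset,
    class_means = rbind(target = m_t, decoy = m_d),
    pooled_cov = pooled, n_target = n_t, n_decoy = n_d
  ), class = "plex_lda")
  # orientation guard (holds by construction for the closed form)
  if (mean(discriminant_score(model, psms)[grp == "target"]) <
      mean(discriminant_score(model, psms)[grp == "decoy"])) {
    model$weights <- -model$weights
    model$offset <- -model$offset
  }
  model
}

discriminant_features <- function(psms) {
  cbind(xcorr = psms$xcorr, delta_cn = psms$delta_cn,
        abs_mass_error_ppm = abs(psms$mass_error_ppm))
}

#' @rdname fit_discriminant
#' @param model A `plex_lda` model.
#' @return `discriminant_score()`: numeric vector of scores, one per PSM.
#' @export
discriminant_score <- function(model, psms) {
  stopifnot(inherits(model, "plex_lda"))
  drop(discriminant_features(psms) %*% model$weights) + model$offset
}

#' @export
print.plex_lda <- function(x, ...) {
  cat("<plex_lda> two-class linear discriminant\n")
  cat("  targets:", x$n_target, " decoys:", x$n_decoy, "\n")
  cat("  weights:", paste(sprintf("%s=%.4g", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.plex_lda <- function(x, ...) {
  tibble::tibble(term = names(x$weights), weight = unname(x$weights))
}

#' @export
glance.plex_lda <- function(x, ...) {
  tibble::tibble(n_target = x$n_target, n_decoy = x$n_decoy,
                 offset = x$offset,
                 separation = sqrt(sum(x$weights *
                                         (x$class_means["target", ] -
                                            x$class_means["decoy", ]))))
}

#' Target-decoy FDR curve
#'
#' At every candidate threshold (each distinct score, scanned from the
#' most stringent down), the estimated false-discovery rate is twice the
#' number of decoy identifications at or above the threshold divided by
#' the total number of identifications (targets plus decoys) at or above
#' it — the concatenated-database convention in which decoy hits estimate
#' an equal number of incorrect target hits. A monotone q-value (the
#' running minimum of the FDR over all more permissive thresholds) is also
#' reported so the retained set at any level is well defined.
#'
#' @param scores Numeric discriminant scores.
#' @param labels Character vector, `"target"`/`"decoy"`.
#' @return A tibble with one row per distinct threshold, columns
#'   `threshold`, `n_total`, `n_decoy`, `fdr` (clipped to `[0, 1]`) and
#'   `q_value`, ordered from the most stringent threshold down.
#' @export
fdr_curve <- function(scores, labels) {
  if (length(scores) == 0) {
    abort("Cannot compute an FDR curve from zero identifications.",
          class = "plex_validation_error")
  }
  stopifnot(length(scores) == length(labels))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  is_decoy <- labels[ord] == "decoy"
  cum_total <- seq_along(s)
  cum_decoy <- cumsum(is_decoy)
  # last index of each distinct score = counts at threshold "score >= s"
  keep <- !duplicated(s, fromLast = TRUE)
  fdr <- pmin(2 * cum_decoy[keep] / cum_total[keep], 1)
  q <- rev(cummin(rev(fdr)))
  tibble::tibble(threshold = s[keep], n_total = cum_total[keep],
                 n_decoy = cum_decoy[keep], fdr = fdr, q_value = q)
}

# most permissive threshold whose q-value is strictly below alpha;
# NA if no threshold achieves it
fdr_threshold <- function(curve, alpha) {
  ok <- which(curve$q_value < alpha)
  if (length(ok) == 0) return(NA_real_)
  curve$threshold[max(ok)]
}

#' Filter PSMs to a peptide-level FDR
#'
#' Scores every PSM with the discriminant model (fitting one if none is
#' given), estimates the target-decoy FDR curve over all PSMs, retains
#' target PSMs scoring at or above the most permissive threshold whose
#' q-value is below `alpha`, removes decoys from the output, and keeps the
#' best-scoring PSM per peptide.
#'
#' @param psms PSM tibble.
#' @param model Optional `plex_lda`; fitted on `psms` when `NULL`.
#' @param alpha FDR level in (0, 1); default 0.01.
#' @return Retained identifications: one row per peptide (the best PSM),
#'   with a `score` column appended. Empty (with a warning) if no
#'   threshold achieves `alpha`.
#' @export
filter_peptides <- function(psms, model = NULL, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  model <- model %||% fit_discriminant(psms)
  scored <- dplyr::mutate(psms, score = discriminant_score(model, psms))
  curve <- fdr_curve(scored$score, scored$label)
  thr <- fdr_threshold(curve, alpha)
  if (is.na(thr)) {
    warn(sprintf("No score threshold achieves FDR < %g; returning no identifications.",
                 alpha))
    return(scored[0, ])
  }
  kept <- dplyr::filter(scored, .data$label == "target", .data$score >= thr)
  kept <- dplyr::arrange(kept, dplyr::desc(.data$score))
  dplyr::ungroup(dplyr::slice_head(dplyr::group_by(kept, .data$peptide_id), n = 1))
}

#' Assign each peptide to a single protein by parsimony
#'
#' Shared peptides are collapsed by assigning every peptide to the
#' largest (longest-sequence) of its candidate proteins; ties are broken
#' deterministically by the lexicographically smallest accession.
#'
#' @param identifications Tibble with `peptide_id` and a
#'   `candidate_proteins` list-column (one row per peptide, e.g. from
#'   [filter_peptides()]).
#' @param protein_lengths Named numeric vector, accession -> residue
#'   count. Every candidate accession must be present.
#' @return `identifications` with a `protein_id` column; the per-protein
#'   peptide counts are attached as attribute `"protein_counts"` (a
#'   tibble).
#' @export
assign_parsimony <- function(identifications, protein_lengths) {
  all_cand <- unique(unlist(identifications$candidate_proteins))
  missing_len <- setdiff(all_cand, names(protein_lengths))
  if (length(missing_len) > 0) {
    abort(paste0("No length for candidate protein(s): ",
                 paste(head(missing_len, 5), collapse = ", ")),
          class = "plex_reference_error")
  }
  pick <- vapply(identifications$candidate_proteins, function(cand) {
    len <- protein_lengths[cand]
    best <- cand[len == max(len)]
    sort(best)[1]
  }, character(1))
  out <- dplyr::mutate(identifications, protein_id = pick)
  attr(out, "protein_counts") <- dplyr::count(
    tibble::tibble(protein_id = pick), .data$protein_id, name = "n_peptides")
  out
}

#' Filter identifications to a protein-level FDR
#'
#' Each protein is scored by its best peptide discriminant score; a
#' protein is a decoy when its accession carries the reversed-database
#' prefix. The same target-decoy FDR estimate (twice decoys over total)
#' and q-value thresholding used at the peptide level are applied at the
#' protein level; peptides of retained proteins are kept.
#'
#' @param identifications Peptide-level tibble with `protein_id` and
#'   `score` columns (from [assign_parsimony()] on [filter_peptides()]
#'   output).
#' @param alpha Protein FDR level; default 0.01.
#' @param decoy_prefix Accession prefix marking reversed-database
#'   proteins.
#' @return Retained identifications (peptides of retained target
#'   proteins).
#' @export
filter_protein_fdr <- function(identifications, alpha = 0.01,
                               decoy_prefix = "rev_") {
  stopifnot(alpha > 0, alpha < 1)
  prot <- dplyr::summarise(
    dplyr::group_by(identifications, .data$protein_id),
    score = max(.data$score), .groups = "drop")
  prot$label <- ifelse(startsWith(prot$protein_id, decoy_prefix),
                       "decoy", "target")
  curve <- fdr_curve(prot$score, prot$label)
  thr <- fdr_threshold(curve, alpha)
  if (is.na(thr)) {
    warn(sprintf("No protein score threshold achieves FDR < %g.", alpha))
    return(identifications[0, ])
  }
  keep <- prot$protein_id[prot$label == "target" & prot$score >= thr]
  dplyr::filter(identifications, .data$protein_id %in% keep)
}

#' Quantification filters on PSM diagnostics
#'
#' Retains rows whose summed TMT reporter intensity strictly exceeds
#' `tmt_total_min` and whose isolation specificity strictly exceeds
#' `isolation_specificity_min` (both printed as strict `>` rules in
#' standard practice; boundary values are removed). Counts of removals
#' per criterion are attached as attribute `"removed"`.
#'
#' @param psms PSM tibble with `tmt_total` and `isolation_specificity`.
#' @param tmt_total_min Summed-reporter floor (default 200).
#' @param isolation_specificity_min Isolation-specificity floor
#'   (default 0.7).
#' @return The retained rows.
#' @export
apply_quant_filters <- function(psms, tmt_total_min = 200,
                                isolation_specificity_min = 0.7) {
  fail_tmt <- !(psms$tmt_total > tmt_total_min)
  fail_iso <- !(psms$isolation_specificity > isolation_specificity_min)
  out <- psms[!(fail_tmt | fail_iso), , drop = FALSE]
  attr(out, "removed") <- c(tmt_total = sum(fail_tmt),
                            isolation_specificity = sum(fail_iso),
                            either = sum(fail_tmt | fail_iso))
  out
}
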