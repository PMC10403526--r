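#' Per-protein linear models of drug response
#'
#' For every protein quantified in all included cell lines, fits the
#' ordinary least-squares model
#' `response ~ standardized protein abundance + receptor status`
#' (the covariate absorbs subtype-specific response differences) and
#' reports the protein coefficient, its two-sided t-test p-value and the
#' Benjamini-Hochberg adjusted p-value across all tested proteins.
#' Abundances are standardized (zero mean, unit variance across lines)
#' so effect sizes are comparable between proteins; a positive effect
#' associates higher abundance with sensitivity (higher GR AOC), a
#' negative effect with resistance.
#'
#' @param proteins Either a long protein tibble (stage `"scaled"` or
#'   `"rolled"`; requires `design` to map samples to cell lines, bridge
#'   channels are dropped and replicate placements averaged) or a
#'   numeric proteins-by-lines matrix with cell lines as column names.
#' @param response Response tibble (`cell_line`, `gr_aoc`,
#'   `receptor_status`); lines absent from the protein data are dropped.
#' @param design Validated study design (needed for long input).
#' @param use_covariate Include receptor status as a covariate; disabled
#'   automatically (with a warning) if fewer than two status groups
#'   remain.
#' @param log_transform Model `log2(x + 1)` of the quantities (default
#'   `TRUE`; intensity-scale data are strongly right-skewed).
#' @return A `plex_assoc` tibble: `protein_id`, `effect_size`,
#'   `std_error`, `statistic`, `p_value`, `adjusted_p`, `n_samples`,
#'   `untestable`. Proteins whose standardized abundance is constant (or
#'   collinear with the covariate) are flagged untestable, not dropped.
#' @export
fit_univariate <- function(proteins, response, design = NULL,
                           use_covariate = TRUE, log_transform = TRUE) {
  mat <- protein_line_matrix(proteins, design)
  lines <- intersect(colnames(mat), response$cell_line)
  if (length(lines) < 4) {
    abort("Too few cell lines shared between protein data and response.",
          class = "plex_validation_error")
  }
  resp <- response[match(lines, response$cell_line), ]
  mat <- mat[, lines, drop = FALSE]
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (log_transform) mat <- log2(mat + 1)

  status <- factor(resp$receptor_status)
  if (use_covariate && nlevels(status) < 2) {
    warn("Fewer than two receptor-status groups; fitting without the covariate.")
    use_covariate <- FALSE
  }
  n <- length(lines)
  n_par <- 2L + if (use_covariate) nlevels(status) - 1L else 0L
  if (n <= n_par) {
    abort("More model parameters than cell lines.", class = "plex_validation_error")
  }

  y <- resp$gr_aoc
  fits <- purrr::map(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      return(tibble::tibble(effect_size = NA_real_, std_error = NA_real_,
                            statistic = NA_real_, p_value = NA_real_,
                            untestable = TRUE))
    }
    z <- (v - mean(v)) / s
    fit <- if (use_covariate) lm(y ~ z + status) else lm(y ~ z)
    cf <- summary(fit)$coefficients
    if (!"z" %in% rownames(cf) || is.na(coef(fit)["z"])) {
      return(tibble::tibble(effect_size = NA_real_, std_error = NA_real_,
                            statistic = NA_real_, p_value = NA_real_,
                            untestable = TRUE))
    }
    tibble::tibble(effect_size = cf["z", "Estimate"],
                   std_error = cf["z", "Std. Error"],
                   statistic = cf["z", "t value"],
                   p_value = cf["z", "Pr(>|t|)"],
                   untestable = FALSE)
  })
  out <- dplyr::bind_cols(tibble::tibble(protein_id = rownames(mat)),
                          dplyr::bind_rows(fits))
  out$adjusted_p <- p.adjust(out$p_value, method = "BH")
  out$n_samples <- n
  out <- dplyr::arrange(out, .data$p_value)
  class(out) <- c("plex_assoc", class(out))
  out
}

# proteins x cell-lines matrix: bridge channels dropped, replicate
# placements of a line averaged
protein_line_matrix <- function(proteins, design = NULL) {
  if (is.matrix(proteins)) {
    if (is.null(colnames(proteins)) || is.null(rownames(proteins))) {
      abort("Protein matrix must have protein rownames and cell-line colnames.",
            class = "plex_validation_error")
    }
    return(proteins)
  }
  if (is.null(design)) {
    abort("`design` is required to map samples to cell lines.",
          class = "plex_design_error")
  }
  tab <- dplyr::inner_join(
    proteins,
    dplyr::select(dplyr::filter(design, !.data$is_bridge),
                  "sample_id", "cell_line"),
    by = "sample_id")
  # complete-case over sets first: only proteins seen in every set
  mat_input <- dplyr::summarise(
    dplyr::group_by(tab, .data$protein_id, .data$cell_line),
    quantity = mean(.data$quantity), .groups = "drop")
  wide <- tidyr::pivot_wider(mat_input, names_from = "cell_line",
                             values_from = "quantity")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$protein_id
  m
}

#' @export
glance.plex_assoc <- function(x, ...) {
  tibble::tibble(n_proteins = nrow(x),
                 n_untestable = sum(x$untestable),
                 n_samples = x$n_samples[1],
                 n_significant_bh_05 = sum(x$adjusted_p < 0.05, na.rm = TRUE))
}

#' Volcano export table
#'
#' Columns for a volcano plot (`-log10(p)` against effect size), sorted
#' by p-value; the `top_hit` flag marks the `top_k` smallest p-values
#' for annotation.
#'
#' @param results A `plex_assoc` tibble from [fit_univariate()].
#' @param top_k Number of proteins to flag for annotation.
#' @return Tibble: `protein_id`, `effect_size`, `neg_log10_p`,
#'   `adjusted_p`, `top_hit`.
#' @export
volcano_table <- function(results, top_k = 10) {
  if (nrow(results) == 0) {
    abort("Empty association results.", class = "plex_validation_error")
  }
  tab <- dplyr::filter(tibble::as_tibble(results), !.data$untestable)
  tab <- dplyr::arrange(tab, .data$p_value)
  tibble::tibble(protein_id = tab$protein_id,
                 effect_size = tab$effect_size,
                 neg_log10_p = -log10(tab$p_value),
                 adjusted_p = tab$adjusted_p,
                 top_hit = seq_len(nrow(tab)) <= top_k)
}
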