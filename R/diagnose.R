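#' Build a feature-by-sample matrix from a long quantity table
#'
#' Pivots a peptide or protein tibble to a numeric matrix (features as
#' rows, samples as columns). By default only complete-case features are
#' kept: those observed in every set represented in the table, the
#' roster on which cross-set comparisons (PCA, replicate correlations)
#' are computed.
#'
#' @param x Peptide tibble (`intensity`) or long protein tibble
#'   (`quantity`).
#' @param complete Keep only features present in all sets.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
quant_matrix <- function(x, complete = TRUE) {
  value_col <- if ("intensity" %in% names(x)) "intensity" else "quantity"
  feature_col <- if (value_col == "intensity") "peptide_id" else "protein_id"
  tab <- x
  if (complete) {
    n_sets <- dplyr::n_distinct(tab$set_id)
    roster <- dplyr::summarise(dplyr::group_by(tab, .data[[feature_col]]),
                               k = dplyr::n_distinct(.data$set_id),
                               .groups = "drop")
    keep <- roster[[feature_col]][roster$k == n_sets]
    tab <- dplyr::filter(tab, .data[[feature_col]] %in% keep)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(tab, dplyr::all_of(c(feature_col, "sample_id", value_col))),
    names_from = "sample_id", values_from = dplyr::all_of(value_col))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide[[feature_col]]
  m
}

#' Principal component embedding of samples
#'
#' Embeds samples (columns) of a feature-by-sample matrix into principal
#' components: optional `log2(x + pseudocount)` transform, per-feature
#' centering, then singular value decomposition. Component signs are
#' fixed deterministically by making each component's largest-magnitude
#' feature loading positive.
#'
#' @param mat Numeric feature-by-sample matrix (e.g. [quant_matrix()]).
#' @param n_components Number of components to retain.
#' @param log_transform Apply `log2(x + pseudocount)` first.
#' @param pseudocount Added before the log (default 1).
#' @return A `plex_pca` object: `scores` (tibble, one row per sample),
#'   `explained_variance` (fractions for the retained components),
#'   `rotation` (feature loadings), `features` (roster used).
#' @export
pca_embed <- function(mat, n_components = 10, log_transform = TRUE,
                      pseudocount = 1) {
  if (ncol(mat) < 2) {
    abort("PCA needs at least two samples.", class = "plex_validation_error")
  }
  if (n_components > min(dim(mat))) {
    abort("More components requested than min(features, samples).",
          class = "plex_validation_error")
  }
  x <- if (log_transform) log2(mat + pseudocount) else mat
  fit <- prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  rot <- fit$rotation[, seq_len(k), drop = FALSE]
  sco <- fit$x[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  sco <- sweep(sco, 2, flip, `*`)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = colnames(mat)),
                              tibble::as_tibble(sco)),
    explained_variance = ev[seq_len(k)],
    rotation = rot,
    features = rownames(mat)
  ), class = "plex_pca")
}

#' @export
print.plex_pca <- function(x, ...) {
  cat("<plex_pca>", nrow(x$scores), "samples,",
      length(x$explained_variance), "components\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * head(x$explained_variance, 5)),
            collapse = " "), "...\n")
  invisible(x)
}

# mean silhouette width of a labeling over embedded coordinates;
# singleton classes contribute 0 (cluster::silhouette convention)
silhouette_score <- function(coords, labels) {
  labels <- as.character(labels)
  if (dplyr::n_distinct(labels) < 2) {
    abort("Silhouette needs at least two label classes.",
          class = "plex_validation_error")
  }
  if (any(table(labels) == 1)) {
    warn("Label class(es) with a single member contribute silhouette 0.")
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' Batch and subtype separation scores
#'
#' Quantifies how strongly samples cluster by a labeling in PC space:
#' the mean silhouette width over samples, using Euclidean distance on
#' the retained components. Values near 1 indicate tight, well-separated
#' label groups; values near 0 (or below) indicate no separation.
#'
#' @param embedding A `plex_pca` from [pca_embed()].
#' @param batch_labels Batch label per embedded sample (in score order).
#' @param subtype_labels Optional subtype label per sample.
#' @param n_components Components used for the distance (default all
#'   retained, up to 10).
#' @return Tibble with one row per labeling: `labeling`, `silhouette`.
#' @export
separation_scores <- function(embedding, batch_labels, subtype_labels = NULL,
                              n_components = 10) {
  coords <- as.matrix(embedding$scores[, -1])
  coords <- coords[, seq_len(min(n_components, ncol(coords))), drop = FALSE]
  if (length(batch_labels) != nrow(coords)) {
    abort("Labels must cover every embedded sample.", class = "plex_validation_error")
  }
  out <- tibble::tibble(labeling = "batch",
                        silhouette = silhouette_score(coords, batch_labels))
  if (!is.null(subtype_labels)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      labeling = "subtype",
      silhouette = silhouette_score(coords, subtype_labels)))
  }
  out
}

#' Replicate correlations against a contrast line
#'
#' Mean pairwise Pearson correlation among the replicate placements of
#' one cell line, and the mean correlation between each replicate and a
#' contrast line, computed over the complete-case feature roster. High
#' within-replicate and markedly lower replicate-vs-contrast correlation
#' indicates that normalization preserved biological identity across
#' sets and batches.
#'
#' @param mat Feature-by-sample matrix of normalized quantities.
#' @param design Validated study design.
#' @param replicate_line Cell line with replicate placements.
#' @param contrast_line Cell line providing the between-line contrast.
#' @param log_transform Correlate on `log2(x + 1)` (default `TRUE`).
#' @return One-row tibble: `n_replicates`, `within_mean_r`,
#'   `between_mean_r`.
#' @export
replicate_correlation <- function(mat, design, replicate_line,
                                  contrast_line, log_transform = TRUE) {
  reps <- design$sample_id[!design$is_bridge &
                             design$cell_line == replicate_line]
  reps <- intersect(reps, colnames(mat))
  ctr <- design$sample_id[!design$is_bridge &
                            design$cell_line == contrast_line]
  ctr <- intersect(ctr, colnames(mat))
  if (length(reps) < 2) {
    abort("Need at least two replicate placements in the matrix.",
          class = "plex_validation_error")
  }
  if (length(ctr) < 1) {
    abort(paste0("Contrast line ", contrast_line, " is not in the matrix."),
          class = "plex_reference_error")
  }
  x <- mat[, c(reps, ctr), drop = FALSE]
  if (log_transform) x <- log2(x + 1)
  if (any(apply(x, 2, sd) == 0)) {
    abort("A sample vector has zero variance; correlation undefined.",
          class = "plex_validation_error")
  }
  cm <- cor(x)
  within <- cm[reps, reps, drop = FALSE][upper.tri(diag(length(reps)))]
  between <- as.vector(cm[reps, ctr, drop = FALSE])
  tibble::tibble(n_replicates = length(reps),
                 within_mean_r = mean(within),
                 between_mean_r = mean(between))
}

#' Cross-set feature intersection accounting
#'
#' Sizes of every non-empty intersection pattern of the per-set feature
#' rosters (the accounting behind an UpSet plot): for each feature, the
#' exact combination of sets it appears in; patterns are counted over
#' features. Per-set totals and the all-sets intersection are attached
#' as attributes.
#'
#' @param rosters Named list of character vectors (one roster per set),
#'   or a long tibble with a feature column and `set_id`.
#' @return Tibble with columns `pattern` (e.g. `"1&3&4"`), `degree`,
#'   `n_features`, sorted by size; attributes `set_totals` and
#'   `all_sets_intersection`.
#' @export
feature_intersections <- function(rosters) {
  if (is.data.frame(rosters)) {
    feature_col <- intersect(c("peptide_id", "protein_id", "feature_id"),
                             names(rosters))[1]
    rosters <- split(rosters[[feature_col]], rosters$set_id)
    rosters <- lapply(rosters, unique)
  }
  if (length(rosters) == 0) {
    abort("At least one roster is required.", class = "plex_validation_error")
  }
  set_names <- names(rosters) %||% as.character(seq_along(rosters))
  features <- unique(unlist(rosters))
  member <- vapply(rosters, function(r) features %in% r,
                   logical(length(features)))
  if (length(features) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row) paste(set_names[row], collapse = "&"))
  counts <- dplyr::count(tibble::tibble(pattern = pattern,
                                        degree = rowSums(member)),
                         .data$pattern, .data$degree, name = "n_features")
  counts <- dplyr::arrange(counts, dplyr::desc(.data$n_features))
  attr(counts, "set_totals") <- vapply(rosters, length, integer(1))
  attr(counts, "all_sets_intersection") <- sum(rowSums(member) == length(rosters))
  counts
}
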