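#' Validate a study-design table
#'
#' The design table describes every TMT channel of every MS set: which cell
#' line was labelled in it, which acquisition batch the set belongs to,
#' whether the channel carries the bridge (common reference) sample, and
#' the biological annotation used downstream (transcriptional subtype,
#' clinical receptor status, replicate grouping).
#'
#' Required columns: `sample_id`, `cell_line`, `set_id`, `batch_id`,
#' `channel`, `is_bridge`, `subtype`, `receptor_status`. Optional:
#' `replicate_group`. Checks performed: unique `sample_id`; unique
#' `(set_id, channel)`; at least one bridge channel in every set; each set
#' has 10 or 11 channels (disable with `check_channels = FALSE` for small
#' fixtures); the reference set is one of the set ids.
#'
#' @param design A data frame of channel annotations.
#' @param reference_set Integer id of the reference set (defaults to the
#'   table's `reference_set` attribute, else 4).
#' @param check_channels Enforce the 10-11 channels-per-set rule.
#' @return The validated design as a tibble, with a `reference_set`
#'   attribute attached.
#' @export
validate_design <- function(design, reference_set = NULL, check_channels = FALSE) {
  required <- c("sample_id", "cell_line", "set_id", "batch_id", "channel",
                "is_bridge", "subtype", "receptor_status")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("Design is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "plex_format_error")
  }
  design <- tibble::as_tibble(design)
  if (anyDuplicated(design$sample_id) > 0) {
    abort("Duplicate sample_id in design.", class = "plex_validation_error")
  }
  if (anyDuplicated(design[, c("set_id", "channel")]) > 0) {
    abort("Duplicate (set_id, channel) in design.", class = "plex_validation_error")
  }
  by_set <- dplyr::summarise(dplyr::group_by(design, .data$set_id),
                             n_bridge = sum(.data$is_bridge),
                             n_channels = dplyr::n(), .groups = "drop")
  if (any(by_set$n_bridge < 1)) {
    bad <- by_set$set_id[by_set$n_bridge < 1]
    abort(paste0("Set(s) without a bridge channel: ", paste(bad, collapse = ", ")),
          class = "plex_design_error")
  }
  if (check_channels && any(!by_set$n_channels %in% c(10L, 11L))) {
    bad <- by_set$set_id[!by_set$n_channels %in% c(10L, 11L)]
    abort(paste0("Set(s) without 10 or 11 channels: ", paste(bad, collapse = ", ")),
          class = "plex_validation_error")
  }
  reference_set <- reference_set %||% attr(design, "reference_set") %||% 4L
  if (!reference_set %in% design$set_id) {
    abort(paste0("Reference set ", reference_set, " is not among the set ids."),
          class = "plex_design_error")
  }
  attr(design, "reference_set") <- as.integer(reference_set)
  design
}

#' @rdname validate_design
#' @export
reference_set_of <- function(design) {
  rs <- attr(design, "reference_set")
  if (is.null(rs)) abort("Design has no reference_set attribute; run validate_design().",
                         class = "plex_design_error")
  rs
}

# sample_id of the designated bridge channel for each set. With several
# bridge channels per set, policy "first" keeps the first-flagged one
# (row order); "average" is resolved by the callers that support it.
bridge_samples <- function(design, policy = "first") {
  br <- dplyr::filter(design, .data$is_bridge)
  if (identical(policy, "first")) {
    br <- dplyr::slice_head(dplyr::group_by(br, .data$set_id), n = 1)
    br <- dplyr::ungroup(br)
  }
  dplyr::select(br, "set_id", "sample_id")
}
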