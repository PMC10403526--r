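#' Read and write the long-format peptide intensity table
#'
#' The canonical on-disk peptide schema is a TSV with columns `peptide`,
#' `protein`, `set`, `sample`, `intensity`: one row per reported peptide
#' per channel. In memory the table is a tibble with columns `peptide_id`,
#' `protein_id`, `set_id`, `sample_id`, `intensity` and a `stage` column
#' recording the processing level (`raw`, `within_set`, `across_set`,
#' `scaled`). Missing peptides are represented by absent rows, never by
#' sentinel values.
#'
#' @param path Path to a TSV file.
#' @param design Validated study design ([validate_design()]); rows whose
#'   sample is not in the design are rejected.
#' @return A peptide tibble at stage `"raw"`.
#' @export
read_peptide_table <- function(path, design) {
  tab <- read_tsv_checked(path, c("peptide", "protein", "set", "sample", "intensity"))
  out <- tibble::tibble(
    peptide_id = as.character(tab$peptide),
    protein_id = as.character(tab$protein),
    set_id = as.integer(tab$set),
    sample_id = as.character(tab$sample),
    intensity = as.numeric(tab$intensity),
    stage = "raw"
  )
  validate_peptide_table(out, design)
}

#' @rdname read_peptide_table
#' @param peptides A peptide tibble.
#' @export
write_peptide_table <- function(peptides, path) {
  out <- tibble::tibble(
    peptide = peptides$peptide_id, protein = peptides$protein_id,
    set = peptides$set_id, sample = peptides$sample_id,
    intensity = peptides$intensity
  )
  readr::write_tsv(out, path)
  invisible(path)
}

validate_peptide_table <- function(peptides, design = NULL) {
  if (any(!is.finite(peptides$intensity)) || any(peptides$intensity < 0)) {
    abort("Peptide intensities must be finite and non-negative.",
          class = "plex_validation_error")
  }
  if (!is.null(design)) {
    unknown <- setdiff(unique(peptides$sample_id), design$sample_id)
    if (length(unknown) > 0) {
      abort(paste0("Samples absent from the design: ",
                   paste(head(unknown, 5), collapse = ", ")),
            class = "plex_reference_error")
    }
  }
  if (anyDuplicated(peptides[, c("peptide_id", "sample_id", "stage")]) > 0) {
    abort("Duplicate (peptide, sample) rows within one stage.",
          class = "plex_validation_error")
  }
  peptides
}

#' Read and write study-design, PSM and drug-response tables
#'
#' TSV schemas: the design file has columns `sample`, `cell_line`, `set`,
#' `batch`, `channel`, `is_bridge`, `subtype`, `receptor_status` and
#' optionally `replicate_group`; the PSM file carries one row per
#' peptide-spectrum match with identification scores, the target/decoy
#' label and quantification diagnostics (`candidate_proteins` is
#' semicolon-separated); the response file has `cell_line`, `gr_aoc`,
#' `receptor_status`.
#'
#' @param path Path to a TSV file.
#' @param reference_set Reference set id to attach (design only).
#' @return A validated tibble of the corresponding type.
#' @export
read_design <- function(path, reference_set = 4L) {
  tab <- read_tsv_checked(path, c("sample", "cell_line", "set", "batch",
                                  "channel", "is_bridge", "subtype",
                                  "receptor_status"))
  out <- tibble::tibble(
    sample_id = as.character(tab$sample),
    cell_line = as.character(tab$cell_line),
    set_id = as.integer(tab$set),
    batch_id = as.integer(tab$batch),
    channel = as.character(tab$channel),
    is_bridge = as.logical(tab$is_bridge),
    subtype = as.character(tab$subtype),
    receptor_status = as.character(tab$receptor_status),
    replicate_group = if ("replicate_group" %in% names(tab))
      as.character(tab$replicate_group) else NA_character_
  )
  validate_design(out, reference_set = reference_set)
}

#' @rdname read_design
#' @param design Validated design tibble.
#' @export
write_design <- function(design, path) {
  out <- tibble::tibble(
    sample = design$sample_id, cell_line = design$cell_line,
    set = design$set_id, batch = design$batch_id, channel = design$channel,
    is_bridge = design$is_bridge, subtype = design$subtype,
    receptor_status = design$receptor_status,
    replicate_group = design$replicate_group %||% NA_character_
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname read_design
#' @export
read_psm_table <- function(path) {
  cols <- c("psm_id", "peptide_id", "candidate_proteins", "xcorr", "delta_cn",
            "mass_error_ppm", "label", "tmt_total", "isolation_specificity",
            "n_labelable_sites", "n_labeled_sites", "peptide_sequence")
  tab <- read_tsv_checked(path, cols)
  out <- tibble::as_tibble(tab[cols])
  out$candidate_proteins <- strsplit(as.character(out$candidate_proteins), ";", fixed = TRUE)
  validate_psm_table(out)
}

#' @rdname read_design
#' @param psms PSM tibble (list-column `candidate_proteins`).
#' @export
write_psm_table <- function(psms, path) {
  out <- psms
  out$candidate_proteins <- vapply(psms$candidate_proteins, paste,
                                   character(1), collapse = ";")
  readr::write_tsv(out, path)
  invisible(path)
}

validate_psm_table <- function(psms) {
  if (any(!psms$label %in% c("target", "decoy"))) {
    abort("PSM label must be 'target' or 'decoy'.", class = "plex_validation_error")
  }
  if (any(psms$isolation_specificity < 0 | psms$isolation_specificity > 1)) {
    abort("Isolation specificity must lie in [0, 1].", class = "plex_validation_error")
  }
  if (any(psms$n_labeled_sites > psms$n_labelable_sites)) {
    abort("n_labeled_sites exceeds n_labelable_sites.", class = "plex_validation_error")
  }
  if (any(psms$tmt_total < 0)) {
    abort("TMT totals must be non-negative.", class = "plex_validation_error")
  }
  psms
}

#' @rdname read_design
#' @export
read_response_table <- function(path) {
  tab <- read_tsv_checked(path, c("cell_line", "gr_aoc", "receptor_status"))
  out <- tibble::tibble(
    cell_line = as.character(tab$cell_line),
    gr_aoc = as.numeric(tab$gr_aoc),
    receptor_status = as.character(tab$receptor_status)
  )
  if (anyDuplicated(out$cell_line) > 0) {
    abort("Response table must have one row per cell line.",
          class = "plex_validation_error")
  }
  out
}

#' @rdname read_design
#' @param response Response tibble.
#' @export
write_response_table <- function(response, path) {
  readr::write_tsv(response, path)
  invisible(path)
}

#' Write a protein quantity matrix
#'
#' Protein matrices live in memory as long tibbles (`protein_id`, `set_id`,
#' `sample_id`, `quantity`, `n_peptides`, `stage`). Three export dialects
#' are supported: `long_tsv` is lossless; `wide_tsv` has proteins as rows
#' and samples as columns; `gct13` is the GCT 1.3 text format used for
#' LINCS-style expression matrices (`#1.3` version line, then a dimensions
#' line, then the data table). Proteins missing from a sample's set are
#' written as `NA` in the wide dialects.
#'
#' @param matrix Long protein tibble.
#' @param path Output path.
#' @param dialect One of `"long_tsv"`, `"wide_tsv"`, `"gct13"`.
#' @return `path`, invisibly.
#' @export
write_protein_matrix <- function(matrix, path,
                                 dialect = c("long_tsv", "wide_tsv", "gct13")) {
  dialect <- match.arg(dialect)
  if (nrow(matrix) == 0) {
    abort("Refusing to write an empty protein matrix.", class = "plex_validation_error")
  }
  if (dialect == "long_tsv") {
    out <- tibble::tibble(
      protein = matrix$protein_id, set = matrix$set_id,
      sample = matrix$sample_id, quantity = matrix$quantity,
      n_peptides = matrix$n_peptides
    )
    readr::write_tsv(out, path)
    return(invisible(path))
  }
  wide <- protein_wide(matrix)
  if (dialect == "wide_tsv") {
    readr::write_tsv(wide, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#1.3", con)
    writeLines(paste(nrow(wide), ncol(wide) - 1L, 0L, 0L, sep = "\t"), con)
    body <- readr::format_tsv(dplyr::rename(wide, id = "protein"))
    writeLines(sub("\n$", "", body), con)
  }
  invisible(path)
}

#' @rdname write_protein_matrix
#' @export
read_protein_matrix <- function(path, dialect = c("long_tsv", "wide_tsv", "gct13")) {
  dialect <- match.arg(dialect)
  if (dialect == "long_tsv") {
    tab <- read_tsv_checked(path, c("protein", "set", "sample", "quantity", "n_peptides"))
    return(tibble::tibble(
      protein_id = as.character(tab$protein), set_id = as.integer(tab$set),
      sample_id = as.character(tab$sample), quantity = as.numeric(tab$quantity),
      n_peptides = as.integer(tab$n_peptides), stage = "rolled"
    ))
  }
  if (dialect == "gct13") {
    lines <- readr::read_lines(path)
    if (lines[1] != "#1.3") {
      abort("Not a GCT 1.3 file (missing '#1.3' version line).",
            class = "plex_format_error")
    }
    tab <- readr::read_tsv(I(paste(lines[-(1:2)], collapse = "\n")),
                           show_col_types = FALSE, progress = FALSE)
    tab <- dplyr::rename(tab, protein = "id")
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  long <- tidyr::pivot_longer(tab, -"protein", names_to = "sample_id",
                              values_to = "quantity")
  long <- dplyr::filter(long, !is.na(.data$quantity))
  tibble::tibble(protein_id = as.character(long$protein),
                 sample_id = long$sample_id, quantity = long$quantity)
}

# proteins x samples pivot, sample columns ordered by (set, sample)
protein_wide <- function(matrix) {
  ord <- dplyr::distinct(dplyr::arrange(matrix, .data$set_id, .data$sample_id),
                         .data$sample_id)$sample_id
  wide <- tidyr::pivot_wider(
    dplyr::select(matrix, protein = "protein_id", "sample_id", "quantity"),
    names_from = "sample_id", values_from = "quantity"
  )
  dplyr::select(wide, "protein", dplyr::all_of(ord))
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "plex_io_error")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0(basename(path), " is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "plex_format_error")
  }
  tab
}
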