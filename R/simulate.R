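#' Configuration for the synthetic multi-batch TMT study generator
#'
#' The generator emulates a bridge-anchored cell-line panel profiled in 8
#' TMT sets over 2 acquisition batches: ~60 cell lines across
#' transcriptional subtypes, one bridge channel per set mixed from six
#' designated lines, five cross-batch replicates of one non-malignant
#' line, per-batch differences in peptide detection depth and intensity
#' scale, multiplicative sample-loading factors and log-normal measurement
#' noise, plus a PSM score table with hidden correct/incorrect labels and
#' a drug response that is linear in one causal protein with
#' subtype-specific offsets.
#'
#' @param n_proteins Number of proteins in the simulated proteome.
#' @param n_cell_lines Number of distinct cell lines.
#' @param n_sets Number of TMT sets; the first half form batch 1, the rest
#'   batch 2.
#' @param subtype_proportions Named proportions over
#'   `luminal`, `basal`, `her2`, `nonmalignant`.
#' @param n_marker_proteins Number of proteins carrying subtype effects.
#' @param subtype_effect_sd SD (log2 units) of per-subtype marker effects.
#' @param line_effect_sd SD (log2 units) of per-line, per-protein effects.
#' @param base_log2_mean,base_log2_sd Mean and SD of per-protein baseline
#'   log2 abundance.
#' @param noise_sd SD (log2 units) of multiplicative measurement noise.
#' @param peptide_pool_mean Mean size of each protein's peptide pool.
#' @param detection_prob Length-2 per-batch probability that a pool
#'   peptide enters a set's roster. The defaults (0.4, 0.7) with a pool
#'   mean of 10 yield ~4 detected peptides/protein in batch 1 and ~7 in
#'   batch 2, the deeper batch.
#' @param peptide_efficiency_sd SD (log2 units) of per-peptide ionization
#'   efficiency.
#' @param batch_intensity_factor Multiplicative intensity scale of batch 2
#'   relative to batch 1.
#' @param loading_factor_sd SD (natural-log scale) of per-sample loading
#'   factors.
#' @param bridge_lines Six cell lines whose equal-parts mixture forms the
#'   bridge sample.
#' @param replicate_line Cell line placed as a biological replicate in
#'   several sets spanning both batches.
#' @param n_replicate_placements Number of sets carrying `replicate_line`.
#' @param n_extra_replicate_lines Number of additional lines duplicated
#'   once (biological replicates beyond `replicate_line`).
#' @param reference_set Set whose bridge anchors across-set normalization.
#' @param psm Named list of PSM-simulation parameters; see
#'   [simulate_psm_table()].
#' @param response Named list of drug-response parameters; see
#'   [simulate_response()].
#' @param seed Integer random seed.
#'
#' @return A validated `sim_config` object (named list).
#' @export
sim_config <- function(n_proteins = 2000,
                       n_cell_lines = 60,
                       n_sets = 8,
                       subtype_proportions = c(luminal = 0.35, basal = 0.35,
                                               her2 = 0.22, nonmalignant = 0.08),
                       n_marker_proteins = 200,
                       subtype_effect_sd = 1.0,
                       line_effect_sd = 0.5,
                       base_log2_mean = 7,
                       base_log2_sd = 1,
                       noise_sd = 0.25,
                       peptide_pool_mean = 10,
                       detection_prob = c(0.4, 0.7),
                       peptide_efficiency_sd = 1.0,
                       batch_intensity_factor = 3.0,
                       loading_factor_sd = 0.15,
                       bridge_lines = c("HCC1806", "HS578T", "MCF7",
                                        "MCF10A", "MDAMB231", "SKBR3"),
                       replicate_line = "MCF10A",
                       n_replicate_placements = 5,
                       n_extra_replicate_lines = 9,
                       reference_set = 4,
                       psm = list(),
                       response = list(),
                       seed = 1L) {
  psm_defaults <- list(
    n_correct = 16000, n_incorrect = 2000, n_decoy = NULL,
    psms_per_correct_peptide = 2,
    correct_mean = c(xcorr = 3.2, delta_cn = 0.45, mass_error_ppm = 0),
    correct_sd = c(xcorr = 0.6, delta_cn = 0.12, mass_error_ppm = 1.2),
    incorrect_mean = c(xcorr = 1.7, delta_cn = 0.12, mass_error_ppm = 0),
    incorrect_sd = c(xcorr = 0.45, delta_cn = 0.08, mass_error_ppm = 5),
    tmt_total_meanlog = log(800), tmt_total_sdlog = 0.9,
    iso_spec_shape = c(12, 3),
    labeling_rate = 0.97, seq_missed_cleavage_rate = 0.08
  )
  resp_defaults <- list(
    causal_protein_id = NULL, beta = 0.5,
    subtype_offsets = c(luminal = 0.2, basal = -0.2, her2 = 0.1,
                        nonmalignant = 0),
    response_noise_sd = 0.5, include_nonmalignant = FALSE
  )
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_cell_lines = as.integer(n_cell_lines),
    n_sets = as.integer(n_sets),
    subtype_proportions = subtype_proportions,
    n_marker_proteins = as.integer(n_marker_proteins),
    subtype_effect_sd = subtype_effect_sd,
    line_effect_sd = line_effect_sd,
    base_log2_mean = base_log2_mean,
    base_log2_sd = base_log2_sd,
    noise_sd = noise_sd,
    peptide_pool_mean = peptide_pool_mean,
    detection_prob = detection_prob,
    peptide_efficiency_sd = peptide_efficiency_sd,
    batch_intensity_factor = batch_intensity_factor,
    loading_factor_sd = loading_factor_sd,
    bridge_lines = bridge_lines,
    replicate_line = replicate_line,
    n_replicate_placements = as.integer(n_replicate_placements),
    n_extra_replicate_lines = as.integer(n_extra_replicate_lines),
    reference_set = as.integer(reference_set),
    psm = modifyList(psm_defaults, psm),
    response = modifyList(resp_defaults, response),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (any(cfg$detection_prob < 0 | cfg$detection_prob > 1)) {
    abort("Detection probabilities must lie in [0, 1].", class = "plex_validation_error")
  }
  if (length(cfg$detection_prob) != 2) {
    abort("`detection_prob` must give one probability per batch (length 2).",
          class = "plex_validation_error")
  }
  sds <- c(cfg$subtype_effect_sd, cfg$line_effect_sd, cfg$base_log2_sd,
           cfg$noise_sd, cfg$peptide_efficiency_sd, cfg$loading_factor_sd,
           cfg$response$response_noise_sd)
  if (any(sds < 0)) {
    abort("Standard deviations must be non-negative.", class = "plex_validation_error")
  }
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-8) {
    abort("Subtype proportions must sum to 1.", class = "plex_validation_error")
  }
  if (length(cfg$bridge_lines) != 6) {
    abort("The bridge mixture uses exactly six cell lines.",
          class = "plex_validation_error")
  }
  if (cfg$batch_intensity_factor <= 0) {
    abort("`batch_intensity_factor` must be strictly positive.",
          class = "plex_validation_error")
  }
  if (any(cfg$psm$correct_sd <= 0) || any(cfg$psm$incorrect_sd <= 0)) {
    abort("PSM score standard deviations must be strictly positive.",
          class = "plex_validation_error")
  }
  if (!cfg$reference_set %in% seq_len(cfg$n_sets)) {
    abort("`reference_set` must be one of the simulated sets.",
          class = "plex_validation_error")
  }
  cfg
}

subtype_to_receptor <- c(luminal = "HR+", basal = "TNBC", her2 = "HER2+",
                         nonmalignant = "non-malignant")

# Deterministic cell-line panel: named lines (bridge-mix members,
# replicate and contrast lines) are seeded into their subtype groups,
# the remainder are filled with generic ids.
sim_cell_lines <- function(cfg) {
  counts <- largest_remainder(cfg$subtype_proportions, cfg$n_cell_lines)
  named <- list(
    luminal = "MCF7",
    basal = c("HCC1806", "HS578T", "MDAMB231"),
    her2 = "SKBR3",
    nonmalignant = c("MCF10A", "HME1", "NM184A1", "NM184B5", "NMMCF12A")
  )
  lines <- purrr::imap(counts, function(n, st) {
    seedy <- head(named[[st]], n)
    fill <- if (n > length(seedy)) {
      sprintf("BC%s%02d", toupper(substr(st, 1, 1)), seq_len(n - length(seedy)))
    } else character(0)
    tibble::tibble(cell_line = c(seedy, fill), subtype = st)
  })
  out <- dplyr::bind_rows(lines)
  out$receptor_status <- unname(subtype_to_receptor[out$subtype])
  out
}

largest_remainder <- function(props, total) {
  raw <- props * total
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  setNames(as.integer(counts), names(props))
}

#' Simulate the latent proteome and study factors
#'
#' Generates the ground truth a study draws from — per-line true protein
#' abundances (baseline + subtype marker effects + line effects, on the
#' linear scale), the peptide pool with per-peptide ionization
#' efficiencies, per-set rosters, batch factors and the causal protein —
#' without the peptide-intensity layer. [simulate_study()] builds on
#' this; use it directly when only abundances and responses are needed
#' (e.g. association studies).
#'
#' @param cfg A [sim_config()] object.
#' @return A `plex_truth` object; `true_abundance` is a lines-by-proteins
#'   matrix.
#' @export
simulate_truth <- function(cfg) {
  set.seed(cfg$seed)
  lines <- sim_cell_lines(cfg)
  protein_ids <- sprintf("P%04d", seq_len(cfg$n_proteins))

  base <- rnorm(cfg$n_proteins, cfg$base_log2_mean, cfg$base_log2_sd)
  marker_ids <- sort(sample(protein_ids, min(cfg$n_marker_proteins, cfg$n_proteins)))
  subtypes <- names(cfg$subtype_proportions)
  marker_fx <- matrix(0, nrow = cfg$n_proteins, ncol = length(subtypes),
                      dimnames = list(protein_ids, subtypes))
  marker_fx[marker_ids, ] <- rnorm(length(marker_ids) * length(subtypes),
                                   0, cfg$subtype_effect_sd)

  line_fx <- matrix(rnorm(nrow(lines) * cfg$n_proteins, 0, cfg$line_effect_sd),
                    nrow = nrow(lines),
                    dimnames = list(lines$cell_line, protein_ids))
  log2_abund <- sweep(line_fx, 2, base, `+`) +
    t(marker_fx[, lines$subtype, drop = FALSE])
  true_abundance <- 2^log2_abund

  pool_n <- 1L + rpois(cfg$n_proteins, max(cfg$peptide_pool_mean - 1, 0))
  peptides <- tibble::tibble(
    protein_id = rep(protein_ids, pool_n),
    peptide_id = paste0(rep(protein_ids, pool_n), "_pep",
                        sprintf("%02d", unlist(lapply(pool_n, seq_len)))),
    efficiency = 2^rnorm(sum(pool_n), 0, cfg$peptide_efficiency_sd)
  )

  # equal labelled-peptide amount per channel: the bench ratio check pools
  # the same total peptide signal from every sample, so each line's
  # profile is scaled to a common expected total MS signal (abundances
  # weighted by the summed peptide efficiencies of each protein); only
  # relative abundances are biologically meaningful
  eff_weight <- vapply(split(peptides$efficiency, peptides$protein_id),
                       sum, numeric(1))[protein_ids]
  signal <- drop(true_abundance %*% eff_weight)
  true_abundance <- true_abundance * (mean(signal) / signal)

  bridge_profile <- if (all(cfg$bridge_lines %in% lines$cell_line)) {
    colMeans(true_abundance[cfg$bridge_lines, , drop = FALSE])
  } else NULL

  batch_of_set <- ifelse(seq_len(cfg$n_sets) <= cfg$n_sets / 2, 1L, 2L)
  batch_factor <- ifelse(batch_of_set == 2L, cfg$batch_intensity_factor, 1)
  rosters <- lapply(seq_len(cfg$n_sets), function(k) {
    p <- cfg$detection_prob[batch_of_set[k]]
    peptides$peptide_id[runif(nrow(peptides)) < p]
  })

  non_markers <- setdiff(protein_ids, marker_ids)
  causal <- cfg$response$causal_protein_id %||%
    (if (length(non_markers) > 0) non_markers[1] else protein_ids[1])
  if (!causal %in% protein_ids) {
    abort(paste0("Causal protein ", causal, " is not in the proteome."),
          class = "plex_reference_error")
  }

  structure(list(
    lines = lines, protein_ids = protein_ids, marker_ids = marker_ids,
    true_abundance = true_abundance, bridge_profile = bridge_profile,
    peptides = peptides, rosters = rosters,
    batch_of_set = batch_of_set, batch_factor = batch_factor,
    causal_protein_id = causal, beta = cfg$response$beta,
    config = cfg
  ), class = "plex_truth")
}

# Allocate samples (one per line, plus replicates) to sets, add one
# bridge channel per set, and label channels with TMT tags.
simulate_design_from_truth <- function(truth) {
  cfg <- truth$config
  lines <- truth$lines
  n_sets <- cfg$n_sets
  batch_of_set <- truth$batch_of_set

  placements <- tibble::tibble(cell_line = lines$cell_line)
  rep_sets <- integer(0)
  if (cfg$n_replicate_placements > 1 && cfg$replicate_line %in% lines$cell_line) {
    # replicate placements alternate between the two batches
    b1 <- which(batch_of_set == 1L); b2 <- which(batch_of_set == 2L)
    n1 <- ceiling(cfg$n_replicate_placements / 2)
    rep_sets <- sort(c(head(b1, n1), head(b2, cfg$n_replicate_placements - n1)))
    placements <- dplyr::bind_rows(
      placements,
      tibble::tibble(cell_line = rep(cfg$replicate_line,
                                     cfg$n_replicate_placements - 1L))
    )
  }
  if (cfg$n_extra_replicate_lines > 0) {
    pool <- setdiff(lines$cell_line, cfg$replicate_line)
    extra <- sample(pool, min(cfg$n_extra_replicate_lines, length(pool)))
    placements <- dplyr::bind_rows(placements, tibble::tibble(cell_line = extra))
  }

  n_samples <- nrow(placements)
  base_size <- n_samples %/% n_sets
  sizes <- rep(base_size, n_sets)
  if (n_samples %% n_sets > 0) {
    sizes[seq_len(n_samples %% n_sets)] <- base_size + 1L
  }

  set_assign <- integer(n_samples)
  is_rep_line <- placements$cell_line == cfg$replicate_line
  if (length(rep_sets) > 0) {
    rep_idx <- which(is_rep_line)[seq_along(rep_sets)]
    set_assign[rep_idx] <- rep_sets
  }
  open_slots <- rep(seq_len(n_sets), sizes)
  for (k in set_assign[set_assign > 0]) {
    open_slots <- open_slots[-match(k, open_slots)]
  }
  rest <- which(set_assign == 0)
  set_assign[rest] <- sample(open_slots, length(rest))

  # no cell line twice in one set: swap conflicting duplicates
  repeat {
    tab <- paste(placements$cell_line, set_assign)
    dup <- which(duplicated(tab) & !is_rep_line)
    if (length(dup) == 0) break
    i <- dup[1]
    cand <- setdiff(rest, i)
    ok <- cand[set_assign[cand] != set_assign[i] &
                 placements$cell_line[cand] != placements$cell_line[i]]
    ok <- ok[!paste(placements$cell_line[i], set_assign[ok]) %in% tab &
               !paste(placements$cell_line[ok], set_assign[i]) %in% tab]
    if (length(ok) == 0) {
      abort("Could not place replicate samples without set collisions.",
            class = "plex_validation_error")
    }
    j <- ok[1]
    tmp <- set_assign[i]; set_assign[i] <- set_assign[j]; set_assign[j] <- tmp
  }

  channels <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                "130N", "130C", "131N", "131C")
  per_set <- lapply(seq_len(n_sets), function(k) {
    members <- placements$cell_line[set_assign == k]
    cl <- c("BRIDGE", members)
    tibble::tibble(
      set_id = k, batch_id = batch_of_set[k],
      channel = channels[seq_along(cl)],
      cell_line = cl, is_bridge = cl == "BRIDGE"
    )
  })
  design <- dplyr::bind_rows(per_set)
  design$sample_id <- sprintf("S%d_%s", design$set_id, design$channel)
  ann <- setNames(lines$subtype, lines$cell_line)
  design$subtype <- ifelse(design$is_bridge, "bridge",
                           unname(ann[design$cell_line]))
  design$receptor_status <- ifelse(
    design$is_bridge, "bridge",
    unname(subtype_to_receptor[design$subtype]))
  design$replicate_group <- ifelse(
    !design$is_bridge & design$cell_line == cfg$replicate_line,
    cfg$replicate_line, NA_character_)
  design <- dplyr::select(design, "sample_id", "cell_line", "set_id",
                          "batch_id", "channel", "is_bridge", "subtype",
                          "receptor_status", "replicate_group")
  validate_design(design, reference_set = cfg$reference_set)
}

#' Simulate a complete bridge-anchored TMT study
#'
#' Generates the latent proteome (per-line true abundances with subtype
#' marker effects), the study design (sets, batches, channels, bridge and
#' replicate placements), per-set peptide rosters, and the raw long-format
#' peptide intensity table. An observed intensity is
#' `true abundance x peptide efficiency x batch factor x loading factor x
#' 2^N(0, noise_sd)`; the bridge channel measures the equal-parts mixture
#' (arithmetic mean on the linear scale) of the six bridge lines. Every
#' rostered peptide is reported for every channel of its set (TMT
#' completeness); peptides absent from a set's roster are absent from that
#' set entirely, emulating between-set under-sampling.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `design` (validated design tibble),
#'   `peptides` (raw-stage peptide tibble), `truth` (a `plex_truth` object
#'   holding every latent factor), and `loading_factor` inside `truth`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_proteins = 50, n_cell_lines = 12,
#'                                    n_sets = 2, n_extra_replicate_lines = 1,
#'                                    n_replicate_placements = 2,
#'                                    reference_set = 1))
#' dplyr::count(study$peptides, set_id)
simulate_study <- function(config) {
  truth <- simulate_truth(config)
  if (is.null(truth$bridge_profile)) {
    abort("All six bridge lines must be present among the cell lines.",
          class = "plex_validation_error")
  }
  design <- simulate_design_from_truth(truth)
  cfg <- config

  loading <- exp(rnorm(nrow(design), 0, cfg$loading_factor_sd))
  names(loading) <- design$sample_id
  truth$loading_factor <- loading
  truth$design <- design

  pep_protein <- setNames(truth$peptides$protein_id, truth$peptides$peptide_id)
  pep_eff <- setNames(truth$peptides$efficiency, truth$peptides$peptide_id)

  per_set <- lapply(seq_len(cfg$n_sets), function(k) {
    roster <- truth$rosters[[k]]
    if (length(roster) == 0) return(NULL)
    samp <- design[design$set_id == k, ]
    n_i <- length(roster); n_j <- nrow(samp)
    prot <- pep_protein[roster]
    # abundance matrix: peptides x samples
    abund <- matrix(0, n_i, n_j)
    for (j in seq_len(n_j)) {
      abund[, j] <- if (samp$is_bridge[j]) {
        truth$bridge_profile[prot]
      } else {
        truth$true_abundance[samp$cell_line[j], prot]
      }
    }
    noise <- 2^rnorm(n_i * n_j, 0, cfg$noise_sd)
    inten <- abund * pep_eff[roster] * truth$batch_factor[k] *
      rep(loading[samp$sample_id], each = n_i) * noise
    tibble::tibble(
      peptide_id = rep(roster, times = n_j),
      protein_id = rep(unname(prot), times = n_j),
      set_id = k,
      sample_id = rep(samp$sample_id, each = n_i),
      intensity = as.vector(inten),
      stage = "raw"
    )
  })
  peptides <- dplyr::bind_rows(per_set)
  list(design = design, peptides = peptides, truth = truth)
}

#' Simulate a PSM score table with hidden correct/incorrect labels
#'
#' Emulates the score table of a concatenated target-decoy database
#' search. Target PSMs are a mixture of correct matches (high cross
#' correlation and score gap, small mass error) and incorrect matches;
#' decoy PSMs are drawn from the same incorrect-match score distribution,
#' and each incorrect match lands in the target or decoy half of the
#' database with equal probability, so decoy counts estimate incorrect
#' target counts. Correct matches share peptides (about
#' `psms_per_correct_peptide` PSMs per peptide, as repeated fragmentation
#' of real peptides produces); incorrect and decoy matches scatter across
#' unique peptides. The hidden `correct` column is retained for
#' calibration tests and is never used by the filtering code.
#'
#' @param config A [sim_config()] object; `config$psm` holds counts,
#'   score means/SDs and quantification-diagnostic parameters.
#' @param seed Optional seed overriding `config$seed`.
#' @return A PSM tibble (see [read_psm_table()]) with the extra logical
#'   column `correct`.
#' @export
simulate_psm_table <- function(config, seed = NULL) {
  cfg <- config$psm
  set.seed(seed %||% config$seed)
  if (cfg$n_correct <= 0) {
    abort("`n_correct` must be positive.", class = "plex_validation_error")
  }
  n_decoy_exp <- cfg$n_decoy %||% cfg$n_incorrect
  n_wrong <- cfg$n_incorrect + n_decoy_exp
  if (n_wrong == 0) {
    abort("At least one incorrect target or decoy PSM is required.",
          class = "plex_validation_error")
  }
  # each incorrect match falls in the target or decoy database half
  p_target <- cfg$n_incorrect / n_wrong
  wrong_is_target <- runif(n_wrong) < p_target

  draw_scores <- function(n, m, s) {
    tibble::tibble(
      xcorr = pmax(rnorm(n, m[["xcorr"]], s[["xcorr"]]), 0),
      delta_cn = pmax(rnorm(n, m[["delta_cn"]], s[["delta_cn"]]), 0),
      mass_error_ppm = rnorm(n, m[["mass_error_ppm"]], s[["mass_error_ppm"]])
    )
  }
  correct <- draw_scores(cfg$n_correct, cfg$correct_mean, cfg$correct_sd)
  wrong <- draw_scores(n_wrong, cfg$incorrect_mean, cfg$incorrect_sd)

  n_cpep <- max(1L, ceiling(cfg$n_correct / cfg$psms_per_correct_peptide))
  correct_pep <- sprintf("pep_t%05d", sample.int(n_cpep, cfg$n_correct, replace = TRUE))
  wrong_pep <- sprintf("pep_w%05d", seq_len(n_wrong))

  n <- cfg$n_correct + n_wrong
  psms <- dplyr::bind_rows(correct, wrong)
  psms$psm_id <- sprintf("psm%06d", seq_len(n))
  psms$peptide_id <- c(correct_pep, wrong_pep)
  psms$label <- c(rep("target", cfg$n_correct),
                  ifelse(wrong_is_target, "target", "decoy"))
  psms$correct <- c(rep(TRUE, cfg$n_correct), rep(FALSE, n_wrong))

  # candidate proteins: forward accessions for targets, reversed-database
  # accessions for decoys; occasional shared peptides get 2-3 candidates
  n_prot <- max(50L, n %/% 40L)
  fwd <- sprintf("PROT%05d", seq_len(n_prot))
  n_cand <- sample(1:3, n, replace = TRUE, prob = c(0.8, 0.15, 0.05))
  cand_pool <- function(is_decoy) if (is_decoy) paste0("rev_", fwd) else fwd
  is_decoy_row <- psms$label == "decoy"
  psms$candidate_proteins <- purrr::map2(n_cand, is_decoy_row, function(nc, dec) {
    sample(cand_pool(dec), nc)
  })

  psms$tmt_total <- rlnorm(n, cfg$tmt_total_meanlog, cfg$tmt_total_sdlog)
  psms$isolation_specificity <- stats::rbeta(n, cfg$iso_spec_shape[1],
                                             cfg$iso_spec_shape[2])
  seqs <- random_tryptic_sequences(n, cfg$seq_missed_cleavage_rate)
  psms$peptide_sequence <- seqs
  psms$n_labelable_sites <- 1L + stringr::str_count(seqs, "K")
  psms$n_labeled_sites <- rbinom(n, psms$n_labelable_sites, cfg$labeling_rate)

  out <- psms[sample.int(n), c("psm_id", "peptide_id", "candidate_proteins",
                               "xcorr", "delta_cn", "mass_error_ppm", "label",
                               "tmt_total", "isolation_specificity",
                               "n_labelable_sites", "n_labeled_sites",
                               "peptide_sequence", "correct")]
  validate_psm_table(tibble::as_tibble(out))
}

# Tryptic-like sequences: non-K/R/P body residues, occasional internal
# missed-cleavage K/R, C-terminal K or R.
random_tryptic_sequences <- function(n, missed_rate) {
  body_aa <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]
  lens <- sample(7:20, n, replace = TRUE)
  vapply(lens, function(L) {
    res <- sample(body_aa, L - 1, replace = TRUE)
    if (runif(1) < missed_rate && L > 3) {
      pos <- sample(2:(L - 2), 1)
      res[pos] <- sample(c("K", "R"), 1)
    }
    paste0(paste(res, collapse = ""), sample(c("K", "R"), 1))
  }, character(1))
}

#' Simulate drug response driven by one causal protein
#'
#' The response (area over the GR curve; higher = more sensitive) of each
#' cell line is a subtype-specific offset plus `beta` times the line's
#' standardized true abundance of the causal protein plus Gaussian noise.
#'
#' @param truth A `plex_truth` object from [simulate_study()] /
#'   the generator internals.
#' @param config A [sim_config()] object; `config$response` holds
#'   `causal_protein_id`, `beta`, `subtype_offsets`, `response_noise_sd`
#'   and `include_nonmalignant`.
#' @param seed Optional seed overriding `config$seed`.
#' @return A response tibble (`cell_line`, `gr_aoc`, `receptor_status`).
#' @export
simulate_response <- function(truth, config, seed = NULL) {
  rc <- config$response
  set.seed(seed %||% (config$seed + 1L))
  lines <- truth$lines
  if (!isTRUE(rc$include_nonmalignant)) {
    lines <- dplyr::filter(lines, .data$subtype != "nonmalignant")
  }
  causal <- rc$causal_protein_id %||% truth$causal_protein_id
  if (!causal %in% truth$protein_ids) {
    abort(paste0("Causal protein ", causal, " is not in the proteome."),
          class = "plex_reference_error")
  }
  ab <- log2(truth$true_abundance[lines$cell_line, causal])
  z <- if (sd(ab) > 0) (ab - mean(ab)) / sd(ab) else ab * 0
  offsets <- rc$subtype_offsets[lines$subtype]
  gr <- unname(offsets) + rc$beta * z +
    rnorm(nrow(lines), 0, rc$response_noise_sd)
  tibble::tibble(cell_line = lines$cell_line, gr_aoc = gr,
                 receptor_status = lines$receptor_status)
}
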