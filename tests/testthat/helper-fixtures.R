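# Shared fixture builders and element-by-element loop oracles. The
# oracles deliberately use nothing from the package's vectorized code
# paths: plain loops over rows and scalar arithmetic.

make_test_design <- function(n_sets = 3, samples_per_set = 5,
                             reference_set = 1) {
  rows <- list()
  for (k in seq_len(n_sets)) {
    for (j in seq_len(samples_per_set)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sprintf("S%d_%02d", k, j),
        cell_line = if (j == 1) "BRIDGE" else sprintf("CL%02d", (k - 1) * samples_per_set + j),
        set_id = k,
        batch_id = if (k <= ceiling(n_sets / 2)) 1L else 2L,
        channel = as.character(125 + j),
        is_bridge = j == 1,
        subtype = if (j == 1) "bridge" else sample(c("luminal", "basal"), 1),
        receptor_status = if (j == 1) "bridge" else "HR+",
        replicate_group = NA_character_
      )
    }
  }
  validate_design(dplyr::bind_rows(rows), reference_set = reference_set)
}

make_test_peptides <- function(design, n_peptides = 60, n_proteins = 12,
                               detection = 0.8, seed = 42) {
  set.seed(seed)
  pep <- sprintf("pep%03d", seq_len(n_peptides))
  prot <- sprintf("prot%02d", sample.int(n_proteins, n_peptides, replace = TRUE))
  rows <- list()
  for (k in unique(design$set_id)) {
    roster <- which(runif(n_peptides) < detection)
    if (length(roster) == 0) roster <- 1L
    samples <- design$sample_id[design$set_id == k]
    for (i in roster) {
      for (s in samples) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          peptide_id = pep[i], protein_id = prot[i], set_id = k,
          sample_id = s, intensity = rlnorm(1, log(100), 0.8), stage = "raw")
      }
    }
  }
  dplyr::bind_rows(rows)
}

# -- loop oracles for the normalization equations ------------------------

# The oracles accumulate the needed totals with one explicit scalar loop
# over rows (an environment as a hash of running sums), then rescale each
# row with a second scalar loop; no vectorized arithmetic, grouping or
# joins from the implementation paths.

oracle_within <- function(peptides, design) {
  totals <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(peptides))) {
    key <- paste(peptides$set_id[r], peptides$sample_id[r])
    prev <- if (exists(key, totals)) get(key, totals) else 0
    assign(key, prev + peptides$intensity[r], totals)
  }
  bridge_of <- list()
  for (k in unique(design$set_id)) {
    bridge_of[[as.character(k)]] <-
      design$sample_id[design$set_id == k & design$is_bridge][1]
  }
  out <- peptides
  for (r in seq_len(nrow(out))) {
    k <- out$set_id[r]
    bt <- get(paste(k, bridge_of[[as.character(k)]]), totals)
    st <- get(paste(k, out$sample_id[r]), totals)
    out$intensity[r] <- peptides$intensity[r] * bt / st
  }
  out$stage <- "within_set"
  out
}

oracle_across <- function(peptides, raw, design, reference_set) {
  btot <- new.env(parent = emptyenv())
  bridge_of <- list()
  for (k in unique(design$set_id)) {
    bridge_of[[as.character(k)]] <-
      design$sample_id[design$set_id == k & design$is_bridge][1]
  }
  for (r in seq_len(nrow(raw))) {
    k <- as.character(raw$set_id[r])
    if (raw$sample_id[r] == bridge_of[[k]]) {
      prev <- if (exists(k, btot)) get(k, btot) else 0
      assign(k, prev + raw$intensity[r], btot)
    }
  }
  ref <- get(as.character(reference_set), btot)
  out <- peptides
  for (r in seq_len(nrow(out))) {
    out$intensity[r] <- peptides$intensity[r] * ref /
      get(as.character(out$set_id[r]), btot)
  }
  out$stage <- "across_set"
  out
}

oracle_rollup <- function(peptides) {
  sums <- new.env(parent = emptyenv())
  rosters <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(peptides))) {
    key <- paste(peptides$protein_id[r], peptides$set_id[r],
                 peptides$sample_id[r])
    prev <- if (exists(key, sums)) get(key, sums) else 0
    assign(key, prev + peptides$intensity[r], sums)
    rkey <- paste(peptides$protein_id[r], peptides$set_id[r])
    seen <- if (exists(rkey, rosters)) get(rkey, rosters) else character(0)
    if (!peptides$peptide_id[r] %in% seen) {
      assign(rkey, c(seen, peptides$peptide_id[r]), rosters)
    }
  }
  keys <- unique(peptides[, c("protein_id", "set_id", "sample_id")])
  quantity <- numeric(nrow(keys)); n_pep <- integer(nrow(keys))
  for (r in seq_len(nrow(keys))) {
    n <- length(get(paste(keys$protein_id[r], keys$set_id[r]), rosters))
    quantity[r] <- get(paste(keys$protein_id[r], keys$set_id[r],
                             keys$sample_id[r]), sums) / n
    n_pep[r] <- n
  }
  tibble::tibble(protein_id = keys$protein_id, set_id = keys$set_id,
                 sample_id = keys$sample_id, quantity = quantity,
                 n_peptides = n_pep, stage = "rolled")
}

oracle_scale <- function(x) {
  value_col <- if ("intensity" %in% names(x)) "intensity" else "quantity"
  feature_col <- if (value_col == "intensity") "peptide_id" else "protein_id"
  totals <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(x))) {
    key <- paste(x[[feature_col]][r], x$set_id[r])
    prev <- if (exists(key, totals)) get(key, totals) else 0
    assign(key, prev + x[[value_col]][r], totals)
  }
  out <- x
  for (r in seq_len(nrow(out))) {
    tot <- get(paste(x[[feature_col]][r], x$set_id[r]), totals)
    out[[value_col]][r] <- if (tot == 0) 0 else 100 * x[[value_col]][r] / tot
  }
  out$stage <- "scaled"
  out
}

# pairwise ranking AUC (probability a target outscores a decoy)
rank_auc <- function(scores, labels) {
  t <- scores[labels == "target"]; d <- scores[labels == "decoy"]
  cmp <- outer(t, d, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  scale <- pmax(abs(expected), 1e-12)
  expect_true(max(abs(actual - expected) / scale) <= tol)
}

# small study used by several diagnostics tests
small_sim_config <- function(seed = 11, ...) {
  sim_config(n_proteins = 120, n_cell_lines = 16, n_sets = 4,
             n_marker_proteins = 30, n_extra_replicate_lines = 2,
             n_replicate_placements = 3, reference_set = 2,
             seed = seed, ...)
}
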