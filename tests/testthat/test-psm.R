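make_two_class_psms <- function(n = 100, sep = 3, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    psm_id = sprintf("m%03d", seq_len(2 * n)),
    peptide_id = sprintf("pep%03d", seq_len(2 * n)),
    candidate_proteins = as.list(sprintf("P%03d", seq_len(2 * n))),
    xcorr = c(rnorm(n, sep, 1), rnorm(n, 0, 1)),
    delta_cn = rnorm(2 * n, 0.3, 0.1),
    mass_error_ppm = rnorm(2 * n, 0, 2),
    label = rep(c("target", "decoy"), each = n),
    tmt_total = rep(500, 2 * n), isolation_specificity = rep(0.9, 2 * n),
    n_labelable_sites = rep(1L, 2 * n), n_labeled_sites = rep(1L, 2 * n),
    peptide_sequence = rep("PEPTIDEK", 2 * n))
}

test_that("discriminant matches the closed-form pooled-covariance direction", {
  psms <- make_two_class_psms(n = 100, sep = 2, seed = 8)
  psms$delta_cn <- psms$delta_cn + ifelse(psms$label == "target", 0.15, 0)
  model <- fit_discriminant(psms)

  # independent recomputation: element-by-element pooled covariance and
  # mean difference on the |mass error| feature space
  x <- cbind(psms$xcorr, psms$delta_cn, abs(psms$mass_error_ppm))
  it <- psms$label == "target"
  mt <- colMeans(x[it, ]); md <- colMeans(x[!it, ])
  p <- ncol(x); S <- matrix(0, p, p)
  for (g in list(which(it), which(!it))) {
    xm <- sweep(x[g, ], 2, colMeans(x[g, ]))
    S <- S + t(xm) %*% xm
  }
  S <- S / (nrow(x) - 2)
  w_oracle <- solve(S, mt - md)
  expect_equal(unname(model$weights), unname(w_oracle), tolerance = 1e-10)

  # cross-check against an established LDA fit: directions proportional
  skip_if_not_installed("MASS")
  fit <- MASS::lda(x, grouping = factor(psms$label))
  ratio <- model$weights / drop(fit$scaling)
  expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-6)
})

test_that("separation drives the discriminant toward the informative score", {
  psms <- make_two_class_psms(n = 300, sep = 6, seed = 3)
  model <- fit_discriminant(psms)
  w <- abs(model$weights)
  expect_gt(w[["xcorr"]], max(w[["delta_cn"]], w[["abs_mass_error_ppm"]]) * 3)
  expect_gt(rank_auc(discriminant_score(model, psms), psms$label), 0.99)

  null <- make_two_class_psms(n = 400, sep = 0, seed = 4)
  m0 <- fit_discriminant(null)
  expect_lt(abs(rank_auc(discriminant_score(m0, null), null$label) - 0.5), 0.08)

  single <- dplyr::filter(psms, label == "target")
  expect_error(fit_discriminant(single), class = "plex_validation_error")
})

test_that("FDR curve follows the twice-decoys-over-total formula", {
  # 1000 identifications above the threshold, 5 of them decoys -> 1%
  scores <- c(seq(1000, 1.001, length.out = 1000), 0.5)
  labels <- c(rep("target", 995), rep("decoy", 5), "target")
  curve <- fdr_curve(scores[1:1000], labels[1:1000])
  at <- curve[curve$n_total == 1000, ]
  expect_equal(at$fdr, 2 * 5 / 1000)
  # zero decoys above a stringent threshold -> fdr 0
  expect_equal(curve$fdr[curve$n_total == 10], 0)
  expect_error(fdr_curve(numeric(0), character(0)),
               class = "plex_validation_error")
})

test_that("FDR curve equals a quadratic-time recount on a random fixture", {
  set.seed(6)
  n <- 1500
  scores <- round(rnorm(n, 3, 1), 2)  # rounding forces ties
  labels <- sample(c("target", "decoy"), n, TRUE, prob = c(0.85, 0.15))
  curve <- fdr_curve(scores, labels)
  for (i in seq(1, nrow(curve), by = 7)) {
    t <- curve$threshold[i]
    above <- scores >= t
    expect_equal(curve$n_total[i], sum(above))
    expect_equal(curve$n_decoy[i], sum(above & labels == "decoy"))
    expect_equal(curve$fdr[i], min(1, 2 * sum(above & labels == "decoy") / sum(above)))
  }
  expect_true(all(diff(curve$q_value) >= 0))  # monotone in threshold order
  expect_true(all(curve$q_value <= curve$fdr))
})

test_that("peptide filtering is monotone in alpha and handles edge cases", {
  psms <- make_two_class_psms(n = 400, sep = 2.2, seed = 12)
  model <- fit_discriminant(psms)
  k1 <- filter_peptides(psms, model, alpha = 0.01)
  k2 <- filter_peptides(psms, model, alpha = 0.05)
  expect_true(all(k1$psm_id %in% k2$psm_id))
  expect_true(all(k1$label == "target"))
  expect_false(anyDuplicated(k1$peptide_id) > 0)

  # perfectly separated: every target retained at alpha = 0.01
  sepd <- make_two_class_psms(n = 50, sep = 30, seed = 2)
  kept <- filter_peptides(sepd, alpha = 0.01)
  expect_setequal(kept$psm_id, sepd$psm_id[sepd$label == "target"])

  # unachievable level (a decoy tops the ranking under a fixed score):
  # empty result + warning
  tiny <- make_two_class_psms(n = 10, sep = 0.1, seed = 5)
  tiny$xcorr[tiny$label == "decoy"][1] <- 100
  fixed <- structure(list(weights = c(xcorr = 1, delta_cn = 0,
                                      abs_mass_error_ppm = 0),
                          offset = 0), class = "plex_lda")
  expect_warning(out <- filter_peptides(tiny, model = fixed, alpha = 1e-6))
  expect_equal(nrow(out), 0)
})

test_that("best PSM per peptide is retained after filtering", {
  psms <- make_two_class_psms(n = 30, sep = 20, seed = 9)
  psms$peptide_id[2] <- psms$peptide_id[1]  # two PSMs, one peptide
  kept <- filter_peptides(psms, alpha = 0.05)
  row <- dplyr::filter(kept, peptide_id == psms$peptide_id[1])
  expect_equal(nrow(row), 1)
  both <- dplyr::filter(psms, peptide_id == psms$peptide_id[1])
  model <- fit_discriminant(psms)
  expect_equal(row$score, max(discriminant_score(model, both)))
})

test_that("parsimony assigns each peptide to its largest candidate protein", {
  ids <- tibble::tibble(
    peptide_id = c("a", "b"),
    candidate_proteins = list(c("P1", "P2"), c("B", "A")))
  lens <- c(P1 = 500, P2 = 300, A = 300, B = 300)
  out <- assign_parsimony(ids, lens)
  expect_equal(out$protein_id, c("P1", "A"))  # max length; tie -> lexicographic

  expect_error(assign_parsimony(ids, lens[-1]), class = "plex_reference_error")

  # 50-peptide random fixture against an exhaustive per-peptide scan
  set.seed(14)
  universe <- sprintf("PR%02d", 1:30)
  lens2 <- setNames(sample(100:900, 30), universe)
  ids2 <- tibble::tibble(
    peptide_id = sprintf("pep%02d", 1:50),
    candidate_proteins = lapply(1:50, function(i)
      sample(universe, sample(1:4, 1))))
  out2 <- assign_parsimony(ids2, lens2)
  for (i in 1:50) {
    cand <- ids2$candidate_proteins[[i]]
    best <- cand[lens2[cand] == max(lens2[cand])]
    expect_identical(out2$protein_id[i], min(best))
  }
  counts <- attr(out2, "protein_counts")
  expect_equal(sum(counts$n_peptides), 50)  # parsimony output is a function
})

test_that("protein-level FDR applies the same formula per protein", {
  # 200 target proteins above the cut with one decoy protein -> 1%
  ids <- tibble::tibble(
    peptide_id = sprintf("pep%03d", 1:201),
    protein_id = c(sprintf("P%03d", 1:199), "rev_X", "P200"),
    score = c(seq(50, 2, length.out = 199), 1.5, 1.0))
  prot_fdr_at_cut <- 2 * 1 / 201
  expect_lt(prot_fdr_at_cut, 0.011)
  kept <- filter_protein_fdr(ids, alpha = 0.011)
  expect_setequal(kept$protein_id, c(sprintf("P%03d", 1:199), "P200"))
  expect_false("rev_X" %in% kept$protein_id)

  # all targets above all decoys: all targets retained
  easy <- tibble::tibble(
    peptide_id = sprintf("pep%02d", 1:12),
    protein_id = c(sprintf("T%d", 1:9), "rev_a", "rev_b", "rev_c"),
    score = c(9:1 + 10, 3, 2, 1))
  kept2 <- filter_protein_fdr(easy, alpha = 0.01)
  expect_setequal(kept2$protein_id, sprintf("T%d", 1:9))

  # brute-force recount on a random fixture
  set.seed(31)
  fix <- tibble::tibble(
    peptide_id = sprintf("pep%03d", 1:300),
    protein_id = sample(c(sprintf("P%02d", 1:60), sprintf("rev_P%02d", 1:15)),
                        300, TRUE),
    score = rnorm(300, 4, 1) + ifelse(grepl("^rev_",
      sample(c(sprintf("P%02d", 1:60), sprintf("rev_P%02d", 1:15)), 300, TRUE)), 0, 0))
  fix$score <- fix$score + ifelse(grepl("^rev_", fix$protein_id), -2, 0)
  prot <- dplyr::summarise(dplyr::group_by(fix, protein_id),
                           score = max(score), .groups = "drop")
  prot$is_decoy <- grepl("^rev_", prot$protein_id)
  alpha <- 0.1
  # oracle: scan protein scores descending, largest set with running-min
  # fdr below alpha
  ord <- order(prot$score, decreasing = TRUE)
  fdrs <- sapply(seq_along(ord), function(i)
    min(1, 2 * sum(prot$is_decoy[ord[1:i]]) / i))
  qs <- rev(cummin(rev(fdrs)))
  ok <- which(qs < alpha)
  expected <- if (length(ok) == 0) character(0) else {
    set_idx <- ord[seq_len(max(ok))]
    prot$protein_id[set_idx][!prot$is_decoy[set_idx]]
  }
  kept3 <- filter_protein_fdr(fix, alpha = alpha)
  expect_setequal(unique(kept3$protein_id), expected)
})

test_that("quantification filters apply strict thresholds", {
  psms <- tibble::tibble(
    psm_id = sprintf("q%02d", 1:4),
    tmt_total = c(150, 500, 500, 200),
    isolation_specificity = c(0.9, 0.70, 0.9, 0.9))
  out <- apply_quant_filters(psms)
  # 150 fails the >200 rule; 0.70 fails the strict >0.7 rule; tmt 200 fails
  expect_equal(out$psm_id, "q03")
  expect_equal(attr(out, "removed")[["either"]], 3)

  # 12-row fixture with hand-enumerated pass/fail: rows 1,3,4,6,8,9,12 pass
  fix <- tibble::tibble(
    psm_id = sprintf("r%02d", 1:12),
    tmt_total = c(300, 200, 201, 1000, 150, 250, 199.9, 500, 10000, 220, 180, 201),
    isolation_specificity = c(0.8, 0.9, 0.71, 0.95, 0.8, 0.75, 0.9, 0.701,
                              0.99, 0.7, 0.72, 0.9))
  kept <- apply_quant_filters(fix)
  expect_equal(kept$psm_id, sprintf("r%02d", c(1, 3, 4, 6, 8, 9, 12)))
})
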