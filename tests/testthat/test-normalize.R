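design3 <- make_test_design(n_sets = 3, samples_per_set = 4)

test_that("within-set normalization equalizes totals to the bridge", {
  # hand example: bridge total 100, sample total 50, peptide value 10 -> 20
  d <- make_test_design(n_sets = 1, samples_per_set = 2)
  peps <- tibble::tibble(
    peptide_id = c("a", "b", "a", "b"), protein_id = "p", set_id = 1L,
    sample_id = rep(d$sample_id, each = 2),
    intensity = c(60, 40, 10, 40), stage = "raw")
  out <- within_set_normalize(peps, d)
  expect_equal(out$intensity[out$sample_id == d$sample_id[2]], c(20, 80))
  # the bridge channel is a fixed point
  expect_equal(out$intensity[out$sample_id == d$sample_id[1]], c(60, 40))
  expect_true(all(out$stage == "within_set"))

  zero <- peps
  zero$intensity[3:4] <- 0
  expect_error(within_set_normalize(zero, d), class = "plex_validation_error")
})

test_that("across-set normalization rescales by raw bridge totals", {
  d <- make_test_design(n_sets = 2, samples_per_set = 2, reference_set = 1)
  # reference-set bridge raw total 100; set-2 bridge raw total 200
  peps <- tibble::tibble(
    peptide_id = rep(c("a", "b"), 4), protein_id = "p",
    set_id = rep(c(1L, 1L, 2L, 2L), each = 2),
    sample_id = rep(d$sample_id, each = 2),
    intensity = c(60, 40, 10, 40, 120, 80, 30, 10), stage = "raw")
  w <- within_set_normalize(peps, d)
  a <- across_set_normalize(w, peps, d)
  # every set-2 intensity halved relative to its within-set value
  expect_equal(a$intensity[a$set_id == 2], w$intensity[w$set_id == 2] / 2)
  # reference set is a fixed point
  expect_equal(a$intensity[a$set_id == 1], w$intensity[w$set_id == 1])
  # bridge totals equal across sets afterwards
  bt <- tapply(a$intensity[a$sample_id %in% d$sample_id[d$is_bridge]],
               a$set_id[a$sample_id %in% d$sample_id[d$is_bridge]], sum)
  expect_equal(unname(diff(range(bt))), 0, tolerance = 1e-12)
})

test_that("protein rollup averages peptides and counts the roster", {
  peps <- tibble::tibble(
    peptide_id = c("a", "b", "a", "b", "c"),
    protein_id = c("P1", "P1", "P1", "P1", "P2"),
    set_id = 1L,
    sample_id = c("s1", "s1", "s2", "s2", "s1"),
    intensity = c(4, 6, 10, 30, 7), stage = "across_set")
  out <- rollup_proteins(peps)
  expect_equal(out$quantity[out$protein_id == "P1" & out$sample_id == "s1"], 5)
  expect_equal(out$quantity[out$protein_id == "P1" & out$sample_id == "s2"], 20)
  expect_equal(out$quantity[out$protein_id == "P2"], 7)  # single peptide
  expect_equal(out$n_peptides[out$protein_id == "P1"], c(2L, 2L))

  # explicit map overrides the table's own column; unmapped -> error
  map <- tibble::tibble(peptide_id = c("a", "b"), protein_id = c("X", "X"))
  expect_error(rollup_proteins(peps, map), class = "plex_reference_error")
})

test_that("0-100 scaling sums to 100 per feature per set", {
  x <- tibble::tibble(
    peptide_id = rep(c("a", "b"), each = 3), protein_id = "p", set_id = 1L,
    sample_id = rep(c("s1", "s2", "s3"), 2),
    intensity = c(10, 30, 60, 5, 5, 5), stage = "across_set")
  out <- scale_0_100(x)
  expect_equal(out$intensity[out$peptide_id == "a"], c(10, 30, 60))
  expect_equal(out$intensity[out$peptide_id == "b"], rep(100 / 3, 3))

  zero <- x
  zero$intensity[zero$peptide_id == "b"] <- 0
  expect_warning(outz <- scale_0_100(zero))
  expect_equal(outz$intensity[outz$peptide_id == "b"], c(0, 0, 0))
})

test_that("all stages match the element-by-element loop oracles", {
  peps <- make_test_peptides(design3, n_peptides = 40, n_proteins = 8,
                             detection = 0.7, seed = 19)
  w <- within_set_normalize(peps, design3)
  expect_rel_equal(w$intensity, oracle_within(peps, design3)$intensity, 1e-12)
  a <- across_set_normalize(w, peps, design3)
  expect_rel_equal(a$intensity,
                   oracle_across(w, peps, design3, 1)$intensity, 1e-12)
  rolled <- rollup_proteins(a)
  o_r <- oracle_rollup(a)
  key <- paste(rolled$protein_id, rolled$set_id, rolled$sample_id)
  o_key <- paste(o_r$protein_id, o_r$set_id, o_r$sample_id)
  expect_rel_equal(rolled$quantity, o_r$quantity[match(key, o_key)], 1e-12)
  expect_equal(rolled$n_peptides, o_r$n_peptides[match(key, o_key)])
  sc <- scale_0_100(rolled)
  o_s <- oracle_scale(rolled)
  expect_rel_equal(sc$quantity, o_s$quantity[match(key, paste(
    o_s$protein_id, o_s$set_id, o_s$sample_id))], 1e-12)
})

test_that("pipeline outputs are invariant to per-sample rescaling of raw data", {
  peps <- make_test_peptides(design3, n_peptides = 30, n_proteins = 6,
                             detection = 0.9, seed = 23)
  cfg <- plex_config(reference_set = 1L)
  base <- run_pipeline(peps, design3, cfg)

  # scale an ordinary sample by 17
  target <- design3$sample_id[!design3$is_bridge][4]
  scaled <- peps
  scaled$intensity[scaled$sample_id == target] <-
    scaled$intensity[scaled$sample_id == target] * 17
  res <- run_pipeline(scaled, design3, cfg)
  expect_rel_equal(res$level2_peptides$intensity,
                   base$level2_peptides$intensity, 1e-10)
  expect_rel_equal(res$level3_proteins$quantity,
                   base$level3_proteins$quantity, 1e-10)

  # scale a bridge channel by 17: scaled outputs still identical
  bridge <- design3$sample_id[design3$is_bridge][2]
  scaled2 <- peps
  scaled2$intensity[scaled2$sample_id == bridge] <-
    scaled2$intensity[scaled2$sample_id == bridge] * 17
  res2 <- run_pipeline(scaled2, design3, cfg)
  expect_rel_equal(res2$level3_proteins$quantity,
                   base$level3_proteins$quantity, 1e-10)
})

test_that("noise-free simulation is recovered exactly up to per-set scaling", {
  cfg <- small_sim_config(seed = 31, noise_sd = 0, loading_factor_sd = 0,
                          detection_prob = c(1, 1))
  study <- simulate_study(cfg)
  res <- run_pipeline(study$peptides, study$design)
  truth <- study$truth
  d <- study$design
  lvl3 <- res$level3_proteins
  # expected: true abundance (bridge = six-line mean) scaled to 100 over
  # the samples of each set
  for (k in c(1, 3)) {
    samp <- d[d$set_id == k, ]
    prot <- unique(lvl3$protein_id[lvl3$set_id == k])[1:20]
    for (p in prot) {
      tru <- vapply(seq_len(nrow(samp)), function(j) {
        if (samp$is_bridge[j]) truth$bridge_profile[[p]]
        else truth$true_abundance[samp$cell_line[j], p]
      }, numeric(1))
      expected <- 100 * tru / sum(tru)
      got <- lvl3[lvl3$set_id == k & lvl3$protein_id == p, ]
      got <- got$quantity[match(samp$sample_id, got$sample_id)]
      expect_rel_equal(got, expected, 1e-9)
    }
  }
})

test_that("stage row counts are conserved through the pipeline", {
  study <- simulate_study(small_sim_config(seed = 41))
  res <- run_pipeline(study$peptides, study$design)
  counts <- res$counts
  expect_equal(counts$n_rows[counts$stage == "raw"], nrow(study$peptides))
  expect_equal(counts$n_rows[counts$stage == "within_set"],
               nrow(study$peptides))
  expect_equal(counts$n_rows[counts$stage == "across_set"],
               nrow(study$peptides))
  # protein rows: one per (protein, set, sample) triple present
  triples <- dplyr::n_distinct(paste(study$peptides$protein_id,
                                     study$peptides$set_id,
                                     study$peptides$sample_id))
  expect_equal(counts$n_rows[counts$stage == "rolled_proteins"], triples)
})
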