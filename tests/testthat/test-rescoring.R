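test_that("pseudo-reversed decoys preserve mass and cleavage specificity", {
  peps <- data.frame(sequence = c("SAMPLEK", "ACAK", "GG"),
                     protein = "P1", stringsAsFactors = FALSE)
  peps$mods <- replicate(3, NULL, simplify = FALSE)
  dec <- build_decoys(peps)
  expect_identical(dec$sequence[1], "ELPMASK")
  ## palindromic-after-rule peptides are perturbed and flagged
  expect_identical(dec$sequence[2], "CAAK")
  expect_true(dec$decoy_perturbed[2])
  expect_false(dec$decoy_perturbed[1])
  expect_true(all(dec$is_decoy))
  ## same residue composition implies exactly equal mass
  expect_identical(peptide_mass("SAMPLEK"), peptide_mass("ELPMASK"))
})

test_that("decoy modification deltas travel with their residues", {
  ox <- mod_oxidation_m()
  peps <- data.frame(sequence = "AMPLEK", protein = "P1",
                     stringsAsFactors = FALSE)
  peps$mods <- list(c(0, ox$delta, 0, 0, 0, 0))
  dec <- build_decoys(peps)
  expect_identical(dec$sequence[1], "ELPMAK")
  ## the delta must still sit on the M (now position 4)
  expect_equal(dec$mods[[1]][4], ox$delta)
  expect_identical(peptide_mass(peps$sequence, peps$mods[[1]]),
                   peptide_mass(dec$sequence, dec$mods[[1]]))
})

test_that("q-values follow the decoy/target ratio with running minimum", {
  psms <- data.frame(scan = c("a", "b", "c", "d"),
                     is_decoy = c(FALSE, FALSE, TRUE, FALSE),
                     rescore = c(10, 9, 8.5, 8), stringsAsFactors = FALSE)
  q <- compute_qvalues(psms)$qvalue
  expect_equal(q[1], 0)
  expect_equal(q[2], 0)
  expect_equal(q[4], 1 / 3)
  ## all decoys above all targets: every target q-value is 1
  worst <- data.frame(scan = letters[1:4],
                      is_decoy = c(TRUE, TRUE, FALSE, FALSE),
                      rescore = c(10, 9, 2, 1), stringsAsFactors = FALSE)
  expect_true(all(compute_qvalues(worst)$qvalue[3:4] == 1))
  ## +1 correction is more conservative
  q1 <- compute_qvalues(psms, plus_one = TRUE)$qvalue
  expect_true(all(q1 >= q))
})

test_that("q-values are monotone non-increasing in score", {
  set.seed(401)
  for (i in 1:20) {
    n <- 200
    psms <- data.frame(scan = paste0("s", 1:n),
                       is_decoy = runif(n) < 0.5,
                       rescore = rnorm(n) + ifelse(runif(n) < 0.5, 2, 0),
                       stringsAsFactors = FALSE)
    psms <- compute_qvalues(psms)
    o <- order(-psms$rescore)
    expect_true(all(diff(psms$qvalue[o]) >= -1e-12))
    expect_true(all(psms$qvalue >= 0 & psms$qvalue <= 1))
  }
})

test_that("rescoring falls back gracefully and preserves tie order", {
  psms <- data.frame(scan = paste0("s", 1:10), is_decoy = FALSE,
                     coarse = 10:1, stringsAsFactors = FALSE)
  expect_warning(out <- rescore_psms(psms, seed = 1), "falling back")
  expect_identical(out$rescore, out$coarse)
})

test_that("rescoring is deterministic and standardization-invariant", {
  u <- test_uaa()
  cfg <- sim_config("sim2", n_spectra = 60, n_alpha = 20, seed = 42)
  res <- run_sim_search(cfg)
  r1 <- suppressMessages(rescore_psms(res$psms[, setdiff(names(res$psms), "rescore")],
                                      seed = 9))
  r2 <- suppressMessages(rescore_psms(res$psms[, setdiff(names(res$psms), "rescore")],
                                      seed = 9))
  expect_identical(r1$rescore, r2$rescore)
  ## rescaling a feature's units must not change the ranking (features are
  ## standardized; the coarse score enters both as feature and as the
  ## rank-based initializer, neither of which depends on units)
  scaled <- res$psms[, setdiff(names(res$psms), "rescore")]
  scaled$coarse <- scaled$coarse * 1e3
  r3 <- suppressMessages(rescore_psms(scaled, seed = 9))
  expect_identical(order(-r1$rescore), order(-r3$rescore))
})

test_that("rescoring does not lose rank-1 precision on partial-ladder data", {
  u <- test_uaa()
  cfg <- sim_config("sim2", n_spectra = 120, n_alpha = 30,
                    entrapment_frac = 0.5, seed = 77)
  sim <- simulate_dataset(cfg, u)
  idx <- index_alpha_database(sim$proteins, enzyme_rule("trypsin"))
  beta <- generate_beta_peptides(sim$beta_protein, sim$beta_uaa_site,
                                 enzyme_rule("trypsin"), u,
                                 mods = list(mod_oxidation_m()))
  psms <- search_spectra(sim$spectra, beta, idx, u, mode = "cleavable")
  before <- rank1_psms(psms, "coarse")
  ev_before <- evaluate_against_truth(before[!before$is_decoy, ], sim$truth)
  psms <- suppressMessages(rescore_psms(psms, seed = 77))
  after <- rank1_psms(psms, "rescore")
  ev_after <- evaluate_against_truth(after[!after$is_decoy, ], sim$truth)
  expect_gte(ev_after$site_precision, ev_before$site_precision)
})

test_that("evaluation distinguishes pair-level from site-level correctness", {
  truth <- data.frame(scan = c("s1", "s2"),
                      alpha_seq = c("SAMPHLER", "AGHTLNVK"),
                      alpha_site = c(5L, 3L),
                      beta_seq = "GLTNUAGELDR", stringsAsFactors = FALSE)
  filtered <- data.frame(scan = c("s1", "s2"),
                         alpha_seq = c("SAMPHLER", "AGHTLNVK"),
                         alpha_site = c(5L, 8L),  # s2 site wrong (K not H)
                         beta_seq = "GLTNUAGELDR", stringsAsFactors = FALSE)
  ev <- evaluate_against_truth(filtered, truth)
  expect_equal(ev$pair_precision, 1.0)
  expect_equal(ev$site_precision, 0.5)
  expect_equal(ev$site_recall, 0.5)
  ## empty filtered set: precision reported 1.0 with n = 0
  ev0 <- evaluate_against_truth(filtered[0, ], truth)
  expect_identical(ev0$n, 0L)
  expect_equal(ev0$pair_precision, 1.0)
  expect_equal(ev0$pair_recall, 0.0)
  expect_error(
    evaluate_against_truth(data.frame(scan = "zz", alpha_seq = "A",
                                      alpha_site = 1L, beta_seq = "AUA",
                                      stringsAsFactors = FALSE), truth),
    "missing")
})
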