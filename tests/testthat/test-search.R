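test_that("alpha index lookups equal a linear mass scan", {
  set.seed(301)
  prot <- data.frame(
    id = paste0("P", 1:10),
    sequence = replicate(10, paste0(random_peptide(40,
      setdiff(names(ORACLE_COMP), c("K", "R"))), "K")),
    stringsAsFactors = FALSE)
  idx <- index_alpha_database(prot, enzyme_rule("trypsin"), mods = list(),
                              min_length = 3)
  peps <- idx$peptides
  expect_false(is.unsorted(peps$mass))
  expect_identical(sum(peps$is_decoy), sum(!peps$is_decoy))
  for (i in 1:50) {
    center <- runif(1, min(peps$mass), max(peps$mass))
    w <- center * 20e-6
    linear <- which(peps$mass >= center - w & peps$mass <= center + w)
    lo <- findInterval(center - w, peps$mass)
    hi <- findInterval(center + w, peps$mass)
    binary <- if (hi > lo) (lo + 1L):hi else integer(0)
    expect_identical(binary, linear)
  }
  expect_error(index_alpha_database(prot[0, ], enzyme_rule("trypsin")),
               "empty")
})

test_that("fragment combinatorics follow site containment", {
  u <- test_uaa()
  ## alpha length 10, site 9 (H): regular b = b1..b8, xl b = b9;
  ## regular y = y1, xl y = y2..y9
  ions <- generate_fragments("AAAAAAAAHK", 9L, "GLTNUAGELDR", 5L, u,
                             mode = "non_cleavable", max_charge = 1L)
  a <- ions[ions$chain == "alpha", ]
  expect_identical(sort(a$index[a$series == "b" & a$class == "regular"]), 1:8)
  expect_identical(a$index[a$series == "b" & a$class == "xl_containing"], 9L)
  expect_identical(a$index[a$series == "y" & a$class == "regular"], 1L)
  expect_identical(sort(a$index[a$series == "y" & a$class == "xl_containing"]), 2:9)
  ## classes partition the set
  expect_true(all(ions$class %in% c("regular", "xl_containing")))
})

test_that("Uaa-Tyr candidates fall back to the non-cleavable ion set", {
  u <- test_uaa()
  ions_y <- generate_fragments("AAAYAAAK", 4L, "GLTNUAGELDR", 5L, u,
                               mode = "cleavable")
  expect_false(any(ions_y$class %in% c("released_chain", "internal",
                                       "neutral_loss")))
  ions_h <- generate_fragments("AAAHAAAK", 4L, "GLTNUAGELDR", 5L, u,
                               mode = "cleavable")
  expect_true(all(c("released_chain", "internal", "neutral_loss") %in%
                    ions_h$class))
  ## cleavable ion set is a superset of the non-cleavable one
  ions_h_nc <- generate_fragments("AAAHAAAK", 4L, "GLTNUAGELDR", 5L, u,
                                  mode = "non_cleavable")
  key <- function(x) paste(x$chain, x$series, x$index, x$class, x$charge)
  expect_true(all(key(ions_h_nc) %in% key(ions_h)))
  expect_error(generate_fragments("AAAAAAAK", 2L, "GLTNUAGELDR", 5L, u),
               "reactive")
})

test_that("released chains conserve the precursor mass channel-wise", {
  u <- test_uaa()
  prec <- crosslink_precursor_mass(peptide_mass("SAMPHLER"),
                                   peptide_mass("GLTNUAGELDR", uaa = u), u)
  ions <- generate_fragments("SAMPHLER", 5L, "GLTNUAGELDR", 5L, u,
                             mode = "cleavable", max_charge = 1L)
  for (chn in names(u$channels)) {
    rel <- ions[ions$class == "released_chain" & ions$channel == chn, ]
    expect_identical(nrow(rel), 2L)
    expect_equal(sum(rel$neutral), prec, tolerance = 1e-6 / prec)
  }
})

test_that("engine fragment masses agree with the independent simulator builder", {
  u <- test_uaa()
  cases <- list(list(a = "SAMPHLER", s = 5L), list(a = "AGHTLNVVK", s = 3L),
                list(a = "LNTAYVEK", s = 8L), list(a = "TAYLDNVR", s = 3L))
  for (cs in cases) {
    eng <- generate_fragments(cs$a, cs$s, "GLTNUAGELDR", 5L, u,
                              mode = "cleavable", max_charge = 2L)
    eng <- eng[eng$class != "neutral_loss", ]
    ind <- uaaxl:::sim_theoretical_ions(cs$a, cs$s, "GLTNUAGELDR", 5L, u,
                                        max_charge = 2L)
    key <- function(x) paste(x$chain, x$series, x$index, x$class, x$channel,
                             x$charge)
    expect_setequal(key(eng), key(ind))
    m <- match(key(ind), key(eng))
    expect_equal(eng$mz[m], ind$mz, tolerance = 1e-6)
  }
})

test_that("peak matching equals the brute-force all-pairs oracle", {
  ## exact and just-out-of-tolerance cases
  sp <- spectrum("s", 500, 3, c(400, 500.005), c(1, 2))
  m <- match_peaks(sp, c(400), tol_ppm = 10)
  expect_identical(m$peak, 1L)
  m2 <- match_peaks(sp, c(500.005 * (1 - 10.1e-6)), tol_ppm = 10)
  expect_identical(nrow(m2), 0L)
  ## randomized equivalence
  set.seed(303)
  for (i in 1:50) {
    np <- sample(5:40, 1)
    pk <- sort(runif(np, 100, 2000))
    it <- runif(np, 1, 100)
    theo <- runif(sample(5:60, 1), 100, 2000)
    ## plant near-collisions
    theo[1:3] <- pk[1:3] * (1 + runif(3, -15e-6, 15e-6))
    sp <- spectrum("r", 500, 3, pk, it)
    got <- match_peaks(sp, theo, tol_ppm = 20)
    want <- oracle_match(pk, it, theo, 20)
    got <- got[order(got$ion), ]
    want <- want[order(want$ion), ]
    expect_identical(got$ion, want$ion)
    expect_identical(got$peak, want$peak)
  }
})

test_that("coarse score is zero without matches and monotone in matches", {
  u <- test_uaa()
  ions <- generate_fragments("SAMPHLER", 5L, "GLTNUAGELDR", 5L, u, "cleavable",
                             max_charge = 1L)
  sp_empty <- spectrum("e", 500, 3, numeric(0), numeric(0))
  sc0 <- coarse_score(ions, match_peaks(sp_empty, ions$mz), sp_empty)
  expect_identical(sc0$score, 0)
  ## adding one more matched ion never decreases the score
  sp1 <- spectrum("m1", 500, 3, ions$mz[1], 100)
  sp2 <- spectrum("m2", 500, 3, ions$mz[1:2], c(100, 50))
  s1 <- coarse_score(ions, match_peaks(sp1, ions$mz), sp1)$score
  s2 <- coarse_score(ions, match_peaks(sp2, ions$mz), sp2)$score
  expect_gte(s2, s1)
})

test_that("candidate generation respects the reactive-residue rule", {
  u <- test_uaa()
  enz <- enzyme_rule("trypsin")
  beta <- generate_beta_peptides(uaaxl:::.SIM_UAA_PROTEIN,
                                 uaaxl:::.SIM_UAA_SITE, enz, u, missed = 0)
  ## alpha without K/H/Y sites (R-terminated, none internal) gives no PSM
  ## even though the precursor mass fits exactly
  no_site <- "SAMPLTTGLDAETR"
  one_site <- "SAMPKLTGLDAETR"  # K at 5 is the single eligible site
  prot <- data.frame(id = c("A1", "A2"),
                     sequence = c(no_site, one_site),
                     stringsAsFactors = FALSE)
  idx <- index_alpha_database(prot, enz, mods = list(), decoys = FALSE)
  mkspec <- function(aseq) {
    prec <- crosslink_precursor_mass(peptide_mass(aseq),
                                     peptide_mass(beta$sequence[1], uaa = u), u)
    ions <- uaaxl:::sim_theoretical_ions(aseq, 5L, beta$sequence[1],
                                         beta$uaa_pos[1], u, max_charge = 1L)
    spectrum(paste0("sp_", aseq), mz_from_neutral(prec, 3), 3L,
             ions$mz, rep(100, nrow(ions)))
  }
  psms_none <- search_spectra(list(mkspec(no_site)), beta[1, ], idx, u,
                              mode = "cleavable")
  expect_identical(nrow(psms_none[psms_none$alpha_seq == no_site, ]), 0L)
  psms_one <- search_spectra(list(mkspec(one_site)), beta[1, ], idx, u,
                             mode = "cleavable")
  hits <- psms_one[psms_one$alpha_seq == one_site, ]
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$alpha_site, 5L)
})

test_that("search is deterministic for identical inputs", {
  u <- test_uaa()
  cfg <- sim_config("sim1", n_spectra = 15, n_alpha = 10, seed = 17)
  sim <- simulate_dataset(cfg, u)
  idx <- index_alpha_database(sim$proteins, enzyme_rule("trypsin"))
  beta <- generate_beta_peptides(sim$beta_protein, sim$beta_uaa_site,
                                 enzyme_rule("trypsin"), u)
  p1 <- search_spectra(sim$spectra, beta, idx, u, mode = "cleavable")
  p2 <- search_spectra(sim$spectra, beta, idx, u, mode = "cleavable")
  expect_identical(p1, p2)
})
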