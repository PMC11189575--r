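## Default synthetic Uaa-bearing protein used as the beta-peptide source.
## Tryptic; the Uaa ('U') sits at protein position 17, inside the tryptic
## peptide GLTNUAGELDR (Uaa position 5). Purely synthetic sequence.
.SIM_UAA_PROTEIN <- "MSTELAANDFVKGLTNUAGELDRAVQSIEKLTAEHGFNDVLRSMPEVTKYLDNAGSVLEK"
.SIM_UAA_SITE <- 17L

#' Simulation configuration
#'
#' Named presets reproduce the four benchmark datasets for Uaa-His/Lys
#' cross-linking: `sim1` (1000 spectra, exactly one H/K in the alpha chain,
#' full b/y ladders), `sim2` (as sim1 but each alpha b ion independently
#' retained with probability 0.5), `sim3` (as sim1 but no alpha b ions),
#' and `sim4` (200 spectra, at least one H/K and at least one Y in the alpha
#' chain, full b/y ladders). In the "one H/K" datasets the alpha chain
#' carries no tyrosine, so the cross-link site is unambiguous by
#' construction; `sim4` deliberately reintroduces the H/K-vs-Y site
#' ambiguity.
#'
#' @param preset "sim1", "sim2", "sim3", "sim4" or "custom".
#' @param n_spectra Number of spectra to emit.
#' @param alpha_constraint "one_hk", "hk_and_y", or "none".
#' @param b_completeness Alpha-chain b-ion retention: "full", "partial"
#'   (probability `partial_p`), or "none".
#' @param partial_p Retention probability for "partial" (default 0.5).
#' @param n_alpha Size of the true alpha-peptide pool (default 60).
#' @param entrapment_frac Fraction of database proteins that are entrapment
#'   (realistic decoy-like proteins never used in spectra); default 0.
#' @param peptides_per_protein Alpha peptides concatenated per synthetic
#'   protein in the companion FASTA (default 8).
#' @param n_noise Noise peaks per spectrum (default 30).
#' @param jitter_ppm Fragment m/z jitter s.d. in ppm (default 20/3, i.e. a
#'   third of the fragment tolerance).
#' @param prec_jitter_ppm Precursor m/z jitter s.d. in ppm (default 10/3).
#' @param charge_probs Precursor charge distribution over 3+..6+.
#' @param beta_protein,beta_uaa_site Uaa protein sequence and site used as
#'   the beta source.
#' @param seed RNG seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(preset = c("sim1", "sim2", "sim3", "sim4", "custom"),
                       n_spectra = NULL, alpha_constraint = NULL,
                       b_completeness = NULL, partial_p = 0.5,
                       n_alpha = 60L, entrapment_frac = 0,
                       peptides_per_protein = 8L,
                       n_noise = 30L, jitter_ppm = 20 / 3,
                       prec_jitter_ppm = 10 / 3,
                       charge_probs = c(`3` = 0.6, `4` = 0.4),
                       beta_protein = .SIM_UAA_PROTEIN,
                       beta_uaa_site = .SIM_UAA_SITE,
                       seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    sim1 = list(n = 1000L, constraint = "one_hk", b = "full"),
    sim2 = list(n = 1000L, constraint = "one_hk", b = "partial"),
    sim3 = list(n = 1000L, constraint = "one_hk", b = "none"),
    sim4 = list(n = 200L, constraint = "hk_and_y", b = "full"),
    custom = list(n = 100L, constraint = "none", b = "full")
  )
  cfg <- list(
    preset = preset,
    n_spectra = if (is.null(n_spectra)) def$n else as.integer(n_spectra),
    alpha_constraint = if (is.null(alpha_constraint)) def$constraint else alpha_constraint,
    b_completeness = if (is.null(b_completeness)) def$b else b_completeness,
    partial_p = partial_p, n_alpha = as.integer(n_alpha),
    entrapment_frac = entrapment_frac,
    peptides_per_protein = as.integer(peptides_per_protein),
    n_noise = as.integer(n_noise), jitter_ppm = jitter_ppm,
    prec_jitter_ppm = prec_jitter_ppm, charge_probs = charge_probs,
    beta_protein = beta_protein, beta_uaa_site = as.integer(beta_uaa_site),
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_spectra > 0L, cfg$jitter_ppm >= 0, cfg$n_noise >= 0L,
            cfg$alpha_constraint %in% c("one_hk", "hk_and_y", "none"),
            cfg$b_completeness %in% c("full", "partial", "none"))
  structure(cfg, class = "sim_config")
}

## residues allowed in alpha interiors: no K/R (tryptic 0-missed), and the
## site-defining residues H/Y are placed explicitly per constraint
.SIM_INTERIOR <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D",
                   "Q", "E", "M", "F", "W")

.sample_alpha_peptide <- function(constraint) {
  len <- sample(6:20, 1L)
  cterm <- sample(c("K", "R"), 1L)
  chars <- sample(.SIM_INTERIOR, len - 1L, replace = TRUE)
  ## no P immediately after the preceding peptide's cleavage point
  while (chars[1L] == "P") chars[1L] <- sample(.SIM_INTERIOR, 1L)
  if (constraint %in% c("one_hk", "hk_and_y")) {
    hk <- sample(c("H", "K"), 1L)
    if (hk == "K") {
      cterm <- "K"
      site <- len
    } else {
      cterm <- "R"  # a C-terminal K would add a second H/K to the chain
      site <- sample(2:(len - 1L), 1L)
      chars[site] <- "H"
    }
    if (constraint == "hk_and_y") {
      free <- setdiff(2:(len - 1L), site)
      ypos <- free[sample(length(free), 1L)]
      chars[ypos] <- "Y"
    }
  } else {
    ## mixed-site sampling: one cross-linkable residue, drawn from H/K/Y
    res <- sample(c("H", "K", "Y"), 1L)
    if (res == "K") {
      cterm <- "K"
      site <- len
    } else {
      cterm <- "R"  # keep the sampled residue the only eligible site
      site <- sample(2:(len - 1L), 1L)
      chars[site] <- res
    }
  }
  list(sequence = paste(c(chars, cterm), collapse = ""), site = as.integer(site))
}

## Independent theoretical-ion builder used by the simulator (plain loops and
## explicit sums; deliberately not the engine's vectorized generator, so the
## two can cross-check each other).
sim_theoretical_ions <- function(alpha_seq, alpha_site, beta_seq, beta_site,
                                 uaa, max_charge = 2L) {
  rt <- residue_masses()
  res_mass <- function(ch) if (ch %in% c("U", "J", uaa$symbol)) uaa$residue_mass else rt[[ch]]
  acc <- list(chain = character(0), series = character(0), index = integer(0),
              neutral = numeric(0), class = character(0), channel = character(0),
              charge = integer(0))
  emit <- function(chain, series, index, neutral, class, channel = "") {
    for (z in seq_len(max_charge)) {
      acc$chain <<- c(acc$chain, chain); acc$series <<- c(acc$series, series)
      acc$index <<- c(acc$index, index); acc$neutral <<- c(acc$neutral, neutral)
      acc$class <<- c(acc$class, class); acc$channel <<- c(acc$channel, channel)
      acc$charge <<- c(acc$charge, z)
    }
  }
  for (chain in c("alpha", "beta")) {
    s <- if (chain == "alpha") alpha_seq else beta_seq
    site <- if (chain == "alpha") alpha_site else beta_site
    partner <- if (chain == "alpha") beta_seq else alpha_seq
    chars <- strsplit(s, "")[[1]]
    pchars <- strsplit(partner, "")[[1]]
    Mp <- sum(vapply(pchars, res_mass, numeric(1))) + mass_h2o()
    n <- length(chars)
    for (i in seq_len(n - 1L)) {
      bmass <- sum(vapply(chars[seq_len(i)], res_mass, numeric(1)))
      ymass <- sum(vapply(chars[(n - i + 1L):n], res_mass, numeric(1))) + mass_h2o()
      if (i < site) emit(chain, "b", i, bmass, "regular")
      else emit(chain, "b", i, bmass + Mp + uaa$delta_xl, "xl_containing")
      if (i <= n - site) emit(chain, "y", i, ymass, "regular")
      else emit(chain, "y", i, ymass + Mp + uaa$delta_xl, "xl_containing")
    }
  }
  site_res <- substr(alpha_seq, alpha_site, alpha_site)
  if (site_res %in% uaa$cleavable) {
    achars <- strsplit(alpha_seq, "")[[1]]
    bchars <- strsplit(beta_seq, "")[[1]]
    Ma <- sum(vapply(achars, res_mass, numeric(1))) + mass_h2o()
    Mb <- sum(vapply(bchars, res_mass, numeric(1))) + mass_h2o()
    for (chn in names(uaa$channels)) {
      ch <- uaa$channels[[chn]]
      emit("alpha", "M", 0L, Ma + ch[["alpha"]], "released_chain", chn)
      emit("beta", "M", 0L, Mb + ch[["beta"]], "released_chain", chn)
      for (chain in c("alpha", "beta")) {
        s <- if (chain == "alpha") alpha_seq else beta_seq
        site <- if (chain == "alpha") alpha_site else beta_site
        d <- if (chain == "alpha") ch[["alpha"]] else ch[["beta"]]
        chars <- strsplit(s, "")[[1]]
        n <- length(chars)
        for (i in seq_len(n - 1L)) {
          if (i >= site) {
            bmass <- sum(vapply(chars[seq_len(i)], res_mass, numeric(1)))
            emit(chain, "b", i, bmass + d, "internal", chn)
          }
          if (i > n - site) {
            ymass <- sum(vapply(chars[(n - i + 1L):n], res_mass, numeric(1))) + mass_h2o()
            emit(chain, "y", i, ymass + d, "internal", chn)
          }
        }
      }
    }
  }
  acc$mz <- (acc$neutral + acc$charge * mass_proton()) / acc$charge
  as.data.frame(acc, stringsAsFactors = FALSE)
}

## Emission model: which theoretical ions appear in the simulated spectrum,
## and how intense. Parameterized so that internal/released intensity is high
## for H/K cross-links and near zero for Y, while xl-containing ions show the
## opposite pattern.
.SIM_PROFILE <- list(
  HK = list(p_xl = 0.25, s_xl = 0.3, p_internal = 0.9, s_internal = 1.0,
            p_released = 0.9, s_released = 1.2, p_nl = 0.5),
  Y  = list(p_xl = 0.9, s_xl = 1.0, p_internal = 0.02, s_internal = 0.2,
            p_released = 0.0, s_released = 0.0, p_nl = 0.0)
)

.sim_emit_spectrum <- function(alpha_seq, alpha_site, beta_seq, beta_site,
                               uaa, charge, cfg, theo = NULL) {
  if (is.null(theo)) {
    theo <- sim_theoretical_ions(alpha_seq, alpha_site, beta_seq, beta_site,
                                 uaa, max_charge = 2L)
    ## only charge-1 backbone ions and charge 1-2 released chains are emitted
    theo <- theo[theo$charge == 1L | theo$series == "M", , drop = FALSE]
  }
  site_res <- substr(alpha_seq, alpha_site, alpha_site)
  prof <- if (site_res %in% c("H", "K")) .SIM_PROFILE$HK else .SIM_PROFILE$Y
  b_keep_p <- switch(cfg$b_completeness, full = 1, partial = cfg$partial_p, none = 0)

  pmap <- c(regular = 1, xl_containing = prof$p_xl, internal = prof$p_internal,
            released_chain = prof$p_released)
  smap <- c(regular = 1, xl_containing = prof$s_xl, internal = prof$s_internal,
            released_chain = prof$s_released)
  p <- unname(pmap[theo$class])
  scale <- unname(smap[theo$class])
  ## alpha b-series completeness applies to every alpha b ion
  ab <- theo$chain == "alpha" & theo$series == "b"
  p[ab] <- p[ab] * b_keep_p
  keep <- stats::runif(nrow(theo)) < p
  theo <- theo[keep, , drop = FALSE]
  scale <- scale[keep]
  channels <- sort(unique(theo$channel[theo$channel != ""]))
  if (nrow(theo)) {
    intens <- stats::rlnorm(nrow(theo), 0, 1) * scale * 1e4
    mz <- theo$mz * (1 + stats::rnorm(nrow(theo), 0, cfg$jitter_ppm * 1e-6))
  } else {
    intens <- numeric(0); mz <- numeric(0)
  }
  ## -SO3 neutral loss on the sulfo-retaining released beta chain (channel A)
  rel_b <- which(theo$class == "released_chain" & theo$chain == "beta" &
                   theo$channel == "A")
  for (i in rel_b) {
    if (stats::runif(1) < prof$p_nl) {
      nlm <- (theo$neutral[i] + uaa$neutral_losses[1] +
                theo$charge[i] * mass_proton()) / theo$charge[i]
      mz <- c(mz, nlm * (1 + stats::rnorm(1, 0, cfg$jitter_ppm * 1e-6)))
      intens <- c(intens, stats::rlnorm(1, 0, 1) * 0.5 * 1e4)
    }
  }
  if (cfg$n_noise > 0L) {
    hi <- if (length(mz)) max(mz) * 1.05 else 2000
    mz <- c(mz, stats::runif(cfg$n_noise, 100, hi))
    intens <- c(intens, stats::rlnorm(cfg$n_noise, 0, 1) * 0.3 * 1e4)
  }
  Mprec <- crosslink_precursor_mass(
    peptide_mass(alpha_seq), peptide_mass(beta_seq, uaa = uaa), uaa)
  pmz <- mz_from_neutral(Mprec, charge) *
    (1 + stats::rnorm(1, 0, cfg$prec_jitter_ppm * 1e-6))
  list(precursor_mz = pmz, mz = mz, intensity = intens, channels = channels)
}

#' Simulate a benchmark cross-linking dataset
#'
#' Emits `n_spectra` synthetic HCD spectra of Uaa cross-linked peptide pairs
#' under the configured composition constraint and ion-completeness profile,
#' together with the per-spectrum ground truth and a companion FASTA in
#' which every alpha peptide is embedded in a tryptic protein context
#' (entrapment proteins, if requested, are built the same way but never used
#' in spectra).
#'
#' @param cfg A [sim_config()].
#' @param uaa [uaa_chemistry()] (default FSY-class chemistry).
#' @return List with `spectra` (list of `spectrum`), `truth` (data.frame:
#'   scan, alpha/beta sequences and sites, charge, channels), `proteins`
#'   (FASTA data.frame with `entrapment` flag), `beta_protein`,
#'   `beta_uaa_site`, and `config`.
#' @export
simulate_dataset <- function(cfg, uaa = uaa_chemistry()) {
  set.seed(cfg$seed)
  ## beta peptide: the 0-missed tryptic peptide covering the Uaa site
  beta <- generate_beta_peptides(cfg$beta_protein, cfg$beta_uaa_site,
                                 enzyme_rule("trypsin"), uaa, missed = 0L)
  stopifnot(nrow(beta) >= 1L)
  beta_seq <- beta$sequence[1L]
  beta_site <- beta$uaa_pos[1L]

  n_entrap <- ceiling(cfg$n_alpha * cfg$entrapment_frac /
                        max(1 - cfg$entrapment_frac, 1e-9))
  if (cfg$entrapment_frac >= 1) stop("entrapment_frac must be < 1")
  pool <- list()
  seen <- character(0)
  total <- cfg$n_alpha + n_entrap
  attempts <- 0L
  while (length(pool) < total) {
    attempts <- attempts + 1L
    if (attempts > 50L * total)
      stop("could not satisfy alpha constraint '", cfg$alpha_constraint,
           "' after bounded sampling")
    p <- .sample_alpha_peptide(cfg$alpha_constraint)
    if (p$sequence %in% seen) next
    seen <- c(seen, p$sequence)
    pool[[length(pool) + 1L]] <- p
  }
  alpha_seqs <- vapply(pool, `[[`, character(1), "sequence")
  alpha_sites <- vapply(pool, `[[`, integer(1), "site")
  is_entrap <- rep(c(FALSE, TRUE), c(cfg$n_alpha, n_entrap))

  ## companion FASTA: concatenate peptides into synthetic tryptic proteins,
  ## keeping true and entrapment peptides in separate proteins
  proteins <- list()
  mk_prots <- function(seqs, prefix) {
    if (!length(seqs)) return(invisible())
    grp <- split(seqs, ceiling(seq_along(seqs) / cfg$peptides_per_protein))
    for (g in seq_along(grp)) {
      proteins[[length(proteins) + 1L]] <<- data.frame(
        id = paste0(prefix, g),
        header = paste0(prefix, g, " synthetic"),
        sequence = paste(grp[[g]], collapse = ""),
        entrapment = startsWith(prefix, "ENTRAP"),
        stringsAsFactors = FALSE)
    }
  }
  mk_prots(alpha_seqs[!is_entrap], "SIMPROT_")
  mk_prots(alpha_seqs[is_entrap], "ENTRAP_")
  proteins <- do.call(rbind, proteins)

  true_idx <- which(!is_entrap)
  charges <- as.integer(names(cfg$charge_probs))
  pick <- sample(true_idx, cfg$n_spectra, replace = TRUE)
  zs <- sample(charges, cfg$n_spectra, replace = TRUE, prob = cfg$charge_probs)

  ## theoretical ion sets are deterministic per alpha peptide; cache them
  theo_cache <- vector("list", length(alpha_seqs))
  spectra <- vector("list", cfg$n_spectra)
  truth <- vector("list", cfg$n_spectra)
  for (i in seq_len(cfg$n_spectra)) {
    a <- pick[i]
    if (is.null(theo_cache[[a]])) {
      th <- sim_theoretical_ions(alpha_seqs[a], alpha_sites[a], beta_seq,
                                 beta_site, uaa, max_charge = 2L)
      theo_cache[[a]] <- th[th$charge == 1L | th$series == "M", , drop = FALSE]
    }
    em <- .sim_emit_spectrum(alpha_seqs[a], alpha_sites[a], beta_seq,
                             beta_site, uaa, zs[i], cfg, theo = theo_cache[[a]])
    scan <- sprintf("%s_scan_%05d", cfg$preset, i)
    spectra[[i]] <- spectrum(scan, em$precursor_mz, zs[i], em$mz, em$intensity)
    truth[[i]] <- data.frame(
      scan = scan, alpha_seq = alpha_seqs[a],
      alpha_protein = proteins$id[ceiling(match(a, true_idx) /
                                            cfg$peptides_per_protein)],
      alpha_site = alpha_sites[a], beta_seq = beta_seq, beta_site = beta_site,
      charge = zs[i], channels = paste(em$channels, collapse = ","),
      n_peaks = length(em$mz), stringsAsFactors = FALSE)
  }
  list(spectra = spectra, truth = do.call(rbind, truth), proteins = proteins,
       beta_protein = cfg$beta_protein, beta_uaa_site = cfg$beta_uaa_site,
       config = cfg)
}

#' Synthetic site-misassignment fixture
#'
#' One deterministic Uaa-His cross-link spectrum whose alpha chain also
#' contains a tyrosine. The spectrum carries strong cleavage-evidence ions
#' (internal b/y with the channel-A zero residual, and both released chains)
#' but lacks the regular b ions that discriminate the His site, reproducing
#' the condition under which regular-ion-only scoring prefers the tyrosine
#' site while cleavable-aware scoring recovers the histidine.
#'
#' @param uaa [uaa_chemistry()].
#' @return List with `spectrum`, `truth` (1-row data.frame), `proteins`
#'   (companion FASTA data.frame), `beta_protein`, `beta_uaa_site`.
#' @export
inject_misassignment_fixture <- function(uaa = uaa_chemistry()) {
  alpha_seq <- "TAYLHNVLER"   # Y at 3, true cross-link site H at 5
  alpha_site <- 5L
  beta <- generate_beta_peptides(.SIM_UAA_PROTEIN, .SIM_UAA_SITE,
                                 enzyme_rule("trypsin"), uaa, missed = 0L)
  beta_seq <- beta$sequence[1L]; beta_site <- beta$uaa_pos[1L]
  theo <- sim_theoretical_ions(alpha_seq, alpha_site, beta_seq, beta_site,
                               uaa, max_charge = 1L)
  keep <-
    (theo$chain == "beta" & theo$class %in% c("regular", "internal")) |
    (theo$chain == "alpha" & theo$series == "b" & theo$class == "regular" &
       theo$index <= 2L) |
    (theo$chain == "alpha" & theo$series == "y" & theo$class == "regular") |
    (theo$chain == "alpha" & theo$class == "internal") |
    (theo$class == "released_chain")
  theo <- theo[keep, , drop = FALSE]
  intens <- ifelse(theo$class == "regular" & theo$chain == "alpha" &
                     theo$series == "b", 2e3, 1e4)
  sp <- spectrum("misassign_fixture_1",
                 mz_from_neutral(crosslink_precursor_mass(
                   peptide_mass(alpha_seq), peptide_mass(beta_seq, uaa = uaa),
                   uaa), 3L),
                 3L, theo$mz, intens)
  proteins <- data.frame(
    id = "FIXPROT_1", header = "FIXPROT_1 synthetic",
    sequence = paste0(alpha_seq, "AGSVTELNDAK"), entrapment = FALSE,
    stringsAsFactors = FALSE)
  truth <- data.frame(scan = sp$scan, alpha_seq = alpha_seq,
                      alpha_protein = "FIXPROT_1", alpha_site = alpha_site,
                      beta_seq = beta_seq, beta_site = beta_site,
                      charge = 3L, channels = "A,B",
                      n_peaks = length(sp$mz), stringsAsFactors = FALSE)
  list(spectrum = sp, truth = truth, proteins = proteins,
       beta_protein = .SIM_UAA_PROTEIN, beta_uaa_site = .SIM_UAA_SITE)
}

#' Summarize a simulated dataset
#'
#' @param truth Ground-truth table from [simulate_dataset()].
#' @param cfg The [sim_config()] used.
#' @return List with constraint-satisfaction rate, charge distribution and
#'   peak-count summary.
#' @export
summarize_sim <- function(truth, cfg) {
  if (nrow(truth) == 0L)
    return(list(n = 0L, constraint_ok = numeric(0),
                charge_table = table(integer(0)), mean_peaks = 0))
  ok <- vapply(seq_len(nrow(truth)), function(i) {
    ch <- strsplit(truth$alpha_seq[i], "")[[1]]
    n_hk <- sum(ch %in% c("H", "K"))
    n_y <- sum(ch == "Y")
    switch(cfg$alpha_constraint,
           one_hk = n_hk == 1L && n_y == 0L,
           hk_and_y = n_hk >= 1L && n_y >= 1L,
           none = TRUE)
  }, logical(1))
  list(n = nrow(truth), constraint_ok = mean(ok),
       charge_table = table(truth$charge),
       mean_peaks = mean(truth$n_peaks))
}
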