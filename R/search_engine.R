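#' Build a mass-indexed alpha-peptide database
#'
#' Digests every protein in the database, enumerates variable modifications,
#' appends pseudo-reversed decoy peptides (see [build_decoys()]), and sorts
#' the combined set by neutral mass for binary-searchable precursor-window
#' lookups.
#'
#' @param proteins data.frame with `id` and `sequence` (see [read_fasta()]),
#'   or a path to a FASTA file.
#' @param enzyme An [enzyme_rule()].
#' @param mods List of variable [mod_spec()]s (default: oxidation on M).
#' @param max_var_mods Per-peptide cap on simultaneous variable mods.
#' @param decoys Append pseudo-reversed decoys (default TRUE).
#' @inheritParams digest
#' @return An `alpha_index` object: a mass-sorted peptide data.frame with a
#'   `mass` column, `mods` list-column and `is_decoy` flag.
#' @export
index_alpha_database <- function(proteins, enzyme, mods = list(mod_oxidation_m()),
                                 max_var_mods = 2L, decoys = TRUE,
                                 missed = 2L, min_length = 5L, max_length = 60L) {
  if (is.character(proteins)) proteins <- read_fasta(proteins)
  if (nrow(proteins) == 0L) stop("empty protein database")
  peps <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
    digest(proteins$sequence[i], enzyme, missed = missed,
           min_length = min_length, max_length = max_length,
           protein = proteins$id[i])))
  peps <- peps[!duplicated(peps$sequence), , drop = FALSE]
  if (length(mods)) {
    peps <- enumerate_variable_mods(peps, mods, cap = max_var_mods)
  } else {
    peps$mods <- replicate(nrow(peps), NULL, simplify = FALSE)
    peps$mod_label <- ""
  }
  peps$is_decoy <- FALSE
  peps$decoy_perturbed <- FALSE
  if (decoys) {
    dec <- build_decoys(peps)
    peps <- rbind(peps, dec)
  }
  peps$mass <- vapply(seq_len(nrow(peps)), function(i)
    peptide_mass(peps$sequence[i], peps$mods[[i]]), numeric(1))
  peps <- peps[order(peps$mass), , drop = FALSE]
  rownames(peps) <- NULL
  structure(list(peptides = peps), class = "alpha_index")
}

#' @export
print.alpha_index <- function(x, ...) {
  p <- x$peptides
  cat(sprintf("alpha-peptide index: %d peptide forms (%d target, %d decoy), mass %.2f-%.2f Da\n",
              nrow(p), sum(!p$is_decoy), sum(p$is_decoy),
              min(p$mass), max(p$mass)))
  invisible(x)
}

#' Pseudo-reversed decoy peptides
#'
#' Reverses each peptide sequence while holding the C-terminal residue fixed,
#' preserving enzymatic cleavage specificity and exact mass (same residue
#' composition). Peptides invariant under the rule (palindromes) are
#' perturbed by swapping their first two residues and flagged.
#'
#' @param peptides Peptide data.frame with `sequence` and optional `mods`
#'   list-column (per-residue delta vectors, reversed alongside).
#' @return Decoy peptide data.frame with `is_decoy = TRUE` and
#'   `decoy_perturbed` flag.
#' @export
build_decoys <- function(peptides) {
  dec <- peptides
  n <- nrow(dec)
  perturbed <- logical(n)
  for (i in seq_len(n)) {
    s <- dec$sequence[i]
    len <- nchar(s)
    body <- substr(s, 1L, len - 1L)
    rev_body <- paste(rev(.seq_chars(body)), collapse = "")
    ds <- paste0(rev_body, substr(s, len, len))
    if (ds == s && len >= 3L) {
      ch <- .seq_chars(ds)
      ch[1:2] <- ch[2:1]
      ds <- paste(ch, collapse = "")
      perturbed[i] <- TRUE
    }
    dec$sequence[i] <- ds
    md <- dec$mods[[i]]
    if (!is.null(md) && is.numeric(md))
      dec$mods[[i]] <- c(rev(md[seq_len(len - 1L)]), md[len])
  }
  dec$is_decoy <- TRUE
  dec$decoy_perturbed <- perturbed
  dec$protein <- paste0("DECOY_", dec$protein)
  dec
}

## ion class codes
.ION_CLASSES <- c("regular", "xl_containing", "released_chain", "internal",
                  "neutral_loss")

#' Theoretical fragment ions of a cross-link candidate
#'
#' Implements the full fragment-ion taxonomy of Uaa-mediated cross-links.
#' Both modes emit, for both chains, regular b/y ions (fragments not spanning
#' the cross-link site) and xl-containing b/y ions (fragment + intact partner
#' chain + delta_xl). When `mode = "cleavable"` and the alpha-site residue is
#' a cleavable partner (K/H by default), the sulfamate bond scission products
#' are added per cleavage channel: released-chain ions (intact linear chain +
#' channel residual), internal ions (b/y fragments spanning the link site
#' carrying only their chain's channel residual), and -SO3 neutral-loss
#' variants of species still bearing the sulfo group. A cleavable-mode
#' request for a Uaa-Tyr candidate falls back to the non-cleavable ion set
#' (the tyrosine sulfonate link does not protonate/fragment).
#'
#' @param alpha_seq,alpha_site Alpha peptide sequence and 1-based cross-link
#'   site (residue must be in `uaa$reactive`).
#' @param beta_seq,beta_site Beta peptide sequence (containing the Uaa
#'   symbol) and 1-based Uaa position.
#' @param uaa [uaa_chemistry()].
#' @param mode "cleavable" or "non_cleavable".
#' @param max_charge Fragment charges 1..max_charge (default 2).
#' @param alpha_mods,beta_mods Optional per-residue mass-delta vectors.
#' @return data.frame of ions: `chain` ("alpha"/"beta"), `series`
#'   ("b"/"y"/"M"), `index`, `charge`, `class`, `channel`, `neutral`, `mz`.
#' @export
generate_fragments <- function(alpha_seq, alpha_site, beta_seq, beta_site,
                               uaa, mode = c("cleavable", "non_cleavable"),
                               max_charge = 2L,
                               alpha_mods = NULL, beta_mods = NULL) {
  mode <- match.arg(mode)
  beta_seq <- canonicalize_uaa(beta_seq, uaa)
  rv_a <- residue_mass_vector(alpha_seq, alpha_mods)
  rv_b <- residue_mass_vector(beta_seq, beta_mods, uaa = uaa)
  na <- length(rv_a); nb <- length(rv_b)
  Ma <- sum(rv_a) + mass_h2o()
  Mb <- sum(rv_b) + mass_h2o()
  dxl <- uaa$delta_xl
  site_res <- substr(alpha_seq, alpha_site, alpha_site)
  if (!site_res %in% uaa$reactive)
    stop("alpha site residue '", site_res, "' is not a reactive partner")
  cleav <- identical(mode, "cleavable") && site_res %in% uaa$cleavable

  blk <- list(); k <- 0L
  add <- function(chain, series, index, neutral, class, channel = "") {
    if (!length(index)) return()
    k <<- k + 1L
    blk[[k]] <<- list(chain = rep(chain, length(index)),
                      series = rep(series, length(index)),
                      index = index, neutral = neutral,
                      class = rep(class, length(index)),
                      channel = rep(channel, length(index)))
  }

  chain_ions <- function(rv, M_self, M_partner, site, chain) {
    n <- length(rv)
    bcum <- cumsum(rv)                 # b_i neutral mass
    ycum <- cumsum(rev(rv)) + mass_h2o()  # y_j neutral mass
    ib <- seq_len(max(n - 1L, 0L))
    iy <- seq_len(max(n - 1L, 0L))
    reg_b <- ib[ib < site]
    xl_b  <- ib[ib >= site]
    reg_y <- iy[iy <= n - site]
    xl_y  <- iy[iy > n - site]
    add(chain, "b", reg_b, bcum[reg_b], "regular")
    add(chain, "y", reg_y, ycum[reg_y], "regular")
    add(chain, "b", xl_b, bcum[xl_b] + M_partner + dxl, "xl_containing")
    add(chain, "y", xl_y, ycum[xl_y] + M_partner + dxl, "xl_containing")
    list(bcum = bcum, ycum = ycum, xl_b = xl_b, xl_y = xl_y)
  }

  a <- chain_ions(rv_a, Ma, Mb, alpha_site, "alpha")
  b <- chain_ions(rv_b, Mb, Ma, beta_site, "beta")

  if (cleav) {
    for (chn in names(uaa$channels)) {
      ch <- uaa$channels[[chn]]
      da <- ch[["alpha"]]; db <- ch[["beta"]]
      ## released intact chains
      add("alpha", "M", 0L, Ma + da, "released_chain", chn)
      add("beta", "M", 0L, Mb + db, "released_chain", chn)
      ## internal ions: fragments spanning the link site, channel residual only
      add("alpha", "b", a$xl_b, cumsum(rv_a)[a$xl_b] + da, "internal", chn)
      add("alpha", "y", a$xl_y, (cumsum(rev(rv_a)) + mass_h2o())[a$xl_y] + da,
          "internal", chn)
      add("beta", "b", b$xl_b, cumsum(rv_b)[b$xl_b] + db, "internal", chn)
      add("beta", "y", b$xl_y, (cumsum(rev(rv_b)) + mass_h2o())[b$xl_y] + db,
          "internal", chn)
    }
  }

  ions <- data.frame(
    chain = unlist(lapply(blk, `[[`, "chain")),
    series = unlist(lapply(blk, `[[`, "series")),
    index = unlist(lapply(blk, `[[`, "index")),
    neutral = unlist(lapply(blk, `[[`, "neutral")),
    class = unlist(lapply(blk, `[[`, "class")),
    channel = unlist(lapply(blk, `[[`, "channel")),
    stringsAsFactors = FALSE)

  if (cleav && length(uaa$neutral_losses)) {
    ## -SO3 (etc.) variants of species still carrying the intact sulfo group:
    ## xl-containing ions, and released/internal species of the chain that
    ## retains the sulfo residual in its channel (residual > 0 means retention).
    sulfo <- ions$class == "xl_containing"
    for (chn in names(uaa$channels)) {
      ch <- uaa$channels[[chn]]
      retains <- if (ch[["beta"]] >= ch[["alpha"]]) "beta" else "alpha"
      sulfo <- sulfo | (ions$channel == chn & ions$chain == retains &
                          ions$class %in% c("released_chain", "internal"))
    }
    for (nl in uaa$neutral_losses) {
      v <- ions[sulfo, , drop = FALSE]
      if (nrow(v)) {
        v$neutral <- v$neutral + nl
        v$class <- "neutral_loss"
        ions <- rbind(ions, v)
      }
    }
  }

  ## expand charges
  charges <- seq_len(max_charge)
  nions <- nrow(ions)
  ions <- ions[rep(seq_len(nions), times = length(charges)), , drop = FALSE]
  ions$charge <- rep(charges, each = nions)
  ions$mz <- mz_from_neutral(ions$neutral, ions$charge)
  rownames(ions) <- NULL
  ions
}

#' Match experimental peaks to theoretical ions
#'
#' Greedy nearest-within-tolerance assignment: all (ion, peak) pairs within
#' the ppm tolerance are ranked by absolute ppm error (ties broken toward
#' higher peak intensity), then assigned greedily so that each peak and each
#' theoretical ion is used at most once.
#'
#' @param sp A `spectrum` (peaks sorted by m/z).
#' @param theo_mz Theoretical m/z vector.
#' @param tol_ppm Fragment tolerance in ppm (default 20).
#' @return data.frame with `ion` (index into `theo_mz`), `peak` (index into
#'   the spectrum peak list), and `ppm` error.
#' @export
match_peaks <- function(sp, theo_mz, tol_ppm = 20) {
  pk <- sp$mz
  if (!length(pk) || !length(theo_mz))
    return(data.frame(ion = integer(0), peak = integer(0), ppm = numeric(0)))
  tol <- tol_ppm * 1e-6
  lo <- findInterval(theo_mz * (1 - tol), pk)
  hi <- findInterval(theo_mz * (1 + tol), pk)
  cnt <- hi - lo
  has <- cnt > 0L
  if (!any(has))
    return(data.frame(ion = integer(0), peak = integer(0), ppm = numeric(0)))
  ion_idx <- rep(which(has), times = cnt[has])
  peak_idx <- sequence(cnt[has]) + rep(lo[has], times = cnt[has])
  ppm <- (pk[peak_idx] - theo_mz[ion_idx]) / theo_mz[ion_idx] * 1e6
  keep <- abs(ppm) <= tol_ppm
  ion_idx <- ion_idx[keep]; peak_idx <- peak_idx[keep]; ppm <- ppm[keep]
  if (!length(ion_idx))
    return(data.frame(ion = integer(0), peak = integer(0), ppm = numeric(0)))
  o <- order(abs(ppm), -sp$intensity[peak_idx], ion_idx)
  ion_idx <- ion_idx[o]; peak_idx <- peak_idx[o]; ppm <- ppm[o]
  used_ion <- logical(length(theo_mz))
  used_peak <- logical(length(pk))
  sel <- logical(length(ion_idx))
  for (t in seq_along(ion_idx)) {
    if (!used_ion[ion_idx[t]] && !used_peak[peak_idx[t]]) {
      sel[t] <- TRUE
      used_ion[ion_idx[t]] <- TRUE
      used_peak[peak_idx[t]] <- TRUE
    }
  }
  data.frame(ion = ion_idx[sel], peak = peak_idx[sel], ppm = ppm[sel])
}

.longest_run <- function(idx) {
  if (!length(idx)) return(0L)
  idx <- sort(unique(idx))
  r <- rle(c(1L, diff(idx)))
  max(c(1L, r$lengths[r$values == 1L] + 1L))
}

#' Coarse score of a matched candidate
#'
#' Weighted log-intensity sum over matched ions plus a beta-chain series
#' coverage bonus:
#' score = sum over matched ions of w_class * ln(1 + I/I_max) +
#' lambda * (fraction of beta-chain backbone cleavage ions matched).
#' Class weights default to 1 for regular and xl-containing, `w_released`
#' and `w_internal` for the cleavage-evidence classes; the bonus rewards
#' contiguous explanation of the Uaa-bearing chain.
#'
#' @param ions Theoretical ion table from [generate_fragments()].
#' @param matches Match table from [match_peaks()].
#' @param sp The matched `spectrum`.
#' @param w_released,w_internal Class weights (default 1).
#' @param lambda Beta-series coverage weight (default 0.5).
#' @return List with `score`, per-class matched counts `n` and summed
#'   intensities `i`, `frac_beta`, longest consecutive runs, and the count of
#'   cleavable-evidence ions.
#' @export
coarse_score <- function(ions, matches, sp, w_released = 1, w_internal = 1,
                         lambda = 0.5) {
  weights <- c(regular = 1, xl_containing = 1, released_chain = w_released,
               internal = w_internal, neutral_loss = 0.5)
  imax <- if (length(sp$intensity)) max(sp$intensity) else 1
  m_ions <- ions[matches$ion, , drop = FALSE]
  rel <- sp$intensity[matches$peak] / imax
  n <- i <- stats::setNames(numeric(length(.ION_CLASSES)), .ION_CLASSES)
  for (cl in .ION_CLASSES) {
    sel <- m_ions$class == cl
    n[cl] <- sum(sel)
    i[cl] <- sum(sp$intensity[matches$peak[sel]])
  }
  ## beta backbone series coverage (distinct series/index over regular+xl b/y)
  beta_bb <- ions$chain == "beta" & ions$series %in% c("b", "y") &
    ions$class %in% c("regular", "xl_containing")
  beta_keys <- unique(paste(ions$series[beta_bb], ions$index[beta_bb]))
  mb <- m_ions$chain == "beta" & m_ions$series %in% c("b", "y")
  beta_matched_keys <- unique(paste(m_ions$series[mb], m_ions$index[mb]))
  frac_beta <- if (length(beta_keys))
    length(intersect(beta_matched_keys, beta_keys)) / length(beta_keys) else 0
  score <- sum(weights[m_ions$class] * log1p(rel)) + lambda * frac_beta
  ma <- m_ions$chain == "alpha" & m_ions$series %in% c("b", "y")
  list(score = score, n = n, i = i, frac_beta = frac_beta,
       n_beta_ions = length(beta_matched_keys),
       run_alpha = .longest_run(m_ions$index[ma]),
       run_beta = .longest_run(m_ions$index[mb]),
       n_cleavable = sum(n[c("released_chain", "internal")]))
}

#' Search spectra for Uaa cross-linked peptides
#'
#' For every spectrum, pairs each beta-peptide form with alpha peptides whose
#' mass fits `M_precursor - M_beta - delta_xl` within the precursor
#' tolerance, enumerates every eligible alpha cross-link site (K/H/Y),
#' generates the theoretical ion set for the requested mode, matches peaks
#' and coarse-scores each candidate. The top `topk` candidates per spectrum
#' (targets and decoys competing) are retained.
#'
#' @param spectra List of `spectrum` objects.
#' @param beta_peptides data.frame from [generate_beta_peptides()].
#' @param index An `alpha_index` from [index_alpha_database()].
#' @param uaa [uaa_chemistry()].
#' @param mode "cleavable" or "non_cleavable".
#' @param prec_tol_ppm Precursor tolerance in ppm (default 10).
#' @param frag_tol_ppm Fragment tolerance in ppm (default 20).
#' @param topk Candidates retained per spectrum (default 5).
#' @param min_beta_ions Minimum distinct matched beta backbone ions for a PSM
#'   to be kept (default 3).
#' @param max_frag_charge Cap on fragment charge; the effective cap is
#'   `min(precursor charge - 1, max_frag_charge)` (default 3).
#' @param w_released,w_internal,lambda Coarse-score parameters
#'   (see [coarse_score()]).
#' @return PSM data.frame, one row per retained candidate, with match-count,
#'   intensity and feature columns, `rank` within spectrum by coarse score,
#'   and `is_decoy`.
#' @export
search_spectra <- function(spectra, beta_peptides, index, uaa,
                           mode = c("cleavable", "non_cleavable"),
                           prec_tol_ppm = 10, frag_tol_ppm = 20, topk = 5L,
                           min_beta_ions = 3L, max_frag_charge = 3L,
                           w_released = 1, w_internal = 1, lambda = 0.5) {
  mode <- match.arg(mode)
  peps <- index$peptides
  beta_mass <- vapply(seq_len(nrow(beta_peptides)), function(i)
    peptide_mass(beta_peptides$sequence[i], beta_peptides$mods[[i]], uaa = uaa),
    numeric(1))
  rows <- list(); nr <- 0L
  for (sp in spectra) {
    if (is.na(sp$charge)) next
    M <- precursor_neutral_mass(sp)
    tol_da <- M * prec_tol_ppm * 1e-6
    cand_rows <- list(); nc <- 0L
    seen <- character(0)
    for (bi in seq_len(nrow(beta_peptides))) {
      need <- M - beta_mass[bi] - uaa$delta_xl
      lo <- findInterval(need - tol_da, peps$mass)
      hi <- findInterval(need + tol_da, peps$mass)
      if (hi <= lo) next
      for (ai in (lo + 1L):hi) {
        aseq <- peps$sequence[ai]
        sites <- which(.seq_chars(aseq) %in% uaa$reactive)
        if (!length(sites)) next
        prec_mass <- crosslink_precursor_mass(peps$mass[ai], beta_mass[bi], uaa)
        err_ppm <- (M - prec_mass) / prec_mass * 1e6
        for (site in sites) {
          key <- paste(aseq, peps$mod_label[ai], beta_peptides$sequence[bi],
                       beta_peptides$mod_label[bi], site, sep = "|")
          if (key %in% seen) next
          seen <- c(seen, key)
          ions <- generate_fragments(
            aseq, site, beta_peptides$sequence[bi], beta_peptides$uaa_pos[bi],
            uaa, mode = mode,
            max_charge = max(1L, min(sp$charge - 1L, max_frag_charge)),
            alpha_mods = peps$mods[[ai]], beta_mods = beta_peptides$mods[[bi]])
          mt <- match_peaks(sp, ions$mz, frag_tol_ppm)
          sc <- coarse_score(ions, mt, sp, w_released, w_internal, lambda)
          if (sc$n_beta_ions < min_beta_ions) next
          if (sum(sc$n) == 0L) next
          nc <- nc + 1L
          cand_rows[[nc]] <- data.frame(
            scan = sp$scan, charge = sp$charge, prec_mass = M,
            alpha_seq = aseq, alpha_protein = peps$protein[ai],
            alpha_site = site, alpha_len = nchar(aseq),
            alpha_missed = peps$missed[ai],
            beta_seq = beta_peptides$sequence[bi],
            beta_site = beta_peptides$uaa_pos[bi],
            beta_len = nchar(beta_peptides$sequence[bi]),
            mod_label = paste0(peps$mod_label[ai], "/",
                               beta_peptides$mod_label[bi]),
            prec_error_ppm = err_ppm, is_decoy = peps$is_decoy[ai],
            coarse = sc$score,
            n_regular = sc$n[["regular"]], n_xl = sc$n[["xl_containing"]],
            n_released = sc$n[["released_chain"]],
            n_internal = sc$n[["internal"]],
            n_neutral_loss = sc$n[["neutral_loss"]],
            i_regular = sc$i[["regular"]], i_xl = sc$i[["xl_containing"]],
            i_released = sc$i[["released_chain"]],
            i_internal = sc$i[["internal"]],
            i_neutral_loss = sc$i[["neutral_loss"]],
            frac_beta = sc$frac_beta, run_alpha = sc$run_alpha,
            run_beta = sc$run_beta, n_cleavable = sc$n_cleavable,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (nc == 0L) next
    cand <- do.call(rbind, cand_rows)
    o <- order(-cand$coarse, cand$is_decoy, cand$alpha_seq, cand$alpha_site)
    cand <- cand[o[seq_len(min(topk, nrow(cand)))], , drop = FALSE]
    cand$rank <- seq_len(nrow(cand))
    nr <- nr + 1L
    rows[[nr]] <- cand
  }
  if (nr == 0L) return(.empty_psms())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

.empty_psms <- function() {
  data.frame(scan = character(0), charge = integer(0), prec_mass = numeric(0),
             alpha_seq = character(0), alpha_protein = character(0),
             alpha_site = integer(0), alpha_len = integer(0),
             alpha_missed = integer(0), beta_seq = character(0),
             beta_site = integer(0), beta_len = integer(0),
             mod_label = character(0), prec_error_ppm = numeric(0),
             is_decoy = logical(0), coarse = numeric(0),
             n_regular = numeric(0), n_xl = numeric(0), n_released = numeric(0),
             n_internal = numeric(0), n_neutral_loss = numeric(0),
             i_regular = numeric(0), i_xl = numeric(0), i_released = numeric(0),
             i_internal = numeric(0), i_neutral_loss = numeric(0),
             frac_beta = numeric(0), run_alpha = integer(0),
             run_beta = integer(0), n_cleavable = numeric(0), rank = integer(0),
             stringsAsFactors = FALSE)
}
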