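#' Per-PSM fragment-intensity ratios
#'
#' Classifies matched ion intensities and computes the two diagnostic
#' ratios: `ratio1` = (internal + cross-link-bond-fragmented released
#' intensity) / regular intensity, and `ratio2` = internal / regular
#' intensity. Ratios are NA-flagged when no regular intensity was matched.
#'
#' @param psms PSM data.frame with per-class intensity columns
#'   (`i_regular`, `i_released`, `i_internal`) and `alpha_seq`/`alpha_site`.
#' @return data.frame of per-PSM stats with `site_residue` in H/K/Y.
#' @export
per_psm_ratios <- function(psms) {
  i_reg <- psms$i_regular
  ratio1 <- ifelse(i_reg > 0, (psms$i_internal + psms$i_released) / i_reg, NA_real_)
  ratio2 <- ifelse(i_reg > 0, psms$i_internal / i_reg, NA_real_)
  ## zero cleavage-evidence intensity with regular evidence present is a true 0
  data.frame(
    scan = psms$scan, alpha_seq = psms$alpha_seq, alpha_site = psms$alpha_site,
    beta_seq = psms$beta_seq, mod_label = psms$mod_label,
    site_residue = substr(psms$alpha_seq, psms$alpha_site, psms$alpha_site),
    i_regular = i_reg, i_released = psms$i_released,
    i_internal = psms$i_internal,
    ratio1 = ratio1, ratio2 = ratio2,
    score = if (!is.null(psms$rescore)) psms$rescore else psms$coarse,
    undefined = i_reg == 0,
    stringsAsFactors = FALSE
  )
}

#' Aggregate intensity ratios by cross-linked residue type
#'
#' Deduplicates to the best-scoring PSM per unique cross-linked peptide
#' (alpha sequence, beta sequence, alpha site, modifications) before
#' aggregating, then reports box-plot summaries (median, quartiles,
#' minimum and maximum as whiskers) per residue class H/K/Y.
#'
#' @param stats Output of [per_psm_ratios()].
#' @return List with `summary` (data.frame per residue class) and `stats`
#'   (the deduplicated per-peptide rows).
#' @export
aggregate_by_residue <- function(stats) {
  if (nrow(stats) == 0L) stop("no fragment statistics to aggregate")
  key <- paste(stats$alpha_seq, stats$beta_seq, stats$alpha_site,
               stats$mod_label, sep = "|")
  o <- order(key, -stats$score)
  dd <- stats[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  classes <- c("H", "K", "Y")
  rows <- lapply(classes, function(cl) {
    v1 <- dd$ratio1[dd$site_residue == cl & !dd$undefined]
    v2 <- dd$ratio2[dd$site_residue == cl & !dd$undefined]
    qs <- function(v) if (length(v)) stats::quantile(v, c(0, .25, .5, .75, 1),
                                                     names = FALSE)
                      else rep(NA_real_, 5)
    q1 <- qs(v1); q2 <- qs(v2)
    data.frame(residue = cl, n = length(v1),
               ratio1_min = q1[1], ratio1_q25 = q1[2], ratio1_median = q1[3],
               ratio1_q75 = q1[4], ratio1_max = q1[5],
               ratio2_min = q2[1], ratio2_q25 = q2[2], ratio2_median = q2[3],
               ratio2_q75 = q2[4], ratio2_max = q2[5],
               stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), stats = dd)
}
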