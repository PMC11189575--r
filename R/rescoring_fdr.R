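.FEATURE_COLS <- c("coarse", "n_regular", "n_xl", "n_released", "n_internal",
                   "n_neutral_loss", "i_regular", "i_xl", "i_released",
                   "i_internal", "frac_beta", "run_alpha", "run_beta",
                   "n_cleavable", "alpha_len", "beta_len", "charge",
                   "alpha_missed")

.psm_features <- function(psms) {
  x <- as.matrix(psms[, .FEATURE_COLS, drop = FALSE])
  x <- cbind(x, abs_ppm = abs(psms$prec_error_ppm))
  itot <- rowSums(x[, c("i_regular", "i_xl", "i_released", "i_internal"),
                    drop = FALSE])
  itot[itot == 0] <- 1
  x <- cbind(x,
             f_reg = x[, "i_regular"] / itot,
             f_cleav = (x[, "i_released"] + x[, "i_internal"]) / itot)
  x
}

#' Semi-supervised linear rescoring of PSMs
#'
#' Percolator-style iterative rescoring with a deterministic linear
#' discriminant (least squares on +/-1 class labels, equivalent to Fisher's
#' LDA direction). Positives are initialized as targets passing a 1%
#' coarse-score FDR, negatives as all decoys; features are standardized
#' (zero-variance features dropped with a note); the model is refit for 3
#' iterations under 3-fold cross-validation, so no PSM is ever scored by a
#' model trained on it. With too few PSMs or no decoys the coarse score is
#' returned unchanged with a warning.
#'
#' @param psms PSM data.frame from [search_spectra()].
#' @param seed Integer seed controlling the cross-validation fold split.
#' @param iterations,folds Iteration and fold counts (default 3 and 3).
#' @param init_fdr FDR level used to pick initial/updated positives
#'   (default 0.01).
#' @param min_psms Minimum PSM count for rescoring (default 50).
#' @return `psms` with a `rescore` column added.
#' @export
rescore_psms <- function(psms, seed = 42L, iterations = 3L, folds = 3L,
                         init_fdr = 0.01, min_psms = 50L) {
  psms$rescore <- psms$coarse
  if (nrow(psms) < min_psms || !any(psms$is_decoy) || !any(!psms$is_decoy)) {
    warning("too few PSMs or missing target/decoy classes; ",
            "falling back to the coarse score")
    return(psms)
  }
  x <- .psm_features(psms)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 1e-12
  if (!all(keep))
    message("dropping zero-variance feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  x <- scale(x[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
  n <- nrow(x)
  ## deterministic fold assignment by spectrum, so candidate PSMs of one
  ## spectrum stay in one fold
  scans <- unique(psms$scan)
  rng <- .seeded_rng(seed)
  fold_of_scan <- stats::setNames(
    (order(rng$runif(length(scans))) %% folds) + 1L, scans)
  fold <- fold_of_scan[psms$scan]

  score <- psms$coarse
  for (it in seq_len(iterations)) {
    ## positives come from rank-1 PSMs only (best current score per scan):
    ## lower-ranked same-spectrum candidates are wrong by construction and
    ## must not enter the positive class
    r1 <- !duplicated(psms$scan[order(psms$scan, -score, psms$is_decoy)])
    r1 <- r1[order(order(psms$scan, -score, psms$is_decoy))]
    q <- rep(1, n)
    q[r1] <- .qvalues_from_scores(score[r1], psms$is_decoy[r1])
    pos <- r1 & !psms$is_decoy & q <= init_fdr
    if (sum(pos) < 5L) {  # degenerate start: take the top decile of targets
      thr <- stats::quantile(score[r1 & !psms$is_decoy], 0.9, names = FALSE)
      pos <- r1 & !psms$is_decoy & score >= thr
    }
    neg <- psms$is_decoy
    new_score <- score
    for (f in seq_len(folds)) {
      train <- fold != f & (pos | neg)
      if (sum(pos & train) < 2L || sum(neg & train) < 2L) next
      y <- ifelse(pos[train], 1, -1)
      xt <- cbind(1, x[train, , drop = FALSE])
      fit <- stats::lm.fit(xt, y)
      w <- fit$coefficients
      w[is.na(w)] <- 0
      new_score[fold == f] <- cbind(1, x[fold == f, , drop = FALSE]) %*% w
    }
    score <- as.numeric(new_score)
  }
  psms$rescore <- score
  psms
}

## tiny deterministic RNG wrapper that does not disturb the global stream
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  env$runif <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(env$state)
    env$state <- (env$state * 69069L + 1L) %% 2147483562L
    stats::runif(n)
  }
  env
}

.qvalues_from_scores <- function(score, is_decoy, plus_one = FALSE) {
  o <- order(-score, !is_decoy)  # at ties, decoys counted first (conservative)
  dec <- cumsum(is_decoy[o])
  tgt <- cumsum(!is_decoy[o])
  fdr <- ifelse(tgt == 0, 0, (dec + if (plus_one) 1 else 0) / tgt)
  fdr <- pmin(fdr, 1)
  q <- rev(cummin(rev(fdr)))
  out <- numeric(length(score))
  out[o] <- q
  out
}

#' Target-decoy q-values for PSMs
#'
#' Sorts by score descending; raw FDR at score s is
#' (number of decoys >= s) / (number of targets >= s) (0 when no targets);
#' the q-value is the running minimum from the bottom of the list. Decoys at
#' a tied score are counted before targets (conservative).
#'
#' @param psms PSM data.frame with `is_decoy` and a score column.
#' @param score_col Score column to rank by (default `"rescore"`, falling
#'   back to `"coarse"` if absent).
#' @param plus_one Use the +1-corrected conservative decoy count.
#' @return `psms` with a `qvalue` column.
#' @export
compute_qvalues <- function(psms, score_col = "rescore", plus_one = FALSE) {
  if (is.null(psms[[score_col]])) score_col <- "coarse"
  psms$qvalue <- if (nrow(psms))
    .qvalues_from_scores(psms[[score_col]], psms$is_decoy, plus_one)
  else numeric(0)
  psms
}

#' Keep the rank-1 PSM per spectrum
#'
#' @param psms PSM data.frame.
#' @param score_col Column to rank by (default `"rescore"`).
#' @return One row per scan: the best-scoring candidate (decoys compete).
#' @export
rank1_psms <- function(psms, score_col = "rescore") {
  if (is.null(psms[[score_col]])) score_col <- "coarse"
  if (nrow(psms) == 0L) return(psms)
  o <- order(psms$scan, -psms[[score_col]], psms$is_decoy, psms$alpha_seq,
             psms$alpha_site)
  p <- psms[o, , drop = FALSE]
  p <- p[!duplicated(p$scan), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Filter PSMs at a PSM-level FDR threshold
#'
#' Computes q-values on the rank-1 PSMs and returns the target PSMs passing
#' the threshold (default 5%, the reporting level used for Uaa cross-link
#' identifications).
#'
#' @param psms PSM data.frame (all ranks; rank-1 is selected internally).
#' @param fdr q-value threshold (default 0.05).
#' @param score_col Score column (default `"rescore"`).
#' @inheritParams compute_qvalues
#' @return Filtered target PSM data.frame with `qvalue`.
#' @export
filter_psms <- function(psms, fdr = 0.05, score_col = "rescore",
                        plus_one = FALSE) {
  r1 <- rank1_psms(psms, score_col)
  r1 <- compute_qvalues(r1, score_col, plus_one)
  out <- r1[!r1$is_decoy & r1$qvalue <= fdr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate identifications against simulator ground truth
#'
#' Precision and recall at two levels: peptide-pair (alpha and beta
#' sequences correct) and site (sequences and alpha cross-link site
#' correct). An empty filtered set reports precision 1.0 with `n = 0`.
#'
#' @param filtered Filtered target PSMs (e.g. from [filter_psms()]).
#' @param truth Ground-truth data.frame with `scan`, `alpha_seq`,
#'   `alpha_site`, `beta_seq`.
#' @return List with `n`, `pair_precision`, `site_precision`, `pair_recall`,
#'   `site_recall`, and the per-PSM correctness flags.
#' @export
evaluate_against_truth <- function(filtered, truth) {
  if (nrow(filtered) == 0L) {
    return(list(n = 0L, pair_precision = 1.0, site_precision = 1.0,
                pair_recall = 0.0, site_recall = 0.0,
                pair_correct = logical(0), site_correct = logical(0)))
  }
  idx <- match(filtered$scan, truth$scan)
  if (anyNA(idx)) stop("scan id(s) missing from ground truth: ",
                       paste(utils::head(filtered$scan[is.na(idx)]), collapse = ", "))
  tr <- truth[idx, , drop = FALSE]
  pair <- filtered$alpha_seq == tr$alpha_seq &
    canonicalize_uaa(filtered$beta_seq) == canonicalize_uaa(tr$beta_seq)
  site <- pair & filtered$alpha_site == tr$alpha_site
  list(n = nrow(filtered),
       pair_precision = mean(pair),
       site_precision = mean(site),
       pair_recall = sum(pair) / nrow(truth),
       site_recall = sum(site) / nrow(truth),
       pair_correct = pair, site_correct = site)
}
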