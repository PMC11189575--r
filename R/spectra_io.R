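#' Construct a tandem spectrum object
#'
#' @param scan Scan identifier (string).
#' @param precursor_mz Precursor m/z.
#' @param charge Precursor charge (integer, NA if unknown).
#' @param mz,intensity Peak arrays; sorted by m/z on construction.
#' @param rt Retention time in seconds (optional).
#' @return A `spectrum` object (list).
#' @export
spectrum <- function(scan, precursor_mz, charge, mz, intensity, rt = NA_real_) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  o <- order(mz)
  structure(list(scan = as.character(scan),
                 precursor_mz = precursor_mz,
                 charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
                 mz = mz[o], intensity = intensity[o], rt = rt),
            class = "spectrum")
}

#' Neutral precursor mass of a spectrum
#' @param sp A `spectrum`.
#' @return Neutral monoisotopic mass (Da); NA if the charge is unknown.
#' @export
precursor_neutral_mass <- function(sp) {
  if (is.na(sp$charge)) return(NA_real_)
  neutral_from_mz(sp$precursor_mz, sp$charge)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum %s: precursor %.4f m/z (z=%s), %d peaks\n",
              x$scan, x$precursor_mz,
              ifelse(is.na(x$charge), "?", x$charge), length(x$mz)))
  invisible(x)
}

#' Read centroided tandem spectra
#'
#' MGF is parsed natively (TITLE/PEPMASS/CHARGE/RTINSECONDS keys; charges
#' "3+" and "3" both accepted). mzML is read through the `mzR` package and
#' restricted to centroided MS2 with recorded precursor charge. An optional
#' precursor charge window drops spectra outside it, reproducing the
#' acquisition filter used for enriched cross-linked samples (charge 3-6).
#'
#' @param path Input file.
#' @param format "mgf" or "mzml"; default guessed from the extension.
#' @param charge_min,charge_max Optional inclusive charge window; NULL = off.
#' @param keep_unknown_charge Keep spectra with unknown charge when a window
#'   is enabled (default FALSE).
#' @return List of `spectrum` objects, with attributes `n_read` and
#'   `n_retained`.
#' @export
read_spectra <- function(path, format = NULL, charge_min = NULL,
                         charge_max = NULL, keep_unknown_charge = FALSE) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("mzml", "xml")) "mzml" else "mgf"
  }
  sps <- switch(tolower(format),
    mgf = .read_mgf(path),
    mzml = .read_mzml(path),
    stop("unknown spectra format: ", format)
  )
  n_read <- length(sps)
  if (!is.null(charge_min) || !is.null(charge_max)) {
    lo <- if (is.null(charge_min)) 1L else charge_min
    hi <- if (is.null(charge_max)) .Machine$integer.max else charge_max
    keep <- vapply(sps, function(s) {
      if (is.na(s$charge)) keep_unknown_charge else (s$charge >= lo && s$charge <= hi)
    }, logical(1))
    sps <- sps[keep]
  }
  message(sprintf("read %d spectra, retained %d", n_read, length(sps)))
  attr(sps, "n_read") <- n_read
  attr(sps, "n_retained") <- length(sps)
  sps
}

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else paste0("scan_", i)
    pm <- if ("PEPMASS" %in% keys)
      as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1]][1])
    else stop("malformed MGF: spectrum '", title, "' lacks PEPMASS")
    ch <- NA_integer_
    if ("CHARGE" %in% keys) {
      chs <- vals[match("CHARGE", keys)]
      ch <- as.integer(sub("\\+$", "", trimws(chs)))
    }
    rt <- if ("RTINSECONDS" %in% keys)
      as.numeric(vals[match("RTINSECONDS", keys)]) else NA_real_
    pk <- block[!kv]
    pk <- pk[nzchar(trimws(pk))]
    if (length(pk)) {
      m <- do.call(rbind, strsplit(trimws(pk), "\\s+"))
      mz <- as.numeric(m[, 1]); it <- as.numeric(m[, 2])
      if (anyNA(mz) || anyNA(it))
        stop("malformed MGF peak list in spectrum '", title, "'")
    } else {
      mz <- numeric(0); it <- numeric(0)
    }
    out[[i]] <- spectrum(title, pm, ch, mz, it, rt)
  }
  out
}

.read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  ms2 <- which(hdr$msLevel == 2L)
  out <- vector("list", length(ms2))
  for (k in seq_along(ms2)) {
    i <- ms2[k]
    if (!is.na(hdr$centroided[i]) && !hdr$centroided[i])
      stop("mzML contains profile-mode MS2 (scan ", hdr$acquisitionNum[i],
           "); only centroided data are supported")
    pk <- mzR::peaks(h, i)
    ch <- hdr$precursorCharge[i]
    out[[k]] <- spectrum(
      scan = as.character(hdr$acquisitionNum[i]),
      precursor_mz = hdr$precursorMZ[i],
      charge = if (is.null(ch) || is.na(ch) || ch == 0) NA_integer_ else ch,
      mz = pk[, 1], intensity = pk[, 2],
      rt = hdr$retentionTime[i]
    )
  }
  out
}

#' Write spectra to an MGF file
#' @param spectra List of `spectrum` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$scan), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.na(sp$charge)) writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    if (!is.na(sp$rt)) writeLines(sprintf("RTINSECONDS=%.3f", sp$rt), con)
    if (length(sp$mz))
      writeLines(sprintf("%.6f %.6f", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Parse a cross-link notation string
#'
#' Notation `"ALPHA(i)-BETA(j)"` where `i` is the 1-based alpha cross-link
#' site and `j` the 1-based Uaa position in the beta chain. The chain
#' containing the Uaa symbol (U or J) is assigned beta regardless of order.
#'
#' @param x Notation string, e.g. `"TSVDNAFNHE(9)-ILHLPNLNJE(9)"`.
#' @return List with `alpha_seq`, `alpha_site`, `beta_seq`, `beta_site`.
#' @export
parse_crosslink_notation <- function(x) {
  m <- regmatches(x, regexec("^([A-Z]+)\\((\\d+)\\)-([A-Z]+)\\((\\d+)\\)$", x))[[1]]
  if (length(m) != 5L) stop("notation does not match 'SEQ(int)-SEQ(int)': ", x)
  seq1 <- m[2]; site1 <- as.integer(m[3])
  seq2 <- m[4]; site2 <- as.integer(m[5])
  has_uaa <- function(s) grepl("[UJ]", s)
  u1 <- has_uaa(seq1); u2 <- has_uaa(seq2)
  if (u1 == u2)
    stop("exactly one chain must contain the Uaa symbol (U/J): ", x)
  if (u1) { tmp <- seq1; seq1 <- seq2; seq2 <- tmp
            tmps <- site1; site1 <- site2; site2 <- tmps }
  if (site1 > nchar(seq1) || site2 > nchar(seq2) || site1 < 1L || site2 < 1L)
    stop("site out of range in notation: ", x)
  if (!substr(seq2, site2, site2) %in% c("U", "J"))
    stop("beta site does not point at the Uaa symbol: ", x)
  list(alpha_seq = seq1, alpha_site = site1, beta_seq = seq2, beta_site = site2)
}

#' Serialize a cross-link as notation
#' @param alpha_seq,alpha_site,beta_seq,beta_site Components as returned by
#'   [parse_crosslink_notation()].
#' @return Notation string `"ALPHA(i)-BETA(j)"`.
#' @export
format_crosslink_notation <- function(alpha_seq, alpha_site, beta_seq, beta_site) {
  sprintf("%s(%d)-%s(%d)", alpha_seq, alpha_site, beta_seq, beta_site)
}

#' Write a PSM table to TSV
#'
#' One row per PSM: scan, alpha sequence/protein/site, beta sequence/site,
#' notation string, precursor error (ppm), coarse and rescored scores,
#' q-value, and per-ion-class matched counts.
#'
#' @param psms PSM data.frame (see [search_spectra()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(psms, path) {
  cols <- c("scan", "alpha_seq", "alpha_protein", "alpha_site", "beta_seq",
            "beta_site", "notation", "prec_error_ppm", "coarse", "rescore",
            "qvalue", "is_decoy", "n_regular", "n_xl", "n_released",
            "n_internal", "n_neutral_loss", "mod_label")
  df <- psms
  if (nrow(df) > 0 && is.null(df$notation))
    df$notation <- format_crosslink_notation(df$alpha_seq, df$alpha_site,
                                             df$beta_seq, df$beta_site)
  for (cl in cols) if (is.null(df[[cl]])) df[[cl]] <- rep(NA, nrow(df))
  ## canonical columns first, then any remaining scalar columns (feature
  ## values etc.), so rescoring can be rerun from the written table
  extra <- setdiff(names(df), cols)
  extra <- extra[!vapply(df[extra], is.list, logical(1))]
  utils::write.table(df[, c(cols, extra), drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PSM TSV written by [write_results()]
#' @param path Input TSV path.
#' @return PSM data.frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(scan = "character"))
}
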