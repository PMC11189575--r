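#' Proteolytic enzyme rule
#'
#' Built-in rules: `"trypsin"` (after K/R, not before P), `"glu-c"` (after E;
#' after D as well when `gluc_de = TRUE`), `"chymotrypsin"` (after F/W/Y/L,
#' not before P). All cleave C-terminally to the listed residues.
#'
#' @param name One of "trypsin", "glu-c", "chymotrypsin", or "custom".
#' @param cleave_after Residues cut C-terminally (custom rules).
#' @param no_cleave_before Residues blocking cleavage on the C-terminal side
#'   (custom rules).
#' @param gluc_de For Glu-C, also cleave after D.
#' @return An `enzyme_rule` object.
#' @export
enzyme_rule <- function(name = c("trypsin", "glu-c", "chymotrypsin", "custom"),
                        cleave_after = NULL, no_cleave_before = NULL,
                        gluc_de = FALSE) {
  name <- match.arg(name)
  rule <- switch(name,
    trypsin      = list(after = c("K", "R"), block = "P"),
    `glu-c`      = list(after = if (gluc_de) c("E", "D") else "E",
                        block = character(0)),
    chymotrypsin = list(after = c("F", "W", "Y", "L"), block = "P"),
    custom       = list(after = cleave_after,
                        block = if (is.null(no_cleave_before)) character(0)
                                else no_cleave_before)
  )
  if (length(rule$after) == 0L) stop("cleavage residue set must be non-empty")
  structure(list(name = name, cleave_after = rule$after,
                 no_cleave_before = rule$block),
            class = "enzyme_rule")
}

## 0-based cleavage point positions (after residue i) for a sequence.
.cleavage_points <- function(chars, rule) {
  n <- length(chars)
  if (n <= 1L) return(integer(0))
  i <- seq_len(n - 1L)
  hit <- chars[i] %in% rule$cleave_after &
    !(chars[i + 1L] %in% rule$no_cleave_before)
  i[hit]
}

#' In-silico enzymatic digestion
#'
#' Enumerates all peptides respecting the cleavage rule, the missed-cleavage
#' cap, and the length window. For sequences starting with methionine, the
#' protein N-terminal peptides are emitted both with and without the
#' initiator Met (common in vivo Met excision leaves both forms observable).
#'
#' @param sequence Protein sequence.
#' @param enzyme An [enzyme_rule()].
#' @param missed Maximum missed cleavages (default 2).
#' @param min_length,max_length Peptide length window (default 5..60).
#' @param protein Protein identifier carried into the output.
#' @return data.frame with columns `sequence`, `protein`, `start`, `end`
#'   (1-based inclusive in the parent), `missed`, `nterm_met_removed`.
#' @export
digest <- function(sequence, enzyme, missed = 2L,
                   min_length = 5L, max_length = 60L, protein = NA_character_) {
  stopifnot(nzchar(sequence), min_length >= 1L, max_length >= min_length)
  chars <- .seq_chars(sequence)
  n <- length(chars)
  cuts <- c(0L, .cleavage_points(chars, enzyme), n)
  nseg <- length(cuts) - 1L
  out <- list(); k <- 0L
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + missed)) {
      s <- cuts[i] + 1L; e <- cuts[j + 1L]
      len <- e - s + 1L
      mc <- j - i
      if (len >= min_length && len <= max_length) {
        k <- k + 1L
        out[[k]] <- list(sequence = substr(sequence, s, e), start = s, end = e,
                         missed = mc, nterm_met_removed = FALSE)
      }
      ## initiator-Met-removed variant of protein N-terminal peptides
      if (s == 1L && chars[1L] == "M" && len - 1L >= min_length &&
          len - 1L <= max_length && e >= 2L) {
        k <- k + 1L
        out[[k]] <- list(sequence = substr(sequence, 2L, e), start = 2L, end = e,
                         missed = mc, nterm_met_removed = TRUE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(sequence = character(0), protein = character(0),
                      start = integer(0), end = integer(0), missed = integer(0),
                      nterm_met_removed = logical(0)))
  df <- data.frame(
    sequence = vapply(out, `[[`, character(1), "sequence"),
    protein = protein,
    start = vapply(out, `[[`, integer(1), "start"),
    end = vapply(out, `[[`, integer(1), "end"),
    missed = vapply(out, `[[`, integer(1), "missed"),
    nterm_met_removed = vapply(out, `[[`, logical(1), "nterm_met_removed"),
    stringsAsFactors = FALSE
  )
  df[!duplicated(df[c("sequence", "start", "end")]), , drop = FALSE]
}

#' Generate beta peptides from the Uaa-bearing protein
#'
#' Digests the engineered protein and keeps only peptides covering the Uaa
#' incorporation site, computing the Uaa position within each peptide. The
#' site residue is substituted by the Uaa symbol if the supplied sequence
#' does not already carry it.
#'
#' @param sequence Protein sequence of the Uaa-incorporated protein.
#' @param uaa_site 1-based position of the Uaa in the protein.
#' @param enzyme An [enzyme_rule()].
#' @param uaa [uaa_chemistry()].
#' @param mods Optional list of variable [mod_spec()]s, enumerated with
#'   [enumerate_variable_mods()].
#' @param max_var_mods Per-peptide cap on simultaneous variable mods.
#' @inheritParams digest
#' @return data.frame of beta peptides with `uaa_pos` (1-based within the
#'   peptide) and a `mods` list-column of per-residue mass-delta vectors.
#' @export
generate_beta_peptides <- function(sequence, uaa_site, enzyme, uaa,
                                   mods = list(), max_var_mods = 2L,
                                   missed = 2L, min_length = 5L,
                                   max_length = 60L, protein = "uaa_protein") {
  n <- nchar(sequence)
  if (uaa_site < 1L || uaa_site > n) stop("uaa site out of range")
  sequence <- canonicalize_uaa(sequence, uaa)
  site_res <- substr(sequence, uaa_site, uaa_site)
  if (site_res != uaa$symbol) {
    substr(sequence, uaa_site, uaa_site) <- uaa$symbol
  }
  peps <- digest(sequence, enzyme, missed = missed, min_length = min_length,
                 max_length = max_length, protein = protein)
  keep <- peps$start <= uaa_site & peps$end >= uaa_site
  peps <- peps[keep, , drop = FALSE]
  if (nrow(peps) == 0L) return(cbind(peps, uaa_pos = integer(0)))
  peps$uaa_pos <- uaa_site - peps$start + 1L
  ## sanity: exactly one Uaa symbol per beta peptide
  nu <- vapply(strsplit(peps$sequence, "", fixed = TRUE),
               function(ch) sum(ch == uaa$symbol), integer(1))
  peps <- peps[nu == 1L, , drop = FALSE]
  rownames(peps) <- NULL
  if (length(mods)) {
    expanded <- enumerate_variable_mods(peps, mods, cap = max_var_mods)
  } else {
    expanded <- peps
    expanded$mods <- replicate(nrow(peps), NULL, simplify = FALSE)
    expanded$mod_label <- ""
  }
  expanded
}

#' Enumerate variable modification forms of peptides
#'
#' All subsets of applicable sites up to `cap` simultaneous modifications,
#' including the unmodified form.
#'
#' @param peptides data.frame with a `sequence` column (e.g. from [digest()]).
#' @param mods List of variable [mod_spec()]s.
#' @param cap Maximum simultaneous variable modifications per peptide.
#' @return The input rows replicated per modification form, with a `mods`
#'   list-column (per-residue mass-delta vector or NULL) and a `mod_label`
#'   string such as `"Oxidation@3"`.
#' @export
enumerate_variable_mods <- function(peptides, mods, cap = 2L) {
  stopifnot(cap >= 0L)
  out <- vector("list", nrow(peptides))
  for (r in seq_len(nrow(peptides))) {
    seqr <- peptides$sequence[r]
    chars <- .seq_chars(seqr)
    sites <- list()
    for (sp in mods) {
      if (isTRUE(sp$fixed)) next
      pos <- which(chars %in% sp$targets)
      if (identical(sp$position, "peptide_nterm")) pos <- intersect(pos, 1L)
      for (p in pos) sites[[length(sites) + 1L]] <- list(pos = p, spec = sp)
    }
    forms <- list(list(delta = NULL, label = ""))
    ns <- length(sites)
    if (ns > 0L && cap > 0L) {
      for (size in seq_len(min(cap, ns))) {
        combos <- utils::combn(ns, size, simplify = FALSE)
        for (cmb in combos) {
          ## at most one mod per site
          pp <- vapply(sites[cmb], `[[`, numeric(1), "pos")
          if (anyDuplicated(pp)) next
          delta <- numeric(length(chars))
          lab <- character(size)
          for (t in seq_along(cmb)) {
            st <- sites[[cmb[t]]]
            delta[st$pos] <- delta[st$pos] + st$spec$delta
            lab[t] <- paste0(st$spec$name, "@", st$pos)
          }
          forms[[length(forms) + 1L]] <-
            list(delta = delta, label = paste(sort(lab), collapse = ";"))
        }
      }
    }
    reps <- peptides[rep(r, length(forms)), , drop = FALSE]
    reps$mods <- lapply(forms, `[[`, "delta")
    reps$mod_label <- vapply(forms, `[[`, character(1), "label")
    out[[r]] <- reps
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file.
#' @return data.frame with `id` (first token of the header), `header`
#'   (full accession line) and `sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  data.frame(
    id = vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L),
    header = headers,
    sequence = as.character(aa),
    stringsAsFactors = FALSE
  )
}

#' Write a protein FASTA file
#' @param proteins data.frame with `id` (or `header`) and `sequence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteins, path) {
  hdr <- if (!is.null(proteins$header)) proteins$header else proteins$id
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
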