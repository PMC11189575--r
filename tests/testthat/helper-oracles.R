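## Independent brute-force oracles used by the tests. These deliberately do
## not call into the package's mass/digestion/matching internals: element
## masses are typed from an independent physical-constants source, and all
## algorithms are naive enumerations.

ORACLE_ELEMENTS <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                     O = 15.9949146221, S = 31.97207069, F = 18.9984032)

ORACLE_COMP <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 5, H = 8, N = 2, O = 2, S = 1),  # carbamidomethylated
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

oracle_comp_mass <- function(comp) {
  total <- 0
  for (el in names(comp)) total <- total + ORACLE_ELEMENTS[[el]] * comp[[el]]
  total
}

oracle_residue_mass <- function(ch, uaa_mass = NA_real_) {
  if (ch %in% c("U", "J")) return(uaa_mass)
  oracle_comp_mass(ORACLE_COMP[[ch]])
}

oracle_peptide_mass <- function(seq, uaa_mass = NA_real_, mod_deltas = 0) {
  chars <- strsplit(seq, "")[[1]]
  total <- oracle_comp_mass(c(H = 2, O = 1))
  for (ch in chars) total <- total + oracle_residue_mass(ch, uaa_mass)
  total + sum(mod_deltas)
}

## all-substrings digestion oracle: every substring whose boundaries are
## valid cleavage points (or termini), filtered by missed cleavages/length
oracle_digest <- function(seq, after, block = character(0), missed = 2L,
                          min_len = 1L, max_len = 100L) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cut_ok <- function(i) {  # boundary after position i (0 = N-term, n = C-term)
    if (i == 0L || i == n) return(TRUE)
    chars[i] %in% after && !(chars[i + 1L] %in% block)
  }
  res <- character(0)
  for (s in 1:n) for (e in s:n) {
    if (!cut_ok(s - 1L) || !cut_ok(e)) next
    internal <- 0L
    for (i in s:e) if (i < e && cut_ok(i)) internal <- internal + 1L
    len <- e - s + 1L
    if (internal <= missed && len >= min_len && len <= max_len)
      res <- c(res, substr(seq, s, e))
  }
  unique(res)
}

## naive all-pairs greedy matcher mirroring the documented contract
oracle_match <- function(peak_mz, peak_int, theo_mz, tol_ppm) {
  pairs <- list()
  for (i in seq_along(theo_mz)) for (j in seq_along(peak_mz)) {
    ppm <- (peak_mz[j] - theo_mz[i]) / theo_mz[i] * 1e6
    if (abs(ppm) <= tol_ppm)
      pairs[[length(pairs) + 1L]] <- c(i, j, ppm)
  }
  if (!length(pairs))
    return(data.frame(ion = integer(0), peak = integer(0), ppm = numeric(0)))
  m <- do.call(rbind, pairs)
  o <- order(abs(m[, 3]), -peak_int[m[, 2]], m[, 1])
  m <- m[o, , drop = FALSE]
  used_i <- used_j <- integer(0)
  keep <- logical(nrow(m))
  for (r in seq_len(nrow(m))) {
    if (!(m[r, 1] %in% used_i) && !(m[r, 2] %in% used_j)) {
      keep[r] <- TRUE
      used_i <- c(used_i, m[r, 1]); used_j <- c(used_j, m[r, 2])
    }
  }
  m <- m[keep, , drop = FALSE]
  data.frame(ion = as.integer(m[, 1]), peak = as.integer(m[, 2]), ppm = m[, 3])
}

random_peptide <- function(len, alphabet = names(ORACLE_COMP)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
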