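## Monoisotopic masses (Da). CODATA-consistent values as used across
## proteomics mass calculators; exact to ~1e-7 Da.
.ELEMENTS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  F  = 18.99840322,
  P  = 30.97376163,
  Se = 79.9165213
)

.PROTON <- 1.007276466

## Residue elemental compositions (as residues, i.e. minus H2O).
.RESIDUE_COMP <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

#' Element monoisotopic mass table
#'
#' @return Named numeric vector of monoisotopic element masses in Da.
#' @export
element_masses <- function() .ELEMENTS

#' Monoisotopic mass of an elemental composition
#'
#' @param composition Named numeric vector or list, element symbol -> count.
#' @return Monoisotopic mass in Da.
#' @examples
#' composition_mass(c(H = 2, O = 1))  # water
#' @export
composition_mass <- function(composition) {
  if (length(composition) == 0L) return(0)
  composition <- unlist(composition)
  unknown <- setdiff(names(composition), names(.ELEMENTS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(composition < 0)) stop("element counts must be >= 0")
  sum(.ELEMENTS[names(composition)] * composition)
}

.MASS_H2O <- composition_mass(c(H = 2, O = 1))
.MASS_HF  <- composition_mass(c(H = 1, F = 1))
.MASS_SO3 <- composition_mass(c(S = 1, O = 3))
.MASS_CAM <- composition_mass(c(C = 2, H = 3, N = 1, O = 1))  # carbamidomethyl
.MASS_OX  <- .ELEMENTS[["O"]]

#' Residue monoisotopic mass table
#'
#' Masses of the 20 standard amino-acid residues (peptide-bond residues,
#' i.e. the free amino acid minus water). Cysteine is reported with the
#' carbamidomethyl fixed modification applied when `fixed_cam = TRUE`,
#' matching routine iodoacetamide alkylation.
#'
#' @param fixed_cam Apply carbamidomethyl (+57.02146 Da) to C. Default TRUE.
#' @return Named numeric vector of residue masses in Da.
#' @export
residue_masses <- function(fixed_cam = TRUE) {
  m <- vapply(.RESIDUE_COMP, composition_mass, numeric(1))
  if (fixed_cam) m[["C"]] <- m[["C"]] + .MASS_CAM
  m
}

#' Modification specification
#'
#' @param name Modification name.
#' @param targets Character vector of one-letter residue codes the
#'   modification applies to.
#' @param delta Monoisotopic mass delta in Da.
#' @param position One of "anywhere", "peptide_nterm", "protein_nterm".
#' @param fixed Logical; fixed modifications are always applied, variable
#'   modifications are enumerated up to a per-peptide cap.
#' @return A `mod_spec` object.
#' @export
mod_spec <- function(name, targets, delta, position = "anywhere", fixed = FALSE) {
  stopifnot(is.finite(delta),
            position %in% c("anywhere", "peptide_nterm", "protein_nterm"))
  structure(list(name = name, targets = targets, delta = delta,
                 position = position, fixed = fixed),
            class = "mod_spec")
}

#' Oxidation of methionine (variable modification)
#' @return A `mod_spec` for Oxidation (M), +15.9949 Da.
#' @export
mod_oxidation_m <- function() {
  mod_spec("Oxidation", "M", .MASS_OX, "anywhere", fixed = FALSE)
}

#' Uaa cross-linker chemistry
#'
#' Defines the latent-bioreactive unnatural amino acid (Uaa), its reaction
#' partners and the mass arithmetic of its cross-link. The default models
#' FSY-class aryl fluorosulfates: conjugation with Lys/His/Tyr eliminates HF
#' (sulfur-fluoride exchange), so the cross-link delta is -mass(HF).
#' For Uaa-His and Uaa-Lys products the sulfamate bond is MS-cleavable;
#' scission is modelled as a set of channels, each a pair of residual masses
#' (delta_alpha, delta_beta) added to the released alpha and beta chains,
#' constrained to conserve mass: delta_alpha + delta_beta = delta_xl.
#'
#' @param symbol Canonical one-letter Uaa symbol. "U" and "J" are accepted
#'   on input and canonicalized; `symbol` is what the package reports.
#' @param composition Elemental composition of the incorporated Uaa residue
#'   (as a residue, minus water). Default is the plain FSY residue C9H8FNO4S;
#'   for derivatives (e.g. alkyne-bearing enrichable analogues) supply the
#'   actual composition, or `residue_mass` directly.
#' @param residue_mass Residue monoisotopic mass in Da; overrides
#'   `composition` when given.
#' @param reactive Residues the Uaa can cross-link to. Default K, H, Y.
#' @param cleavable Subset of `reactive` whose cross-link bond fragments in
#'   the gas phase (protonatable sulfamate). Default K, H.
#' @param delta_xl Cross-link mass delta in Da. Default -mass(HF).
#' @param channels List of cleavage channels, each `c(alpha=, beta=)`
#'   residual masses. Default: channel A returns the alpha residue unmodified
#'   (0, delta_xl); channel B retains the sulfo group on alpha
#'   (delta_xl + SO3, -SO3).
#' @param neutral_losses Neutral losses applicable to sulfo-bearing species.
#'   Default -mass(SO3).
#' @param tag_mass Optional enrichment-tag adduct mass (e.g. the biotin-azide
#'   click product) in Da, or NULL.
#' @return A `uaa_chemistry` object.
#' @export
uaa_chemistry <- function(symbol = "U",
                          composition = c(C = 9, H = 8, F = 1, N = 1, O = 4, S = 1),
                          residue_mass = NULL,
                          reactive = c("K", "H", "Y"),
                          cleavable = c("K", "H"),
                          delta_xl = -.MASS_HF,
                          channels = NULL,
                          neutral_losses = -.MASS_SO3,
                          tag_mass = NULL) {
  if (is.null(residue_mass)) residue_mass <- composition_mass(composition)
  stopifnot(residue_mass > 0, is.finite(delta_xl))
  if (!all(cleavable %in% reactive))
    stop("cleavable partner residues must be a subset of reactive partner residues")
  if (is.null(channels)) {
    channels <- list(
      A = c(alpha = 0, beta = delta_xl),
      B = c(alpha = delta_xl + .MASS_SO3, beta = -.MASS_SO3)
    )
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (abs(ch[["alpha"]] + ch[["beta"]] - delta_xl) > 1e-9)
      stop("cleavage channel '", nm, "' violates mass conservation: ",
           "delta_alpha + delta_beta must equal delta_xl")
  }
  structure(list(symbol = symbol, residue_mass = residue_mass,
                 composition = composition,
                 reactive = reactive, cleavable = cleavable,
                 delta_xl = delta_xl, channels = channels,
                 neutral_losses = neutral_losses, tag_mass = tag_mass),
            class = "uaa_chemistry")
}

#' @export
print.uaa_chemistry <- function(x, ...) {
  cat("Uaa cross-linker chemistry\n")
  cat(sprintf("  symbol:        %s (aliases U/J accepted)\n", x$symbol))
  cat(sprintf("  residue mass:  %.6f Da\n", x$residue_mass))
  cat(sprintf("  reactive:      %s\n", paste(x$reactive, collapse = ", ")))
  cat(sprintf("  MS-cleavable:  %s\n", paste(x$cleavable, collapse = ", ")))
  cat(sprintf("  delta_xl:      %.6f Da\n", x$delta_xl))
  for (nm in names(x$channels))
    cat(sprintf("  channel %s:     delta_alpha = %+.6f, delta_beta = %+.6f\n",
                nm, x$channels[[nm]][["alpha"]], x$channels[[nm]][["beta"]]))
  invisible(x)
}

## Canonicalize Uaa aliases in a sequence: 'J' -> canonical symbol.
canonicalize_uaa <- function(sequence, uaa = NULL) {
  sym <- if (is.null(uaa)) "U" else uaa$symbol
  chartr("UJ", paste0(sym, sym), sequence)
}

.seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water, plus any modification deltas. The Uaa
#' symbol ("U" or "J") contributes the configured Uaa residue mass.
#'
#' @param sequence Peptide sequence (one-letter codes; may contain the Uaa
#'   symbol).
#' @param mods Optional list of modifications, each `list(position =, spec =)`
#'   with `spec` a [mod_spec()], or a single numeric vector of per-position
#'   mass deltas. Positions are 1-based within the peptide.
#' @param uaa Optional [uaa_chemistry()]; required if the sequence contains
#'   the Uaa symbol.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")
#' @export
peptide_mass <- function(sequence, mods = NULL, uaa = NULL) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  rt <- residue_masses()
  chars <- .seq_chars(sequence)
  is_uaa <- chars %in% c("U", "J", if (!is.null(uaa)) uaa$symbol)
  if (any(is_uaa) && is.null(uaa))
    stop("sequence contains the Uaa symbol but no uaa chemistry was provided")
  known <- chars %in% names(rt) | is_uaa
  if (!all(known))
    stop("unknown residue symbol(s): ",
         paste(unique(chars[!known]), collapse = ", "))
  m <- sum(rt[chars[!is_uaa]]) + sum(is_uaa) * (if (is.null(uaa)) 0 else uaa$residue_mass) +
    .MASS_H2O
  m + .mods_total_delta(mods, nchar(sequence))
}

.mods_total_delta <- function(mods, len) {
  if (is.null(mods) || length(mods) == 0L) return(0)
  if (is.numeric(mods)) return(sum(mods))
  total <- 0
  for (md in mods) {
    pos <- md$position
    if (pos < 1L || pos > len) stop("modification position out of range: ", pos)
    total <- total + md$spec$delta
  }
  total
}

#' Per-residue mass vector of a peptide
#'
#' Residue masses in sequence order with modification deltas folded in at
#' their positions; used by fragment-ion generation.
#' @inheritParams peptide_mass
#' @return Numeric vector, one mass per residue.
#' @keywords internal
residue_mass_vector <- function(sequence, mods = NULL, uaa = NULL) {
  rt <- residue_masses()
  chars <- .seq_chars(sequence)
  is_uaa <- chars %in% c("U", "J", if (!is.null(uaa)) uaa$symbol)
  v <- numeric(length(chars))
  v[!is_uaa] <- rt[chars[!is_uaa]]
  if (any(is_uaa)) {
    if (is.null(uaa)) stop("Uaa symbol present but no uaa chemistry provided")
    v[is_uaa] <- uaa$residue_mass
  }
  if (!is.null(mods) && length(mods)) {
    if (is.numeric(mods)) {
      v <- v + mods
    } else {
      for (md in mods) v[md$position] <- v[md$position] + md$spec$delta
    }
  }
  v
}

#' Neutral precursor mass of a cross-linked peptide pair
#'
#' @param alpha_mass Neutral mass of the alpha peptide (Da), > 0.
#' @param beta_mass Neutral mass of the beta (Uaa-bearing) peptide (Da), > 0.
#' @param uaa [uaa_chemistry()] supplying the cross-link delta.
#' @return alpha_mass + beta_mass + delta_xl, in Da.
#' @export
crosslink_precursor_mass <- function(alpha_mass, beta_mass, uaa) {
  if (alpha_mass <= 0 || beta_mass <= 0)
    stop("peptide masses must be > 0")
  alpha_mass + beta_mass + uaa$delta_xl
}

#' Convert neutral mass to m/z
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @return m/z.
#' @export
mz_from_neutral <- function(mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (mass + charge * .PROTON) / charge
}

#' Convert m/z to neutral mass
#' @param mz Observed m/z.
#' @param charge Positive integer charge.
#' @return Neutral monoisotopic mass (Da).
#' @export
neutral_from_mz <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  mz * charge - charge * .PROTON
}

#' Load a chemistry configuration file
#'
#' Reads a YAML (or JSON) document describing the Uaa definition, cleavage
#' channels, neutral losses and optional tag adduct, and returns a validated
#' [uaa_chemistry()]. Channel mass conservation (delta_alpha + delta_beta =
#' delta_xl) is enforced at load.
#'
#' @param path Path to a YAML/JSON chemistry configuration.
#' @return A `uaa_chemistry` object.
#' @export
read_chemistry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ## catch the YAML-1.1 pitfall where bare F/N/Y/T parse as booleans
  lit <- c(names(cfg$composition), unlist(cfg$reactive), unlist(cfg$cleavable))
  if (any(lit %in% c("TRUE", "FALSE")) || any(is.logical(cfg$reactive)) ||
      any(is.logical(cfg$cleavable)))
    stop("single-letter element/residue symbols must be quoted in the ",
         "chemistry YAML (bare F, N, Y, T parse as booleans)")
  args <- list()
  if (!is.null(cfg$symbol)) args$symbol <- cfg$symbol
  if (!is.null(cfg$composition)) args$composition <- unlist(cfg$composition)
  if (!is.null(cfg$residue_mass)) args$residue_mass <- cfg$residue_mass
  if (!is.null(cfg$reactive)) args$reactive <- cfg$reactive
  if (!is.null(cfg$cleavable)) args$cleavable <- cfg$cleavable
  if (!is.null(cfg$delta_xl)) args$delta_xl <- cfg$delta_xl
  if (!is.null(cfg$channels)) {
    args$channels <- lapply(cfg$channels, function(ch)
      c(alpha = ch$alpha, beta = ch$beta))
  }
  if (!is.null(cfg$neutral_losses)) args$neutral_losses <- unlist(cfg$neutral_losses)
  if (!is.null(cfg$tag_mass)) args$tag_mass <- cfg$tag_mass
  do.call(uaa_chemistry, args)
}

## Internal constants used across modules
mass_h2o <- function() .MASS_H2O
mass_proton <- function() .PROTON
mass_so3 <- function() .MASS_SO3
mass_hf <- function() .MASS_HF
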