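---
title: "Identifying Uaa-mediated cross-linked peptides: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying Uaa-mediated cross-linked peptides: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaaxl)
```

## The identification problem

Latent-bioreactive unnatural amino acids (Uaas) of the
fluorosulfate-L-tyrosine (FSY) class are genetically incorporated into a
target protein at a chosen site. Their aryl fluorosulfate warhead reacts
with a proximal lysine, histidine or tyrosine on an interacting protein via
sulfur-fluoride exchange (SuFEx), eliminating HF and forming a covalent
cross-link in situ. After digestion, each cross-linked product is a pair of
peptides: the **β peptide**, which carries the Uaa and comes from the one
engineered protein, and the **α peptide**, which comes from anywhere in the
proteome and must be found by database search.

What makes these cross-links unusual is their gas-phase chemistry. The
sulfamate bond formed with His or Lys can be protonated and fragments under
HCD, so a Uaa–His/Lys spectrum is effectively a mixture of two linear
peptides and their backbone fragments. The sulfonate ester formed with Tyr
does not fragment this way. Consequently:

* conventional *non-cleavable* cross-link software expects fragments that
  still carry the intact partner chain; for Uaa–His/Lys those ions are rare,
  and the abundant bond-cleaved fragments are either misassigned or ignored,
  which can shift the reported cross-link site (typically onto a nearby
  tyrosine);
* conventional *cleavable* cross-link software expects a paired
  signature-ion doublet (as for DSSO-class linkers); the sulfamate scission
  here produces no such pair.

This package models the full fragment-ion taxonomy so that both chemistries
are handled in one search.

## Fragment-ion model

For a candidate (α, site *i*; β, Uaa at *j*) the generator emits, in both
modes and for both chains:

* **regular** b/y ions — backbone fragments that do not span the
  cross-link site;
* **xl-containing** b/y ions — fragments spanning the site, carrying the
  intact partner chain plus the cross-link delta
  \(\Delta_{xl} = -m(\mathrm{HF})\).

When the search mode is `cleavable` and the α-site residue is His or Lys,
scission of the sulfamate bond is modelled as a set of *channels*, each a
pair of residual masses \((\delta_\alpha, \delta_\beta)\) with
\(\delta_\alpha + \delta_\beta = \Delta_{xl}\) enforced at configuration
load. Two channels ship by default: channel A returns the α residue to its
unmodified form (\(\delta_\alpha = 0\)), and channel B retains the sulfo
group on α (\(\delta_\alpha = \Delta_{xl} + m(\mathrm{SO_3})\)). Because no
signature-ion pair is observed for Uaa–His links, neither channel is
privileged; both are generated and matched. Per channel the generator adds:

* **released-chain** ions — the intact linear α (mass \(M_\alpha +
  \delta_\alpha\)) and β (\(M_\beta + \delta_\beta\)) chains;
* **internal** ions — b/y fragments spanning the link site that carry only
  their chain's channel residual (with channel A's \(\delta_\alpha = 0\),
  internal α ions coincide with plain linear-peptide fragments — exactly the
  peaks a regular-ion-only engine mistakes for evidence of a different
  site);
* **−SO3 neutral-loss** variants of species still bearing the intact sulfo
  group (xl-containing ions and the sulfo-retaining side of each channel);
  species whose channel already removed SO3 are not given a second loss.

A `cleavable`-mode request for a Uaa–Tyr candidate falls back to the
non-cleavable ion set. The cleavable ion set is therefore always a superset
of the non-cleavable one.

The exact residual masses carried by each released chain are not established
independently here; the two defaults are mass-conserving models, and both
channels plus the loss masses are configurable through the chemistry YAML
(`inst/extdata/fsy_chemistry.yaml`).

Only b/y series are generated (HCD), at fragment charges
1..min(precursor charge − 1, 3).

## Scoring, rescoring and FDR

Candidates are assembled per spectrum: for each β-peptide form, α peptides
whose neutral mass lies within the precursor tolerance of
\(M_{prec} - M_\beta - \Delta_{xl}\) are fetched from a mass-sorted index,
and every K/H/Y position in α becomes one candidate site. Peaks are matched
greedily, nearest-in-ppm first, each peak used at most once.

The **coarse score** is a class-weighted sum of \(\ln(1 + I/I_{max})\) over
matched ions plus \(\lambda \cdot\) (fraction of the β-chain backbone series
matched), with default weights 1.0 for all backbone classes, 0.5 for
neutral-loss variants, \(\lambda = 0.5\), and a minimum of 3 distinct
matched β backbone ions per PSM. The formula is this package's own design:
it rewards precisely the ion classes that distinguish the two cross-link
chemistries while staying monotone in the matched set (adding a matched ion
never lowers the score). The top 5 candidates per spectrum are retained.

**Decoys** are pseudo-reversed α peptides (sequence reversed with the
C-terminal residue held fixed, preserving tryptic specificity and exact
mass); β is never decoyed because it comes from one known engineered
protein. **Rescoring** is a Percolator-style semi-supervised linear model:
positives are rank-1 target PSMs passing a 1% coarse-score FDR, negatives
are all decoy PSMs; features (match counts and intensity fractions per ion
class, ladder run lengths, precursor error, lengths, charge, cleavable
evidence count) are standardized, zero-variance features dropped, and a
least-squares discriminant on ±1 labels is refit for 3 iterations under
3-fold spectrum-level cross-validation, so no PSM is scored by a model
trained on it. Restricting the positive class to rank-1 PSMs matters:
training on all retained candidates would teach the model that wrong-site
siblings of confident identifications are positive, inverting within-
spectrum site ranking. With fewer than 50 PSMs, or without both classes,
the coarse score is used unchanged.

**q-values** follow the simple decoy/target ratio (a +1-corrected variant
is available) with a running minimum from the bottom of the ranked list;
decoys are counted before targets at tied scores. Reporting filters rank-1
target PSMs at q ≤ 0.05, the PSM-level threshold conventional for this
chemistry. One combined FDR is computed over cleavable and non-cleavable
matches, since both are scored on the same target-decoy scale.

## The simulator

The simulator exists so the engine is fully testable with no external data.
Four named presets reproduce the structure of the published benchmark:
`sim1` (1000 spectra, exactly one H/K in the α chain, full b/y ladders),
`sim2` (α b ions each retained with probability 0.5), `sim3` (no α b ions),
and `sim4` (200 spectra, at least one H/K *and* one Y in α). Details the
benchmark description leaves open were fixed once, as follows:

* α peptides are tryptic-like strings, length 6–20, C-terminal K/R,
  interior residues drawn uniformly from the non-cleaving alphabet. In the
  "one H/K" presets the chain carries no tyrosine: Y residues are
  cross-link-eligible, so an incidental Y would reintroduce precisely the
  site ambiguity those datasets are defined to exclude; `sim4`
  reintroduces it deliberately. The unconstrained (`custom`) mode draws the
  single cross-linked residue uniformly from {H, K, Y}, giving the mixed
  populations used for the intensity-ratio statistics.
* the β source is a fixed synthetic 60-residue engineered protein (shipped
  constant) whose tryptic digest yields one Uaa-bearing peptide, matching
  the single-probe-protein design of a genetic-encoding experiment.
* emission: regular ions are always emitted (subject to the b-completeness
  profile); for H/K sites internal and released ions are emitted with
  probability 0.9 at full log-normal intensity and xl-containing ions
  weakly (p = 0.25, scaled 0.3); for Y sites the pattern reverses
  (xl p = 0.9, internal p = 0.02, no released chains). Intensities are
  log-normal(0, 1); 30 uniform noise peaks per spectrum; m/z jitter is
  normal with σ = one third of the matching tolerance (20/3 ppm for
  fragments, 10/3 ppm for precursors); precursor charges 3+ (60%) and
  4+ (40%), inside the 3–6 acquisition window used for enriched samples.
* the companion FASTA embeds α peptides in concatenated synthetic proteins
  so that tryptic digestion regenerates them; entrapment proteins (built
  identically but never used in spectra) measure empirical FDR.

The simulator computes its theoretical ions with its own loop-based
builder, independent of the engine's vectorized generator; the two are
cross-checked against each other in the tests. What the simulator does
*not* emulate: isotope envelopes, retention time, co-isolation/chimeric
spectra, intensity structure of real HCD (mobile-proton effects), and real
proteome-scale databases. Passing these benchmarks therefore demonstrates
correctness of the scoring and FDR machinery under the stated generative
model, not instrument-level performance.

The site-misassignment fixture is a single deterministic Uaa–His spectrum
(α chain `TAYLHNVLER`, true site H5, with Y3 as the trap) carrying full
plain y ladders and internal/released ions but no site-discriminating
regular b ions beyond b2 — the condition under which regular-ion scoring
prefers Y and cleavable-aware scoring recovers H.

## Numerical and design choices

* Monoisotopic masses throughout; proton mass 1.007276 Da; all masses in
  Da. Elemental composition of the shipped Uaa residue is plain FSY
  (C9H8FNO4S, 245.0158 Da as a residue); enrichable derivatives are
  configured by composition or residue mass, with an optional
  enrichment-tag adduct mass for post-click spectra.
* Tolerances default to 10 ppm (precursor) and 20 ppm (fragment);
  search settings of the original acquisition are not published, so these
  are conventional Orbitrap values.
* Digestion defaults: ≤ 2 missed cleavages, peptide length 5–60; trypsin
  (not before P), Glu-C (after E, optionally D), chymotrypsin (F/W/Y/L, not
  before P). Protein N-terminal peptides are generated with and without the
  initiator methionine.
* Carbamidomethyl (C) is fixed; oxidation (M) is variable with a
  per-peptide cap of 2; 'U' and 'J' are both accepted as the Uaa symbol.
* Ties in peak assignment break toward higher peak intensity then smaller
  |ppm|; ties in candidate ranking break deterministically (decoys ranked
  below targets at equal score, then lexicographically), so identical
  inputs give byte-identical outputs.
* Benchmark problem sizes used in the shipped checks: the FDR-calibration
  study runs 20 seeded partial-ladder datasets of 500 spectra each against
  a 50% entrapment database; precision checks run the full preset sizes
  (1000/200 spectra). These sizes give a few thousand accepted PSMs, enough
  for the binomial tolerance on the 5% level to be a few tenths of a
  percent.

## Known limitations

* The coarse-score form and rescoring feature set are reasoned stand-ins;
  no claim is made that they match any external engine's internals.
* Channel residual masses beyond mass conservation are configuration, not
  established chemistry; if annotated spectra indicate different residuals,
  the YAML is the place to change them.
* Loop-links, mono-links/dead-ends, ordinary linear-peptide identification
  and double cross-linking are out of scope; exactly one Uaa per β peptide
  and one cross-link per pair are assumed, matching the genetic-encoding
  design.
* mzML support is limited to centroided MS2 with recorded precursor charge;
  profile data are rejected.

## Reproducing the benchmark numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates the
FDR-calibration study from scratch (simulate, search, rescore, filter,
evaluate) and writes the mean observed false-discovery proportion as a
percentage. The testthat suite runs the same acceptance checks plus the
module-level oracle equivalences.
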