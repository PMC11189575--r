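# FSY-class Uaa cross-linker chemistry.
# The shipped composition is the plain FSY residue; for enrichable
# derivatives replace `composition` (or give `residue_mass`) with the actual
# incorporated residue, and set `tag_mass` to the post-click enrichment-tag
# adduct if spectra were acquired after biotin labeling.
# note: single-letter keys/values are quoted ("F", "Y", "N" are YAML booleans)
symbol: "U"
composition:
  "C": 9
  "H": 8
  "F": 1
  "N": 1
  "O": 4
  "S": 1
reactive: ["K", "H", "Y"]
cleavable: ["K", "H"]
# cross-link delta: -mass(HF), eliminated by sulfur-fluoride exchange
delta_xl: -20.0062285
channels:
  A: {alpha: 0.0, beta: -20.0062285}          # S-N scission, alpha unmodified
  B: {alpha: 59.9505861, beta: -79.9568146}   # sulfo retained on alpha
neutral_losses: [-79.9568146]
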