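## Shared fixtures: default chemistry, a compact search wrapper, and a
## minimal mzML writer (uncompressed 64-bit little-endian base64 arrays).

test_uaa <- function() uaa_chemistry()

## simulate + index + search + rescore + filter in one call
run_sim_search <- function(cfg, mode = "cleavable", seed = cfg$seed,
                           uaa = test_uaa(), fdr = 0.05) {
  sim <- simulate_dataset(cfg, uaa)
  idx <- index_alpha_database(sim$proteins, enzyme_rule("trypsin"))
  beta <- generate_beta_peptides(sim$beta_protein, sim$beta_uaa_site,
                                 enzyme_rule("trypsin"), uaa,
                                 mods = list(mod_oxidation_m()))
  psms <- search_spectra(sim$spectra, beta, idx, uaa, mode = mode)
  psms <- suppressWarnings(suppressMessages(rescore_psms(psms, seed = seed)))
  list(sim = sim, psms = psms,
       filtered = filter_psms(psms, fdr = fdr),
       index = idx, beta = beta)
}

write_test_mzml <- function(path, spectra) {
  enc <- function(x) jsonlite::base64_enc(
    writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
  spec_xml <- vapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>\n',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>\n',
      '</selectedIon></selectedIonList></precursor></precursorList>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray encodedLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>\n',
      '<binary>%s</binary></binaryDataArray>\n',
      '<binaryDataArray encodedLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>\n',
      '<binary>%s</binary></binaryDataArray>\n',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, length(sp$mz), sp$precursor_mz, sp$charge,
      nchar(enc(sp$mz)), enc(sp$mz), nchar(enc(sp$intensity)), enc(sp$intensity))
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="x"/></cvList>\n',
    '<run id="r1">\n<spectrumList count="', length(spectra),
    '" defaultDataProcessingRef="dp1">\n',
    paste(spec_xml, collapse = "\n"),
    '\n</spectrumList>\n</run>\n</mzML>\n')
  writeLines(xml, path)
  invisible(path)
}
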