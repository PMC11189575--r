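#' End-to-end identification pipeline
#'
#' Orchestrates simulate (or load) -> search -> rescore -> FDR filter ->
#' evaluate -> fragment statistics, writing every stage output and a run
#' manifest into `out_dir`. Reruns with the same configuration and seed
#' reproduce identical outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param preset Simulator preset to run ("sim1".."sim4"), or NULL when
#'   `spectra_path` is supplied.
#' @param spectra_path,fasta_path Optional real inputs: an MGF/mzML file and
#'   an alpha protein FASTA; used instead of the simulator.
#' @param uaa_protein,uaa_site Uaa-bearing protein sequence and site; default
#'   the simulator's synthetic probe protein.
#' @param uaa [uaa_chemistry()], or a path readable by
#'   [read_chemistry_config()].
#' @param enzyme An [enzyme_rule()] (default trypsin).
#' @param mode Search mode (default "cleavable").
#' @param fdr PSM-level q-value threshold (default 0.05).
#' @param entrapment_frac Entrapment fraction passed to the simulator.
#' @param n_spectra Override the preset's spectrum count.
#' @param seed Seed controlling simulation and rescoring.
#' @param prec_tol_ppm,frag_tol_ppm Search tolerances.
#' @param charge_window Optional c(min, max) precursor-charge window applied
#'   to loaded spectra.
#' @return Invisibly, a list with `psms`, `filtered`, `evaluation` (when
#'   ground truth exists), `fragstats`, and the manifest.
#' @export
run_pipeline <- function(out_dir, preset = "sim1", spectra_path = NULL,
                         fasta_path = NULL,
                         uaa_protein = NULL, uaa_site = NULL,
                         uaa = uaa_chemistry(), enzyme = enzyme_rule("trypsin"),
                         mode = "cleavable", fdr = 0.05,
                         entrapment_frac = 0, n_spectra = NULL, seed = 1L,
                         prec_tol_ppm = 10, frag_tol_ppm = 20,
                         charge_window = NULL) {
  if (fdr <= 0 || fdr > 1) stop("fdr threshold must be in (0, 1]")
  if (is.character(uaa)) uaa <- read_chemistry_config(uaa)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("uaaxl")),
                   seed = seed, mode = mode, fdr = fdr, stages = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (is.null(spectra_path)) {
    sim <- stage("simulate", {
      cfg <- sim_config(preset, n_spectra = n_spectra,
                        entrapment_frac = entrapment_frac, seed = seed)
      simulate_dataset(cfg, uaa)
    })
    spectra <- sim$spectra
    truth <- sim$truth
    proteins <- sim$proteins
    if (is.null(uaa_protein)) { uaa_protein <- sim$beta_protein
                                uaa_site <- sim$beta_uaa_site }
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_fasta(proteins, file.path(out_dir, "proteins.fasta"))
    manifest$stages <- c(manifest$stages, "simulate")
  } else {
    spectra <- stage("read_spectra", read_spectra(
      spectra_path,
      charge_min = if (is.null(charge_window)) NULL else charge_window[1],
      charge_max = if (is.null(charge_window)) NULL else charge_window[2]))
    proteins <- stage("read_fasta", read_fasta(fasta_path))
    if (is.null(uaa_protein)) stop("uaa_protein is required for real inputs")
    manifest$stages <- c(manifest$stages, "load")
  }

  index <- stage("index", index_alpha_database(proteins, enzyme))
  beta <- stage("beta_peptides",
                generate_beta_peptides(uaa_protein, uaa_site, enzyme, uaa,
                                       mods = list(mod_oxidation_m())))
  psms <- stage("search",
                search_spectra(spectra, beta, index, uaa, mode = mode,
                               prec_tol_ppm = prec_tol_ppm,
                               frag_tol_ppm = frag_tol_ppm))
  manifest$stages <- c(manifest$stages, "search")
  psms <- stage("rescore", rescore_psms(psms, seed = seed))
  manifest$stages <- c(manifest$stages, "rescore")
  filtered <- stage("fdr", filter_psms(psms, fdr = fdr))
  manifest$stages <- c(manifest$stages, "fdr")
  write_results(compute_qvalues(rank1_psms(psms)), file.path(out_dir, "psms.tsv"))
  write_results(filtered, file.path(out_dir, "filtered.tsv"))

  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- stage("evaluate", evaluate_against_truth(filtered, truth))
    jsonlite::write_json(
      evaluation[c("n", "pair_precision", "site_precision", "pair_recall",
                   "site_recall")],
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages <- c(manifest$stages, "evaluate")
  }
  fs <- NULL
  if (nrow(filtered) > 0L) {
    fs <- stage("fragstats", aggregate_by_residue(per_psm_ratios(filtered)))
    utils::write.table(fs$summary, file.path(out_dir, "fragstats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages <- c(manifest$stages, "fragstats")
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(psms = psms, filtered = filtered, evaluation = evaluation,
                 fragstats = fs, manifest = manifest))
}
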