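make_spec <- function(scan = "s1", pmz = 500.25, z = 3,
                      mz = c(200.1, 300.2, 400.3), int = c(10, 20, 30)) {
  spectrum(scan, pmz, z, mz, int)
}

test_that("spectrum construction normalizes unsorted peak lists", {
  sp <- spectrum("s", 500, 3, c(300, 100, 200), c(2, 1, 3))
  expect_identical(sp$mz, c(100, 200, 300))
  expect_identical(sp$intensity, c(1, 3, 2))
  expect_error(spectrum("s", 500, 3, c(1, 2), c(-1, 1)))
})

test_that("MGF round-trips content-identically", {
  sps <- list(make_spec("a", 500.123456, 3),
              make_spec("b", 600.5, 4, c(150.5, 250.75), c(5, 6)))
  tmp <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sps, tmp)
  back <- suppressMessages(read_spectra(tmp))
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$scan, sps[[i]]$scan)
    expect_equal(back[[i]]$precursor_mz, sps[[i]]$precursor_mz, tolerance = 1e-6)
    expect_identical(back[[i]]$charge, sps[[i]]$charge)
    expect_equal(back[[i]]$mz, sps[[i]]$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$intensity, sps[[i]]$intensity, tolerance = 1e-6)
  }
  ## second round trip is byte-identical
  tmp2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("charge window filters spectra as in enriched-sample acquisition", {
  sps <- list(make_spec("a", 500, 2), make_spec("b", 500, 3),
              make_spec("c", 500, 4))
  tmp <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sps, tmp)
  kept <- suppressMessages(read_spectra(tmp, charge_min = 3, charge_max = 6))
  expect_length(kept, 2L)
  expect_identical(attr(kept, "n_read"), 3L)
  expect_setequal(vapply(kept, `[[`, character(1), "scan"), c("b", "c"))
  ## empty file gives an empty stream without error
  empty <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(0), empty)
  expect_length(suppressMessages(read_spectra(empty)), 0L)
})

test_that("charge strings '3' and '3+' both parse", {
  tmp <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=500.5", "CHARGE=3",
               "100.0 1.0", "END IONS",
               "BEGIN IONS", "TITLE=y", "PEPMASS=600.5", "CHARGE=4+",
               "100.0 1.0", "END IONS"), tmp)
  sps <- suppressMessages(read_spectra(tmp))
  expect_identical(vapply(sps, `[[`, integer(1), "charge"), c(3L, 4L))
})

test_that("mzML MS2 spectra are read through mzR", {
  sps <- list(make_spec("1", 500.25, 3), make_spec("2", 612.75, 4))
  tmp <- withr::local_tempfile(fileext = ".mzML")
  write_test_mzml(tmp, sps)
  back <- suppressMessages(read_spectra(tmp, format = "mzml"))
  expect_length(back, 2L)
  expect_equal(back[[1]]$precursor_mz, 500.25, tolerance = 1e-6)
  expect_identical(back[[2]]$charge, 4L)
  expect_equal(back[[1]]$mz, sps[[1]]$mz, tolerance = 1e-9)
})

test_that("precursor neutral mass inverts the m/z conversion", {
  sp <- make_spec(pmz = mz_from_neutral(2179.9938, 3), z = 3)
  expect_equal(precursor_neutral_mass(sp), 2179.9938, tolerance = 1e-6)
})

test_that("cross-link notation parses, validates and serializes losslessly", {
  p <- parse_crosslink_notation("TSVDNAFNHE(9)-ILHLPNLNJE(9)")
  expect_identical(p$alpha_seq, "TSVDNAFNHE")
  expect_identical(p$alpha_site, 9L)
  expect_identical(substr(p$alpha_seq, p$alpha_site, p$alpha_site), "H")
  expect_identical(p$beta_seq, "ILHLPNLNJE")
  expect_identical(p$beta_site, 9L)
  expect_identical(
    format_crosslink_notation(p$alpha_seq, p$alpha_site, p$beta_seq, p$beta_site),
    "TSVDNAFNHE(9)-ILHLPNLNJE(9)")

  ## Met-retained alpha chain shifts the site to 10, still histidine
  p2 <- parse_crosslink_notation("MTSVDNAFNHE(10)-ILHLPNLNJE(9)")
  expect_identical(p2$alpha_site, 10L)
  expect_identical(substr(p2$alpha_seq, p2$alpha_site, p2$alpha_site), "H")

  ## beta is recognized by the Uaa symbol regardless of order
  p3 <- parse_crosslink_notation("ILHLPNLNJE(9)-TSVDNAFNHE(9)")
  expect_identical(p3$alpha_seq, "TSVDNAFNHE")

  expect_error(parse_crosslink_notation("AAAA(5)-AJAA(2)"), "out of range")
  expect_error(parse_crosslink_notation("AAAA(1)-AAAA(1)"), "Uaa")
  expect_error(parse_crosslink_notation("AJAA(2)-AUAA(2)"), "Uaa")
  expect_error(parse_crosslink_notation("AAAA-AJAA"), "notation")
})

test_that("PSM tables round-trip through TSV", {
  psms <- data.frame(
    scan = "s1", alpha_seq = "TSVDNAFNHE", alpha_protein = "P1",
    alpha_site = 9L, beta_seq = "ILHLPNLNUE", beta_site = 9L,
    prec_error_ppm = 1.5, coarse = 12.5, rescore = 3.2, qvalue = 0.01,
    is_decoy = FALSE, n_regular = 10, n_xl = 2, n_released = 3,
    n_internal = 5, n_neutral_loss = 1, mod_label = "/",
    stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_results(psms, tmp)
  back <- read_results(tmp)
  expect_identical(back$notation, "TSVDNAFNHE(9)-ILHLPNLNUE(9)")
  expect_identical(back$scan, "s1")
  expect_equal(back$coarse, 12.5)
  expect_equal(back$qvalue, 0.01)
  expect_identical(back$n_internal, 5L)
  ## empty table writes a header-only file
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(psms[0, ], tmp2)
  expect_identical(nrow(read_results(tmp2)), 0L)
})
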