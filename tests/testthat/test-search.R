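search_instance <- function(seed, n_spectra, n_proteins, n_extra_noise = 2L) {
  set.seed(seed)
  spec <- synthetic_run_spec(n_proteins = n_proteins,
                             protein_length = c(60L, 150L),
                             n_spectra = n_spectra, fraction_true = 0.8)
  prot <- make_proteome(spec, seed = seed)
  run <- simulate_run(prot, spec, seed = seed)
  cfg <- search_config(chunk_size = 1000L)
  sels <- lapply(run$spectra, select_top_k, k = cfg$k)
  idx <- build_spectrum_index(sels, cfg$scheme, spectra = run$spectra)
  peps <- build_peptide_db(prot)
  list(run = run, cfg = cfg, sels = sels, idx = idx, peps = peps)
}

test_that("indexed search equals the all-pairs reference matcher bit for bit", {
  inst <- search_instance(101, n_spectra = 40L, n_proteins = 6L)
  fast <- search_all(inst$idx, inst$peps, config = inst$cfg)
  slow <- search_all_naive(inst$sels, inst$run$spectra, inst$peps,
                           config = inst$cfg)
  expect_identical(psm_pair(fast)$spectrum, psm_pair(slow)$spectrum)
  expect_identical(psm_pair(fast)$peptide, psm_pair(slow)$peptide)
  expect_gt(nrow(fast), 0L)
})

test_that("a noiseless ladder spectrum is won by its own peptide", {
  cfg <- search_config()
  pepA <- "LVNEVTEFAK"
  pepQ <- "GYSLGNWVCAAK"
  sp <- ladder_spectrum(0L, pepA)
  sels <- list(select_top_k(sp, cfg$k))
  idx <- build_spectrum_index(sels, cfg$scheme, spectra = list(sp))
  psms <- search_all(idx, peptide_table(c(pepA, pepQ)), config = cfg)
  expect_equal(nrow(psms), 1L)
  expect_equal(psms$peptide, pepA)
  expect_false(psms$is_decoy)
  expect_equal(psms$delta_mass, 0, tolerance = 1e-3)
})

test_that("one candidate can win several spectra independently", {
  cfg <- search_config()
  pep <- "LVNEVTEFAK"
  sp1 <- ladder_spectrum(0L, pep, rt = 10)
  sp2 <- ladder_spectrum(1L, pep, rt = 99)
  sels <- lapply(list(sp1, sp2), select_top_k, k = cfg$k)
  idx <- build_spectrum_index(sels, cfg$scheme, spectra = list(sp1, sp2))
  psms <- search_all(idx, peptide_table(pep), config = cfg)
  expect_equal(nrow(psms), 2L)
  expect_equal(psms$peptide, rep(pep, 2L))
  # the per-peptide stream keeps only the candidate's single best spectrum
  expect_equal(nrow(attr(psms, "peptide_psms")), 1L)
})

test_that("spectra below the matched-ion floor are not scored", {
  cfg <- search_config(min_matched = 4L)
  # three matching ions only: b2/y1/y2 of the candidate, planted exactly
  pep <- "LVNEVTEFAK"
  fr <- fragment_ions(pep, charges = 1L)
  sp <- make_spectrum(0L, c(fr$b[["1"]][2], fr$y[["1"]][1:2]), rep(10, 3),
                      precursor_mz = (peptide_mass(pep) + 2 * PROTON_MASS) / 2)
  idx <- build_spectrum_index(list(select_top_k(sp, cfg$k)), cfg$scheme,
                              spectra = list(sp))
  psms <- search_all(idx, peptide_table(pep), config = cfg)
  expect_equal(nrow(psms), 0L)
  # lowering the floor admits the match
  cfg2 <- search_config(min_matched = 3L)
  psms2 <- search_all(idx, peptide_table(pep), config = cfg2)
  expect_equal(nrow(psms2), 1L)
  expect_equal(psms2$Nb + psms2$Ny, 3L)
})

test_that("narrow-mode gating and the ppm filter agree with arithmetic", {
  psms <- data.frame(delta_mass = c(0, 0.05, -0.01), pep_mass = c(1000, 1000, 1000))
  class(psms) <- c("psm_table", "data.frame")
  kept <- narrow_window_filter(psms, 20)
  expect_equal(kept$delta_mass, c(0, -0.01))  # 0.05/1000 = 50 ppm rejected
  expect_equal(nrow(narrow_window_filter(psms, Inf)), 3L)
  expect_error(narrow_window_filter(psms, 0))

  # in narrow mode the gate is applied during search
  inst <- search_instance(202, n_spectra = 25L, n_proteins = 4L)
  full <- search_all(inst$idx, inst$peps, config = inst$cfg)
  cfg_n <- search_config(mode = "narrow", narrow_ppm = 20, chunk_size = 1000L)
  narrow <- search_all(inst$idx, inst$peps, config = cfg_n)
  expect_lte(nrow(narrow), nrow(full))
  # narrow results are exactly the full results that satisfy the tolerance
  in_tol <- abs(full$delta_mass) / full$pep_mass * 1e6 <= 20
  expect_setequal(narrow$spectrum_id, full$spectrum_id[in_tol])
})

test_that("search is deterministic and rejects scheme mismatches", {
  inst <- search_instance(303, n_spectra = 20L, n_proteins = 3L)
  a <- search_all(inst$idx, inst$peps, config = inst$cfg)
  b <- search_all(inst$idx, inst$peps, config = inst$cfg)
  expect_identical(psm_pair(a), psm_pair(b))
  cfg_bad <- search_config(bin_width = 0.05)
  expect_error(search_all(inst$idx, inst$peps, config = cfg_bad), "mismatch")
})

test_that("fragment charge 2 is only counted for multiply charged precursors", {
  cfg <- search_config(min_matched = 2L)
  pep <- "LVNEVTEFAK"
  fr <- fragment_ions(pep, charges = 2L)  # 2+ ions only
  mz <- c(fr$b[["2"]][3:6], fr$y[["2"]][3:6])
  M <- peptide_mass(pep)
  sp1 <- make_spectrum(0L, mz, rep(10, 8), precursor_mz = M + PROTON_MASS,
                       charge = 1L)
  sp2 <- make_spectrum(1L, mz, rep(10, 8),
                       precursor_mz = (M + 2 * PROTON_MASS) / 2, charge = 2L)
  sels <- lapply(list(sp1, sp2), select_top_k, k = cfg$k)
  idx <- build_spectrum_index(sels, cfg$scheme, spectra = list(sp1, sp2))
  psms <- search_all(idx, peptide_table(pep), config = cfg)
  # the 1+ precursor cannot use 2+ fragments, so only spectrum 1 matches
  expect_equal(psms$spectrum_id, 1L)
})
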