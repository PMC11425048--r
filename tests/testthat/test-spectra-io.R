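test_that("MGF parsing assigns ids in file order and derives neutral mass", {
  f <- tempfile(fileext = ".mgf")
  write_tiny_mgf(f, list(
    c("BEGIN IONS", "TITLE=a", "PEPMASS=500.5", "CHARGE=2+",
      "RTINSECONDS=12.5", "100.1 10", "200.2 20", "END IONS"),
    c("BEGIN IONS", "TITLE=b", "PEPMASS=400.25 12345", "CHARGE=3+",
      "300.3 5", "END IONS")
  ))
  sp <- read_spectra(f, "mgf")
  expect_length(sp, 2L)
  expect_identical(vapply(sp, `[[`, integer(1L), "spectrum_id"), 0:1)
  expect_equal(sp[[1]]$precursor_neutral_mass, 2 * (500.5 - 1.007276),
               tolerance = 1e-5)
  expect_equal(sp[[1]]$retention_time, 12.5)
  expect_equal(sp[[2]]$precursor_mz, 400.25)  # first PEPMASS token only
  expect_equal(sp[[2]]$precursor_charge, 3L)
})

test_that("MGF degenerate blocks: empty peak lists and missing headers", {
  f <- tempfile(fileext = ".mgf")
  write_tiny_mgf(f, list(
    c("BEGIN IONS", "PEPMASS=500.5", "CHARGE=2+", "END IONS"),
    c("BEGIN IONS", "PEPMASS=300.1", "150.5 7", "END IONS"),
    c("BEGIN IONS", "CHARGE=2+", "100 1", "END IONS")
  ))
  expect_warning(expect_warning(
    expect_warning(sp <- read_spectra(f, "mgf"), "empty peak list"),
    "assuming 2\\+"), "no PEPMASS")
  expect_length(sp, 2L)  # the PEPMASS-less scan is skipped
  expect_length(sp[[1]]$mz, 0L)
  expect_equal(sp[[2]]$precursor_charge, 2L)  # missing charge default
  expect_error(read_spectra(tempfile(), "mgf"), "not found")
})

test_that("mzML scans are read through mzR, skipping MS1", {
  f <- tempfile(fileext = ".mzML")
  write_tiny_mzml(f, list(
    list(ms_level = 1L, rt = 10, mz = c(400.1, 500.1), intensity = c(1, 2)),
    list(ms_level = 2L, rt = 61, mz = c(100.5, 200.25, 300.125),
         intensity = c(10, 20, 30), precursor_mz = 500.5, charge = 2L),
    list(ms_level = 2L, rt = 62, mz = c(150.1), intensity = c(5),
         precursor_mz = 600.25, charge = 3L)
  ))
  sp <- read_spectra(f, "mzml")
  expect_length(sp, 2L)
  expect_identical(vapply(sp, `[[`, integer(1L), "spectrum_id"), 0:1)
  expect_equal(sp[[1]]$mz, c(100.5, 200.25, 300.125))
  expect_equal(sp[[1]]$intensity, c(10, 20, 30))
  expect_equal(sp[[1]]$retention_time, 61)
  expect_equal(sp[[2]]$precursor_charge, 3L)
})

test_that("MGF writer round-trips synthetic spectra to text precision", {
  spec <- synthetic_run_spec(n_proteins = 5L, n_spectra = 8L)
  prot <- make_proteome(spec, seed = 11)
  run <- simulate_run(prot, spec, seed = 11)
  f <- tempfile(fileext = ".mgf")
  write_mgf(run$spectra, f)
  back <- read_spectra(f, "mgf")
  expect_length(back, length(run$spectra))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$mz, run$spectra[[i]]$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$intensity, run$spectra[[i]]$intensity,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$precursor_charge, run$spectra[[i]]$precursor_charge)
  }
})

test_that("top-K selection keeps the K most intense peaks, m/z-sorted", {
  s <- make_spectrum(0L, c(100, 200, 300), c(5, 1, 9))
  sel <- select_top_k(s, 2L)
  expect_equal(sel$mz, c(100, 300))
  expect_equal(sel$intensity, c(5, 9))
  # intensity ties break toward lower m/z
  s2 <- make_spectrum(1L, c(100, 200), c(5, 5))
  expect_equal(select_top_k(s2, 1L)$mz, 100)
  # k beyond the peak count retains everything (default K = 150)
  s3 <- make_spectrum(2L, seq(100, 1000, length.out = 10), runif(10))
  expect_length(select_top_k(s3, 150L)$mz, 10L)
})

test_that("top-K intensity multiset matches a sort-based oracle", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:200, 1L)
    k <- sample(1:150, 1L)
    s <- make_spectrum(0L, runif(n, 100, 1500), round(runif(n, 0, 50)))
    sel <- select_top_k(s, k)
    oracle <- sort(s$intensity, decreasing = TRUE)[seq_len(min(k, n))]
    expect_equal(sort(sel$intensity, decreasing = TRUE), oracle)
    expect_false(is.unsorted(sel$mz))
  }
})

test_that("m/z binning follows the floor convention with half-open bins", {
  sc <- binning_scheme(0.02)
  expect_equal(bin_mz(500.25, sc), 25012)
  expect_equal(bin_mz(0.02, sc), 1)  # [0.02, 0.04) is bin 1
  expect_equal(bin_mz(1000.004, sc), bin_mz(1000.016, sc))
  expect_equal(bin_mz(1000.004, sc), 50000)
  expect_error(bin_mz(0, sc), "offset")
  expect_error(binning_scheme(0), "bin_width > 0")
  # round trip: every m/z is within half a bin width of its bin center
  set.seed(2)
  mz <- runif(500, 100, 2000)
  expect_true(all(abs(bin_center(bin_mz(mz, sc), sc) - mz) <= sc$bin_width / 2))
})

test_that("bin-width calibration: zero case and brute-force totals", {
  sc <- binning_scheme(0.02)
  ctr <- bin_center(1000L, sc)
  r <- optimal_bin_width(ctr, widths = c(0.02))
  expect_equal(r$curve$total_error, 0)

  mz <- c(250.013, 977.402)
  r2 <- optimal_bin_width(mz, widths = c(0.01, 0.02))
  brute <- vapply(c(0.01, 0.02), function(w) {
    sum(vapply(mz, function(x) {
      b <- floor(x / w)
      (x - (b + 0.5) * w)^2
    }, numeric(1L)))
  }, numeric(1L))
  expect_equal(r2$curve$total_error, brute)
  expect_equal(r2$best_width, c(0.01, 0.02)[which.min(brute)])
  expect_error(optimal_bin_width(mz, widths = numeric(0)), "empty")
})

test_that("calibration against known true m/z has one interior minimum", {
  set.seed(7)
  true_mz <- runif(20000, 200, 1500)
  obs <- true_mz + rnorm(20000, 0, 0.01)
  r <- optimal_bin_width(obs, reference = true_mz)
  te <- r$curve$total_error
  n <- length(te)
  n_min <- sum(vapply(2:(n - 1), function(i) {
    te[i] < te[i - 1] && te[i] < te[i + 1]
  }, logical(1L)))
  expect_identical(n_min, 1L)
  # the optimum sits in the interior, near twice the instrument sigma
  expect_gt(r$best_width, min(r$curve$width))
  expect_lt(r$best_width, max(r$curve$width))
  expect_gt(r$best_width, 0.01)
  expect_lt(r$best_width, 0.04)
})
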