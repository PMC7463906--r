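test_that("spectrum container enforces its axis and metadata invariants", {
  m <- matrix(rnorm(20), 2, 10)
  expect_error(tiny_spectrum_set(m, wavenumber = seq(400, 4000, length.out = 10)),
               "decreasing")
  expect_error(tiny_spectrum_set(m, wavenumber = c(4000, 3996, 3990, 3986, 3982,
                                                   3978, 3974, 3970, 3966, 3962)),
               "uniform")
  meta <- tibble::tibble(sample_id = c("s", "s"), strain = "x",
                         condition = 0, replicate = 1:2)
  expect_error(spectrum_set(c(4000, 3996), matrix(0, 2, 2), meta), "Duplicate")
})

test_that("spectra CSV round-trips and parses metadata from sample ids", {
  sc <- line_scenario(seed = 3, noise_sd = 0.01, baseline_sd = 0.01)
  sp <- simulate_spectra(sc)
  path <- tempfile(fileext = ".csv")
  write_spectra_csv(sp, path)
  back <- read_spectra_csv(path)
  expect_equal(back$wavenumber, sp$wavenumber)
  expect_equal(back$absorbance, sp$absorbance, tolerance = 1e-12)
  expect_equal(back$meta$strain, sp$meta$strain)
  expect_equal(back$meta$condition, sp$meta$condition)

  # shuffled axis: sorted silently, or an error in strict mode
  df <- readr::read_csv(path, show_col_types = FALSE)
  shuffled <- tempfile(fileext = ".csv")
  readr::write_csv(df[sample.int(nrow(df)), ], shuffled)
  expect_equal(read_spectra_csv(shuffled)$absorbance, sp$absorbance,
               tolerance = 1e-12)
  expect_error(read_spectra_csv(shuffled, strict = TRUE), "decreasing")

  # a column whose name cannot yield strain/condition/replicate
  names(df)[2] <- "badname"
  bad <- tempfile(fileext = ".csv")
  readr::write_csv(df, bad)
  expect_error(read_spectra_csv(bad), "badname")
})

test_that("SNR quality test handles clean, noisy and degenerate spectra", {
  wn <- seq(4000, 400, by = -4)
  peak <- 1000 * exp(-((wn - 2900) / 30)^2)
  clean <- tiny_spectrum_set(rbind(peak))
  q <- quality_snr(clean)
  expect_true(is.infinite(q$snr) && q$pass)

  flat <- tiny_spectrum_set(matrix(1, 1, 901))
  q0 <- quality_snr(flat)
  expect_equal(q0$snr, 0)
  expect_false(q0$pass)

  # planted noise sd 1 against amplitude 1000: mean SNR within 10% of 1000
  snrs <- vapply(1:50, function(seed) {
    set.seed(seed)
    noisy <- tiny_spectrum_set(rbind(peak + rnorm(901)))
    quality_snr(noisy)$snr
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 1000) / 1000, 0.1)

  expect_error(quality_snr(clean, quality_interval = c(2100, 2090)), "< 8")
})

test_that("rubberband correction removes lines and preserves peaks", {
  wn <- seq(4000, 400, by = -4)
  line <- 2 + 0.001 * wn
  corrected <- rubberband_baseline(tiny_spectrum_set(rbind(line)))
  expect_lt(max(abs(corrected$absorbance)), 1e-9)

  peak <- exp(-((wn - 1650) / 20)^2)
  both <- rubberband_baseline(tiny_spectrum_set(rbind(line + peak)))
  outside <- abs(wn - 1650) > 150 # clear of the hull-bridged interval
  expect_lt(max(abs(both$absorbance[1, outside] - peak[outside])), 1e-6)
  # the peak itself survives near its apex
  expect_gt(max(both$absorbance), 0.9)

  # convex-up bowl lies entirely on its own lower hull
  bowl <- ((wn - 2200) / 1800)^2
  flat <- rubberband_baseline(tiny_spectrum_set(rbind(bowl)))
  expect_lt(max(abs(flat$absorbance)), 1e-3) # 64-anchor interpolation error

  expect_error(rubberband_baseline(tiny_spectrum_set(rbind(line)),
                                   n_points = 1), ">= 2")
})

test_that("rubberband is idempotent up to its anchor interpolation error", {
  # smooth spectra: the 64-anchor baseline of an already-corrected spectrum
  # is essentially zero
  sc_smooth <- line_scenario(seed = 9, noise_sd = 0, baseline_sd = 0.05,
                             amplitudes = c(0, 0, 0, 0))
  once <- rubberband_baseline(simulate_spectra(sc_smooth))
  twice <- rubberband_baseline(once)
  expect_lt(max(abs(twice$absorbance - once$absorbance)), 1e-4)

  # noisy spectra: the hull kinks at noise minima, so the residual baseline
  # is bounded by a few times the noise scale, not machine precision
  sc_noisy <- line_scenario(seed = 9, noise_sd = 0.005, baseline_sd = 0.05,
                            amplitudes = c(0.1, 0.1, 0.1, 0.1))
  once_n <- rubberband_baseline(simulate_spectra(sc_noisy))
  twice_n <- rubberband_baseline(once_n)
  expect_lt(max(abs(twice_n$absorbance - once_n$absorbance)), 5 * 0.005)
})

test_that("vector normalization centers, scales and is scale invariant", {
  s <- tiny_spectrum_set(rbind(c(1, 2, 3)), wavenumber = c(4000, 3996, 3992))
  out <- vector_normalize(s)
  expect_equal(as.vector(out$absorbance),
               c(-1, 0, 1) / sqrt(2), tolerance = 1e-9)
  expect_equal(as.vector(out$absorbance), c(-0.70711, 0, 0.70711),
               tolerance = 1e-5)

  sc <- line_scenario(seed = 2, noise_sd = 0.01, baseline_sd = 0.02)
  sp <- simulate_spectra(sc)
  n1 <- vector_normalize(sp)
  expect_equal(rowSums(n1$absorbance^2), rep(1, nrow(n1$absorbance)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rowMeans(n1$absorbance), rep(0, nrow(n1$absorbance)),
               tolerance = 1e-12, ignore_attr = TRUE)
  scaled <- spectrum_set(sp$wavenumber, sp$absorbance * 5, sp$meta)
  expect_equal(vector_normalize(scaled)$absorbance, n1$absorbance,
               tolerance = 1e-12)
  # normalizing twice equals once
  expect_equal(vector_normalize(n1)$absorbance, n1$absorbance,
               tolerance = 1e-12)

  expect_error(vector_normalize(tiny_spectrum_set(matrix(3, 1, 10))),
               "constant")
})

test_that("region extraction matches the documented window arithmetic", {
  sc <- line_scenario(seed = 1)
  sp <- simulate_spectra(sc)
  w1 <- extract_region(sp, "W1")
  expect_equal(ncol(w1$absorbance), 100) # (3200 - 2800) / 4
  expect_true(all(w1$wavenumber <= 3200 & w1$wavenumber > 2800))

  full <- extract_region(sp, c(4000, 399))
  expect_equal(full$absorbance, sp$absorbance)

  expect_error(extract_region(sp, c(300, 200)), "intersect")
  expect_error(extract_region(sp, "W9"), "Unknown region")
})

test_that("replicate averaging commutes with region extraction", {
  sc <- line_scenario(seed = 8, noise_sd = 0.01, baseline_sd = 0.02)
  sp <- simulate_spectra(sc)
  a <- extract_region(average_replicates(sp), "W2")
  b <- average_replicates(extract_region(sp, "W2"))
  expect_equal(a$absorbance, b$absorbance, tolerance = 1e-12)
  expect_equal(a$meta$n_averaged, b$meta$n_averaged)

  # identical replicates average to themselves
  one <- sp$absorbance[1, ]
  rep3 <- tiny_spectrum_set(rbind(one, one, one), strains = rep("x", 3),
                            conditions = rep(0, 3))
  expect_equal(as.vector(average_replicates(rep3)$absorbance), unname(one))

  # two replicates at 0 and 2 average to 1
  pair <- tiny_spectrum_set(rbind(rep(0, 10), rep(2, 10)),
                            strains = c("x", "x"), conditions = c(0, 0))
  expect_true(all(average_replicates(pair)$absorbance == 1))

  # grouping by strain only pools conditions
  by_strain <- average_replicates(sp, by = "strain")
  expect_equal(nrow(by_strain$absorbance), 4)
})

test_that("interval masking zeroes only the requested bands", {
  sc <- line_scenario(seed = 2, noise_sd = 0.01, baseline_sd = 0.02)
  sp <- simulate_spectra(sc)
  masked <- mask_intervals(sp, list(c(2400, 2300)))
  cols <- sp$wavenumber <= 2400 & sp$wavenumber > 2300
  expect_true(all(masked$absorbance[, cols] == 0))
  expect_equal(masked$absorbance[, !cols], sp$absorbance[, !cols])
})
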