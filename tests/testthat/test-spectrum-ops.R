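make_raw_set <- function(grid, reflectance, ref_level = 1000, dark_level = 50) {
  ref <- spectrum(grid, rep(ref_level, length(grid)), "reference")
  drk <- spectrum(grid, rep(dark_level, length(grid)), "dark")
  sig <- spectrum(grid, dark_level + reflectance * (ref_level - dark_level), "raw")
  list(signal = sig, reference = ref, dark = drk)
}

test_that("normalization implements (S - D) / (REF - D) pointwise", {
  grid <- wavelength_grid(points = 64)
  rs <- make_raw_set(grid, rep(0.36, 64))
  r <- normalize_reflectance(rs$signal, rs$reference, rs$dark)
  expect_equal(r$value, rep(0.36, 64), tolerance = 1e-14)
  expect_identical(attr(r, "kind"), "reflectance")

  # S = REF gives 1 everywhere; S = D gives 0 everywhere
  r1 <- normalize_reflectance(rs$reference, rs$reference, rs$dark)
  expect_equal(r1$value, rep(1, 64))
  r0 <- normalize_reflectance(rs$dark, rs$reference, rs$dark)
  expect_equal(r0$value, rep(0, 64))

  # a full simulated chip spectrum survives the raw round trip
  chip_r <- simulate_spectrum(canonical_chip(), grid)
  rs2 <- make_raw_set(grid, chip_r$value)
  expect_equal(normalize_reflectance(rs2$signal, rs2$reference, rs2$dark)$value,
               chip_r$value, tolerance = 1e-12)
})

test_that("normalization rejects mismatched grids and degenerate references", {
  g1 <- wavelength_grid(points = 32)
  g2 <- wavelength_grid(points = 33)
  s1 <- spectrum(g1, rep(1, 32))
  expect_error(
    normalize_reflectance(s1, spectrum(g2, rep(2, 33)), spectrum(g2, rep(0, 33))),
    class = "wlrs_invalid_input"
  )
  ref <- spectrum(g1, c(rep(100, 20), rep(0, 12)), "reference")
  drk <- spectrum(g1, rep(10, 32), "dark")
  err <- expect_error(normalize_reflectance(s1, ref, drk),
                      class = "wlrs_degenerate_reference")
  # the error names the first offending wavelength
  expect_match(conditionMessage(err), sprintf("%.6g", g1[21]), fixed = TRUE)
})

test_that("extremum localization reaches sub-grid accuracy on a known cosine", {
  # cosine with period 80 nm: minima at 500 + 40 + 80 k
  grid <- seq(450, 800, by = 0.7)
  sp <- spectrum(grid, 0.2 + 0.1 * cos(2 * pi * (grid - 500) / 80), "reflectance")
  ext <- locate_extrema(sp)
  mins <- ext$wavelength_nm[ext$type == "min"]
  maxs <- ext$wavelength_nm[ext$type == "max"]
  expect_equal(mins, seq(460, 780, by = 80), tolerance = 1e-2 / 460)
  expect_equal(maxs, seq(500, 790, by = 80), tolerance = 1e-2 / 500)
  expect_equal(ext$value[ext$type == "min"], rep(0.1, length(mins)), tolerance = 1e-4)
})

test_that("monotone spectra yield no extrema and short windows error", {
  grid <- wavelength_grid(points = 64)
  mono <- spectrum(grid, seq(0.1, 0.5, length.out = 64), "reflectance")
  expect_identical(nrow(locate_extrema(mono)), 0L)
  expect_error(locate_extrema(mono, range = c(450, 451)),
               class = "wlrs_invalid_input")
})

test_that("fringe counting matches the analytic minimum condition", {
  expect_identical(count_fringes(simulate_spectrum(layer_stack(), wavelength_grid())), 0L)
  expect_identical(count_fringes(simulate_spectrum(canonical_chip(), wavelength_grid())), 2L)
  expect_gte(count_fringes(simulate_spectrum(canonical_chip(oxide_nm = 500),
                                             wavelength_grid())), 1L)
  # analytic count: minima at 2 n d = (m + 1/2) lambda strictly inside
  # 450-800 nm; prominence 0 counts every strict minimum, so the analytic
  # enumeration applies exactly (the default 2 percent filter additionally
  # drops minima squeezed against the range edge)
  analytic_fringes <- function(d) {
    m <- 0:100
    lam <- 2 * 1.46 * d / (m + 0.5)
    sum(lam > 450 & lam < 800)
  }
  for (d in c(600, 900, 1500, 2200, 3000)) {
    sp <- simulate_spectrum(canonical_chip(oxide_nm = d), wavelength_grid(points = 2048))
    expect_identical(count_fringes(sp, prominence = 0), analytic_fringes(d))
  }
})

test_that("fringe count is non-decreasing in oxide thickness", {
  set.seed(11)
  d <- sort(runif(12, 300, 3000))
  counts <- vapply(d, function(di) {
    count_fringes(simulate_spectrum(canonical_chip(oxide_nm = di),
                                    wavelength_grid(points = 1024)),
                  prominence = 0)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("peak tracking follows a growing adlayer and recovers the shift", {
  grid <- wavelength_grid()
  adlayer_seq <- seq(0, 5, length.out = 11)
  spectra <- lapply(adlayer_seq, function(d) {
    simulate_spectrum(canonical_chip(adlayer_nm = d), grid)
  })
  series <- spectrum_series(seq(0, 100, length.out = 11), spectra)
  trk <- track_peak(series, window = c(610, 690))
  # optical path grows with the adlayer, so lambda_max must increase strictly
  expect_true(all(diff(trk$lambda_max_nm) > 0))
  # against the dense-grid oracle, the recovered shifts are sub-0.01 nm
  oracle <- vapply(adlayer_seq, function(d) {
    oracle_lambda_min(canonical_chip(adlayer_nm = d), c(610, 690))
  }, numeric(1))
  expect_lt(max(abs((trk$lambda_max_nm - trk$lambda_max_nm[1]) -
                      (oracle - oracle[1]))), 0.01)

  # a static stack tracks a constant lambda_max
  static <- spectrum_series(0:3, rep(spectra[1], 4))
  trk0 <- track_peak(static, window = c(610, 690))
  expect_equal(diff(range(trk0$lambda_max_nm)), 0)
})

test_that("tracking fails loudly when the window loses the peak", {
  grid <- wavelength_grid()
  sp <- simulate_spectrum(canonical_chip(), grid)
  series <- spectrum_series(c(0, 10), list(sp, sp))
  # window with no minimum
  expect_error(track_peak(series, window = c(560, 610)),
               class = "wlrs_tracking_failure")
  # window containing both minima
  err <- expect_error(track_peak(series, window = c(460, 790)),
                      class = "wlrs_tracking_failure")
  expect_match(conditionMessage(err), "t = 0")
})

test_that("peak-shift conversion is the stated linear formula", {
  p <- shift_conversion_params(d2 = 100, lambda_ref = 600)
  expect_identical(shift_to_thickness(0, p), 0)
  # a 1 percent relative shift on a 100 nm transducer gives 2.06 nm
  expect_equal(shift_to_thickness(6, p), 2.06)
  p2 <- shift_conversion_params(d2 = 1040, lambda_ref = 600)
  expect_equal(shift_to_thickness(1, p2), 2.06 * 1040 / 600, tolerance = 1e-12)
  # exact linearity and homogeneity in the shift
  dl <- c(-2, -0.5, 0.3, 1, 4)
  expect_equal(shift_to_thickness(3 * dl, p2), 3 * shift_to_thickness(dl, p2))
  expect_error(shift_conversion_params(d2 = 0, lambda_ref = 600),
               class = "wlrs_invalid_input")
})
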