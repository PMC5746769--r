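test_that("Langmuir generator honors its closed-form identities", {
  times <- seq(0, 3600, by = 10)
  # no analyte, no growth
  sg0 <- simulate_binding(binding_params(1e5, 1e-3, 0, 5), times)
  expect_equal(sg0$thickness_nm, rep(0, length(times)))

  # equilibrium plateau = d_max C / (C + K_D), for many parameter draws
  set.seed(21)
  for (rep in 1:20) {
    k_on <- 10^runif(1, 3, 6)
    k_off <- 10^runif(1, -4, -2)
    conc <- 10^runif(1, -10, -6)
    d_max <- runif(1, 1, 10)
    p <- binding_params(k_on, k_off, conc, d_max)
    t_long <- 50 / (k_on * conc + k_off)
    sg <- simulate_binding(p, c(0, t_long))
    K_D <- k_off / k_on
    expect_equal(sg$thickness_nm[2] / d_max, conc / (conc + K_D),
                 tolerance = 1e-9)
  }
})

test_that("initial binding slope matches the analytic derivative", {
  p <- binding_params(k_on = 1e5, k_off = 1e-3, conc = 1e-8, d_max = 5)
  h <- 1e-4
  sg <- simulate_binding(p, c(0, h))
  fd_slope <- diff(sg$thickness_nm) / h
  analytic <- p$d_max * p$k_on * p$conc
  expect_equal(fd_slope, analytic, tolerance = 1e-3)
})

test_that("dissociation continues from the association plateau", {
  p <- binding_params(1e5, 1e-3, 1e-8, 5)
  assoc <- simulate_binding(p, seq(0, 5000, by = 100))
  theta_end <- tail(assoc$thickness_nm, 1) / p$d_max
  dis <- simulate_binding(binding_params(1e5, 1e-3, 0, 5),
                          seq(0, 5000, by = 100), theta0 = theta_end)
  expect_equal(dis$thickness_nm[1], tail(assoc$thickness_nm, 1))
  expect_true(all(diff(dis$thickness_nm) < 0))
  # decay rate is k_off alone
  expect_equal(dis$thickness_nm[2] / dis$thickness_nm[1], exp(-1e-3 * 100),
               tolerance = 1e-9)
})

test_that("swelling relaxation hits the exponential landmarks", {
  tau <- 30
  sg_flat <- simulate_swelling(0, tau, 100, seq(0, 300, by = 5))
  expect_equal(sg_flat$thickness_nm, rep(100, 61))

  times <- seq(0, 300, by = 0.5)
  sg <- simulate_swelling(0.05, tau, 100, times)
  # 63.2 percent of the step completed at t = tau
  at_tau <- sg$thickness_nm[times == tau]
  expect_equal((at_tau - 100) / 5, 1 - exp(-1), tolerance = 1e-12)

  # sorption then desorption returns to baseline within 0.1 percent
  full <- simulate_swelling(0.05, tau, 100, seq(0, 12 * tau, by = 1),
                            t_switch = 6 * tau)
  final <- tail(full$thickness_nm, 1)
  expect_lt(abs(final - 100) / 100, 0.001)
  # desorption is symmetric: same time constant on the way down
  after <- full$thickness_nm[full$time_s >= 6 * tau]
  excess <- after - 100
  expect_equal(excess[31] / excess[1], exp(-30 / tau), tolerance = 1e-6)
})

test_that("sensorgram-to-spectra bridging is deterministic and invertible", {
  grid <- wavelength_grid(points = 128)
  chip <- canonical_chip(adlayer_nm = 0)
  sg <- sensorgram(c(0, 60, 120), c(1, 2, 3))

  # noiseless constant sensorgram gives identical spectra
  sgc <- sensorgram(c(0, 60, 120), rep(2, 3))
  ser <- sensorgram_to_spectra(sgc, chip, "adlayer", grid)
  expect_identical(ser$spectra[[1]]$value, ser$spectra[[3]]$value)

  # fixed seed gives bit-identical noisy series
  s1 <- sensorgram_to_spectra(sg, chip, "adlayer", grid, noise_sd = 0.01, seed = 9)
  s2 <- sensorgram_to_spectra(sg, chip, "adlayer", grid, noise_sd = 0.01, seed = 9)
  expect_identical(s1$spectra[[2]]$value, s2$spectra[[2]]$value)

  # round trip through the fitter recovers the sensorgram (noiseless)
  pr <- fit_problem(chip, free = "adlayer", grid = grid)
  rec <- fit_time_series(sensorgram_to_spectra(sg, chip, "adlayer", grid), pr)
  expect_lt(10 * sqrt(mean((rec$thickness_nm - sg$thickness_nm)^2)), 0.1)
})

test_that("reagent enhancement scales the response multiplicatively", {
  p <- binding_params(1e5, 1e-3, 1e-8, 5)
  sg <- simulate_binding(p, seq(0, 600, by = 10))
  enh <- enhance_response(sg, gain = 4)
  expect_equal(enh$thickness_nm, 4 * sg$thickness_nm)
  expect_equal(endpoint_signal(enh, 600), 4 * endpoint_signal(sg, 600))
  # enhancement rescales a calibration but leaves its midpoint alone
  concs <- c(0, 1, 3, 10, 30, 100)
  resp <- 5 * concs / (concs + 10)
  cal1 <- build_calibration(concs, resp, format = "two_site")
  cal4 <- build_calibration(concs, 4 * resp, format = "two_site")
  expect_equal(cal4$params["d"], 4 * cal1$params["d"], tolerance = 1e-4)
  expect_equal(cal4$params["c"], cal1$params["c"], tolerance = 1e-4)
  expect_error(enhance_response(sg, gain = 0), class = "wlrs_invalid_input")
})

test_that("endpoint and initial-rate readouts match their closed forms", {
  p <- binding_params(1e5, 1e-3, 1e-8, 5)
  times <- seq(0, 1200, by = 1)
  sg <- simulate_binding(p, times)
  rate <- p$k_on * p$conc + p$k_off
  theta_eq <- p$k_on * p$conc / rate

  # mid-course endpoint equals the closed form, including interpolation
  t_end <- 599.5
  expected <- p$d_max * theta_eq * (1 - exp(-rate * t_end))
  expect_equal(endpoint_signal(sg, t_end), expected, tolerance = 1e-6)
  expect_equal(endpoint_signal(sg, 0), 0)
  # long-run endpoint reaches the plateau
  sg_long <- simulate_binding(p, seq(0, 50 / rate, length.out = 200))
  expect_equal(endpoint_signal(sg_long, 50 / rate), p$d_max * theta_eq,
               tolerance = 1e-6)

  # constant sensorgram has zero rate; short-window slope tends to the
  # analytic initial derivative
  expect_equal(initial_rate(sensorgram(0:9, rep(2, 10)), 9), 0)
  fine <- simulate_binding(p, seq(0, 5, by = 0.1))
  expect_equal(initial_rate(fine, 5), p$d_max * p$k_on * p$conc,
               tolerance = 5e-3)
  expect_error(initial_rate(fine, 100), class = "wlrs_invalid_input")
})

test_that("initial rate is proportional to concentration well below K_D", {
  concs <- c(1, 2, 5, 10, 20) * 1e-10 # K_D is 1e-8 M here
  rates <- vapply(concs, function(cc) {
    sg <- simulate_binding(binding_params(1e5, 1e-3, cc, 5), seq(0, 60, by = 1))
    initial_rate(sg, 60)
  }, numeric(1))
  fit <- lm(rates ~ concs)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("endpoint and rate readouts rank concentrations identically", {
  concs <- c(1e-10, 1e-9, 5e-9, 2e-8, 1e-7)
  ep <- ir <- numeric(length(concs))
  for (i in seq_along(concs)) {
    sg <- simulate_binding(binding_params(1e5, 1e-3, concs[i], 5),
                           seq(0, 600, by = 5))
    ep[i] <- endpoint_signal(sg, 600)
    ir[i] <- initial_rate(sg, 60)
  }
  expect_identical(order(ep), order(ir))
  expect_equal(suppressWarnings(cor(ep, ir, method = "spearman")), 1)
})
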