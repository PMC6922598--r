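# Binding equilibrium arithmetic, two-state lineshapes, titration fitting
# and melt-curve processing.

three_peak_params <- function(kd = 24.1e-6, koff = 60.7, r2b = 30, scale = 1)
  two_state_params(
    kd = kd, koff = koff,
    delta_free = rbind(c(0.80, 13.5), c(0.52, 23.1), c(1.05, 17.4)),
    delta_bound = rbind(c(0.93, 13.8), c(0.41, 22.8), c(1.17, 17.1)),
    r2_free = 25, r2_bound = r2b, scale = scale)

test_that("free_ligand solves the binding quadratic exactly", {
  expect_equal(free_ligand(1e-4, 0, 1e-5),
               c(l_free = 0, complex = 0))
  # weak-binding limit: almost all ligand free
  fl <- free_ligand(1e-4, 1e-4, 10)
  expect_equal(fl[["l_free"]], 1e-4, tolerance = 1e-4)
  # P = L = K has the closed-form solution K(3 - sqrt(5))/2
  K <- 3.3e-5
  expect_equal(free_ligand(K, K, K)[["complex"]], K * (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  expect_error(free_ligand(-1, 0, 1), ">= 0")
  # mass conservation and monotonicity in kd
  set.seed(19)
  prev <- Inf
  for (kd in 10^seq(-7, -3, length.out = 9)) {
    fl <- free_ligand(118e-6, 150e-6, kd)
    expect_equal(fl[["l_free"]] + fl[["complex"]], 150e-6, tolerance = 1e-18)
    expect_lte(fl[["complex"]], prev)
    prev <- fl[["complex"]]
  }
})

test_that("kon_from implements koff/kd with the reported magnitude", {
  expect_equal(signif(kon_from(24.1e-6, 60.7), 2), 2.5e6)
  expect_equal(kon_from(1, 0), 0)
  expect_equal(kon_from(1, 1), 1)
  expect_error(kon_from(0, 1), "positive")
})

test_that("lineshape limits: apo Lorentzian, saturation, fast exchange", {
  p <- three_peak_params()
  grid <- list(seq(0.7, 1.05, length.out = 3001), seq(13.2, 14.1, length.out = 501))
  apo <- simulate_lineshape(p, 118e-6, 0, grid)
  d1 <- apo$peak1$dims[[1]]
  expect_equal(d1$ppm[which.max(d1$amp)], 0.80, tolerance = 1e-3)
  # FWHM = R2/pi Hz for the pure Lorentzian
  half <- max(d1$amp) / 2
  fw_ppm <- diff(range(d1$ppm[d1$amp >= half]))
  expect_equal(fw_ppm * 800, 25 / pi, tolerance = 0.3)

  sat <- simulate_lineshape(p, 118e-6, 0.5, grid)
  d1s <- sat$peak1$dims[[1]]
  expect_equal(d1s$ppm[which.max(d1s$amp)], 0.93, tolerance = 1e-3)

  # fast exchange: single peak at the population-weighted shift
  pf <- two_state_params(kd = 1e-3, koff = 1e6, delta_free = 0.8,
                         delta_bound = 0.95, r2_free = 25, r2_bound = 25,
                         field_mhz = 800)
  eq <- free_ligand(118e-6, 2e-3, 1e-3)
  fb <- eq[["complex"]] / 118e-6
  want <- 0.8 + fb * 0.15
  sf <- simulate_lineshape(pf, 118e-6, 2e-3, list(seq(0.7, 1.05, length.out = 7001)))
  got <- sf$peak1$dims[[1]]$ppm[which.max(sf$peak1$dims[[1]]$amp)]
  expect_equal(got, want, tolerance = 0.01 * want)
})

test_that("slow exchange shows two peaks with population-proportional areas", {
  # koff << delta-omega: 0.15 ppm at 800 MHz ~ 754 rad/s >> koff = 5/s
  p <- two_state_params(kd = 24.1e-6, koff = 5, delta_free = 0.8,
                        delta_bound = 0.95, r2_free = 15, r2_bound = 15,
                        field_mhz = 800)
  P <- 118e-6
  L <- 0.8 * P
  eq <- free_ligand(P, L, p$kd)
  pb <- eq[["complex"]] / P
  grid <- seq(0.65, 1.1, length.out = 9001)
  s <- simulate_lineshape(p, P, L, list(grid))$peak1$dims[[1]]
  cut <- mean(c(0.8, 0.95))
  a_free <- sum(s$amp[s$ppm < cut])
  a_bound <- sum(s$amp[s$ppm >= cut])
  expect_equal(a_bound / (a_free + a_bound), pb, tolerance = 0.05)
  # peak position moves monotonically with bound fraction (here: two
  # maxima at the free/bound shifts; intensity transfers between them)
  expect_equal(s$ppm[which.max(s$amp)], 0.95, tolerance = 5e-3)
})

test_that("fit_titration recovers generating parameters", {
  truth <- three_peak_params()
  ser0 <- make_titration_series(truth, noise_sd = 0)
  init <- three_peak_params(kd = 6e-5, koff = 120, r2b = 25, scale = 1.15)
  init$delta_bound <- truth$delta_bound + 0.02
  fit0 <- fit_titration(ser0, init, seed = 1, n_boot = 0)
  expect_equal(fit0$params$kd, 24.1e-6, tolerance = 0.01 * 24.1e-6)
  expect_equal(fit0$params$koff, 60.7, tolerance = 0.01 * 60.7)

  # constrained fits at half and twice the generating KD are worse
  noisy <- make_titration_series(truth, noise_sd = 0.02, seed = 5)
  fit_free <- fit_titration(noisy, init, seed = 2, n_boot = 0)
  fit_half <- fit_titration(noisy, init, seed = 2, n_boot = 0, fix_kd = 12e-6)
  fit_twice <- fit_titration(noisy, init, seed = 2, n_boot = 0, fix_kd = 48e-6)
  expect_gt(fit_half$chisq, fit_free$chisq)
  expect_gt(fit_twice$chisq, fit_free$chisq)

  short <- ser0
  short$points <- short$points[1:2]
  expect_error(fit_titration(short, init), "at least 3")
})

test_that("fraction_bound_kd brackets the generating KD", {
  P <- 118e-6
  ratios <- c(0, 0.25, 0.5, 1, 2, 4, 8)
  kd_true <- 30e-6
  fb <- vapply(ratios * P, function(L) free_ligand(P, L, kd_true)[["complex"]] / P, 1)
  shifts <- 0.8 + fb * 0.15
  r <- fraction_bound_kd(shifts, P, ratios * P)
  expect_lte(r$kd_lower, kd_true * 1.001)
  expect_gte(r$kd_upper, kd_true * 0.999)
  expect_false(r$wide_bounds)
  expect_error(fraction_bound_kd(rep(0.8, 7), P, ratios * P), "no binding signal")
  expect_error(fraction_bound_kd(c(0.8, 0.85), P, c(0, P)), ">= 2 points")
  two <- fraction_bound_kd(c(0.8, 0.86, 0.9), P, c(0, P, 3 * P))
  expect_true(two$wide_bounds)
})

test_that("detailed balance: simulated populations reconstruct the KD", {
  p <- three_peak_params()
  P <- 118e-6
  for (L in c(0.4, 1.2, 2.5) * P) {
    eq <- free_ligand(P, L, p$kd)
    pb <- eq[["complex"]] / P
    # the exchange rates used in the simulator satisfy
    # kon * l_free * p_free = koff * p_bound at equilibrium
    kon <- p$koff / p$kd
    expect_equal(kon * eq[["l_free"]] * (1 - pb), p$koff * pb,
                 tolerance = 1e-9 * p$koff * pb)
    # reconstructing kd from the populations returns the model kd
    expect_equal(eq[["l_free"]] * (1 - pb) / pb, p$kd, tolerance = 1e-12)
  }
})

test_that("thermofluor processing subtracts background and finds the melt", {
  temp <- seq(25, 95, by = 0.5)
  expect_length(temp, 141)
  base <- data.frame(temperature = temp, r1 = 100, r2 = 100, r3 = 100)
  zero <- process_thermofluor(base, base)
  expect_true(all(zero$fluorescence == 0))
  expect_equal(zero$metrics$n_points, 141)

  sig <- 1000 / (1 + exp(-(temp - 80) / 2.5))
  smp <- data.frame(temperature = temp, r1 = sig + 150, r2 = sig + 150,
                    r3 = sig + 150)
  bkg <- data.frame(temperature = temp, r1 = 150, r2 = 150, r3 = 150)
  mc <- process_thermofluor(smp, bkg)
  expect_equal(mc$metrics$tm_dfdt, 80, tolerance = 0.5)
  expect_false(mc$metrics$monotonic_decrease)
  # a decreasing curve is flagged as such
  dec <- data.frame(temperature = temp, r1 = rev(sig) + 150)
  mc2 <- process_thermofluor(dec, bkg[, 1:2])
  expect_true(mc2$metrics$monotonic_decrease)
  expect_error(process_thermofluor(smp, bkg[1:100, ]), "grids differ")
})
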