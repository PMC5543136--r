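# shared small synthetic problem for projection tests
make_seq_problem <- function(lifetimes = c(1, 20, Inf), noise = 0,
                             seed = 3, n_t = 60, n_wl = 40) {
  irf <- std_irf()
  tt <- linlog_time_axis(t_min = -1, t_switch = 1, t_max = 500,
                         n_points = n_t)
  wl <- seq(400, 660, length.out = n_wl)
  pre <- c1c2_presets(8)
  spectra <- preset_component_spectra(pre, wl)[seq_along(lifetimes), ,
                                               drop = FALSE]
  ds <- simulate_sequential_dataset(lifetimes, spectra, irf, tt, wl,
                                    noise_sigma = noise, seed = seed)
  list(ds = ds, irf = irf, tt = tt, wl = wl, spectra = spectra,
       lifetimes = lifetimes)
}

test_that("spectral projection recovers known spectra from noiseless data", {
  p <- make_seq_problem()
  rates <- ifelse(is.finite(p$lifetimes), 1 / p$lifetimes, 0)
  C <- sequential_concentrations(rates, p$tt, p$irf)$C
  pr <- project_spectra(p$ds, C)
  live <- p$ds$weights[1, ] > 0
  expect_lt(max(abs(pr$spectra[, live] - p$spectra[, live])), 1e-8)
  # residuals orthogonal to the concentration columns under the weights
  g <- t(C) %*% (p$ds$weights * pr$residuals)
  expect_lt(max(abs(g)), 1e-8)
})

test_that("collinear concentration columns raise an identifiability error", {
  p <- make_seq_problem()
  rates <- ifelse(is.finite(p$lifetimes), 1 / p$lifetimes, 0)
  C <- sequential_concentrations(rates, p$tt, p$irf)$C
  C2 <- cbind(C, C[, 2])   # duplicated kinetics
  expect_error(project_spectra(p$ds, C2), "rank deficient")
})

test_that("exponential fit without IRF recovers an exact lifetime", {
  tt <- seq(0.1, 30, by = 0.25)
  wl <- seq(450, 550, length.out = 12)
  sp <- matrix(exp(-(wl - 500)^2 / 500), 1)
  ds <- simulate_sequential_dataset(2.5, sp, NULL, tt, wl, noise_sigma = 0,
                                    mask_windows = list())
  f <- fit_sequential(ds, init_lifetimes = 5, irf = NULL, n_starts = 1)
  expect_equal(unname(f$lifetimes), 2.5, tolerance = 1e-8)
  expect_lt(f$ssq, 1e-16)
  # standard errors collapse on exact data
  expect_lt(f$std_errors$se[1], 1e-6)
})

test_that("noiseless multi-component fit recovers generating parameters", {
  p <- make_seq_problem(lifetimes = c(0.8, 6, 80, Inf))
  f <- fit_sequential(p$ds, init_lifetimes = c(0.4, 3, 40, Inf),
                      irf = irf_model(0.01, fwhm = 0.2), n_starts = 1)
  expect_equal(unname(f$lifetimes[1:3]), c(0.8, 6, 80), tolerance = 1e-6)
  expect_equal(f$irf$width, std_irf()$width, tolerance = 1e-6)
  live <- p$ds$weights[1, ] > 0
  expect_lt(max(abs(f$eads[, live] - p$spectra[, live])), 1e-6)
})

test_that("EADS/DADS round trip is the identity and reconstructs the data", {
  # single component: DADS = EADS
  sp1 <- matrix(1:5, 1)
  expect_equal(dads_from_eads(sp1, 3), sp1)
  # two far-separated components: first DADS ~ EADS1 - EADS2
  lt <- c(1, 1e4)
  A <- seq_amplitude_matrix(1 / lt)
  e <- rbind(c(1, 0.5, 0.2), c(0.3, 0.8, 0.1))
  d2 <- dads_from_eads(e, lt)
  expect_equal(d2[1, ], e[1, ] - e[2, ], tolerance = 1e-3)
  # brute-force basis change on a random 4-component case
  lt4 <- c(0.5, 4, 60, 900)
  tt <- linlog_time_axis(t_min = -1, t_switch = 1, t_max = 5e4, n_points = 80)
  e4 <- withr::with_seed(7, matrix(rnorm(4 * 9), 4))
  sc <- sequential_concentrations(1 / lt4, tt, std_irf())
  d4 <- dads_from_eads(e4, lt4)
  # parallel basis times DADS reproduces sequential basis times EADS
  expect_lt(max(abs(sc$Phi %*% d4 - sc$C %*% e4)), 1e-10)
  # round trip identity
  expect_lt(max(abs(eads_from_dads(d4, lt4) - e4)), 1e-10)
})

test_that("six-component recovery at 1% noise stays within 10% error", {
  pre <- c1c2_presets(8)
  eads <- preset_component_spectra(pre)
  tt <- linlog_time_axis(n_points = 150, t_max = 1.25e8)
  errs <- sapply(c(42, 43, 44), function(seed) {
    ds <- simulate_sequential_dataset(pre$sequential_lifetimes, eads,
                                      pre$irf, tt, pre$wavelengths,
                                      noise_sigma = 0.01, seed = seed)
    f <- fit_sequential(ds, c(0.2, 3, 30, 1500, 1e5, Inf),
                        irf = irf_model(0.02, fwhm = 0.2), n_starts = 2,
                        seed = 1)
    truth <- pre$sequential_lifetimes[1:5]
    abs(f$lifetimes[1:5] - truth) / truth
  })
  expect_lt(median(errs), 0.10)
  expect_lt(max(apply(errs, 2, median)), 0.10)
})

test_that("near-degenerate components at high noise widen errors, no crash", {
  p <- make_seq_problem(lifetimes = c(5, 6), noise = 0.05, seed = 12)
  f <- fit_sequential(p$ds, init_lifetimes = c(4, 8),
                      irf = irf_model(0, fwhm = 0.15), fit_irf = FALSE,
                      n_starts = 2)
  expect_true(all(is.finite(f$lifetimes)))
  # relative errors far larger than for well-separated components
  expect_gt(max(f$std_errors$se[1:2] / f$std_errors$value[1:2]), 0.10)
})

test_that("masked cells have no influence on the fitted parameters", {
  p <- make_seq_problem(lifetimes = c(1, 20, Inf), noise = 0.01, seed = 8)
  f1 <- fit_sequential(p$ds, c(0.5, 10, Inf), irf = std_irf(),
                       fit_irf = FALSE, n_starts = 1)
  ds2 <- p$ds
  masked <- ds2$weights == 0
  expect_gt(sum(masked), 0)
  ds2$delta_A[masked] <- 1e6 * seq_len(sum(masked))   # arbitrary garbage
  f2 <- fit_sequential(ds2, c(0.5, 10, Inf), irf = std_irf(),
                       fit_irf = FALSE, n_starts = 1)
  expect_lt(max(abs(f1$lifetimes[1:2] - f2$lifetimes[1:2])), 1e-12)
  expect_lt(max(abs(f1$eads - f2$eads)), 1e-12)
})

test_that("residual SVD flags under-fitted data and passes pure noise", {
  pre <- c1c2_presets(8)
  eads <- preset_component_spectra(pre)
  tt <- linlog_time_axis(n_points = 120, t_max = 1.25e8)
  # low noise so that the missing-component structure dominates the floor
  ds <- simulate_sequential_dataset(pre$sequential_lifetimes, eads, pre$irf,
                                    tt, pre$wavelengths, noise_sigma = 0.002,
                                    seed = 19)
  good <- fit_sequential(ds, c(0.2, 3, 30, 1500, 1e5, Inf),
                         irf = irf_model(0.02, fwhm = 0.2), n_starts = 2)
  expect_false(svd_residual_diagnostics(good)$structured)
  # drop one component: leftover structure must be flagged
  bad <- fit_sequential(ds, c(0.2, 3, 1500, 1e5, Inf),
                        irf = irf_model(0.02, fwhm = 0.2), n_starts = 2)
  expect_true(svd_residual_diagnostics(bad)$structured)
  # masked cells carry no residual and hence no structure
  expect_true(all(do.call(rbind, list(good$residuals))[,
    good$dataset$weights[1, ] == 0] == 0))
})

test_that("linearized standard errors track a bootstrap on a 3-component fit", {
  p <- make_seq_problem(lifetimes = c(1, 20, 200), noise = 0.02, seed = 31,
                        n_t = 80, n_wl = 30)
  f <- fit_sequential(p$ds, c(0.7, 15, 300), irf = std_irf(),
                      fit_irf = FALSE, n_starts = 1)
  boots <- sapply(1:48, function(b) {
    db <- simulate_sequential_dataset(p$lifetimes, p$spectra, p$irf, p$tt,
                                      p$wl, noise_sigma = 0.02,
                                      seed = 1000 + b)
    fb <- fit_sequential(db, c(0.7, 15, 300), irf = std_irf(),
                         fit_irf = FALSE, n_starts = 1)
    fb$lifetimes
  })
  boot_se <- apply(boots, 1, sd)
  lin_se <- f$std_errors$se[1:3]
  expect_true(all(abs(lin_se - boot_se) / boot_se < 0.3))
})
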