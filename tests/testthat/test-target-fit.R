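# joint fixture: PP (+ optional PDP) matrices generated from the branched
# excited-state scheme with its species spectra
make_target_problem <- function(noise = 0.01, seed = 21, with_pdp = FALSE,
                                dump = std_dump(0.1, 0.1), t_max = 100,
                                n_t = 100) {
  pre <- c1c2_presets(8)
  sch <- pre$scheme
  wl <- pre$wavelengths
  sads <- suppressWarnings(
    eval_spectra(pre$species, wl,
                 species = setdiff(sch$compartments, sch$ground)))
  tt <- linlog_time_axis(t_min = -1, t_switch = 1, t_max = t_max,
                         n_points = n_t)
  pp <- simulate_dataset(sch, sads, pre$irf, tt, wl, noise_sigma = noise,
                         seed = seed)
  out <- list(pre = pre, scheme = sch, wl = wl, tt = tt, sads = sads,
              pp = pp)
  if (with_pdp) {
    schd <- sch
    schd$dumps <- list(dump)
    out$pdp <- simulate_dataset(schd, sads, pre$pdp_irf, tt, wl,
                                noise_sigma = noise, seed = seed + 1,
                                with_dump = TRUE)
    out$dump <- dump
  }
  out
}

test_that("fitting the generating scheme reaches the noise floor", {
  p <- make_target_problem(noise = 0.01, seed = 33)
  f <- fit_target(p$pp, p$scheme, free_rates = c("ES3->GS"), irf = p$pre$irf,
                  n_starts = 1)
  # chi^2 per used cell ~ noise variance
  n_used <- sum(p$pp$weights > 0)
  sigma2 <- (0.01 * max(abs(attr(p$pp, "truth")$model)))^2
  expect_lt(abs(f$ssq / n_used / sigma2 - 1), 0.1)
  expect_equal(f$std_errors$value[1], 0.09, tolerance = 0.1)
  # GSI is never populated without a dump: excluded but reported as zero
  expect_false("GSI" %in% f$observed)
  expect_true(all(f$sads["GSI", ] == 0))
})

test_that("noiseless target fit recovers a free decay rate to 1e-6", {
  p <- make_target_problem(noise = 0)
  sch_init <- targetkin:::set_edge_rate(p$scheme, "ES3", "GS", 0.05)
  f <- fit_target(p$pp, sch_init, free_rates = c("ES3->GS"),
                  irf = p$pre$irf, n_starts = 1)
  expect_equal(f$std_errors$value[1], 0.09, tolerance = 1e-6)
})

test_that("equal-bleach constraint pins the ES2 branch split", {
  # the split between ES2 -> ES3 and ES2 -> GS only rescales the ES3
  # population, which a free ES3 spectrum absorbs: the data fix the total
  # (0.50 ps^-1) but not the split. The equal-bleach assumption supplies
  # the missing amplitude scale, as in the published analysis.
  p <- make_target_problem(noise = 0.01, seed = 51)
  sch_init <- p$scheme
  sch_init$rates$rate[sch_init$rates$from == "ES2"] <- c(0.2, 0.2)
  bc <- bleach_constraint(window = c(430, 465),
                          species = c("ES1", "ES2", "ES3", "K1"))
  f <- fit_target(p$pp, sch_init, free_rates = c("ES2->ES3", "ES2->GS"),
                  irf = p$pre$irf, bleach_constraint = bc, n_starts = 4,
                  seed = 2)
  expect_lt(abs(f$std_errors$value[1] - 0.12) / 0.12, 0.10)
  expect_lt(abs(f$std_errors$value[2] - 0.38) / 0.38, 0.10)
  # without the constraint the total outflow is still recovered
  f0 <- fit_target(p$pp, sch_init, free_rates = c("ES2->ES3", "ES2->GS"),
                   irf = p$pre$irf, n_starts = 2, seed = 2)
  expect_lt(abs(sum(f0$std_errors$value[1:2]) - 0.50) / 0.50, 0.05)
})

test_that("joint PP+PDP fit recovers the intermediate's decay rate", {
  p <- make_target_problem(noise = 0.01, seed = 61, with_pdp = TRUE)
  sch_init <- targetkin:::set_edge_rate(p$scheme, "GSI", "GS", 0.6)
  d_init <- std_dump(0.05, 0.05)
  f <- fit_target(list(p$pp, p$pdp), sch_init, free_rates = c("GSI->GS"),
                  dumps = list(NULL, list(d_init)), free_dumps = TRUE,
                  irf = list(p$pre$irf, p$pre$pdp_irf), n_starts = 4,
                  seed = 2)
  est <- f$std_errors
  expect_lt(abs(est$value[est$parameter == "k(GSI->GS)"] - 1.0), 0.15)
  # dump transfer fractions come back near the generating 0.1
  dumps_est <- est$value[grepl("^dump", est$parameter)]
  expect_lt(max(abs(dumps_est - 0.1)), 0.05)
  # GSI now observed, with a nonzero spectrum
  expect_true("GSI" %in% f$observed)
  expect_gt(max(abs(f$sads["GSI", ])), 0)
})

test_that("structurally unidentifiable parameter sets are refused by name", {
  p <- make_target_problem(noise = 0)
  # two rates out of the same compartment into terminals GS/K1 exchange
  # roles with the branch scale only when totals are also free; freeing the
  # same edge twice is the canonical degenerate request
  expect_error(
    fit_target(p$pp, p$scheme, free_rates = c("ES3->GS", "ES3->GS"),
               irf = p$pre$irf, n_starts = 1),
    "unidentifiable")
})

test_that("equal-bleach constraint resolves the branch/scale degeneracy", {
  p <- make_target_problem(noise = 0.005, seed = 71)
  # the K1-vs-GS branch at fixed ES1 total is invisible to the data: the
  # photoproduct spectrum absorbs any rescaling (here started at 2x off)
  sch_wrong <- targetkin:::set_edge_rate(p$scheme, "ES1", "K1", 0.15 * 1.32)
  sch_wrong <- targetkin:::set_edge_rate(sch_wrong, "ES1", "GS", 0.85 * 1.32)
  f <- fit_target(p$pp, sch_wrong, free_branches = c("ES1->K1/GS"),
                  irf = p$pre$irf, n_starts = 1)
  expect_lt(unname(f$yields["K1"]), 0.15)   # stuck at the wrong init
  fc <- apply_bleach_constraint(f, window = c(430, 465),
                                species = c("ES1", "ES2", "ES3", "K1"))
  # constraint restores the generating 30% yield to within 3 points
  expect_lt(abs(unname(fc$yields["K1"]) - 0.30), 0.03)
  expect_lt(fc$bleach$post_spread, fc$bleach$pre_spread / 10)
  # already-equal spectra: penalty leaves the fit essentially unchanged
  f_true <- fit_target(p$pp, p$scheme, free_branches = c("ES1->K1/GS"),
                       irf = p$pre$irf, n_starts = 1)
  fc_true <- apply_bleach_constraint(f_true, window = c(430, 465),
                                     species = c("ES1", "ES2", "ES3", "K1"))
  expect_lt(abs(unname(fc_true$yields["K1"] - f_true$yields["K1"])), 0.03)
  # empty window is a configuration error
  expect_error(apply_bleach_constraint(f, window = c(465.1, 465.2)),
               "no wavelength")
})

test_that("quantum yield from fit matches branching arithmetic with errors", {
  p <- make_target_problem(noise = 0.01, seed = 81)
  sch_init <- p$scheme
  sch_init$rates$rate[sch_init$rates$from == "ES2"] <- c(0.2, 0.2)
  f <- fit_target(p$pp, sch_init, free_rates = c("ES2->ES3", "ES2->GS"),
                  irf = p$pre$irf, n_starts = 2, seed = 5)
  qy <- quantum_yield_from_fit(f, photoproduct = "K1")
  # K1 is fed by ES1 only; its yield is the closed-form branching product
  expect_equal(qy$yield,
               unname(branching_probabilities(f$scheme, "ES1")["K1"]),
               tolerance = 1e-12)
  expect_gte(qy$se, 0)
  # all branches into the photoproduct: yield 1
  all_in <- kinetic_scheme(c("A", "P"),
                           rates = data.frame(from = "A", to = "P", rate = 2))
  expect_equal(terminal_yields(all_in), c(P = 1))
})

test_that("yield uncertainty is consistent with refit scatter", {
  # scatter of the fitted yield over noise realizations vs the delta-method
  # error of one fit (free ES1 branch rates, total observable)
  p0 <- make_target_problem(noise = 0.02, seed = 90)
  fits <- sapply(1:12, function(b) {
    pb <- make_target_problem(noise = 0.02, seed = 400 + b)
    sch_init <- targetkin:::set_edge_rate(p0$scheme, "ES1", "K1", 0.5)
    f <- fit_target(pb$pp, sch_init, free_rates = c("ES1->K1"),
                    irf = pb$pre$irf, n_starts = 1)
    c(unname(f$yields["K1"]),
      quantum_yield_from_fit(f, photoproduct = "K1")$se)
  })
  emp <- sd(fits[1, ])
  lin <- median(fits[2, ])
  expect_lt(abs(lin - emp) / emp, 0.75)
})
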