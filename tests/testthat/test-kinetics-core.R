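test_that("rate matrix has branching off-diagonals, conserving columns", {
  sch <- fig_scheme()
  K <- rate_matrix(sch)
  expect_equal(K["ES2", "ES1"], 0.88)
  expect_equal(K["K1", "ES1"], 0.66)
  expect_equal(K["GS", "ES1"], 0.66)
  expect_equal(K["ES1", "ES1"], -2.2)
  # all destinations are compartments here, so columns sum to zero
  expect_equal(colSums(K), setNames(rep(0, 6), colnames(K)))

  # single absorbing state
  one <- kinetic_scheme("A")
  expect_equal(rate_matrix(one), matrix(0, 1, 1, dimnames = list("A", "A")))

  # two-state reversible pair: column sums 0, eigenvalues {0, -2}
  rev2 <- kinetic_scheme(c("A", "B"),
                         rates = data.frame(from = c("A", "B"),
                                            to = c("B", "A"), rate = 1))
  Kr <- rate_matrix(rev2)
  expect_equal(colSums(Kr), setNames(c(0, 0), c("A", "B")))
  expect_equal(sort(eigen(Kr)$values), c(-2, 0))

  expect_error(
    kinetic_scheme(c("A", "B"),
                   rates = data.frame(from = "A", to = "C", rate = 1)),
    "unknown compartment.*A -> C")
})

test_that("IRF-convolved kernel matches its limits and a quadrature oracle", {
  irf <- std_irf()
  # delta-IRF limit
  narrow <- irf_model(center = 0, width = 1e-8)
  tt <- c(0.05, 0.3, 1, 5)
  expect_equal(exp_gauss_kernel(2.2, tt, narrow), exp(-2.2 * tt),
               tolerance = 1e-10)
  # rate 0: cumulative Gaussian
  tt2 <- seq(-0.3, 0.5, by = 0.07)
  expect_equal(exp_gauss_kernel(0, tt2, irf),
               pnorm(tt2, 0, irf$width), tolerance = 1e-12)
  # frozen quadrature value: convolution of exp(-2.2 t) with the 150 fs
  # FWHM Gaussian evaluated at t = 0.3 ps, computed by adaptive quadrature
  # of integrate(exp(-k u) * dnorm(t - u, 0, sigma), 0, Inf)
  expect_equal(exp_gauss_kernel(2.2, 0.3, irf), 0.52195019824933331,
               tolerance = 1e-8)
  # overflow safety at extreme rate * sigma
  expect_true(is.finite(exp_gauss_kernel(1e4, 0.1, irf)))
  expect_error(irf_model(center = 0, width = -1), "positive")
})

test_that("branching probabilities follow rate ratios", {
  sch <- fig_scheme()
  expect_equal(branching_probabilities(sch, "ES1"),
               c(ES2 = 0.4, GS = 0.3, K1 = 0.3))
  expect_equal(branching_probabilities(sch, "ES2"),
               c(ES3 = 0.24, GS = 0.76))
  expect_equal(branching_probabilities(sch, "GSI"), c(GS = 1))
  expect_error(branching_probabilities(sch, "K1"), "no outgoing")
})

test_that("terminal yields solve the absorbing-state equations", {
  sch <- fig_scheme()
  y <- terminal_yields(sch)
  expect_equal(unname(y["K1"]), 0.30, tolerance = 1e-12)
  expect_equal(unname(y["GS"]), 0.70, tolerance = 1e-12)
  expect_equal(sum(y), 1)
  # the fastest component's direct-decay share: 1 - P(ES1 -> ES2) = 60%
  expect_equal(unname(1 - branching_probabilities(sch, "ES1")["ES2"]), 0.60)
  # everything into one terminal
  all_in <- kinetic_scheme(c("A", "B"),
                           rates = data.frame(from = "A", to = "B", rate = 3))
  expect_equal(terminal_yields(all_in), c(B = 1))
  # trapped cycle with no exit is refused by name
  trap <- kinetic_scheme(c("A", "B", "C"),
                         rates = data.frame(from = c("A", "B"),
                                            to = c("B", "A"), rate = 1),
                         terminal = "C")
  expect_error(terminal_yields(trap), "no terminal.*A, B")
})

test_that("analytic profiles match the ODE oracle on random schemes", {
  irf <- std_irf()
  tt <- c(-0.3, 0, 0.2, 0.5, 1, 3, 10, 100, 1e4)
  for (seed in 1:10) {
    sch <- random_scheme(sample(2:5, 1), seed = seed)
    a <- suppressMessages(concentration_profiles(sch, irf, tt))
    o <- concentration_profiles_ode(sch, irf, tt)
    expect_conc_close(a, o, tol = 1e-6)
  }
})

test_that("population is conserved and matches cumulative excitation", {
  sch <- fig_scheme()
  irf <- std_irf()
  tt <- c(-0.5, -0.1, 0, 0.1, 0.5, 2, 20, 500)
  conc <- concentration_profiles(sch, irf, tt)
  expect_equal(rowSums(conc$values), pnorm(tt, 0, irf$width),
               tolerance = 1e-8)
  # before any excitation has arrived the profiles are identically zero
  expect_true(all(concentration_profiles(sch, irf, c(-5, -2, -1))$values
                  < 1e-10))
  # an all-zero excitation vector is rejected up front
  expect_error(kinetic_scheme(c("A", "B"),
                              rates = data.frame(from = "A", to = "B",
                                                 rate = 1),
                              input = c(A = 0)), "not all be zero")
})

test_that("delta-IRF limit reduces to matrix-exponential propagation", {
  sch <- fig_scheme()
  narrow <- irf_model(center = 0, width = 1e-7)
  tt <- c(0.05, 0.2, 1, 5, 50)
  conc <- concentration_profiles(sch, narrow, tt)
  K <- rate_matrix(sch)
  p0 <- sch$input[sch$compartments]
  expm_vals <- t(vapply(tt, function(t)
    as.numeric(Matrix::expm(K * t) %*% p0), numeric(6)))
  expect_lt(max(abs(conc$values - expm_vals)), 1e-6)
})

test_that("degenerate rates fall back to numerical propagation", {
  # sequential 1 -> 2 -> sink with equal rates: confluent case
  sch <- kinetic_scheme(c("A", "B", "SINK"),
                        rates = data.frame(from = c("A", "B"),
                                           to = c("B", "SINK"), rate = 1))
  irf <- std_irf()
  tt <- c(0.1, 0.5, 1, 2, 5)
  expect_message(conc <- concentration_profiles(sch, irf, tt),
                 "numerical propagation")
  # oracle: B(t) = t exp(-t) for delta excitation; with the narrow IRF the
  # convolved solution from the stiff integrator is authoritative
  o <- concentration_profiles_ode(sch, irf, tt)
  expect_conc_close(conc, o, tol = 1e-8)
})

test_that("MC jump oracle reproduces analytic yields within 3 sigma", {
  sch <- fig_scheme()
  mc <- mc_jump_yields(sch, n_traj = 1e5, seed = 11)
  y <- terminal_yields(sch)
  for (i in seq_len(nrow(mc)))
    expect_lt(abs(mc$yield[i] - y[[mc$compartment[i]]]), 3 * mc$se[i])
  # reproducibility under fixed seed
  mc2 <- mc_jump_yields(sch, n_traj = 1e5, seed = 11)
  expect_identical(mc, mc2)
  # random schemes
  for (seed in c(3, 17, 29)) {
    sch_r <- random_scheme(4, seed = seed)
    yr <- terminal_yields(sch_r)
    mcr <- mc_jump_yields(sch_r, n_traj = 2e4, seed = seed)
    for (i in seq_len(nrow(mcr)))
      expect_lt(abs(mcr$yield[i] - yr[[mcr$compartment[i]]]),
                3 * mcr$se[i] + 1e-9)
  }
})
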