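# shared fixtures: the primary-photochemistry target scheme and small
# random rate networks for property-style checks

fig_scheme <- function() {
  kinetic_scheme(
    c("ES1", "ES2", "ES3", "K1", "GSI", "GS"),
    rates = data.frame(
      from = c("ES1", "ES1", "ES1", "ES2", "ES2", "ES3", "GSI"),
      to   = c("ES2", "K1", "GS", "ES3", "GS", "GS", "GS"),
      rate = c(0.88, 0.66, 0.66, 0.12, 0.38, 0.09, 1.0)),
    input = c(ES1 = 1))
}

std_irf <- function() irf_model(center = 0, fwhm = 0.150)

std_dump <- function(f1 = 0.1, f2 = f1) {
  dump_event(0.3, data.frame(from = c("ES1", "ES2"), to = "GSI",
                             fraction = c(f1, f2)))
}

# random acyclic-ish scheme: chain with random extra forward edges into a
# terminal sink, rates log-uniform
random_scheme <- function(n_comp, seed) {
  withr::with_seed(seed, {
    labels <- c(paste0("S", seq_len(n_comp)), "SINK")
    from <- to <- character(); rate <- numeric()
    for (i in seq_len(n_comp)) {
      pool <- setdiff(seq_len(n_comp + 1), seq_len(i))
      n_out <- min(sample(1:2, 1), length(pool))
      dests <- pool[sample.int(length(pool), n_out)]
      from <- c(from, rep(labels[i], n_out))
      to <- c(to, labels[dests])
      rate <- c(rate, exp(stats::runif(n_out, log(1e-4), log(10))))
    }
    kinetic_scheme(labels, rates = data.frame(from = from, to = to,
                                              rate = rate),
                   input = stats::setNames(1, labels[1]))
  })
}

expect_conc_close <- function(a, b, tol = 1e-6) {
  scale <- max(abs(b$values), 1e-12)
  expect_lt(max(abs(a$values - b$values)) / scale, tol)
}
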