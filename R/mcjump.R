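#' Monte-Carlo jump-process estimate of terminal yields
#'
#' Samples continuous-time trajectories of the first-order rate network
#' (Gillespie-style: exponential waiting times, jump destinations drawn
#' with probability rate/total outflow) and tabulates the terminal
#' compartment of each trajectory. Serves as the stochastic oracle for
#' [terminal_yields()] and, with a dump event, for [dump_readout()].
#'
#' When a `dump_event` is supplied, a trajectory that is still in one of the
#' dump's source compartments when the dump fires is transferred to the
#' destination with probability equal to the transfer fraction.
#'
#' @param scheme a [kinetic_scheme()].
#' @param n_traj number of trajectories.
#' @param seed integer seed; the run is reproducible.
#' @param dump optional [dump_event()] applied during the simulation.
#' @param irf optional [irf_model()]; trajectory birth times are then drawn
#'   from the Gaussian pump profile (relevant only when a dump competes with
#'   the excitation window — terminal yields without dump are IRF-free).
#' @return a data frame with one row per terminal compartment: `yield`
#'   (empirical fraction) and `se` (binomial standard error).
#' @export
mc_jump_yields <- function(scheme, n_traj = 1e5, seed = 1, dump = NULL,
                           irf = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  comps <- scheme$compartments
  n <- length(comps)
  K <- rate_matrix(scheme)
  out_rate <- -diag(K)
  # jump probabilities per source compartment
  jump <- lapply(seq_len(n), function(i) {
    if (out_rate[i] <= 0) return(NULL)
    p <- K[, i]; p[i] <- 0
    list(dest = which(p > 0), prob = p[p > 0] / out_rate[i])
  })
  has_dump <- !is.null(dump)
  if (has_dump) {
    stopifnot(inherits(dump, "dump_event"))
    t_dump <- dump$time
    frac <- stats::setNames(numeric(n), comps)
    dest <- stats::setNames(integer(n), comps)
    for (i in seq_len(nrow(dump$transfers))) {
      tr <- dump$transfers[i, ]
      frac[tr$from] <- frac[tr$from] + tr$fraction
      dest[tr$from] <- match(tr$to, comps)
    }
  }
  withr::with_seed(seed, {
    state <- sample.int(n, n_traj, replace = TRUE,
                        prob = scheme$input[comps])
    tnow <- if (is.null(irf)) numeric(n_traj) else
      stats::rnorm(n_traj, irf$center, irf$width)
    dump_done <- rep(!has_dump, n_traj)
    if (has_dump) dump_done <- dump_done | tnow > t_dump
    active <- out_rate[state] > 0
    while (any(active)) {
      for (i in which(out_rate > 0)) {
        idx <- which(active & state == i)
        if (!length(idx)) next
        wait <- stats::rexp(length(idx), out_rate[i])
        if (has_dump) {
          cross <- !dump_done[idx] & tnow[idx] + wait > t_dump
          if (any(cross)) {
            ci <- idx[cross]
            dump_done[ci] <- TRUE
            tnow[ci] <- t_dump
            if (frac[i] > 0) {
              hit <- stats::runif(length(ci)) < frac[i]
              state[ci[hit]] <- dest[i]
            }
            idx <- idx[!cross]
            wait <- wait[!cross]
          }
        }
        if (length(idx)) {
          tnow[idx] <- tnow[idx] + wait
          jp <- jump[[i]]
          if (length(jp$dest) == 1) {
            state[idx] <- jp$dest
          } else {
            state[idx] <- jp$dest[sample.int(length(jp$dest), length(idx),
                                             replace = TRUE, prob = jp$prob) ]
          }
        }
      }
      active <- out_rate[state] > 0
    }
    counts <- tabulate(state, nbins = n)
  })
  term <- comps %in% scheme$terminal
  y <- counts[term] / n_traj
  data.frame(compartment = comps[term], yield = y,
             se = sqrt(pmax(y * (1 - y), 1 / n_traj) / n_traj),
             stringsAsFactors = FALSE)
}
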