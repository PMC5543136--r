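#' Construct a compartmental kinetic scheme
#'
#' A kinetic scheme is a first-order rate network: a set of named
#' compartments (species), directed edges carrying rate constants in
#' reciprocal picoseconds, an initial-excitation vector, and optionally
#' instantaneous dump-pulse transfer events. Terminal compartments are
#' absorbing (no outflow); a non-decaying but spectrally observed component
#' ("infinity") is simply a terminal compartment with a spectrum. The
#' recovered ground state is a terminal compartment with, by convention, a
#' zero difference spectrum (see `ground`).
#'
#' Reversible steps (e.g. a K/L equilibrium) are represented as two directed
#' edges. All times and rates are picoseconds internally; converters in the
#' I/O layer accept fs/ps/ns/us/ms/s.
#'
#' @param compartments character vector of unique compartment labels, e.g.
#'   `c("ES1","ES2","ES3","K1","GSI","GS")`.
#' @param rates data frame with columns `from`, `to`, `rate` (ps^-1), one row
#'   per directed edge. May be `NULL` for a single absorbing state.
#' @param input named numeric vector of initial excitation fractions
#'   (defaults to 1 on the first compartment); must be nonnegative and is
#'   normalized to sum to 1.
#' @param terminal labels of absorbing compartments. Compartments without
#'   outgoing edges are treated as terminal automatically.
#' @param ground label of the recovered ground state (zero difference
#'   spectrum), or `NULL`. Defaults to `"GS"` when present.
#' @param dumps list of [dump_event()] objects.
#' @return an object of class `kinetic_scheme`.
#' @seealso [rate_matrix()], [concentration_profiles()], [terminal_yields()]
#' @export
kinetic_scheme <- function(compartments, rates = NULL, input = NULL,
                           terminal = character(), ground = NULL,
                           dumps = list()) {
  compartments <- as.character(compartments)
  if (anyDuplicated(compartments))
    stop("duplicate compartment labels: ",
         paste(unique(compartments[duplicated(compartments)]), collapse = ", "))
  if (is.null(rates)) {
    rates <- data.frame(from = character(), to = character(),
                        rate = numeric(), stringsAsFactors = FALSE)
  } else {
    rates <- as.data.frame(rates, stringsAsFactors = FALSE)
    stopifnot(all(c("from", "to", "rate") %in% names(rates)))
    rates$from <- as.character(rates$from)
    rates$to <- as.character(rates$to)
    rates$rate <- as.numeric(rates$rate)
  }
  bad <- !(rates$from %in% compartments) | !(rates$to %in% compartments)
  if (any(bad))
    stop("edge refers to unknown compartment: ",
         paste(sprintf("%s -> %s", rates$from[bad], rates$to[bad]),
               collapse = "; "))
  if (any(rates$rate < 0))
    stop("negative rate constant on edge ",
         paste(sprintf("%s -> %s", rates$from[rates$rate < 0],
                       rates$to[rates$rate < 0]), collapse = "; "))
  if (any(rates$from == rates$to))
    stop("self-edges are not allowed")

  if (is.null(input)) {
    input <- stats::setNames(1, compartments[1])
  }
  if (is.null(names(input)) || !all(names(input) %in% compartments))
    stop("'input' must be a named vector over scheme compartments")
  if (any(input < 0)) stop("input weights must be nonnegative")
  if (sum(input) <= 0) stop("input weights must not all be zero")
  input <- input / sum(input)
  w <- stats::setNames(numeric(length(compartments)), compartments)
  w[names(input)] <- input

  has_out <- compartments %in% rates$from
  terminal <- unique(c(as.character(terminal), compartments[!has_out]))
  if (!all(terminal %in% compartments))
    stop("unknown terminal compartment: ",
         paste(setdiff(terminal, compartments), collapse = ", "))
  if (any(terminal %in% rates$from))
    stop("terminal compartment has outgoing edges: ",
         paste(intersect(terminal, rates$from), collapse = ", "))

  if (is.null(ground) && "GS" %in% compartments) ground <- "GS"
  if (!is.null(ground) && !ground %in% compartments)
    stop("ground label ", ground, " is not a compartment")

  if (length(dumps)) {
    if (inherits(dumps, "dump_event")) dumps <- list(dumps)
    for (d in dumps) {
      stopifnot(inherits(d, "dump_event"))
      lbl <- unique(c(d$transfers$from, d$transfers$to))
      if (!all(lbl %in% compartments))
        stop("dump transfer refers to unknown compartment: ",
             paste(setdiff(lbl, compartments), collapse = ", "))
    }
    dumps <- dumps[order(vapply(dumps, function(d) d$time, 0))]
  }

  structure(list(compartments = compartments, rates = rates, input = w,
                 terminal = terminal, ground = ground, dumps = dumps),
            class = "kinetic_scheme")
}

#' Instantaneous dump-pulse transfer event
#'
#' Models a delayed dump pulse (resonant with stimulated emission) that
#' instantaneously transfers a fraction of one or more source populations to
#' destination compartments at a fixed delay after the pump. The dump-pulse
#' duration is ignored: transfer is a delta-function event acting on the
#' populations present at `time`.
#'
#' @param time dump delay relative to the pump (ps).
#' @param transfers data frame with columns `from`, `to`, `fraction`; each
#'   row moves `fraction` of the `from` population into `to`. Total fraction
#'   removed from any one source must not exceed 1.
#' @return an object of class `dump_event`.
#' @export
dump_event <- function(time, transfers) {
  transfers <- as.data.frame(transfers, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "fraction") %in% names(transfers)))
  transfers$fraction <- as.numeric(transfers$fraction)
  if (any(transfers$fraction < 0) || any(transfers$fraction > 1))
    stop("dump transfer fraction outside [0, 1]")
  tot <- tapply(transfers$fraction, transfers$from, sum)
  if (any(tot > 1 + 1e-12))
    stop("total dump fraction exceeds 1 for source ",
         paste(names(tot)[tot > 1 + 1e-12], collapse = ", "))
  structure(list(time = as.numeric(time), transfers = transfers),
            class = "dump_event")
}

#' Gaussian instrument-response model
#'
#' The instrument response function (IRF) is a unit-area Gaussian in time
#' with center `center` (the time-zero offset) and standard deviation
#' `width`. All kinetic responses are analytically convolved with it.
#'
#' @param center time-zero offset mu (ps).
#' @param width Gaussian standard deviation sigma (ps); must be positive.
#'   Use `fwhm` instead to specify the full width at half maximum.
#' @param fwhm alternative to `width`: FWHM in ps (`fwhm = sigma*2*sqrt(2*log 2)`).
#' @return an object of class `irf_model` with fields `center` and `width`.
#' @export
irf_model <- function(center = 0, width = NULL, fwhm = NULL) {
  if (is.null(width)) {
    if (is.null(fwhm)) stop("give either 'width' (sigma) or 'fwhm'")
    width <- fwhm / (2 * sqrt(2 * log(2)))
  }
  if (width <= 0) stop("IRF width must be positive")
  structure(list(center = as.numeric(center), width = as.numeric(width)),
            class = "irf_model")
}

#' @rdname irf_model
#' @param irf an `irf_model`.
#' @export
irf_fwhm <- function(irf) irf$width * 2 * sqrt(2 * log(2))

#' Rate matrix of a kinetic scheme
#'
#' Builds the square first-order rate (generator) matrix K over the scheme's
#' compartments: off-diagonal entry `(j, i)` is the rate of the edge i -> j,
#' the diagonal entry `(i, i)` is minus the total outflow of i, so that
#' `dc/dt = K c`. When every edge destination (including the recovered
#' ground state) is a compartment, columns sum to zero and total population
#' is conserved.
#'
#' @param scheme a [kinetic_scheme()].
#' @return numeric matrix with compartment dimnames.
#' @export
rate_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  n <- length(scheme$compartments)
  K <- matrix(0, n, n, dimnames = list(scheme$compartments, scheme$compartments))
  r <- scheme$rates
  for (i in seq_len(nrow(r))) {
    K[r$to[i], r$from[i]] <- K[r$to[i], r$from[i]] + r$rate[i]
    K[r$from[i], r$from[i]] <- K[r$from[i], r$from[i]] - r$rate[i]
  }
  K
}

#' Branching probabilities out of a compartment
#'
#' For a decaying compartment the probability of each destination is its
#' edge rate divided by the total outflow; probabilities sum to 1.
#'
#' @param scheme a [kinetic_scheme()].
#' @param compartment source compartment label (must have outgoing edges).
#' @return named numeric vector of per-destination probabilities.
#' @export
branching_probabilities <- function(scheme, compartment) {
  r <- scheme$rates[scheme$rates$from == compartment, , drop = FALSE]
  if (nrow(r) == 0)
    stop("compartment ", compartment, " has no outgoing edges")
  p <- tapply(r$rate, r$to, sum)
  p <- p / sum(p)
  stats::setNames(as.numeric(p), names(p))
}

## transient/terminal split used by yields and propagation
scheme_partition <- function(scheme) {
  list(transient = setdiff(scheme$compartments, scheme$terminal),
       terminal = scheme$terminal)
}

## compartments from which some terminal is reachable; used to detect traps
reachable_terminal <- function(scheme) {
  ok <- scheme$compartments %in% scheme$terminal
  names(ok) <- scheme$compartments
  repeat {
    new <- ok
    for (i in seq_len(nrow(scheme$rates))) {
      e <- scheme$rates[i, ]
      if (e$rate > 0 && ok[e$to]) new[e$from] <- TRUE
    }
    if (identical(new, ok)) break
    ok <- new
  }
  ok
}

#' Terminal (absorbing-state) yields of a kinetic scheme
#'
#' Solves the first-step linear equations for the probability that an
#' initially excited molecule is eventually absorbed in each terminal
#' compartment. For the primary photochemistry scheme this gives the
#' photoisomerization quantum yield directly: the terminal probability of
#' the first photoproduct compartment.
#'
#' @param scheme a [kinetic_scheme()]. Dump events are ignored here (see
#'   [dump_readout()] for dumped yields).
#' @return named numeric vector of absorbing probabilities over the terminal
#'   compartments; sums to 1.
#' @export
terminal_yields <- function(scheme) {
  part <- scheme_partition(scheme)
  ok <- reachable_terminal(scheme)
  trapped <- names(ok)[!ok]
  if (length(trapped))
    stop("no terminal compartment reachable from: ",
         paste(trapped, collapse = ", "))
  K <- rate_matrix(scheme)
  w <- scheme$input
  y <- stats::setNames(numeric(length(part$terminal)), part$terminal)
  y[] <- w[part$terminal]
  if (length(part$transient)) {
    A <- K[part$transient, part$transient, drop = FALSE]
    R <- K[part$terminal, part$transient, drop = FALSE]
    occ <- solve(-A, w[part$transient])   # time-integrated occupancies
    y <- y + as.numeric(R %*% occ)
  }
  y
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", length(x$compartments), " compartments: ",
      paste(x$compartments, collapse = ", "), "\n", sep = "")
  if (nrow(x$rates))
    cat(sprintf("  %s -> %s  %g /ps\n", x$rates$from, x$rates$to, x$rates$rate),
        sep = "")
  cat("  input:", paste(sprintf("%s=%g", names(x$input)[x$input > 0],
                                x$input[x$input > 0]), collapse = ", "), "\n")
  cat("  terminal:", paste(x$terminal, collapse = ", "),
      if (!is.null(x$ground)) paste0("(ground: ", x$ground, ")"), "\n")
  for (d in x$dumps)
    cat(sprintf("  dump at %g ps: %s\n", d$time,
                paste(sprintf("%s -> %s (%.3g)", d$transfers$from,
                              d$transfers$to, d$transfers$fraction),
                      collapse = ", ")))
  invisible(x)
}

## replace the rate of a named edge (used by target fitting)
set_edge_rate <- function(scheme, from, to, rate) {
  i <- which(scheme$rates$from == from & scheme$rates$to == to)
  if (length(i) != 1)
    stop("no unique edge ", from, " -> ", to, " in scheme")
  scheme$rates$rate[i] <- rate
  scheme
}

edge_rate <- function(scheme, from, to) {
  i <- which(scheme$rates$from == from & scheme$rates$to == to)
  if (length(i) != 1)
    stop("no unique edge ", from, " -> ", to, " in scheme")
  scheme$rates$rate[i]
}
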