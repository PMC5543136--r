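#' Time-dependent compartment populations under Gaussian-IRF excitation
#'
#' Propagates a first-order compartmental scheme excited through a Gaussian
#' instrument response: the rate matrix is eigendecomposed and every
#' eigenmode is carried by the analytic IRF-convolved exponential kernel
#' ([exp_gauss_kernel()]), which is exact for diagonalizable rate matrices.
#' When eigenvalues are complex or (nearly) degenerate the function falls
#' back to adaptive numerical integration of the rate equations with a
#' Gaussian source term ([concentration_profiles_ode()]) and emits a
#' message.
#'
#' Populations are fractions of the initially excited molecules; with the
#' recovered ground state included as a compartment, the total population at
#' any delay equals the cumulative excitation (conservation).
#'
#' @param scheme a [kinetic_scheme()]. Dump events on the scheme are NOT
#'   applied here; see [apply_dump()].
#' @param irf an [irf_model()] or `NULL` for delta-function excitation at
#'   t = 0.
#' @param times numeric vector of delays (ps).
#' @return an object of class `concentration_matrix`: list with `times` and
#'   `values` (delay x compartment matrix).
#' @export
concentration_profiles <- function(scheme, irf, times) {
  eg <- scheme_eigen(scheme)
  if (is.null(eg)) {
    message("near-degenerate or complex eigenvalues; using numerical propagation")
    return(concentration_profiles_ode(scheme, irf, times))
  }
  b <- eg$Vinv %*% scheme$input[scheme$compartments]
  Kt <- vapply(-eg$values, exp_gauss_kernel, numeric(length(times)),
               t = times, irf = irf)
  if (is.null(dim(Kt))) Kt <- matrix(Kt, nrow = length(times))
  # Kt is (nt x n) of per-mode kernels; c(t) rows = Kt %*% diag(b) %*% t(V)
  vals <- Kt %*% (t(eg$V) * as.numeric(b))
  colnames(vals) <- scheme$compartments
  new_concentration_matrix(times, clip_negative(vals))
}

new_concentration_matrix <- function(times, values) {
  structure(list(times = as.numeric(times), values = values),
            class = "concentration_matrix")
}

#' @export
print.concentration_matrix <- function(x, ...) {
  cat("<concentration_matrix> ", length(x$times), " delays x ",
      ncol(x$values), " compartments (",
      paste(colnames(x$values), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

## eigendecomposition of the rate matrix, or NULL when the analytic path is
## unsafe (complex or near-degenerate eigenvalues)
scheme_eigen <- function(scheme, tol = 1e-9) {
  K <- rate_matrix(scheme)
  eg <- eigen(K)
  if (is.complex(eg$values)) {
    if (max(abs(Im(eg$values))) > 1e-12 * max(1, max(abs(Re(eg$values)))))
      return(NULL)
    eg$values <- Re(eg$values)
    eg$vectors <- Re(eg$vectors)
  }
  lam <- eg$values
  if (length(lam) > 1) {
    s <- sort(lam)
    gap <- diff(s)
    scale <- pmax(abs(s[-1]), abs(s[-length(s)]), 1e-300)
    near <- gap / scale < tol
    # identical zero eigenvalues (several terminals) are fine: their modes
    # are genuinely decoupled absorbing states with independent eigenvectors
    zero_pair <- abs(s[-1]) < 1e-14 & abs(s[-length(s)]) < 1e-14
    if (any(near & !zero_pair)) return(NULL)
  }
  Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  if (is.null(Vinv)) return(NULL)
  list(values = lam, V = eg$vectors, Vinv = Vinv, K = K)
}

clip_negative <- function(vals, hard = -1e-9) {
  m <- min(vals)
  if (m < hard)
    stop("negative population ", format(m), " below tolerance; model is inconsistent")
  vals[vals < 0] <- 0
  vals
}

#' Numerical reference propagation of compartment populations
#'
#' Integrates the rate equations `dc/dt = K c + g(t) w` with a Gaussian
#' source term `g` (the IRF) using an adaptive stiff ODE solver. Serves as
#' the independent oracle for [concentration_profiles()] and as its fallback
#' for degenerate rate matrices. Dump events present on the scheme are
#' applied as instantaneous transfer events when `apply_dumps = TRUE`.
#'
#' @inheritParams concentration_profiles
#' @param apply_dumps apply the scheme's dump events (default `FALSE`).
#' @param rtol,atol solver tolerances.
#' @return a `concentration_matrix`.
#' @export
concentration_profiles_ode <- function(scheme, irf, times, apply_dumps = FALSE,
                                       rtol = 1e-10, atol = 1e-12) {
  K <- rate_matrix(scheme)
  w <- scheme$input[scheme$compartments]
  n <- length(w)
  if (is.null(irf)) {
    t0 <- 0
    y0 <- as.numeric(w)
    src <- function(t) 0
  } else {
    t0 <- irf$center - 10 * irf$width
    y0 <- numeric(n)
    src <- function(t) stats::dnorm(t, irf$center, irf$width)
  }
  deriv <- function(t, y, parms) list(as.numeric(K %*% y) + src(t) * as.numeric(w))
  tt <- sort(unique(c(t0, times[times >= t0])))
  ev <- NULL
  if (apply_dumps && length(scheme$dumps)) {
    dump_times <- vapply(scheme$dumps, function(d) d$time, 0)
    Ts <- lapply(scheme$dumps, function(d)
      transfer_matrix(scheme$compartments, d))
    evf <- function(t, y, parms) {
      i <- which.min(abs(dump_times - t))
      as.numeric(Ts[[i]] %*% y)
    }
    ## drop grid points nearly coincident with an event time, then add the
    ## exact event times (the solver rejects zero-length steps)
    tol <- 1e-9 * pmax(abs(dump_times), 1e-6)
    near_event <- vapply(tt, function(x)
      any(abs(x - dump_times) < tol & x != dump_times), TRUE)
    tt <- sort(unique(c(tt[!near_event], dump_times)))
    ev <- list(func = evf, time = dump_times)
  }
  ## collapse remaining near-coincident grid points
  keep <- c(TRUE, diff(tt) > 1e-12 * pmax(abs(tt[-1]), 1e-6))
  tt <- tt[keep]
  sol <- deSolve::ode(y = y0, times = tt, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol, events = ev)
  vals <- matrix(0, length(times), n, dimnames = list(NULL, scheme$compartments))
  inside <- times >= t0
  ## nearest-grid-point lookup (requested times may have been collapsed)
  idx <- vapply(times[inside], function(x) which.min(abs(tt - x)), 0L)
  vals[inside, ] <- unname(sol[idx, -1, drop = FALSE])
  new_concentration_matrix(times, clip_negative(vals, hard = -1e-7))
}

## n x n instantaneous transfer matrix of a dump event
transfer_matrix <- function(compartments, dump) {
  Tm <- diag(length(compartments))
  dimnames(Tm) <- list(compartments, compartments)
  for (i in seq_len(nrow(dump$transfers))) {
    tr <- dump$transfers[i, ]
    Tm[tr$from, tr$from] <- Tm[tr$from, tr$from] - tr$fraction
    Tm[tr$to, tr$from] <- Tm[tr$to, tr$from] + tr$fraction
  }
  Tm
}

#' Populations with instantaneous dump-pulse transfers applied
#'
#' Piecewise-analytic propagation of a scheme whose dump events move a
#' fraction of one or more populations between compartments at fixed delays.
#' Up to each event the ordinary IRF-convolved solution is used; at the
#' event the transfer matrix is applied to the populations present at that
#' instant; afterwards the homogeneous propagation of the transferred
#' populations is carried together with the analytically continued tail of
#' the Gaussian excitation, so conservation holds exactly across the event.
#'
#' @inheritParams concentration_profiles
#' @param dumps list of [dump_event()]s; defaults to the scheme's own.
#' @return a `concentration_matrix`.
#' @export
apply_dump <- function(scheme, irf, times, dumps = NULL) {
  if (is.null(dumps)) dumps <- scheme$dumps
  if (inherits(dumps, "dump_event")) dumps <- list(dumps)
  # events that transfer nothing are no-ops
  dumps <- Filter(function(d) any(d$transfers$fraction > 0), dumps)
  if (!length(dumps)) return(concentration_profiles(scheme, irf, times))
  dumps <- dumps[order(vapply(dumps, function(d) d$time, 0))]
  if (!is.null(irf)) {
    for (d in dumps)
      if (d$time < irf$center + irf$width)
        warning("dump at ", d$time, " ps is within the IRF (center ",
                irf$center, ", sigma ", irf$width, " ps)")
  }
  eg <- scheme_eigen(scheme)
  if (is.null(eg)) {
    message("near-degenerate or complex eigenvalues; using numerical propagation")
    sch <- scheme
    sch$dumps <- dumps
    return(concentration_profiles_ode(sch, irf, times, apply_dumps = TRUE))
  }
  n <- length(scheme$compartments)
  b <- as.numeric(eg$Vinv %*% scheme$input[scheme$compartments])
  kern <- function(t) {
    m <- vapply(-eg$values, exp_gauss_kernel, numeric(length(t)),
                t = t, irf = irf)
    if (is.null(dim(m))) m <- matrix(m, nrow = length(t))
    m
  }
  state_at <- function(t, t_ref, a_ref) {
    # c(t) = V [ e^{lam (t-t_ref)} a_ref + (K(t) - e^{lam (t-t_ref)} K(t_ref)) b ]
    if (is.null(t_ref))
      return(as.numeric(eg$V %*% (kern(t)[1, ] * b)))
    e <- exp(eg$values * (t - t_ref))
    as.numeric(eg$V %*% (e * a_ref + (kern(t)[1, ] - e * kern(t_ref)[1, ]) * b))
  }
  # modal coefficient of the homogeneous part after each event
  t_ref <- NULL; a_ref <- NULL
  segments <- list()
  bounds <- c(vapply(dumps, function(d) d$time, 0), Inf)
  for (i in seq_along(dumps)) {
    d <- dumps[[i]]
    c_before <- state_at(d$time, t_ref, a_ref)
    c_after <- as.numeric(transfer_matrix(scheme$compartments, d) %*% c_before)
    segments[[i]] <- list(t_ref = d$time,
                          a_ref = as.numeric(eg$Vinv %*% c_after))
    t_ref <- d$time; a_ref <- segments[[i]]$a_ref
  }
  vals <- matrix(0, length(times), n,
                 dimnames = list(NULL, scheme$compartments))
  pre <- times <= bounds[1]
  if (any(pre)) {
    Kt <- kern(times[pre])
    if (is.null(dim(Kt))) Kt <- matrix(Kt, nrow = sum(pre))
    vals[pre, ] <- Kt %*% (t(eg$V) * b)
  }
  for (i in seq_along(dumps)) {
    in_seg <- times > bounds[i] & times <= bounds[i + 1]
    if (!any(in_seg)) next
    seg <- segments[[i]]
    tt <- times[in_seg]
    E <- exp(outer(tt - seg$t_ref, eg$values))          # nt x n modes
    Kt <- kern(tt)
    if (is.null(dim(Kt))) Kt <- matrix(Kt, nrow = length(tt))
    K0 <- kern(seg$t_ref)[1, ]
    modal <- E * rep(seg$a_ref, each = length(tt)) +
      (Kt - E * rep(K0, each = length(tt))) * rep(b, each = length(tt))
    vals[in_seg, ] <- modal %*% t(eg$V)
  }
  new_concentration_matrix(times, clip_negative(vals))
}
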