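#' Target analysis: scheme-based global fitting with SADS
#'
#' Fits one or more difference-absorption datasets with an explicit
#' compartmental kinetic scheme by variable projection: the species
#' associated difference spectra (SADS) are eliminated by weighted linear
#' least squares at every step while any chosen subset of rate constants,
#' dump transfer fractions and per-dataset IRF centers is optimized by
#' Levenberg-Marquardt. Multiple datasets (e.g. pump-probe and
#' pump-dump-probe twins) are fitted jointly with shared kinetic parameters
#' and shared SADS; dump events are dataset-specific. SADS are returned on
#' the unit-initial-excitation scale.
#'
#' Compartments that stay unpopulated in every supplied dataset (e.g. a
#' dump-populated intermediate in the dump-free dataset alone) are excluded
#' from the projection automatically and get zero spectra. A structural
#' identifiability check at the initial point rejects free-parameter
#' combinations whose concentration sensitivities are rank deficient,
#' naming the null-space direction.
#'
#' @param datasets a [ta_dataset()] or list of them (shared wavelength axis).
#' @param scheme a [kinetic_scheme()] whose rates provide the initial values.
#' @param free_rates character vector of edges to optimize, as
#'   `"from->to"` strings; all other rates stay fixed.
#' @param free_branches character vector of branch fractions to optimize at
#'   fixed total outflow, as `"from->to1/to2"` strings: the fraction
#'   `k(from->to1) / (k(from->to1) + k(from->to2))` is freed
#'   (logit-parameterized) while the sum of the two rates keeps its initial
#'   value. This is the natural parameter when only the branching ratio --
#'   not the decay time -- is in question (e.g. photoproduct vs ground-state
#'   return), and it is exactly the direction that the equal-bleach
#'   constraint resolves: without a spectral constraint a branch fraction
#'   into a terminal photoproduct trades off freely against the scale of
#'   that photoproduct's spectrum.
#' @param dumps per-dataset dump events: list (parallel to `datasets`) of
#'   `NULL`, a [dump_event()], or a list of them. Default: no dumps.
#' @param free_dumps optimize the transfer fractions of all supplied dump
#'   events (logit-parameterized, per dataset).
#' @param irf an [irf_model()] or per-dataset list of them (or `NULL`s).
#' @param fit_irf_center optimize a time-zero offset per dataset.
#' @param bleach_constraint optional equal-bleach spectral constraint, a
#'   list as produced by [bleach_constraint()].
#' @param n_starts,seed multi-start policy as in [fit_sequential()].
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return object of class `ta_fit` (kind `"target"`) with elements `scheme`
#'   (fitted rates), `sads`, `dumps` (fitted), `concentrations` and
#'   `residuals` (per dataset), `ssq`, `std_errors`, `covariance`, `yields`
#'   (terminal yields of the fitted scheme).
#' @export
fit_target <- function(datasets, scheme, free_rates = character(),
                       free_branches = character(),
                       dumps = NULL, free_dumps = FALSE, irf = NULL,
                       fit_irf_center = FALSE, bleach_constraint = NULL,
                       n_starts = 8, seed = 1,
                       control = minpack.lm::nls.lm.control(maxiter = 200)) {
  if (inherits(datasets, "ta_dataset")) datasets <- list(datasets)
  nd <- length(datasets)
  if (is.null(dumps)) dumps <- vector("list", nd)
  if (inherits(dumps, "dump_event")) dumps <- list(list(dumps))
  dumps <- lapply(dumps, function(d)
    if (inherits(d, "dump_event")) list(d) else d)
  if (length(dumps) != nd) stop("'dumps' must be parallel to 'datasets'")
  if (!is.list(irf) || inherits(irf, "irf_model")) irf <- rep(list(irf), nd)
  if (length(irf) != nd) stop("'irf' must be parallel to 'datasets'")

  ## --- parameter vector ---------------------------------------------------
  edges <- lapply(free_rates, function(s) {
    p <- strsplit(gsub(" ", "", s), "->", fixed = TRUE)[[1]]
    if (length(p) != 2) stop("free rate must be given as 'from->to': ", s)
    p
  })
  par0 <- vapply(edges, function(e)
    log(edge_rate(scheme, e[1], e[2])), 0)
  par_names <- vapply(edges, function(e) paste0("k(", e[1], "->", e[2], ")"), "")
  branches <- lapply(free_branches, function(s) {
    m <- regmatches(gsub(" ", "", s),
                    regexec("^([^-]+)->([^/]+)/(.+)$", gsub(" ", "", s)))[[1]]
    if (length(m) != 4)
      stop("free branch must be given as 'from->to1/to2': ", s)
    m[2:4]
  })
  for (b in branches) {
    k1 <- edge_rate(scheme, b[1], b[2])
    k2 <- edge_rate(scheme, b[1], b[3])
    par0 <- c(par0, stats::qlogis(min(max(k1 / (k1 + k2), 1e-4), 1 - 1e-4)))
    par_names <- c(par_names, sprintf("branch(%s->%s/%s)", b[1], b[2], b[3]))
  }
  branch_totals <- vapply(branches, function(b)
    edge_rate(scheme, b[1], b[2]) + edge_rate(scheme, b[1], b[3]), 0)
  n_branch <- length(branches)
  dump_index <- NULL
  if (free_dumps) {
    for (i in seq_len(nd)) for (j in seq_along(dumps[[i]])) {
      tr <- dumps[[i]][[j]]$transfers
      for (r in seq_len(nrow(tr))) {
        par0 <- c(par0, stats::qlogis(min(max(tr$fraction[r], 1e-4), 1 - 1e-4)))
        par_names <- c(par_names,
                       sprintf("dump%d(%s->%s)", i, tr$from[r], tr$to[r]))
        dump_index <- rbind(dump_index, c(i, j, r))
      }
    }
  }
  if (fit_irf_center) {
    for (i in seq_len(nd)) {
      if (is.null(irf[[i]])) next
      par0 <- c(par0, irf[[i]]$center)
      par_names <- c(par_names, sprintf("irf_center%d", i))
    }
  }
  names(par0) <- par_names
  n_rate <- length(edges)

  apply_par <- function(par) {
    sch <- scheme
    for (i in seq_len(n_rate))
      sch <- set_edge_rate(sch, edges[[i]][1], edges[[i]][2], exp(par[[i]]))
    for (i in seq_len(n_branch)) {
      b <- branches[[i]]
      f <- stats::plogis(par[[n_rate + i]])
      sch <- set_edge_rate(sch, b[1], b[2], f * branch_totals[i])
      sch <- set_edge_rate(sch, b[1], b[3], (1 - f) * branch_totals[i])
    }
    dmp <- dumps
    if (free_dumps && !is.null(dump_index)) {
      for (r in seq_len(nrow(dump_index))) {
        ix <- dump_index[r, ]
        dmp[[ix[1]]][[ix[2]]]$transfers$fraction[ix[3]] <-
          stats::plogis(par[[n_rate + n_branch + r]])
      }
    }
    ir <- irf
    if (fit_irf_center) {
      off <- n_rate + n_branch + if (is.null(dump_index)) 0 else nrow(dump_index)
      k <- 0
      for (i in seq_len(nd)) {
        if (is.null(ir[[i]])) next
        k <- k + 1
        ir[[i]]$center <- par[[off + k]]
      }
    }
    list(scheme = sch, dumps = dmp, irf = ir)
  }

  obs <- observed_compartments(scheme)
  model_C <- function(par) {
    mp <- apply_par(par)
    lapply(seq_len(nd), function(i) {
      conc <- if (length(mp$dumps[[i]]))
        apply_dump(mp$scheme, mp$irf[[i]], datasets[[i]]$times,
                   dumps = mp$dumps[[i]])
      else concentration_profiles(mp$scheme, mp$irf[[i]], datasets[[i]]$times)
      conc$values[, obs, drop = FALSE]
    })
  }

  ## compartments never populated in any dataset carry no spectral information
  C0 <- model_C(par0)
  peak <- max(vapply(C0, function(m) max(abs(m)), 0))
  live <- Reduce(`|`, lapply(C0, function(m)
    apply(abs(m) > 1e-12 * peak, 2, any)))
  observed <- obs[live]
  if (!any(live)) stop("no compartment is ever populated")

  check_identifiability(model_C, par0, live)

  penalty <- function(spectra, wavelengths) {
    if (is.null(bleach_constraint)) return(numeric())
    bleach_penalty(spectra, wavelengths, bleach_constraint)
  }
  resid_fn <- function(par) {
    Cs <- lapply(model_C(par), function(m) m[, live, drop = FALSE])
    pr <- joint_projection(datasets, Cs, rank_check = FALSE)
    W <- do.call(rbind, lapply(datasets, function(d) d$weights))
    c(as.numeric(sqrt(W) * pr$residuals),
      penalty(pr$spectra, datasets[[1]]$wavelengths))
  }

  if (length(par0)) {
    best <- run_multistart(resid_fn, par0,
                           jitter_idx = seq_len(n_rate + n_branch),
                           n_starts = n_starts, seed = seed, control = control)
    par <- best$par
    converged <- best$converged
  } else {
    par <- par0
    converged <- TRUE
  }

  mp <- apply_par(par)
  Cs_full <- model_C(par)
  Cs <- lapply(Cs_full, function(m) m[, live, drop = FALSE])
  pr <- joint_projection(datasets, Cs)
  sads <- matrix(0, length(obs), length(datasets[[1]]$wavelengths),
                 dimnames = list(obs, NULL))
  sads[observed, ] <- pr$spectra
  ## split stacked residuals back per dataset
  nts <- vapply(datasets, function(d) length(d$times), 0)
  splits <- rep(seq_len(nd), nts)
  residuals <- lapply(seq_len(nd), function(i)
    pr$residuals[splits == i, , drop = FALSE])

  errs <- if (length(par)) fit_errors(resid_fn, par, sum(resid_fn(par)^2))
          else list(se = numeric(), cov = matrix(0, 0, 0))
  value <- se <- numeric(length(par))
  if (length(par)) {
    value[seq_len(n_rate)] <- exp(par[seq_len(n_rate)])
    se[seq_len(n_rate)] <- value[seq_len(n_rate)] * errs$se[seq_len(n_rate)]
    logit_ii <- n_rate + seq_len(n_branch + NROW(dump_index))
    value[logit_ii] <- stats::plogis(par[logit_ii])
    se[logit_ii] <- value[logit_ii] * (1 - value[logit_ii]) *
      errs$se[logit_ii]                      # d plogis / d x = p(1-p)
    rest <- setdiff(seq_along(par), c(seq_len(n_rate), logit_ii))
    value[rest] <- par[rest]
    se[rest] <- errs$se[rest]
  }
  std_errors <- data.frame(parameter = names(par), value = value, se = se,
                           stringsAsFactors = FALSE)

  outflow <- -diag(rate_matrix(mp$scheme))
  lifetimes <- sort(1 / unique(outflow[outflow > 0]))
  n_scheme_par <- n_rate + n_branch
  scheme_fn <- function(th) apply_par(c(th, par[-seq_len(n_scheme_par)]))$scheme
  fit <- structure(list(
    kind = "target", scheme = mp$scheme, dumps = mp$dumps, irf = mp$irf,
    sads = sads, spectra = sads, observed = observed,
    concentrations = Cs_full, residuals = residuals, ssq = pr$ssq,
    lifetimes = lifetimes,
    std_errors = std_errors, covariance = errs$cov, par = par,
    free_rates = free_rates, free_branches = free_branches,
    n_scheme_par = n_scheme_par, scheme_fn = scheme_fn,
    converged = converged,
    yields = terminal_yields(mp$scheme),
    bleach = if (!is.null(bleach_constraint))
      bleach_report(sads, datasets[[1]]$wavelengths, bleach_constraint),
    call_args = list(datasets = datasets, scheme = scheme,
                     free_rates = free_rates, free_branches = free_branches,
                     dumps = dumps, free_dumps = free_dumps, irf = irf,
                     fit_irf_center = fit_irf_center,
                     n_starts = n_starts, seed = seed, control = control),
    dataset = datasets[[1]]), class = "ta_fit")
  fit
}

## sensitivity-rank check of the free parameters at the initial point
check_identifiability <- function(model_C, par0, live) {
  p <- length(par0)
  if (p < 2) return(invisible(TRUE))
  f <- function(par) as.numeric(do.call(
    rbind, lapply(model_C(par), function(m) m[, live, drop = FALSE])))
  J <- numeric_jacobian(f, par0)
  sv <- svd(J)
  if (sv$d[p] < 1e-10 * sv$d[1]) {
    dir <- round(sv$v[, p], 3)
    stop("free parameters are structurally unidentifiable at the initial ",
         "point; null-space direction: ",
         paste(sprintf("%+.3f*%s", dir[dir != 0], names(par0)[dir != 0]),
               collapse = " "))
  }
  invisible(TRUE)
}

#' Equal-bleach spectral constraint
#'
#' Constraint specification for [fit_target()] /
#' [apply_bleach_constraint()]: a penalty that equalizes the integrated SADS
#' amplitude over the ground-state-bleach window across the named species.
#' Used to fix the scaling degeneracy between a photoproduct's branching
#' fraction and its spectrum, which is what turns SADS amplitudes into a
#' quantum yield.
#'
#' @param window `c(lo, hi)` in nm (default 430-465, the bleach region).
#' @param species character vector of species to equalize (default: all
#'   observed species except dump-populated intermediates, chosen by the
#'   caller).
#' @param weight penalty weight multiplying the amplitude differences, in
#'   units of the data (default 1).
#' @return list of class `bleach_constraint`.
#' @export
bleach_constraint <- function(window = c(430, 465), species = NULL,
                              weight = 1) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("bleach window must be c(lo, hi) with lo < hi")
  structure(list(window = window, species = species, weight = weight),
            class = "bleach_constraint")
}

## integrated in-window amplitude per constrained species
bleach_amplitudes <- function(spectra, wavelengths, bc) {
  sel <- wavelengths >= bc$window[1] & wavelengths <= bc$window[2]
  if (!any(sel))
    stop("bleach window [", bc$window[1], ", ", bc$window[2],
         "] nm contains no wavelength grid points")
  sp <- if (is.null(bc$species)) rownames(spectra) else bc$species
  missing <- setdiff(sp, rownames(spectra))
  if (length(missing))
    stop("constrained species not in fit: ", paste(missing, collapse = ", "))
  apply(spectra[sp, sel, drop = FALSE], 1, function(y)
    pracma::trapz(wavelengths[sel], y))
}

## dimensionless penalty: relative spread of the integrated amplitudes, so
## that with weight ~1 it settles flat directions (where the data gradient
## vanishes) while barely perturbing data-determined parameters
bleach_penalty <- function(spectra, wavelengths, bc) {
  a <- bleach_amplitudes(spectra, wavelengths, bc)
  scale <- mean(abs(a))
  if (scale == 0) return(numeric(length(a)))
  bc$weight * (a - mean(a)) / scale
}

bleach_report <- function(spectra, wavelengths, bc) {
  a <- bleach_amplitudes(spectra, wavelengths, bc)
  list(window = bc$window, amplitudes = a,
       spread = if (mean(abs(a)) > 0) (max(a) - min(a)) / mean(abs(a)) else 0)
}

#' Refit a target analysis under the equal-bleach constraint
#'
#' Takes a fitted target analysis, adds the equal-bleach penalty and refits
#' starting from the fitted parameters. The returned fit records the
#' integrated bleach amplitudes and their relative spread before and after
#' the constraint.
#'
#' @param fit a `ta_fit` of kind `"target"`.
#' @param window,species,weight see [bleach_constraint()].
#' @return the constrained `ta_fit`, with element `bleach` carrying
#'   `pre_spread`/`post_spread`.
#' @export
apply_bleach_constraint <- function(fit, window = c(430, 465),
                                    species = NULL, weight = 1) {
  stopifnot(inherits(fit, "ta_fit"))
  if (!identical(fit$kind, "target"))
    stop("bleach constraint applies to target fits")
  bc <- bleach_constraint(window, species, weight)
  pre <- bleach_report(fit$sads, fit$call_args$datasets[[1]]$wavelengths, bc)
  args <- fit$call_args
  sch <- fit$scheme            # start from the fitted rates
  refit <- fit_target(args$datasets, sch, free_rates = args$free_rates,
                      free_branches = args$free_branches,
                      dumps = fit$dumps, free_dumps = args$free_dumps,
                      irf = fit$irf, fit_irf_center = args$fit_irf_center,
                      bleach_constraint = bc, n_starts = 1,
                      seed = args$seed, control = args$control)
  refit$bleach$pre_spread <- pre$spread
  refit$bleach$post_spread <- refit$bleach$spread
  refit
}

#' Quantum yield(s) from a fitted target scheme
#'
#' Terminal absorbing probabilities of the fitted kinetic scheme, with a
#' delta-method standard error propagated from the fitted rate covariance.
#'
#' @param fit a `ta_fit` of kind `"target"`.
#' @param photoproduct terminal compartment(s) of interest (default: all
#'   terminals except the ground state).
#' @return data frame with `compartment`, `yield`, `se`.
#' @export
quantum_yield_from_fit <- function(fit, photoproduct = NULL) {
  stopifnot(inherits(fit, "ta_fit"), identical(fit$kind, "target"))
  y <- terminal_yields(fit$scheme)
  if (is.null(photoproduct))
    photoproduct <- setdiff(names(y), fit$scheme$ground)
  se <- rep(0, length(photoproduct))
  np <- fit$n_scheme_par %||% 0
  if (np > 0 && all(is.finite(fit$covariance))) {
    yfun <- function(th)
      as.numeric(terminal_yields(fit$scheme_fn(th))[photoproduct])
    th0 <- fit$par[seq_len(np)]
    G <- numeric_jacobian(yfun, th0)
    V <- fit$covariance[seq_len(np), seq_len(np), drop = FALSE]
    se <- sqrt(pmax(diag(G %*% V %*% t(G)), 0))
  }
  data.frame(compartment = photoproduct, yield = as.numeric(y[photoproduct]),
             se = se, stringsAsFactors = FALSE)
}

#' Parameter standard errors of a fit
#'
#' Returns the linearized (Jacobian-based) standard errors computed at the
#' optimum, flagging parameters whose error is unbounded (singular
#' information matrix) or that sit at an effective bound of their
#' transformed scale.
#'
#' @param fit a `ta_fit`.
#' @return data frame `parameter`, `value`, `se`, `flag`.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "ta_fit"))
  out <- fit$std_errors
  out$flag <- ""
  out$flag[!is.finite(out$se)] <- "infinite (singular information)"
  if (!is.null(fit$par)) {
    at_bound <- grepl("^dump", names(fit$par)) & abs(fit$par) > 8
    if (any(at_bound))
      out$flag[at_bound] <- "at bound"
  }
  out
}

#' Residual-matrix SVD diagnostics
#'
#' Singular-value decomposition of the (masked-excluded) residual matrix of
#' a fit: for an adequate fit the leading singular value stays within about
#' twice the expectation for pure noise of the same size
#' (`sd * (sqrt(m) + sqrt(n))`); structure above that threshold indicates
#' missing kinetic components.
#'
#' @param fit a `ta_fit`, or a plain residual matrix.
#' @param n_vectors number of singular vectors to return.
#' @return list with `d` (singular values), `u`, `v`, `noise_floor`,
#'   `threshold`, `structured` (logical flag).
#' @export
svd_residual_diagnostics <- function(fit, n_vectors = 3) {
  R <- if (inherits(fit, "ta_fit")) {
    if (is.list(fit$residuals) && !is.matrix(fit$residuals))
      do.call(rbind, fit$residuals) else fit$residuals
  } else as.matrix(fit)
  W <- NULL
  if (inherits(fit, "ta_fit")) {
    ds <- if (!is.null(fit$call_args)) fit$call_args$datasets else list(fit$dataset)
    W <- do.call(rbind, lapply(ds, function(d) d$weights))
  }
  live <- if (is.null(W)) is.finite(R) else W > 0
  sigma_hat <- stats::sd(R[live])
  sv <- svd(R, nu = n_vectors, nv = n_vectors)
  floor_sv <- sigma_hat * (sqrt(nrow(R)) + sqrt(ncol(R)))
  list(d = sv$d, u = sv$u, v = sv$v, noise_floor = floor_sv,
       threshold = 2 * floor_sv, structured = sv$d[1] > 2 * floor_sv)
}
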