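#' Sequential-model concentration matrix
#'
#' Populations of an unbranched sequential chain 1 -> 2 -> ... -> n under
#' Gaussian-IRF excitation, expressed in closed form as a linear combination
#' of per-rate IRF-convolved exponential kernels: `C_seq = Phi %*% A` where
#' `Phi` has one kernel column per decay rate and `A` is the upper-triangular
#' amplitude matrix of the chain (see [seq_amplitude_matrix()]). A zero rate
#' (infinite lifetime) yields a non-decaying final component.
#'
#' @param rates per-component decay rates (ps^-1), 0 for the non-decaying
#'   component; must be pairwise distinct.
#' @param times delay grid (ps).
#' @param irf an [irf_model()] or `NULL`.
#' @return list with `C` (delay x component), `Phi`, and `A`.
#' @export
sequential_concentrations <- function(rates, times, irf = NULL) {
  A <- seq_amplitude_matrix(rates)
  Phi <- vapply(rates, exp_gauss_kernel, numeric(length(times)),
                t = times, irf = irf)
  if (is.null(dim(Phi))) Phi <- matrix(Phi, nrow = length(times))
  list(C = Phi %*% A, Phi = Phi, A = A)
}

#' Sequential-to-parallel amplitude matrix
#'
#' Upper-triangular matrix `A` with `A[j, l]` the amplitude of the j-th
#' exponential (rate `k_j`) in the population of sequential component l:
#' `A[j, l] = prod(k_m, m < l) / prod(k_m - k_j, m <= l, m != j)`.
#' This matrix is the exact linear map between the parallel (DADS) and
#' sequential (EADS) representations of a multiexponential fit.
#'
#' @param rates pairwise-distinct decay rates (ps^-1; 0 allowed once).
#' @return n x n upper-triangular matrix.
#' @export
seq_amplitude_matrix <- function(rates) {
  n <- length(rates)
  if (n > 1) {
    gap <- min(abs(outer(rates, rates, "-")[lower.tri(matrix(0, n, n))]))
    if (gap < 1e-12 * max(rates, 1e-300))
      stop("sequential amplitudes undefined for (near-)equal rates; ",
           "use distinct rates or numerical propagation")
  }
  A <- matrix(0, n, n)
  for (l in seq_len(n)) {
    for (j in seq_len(l)) {
      num <- prod(rates[seq_len(l - 1)])
      den <- prod(rates[setdiff(seq_len(l), j)] - rates[j])
      A[j, l] <- num / den
    }
  }
  A
}

#' Decay-associated from evolution-associated spectra (and back)
#'
#' The sequential (EADS) and parallel (DADS) descriptions of a global fit
#' are linearly equivalent: with `A = seq_amplitude_matrix(1/lifetimes)`,
#' `DADS = A %*% EADS`. Both reconstruct the identical model matrix.
#'
#' @param eads,dads component x wavelength spectra matrices.
#' @param lifetimes component lifetimes (ps), ascending, last may be `Inf`.
#' @return the transformed spectra matrix.
#' @export
dads_from_eads <- function(eads, lifetimes) {
  A <- seq_amplitude_matrix(1 / lifetimes)
  out <- A %*% eads
  rownames(out) <- rownames(eads)
  out
}

#' @rdname dads_from_eads
#' @export
eads_from_dads <- function(dads, lifetimes) {
  A <- seq_amplitude_matrix(1 / lifetimes)
  out <- solve(A, dads)
  rownames(out) <- rownames(dads)
  out
}

#' Project spectra out of a difference-absorption matrix
#'
#' The variable-projection (separable least squares) step: given a
#' concentration matrix, solves the weighted linear least-squares problem
#' for the component spectra at every wavelength, leaving residuals
#' orthogonal to the concentration columns under the weights. Fully masked
#' wavelengths get zero spectra and zero residual weight.
#'
#' @param dataset a [ta_dataset()].
#' @param C concentration matrix (delay x component) or a
#'   `concentration_matrix`.
#' @param rank_check error on a rank-deficient concentration matrix
#'   (default). With `rank_check = FALSE` a minimum-norm (pseudoinverse)
#'   solution is returned instead -- the mode used internally while the
#'   nonlinear optimizer explores parameter space, where transient
#'   quasi-degeneracies must not abort the search.
#' @return list with `spectra` (component x wavelength), `residuals`
#'   (unweighted, delay x wavelength, zero where masked), `ssq` (weighted
#'   sum of squared residuals) and `fitted`.
#' @export
project_spectra <- function(dataset, C, rank_check = TRUE) {
  if (inherits(C, "concentration_matrix")) C <- C$values
  C <- as.matrix(C)
  stopifnot(nrow(C) == length(dataset$times))
  ncomp <- ncol(C)
  # judge rank on unit-scaled columns: raw populations may differ by orders
  # of magnitude without being degenerate
  cn <- sqrt(colSums(C^2))
  Cs <- C / rep(pmax(cn, 1e-300), each = nrow(C))
  deficient <- any(cn == 0) || qr(Cs, tol = 1e-10)$rank < ncomp
  if (deficient && rank_check) {
    cc <- suppressWarnings(stats::cor(C))
    cc[!is.finite(cc)] <- 1
    pairs <- which(abs(cc) > 1 - 1e-8 & upper.tri(cc), arr.ind = TRUE)
    lbl <- colnames(C); if (is.null(lbl)) lbl <- paste0("comp", seq_len(ncomp))
    stop("concentration matrix is rank deficient; collinear components: ",
         if (nrow(pairs)) paste(lbl[pairs[, 1]], lbl[pairs[, 2]],
                                sep = " ~ ", collapse = ", ")
         else "(no single collinear pair; joint degeneracy)")
  }
  solve_ls <- function(A, B) {
    # minimum-norm weighted least squares via SVD, tolerant of degeneracy
    sv <- svd(A)
    pos <- sv$d > 1e-12 * sv$d[1]
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% B) / sv$d[pos])
  }
  D <- dataset$delta_A
  W <- dataset$weights
  nl <- ncol(D)
  S <- matrix(0, ncomp, nl, dimnames = list(colnames(C), NULL))
  uniform <- apply(W, 2, function(x) all(x == x[1]))
  live <- colSums(W) > 0
  easy <- uniform & live
  if (any(easy))
    S[, easy] <- solve_ls(C, D[, easy, drop = FALSE])
  for (j in which(!uniform & live)) {
    sw <- sqrt(W[, j])
    S[, j] <- solve_ls(C * sw, D[, j] * sw)
  }
  S[!is.finite(S)] <- 0
  fitted <- C %*% S
  res <- D - fitted
  res[W == 0] <- 0
  list(spectra = S, residuals = res, ssq = sum(W * res^2), fitted = fitted)
}

## projection with spectra shared across stacked datasets: rows of the
## per-dataset concentration matrices and data are concatenated in time
joint_projection <- function(datasets, Cs, rank_check = TRUE) {
  D <- do.call(rbind, lapply(datasets, function(d) d$delta_A))
  W <- do.call(rbind, lapply(datasets, function(d) d$weights))
  C <- do.call(rbind, Cs)
  stacked <- structure(list(times = seq_len(nrow(D)),
                            wavelengths = datasets[[1]]$wavelengths,
                            delta_A = D, weights = W, meta = list()),
                       class = "ta_dataset")
  project_spectra(stacked, C, rank_check = rank_check)
}

#' Sequential (EADS/DADS) global analysis by variable projection
#'
#' Fits an n-component sequential chain convolved with a Gaussian IRF to a
#' difference-absorption matrix. The nonlinear parameters (log lifetimes
#' and, optionally, IRF center and width) are optimized by
#' Levenberg-Marquardt least squares with the component spectra eliminated
#' analytically at every step ([project_spectra()]). A trailing `Inf` in
#' `init_lifetimes` adds a non-decaying final component. Both EADS and DADS
#' are returned; the time constants apply to both. Lifetimes are reported
#' sorted ascending (relabelled only at convergence).
#'
#' A configurable number of jittered multi-starts (factors up to x/÷3
#' around the initial lifetimes, fixed seed) guards against local minima;
#' the best weighted sum of squares wins.
#'
#' @param dataset a [ta_dataset()].
#' @param init_lifetimes initial lifetimes (ps), distinct, optionally ending
#'   in `Inf`.
#' @param irf an [irf_model()] with the initial IRF, or `NULL` to fit
#'   without IRF convolution (then kinetics start at t = 0).
#' @param fit_irf optimize the IRF center and width (default `TRUE` when an
#'   IRF is given).
#' @param n_starts number of jittered starts (default 8).
#' @param seed seed for the start jitter.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return object of class `ta_fit` with elements `lifetimes`, `rates`,
#'   `irf`, `eads`, `dads`, `residuals`, `ssq`, `std_errors` (data frame),
#'   `covariance`, `converged`, `dataset`.
#' @export
fit_sequential <- function(dataset, init_lifetimes, irf = NULL,
                           fit_irf = !is.null(irf), n_starts = 8, seed = 1,
                           control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(dataset, "ta_dataset"), length(init_lifetimes) >= 1)
  has_inf <- !is.finite(init_lifetimes[length(init_lifetimes)])
  taus <- init_lifetimes[is.finite(init_lifetimes)]
  if (any(!is.finite(init_lifetimes)) && !has_inf)
    stop("only the final component may be non-decaying (Inf lifetime)")
  if (any(taus <= 0)) stop("lifetimes must be positive")
  if (anyDuplicated(taus)) stop("initial lifetimes must be distinct")

  par0 <- log(taus)
  par_names <- paste0("log_tau", seq_along(taus))
  if (fit_irf) {
    if (is.null(irf)) stop("fit_irf requires an initial IRF")
    par0 <- c(par0, irf$center, log(irf$width))
    par_names <- c(par_names, "irf_center", "log_irf_width")
  }
  names(par0) <- par_names

  model_C <- function(par) {
    k <- c(1 / exp(par[seq_along(taus)]), if (has_inf) 0)
    this_irf <- irf
    if (fit_irf)
      this_irf <- irf_model(center = par[["irf_center"]],
                            width = exp(par[["log_irf_width"]]))
    sequential_concentrations(k, dataset$times, this_irf)$C
  }
  resid_fn <- function(par) {
    C <- model_C(par)
    pr <- project_spectra(dataset, C)
    as.numeric(sqrt(dataset$weights) * pr$residuals)
  }
  best <- run_multistart(resid_fn, par0, jitter_idx = seq_along(taus),
                         n_starts = n_starts, seed = seed, control = control)
  par <- best$par

  ## relabel by ascending lifetime at convergence
  ord <- order(exp(par[seq_along(taus)]))
  par[seq_along(taus)] <- par[seq_along(taus)][ord]
  lifetimes <- c(exp(par[seq_along(taus)]), if (has_inf) Inf)
  rates <- 1 / lifetimes
  rates[!is.finite(lifetimes)] <- 0
  fit_irf_out <- if (fit_irf)
    irf_model(center = par[["irf_center"]], width = exp(par[["log_irf_width"]]))
  else irf
  C <- model_C(par)
  colnames(C) <- paste0("EADS", seq_along(lifetimes))
  pr <- project_spectra(dataset, C)
  eads <- pr$spectra
  dads <- dads_from_eads(eads, lifetimes)
  rownames(dads) <- paste0("DADS", seq_along(lifetimes))

  errs <- fit_errors(resid_fn, par, pr$ssq)
  se_tau <- exp(par[seq_along(taus)]) * errs$se[seq_along(taus)]
  std_errors <- data.frame(
    parameter = c(paste0("tau", seq_along(taus)),
                  if (fit_irf) c("irf_center", "irf_width")),
    value = c(exp(par[seq_along(taus)]),
              if (fit_irf) c(fit_irf_out$center, fit_irf_out$width)),
    se = c(se_tau,
           if (fit_irf) c(errs$se[["irf_center"]],
                          fit_irf_out$width * errs$se[["log_irf_width"]])),
    stringsAsFactors = FALSE)

  structure(list(kind = "sequential", lifetimes = lifetimes, rates = rates,
                 irf = fit_irf_out, eads = eads, dads = dads,
                 spectra = eads, concentrations = C,
                 residuals = pr$residuals, ssq = pr$ssq,
                 std_errors = std_errors, covariance = errs$cov,
                 par = par, converged = best$converged,
                 info = best$info, dataset = dataset),
            class = "ta_fit")
}

## shared multi-start Levenberg-Marquardt driver
run_multistart <- function(resid_fn, par0, jitter_idx, n_starts, seed,
                           control, lower = NULL, upper = NULL) {
  starts <- list(par0)
  if (n_starts > 1) {
    starts <- c(starts, withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        p <- par0
        p[jitter_idx] <- p[jitter_idx] +
          stats::runif(length(jitter_idx), -log(3), log(3))
        p
      })
    }))
  }
  best <- NULL
  last_err <- NULL
  for (p in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p, fn = resid_fn, control = control,
                         lower = lower, upper = upper),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (is.null(fit)) next
    ssq <- sum(fit$fvec^2)
    if (is.null(best) || ssq < best$ssq)
      best <- list(par = stats::setNames(coef(fit), names(p)), ssq = ssq,
                   converged = fit$info %in% 1:4, info = fit$message)
  }
  if (is.null(best))
    stop("all optimization starts failed; last error: ", last_err)
  if (!best$converged)
    warning("fit did not formally converge: ", best$info)
  best
}

## linearized (Jacobian-based) standard errors at the optimum
fit_errors <- function(resid_fn, par, ssq) {
  J <- numeric_jacobian(resid_fn, par)
  dof <- max(length(resid_fn(par)) - length(par), 1)
  s2 <- ssq / dof
  JtJ <- crossprod(J)
  cov <- tryCatch(s2 * solve(JtJ), error = function(e) NULL)
  if (is.null(cov)) {
    se <- rep(Inf, length(par))
    cov <- matrix(Inf, length(par), length(par))
  } else {
    se <- sqrt(pmax(diag(cov), 0))
  }
  names(se) <- names(par)
  dimnames(cov) <- list(names(par), names(par))
  list(se = se, cov = cov, jacobian = J)
}

numeric_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (i in seq_along(par)) {
    h <- eps * max(abs(par[i]), 1)
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    J[, i] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

#' @export
print.ta_fit <- function(x, ...) {
  cat("<ta_fit> ", x$kind, " fit, ", length(x$lifetimes), " components, ssq = ",
      format(x$ssq, digits = 6), "\n", sep = "")
  lt <- x$lifetimes
  cat("  lifetimes (ps):", paste(format(lt, digits = 4), collapse = ", "), "\n")
  if (!is.null(x$std_errors)) {
    cat("  parameters:\n")
    print(x$std_errors, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Simulate a sequential-model dataset
#'
#' Convenience forward generator for sequential global analysis: builds the
#' chain concentrations for the given lifetime ladder and multiplies by the
#' supplied component (EADS) spectra; noise and masking as in
#' [simulate_dataset()].
#'
#' @param lifetimes ascending lifetimes (ps), last may be `Inf`.
#' @param spectra component x wavelength EADS matrix.
#' @inheritParams simulate_dataset
#' @return a [ta_dataset()] with attribute `"truth"`.
#' @export
simulate_sequential_dataset <- function(lifetimes, spectra, irf, times,
                                        wavelengths, noise_sigma = 0.01,
                                        seed = 1,
                                        mask_windows = list(c(465, 495)),
                                        meta = list()) {
  rates <- ifelse(is.finite(lifetimes), 1 / lifetimes, 0)
  C <- sequential_concentrations(rates, times, irf)$C
  model <- C %*% spectra
  peak <- max(abs(model))
  noisy <- withr::with_seed(seed, {
    model + matrix(stats::rnorm(length(model), sd = noise_sigma * peak),
                   nrow(model), ncol(model))
  })
  w <- matrix(1, nrow(model), ncol(model))
  for (win in mask_windows)
    w[, wavelengths >= win[1] & wavelengths <= win[2]] <- 0
  ds <- ta_dataset(times, wavelengths, noisy, weights = w, meta = meta)
  attr(ds, "truth") <- list(lifetimes = lifetimes, spectra = spectra,
                            irf = irf, model = model,
                            noise_sigma = noise_sigma, seed = seed)
  ds
}
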