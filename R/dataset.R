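#' Time-resolved difference-absorption dataset
#'
#' Container for a delay x wavelength matrix of pump-induced absorbance
#' changes, with a same-shape nonnegative weight matrix (0 = masked cell,
#' e.g. the pump-scatter window) and free-form metadata (pump/dump
#' wavelengths, pH label, ...). Masked cells are ignored by every fit and
#' every statistic in the package.
#'
#' @param times strictly increasing delay grid (ps).
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param delta_A numeric matrix, `length(times)` x `length(wavelengths)`.
#' @param weights same-shape nonnegative matrix; defaults to all 1 with 0
#'   where `delta_A` is not finite (those cells are zeroed).
#' @param meta named list of metadata.
#' @return object of class `ta_dataset`.
#' @export
ta_dataset <- function(times, wavelengths, delta_A, weights = NULL,
                       meta = list()) {
  times <- as.numeric(times); wavelengths <- as.numeric(wavelengths)
  if (any(diff(times) <= 0)) stop("delay axis must be strictly increasing")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength axis must be strictly increasing")
  delta_A <- as.matrix(delta_A)
  if (!all(dim(delta_A) == c(length(times), length(wavelengths))))
    stop("delta_A must be length(times) x length(wavelengths)")
  if (is.null(weights)) weights <- matrix(1, nrow(delta_A), ncol(delta_A))
  weights <- as.matrix(weights)
  if (!all(dim(weights) == dim(delta_A)))
    stop("weights must have the shape of delta_A")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative")
  bad <- !is.finite(delta_A)
  weights[bad] <- 0
  delta_A[bad] <- 0
  structure(list(times = times, wavelengths = wavelengths,
                 delta_A = delta_A, weights = weights, meta = meta),
            class = "ta_dataset")
}

#' @export
print.ta_dataset <- function(x, ...) {
  cat("<ta_dataset> ", length(x$times), " delays (", format(min(x$times)),
      " .. ", format(max(x$times)), " ps) x ", length(x$wavelengths),
      " wavelengths (", min(x$wavelengths), " .. ", max(x$wavelengths),
      " nm), ", sum(x$weights == 0), " masked cells\n", sep = "")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Gaussian-band species spectrum model
#'
#' Each species' difference spectrum is a sum of Gaussian bands
#' (center in nm, FWHM in nm, signed amplitude). By the usual difference
#' conventions, ground-state bleach and stimulated emission carry negative
#' amplitudes, (excited-state or product) absorptions positive ones.
#'
#' @param species named list; each element is a data frame with columns
#'   `center`, `fwhm`, `amplitude` (one row per band).
#' @return object of class `spectrum_model`.
#' @export
spectrum_model <- function(species) {
  stopifnot(is.list(species), !is.null(names(species)))
  for (nm in names(species)) {
    b <- species[[nm]]
    if (!all(c("center", "fwhm", "amplitude") %in% names(b)))
      stop("bands for ", nm, " need columns center, fwhm, amplitude")
    if (any(b$fwhm <= 0)) stop("band FWHM must be positive (", nm, ")")
  }
  structure(list(species = species), class = "spectrum_model")
}

#' Evaluate model spectra on a wavelength grid
#'
#' @param model a [spectrum_model()].
#' @param wavelengths nm grid. A warning is issued if the grid does not
#'   cover every band center to +/- 2 FWHM.
#' @param species subset of species names (default all).
#' @return matrix, species x wavelength.
#' @export
eval_spectra <- function(model, wavelengths, species = NULL) {
  if (is.null(species)) species <- names(model$species)
  out <- matrix(0, length(species), length(wavelengths),
                dimnames = list(species, NULL))
  uncovered <- character()
  for (nm in species) {
    for (i in seq_len(nrow(model$species[[nm]]))) {
      b <- model$species[[nm]][i, ]
      s <- b$fwhm / (2 * sqrt(2 * log(2)))
      out[nm, ] <- out[nm, ] +
        b$amplitude * exp(-(wavelengths - b$center)^2 / (2 * s^2))
      if (b$center - 2 * b$fwhm < min(wavelengths) - 1e-9 ||
          b$center + 2 * b$fwhm > max(wavelengths) + 1e-9)
        uncovered <- c(uncovered, nm)
    }
  }
  if (length(uncovered))
    warning("wavelength grid does not cover band center +/- 2 FWHM for: ",
            paste(unique(uncovered), collapse = ", "))
  out
}

#' Linear-logarithmic delay axis
#'
#' Delay grid that is linearly spaced (step `lin_step`) from `t_min` up to
#' the switch time and logarithmically spaced beyond it, as commonly used
#' to cover femtosecond-to-microsecond dynamics in a single scan. The
#' defaults reproduce a 169-point axis from -1 ps to 125 us with a 50 fs
#' minimum step and a lin-log switch at 1 ps.
#'
#' @param t_min first delay (ps), may be negative.
#' @param t_switch linear-to-log switch time (ps), `> 0`.
#' @param t_max last delay (ps).
#' @param n_points total number of points.
#' @param lin_step linear spacing below `t_switch` (ps).
#' @return strictly increasing numeric vector of length `n_points`.
#' @export
linlog_time_axis <- function(t_min = -1, t_switch = 1, t_max = 1.25e8,
                             n_points = 169, lin_step = 0.05) {
  stopifnot(t_min < t_max, t_switch > 0, lin_step > 0, n_points >= 2)
  if (t_switch >= t_max)
    return(seq(t_min, t_max, length.out = n_points))
  lin <- seq(t_min, t_switch, by = lin_step)
  if (abs(lin[length(lin)] - t_switch) > 1e-12 * max(1, t_switch))
    lin <- c(lin, t_switch)
  n_log <- n_points - length(lin)
  if (n_log < 1)
    stop("n_points too small for the linear section (needs > ", length(lin), ")")
  lg <- exp(seq(log(t_switch), log(t_max), length.out = n_log + 1))[-1]
  out <- c(lin, lg)
  stopifnot(all(diff(out) > 0), length(out) == n_points)
  out
}

#' Simulate a difference-absorption dataset from a kinetic model
#'
#' Forward model: `delta_A = concentrations %*% spectra` plus additive
#' Gaussian noise scaled to the peak absolute model signal. Mask windows
#' (e.g. the 465-495 nm pump-scatter region) are zero-weighted; the
#' generating truth (scheme, spectra, concentrations, noise-free matrix) is
#' attached as attribute `"truth"` for test harnesses.
#'
#' @param scheme a [kinetic_scheme()]; its dump events are applied when
#'   `with_dump = TRUE`.
#' @param spectra species x wavelength matrix (rows named by the observed
#'   compartments), or a [spectrum_model()].
#' @param irf an [irf_model()] or `NULL`.
#' @param times,wavelengths axes (ps, nm).
#' @param noise_sigma additive Gaussian noise SD as a fraction of the peak
#'   absolute signal (default 0.01).
#' @param seed integer seed for the noise.
#' @param mask_windows list of `c(lo, hi)` nm windows to zero-weight
#'   (default the 465-495 nm scatter window; use `list()` for none).
#' @param with_dump apply the scheme's dump events.
#' @param meta metadata list stored on the dataset.
#' @return a [ta_dataset()] with attribute `"truth"`.
#' @export
simulate_dataset <- function(scheme, spectra, irf, times, wavelengths,
                             noise_sigma = 0.01, seed = 1,
                             mask_windows = list(c(465, 495)),
                             with_dump = FALSE, meta = list()) {
  conc <- if (with_dump && length(scheme$dumps))
    apply_dump(scheme, irf, times) else concentration_profiles(scheme, irf, times)
  obs <- observed_compartments(scheme)
  if (inherits(spectra, "spectrum_model"))
    spectra <- eval_spectra(spectra, wavelengths, species = obs)
  if (is.null(rownames(spectra)))
    stop("spectra must have species rownames")
  missing <- setdiff(obs, rownames(spectra))
  if (length(missing))
    stop("no spectrum for observed compartment(s): ",
         paste(missing, collapse = ", "))
  C <- conc$values[, obs, drop = FALSE]
  S <- spectra[obs, , drop = FALSE]
  model <- C %*% S
  peak <- max(abs(model))
  noisy <- withr::with_seed(seed, {
    model + matrix(stats::rnorm(length(model), sd = noise_sigma * peak),
                   nrow(model), ncol(model))
  })
  w <- matrix(1, nrow(model), ncol(model))
  for (win in mask_windows)
    w[, wavelengths >= win[1] & wavelengths <= win[2]] <- 0
  ds <- ta_dataset(times, wavelengths, noisy, weights = w, meta = meta)
  attr(ds, "truth") <- list(scheme = scheme, irf = irf, spectra = S,
                            concentrations = conc, model = model,
                            noise_sigma = noise_sigma, seed = seed)
  ds
}

## compartments carrying a difference spectrum: everything except the
## recovered ground state
observed_compartments <- function(scheme) {
  setdiff(scheme$compartments, scheme$ground)
}
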