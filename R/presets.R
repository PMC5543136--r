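#' Channelrhodopsin-chimera (C1C2-like) synthetic presets
#'
#' Bundles the kinetic schemes, species band spectra, IRF and sequential
#' lifetime sets used by the synthetic-data generator to emulate
#' femtosecond-to-second datasets of the C1C2 channelrhodopsin chimera:
#'
#' * the primary-photochemistry target scheme — three excited states
#'   (ES1 branching at 2.2 ps^-1, 40/30/30 to ES2 / photoproduct K1 /
#'   ground state; ES2 at 0.12 + 0.38 ps^-1 to ES3/GS; ES3 at 0.09 ps^-1),
#'   a dump-populated ground-state intermediate (GSI, 1.0 ps^-1), terminal
#'   photoproduct yield 30%;
#' * sequential lifetime ladders for global analysis: 0.45, 2.0, 11, 630 ps,
#'   490 ns and a non-decaying component at pH 8; 0.45, 2.0, 11, 650 ps,
#'   200 ns, 26 us and a non-decaying component at pH 10;
#' * a microsecond-to-second photocycle chain for flash photolysis
#'   (20 us, 15 ms, 100 ms stages; the K/L/M equilibrium is represented as
#'   one equilibrated compartment with a mixture spectrum);
#' * Gaussian band spectra: excited-state absorption blue-shifting
#'   541 -> 535 -> 528 nm across ES1/ES2/ES3, photoproduct absorption at
#'   522 nm (K1) red-shifting to 530 nm (K2), L at 440 nm, M near 390 nm,
#'   O at 530 nm, ground-state bleach near 460 nm, stimulated emission
#'   beyond 630 nm, and a red-shifted GSI spectrum. Band widths and
#'   amplitudes are invented calibration constants (see the package
#'   vignette); band centers follow the observed spectral evolution.
#'
#' @param ph 8 or 10.
#' @return a list of class `c1c2_preset` with elements `scheme` (target
#'   scheme), `irf` (150 fs FWHM), `pdp_irf` (240 fs FWHM),
#'   `sequential_lifetimes` (ps, last entry `Inf`), `flash_lifetimes` (ps),
#'   `photocycle_scheme`, `species` (a [spectrum_model()]), `wavelengths`
#'   (default 380-680 nm grid), and mixing matrices `eads_mix`, `flash_mix`
#'   mapping species spectra onto sequential-component spectra.
#' @export
c1c2_presets <- function(ph = 8) {
  if (!ph %in% c(8, 10)) stop("preset available for pH 8 and pH 10 only")
  scheme <- kinetic_scheme(
    c("ES1", "ES2", "ES3", "K1", "GSI", "GS"),
    rates = data.frame(
      from = c("ES1", "ES1", "ES1", "ES2", "ES2", "ES3", "GSI"),
      to   = c("ES2", "K1", "GS", "ES3", "GS", "GS", "GS"),
      rate = c(2.2 * 0.40, 2.2 * 0.30, 2.2 * 0.30, 0.12, 0.38, 0.09, 1.0)),
    input = c(ES1 = 1))

  species <- spectrum_model(list(
    ES1 = data.frame(center = c(460, 541, 680), fwhm = c(45, 48, 70),
                     amplitude = c(-1, 1.10, -0.55)),
    ES2 = data.frame(center = c(460, 535, 670), fwhm = c(45, 44, 65),
                     amplitude = c(-1, 1.00, -0.50)),
    ES3 = data.frame(center = c(460, 528, 660), fwhm = c(45, 42, 60),
                     amplitude = c(-1, 0.90, -0.45)),
    K1  = data.frame(center = c(460, 522), fwhm = c(45, 75),
                     amplitude = c(-1, 0.85)),
    GSI = data.frame(center = c(480, 610), fwhm = c(45, 100),
                     amplitude = c(-0.80, 0.35)),
    K2  = data.frame(center = c(460, 530), fwhm = c(45, 75),
                     amplitude = c(-1, 0.85)),
    L   = data.frame(center = c(460, 440), fwhm = c(45, 38),
                     amplitude = c(-1, 0.70)),
    M   = data.frame(center = c(460, 390), fwhm = c(45, 35),
                     amplitude = c(-1, 0.60)),
    O   = data.frame(center = c(460, 530), fwhm = c(45, 46),
                     amplitude = c(-1, 0.75))))

  sp_names <- names(species$species)
  mix_row <- function(...) {
    v <- stats::setNames(numeric(length(sp_names)), sp_names)
    coef <- c(...)
    v[names(coef)] <- coef
    v
  }
  qy <- 0.30   # photoproduct yield implied by the target scheme
  eads_mix <- rbind(
    mix_row(ES1 = 1),
    mix_row(ES2 = 0.40, K1 = qy),
    mix_row(ES3 = 0.40 * 0.24, K1 = qy),
    mix_row(K1 = qy),
    mix_row(K2 = qy),
    mix_row(K2 = 0.60 * qy, L = 0.40 * qy))
  if (ph == 10) {
    eads_mix <- rbind(eads_mix,
                      mix_row(K2 = 0.40 * qy, L = 0.35 * qy, M = 0.25 * qy))
    lifetimes <- c(0.45, 2.0, 11, 650, 200e3, 26e6, Inf)
  } else {
    lifetimes <- c(0.45, 2.0, 11, 630, 490e3, Inf)
  }
  rownames(eads_mix) <- paste0("EADS", seq_len(nrow(eads_mix)))

  flash_lifetimes <- c(20e6, 15e9, 100e9)   # 20 us, 15 ms, 100 ms in ps
  flash_mix <- rbind(
    mix_row(K2 = 0.55 * qy, L = 0.45 * qy),
    mix_row(K2 = 0.40 * qy, L = 0.35 * qy, M = 0.25 * qy),
    mix_row(O = qy))
  rownames(flash_mix) <- c("KL", "KLM", "O")
  photocycle_scheme <- kinetic_scheme(
    c("KL", "KLM", "O", "GS"),
    rates = data.frame(from = c("KL", "KLM", "O"),
                       to = c("KLM", "O", "GS"),
                       rate = 1 / flash_lifetimes),
    input = c(KL = 1))

  structure(list(
    ph = ph,
    scheme = scheme,
    irf = irf_model(center = 0, fwhm = 0.150),
    pdp_irf = irf_model(center = 0, fwhm = 0.240),
    sequential_lifetimes = lifetimes,
    flash_lifetimes = flash_lifetimes,
    photocycle_scheme = photocycle_scheme,
    species = species,
    wavelengths = seq(380, 680, length.out = 120),
    eads_mix = eads_mix,
    flash_mix = flash_mix), class = "c1c2_preset")
}

#' Sequential chain scheme from a lifetime ladder
#'
#' Builds the unbranched compartment chain underlying a sequential
#' (EADS-style) analysis: component l evolves into component l+1 with rate
#' `1/lifetimes[l]`; a final `Inf` lifetime makes the last compartment a
#' non-decaying terminal.
#'
#' @param lifetimes ascending lifetimes in ps; last may be `Inf`.
#' @param labels optional compartment labels.
#' @return a [kinetic_scheme()] with no ground compartment (every component
#'   is observed).
#' @export
sequential_scheme <- function(lifetimes, labels = NULL) {
  n <- length(lifetimes)
  if (is.null(labels)) labels <- paste0("comp", seq_len(n))
  if (any(!is.finite(lifetimes[-n])))
    stop("only the last lifetime may be infinite")
  rates <- NULL
  if (n > 1 || is.finite(lifetimes[n])) {
    from <- labels[is.finite(lifetimes)]
    idx <- which(is.finite(lifetimes))
    to <- ifelse(idx < n, labels[pmin(idx + 1, n)], NA)
    if (is.finite(lifetimes[n])) {
      labels <- c(labels, "sink")
      to[length(to)] <- "sink"
    }
    rates <- data.frame(from = from, to = to,
                        rate = 1 / lifetimes[is.finite(lifetimes)])
  }
  kinetic_scheme(labels, rates = rates,
                 input = stats::setNames(1, labels[1]),
                 ground = if ("sink" %in% labels) "sink" else NULL)
}

#' Component spectra of a preset on a wavelength grid
#'
#' Evaluates the preset's species bands and mixes them into the spectra of
#' the sequential components (`which = "eads"`) or of the flash-photolysis
#' stages (`which = "flash"`).
#'
#' @param preset a [c1c2_presets()] object.
#' @param wavelengths nm grid (default the preset grid).
#' @param which `"eads"` or `"flash"`.
#' @return matrix, component x wavelength.
#' @export
preset_component_spectra <- function(preset, wavelengths = preset$wavelengths,
                                     which = c("eads", "flash")) {
  which <- match.arg(which)
  mix <- if (which == "eads") preset$eads_mix else preset$flash_mix
  sp <- suppressWarnings(eval_spectra(preset$species, wavelengths))
  out <- mix %*% sp[colnames(mix), , drop = FALSE]
  out
}
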