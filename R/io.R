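## unit handling: everything is picoseconds internally
TIME_UNITS <- c(fs = 1e-3, ps = 1, ns = 1e3, us = 1e6, ms = 1e9, s = 1e12)

time_unit_factor <- function(unit) {
  unit <- sub("µs", "us", unit)
  if (!unit %in% names(TIME_UNITS))
    stop("unknown time unit '", unit, "' (use fs/ps/ns/us/ms/s)")
  TIME_UNITS[[unit]]
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.nan(x)] <- "NaN"
  out
}

#' Read and write time-explicit difference-absorption matrices
#'
#' The on-disk layout is the de-facto standard for global-analysis input:
#' optional `#`-prefixed header lines (`# key: value`), then a header row
#' whose first field is the time-axis label and whose remaining fields are
#' the wavelengths (nm), then one row per delay (first column the delay,
#' remaining columns the signal). Masked cells are stored as `NaN` and come
#' back as zero-weight entries. The declared `time_unit` (fs/ps/ns/us/ms/s)
#' is converted to picoseconds on read; values are written with full
#' precision so that read -> write -> read round-trips are bit-identical
#' for finite values.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return `read_ta_matrix` returns a [ta_dataset()]; `write_ta_matrix`
#'   returns `path` invisibly.
#' @export
read_ta_matrix <- function(path, sep = "\t") {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[h]))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("no data rows in ", path)
  split_row <- function(s) strsplit(s, sep, fixed = TRUE)[[1]]
  head_fields <- split_row(body[1])
  wavelengths <- as.numeric(head_fields[-1])
  if (anyNA(wavelengths))
    stop("unparseable wavelength header in ", path)
  n <- length(wavelengths)
  rows <- lapply(seq_along(body[-1]), function(i) {
    f <- split_row(body[-1][i])
    if (length(f) != n + 1)
      stop("ragged row at line ", which(lines == body[-1][i])[1], " of ",
           path, " (", length(f), " fields, expected ", n + 1, ")")
    suppressWarnings(as.numeric(f))
  })
  M <- do.call(rbind, rows)
  times <- M[, 1]
  if (anyNA(times)) stop("unparseable delay value in ", path)
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1] + 1
    stop("non-monotone delay axis at line ",
         bad + length(hdr) + 1, " of ", path)
  }
  if (any(diff(wavelengths) <= 0))
    stop("non-monotone wavelength axis in header of ", path)
  unit <- meta[["time_unit"]] %||% "ps"
  times <- times * time_unit_factor(unit)
  meta[["time_unit"]] <- NULL
  meta[["wavelength_unit"]] <- NULL
  ta_dataset(times, wavelengths, M[, -1, drop = FALSE], meta = meta)
}

#' @rdname read_ta_matrix
#' @param dataset a [ta_dataset()]; zero-weight cells are written as `NaN`.
#' @param time_unit unit for the delay column on disk.
#' @export
write_ta_matrix <- function(dataset, path, sep = "\t", time_unit = "ps") {
  stopifnot(inherits(dataset, "ta_dataset"))
  fac <- time_unit_factor(time_unit)
  hdr <- c(sprintf("# time_unit: %s", time_unit),
           sprintf("# wavelength_unit: nm"))
  for (nm in names(dataset$meta))
    hdr <- c(hdr, sprintf("# %s: %s", nm, format(dataset$meta[[nm]])))
  M <- dataset$delta_A
  M[dataset$weights == 0] <- NaN
  head_row <- paste(c("time", fmt_num(dataset$wavelengths)), collapse = sep)
  body <- vapply(seq_along(dataset$times), function(i)
    paste(c(fmt_num(dataset$times[i] / fac), fmt_num(M[i, ])), collapse = sep),
    "")
  writeLines(c(hdr, head_row, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write kinetic-scheme configuration files
#'
#' Plain-text key-value format describing a [kinetic_scheme()]; round-trips
#' losslessly. Directives (one per line, `#` comments allowed):
#' \preformatted{
#' compartments: ES1 ES2 ES3 K1 GSI GS
#' input: ES1 1
#' rate: ES1 -> ES2 0.88 /ps
#' terminal: K1 GS
#' ground: GS
#' dump: 0.3 ps
#' transfer: ES1 -> GSI 0.1
#' }
#' A `dump:` line opens a dump event at the given time; subsequent
#' `transfer:` lines belong to it. Rate units are the reciprocal of any
#' supported time unit; dump times accept fs/ps/ns/us/ms/s.
#'
#' @param path file path.
#' @return `read_scheme` returns a [kinetic_scheme()].
#' @export
read_scheme <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  comps <- character(); terminal <- character(); ground <- NULL
  input <- c(); rates <- NULL; dumps <- list(); cur_dump <- NULL
  flush_dump <- function() {
    if (!is.null(cur_dump) && !is.null(cur_dump$transfers))
      dumps[[length(dumps) + 1]] <<- dump_event(cur_dump$time,
                                                cur_dump$transfers)
    cur_dump <<- NULL
  }
  for (i in seq_along(lines)) {
    kv <- regmatches(lines[i], regexec("^([a-z_]+)\\s*:\\s*(.*)$", lines[i]))[[1]]
    if (length(kv) != 3)
      stop("unparseable directive at line ", i, ": ", lines[i])
    key <- kv[2]; val <- trimws(kv[3])
    toks <- strsplit(val, "\\s+")[[1]]
    if (key == "compartments") comps <- c(comps, toks)
    else if (key == "terminal") terminal <- c(terminal, toks)
    else if (key == "ground") ground <- toks[1]
    else if (key == "input") {
      input <- c(input, stats::setNames(as.numeric(toks[2]), toks[1]))
    } else if (key == "rate") {
      m <- regmatches(val, regexec(
        "^(\\S+)\\s*->\\s*(\\S+)\\s+([0-9.eE+-]+)\\s*(/\\w+)?$", val))[[1]]
      if (length(m) < 4) stop("unparseable rate at line ", i, ": ", val)
      fac <- if (nzchar(m[5])) time_unit_factor(sub("^/", "", m[5])) else 1
      rates <- rbind(rates, data.frame(from = m[2], to = m[3],
                                       rate = as.numeric(m[4]) / fac))
    } else if (key == "dump") {
      flush_dump()
      m <- regmatches(val, regexec("^([0-9.eE+-]+)\\s*(\\w+)?$", val))[[1]]
      fac <- if (nzchar(m[3])) time_unit_factor(m[3]) else 1
      cur_dump <- list(time = as.numeric(m[2]) * fac, transfers = NULL)
    } else if (key == "transfer") {
      if (is.null(cur_dump))
        stop("transfer outside a dump block at line ", i)
      m <- regmatches(val, regexec(
        "^(\\S+)\\s*->\\s*(\\S+)\\s+([0-9.eE+-]+)$", val))[[1]]
      if (length(m) < 4) stop("unparseable transfer at line ", i, ": ", val)
      cur_dump$transfers <- rbind(cur_dump$transfers,
                                  data.frame(from = m[2], to = m[3],
                                             fraction = as.numeric(m[4])))
    } else stop("unknown directive '", key, "' at line ", i)
  }
  flush_dump()
  kinetic_scheme(comps, rates = rates,
                 input = if (length(input)) input else NULL,
                 terminal = terminal, ground = ground, dumps = dumps)
}

#' @rdname read_scheme
#' @param scheme a [kinetic_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  out <- c(paste("compartments:", paste(scheme$compartments, collapse = " ")))
  for (nm in names(scheme$input)[scheme$input > 0])
    out <- c(out, sprintf("input: %s %s", nm, fmt_num(scheme$input[[nm]])))
  for (i in seq_len(nrow(scheme$rates)))
    out <- c(out, sprintf("rate: %s -> %s %s /ps", scheme$rates$from[i],
                          scheme$rates$to[i], fmt_num(scheme$rates$rate[i])))
  out <- c(out, paste("terminal:", paste(scheme$terminal, collapse = " ")))
  if (!is.null(scheme$ground)) out <- c(out, paste("ground:", scheme$ground))
  for (d in scheme$dumps) {
    out <- c(out, sprintf("dump: %s ps", fmt_num(d$time)))
    for (i in seq_len(nrow(d$transfers)))
      out <- c(out, sprintf("transfer: %s -> %s %s", d$transfers$from[i],
                            d$transfers$to[i], fmt_num(d$transfers$fraction[i])))
  }
  writeLines(out, path)
  invisible(path)
}

#' Export a fit as delimited text
#'
#' Writes the fitted spectra (one file), the model concentration profiles
#' (one file) and a structured plain-text report (parameters with standard
#' errors, weighted sum of squares, lifetimes, terminal yields) under a
#' common file stem.
#'
#' @param fit a `ta_fit`.
#' @param stem output path stem; files `<stem>_spectra.tsv`,
#'   `<stem>_concentrations.tsv`, `<stem>_report.txt` are created.
#' @param sep field delimiter.
#' @return invisibly, the vector of files written.
#' @export
write_fit_report <- function(fit, stem, sep = "\t") {
  stopifnot(inherits(fit, "ta_fit"))
  sp_file <- paste0(stem, "_spectra.tsv")
  sp <- fit$spectra
  wl <- fit$dataset$wavelengths
  writeLines(c(paste(c("wavelength_nm", rownames(sp)), collapse = sep),
               vapply(seq_along(wl), function(j)
                 paste(fmt_num(c(wl[j], sp[, j])), collapse = sep), "")),
             sp_file)
  cc_file <- paste0(stem, "_concentrations.tsv")
  C <- if (is.list(fit$concentrations) && !is.matrix(fit$concentrations))
    fit$concentrations[[1]] else fit$concentrations
  tt <- fit$dataset$times
  writeLines(c(paste(c("time_ps", colnames(C)), collapse = sep),
               vapply(seq_along(tt), function(i)
                 paste(fmt_num(c(tt[i], C[i, ])), collapse = sep), "")),
             cc_file)
  rp_file <- paste0(stem, "_report.txt")
  rpt <- c(sprintf("fit kind: %s", fit$kind),
           sprintf("weighted ssq: %.10g", fit$ssq),
           sprintf("converged: %s", fit$converged),
           "",
           "parameters (value +/- se):")
  se <- fit$std_errors
  rpt <- c(rpt, sprintf("  %-22s %.8g +/- %.3g", se$parameter, se$value, se$se))
  rpt <- c(rpt, "", sprintf("lifetimes (ps): %s",
                            paste(format(fit$lifetimes, digits = 6),
                                  collapse = ", ")))
  if (!is.null(fit$yields))
    rpt <- c(rpt, sprintf("terminal yields: %s",
                          paste(sprintf("%s=%.4f", names(fit$yields),
                                        fit$yields), collapse = ", ")))
  writeLines(rpt, rp_file)
  invisible(c(sp_file, cc_file, rp_file))
}
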