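#' Spectral region
#'
#' A chemical-shift window with its proton-group assignment, used for
#' region integration of spectra.
#'
#' @param ppm_lo,ppm_hi Chemical-shift bounds in ppm, `ppm_lo < ppm_hi`.
#' @param assignment Proton group, e.g. `"(CH2)n"`.
#' @param attribution Fatty component the signal is attributed to.
#' @return An object of class `spectral_region`.
#' @export
spectral_region <- function(ppm_lo, ppm_hi, assignment = "",
                            attribution = "") {
  stopifnot(is.numeric(ppm_lo), is.numeric(ppm_hi))
  if (!is.finite(ppm_lo) || !is.finite(ppm_hi) || ppm_lo >= ppm_hi)
    stop("need ppm_lo < ppm_hi", call. = FALSE)
  structure(list(ppm_lo = ppm_lo, ppm_hi = ppm_hi,
                 assignment = assignment, attribution = attribution),
            class = "spectral_region")
}

#' Catalog of EVOO 1H spectral regions
#'
#' The ten resolved proton signals of a high-resolution (400 MHz) EVOO
#' spectrum with their chemical-shift windows, proton-group assignments
#' and fatty-component attributions, shipped as packaged data. The
#' windows are non-overlapping at high field; at 100 MHz several of them
#' merge into three broad regions.
#'
#' @return A data frame with columns `ppm_lo`, `ppm_hi`, `assignment`,
#'   `attribution`.
#' @export
spectral_regions <- function() {
  path <- system.file("extdata", "spectral_regions.csv",
                      package = "olivenmr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Integrate a spectrum over a chemical-shift region
#'
#' Trapezoidal integral of intensity over `[ppm_lo, ppm_hi]`, with linear
#' interpolation at the region boundaries. Linear in the intensity scale.
#'
#' @param spectrum Data frame with columns `ppm` (strictly monotone) and
#'   `intensity`.
#' @param region A [spectral_region()], or any list/row with `ppm_lo` and
#'   `ppm_hi`.
#' @return The integrated area (intensity units x ppm).
#' @export
integrate_region <- function(spectrum, region) {
  stopifnot(is.data.frame(spectrum),
            all(c("ppm", "intensity") %in% names(spectrum)))
  lo <- region$ppm_lo; hi <- region$ppm_hi
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  x <- spectrum$ppm; y <- spectrum$intensity
  if (any(diff(x) < 0)) { ord <- order(x); x <- x[ord]; y <- y[ord] }
  if (lo < min(x) || hi > max(x))
    stop(sprintf("region [%g, %g] ppm outside spectrum span [%g, %g]",
                 lo, hi, min(x), max(x)), call. = FALSE)
  ylo <- stats::approx(x, y, xout = lo)$y
  yhi <- stats::approx(x, y, xout = hi)$y
  keep <- x > lo & x < hi
  xs <- c(lo, x[keep], hi); ys <- c(ylo, y[keep], yhi)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

seq_kinds <- c("inversion_recovery", "cpmg", "spin_echo")

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a decay curve to a plain-text file
#'
#' Serialises a [decay_curve()] in one of three documented dialects:
#' `"csv"` (default) and `"whitespace"` write `# key = value` metadata
#' header lines followed by a delimited table with columns `delay_s`,
#' `signal` and, when present, `sigma`; `"json"` writes the same schema
#' as a JSON object. Numbers round-trip at full double precision.
#'
#' @param curve A [decay_curve()].
#' @param path Output file path.
#' @param dialect `"csv"`, `"json"` or `"whitespace"`.
#' @return `path`, invisibly.
#' @seealso [read_decay()]
#' @export
write_decay <- function(curve, path, dialect = c("csv", "json",
                                                 "whitespace")) {
  stopifnot(inherits(curve, "decay_curve"))
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    obj <- list(sample_id = curve$sample_id,
                sequence = curve$sequence_kind,
                larmor_mhz = curve$larmor_mhz,
                temperature_c = curve$temperature_c,
                delay_s = curve$delays, signal = curve$magnetization)
    if (!is.null(curve$sigma)) obj$sigma <- curve$sigma
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         na = "null")
    return(invisible(path))
  }
  sep <- if (dialect == "csv") "," else " "
  hdr <- c(sprintf("# sample_id = %s", curve$sample_id),
           sprintf("# sequence = %s", curve$sequence_kind),
           sprintf("# larmor_mhz = %s", fmt_num(curve$larmor_mhz)),
           sprintf("# temperature_c = %s",
                   if (is.na(curve$temperature_c)) "NA"
                   else fmt_num(curve$temperature_c)))
  cols <- c("delay_s", "signal", if (!is.null(curve$sigma)) "sigma")
  mat <- cbind(fmt_num(curve$delays), fmt_num(curve$magnetization))
  if (!is.null(curve$sigma)) mat <- cbind(mat, fmt_num(curve$sigma))
  lines <- c(hdr, paste(cols, collapse = sep),
             apply(mat, 1, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

parse_error <- function(path, line, msg)
  stop(sprintf("%s:%s: %s", path, line, msg), call. = FALSE)

#' Read a decay curve from a plain-text file
#'
#' Inverse of [write_decay()]; `write_decay()` then `read_decay()` is the
#' identity on valid curves. Malformed files (missing columns,
#' non-increasing delays, unknown sequence kind) produce a parse error
#' naming the offending line, never a crash or silent misread.
#'
#' @param path Input file path.
#' @param dialect `"csv"`, `"json"` or `"whitespace"`.
#' @return A [decay_curve()].
#' @export
read_decay <- function(path, dialect = c("csv", "json", "whitespace")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      parse_error(path, 1, conditionMessage(e)))
    for (k in c("sequence", "larmor_mhz", "delay_s", "signal"))
      if (is.null(obj[[k]]))
        parse_error(path, 1, sprintf("missing field `%s`", k))
    if (!obj$sequence %in% seq_kinds)
      parse_error(path, 1, sprintf("unknown sequence kind `%s`", obj$sequence))
    if (any(diff(obj$delay_s) <= 0))
      parse_error(path, 1, "delays not strictly increasing")
    tc <- obj$temperature_c
    return(decay_curve(obj$delay_s, obj$signal, sigma = obj$sigma,
                       sequence_kind = obj$sequence,
                       larmor_mhz = obj$larmor_mhz,
                       sample_id = obj$sample_id %||% "",
                       temperature_c = if (is.null(tc)) NA_real_ else tc))
  }
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*#", lines[i])) {
    m <- regmatches(lines[i],
                    regexec("^\\s*#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
    i <- i + 1L
  }
  if (i > length(lines)) parse_error(path, i, "no data table found")
  sep <- if (dialect == "csv") "," else "\\s+"
  cols <- strsplit(trimws(lines[i]), sep)[[1]]
  if (!all(c("delay_s", "signal") %in% cols))
    parse_error(path, i, "header must name columns `delay_s` and `signal`")
  header_line <- i
  body <- lines[-seq_len(i)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) parse_error(path, header_line + 1, "empty data table")
  vals <- lapply(seq_along(body), function(j) {
    parts <- strsplit(trimws(body[j]), sep)[[1]]
    if (length(parts) != length(cols))
      parse_error(path, header_line + j,
                  sprintf("expected %d fields, found %d", length(cols),
                          length(parts)))
    v <- suppressWarnings(as.numeric(parts))
    if (any(is.na(v)))
      parse_error(path, header_line + j, "non-numeric value in data row")
    v
  })
  tab <- do.call(rbind, vals)
  colnames(tab) <- cols
  d <- tab[, "delay_s"]
  bad <- which(diff(d) <= 0)
  if (length(bad))
    parse_error(path, header_line + bad[1] + 1L,
                "delays not strictly increasing")
  if (is.null(meta$sequence))
    parse_error(path, 1, "missing `# sequence = ...` metadata")
  if (!meta$sequence %in% seq_kinds)
    parse_error(path, 1, sprintf("unknown sequence kind `%s`", meta$sequence))
  if (is.null(meta$larmor_mhz))
    parse_error(path, 1, "missing `# larmor_mhz = ...` metadata")
  tc <- meta$temperature_c
  decay_curve(d, tab[, "signal"],
              sigma = if ("sigma" %in% cols) tab[, "sigma"] else NULL,
              sequence_kind = meta$sequence,
              larmor_mhz = as.numeric(meta$larmor_mhz),
              sample_id = meta$sample_id %||% "",
              temperature_c = if (is.null(tc) || tc == "NA") NA_real_
                              else as.numeric(tc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an NMRD dispersion profile
#'
#' CSV interchange for dispersion profiles: `# key = value` metadata
#' header, then columns `freq_mhz`, `r1_s` and, when present, `r1_err_s`.
#'
#' @param profile A [dispersion_profile()].
#' @param path File path.
#' @return `write_dispersion()` returns `path` invisibly;
#'   `read_dispersion()` returns a [dispersion_profile()].
#' @export
write_dispersion <- function(profile, path) {
  stopifnot(inherits(profile, "dispersion_profile"))
  hdr <- c(sprintf("# sample_id = %s", profile$sample_id),
           sprintf("# component = %s", profile$component_label))
  cols <- c("freq_mhz", "r1_s", if (!is.null(profile$r1_err)) "r1_err_s")
  mat <- cbind(fmt_num(profile$freqs_mhz), fmt_num(profile$r1))
  if (!is.null(profile$r1_err)) mat <- cbind(mat, fmt_num(profile$r1_err))
  writeLines(c(hdr, paste(cols, collapse = ","),
               apply(mat, 1, paste, collapse = ",")), path)
  invisible(path)
}

#' @rdname write_dispersion
#' @export
read_dispersion <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list(); i <- 1L
  while (i <= length(lines) && grepl("^\\s*#", lines[i])) {
    m <- regmatches(lines[i],
                    regexec("^\\s*#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
    i <- i + 1L
  }
  if (i > length(lines)) parse_error(path, i, "no data table found")
  cols <- strsplit(trimws(lines[i]), ",")[[1]]
  if (!all(c("freq_mhz", "r1_s") %in% cols))
    parse_error(path, i, "header must name columns `freq_mhz` and `r1_s`")
  body <- lines[-seq_len(i)]; body <- body[nzchar(trimws(body))]
  tab <- do.call(rbind, lapply(seq_along(body), function(j) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[j]), ",")[[1]]))
    if (length(v) != length(cols) || any(is.na(v)))
      parse_error(path, i + j, "malformed data row")
    v
  }))
  colnames(tab) <- cols
  dispersion_profile(tab[, "freq_mhz"], tab[, "r1_s"],
                     r1_err = if ("r1_err_s" %in% cols) tab[, "r1_err_s"]
                              else NULL,
                     component_label = meta$component %||% "a",
                     sample_id = meta$sample_id %||% "")
}
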