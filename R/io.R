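# Sniff the delimiter of a delimited text file (comma, tab or semicolon).
sniff_delim <- function(path) {
  first <- readLines(path, n = 5L, warn = FALSE)
  first <- first[nzchar(first)]
  if (length(first) == 0) stop("format error: empty file: ", path, call. = FALSE)
  counts <- vapply(c(",", "\t", ";"), function(d)
    sum(vapply(strsplit(first, d, fixed = TRUE), length, 1L) - 1L), 0L)
  if (all(counts == 0)) stop("format error: no delimiter found in ", path,
                             call. = FALSE)
  names(counts)[which.max(counts)]
}

read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, dec = ".",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("format error: no data rows in ", path, call. = FALSE)
  df
}

# Resolve one column by name or 1-based index; error if absent/non-numeric.
pick_column <- function(df, key, what, required = TRUE) {
  if (is.null(key)) {
    if (required) stop("format error: no column mapping for ", what,
                       call. = FALSE)
    return(NULL)
  }
  col <- if (is.numeric(key)) {
    if (key < 1 || key > ncol(df)) NULL else df[[as.integer(key)]]
  } else if (key %in% names(df)) df[[key]] else NULL
  if (is.null(col)) {
    if (!required) return(NULL)
    stop("format error: column '", key, "' (", what, ") not found",
         call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(col))
  if (anyNA(x)) stop("format error: non-numeric values in column '", key,
                     "' (", what, ")", call. = FALSE)
  x
}

unit_factor <- function(unit, kind) {
  # factors into canonical units: s, mV, V, uA, Hz, Ohm
  tab <- switch(kind,
    time      = c(s = 1, ms = 1e-3, min = 60, h = 3600),
    potential = c(mV = 1, V = 1000, uV = 1e-3),
    volt      = c(V = 1, mV = 1e-3),
    current   = c(uA = 1, mA = 1e3, nA = 1e-3, A = 1e6),
    freq      = c(Hz = 1, kHz = 1e3, mHz = 1e-3),
    ohm       = c(Ohm = 1, ohm = 1, kOhm = 1e3, MOhm = 1e6))
  if (!unit %in% names(tab))
    stop("unknown ", kind, " unit: '", unit, "'", call. = FALSE)
  unname(tab[unit])
}

#' Read a voltage trace from a delimited text file
#'
#' Reads a potential-versus-time recording from CSV/TSV (delimiter sniffed
#' among comma, tab and semicolon; decimal separator "."). Columns are
#' resolved by name or 1-based index through `column_map`, and units are
#' converted to the package's canonical seconds / millivolts.
#'
#' @param path Path to the file.
#' @param column_map Named list with entries `time` and `potential` (column
#'   name or index) and optional `time_unit` (`"s"`, `"ms"`, `"min"`, `"h"`)
#'   and `potential_unit` (`"mV"`, `"V"`, `"uV"`). Defaults to header names
#'   `time`/`potential` in s/mV.
#' @param label Label attached to the trace.
#'
#' @return A [voltage_trace()].
#' @export
read_trace <- function(path,
                       column_map = list(time = "time", potential = "potential"),
                       label = "") {
  df <- read_table_file(path)
  cm <- utils::modifyList(list(time = "time", potential = "potential",
                               time_unit = "s", potential_unit = "mV"),
                          column_map)
  t <- pick_column(df, cm$time, "time") * unit_factor(cm$time_unit, "time")
  v <- pick_column(df, cm$potential, "potential") *
    unit_factor(cm$potential_unit, "potential")
  voltage_trace(t = t, v = v, label = label)
}

#' Read a cyclic voltammogram from a delimited text file
#'
#' @inheritParams read_trace
#' @param column_map Named list with entries `potential`, `current`, optional
#'   `cycle`, plus optional `potential_unit` (`"V"`, `"mV"`) and
#'   `current_unit` (`"uA"`, `"mA"`, `"nA"`, `"A"`). If the cycle column is
#'   absent, cycles are left unassigned and can be inferred with
#'   [segment_cycles()].
#' @param scan_rate Scan rate in V/s attached to the voltammogram.
#'
#' @return A [voltammogram()].
#' @export
read_voltammogram <- function(path,
                              column_map = list(potential = "potential",
                                                current = "current",
                                                cycle = "cycle"),
                              scan_rate = 0.1) {
  df <- read_table_file(path)
  cm <- utils::modifyList(list(potential = "potential", current = "current",
                               cycle = "cycle", potential_unit = "V",
                               current_unit = "uA"),
                          column_map)
  e <- pick_column(df, cm$potential, "potential") *
    unit_factor(cm$potential_unit, "volt")
  i <- pick_column(df, cm$current, "current") *
    unit_factor(cm$current_unit, "current")
  cyc <- if (!is.null(cm$cycle) && (is.numeric(cm$cycle) || cm$cycle %in% names(df)))
    as.integer(pick_column(df, cm$cycle, "cycle")) else NULL
  voltammogram(e = e, i = i, cycle = cyc, scan_rate = scan_rate)
}

#' Read an impedance spectrum from a delimited text file
#'
#' Accepts either rectangular columns (real and imaginary impedance) or polar
#' columns (modulus and phase in degrees), which are normalised to rectangular
#' form `z_re + j z_im`.
#'
#' @inheritParams read_trace
#' @param column_map Named list. Rectangular form: entries `frequency`,
#'   `zreal`, `zimag`. Polar form: entries `frequency`, `zmod`, `zphase`
#'   (degrees). Optional `z_unit` (`"Ohm"`, `"kOhm"`, `"MOhm"`) and
#'   `frequency_unit`.
#'
#' @return An [impedance_spectrum()].
#' @export
read_spectrum <- function(path,
                          column_map = list(frequency = "frequency",
                                            zreal = "zreal", zimag = "zimag")) {
  df <- read_table_file(path)
  cm <- utils::modifyList(list(frequency = "frequency", zreal = "zreal",
                               zimag = "zimag", zmod = "zmod",
                               zphase = "zphase", z_unit = "Ohm",
                               frequency_unit = "Hz"),
                          column_map)
  f <- pick_column(df, cm$frequency, "frequency") *
    unit_factor(cm$frequency_unit, "freq")
  zf <- unit_factor(cm$z_unit, "ohm")
  zre <- pick_column(df, cm$zreal, "zreal", required = FALSE)
  zim <- pick_column(df, cm$zimag, "zimag", required = FALSE)
  if (is.null(zre) || is.null(zim)) {
    zmod <- pick_column(df, cm$zmod, "zmod", required = FALSE)
    zph <- pick_column(df, cm$zphase, "zphase (degrees)", required = FALSE)
    if (is.null(zmod) || is.null(zph))
      stop("format error: need (zreal, zimag) or (zmod, zphase) columns",
           call. = FALSE)
    zre <- zmod * cos(zph * pi / 180)
    zim <- zmod * sin(zph * pi / 180)
  }
  impedance_spectrum(f = f, z_re = zre * zf, z_im = zim * zf)
}

#' Write an analysis result table to CSV
#'
#' Writes a machine-readable CSV that round-trips numerically: reading the
#' file back with [read_report()] reproduces the values within floating-point
#' precision (15 significant digits are written). An empty data frame yields a
#' header-only file.
#'
#' @param results A data frame (e.g. a per-cycle feature table or a summary).
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_report <- function(results, path) {
  stopifnot(is.data.frame(results))
  # write.csv serialises doubles at 15 significant digits, which round-trips
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
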