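#' Voltage trace
#'
#' A uniformly or non-uniformly sampled potential-versus-time series, the
#' input type for spike detection, phase segmentation and the complexity
#' metrics. Canonical units are seconds and millivolts.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param v Numeric vector of potentials in millivolts, same length as `t`.
#' @param label Free-text label for the system recorded (e.g. `"P"`, `"PS"`,
#'   `"PSP"`).
#' @param sample_interval Sampling interval in seconds, or `NULL` for
#'   non-uniform sampling. If `NULL` and `t` is (numerically) uniform, the
#'   interval is inferred.
#'
#' @return An object of class `voltage_trace`: a list with elements `t`, `v`,
#'   `label` and `sample_interval`.
#' @export
#' @examples
#' tr <- voltage_trace(t = 0:9, v = sin(0:9), label = "demo")
#' tr$sample_interval
voltage_trace <- function(t, v, label = "", sample_interval = NULL) {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v))
    stop("`t` and `v` must have equal length", call. = FALSE)
  if (length(t) < 2)
    stop("a voltage trace needs at least 2 samples", call. = FALSE)
  if (anyNA(t) || anyNA(v) || any(!is.finite(t)) || any(!is.finite(v)))
    stop("`t` and `v` must be finite", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("`t` must be strictly increasing", call. = FALSE)
  if (is.null(sample_interval)) {
    dt <- diff(t)
    if (diff(range(dt)) <= 1e-9 * max(abs(dt))) sample_interval <- mean(dt)
  }
  structure(list(t = t, v = v, label = as.character(label)[1],
                 sample_interval = sample_interval),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %s: %d samples, %.6g-%.6g s, v in [%.4g, %.4g] mV\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$t), min(x$t), max(x$t), min(x$v), max(x$v)))
  invisible(x)
}

#' Cyclic voltammogram
#'
#' Ordered (potential, current) samples, optionally partitioned into cycles.
#' Canonical units are volts and microamperes.
#'
#' @param e Numeric vector of applied potentials in volts.
#' @param i Numeric vector of currents in microamperes.
#' @param cycle Optional integer vector of 1-based cycle indices per sample;
#'   `NULL` if cycles have not yet been assigned (see [segment_cycles()]).
#' @param scan_rate Potential scan rate in volts/second (> 0).
#'
#' @return An object of class `voltammogram`.
#' @export
voltammogram <- function(e, i, cycle = NULL, scan_rate) {
  e <- as.numeric(e)
  i <- as.numeric(i)
  if (length(e) != length(i))
    stop("`e` and `i` must have equal length", call. = FALSE)
  if (length(e) < 4) stop("voltammogram too short", call. = FALSE)
  if (anyNA(e) || anyNA(i)) stop("`e` and `i` must be finite", call. = FALSE)
  if (!is.numeric(scan_rate) || length(scan_rate) != 1 || scan_rate <= 0)
    stop("`scan_rate` must be a positive scalar (V/s)", call. = FALSE)
  if (!is.null(cycle)) {
    cycle <- as.integer(cycle)
    if (length(cycle) != length(e))
      stop("`cycle` must match the sample length", call. = FALSE)
    u <- sort(unique(cycle))
    if (!identical(u, seq_along(u)))
      stop("cycle indices must be contiguous and start at 1", call. = FALSE)
  }
  structure(list(e = e, i = i, cycle = cycle, scan_rate = scan_rate),
            class = "voltammogram")
}

#' @export
print.voltammogram <- function(x, ...) {
  nc <- if (is.null(x$cycle)) "unsegmented" else
    sprintf("%d cycle(s)", max(x$cycle))
  cat(sprintf("<voltammogram> %d samples, %s, E in [%.3g, %.3g] V @ %g V/s\n",
              length(x$e), nc, min(x$e), max(x$e), x$scan_rate))
  invisible(x)
}

#' Impedance spectrum
#'
#' Per-frequency complex impedance. Sign convention: capacitive points have
#' `z_im < 0`; the Nyquist ordinate conventionally plotted is `-z_im`.
#'
#' @param f Numeric vector of frequencies in hertz, all positive.
#' @param z_re,z_im Real and imaginary parts of the impedance in ohms.
#'
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(f, z_re, z_im) {
  f <- as.numeric(f); z_re <- as.numeric(z_re); z_im <- as.numeric(z_im)
  n <- length(f)
  if (length(z_re) != n || length(z_im) != n)
    stop("`f`, `z_re`, `z_im` must have equal length", call. = FALSE)
  if (n < 1) stop("empty spectrum", call. = FALSE)
  if (anyNA(f) || anyNA(z_re) || anyNA(z_im) ||
      any(!is.finite(c(f, z_re, z_im))))
    stop("spectrum values must be finite", call. = FALSE)
  if (any(f <= 0)) stop("frequencies must be positive", call. = FALSE)
  structure(list(f = f, z_re = z_re, z_im = z_im),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  zmod <- sqrt(x$z_re^2 + x$z_im^2)
  cat(sprintf("<impedance_spectrum> %d points, f in [%.3g, %.3g] Hz, |Z| in [%.4g, %.4g] Ohm\n",
              length(x$f), min(x$f), max(x$f), min(zmod), max(zmod)))
  invisible(x)
}
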