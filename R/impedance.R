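#' R(RC)(RC) circuit impedance
#'
#' Total impedance of a series resistance followed by two parallel RC
#' elements:
#' `Z(w) = R1 + R2 / (1 + j w R2 C1) + R3 / (1 + j w R3 C2)`, `w = 2 pi f`.
#' In the DC limit `Z -> R1 + R2 + R3`; at high frequency the capacitors
#' short and `Z -> R1`. The imaginary part is non-positive at every
#' frequency, as required of a passive RC network.
#'
#' @param params A [circuit_params()].
#' @param f Frequencies in Hz (> 0).
#' @return Complex impedance vector in ohms.
#' @export
circuit_impedance <- function(params, f) {
  stopifnot(inherits(params, "circuit_params"), all(f > 0))
  w <- 2 * pi * f
  params$r1 + params$r2 / (1 + 1i * w * params$r2 * params$c1) +
    params$r3 / (1 + 1i * w * params$r3 * params$c2)
}

#' Impedance magnitude and phase
#'
#' @param z_re,z_im Real and imaginary impedance in ohms.
#' @return List with `z_mod` (ohms) and `phase` (degrees,
#'   `atan2(z_im, z_re)`; capacitive points give negative phase).
#' @export
magnitude_phase <- function(z_re, z_im) {
  list(z_mod = sqrt(z_re^2 + z_im^2),
       phase = atan2(z_im, z_re) * 180 / pi)
}

#' Summarise an impedance spectrum
#'
#' Arithmetic mean, maximum and minimum of |Z| over all frequency points,
#' and the mean absolute phase (reported unsigned, the convention under
#' which capacitive spectra have positive mean phase).
#'
#' @param spec An [impedance_spectrum()].
#' @return One-row data frame with `mean_z`, `max_z`, `min_z` (ohms) and
#'   `mean_phase` (degrees).
#' @export
summarize_spectrum <- function(spec) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  mp <- magnitude_phase(spec$z_re, spec$z_im)
  data.frame(mean_z = mean(mp$z_mod), max_z = max(mp$z_mod),
             min_z = min(mp$z_mod), mean_phase = mean(abs(mp$phase)))
}

#' Signed percent difference
#'
#' `(b - a) / a * 100` with `a` the reference.
#'
#' @param a Reference value (nonzero).
#' @param b Comparison value.
#' @return Percent difference.
#' @export
#' @examples
#' percent_difference(202.84, 3.59)    # -98.23
#' percent_difference(202.84, 293.40)  # +44.65
percent_difference <- function(a, b) {
  if (any(a == 0)) stop("reference value must be nonzero", call. = FALSE)
  (b - a) / a * 100
}

# Data-driven initial guess: R1 from the high-frequency |Z| floor, arc
# diameters and apex frequencies from local maxima of -z_im (for a single RC
# element, max(-z_im) = R/2 at w = 1/(R C)).
auto_init_circuit <- function(spec) {
  o <- order(spec$f)
  f <- spec$f[o]; zre <- spec$z_re[o]; zim <- spec$z_im[o]
  zmod <- sqrt(zre^2 + zim^2)
  r1 <- max(min(zmod), 1e-6)
  total <- max(max(zre), r1 * (1 + 1e-3))
  y <- -zim
  n <- length(y)
  # locate arcs on the phase-like ratio -z_im/|Z|: arc apexes stand out there
  # while the flanks of a dominant arc (where raw -z_im noise is large in
  # absolute terms) stay flat; smooth both against point noise
  ysm <- if (n >= 9) stats::runmed(y, 7) else y
  rsm <- if (n >= 9) stats::runmed(y / zmod, 7) else y / zmod
  pk <- which(rsm[2:(n - 1)] > rsm[1:(n - 2)] & rsm[2:(n - 1)] >= rsm[3:n]) + 1L
  pk <- pk[ysm[pk] > 0]
  pk <- pk[order(rsm[pk], decreasing = TRUE)]
  if (length(pk) > 1) {
    # second arc must sit at least a decade away from the first
    far <- pk[abs(log10(f[pk] / f[pk[1]])) >= 1]
    pk <- c(pk[1], far[1])
    pk <- pk[!is.na(pk)]
  }
  y <- ysm
  if (length(pk) == 2) {
    pk <- pk[order(f[pk])]                     # low-frequency arc first
    r3 <- 2 * y[pk[1]]; c2 <- 1 / (2 * pi * f[pk[1]] * r3)
    r2 <- 2 * y[pk[2]]; c1 <- 1 / (2 * pi * f[pk[2]] * r2)
  } else {
    rsum <- max(total - r1, r1)
    r3 <- 0.9 * rsum; r2 <- 0.1 * rsum
    fa <- if (length(pk) == 1) f[pk] else sqrt(min(f) * max(f))
    c2 <- 1 / (2 * pi * fa * r3)
    c1 <- 1 / (2 * pi * (fa * 100) * r2)
  }
  circuit_params(r1 = r1, r2 = max(r2, 1e-6), c1 = max(c1, 1e-15),
                 r3 = max(r3, 1e-6), c2 = max(c2, 1e-15))
}

#' Fit the R(RC)(RC) circuit to an impedance spectrum
#'
#' Complex nonlinear least squares minimising
#' `sum_k |Z_obs(f_k) - Z_model(f_k)|^2 / |Z_obs(f_k)|^2` (modulus
#' weighting, so decades with kilo-ohm and mega-ohm impedance contribute
#' comparably) by Levenberg-Marquardt ([minpack.lm::nls.lm()]) over the log
#' of the five parameters, which enforces positivity without box
#' constraints. The reported `chi2` is the weighted residual sum divided by
#' `2 * n_points - 5`. The fit is deterministic given the initial guess.
#'
#' @param spec An [impedance_spectrum()] with at least 10 frequencies
#'   spanning at least 3 decades.
#' @param init A [circuit_params()] initial guess, or `NULL` for a
#'   data-derived start.
#' @return List of class `circuit_fit` with `params` ([circuit_params()]),
#'   `param_errors` (relative % per parameter, `NA` if the covariance is
#'   singular), `chi2`, `n_iter`, `converged`.
#' @export
fit_circuit <- function(spec, init = NULL) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  if (length(spec$f) < 10)
    stop("need at least 10 frequencies", call. = FALSE)
  if (log10(max(spec$f) / min(spec$f)) < 3)
    stop("spectrum must span at least 3 decades", call. = FALSE)
  if (is.null(init)) init <- auto_init_circuit(spec)
  stopifnot(inherits(init, "circuit_params"))
  zobs <- complex(real = spec$z_re, imaginary = spec$z_im)
  w <- 1 / Mod(zobs)
  resid_fn <- function(logp) {
    p <- exp(logp)
    zm <- circuit_impedance(
      circuit_params(p[1], p[2], p[3], p[4], p[5]), spec$f)
    dz <- zm - zobs
    c(Re(dz) * w, Im(dz) * w)
  }
  start <- log(unlist(init))
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  p <- exp(fit$par)
  names(p) <- c("r1", "r2", "c1", "r3", "c2")
  perm <- seq_len(5)
  if (p["r2"] * p["c1"] > p["r3"] * p["c2"]) {
    # the two RC branches are interchangeable in the model; report the
    # faster branch (smaller time constant) as (r2, c1)
    p <- p[c("r1", "r3", "c2", "r2", "c1")]
    names(p) <- c("r1", "r2", "c1", "r3", "c2")
    perm <- c(1L, 4L, 5L, 2L, 3L)
  }
  nobs <- 2 * length(spec$f)
  chi2 <- sum(fit$fvec^2) / (nobs - 5)
  err <- tryCatch({
    cov <- chi2 * solve(fit$hessian)
    100 * sqrt(pmax(diag(cov), 0))[perm]  # log-scale SD ~ relative error
  }, error = function(e) rep(NA_real_, 5))
  names(err) <- names(p)
  structure(list(params = circuit_params(p[1], p[2], p[3], p[4], p[5]),
                 param_errors = err, chi2 = chi2, n_iter = fit$niter,
                 converged = fit$info %in% 1:3),
            class = "circuit_fit")
}

#' @export
print.circuit_fit <- function(x, ...) {
  p <- unlist(x$params)
  cat("<circuit_fit> R(RC)(RC)\n")
  for (nm in names(p))
    cat(sprintf("  %-3s %.6g %s (%.3g%% err)\n", nm, p[nm],
                if (grepl("^c", nm)) "F" else "Ohm", x$param_errors[nm]))
  cat(sprintf("  chi2 = %.4g, %d iterations, converged: %s\n",
              x$chi2, x$n_iter, x$converged))
  invisible(x)
}
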