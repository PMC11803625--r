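#' Phase specification for synthetic spiking traces
#'
#' Describes one activity phase of a spontaneous recording: a homogeneous
#' Poisson spike process on top of a constant baseline with Gaussian noise.
#'
#' @param t_start,t_end Phase limits in seconds (`t_end > t_start`).
#' @param spike_rate Mean spike rate in spikes/minute (>= 0).
#' @param amp_mean,amp_sd Spike amplitude distribution in mV; amplitudes are
#'   drawn Normal(`amp_mean`, `amp_sd`) truncated at 0.
#' @param baseline Baseline potential in mV.
#' @param noise_sd Gaussian noise SD in mV.
#' @return A `phase_spec` list.
#' @export
phase_spec <- function(t_start, t_end, spike_rate, amp_mean, amp_sd = 0,
                       baseline = 0, noise_sd = 0) {
  stopifnot(t_end > t_start, spike_rate >= 0, amp_sd >= 0, noise_sd >= 0)
  structure(list(t_start = t_start, t_end = t_end, spike_rate = spike_rate,
                 amp_mean = amp_mean, amp_sd = amp_sd, baseline = baseline,
                 noise_sd = noise_sd),
            class = "phase_spec")
}

#' Burst oscillation specification
#'
#' Parameters of a burst-like oscillatory voltage pattern: a sinusoid between
#' `v_min` and `v_max` switched on by a logistic envelope with characteristic
#' time `tau`.
#'
#' @param v_max,v_min Peak and baseline potential in mV (`v_max > v_min`).
#' @param tau Envelope time constant in seconds (> 0).
#' @param freq Oscillation frequency in cycles per minute.
#' @param duration Trace duration in seconds (must exceed `tau`).
#' @return A `burst_spec` list.
#' @export
burst_spec <- function(v_max, v_min, tau, freq, duration) {
  stopifnot(v_max > v_min, tau > 0, freq >= 0, duration > tau)
  structure(list(v_max = v_max, v_min = v_min, tau = tau, freq = freq,
                 duration = duration),
            class = "burst_spec")
}

#' Cyclic-voltammogram generator specification
#'
#' @param e_min,e_max Potential window in V (`e_max > e_min`).
#' @param scan_rate Scan rate in V/s.
#' @param n_cycles Number of triangular cycles (>= 1).
#' @param epa0,epc0 Anodic and cathodic peak potentials in V, inside the
#'   window.
#' @param ipa0,ipc0 First-cycle peak currents in uA; `ipa0 > 0`, `ipc0 < 0`
#'   by the anodic/cathodic sign convention.
#' @param alpha Per-cycle exponential decay constant (>= 0); peak currents on
#'   cycle n scale as `exp(-alpha * (n - 1))`.
#' @param peak_width Gaussian peak SD in V.
#' @param noise_sd Current noise SD in uA.
#' @return A `cv_spec` list.
#' @export
cv_spec <- function(e_min = -1.5, e_max = 1.5, scan_rate = 0.1,
                    n_cycles = 100, epa0 = 0.3, epc0 = 0.134,
                    ipa0 = 3.53, ipc0 = -17.6, alpha = 0.01,
                    peak_width = 0.1, noise_sd = 0) {
  stopifnot(e_max > e_min, scan_rate > 0, n_cycles >= 1, alpha >= 0,
            peak_width > 0, noise_sd >= 0, ipa0 > 0, ipc0 < 0)
  if (epa0 <= e_min || epa0 >= e_max || epc0 <= e_min || epc0 >= e_max)
    stop("peak potentials must lie strictly inside (e_min, e_max)",
         call. = FALSE)
  structure(list(e_min = e_min, e_max = e_max, scan_rate = scan_rate,
                 n_cycles = as.integer(n_cycles), epa0 = epa0, epc0 = epc0,
                 ipa0 = ipa0, ipc0 = ipc0, alpha = alpha,
                 peak_width = peak_width, noise_sd = noise_sd),
            class = "cv_spec")
}

#' R(RC)(RC) equivalent-circuit parameters
#'
#' A series resistance followed by two parallel RC elements, the standard
#' ladder used for interfacial charge-transfer processes: `r1` plays the role
#' of the solution resistance and each RC pair a charge-transfer resistance
#' with its double-layer capacitance.
#'
#' @param r1,r2,r3 Resistances in ohms (> 0).
#' @param c1,c2 Capacitances in farads (> 0).
#' @return A `circuit_params` list.
#' @export
circuit_params <- function(r1, r2, c1, r3, c2) {
  vals <- c(r1 = unname(r1), r2 = unname(r2), c1 = unname(c1),
            r3 = unname(r3), c2 = unname(c2))
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all circuit parameters must be positive and finite", call. = FALSE)
  structure(as.list(vals), class = "circuit_params")
}

# Truncated-at-zero normal draws (rejection sampling; mean expected > 0).
rnorm_pos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(max(mean, 0), n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > 0
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# Add exponential-decay spike templates (instantaneous rise) to a signal.
add_spike_templates <- function(t, v, times, amps, decay_tau) {
  for (k in seq_along(times)) {
    idx <- which(t >= times[k])
    if (length(idx))
      v[idx] <- v[idx] + amps[k] * exp(-(t[idx] - times[k]) / decay_tau)
  }
  v
}

#' Generate a spiking voltage trace
#'
#' Simulates a spontaneous recording over one or more activity phases. Within
#' each phase, spike times follow a homogeneous Poisson process at the phase's
#' rate, amplitudes are Normal truncated at zero, and each spike contributes a
#' template pulse (instantaneous rise, exponential decay) added to the phase
#' baseline plus Gaussian noise. The true injected spikes are attached as
#' attribute `"spikes"` (a data frame with `time` and `amplitude`) for
#' detector validation.
#'
#' @param phases A single [phase_spec()] or a list of them, ordered and
#'   non-overlapping.
#' @param dt Sampling interval in seconds.
#' @param seed Integer seed; the generator is deterministic given
#'   (`phases`, `dt`, `seed`).
#' @param decay_tau Spike template decay time constant in seconds.
#' @param refractory Minimum spacing between spikes in seconds; the Poisson
#'   times are thinned so no spike falls within `refractory` of the previous
#'   kept one. Default 0 (pure Poisson).
#' @param label Trace label.
#' @return A [voltage_trace()].
#' @export
#' @examples
#' ph <- phase_spec(0, 600, spike_rate = 1.8, amp_mean = 10, amp_sd = 2)
#' tr <- gen_spike_trace(ph, dt = 1, seed = 1)
gen_spike_trace <- function(phases, dt, seed = NULL, decay_tau = 30,
                            refractory = 0, label = "") {
  if (inherits(phases, "phase_spec")) phases <- list(phases)
  stopifnot(length(phases) >= 1, dt > 0)
  starts <- vapply(phases, `[[`, 0, "t_start")
  ends <- vapply(phases, `[[`, 0, "t_end")
  if (is.unsorted(starts, strictly = TRUE) && length(starts) > 1)
    stop("phases must be ordered by start time", call. = FALSE)
  if (length(phases) > 1 && any(starts[-1] < ends[-length(ends)]))
    stop("phases must not overlap", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  t <- seq(starts[1], ends[length(ends)], by = dt)
  v <- numeric(length(t))
  sp_t <- numeric(0); sp_a <- numeric(0)
  last_base <- phases[[1]]$baseline
  in_any <- rep(FALSE, length(t))
  for (ph in phases) {
    idx <- which(t >= ph$t_start & t < ph$t_end)
    in_any[idx] <- TRUE
    v[idx] <- ph$baseline +
      if (ph$noise_sd > 0) stats::rnorm(length(idx), 0, ph$noise_sd) else 0
    dur <- ph$t_end - ph$t_start
    n_sp <- stats::rpois(1, ph$spike_rate / 60 * dur)
    if (n_sp > 0) {
      tk <- sort(stats::runif(n_sp, ph$t_start, ph$t_end))
      ak <- rnorm_pos(n_sp, ph$amp_mean, ph$amp_sd)
      sp_t <- c(sp_t, tk); sp_a <- c(sp_a, ak)
    }
    last_base <- ph$baseline
  }
  v[!in_any] <- last_base  # samples in gaps / at the very end
  if (refractory > 0 && length(sp_t) > 1) {
    keep <- rep(TRUE, length(sp_t))
    last <- sp_t[1]
    for (k in 2:length(sp_t)) {
      if (sp_t[k] - last < refractory) keep[k] <- FALSE else last <- sp_t[k]
    }
    sp_t <- sp_t[keep]; sp_a <- sp_a[keep]
  }
  v <- add_spike_templates(t, v, sp_t, sp_a, decay_tau)
  out <- voltage_trace(t = t, v = v, label = label, sample_interval = dt)
  attr(out, "spikes") <- data.frame(time = sp_t, amplitude = sp_a)
  out
}

#' Generate a burst-like oscillatory trace
#'
#' A sinusoidal oscillation between `v_min` and `v_max` multiplied by a
#' logistic onset envelope with characteristic time `tau` (half-activation at
#' `2 * tau`, rise scale `tau / 4`). With `freq = 0` the trace is the constant
#' baseline `v_min`. The oscillation amplitude scales linearly with
#' `v_max - v_min`.
#'
#' @param spec A [burst_spec()].
#' @param dt Sampling interval in seconds (> 0).
#' @param seed Integer seed (used only if `noise_sd > 0`).
#' @param noise_sd Optional additive Gaussian noise SD in mV.
#' @param label Trace label.
#' @return A [voltage_trace()].
#' @export
gen_burst_trace <- function(spec, dt, seed = NULL, noise_sd = 0, label = "") {
  stopifnot(inherits(spec, "burst_spec"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, spec$duration, by = dt)
  env <- stats::plogis((t - 2 * spec$tau) / (spec$tau / 4))
  osc <- if (spec$freq > 0)
    0.5 * (1 - cos(2 * pi * (spec$freq / 60) * t)) else rep(0, length(t))
  v <- spec$v_min + (spec$v_max - spec$v_min) * env * osc
  if (noise_sd > 0) v <- v + stats::rnorm(length(t), 0, noise_sd)
  voltage_trace(t = t, v = v, label = label, sample_interval = dt)
}

#' Generate a multi-cycle synthetic voltammogram
#'
#' Builds a triangular potential sweep per cycle with a Gaussian anodic peak
#' at `epa0` on the forward sweep and a Gaussian cathodic peak at `epc0` on
#' the reverse sweep. Peak currents on cycle `n` are scaled by
#' `exp(-alpha * (n - 1))`, so at zero noise the per-cycle integrated charge
#' satisfies `Q(n + 1) / Q(n) = exp(-alpha)` exactly.
#'
#' @param spec A [cv_spec()].
#' @param seed Integer seed (used only if `noise_sd > 0`).
#' @param points_per_sweep Samples per half-sweep.
#' @return A [voltammogram()] with cycle indices assigned; the generating
#'   spec is attached as attribute `"truth"`.
#' @export
gen_voltammogram <- function(spec, seed = NULL, points_per_sweep = 200) {
  stopifnot(inherits(spec, "cv_spec"), points_per_sweep >= 10)
  if (!is.null(seed)) set.seed(seed)
  m <- points_per_sweep
  fwd <- seq(spec$e_min, spec$e_max, length.out = m)
  bwd <- rev(fwd)[-1]
  bwd <- bwd[-length(bwd)]              # open cycle: next cycle restarts at e_min
  e1 <- c(fwd, bwd)
  dir1 <- c(rep(1L, m), rep(-1L, length(bwd)))
  e <- rep(e1, spec$n_cycles)
  dir <- rep(dir1, spec$n_cycles)
  cyc <- rep(seq_len(spec$n_cycles), each = length(e1))
  scale_n <- exp(-spec$alpha * (cyc - 1))
  i <- scale_n * (spec$ipa0 * (dir == 1) *
                    exp(-(e - spec$epa0)^2 / (2 * spec$peak_width^2)) +
                  spec$ipc0 * (dir == -1) *
                    exp(-(e - spec$epc0)^2 / (2 * spec$peak_width^2)))
  if (spec$noise_sd > 0) i <- i + stats::rnorm(length(i), 0, spec$noise_sd)
  out <- voltammogram(e = e, i = i, cycle = cyc, scan_rate = spec$scan_rate)
  attr(out, "truth") <- spec
  out
}

#' Generate a synthetic impedance spectrum from an R(RC)(RC) circuit
#'
#' Frequencies are logarithmically spaced at `points_per_decade` points per
#' decade from `f_min` to `f_max` (11 decades at 12.3 points/decade give 136
#' points). The model impedance is perturbed by multiplicative complex
#' Gaussian noise of relative standard deviation `noise_frac`.
#'
#' @param params A [circuit_params()].
#' @param f_min,f_max Frequency range in Hz (`f_min < f_max`).
#' @param points_per_decade Sampling density (> 0); may be non-integer.
#' @param noise_frac Relative noise SD (0 for the exact model spectrum).
#' @param seed Integer seed.
#' @return An [impedance_spectrum()].
#' @export
gen_spectrum <- function(params, f_min = 1e-5, f_max = 1e6,
                         points_per_decade = 12.3, noise_frac = 0,
                         seed = NULL) {
  stopifnot(inherits(params, "circuit_params"), f_min > 0, f_min < f_max,
            points_per_decade > 0, noise_frac >= 0)
  if (!is.null(seed)) set.seed(seed)
  f <- 10^seq(log10(f_min), log10(f_max), by = 1 / points_per_decade)
  z <- circuit_impedance(params, f)
  if (noise_frac > 0)
    z <- z * (1 + noise_frac * stats::rnorm(length(f)) +
                1i * noise_frac * stats::rnorm(length(f)))
  impedance_spectrum(f = f, z_re = Re(z), z_im = Im(z))
}

#' Generate a system-analog voltage trace (P, PS or PSP)
#'
#' Emulates the qualitative electrical signatures of the three protocell
#' systems: pristine proteinoid ("P"), proteinoid-serotonin ("PS") and
#' proteinoid-serotonin-paroxetine ("PSP"). Each analog is a slow baseline
#' oscillation (period and amplitude set from the reported median inter-event
#' periods and potential ranges) plus a Poisson spike train with the reported
#' rate and amplitude distribution, plus AR(1) background noise at the
#' reported RMS scale. The PSP analog has three phases with spike rate rising
#' from 0.2 to 1.8 per minute.
#'
#' @param system One of `"P"`, `"PS"`, `"PSP"`.
#' @param duration Trace duration in seconds.
#' @param dt Sampling interval in seconds.
#' @param seed Integer seed.
#' @return A [voltage_trace()] labelled with the system name.
#' @export
gen_system_trace <- function(system = c("P", "PS", "PSP"), duration = 30000,
                             dt = 1, seed = NULL) {
  system <- match.arg(system)
  if (!is.null(seed)) set.seed(seed)
  par <- switch(system,
    P   = list(period = 600, osc_amp = 3,  rates = 0.5,
               amp_mean = 7.62,  amp_sd = 4.69, noise_sd = 0.5, corr = 30),
    PS  = list(period = 150, osc_amp = 20, rates = 1.2,
               amp_mean = 14.87, amp_sd = 7.80, noise_sd = 4, corr = 5),
    PSP = list(period = 300, osc_amp = 8,  rates = c(0.2, 1.0, 1.8),
               amp_mean = 10.84, amp_sd = 4.36, noise_sd = 1.0, corr = 10))
  t <- seq(0, duration, by = dt)
  n <- length(t)
  v <- par$osc_amp * sin(2 * pi * t / par$period)
  # AR(1) background noise, stationary SD = noise_sd; the pristine system's
  # background is a slow low-amplitude drift, the modified systems' a faster
  # higher-RMS fluctuation
  phi <- exp(-dt / par$corr)
  innov_sd <- par$noise_sd * sqrt(1 - phi^2)
  noise <- stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                         method = "recursive")
  v <- v + as.numeric(noise)
  # phased Poisson spikes
  k <- length(par$rates)
  bounds <- seq(0, duration, length.out = k + 1)
  sp_t <- numeric(0); sp_a <- numeric(0)
  for (j in seq_len(k)) {
    dur_j <- bounds[j + 1] - bounds[j]
    n_sp <- stats::rpois(1, par$rates[j] / 60 * dur_j)
    if (n_sp > 0) {
      sp_t <- c(sp_t, sort(stats::runif(n_sp, bounds[j], bounds[j + 1])))
      sp_a <- c(sp_a, rnorm_pos(n_sp, par$amp_mean, par$amp_sd))
    }
  }
  v <- add_spike_templates(t, v, sp_t, sp_a, decay_tau = 10)
  out <- voltage_trace(t = t, v = v, label = system, sample_interval = dt)
  attr(out, "spikes") <- data.frame(time = sp_t, amplitude = sp_a)
  out
}
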