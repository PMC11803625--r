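#' Segment a voltammogram into cycles
#'
#' Assigns 1-based cycle indices by locating sweep-direction reversals at the
#' lower potential limit: a new cycle starts wherever the sweep turns from
#' descending to ascending. Each cycle must contain one forward (ascending)
#' and one reverse (descending) sweep; leading samples before the first full
#' cycle and a trailing incomplete cycle are dropped with a warning.
#'
#' @param vg A [voltammogram()] (its `cycle` field, if any, is recomputed).
#' @return The voltammogram with `cycle` assigned.
#' @export
segment_cycles <- function(vg) {
  stopifnot(inherits(vg, "voltammogram"))
  d <- sign(diff(vg$e))
  # carry direction through zero-steps
  if (all(d == 0)) stop("potential is constant; no sweep found", call. = FALSE)
  for (k in seq_along(d)) if (d[k] == 0) d[k] <- if (k > 1) d[k - 1] else 0
  if (d[1] == 0) d[d == 0] <- d[which(d != 0)[1]]
  n <- length(vg$e)
  # sample s (>= 2) starts a new ascent if step into it is +1 after a -1 step
  # sentinel -1 ahead of the first step makes an initially ascending sweep
  # open its own cycle at sample 1
  starts <- which(d == 1 & c(-1, utils::head(d, -1)) == -1)
  if (length(starts) == 0)
    stop("fewer than one full cycle in voltammogram", call. = FALSE)
  ends <- c(starts[-1] - 1L, n)
  # a full cycle needs both sweep directions
  has_rev <- vapply(seq_along(starts), function(j) {
    idx <- starts[j]:ends[j]
    any(diff(vg$e[idx]) < 0) && any(diff(vg$e[idx]) > 0)
  }, TRUE)
  if (!any(has_rev))
    stop("fewer than one full cycle in voltammogram", call. = FALSE)
  if (starts[1] > 1 || !all(has_rev))
    warning("dropping samples outside complete cycles")
  keep_j <- which(has_rev)
  cyc <- rep(NA_integer_, n)
  for (j in seq_along(keep_j))
    cyc[starts[keep_j[j]]:ends[keep_j[j]]] <- j
  keep <- !is.na(cyc)
  voltammogram(e = vg$e[keep], i = vg$i[keep], cycle = cyc[keep],
               scan_rate = vg$scan_rate)
}

split_cycles <- function(vg) {
  if (is.null(vg$cycle)) vg <- segment_cycles(vg)
  lapply(seq_len(max(vg$cycle)), function(j) {
    idx <- vg$cycle == j
    list(e = vg$e[idx], i = vg$i[idx])
  })
}

#' Locate anodic and cathodic peaks in one cycle
#'
#' The anodic peak is the maximum current on the forward (ascending) sweep;
#' the cathodic peak is the minimum current on the reverse sweep. If the
#' current has no extremum exceeding `noise_floor` (peak-to-peak), all values
#' are returned as `NA` with a warning (peaks-not-found signal).
#'
#' @param e,i Potential (V) and current (uA) samples of one cycle, forward
#'   sweep first.
#' @param noise_floor Minimum peak-to-peak current (uA) for peaks to count.
#' @return A list with `epa`, `ipa`, `epc`, `ipc` (V and uA; `ipc` negative
#'   by convention when found).
#' @export
find_redox_peaks <- function(e, i, noise_floor = 0) {
  stopifnot(length(e) == length(i), length(e) >= 20)
  if (diff(range(i)) <= noise_floor) {
    warning("no redox peaks found (flat current)")
    return(list(epa = NA_real_, ipa = NA_real_, epc = NA_real_,
                ipc = NA_real_))
  }
  m <- which.max(e)
  fwd <- seq_len(m)
  rv <- m:length(e)
  ka <- which.max(i[fwd])
  kc <- which.min(i[rv])
  list(epa = e[fwd][ka], ipa = i[fwd][ka], epc = e[rv][kc], ipc = i[rv][kc])
}

#' Peak separation
#'
#' `delta_ep = epa - epc`, the potential gap between the anodic and cathodic
#' peaks; small values indicate fast, nearly reversible electron transfer.
#'
#' @param epa,epc Peak potentials in V.
#' @return Peak separation in V.
#' @export
peak_separation <- function(epa, epc) epa - epc

#' Peak current ratio
#'
#' `|ipa / ipc|`; the sign of the cathodic current is irrelevant.
#'
#' @param ipa,ipc Peak currents in uA.
#' @return Dimensionless ratio, or `NA` with a warning when `ipc` is zero.
#' @export
peak_ratio <- function(ipa, ipc) {
  if (any(ipc == 0)) {
    warning("peak ratio undefined for ipc = 0")
    return(ifelse(ipc == 0, NA_real_, abs(ipa / ipc)))
  }
  abs(ipa / ipc)
}

#' Integrated charge of one cycle
#'
#' Trapezoidal integral of |i| over time, with time reconstructed from the
#' potential program as `dt = |dE| / scan_rate`. Integrating the absolute
#' current gives the total charge passed, which is positive and decays over
#' cycling.
#'
#' @param e,i Potential (V) and current (uA) samples of one cycle.
#' @param scan_rate Scan rate in V/s (> 0).
#' @return Charge in uC.
#' @export
integrated_charge <- function(e, i, scan_rate) {
  stopifnot(scan_rate > 0, length(e) == length(i), length(e) >= 2)
  t <- cumsum(c(0, abs(diff(e)))) / scan_rate
  pracma::trapz(t, abs(i))
}

#' Fit an exponential charge decay over cycles
#'
#' Least-squares fit of `Q(n) = Q0 * exp(-alpha * n)` by ordinary linear
#' regression of `log Q` on the cycle number, the stable choice for a pure
#' exponential.
#'
#' @param q Per-cycle charges (uC), all positive, length >= 5.
#' @param n Cycle numbers (defaults to `1:length(q)`).
#' @return List with `q0`, `alpha` and `resid_var` (residual variance of the
#'   log fit).
#' @export
fit_charge_decay <- function(q, n = seq_along(q)) {
  if (length(q) < 5) stop("need at least 5 cycles", call. = FALSE)
  if (any(q <= 0)) stop("charges must be positive", call. = FALSE)
  fit <- stats::lm(log(q) ~ n)
  co <- stats::coef(fit)
  list(q0 = exp(unname(co[1])), alpha = -unname(co[2]),
       resid_var = stats::deviance(fit) / stats::df.residual(fit))
}

#' Per-cycle relative decay rate
#'
#' Relative change between consecutive cycles,
#' `(x(n) - x(n-1)) / x(n-1) * 100` percent; the first cycle is undefined
#' (`NA`), as is any cycle following a zero value.
#'
#' @param x Per-cycle values (e.g. peak currents).
#' @return Vector of percentages, same length as `x`.
#' @export
decay_rate <- function(x) {
  stopifnot(length(x) >= 2)
  prev <- utils::head(x, -1)
  out <- c(NA_real_, ifelse(prev == 0, NA_real_, diff(x) / prev * 100))
  if (any(prev == 0)) warning("decay rate undefined after zero values")
  out
}

#' Reversibility index
#'
#' The composite statistic `eta = |ipa / ipc| / delta_ep` in 1/V, combining
#' the peak current ratio with the peak separation; larger values indicate
#' more reversible, faster electron transfer.
#'
#' @param ipa,ipc Peak currents in uA.
#' @param delta_ep Peak separation in V (> 0).
#' @return `eta` in 1/V; `NA` with a warning when `delta_ep` is zero.
#' @export
reversibility_index <- function(ipa, ipc, delta_ep) {
  if (any(delta_ep == 0)) {
    warning("reversibility index undefined for delta_ep = 0")
    return(ifelse(delta_ep == 0, NA_real_, abs(ipa / ipc) / delta_ep))
  }
  abs(ipa / ipc) / delta_ep
}

#' Electron transfer efficiency
#'
#' `epsilon = |ipa * ipc| / delta_ep` in uA^2/V; scaling both currents by a
#' factor `c` scales `epsilon` by `c^2`.
#'
#' @inheritParams reversibility_index
#' @return `epsilon` in uA^2/V; `NA` with a warning when `delta_ep` is zero.
#' @export
transfer_efficiency <- function(ipa, ipc, delta_ep) {
  if (any(delta_ep == 0)) {
    warning("transfer efficiency undefined for delta_ep = 0")
    return(ifelse(delta_ep == 0, NA_real_, abs(ipa * ipc) / delta_ep))
  }
  abs(ipa * ipc) / delta_ep
}

#' Efficiency enhancement
#'
#' Percent change of a modified system's electron transfer efficiency over a
#' reference: `(eps_mod - eps_ref) / eps_ref * 100`.
#'
#' @param eps_ref Reference efficiency (> 0).
#' @param eps_mod Modified-system efficiency.
#' @return Enhancement in percent.
#' @export
efficiency_enhancement <- function(eps_ref, eps_mod) {
  if (any(eps_ref <= 0))
    stop("reference efficiency must be positive", call. = FALSE)
  (eps_mod - eps_ref) / eps_ref * 100
}

#' Zero-crossing potential and current of one cycle
#'
#' `E_zc` is the potential at which the current crosses zero on the forward
#' sweep (linear interpolation between the bracketing samples; if the current
#' crosses several times, the first crossing after the lower potential limit
#' is used). `I_zc` is the current on the reverse sweep interpolated at that
#' same potential, which is generally nonzero because of hysteresis.
#'
#' @param e,i Potential (V) and current (uA) samples of one cycle.
#' @return List with `ezc` (V) and `izc` (uA); both `NA` with a warning when
#'   the forward current never changes sign.
#' @export
zero_crossings <- function(e, i) {
  stopifnot(length(e) == length(i), length(e) >= 4)
  m <- which.max(e)
  ef <- e[seq_len(m)]; iff <- i[seq_len(m)]
  cross <- which(iff[-m] * iff[-1] < 0 | iff[-m] == 0)
  if (length(cross) == 0) {
    if (iff[m] == 0) cross <- m - 1L else {
      warning("no zero crossing on forward sweep")
      return(list(ezc = NA_real_, izc = NA_real_))
    }
  }
  k <- cross[1]
  ezc <- if (iff[k] == 0) ef[k] else
    ef[k] + (0 - iff[k]) * (ef[k + 1] - ef[k]) / (iff[k + 1] - iff[k])
  er <- e[m:length(e)]; ir <- i[m:length(e)]
  izc <- stats::approx(er, ir, xout = ezc, ties = mean)$y
  list(ezc = ezc, izc = izc)
}

#' Hysteresis area of one cycle
#'
#' Absolute shoelace (polygon) area of the closed current-potential loop in
#' uA.V, a measure of overall electrochemical activity. An open loop
#' (endpoints further apart than `tol` of the loop's normalised extent) is
#' closed by joining the endpoints, with a warning; a mismatch of one grid
#' step, as in sweeps that restart at the lower limit, stays silent.
#'
#' @param e,i Potential (V) and current (uA) samples of one cycle.
#' @param tol Relative endpoint-mismatch tolerance (default 1% of range).
#' @return Area in uA.V (>= 0).
#' @export
hysteresis_area <- function(e, i, tol = 0.01) {
  n <- length(e)
  stopifnot(n == length(i), n >= 3)
  gap <- sqrt((e[1] - e[n])^2 / max(diff(range(e)), .Machine$double.eps)^2 +
              (i[1] - i[n])^2 / max(diff(range(i)), .Machine$double.eps)^2)
  if (gap > tol) warning("open I-V loop; closing by joining endpoints")
  0.5 * abs(sum(e * c(i[-1], i[1]) - c(e[-1], e[1]) * i))
}

#' Per-cycle feature table of a voltammogram
#'
#' Runs the full per-cycle analysis: redox peaks, peak separation and ratio,
#' integrated charge, zero crossings, hysteresis area and current extremes.
#'
#' @param vg A [voltammogram()]; cycles are inferred with [segment_cycles()]
#'   if not assigned.
#' @param noise_floor Passed to [find_redox_peaks()].
#' @return A data frame with one row per cycle and columns `cycle`, `epa`,
#'   `epc`, `ipa`, `ipc`, `delta_ep`, `ratio`, `q`, `ezc`, `izc`,
#'   `hyst_area`, `i_max`, `i_min`.
#' @export
cv_features <- function(vg, noise_floor = 0) {
  cycles <- split_cycles(vg)
  rows <- lapply(seq_along(cycles), function(j) {
    cy <- cycles[[j]]
    pk <- find_redox_peaks(cy$e, cy$i, noise_floor)
    zc <- suppressWarnings(zero_crossings(cy$e, cy$i))
    data.frame(cycle = j, epa = pk$epa, epc = pk$epc, ipa = pk$ipa,
               ipc = pk$ipc,
               delta_ep = peak_separation(pk$epa, pk$epc),
               ratio = if (is.na(pk$ipc) || pk$ipc == 0) NA_real_ else
                 abs(pk$ipa / pk$ipc),
               q = integrated_charge(cy$e, cy$i, vg$scan_rate),
               ezc = zc$ezc, izc = zc$izc,
               # segmented cycles are open by one grid step by construction
               hyst_area = suppressWarnings(hysteresis_area(cy$e, cy$i)),
               i_max = max(cy$i), i_min = min(cy$i))
  })
  do.call(rbind, rows)
}

#' Summarise per-cycle features over all cycles
#'
#' Mean and sample standard deviation (N - 1 denominator) of every feature
#' across cycles.
#'
#' @param features Data frame from [cv_features()].
#' @return A data frame with columns `feature`, `mean`, `sd`; the number of
#'   cycles is attached as attribute `"n_cycles"`.
#' @export
summarize_cv <- function(features) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0) stop("no cycles to summarise", call. = FALSE)
  cols <- setdiff(names(features), "cycle")
  out <- data.frame(
    feature = cols,
    mean = vapply(cols, function(c) mean(features[[c]], na.rm = TRUE), 0),
    sd = vapply(cols, function(c) stats::sd(features[[c]], na.rm = TRUE), 0),
    row.names = NULL)
  attr(out, "n_cycles") <- nrow(features)
  out
}
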