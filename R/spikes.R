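#' Spike train
#'
#' @param times Spike times in seconds, strictly increasing.
#' @param amplitudes Spike amplitudes in mV (topographic prominence above the
#'   local baseline), all positive.
#' @param source_label Label of the source trace.
#' @return A `spike_train` list.
#' @export
spike_train <- function(times, amplitudes, source_label = "") {
  stopifnot(length(times) == length(amplitudes))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (any(amplitudes <= 0))
    stop("spike amplitudes must be positive", call. = FALSE)
  structure(list(times = as.numeric(times),
                 amplitudes = as.numeric(amplitudes),
                 source_label = source_label),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes%s\n", length(x$times),
              if (nzchar(x$source_label)) paste0(" from ", x$source_label)
              else ""))
  invisible(x)
}

# Topographic prominence of local maxima at indices `peaks` in `v`:
# height above the higher of the two key saddles, i.e. the minima separating
# the peak from the nearest higher terrain (or the trace edge) on each side.
peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    left <- v[seq_len(p)]
    higher_l <- which(left > v[p])
    lmin <- min(left[(if (length(higher_l)) max(higher_l) else 1):p])
    right <- v[p:length(v)]
    higher_r <- which(right > v[p])
    rmin <- min(right[1:(if (length(higher_r)) min(higher_r) else
      length(right))])
    v[p] - max(lmin, rmin)
  }, 0)
}

#' Detect spontaneous spikes in a voltage trace
#'
#' Finds local maxima with topographic prominence of at least
#' `min_prominence` and enforces a minimum pairwise separation by keeping
#' peaks greedily in order of decreasing prominence. The reported amplitude
#' is the prominence, which makes detection invariant to baseline offset and
#' drift across phases. Detection is deterministic.
#'
#' @param trace A [voltage_trace()].
#' @param min_prominence Minimum prominence in mV. The default 2 mV sits
#'   above typical instrument noise while catching the small-amplitude tail
#'   of spontaneous events (reported minima near 1 mV need a lower value).
#' @param min_separation Minimum spacing between kept spikes in seconds. The
#'   default 60 s suits sparse spontaneous spiking (rates of order 1/min);
#'   dense trains need a smaller value, so this is an analysis choice, not a
#'   physical constant.
#' @return A [spike_train()] (possibly empty).
#' @export
detect_spikes <- function(trace, min_prominence = 2, min_separation = 60) {
  stopifnot(inherits(trace, "voltage_trace"), length(trace$v) >= 3)
  v <- trace$v
  n <- length(v)
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(cand) == 0)
    return(spike_train(numeric(0), numeric(0), trace$label))
  prom <- peak_prominence(v, cand)
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0)
    return(spike_train(numeric(0), numeric(0), trace$label))
  ord <- order(prom, decreasing = TRUE)
  sel_t <- numeric(0); sel_idx <- integer(0)
  for (k in ord) {
    tk <- trace$t[cand[k]]
    if (all(abs(sel_t - tk) >= min_separation)) {
      sel_t <- c(sel_t, tk)
      sel_idx <- c(sel_idx, k)
    }
  }
  o <- order(sel_t)
  spike_train(sel_t[o], prom[sel_idx][o], trace$label)
}

#' Inter-spike periods
#'
#' Successive differences of spike times; with fewer than two spikes an empty
#' vector is returned with a warning.
#'
#' @param train A [spike_train()].
#' @return Periods in seconds, length `n_spikes - 1`.
#' @export
interspike_periods <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) < 2) {
    warning("fewer than 2 spikes; no periods")
    return(numeric(0))
  }
  diff(train$times)
}

#' Spike frequency in a time window
#'
#' @param train A [spike_train()].
#' @param t0,t1 Window limits in seconds (`t1 > t0`); spikes in `[t0, t1)`
#'   are counted.
#' @return Frequency in spikes/minute.
#' @export
spike_frequency <- function(train, t0, t1) {
  stopifnot(inherits(train, "spike_train"), t1 > t0)
  sum(train$times >= t0 & train$times < t1) * 60 / (t1 - t0)
}

#' Segment a trace into activity phases by RMS
#'
#' In boundary mode, computes the RMS of the mean-subtracted signal in each
#' window delimited by the supplied interior boundary times (plus the trace
#' start and end). In auto mode, the trace is cut into contiguous windows of
#' `window` seconds, each window's RMS is computed, and windows are assigned
#' to phases by the supplied RMS `thresholds` (ascending cut points in mV).
#'
#' @param trace A [voltage_trace()].
#' @param boundaries Interior boundary times in seconds (boundary mode), or
#'   `NULL` for auto mode.
#' @param window Auto-mode window length in seconds.
#' @param thresholds Auto-mode ascending RMS cut points in mV; phase k
#'   collects windows with RMS in the k-th interval.
#' @return A data frame with `t_start`, `t_end`, `v_rms` and (auto mode)
#'   `phase`.
#' @export
segment_phases <- function(trace, boundaries = NULL, window = 1000,
                           thresholds = c(5, 15)) {
  stopifnot(inherits(trace, "voltage_trace"))
  rng <- range(trace$t)
  if (!is.null(boundaries)) {
    if (any(boundaries <= rng[1]) || any(boundaries >= rng[2]))
      stop("boundaries must lie strictly inside the trace span",
           call. = FALSE)
    edges <- c(rng[1], sort(boundaries), rng[2] + 1e-9)
  } else {
    stopifnot(window > 0)
    edges <- seq(rng[1], rng[2], by = window)
    if (utils::tail(edges, 1) < rng[2]) edges <- c(edges, rng[2] + 1e-9)
    else edges[length(edges)] <- rng[2] + 1e-9
  }
  out <- do.call(rbind, lapply(seq_len(length(edges) - 1), function(k) {
    idx <- trace$t >= edges[k] & trace$t < edges[k + 1]
    x <- trace$v[idx]
    data.frame(t_start = edges[k], t_end = min(edges[k + 1], rng[2]),
               v_rms = if (length(x)) sqrt(mean((x - mean(x))^2)) else
                 NA_real_)
  }))
  if (is.null(boundaries))
    out$phase <- findInterval(out$v_rms, sort(thresholds)) + 1L
  out
}

#' Distribution summary with quartiles and Pearson moments
#'
#' Quartiles use linear interpolation (type-7). Skewness and kurtosis use
#' central moments with a `1/n` denominator: `gamma = m3 / m2^(3/2)` and
#' `kappa = m4 / m2^2` (Pearson convention, so a normal sample gives kappa
#' near 3, not 0). Degenerate cases give `NA`: skewness/kurtosis for constant
#' samples, kurtosis for `n < 4`, and everything beyond `n`, `min`, `max`,
#' `mean` for `n < 2`.
#'
#' @param x Numeric sample.
#' @return One-row data frame with `q25`, `q50`, `q75`, `mean`, `sd`, `min`,
#'   `max`, `skewness`, `kurtosis`, `n`.
#' @export
summarize_distribution <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) stop("empty sample", call. = FALSE)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  m <- mean(x)
  s <- if (n >= 2) stats::sd(x) else NA_real_
  m2 <- mean((x - m)^2)
  skw <- if (n >= 2 && m2 > 0) mean((x - m)^3) / m2^1.5 else NA_real_
  krt <- if (n >= 4 && m2 > 0) mean((x - m)^4) / m2^2 else NA_real_
  data.frame(q25 = qs[1], q50 = qs[2], q75 = qs[3], mean = m, sd = s,
             min = min(x), max = max(x), skewness = skw, kurtosis = krt,
             n = n)
}
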