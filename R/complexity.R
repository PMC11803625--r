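#' Binarize a voltage trace into a symbol string
#'
#' Emits '1' where the potential exceeds the threshold (median by default,
#' optionally the mean) and '0' elsewhere. Thresholding on a data-relative
#' statistic makes the string invariant to offsets and positive rescaling of
#' the signal.
#'
#' @param trace A [voltage_trace()] (or a bare numeric vector).
#' @param method `"median"` (default) or `"mean"`.
#' @return A character scalar of '0'/'1' symbols, one per sample.
#' @export
#' @examples
#' binarize(voltage_trace(1:4, c(1, 2, 3, 4)))  # "0011"
binarize <- function(trace, method = c("median", "mean")) {
  v <- if (inherits(trace, "voltage_trace")) trace$v else as.numeric(trace)
  stopifnot(length(v) >= 2)
  method <- match.arg(method)
  thr <- if (method == "median") stats::median(v) else mean(v)
  paste(ifelse(v > thr, "1", "0"), collapse = "")
}

#' Lempel-Ziv-Welch complexity of a symbol string
#'
#' Runs standard LZW compression with the dictionary initialised to the
#' symbol alphabet and returns `C = |D(s)| / |s|`, where `|D(s)|` is the
#' number of phrases (output codes) emitted. Higher values mean the string
#' is less compressible, i.e. richer in novel patterns; an incompressible
#' fair-coin string scores far above a constant string of the same length,
#' whose phrase count grows only like the square root of the length.
#'
#' @param s Character scalar (e.g. from [binarize()]).
#' @param alphabet Initial dictionary symbols; defaults to `c("0", "1")`,
#'   extended automatically if `s` contains other characters.
#' @return `C_LZW` in (0, 1].
#' @export
#' @examples
#' lzw_complexity("00000000")  # 4 phrases / 8 symbols = 0.5
lzw_complexity <- function(s, alphabet = c("0", "1")) {
  stopifnot(is.character(s), length(s) == 1, nchar(s) >= 1)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  dict <- new.env(hash = TRUE, parent = emptyenv())
  for (a in unique(c(alphabet, chars))) assign(a, TRUE, envir = dict)
  w <- ""
  phrases <- 0L
  for (ch in chars) {
    wc <- paste0(w, ch)
    if (exists(wc, envir = dict, inherits = FALSE)) {
      w <- wc
    } else {
      phrases <- phrases + 1L       # emit code for w
      assign(wc, TRUE, envir = dict)
      w <- ch
    }
  }
  if (nzchar(w)) phrases <- phrases + 1L
  phrases / nchar(s)
}

# Cut v into n_windows equal non-overlapping windows, truncating the
# remainder; returns a list of numeric vectors.
cut_windows <- function(v, n_windows) {
  if (n_windows < 2) stop("need at least 2 windows", call. = FALSE)
  len <- length(v) %/% n_windows
  if (len < 2) stop("windows would have fewer than 2 samples", call. = FALSE)
  lapply(seq_len(n_windows), function(k) v[((k - 1) * len + 1):(k * len)])
}

#' Perturbational complexity index (compression variant)
#'
#' `PCI = C_whole - mean(C_i)`: the LZW complexity of the whole binarized
#' signal minus the mean LZW complexity of its `n_windows` equal
#' non-overlapping windows, each binarized by its own threshold. When every
#' window and the whole have equal complexity the index is 0. A signal whose
#' binarization is a single repeated symbol (e.g. a constant trace) carries
#' no information at this quantization and returns 0 with a warning.
#'
#' @param trace A [voltage_trace()] (or numeric vector).
#' @param n_windows Number of windows (>= 2); the trailing remainder of the
#'   signal is truncated.
#' @param method Binarization threshold, see [binarize()].
#' @return PCI (dimensionless).
#' @export
pci <- function(trace, n_windows = 10, method = "median") {
  v <- if (inherits(trace, "voltage_trace")) trace$v else as.numeric(trace)
  s <- binarize(v, method)
  if (!grepl("0", s) || !grepl("1", s)) {
    warning("degenerate binarization (single symbol); PCI = 0")
    return(0)
  }
  c_whole <- lzw_complexity(s)
  c_win <- vapply(cut_windows(v, n_windows),
                  function(wv) lzw_complexity(binarize(wv, method)), 0)
  c_whole - mean(c_win)
}

#' Integration score of consecutive windows
#'
#' Mean zero-lag Pearson correlation between consecutive equal-length
#' windows of the signal: `I = mean(R(x_i, x_{i+1}))` over the `N - 1`
#' consecutive pairs (optionally divided by `N` instead, see `divisor`).
#' Identical consecutive windows give 1, sign-alternating windows -1, and
#' independent noise windows about 0. A zero-variance window contributes
#' R = 0 with a warning.
#'
#' @param trace A [voltage_trace()] (or numeric vector).
#' @param n_windows Number of windows N (>= 2).
#' @param divisor `"pairs"` (divide by N - 1, default) or `"windows"`
#'   (divide by N).
#' @return Integration score in `[-1, 1]`.
#' @export
integration_score <- function(trace, n_windows = 10,
                              divisor = c("pairs", "windows")) {
  divisor <- match.arg(divisor)
  v <- if (inherits(trace, "voltage_trace")) trace$v else as.numeric(trace)
  wins <- cut_windows(v, n_windows)
  rs <- vapply(seq_len(n_windows - 1), function(k) {
    a <- wins[[k]]; b <- wins[[k + 1]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance window; correlation taken as 0")
      0
    } else stats::cor(a, b)
  }, 0)
  sum(rs) / (if (divisor == "pairs") n_windows - 1 else n_windows)
}

# Shannon entropy (bits) of counts.
entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Integrated information of a voltage trace
#'
#' `Phi = H(X) - mean(MI(X_i, X_{i+1}))`: the Shannon entropy (bits) of the
#' whole signal's histogram over `bins` equal-width bins spanning the signal
#' range, minus the mean mutual information between consecutive equal-length
#' windows (estimated from the 2-D histogram of paired samples, with the
#' same global bin edges on both axes). The average runs over the `N - 1`
#' consecutive pairs by default (`divisor = "pairs"`). High Phi means the
#' whole signal is information-rich while consecutive segments share little
#' information. A constant trace (all histogram mass in one bin) returns 0
#' with a warning.
#'
#' @param trace A [voltage_trace()] (or numeric vector).
#' @param n_windows Number of windows N (>= 2).
#' @param bins Number of histogram bins (>= 2).
#' @param divisor `"pairs"` or `"windows"`, as in [integration_score()].
#' @return Phi in bits. Negative estimates are possible in principle (the MI
#'   term is not bounded by H(X) sample-wise) and are reported as-is with a
#'   warning, never clipped.
#' @export
integrated_information <- function(trace, n_windows = 10, bins = 16,
                                   divisor = c("pairs", "windows")) {
  divisor <- match.arg(divisor)
  stopifnot(bins >= 2)
  v <- if (inherits(trace, "voltage_trace")) trace$v else as.numeric(trace)
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("degenerate binning (all mass in one bin); Phi = 0")
    return(0)
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  bin_of <- function(x) pmin(pmax(findInterval(x, edges, all.inside = TRUE),
                                  1L), bins)
  h_whole <- entropy_bits(tabulate(bin_of(v), bins))
  wins <- cut_windows(v, n_windows)
  mis <- vapply(seq_len(n_windows - 1), function(k) {
    a <- bin_of(wins[[k]]); b <- bin_of(wins[[k + 1]])
    joint <- tabulate((a - 1L) * bins + b, bins * bins)
    entropy_bits(tabulate(a, bins)) + entropy_bits(tabulate(b, bins)) -
      entropy_bits(joint)
  }, 0)
  phi <- h_whole - sum(mis) / (if (divisor == "pairs") n_windows - 1 else
    n_windows)
  if (phi < 0) warning("negative Phi estimate (MI average exceeds H)")
  phi
}

#' Bundle the four complexity metrics for one trace
#'
#' Computes LZW complexity, the perturbational complexity index, the
#' integration score and integrated information with a single shared
#' configuration, so labelled systems can be compared and ranked.
#'
#' @param trace A [voltage_trace()].
#' @param n_windows Number of windows (default 10).
#' @param bins Histogram bins for the entropy terms (default 16). Reported
#'   Phi magnitudes depend on both settings, which is why they are explicit
#'   here rather than hidden.
#' @param method Binarization threshold for the compression metrics.
#' @param divisor Pair-average convention, see [integration_score()].
#' @return One-row data frame with `label`, `c_lzw`, `pci`, `integration`,
#'   `phi`, `n_windows`, `bins`.
#' @export
consciousness_report <- function(trace, n_windows = 10, bins = 16,
                                 method = "median", divisor = "pairs") {
  stopifnot(inherits(trace, "voltage_trace"))
  data.frame(label = trace$label,
             c_lzw = lzw_complexity(binarize(trace, method)),
             pci = pci(trace, n_windows, method),
             integration = integration_score(trace, n_windows, divisor),
             phi = integrated_information(trace, n_windows, bins, divisor),
             n_windows = n_windows, bins = bins)
}
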