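---
title: "Methods: electrochemical and information-theoretic analysis of proteinoid protocell signals"
output: html_document
vignette: >
  %\VignetteIndexEntry{Methods: electrochemical and information-theoretic analysis of proteinoid protocell signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoneuro)
```

# Background

Proteinoids — thermal polymers of amino acids — self-assemble in water into
cell-like microspheres that exhibit spontaneous electrical activity:
voltage spikes, slow oscillations and measurable redox chemistry. Doping
these protocells with serotonin (5-HT), and further with the SSRI
paroxetine, changes their electron-transfer kinetics and the statistics of
their spontaneous potential fluctuations. `protoneuro` implements the full
quantitative pipeline used to characterise the three systems — pristine
proteinoid (P), proteinoid–serotonin (PS) and
proteinoid–serotonin–paroxetine (PSP) — from four kinds of raw signal:

1. **Cyclic voltammograms** (potential–current loops over many cycles),
2. **Spontaneous voltage traces** (potential vs time over tens of hours),
3. **Impedance spectra** (complex impedance over $10^{-5}$–$10^{6}$ Hz),
4. **Derived comparisons** (distribution tests, effect sizes, and
   information-theoretic complexity metrics).

Because raw potentiostat recordings are bulky and instrument-specific, the
package ships a synthetic-signal module that generates all three signal
types with the statistical structure the analyses assume. Every analysis
stage is therefore testable end-to-end from code alone.

# Cyclic voltammetry

A voltammogram is segmented into cycles at sweep-direction reversals from
the lower potential limit ([segment_cycles()]). Per cycle the package
computes:

* **Redox peaks**: the anodic peak is the current maximum on the forward
  sweep ($E_{pa}$, $i_{pa} > 0$), the cathodic peak the minimum on the
  reverse sweep ($E_{pc}$, $i_{pc} < 0$). Baseline correction is off by
  default: the analyses this package mirrors used none.
* **Peak separation** $\Delta E_p = E_{pa} - E_{pc}$ (V), the standard
  marker of electron-transfer reversibility (59 mV for an ideal
  one-electron couple).
* **Peak current ratio** $|i_{pa}/i_{pc}|$.
* **Integrated charge** $Q = \int |i|\,dt$ (µC), with time reconstructed
  from the potential program as $dt = |dE|/\nu$ at scan rate $\nu$.
  Integrating $|i|$ gives the total charge passed, which is positive and
  decays over cycling; this choice is configurable in principle but is the
  convention under which per-cycle charge decays exponentially.
* **Charge decay**: $Q(n) = Q_0 e^{-\alpha n}$ fitted by ordinary least
  squares on $\log Q$ — for a pure exponential the log-linear fit is the
  numerically stable choice, and at zero noise it is exact.
* **Reversibility index** $\eta = |i_{pa}/i_{pc}| / \Delta E_p$ (V⁻¹) and
  **electron-transfer efficiency**
  $\epsilon = |i_{pa} \cdot i_{pc}| / \Delta E_p$ (µA²/V), composite
  statistics combining peak currents with peak separation. These forms
  reproduce every published worked value for the three systems (η of
  1.10 and 0.46; ε near 374 µA²/V; enhancements of ~2200% and ~12,295%),
  which is how they were validated.
* **Zero crossings**: $E_{zc}$ is the first zero crossing of the forward
  current after the lower limit (linear interpolation between bracketing
  samples; the first-crossing rule is the documented tie-break when noise
  produces several). $I_{zc}$ is the reverse-sweep current interpolated at
  $E_{zc}$, generally nonzero because of hysteresis.
* **Hysteresis area** $\Delta A$: the absolute shoelace area of the closed
  I–V polygon. Endpoint mismatches under 1% of the loop's extent (one grid
  step, as produced by cycle segmentation) are closed silently; larger
  gaps are closed with a warning.

Summaries over cycles use the mean and sample standard deviation (N − 1).

# Spontaneous spike analysis

Spike detection is deliberately simple and deterministic: local maxima
with **topographic prominence** at least `min_prominence`, thinned to a
minimum pairwise separation by keeping peaks in order of decreasing
prominence. Amplitude is defined as the prominence, not the absolute
height, because baselines drift substantially across activity phases; the
definition also makes detection exactly invariant under potential offsets.
Defaults (2 mV, 60 s) suit sparse spontaneous spiking at rates of order
one per minute; both are explicit arguments because the appropriate
separation is analysis-dependent (reported inter-spike periods range from
seconds to an hour). Note that a spike within one template decay constant
of the recording's end has a truncated flank and an underestimated
prominence; validation against generated ground truth therefore scores the
interior of a trace.

Phase structure is quantified by windowed RMS of the mean-subtracted
signal, either at user-given boundaries or automatically with contiguous
fixed-length windows classified by RMS thresholds. Distribution summaries
report type-7 (linearly interpolated) quartiles and moment statistics with
the $1/n$ central-moment convention: skewness $\gamma = m_3/m_2^{3/2}$ and
**Pearson (non-excess) kurtosis** $\kappa = m_4/m_2^2$, so near-normal
data score $\kappa \approx 3$ — the convention that matches the magnitudes
reported for these systems.

# Distribution comparison

The two-sample Kolmogorov–Smirnov statistic is computed exactly on the
pooled sorted samples; the p-value uses the asymptotic Kolmogorov
distribution at $\sqrt{n_e}\,D$ with $n_e = n_1 n_2/(n_1+n_2)$. At the
sample sizes these comparisons target (hundreds of spikes) the asymptotic
form is adequate; no exact small-sample enumeration is attempted, and no
multiple-testing correction is applied (pairwise p-values are reported
raw). Cohen's d uses the equal-weight pooled SD
$\sqrt{(\sigma_1^2+\sigma_2^2)/2}$ — the form that reproduces the
published amplitude and period effect sizes (0.71 and −1.17) from the
tabulated means and SDs of the PSP and P systems.

# Impedance spectroscopy

The equivalent circuit is the R(RC)(RC) ladder

$$Z(\omega) = R_1 + \frac{R_2}{1 + j\omega R_2 C_1}
                  + \frac{R_3}{1 + j\omega R_3 C_2},$$

with DC limit $R_1+R_2+R_3$ and high-frequency limit $R_1$; its imaginary
part is non-positive at all frequencies. Fitting is complex nonlinear
least squares with **modulus weighting** $w_k = 1/|Z_{obs}(f_k)|$ applied
to real and imaginary residuals — without it the mega-ohm arc would
dominate a spectrum spanning more than four orders of magnitude in |Z|.
Parameters are optimised in log space, which enforces positivity without
box constraints (capacitances span nF–µF). The reported $\chi^2$ is the
weighted residual sum over $2n - 5$; because the original study's
weighting convention is unstated, its printed $\chi^2$ is not a
reproduction target. The two RC branches are interchangeable in the
model, so fits are canonicalised with the faster branch (smaller RC time
constant) reported as $(R_2, C_1)$.

The data-driven initial guess locates arc apexes on the smoothed ratio
$-Z''/|Z|$ (a phase-like quantity on which both arcs stand out even when
one is thousands of times larger), then uses the single-RC geometry
— apex height $R/2$ at $\omega = 1/(RC)$ — to seed each branch, and the
high-frequency $|Z|$ floor to seed $R_1$. Requiring at least a decade
between apex frequencies prevents both picks landing on one arc.

# Complexity metrics

All four metrics operate on data-relative quantities and are invariant
under positive affine transforms of the signal.

* **LZW complexity**: the signal is binarized at its median ('1' above),
  compressed with standard LZW initialised with the alphabet {0, 1}, and
  scored $C_{LZW} = |D(s)|/|s|$, the emitted-phrase count over the signal
  length. Hand-traceable anchor: the 8-symbol constant string compresses
  to 4 phrases, $C = 0.5$. For constant strings the phrase count grows
  like $\sqrt{2n}$, so $C \to 0$; note $C$ is *not* strictly monotone in
  length (it ticks up by $1/n$ each time a new phrase opens), only
  monotone along the triangular lengths $n = m(m+1)/2$.
* **PCI** (compression variant): $C_{whole}$ minus the mean complexity of
  `n_windows` equal windows, each binarized by its own threshold. When
  every window and the whole have equal complexity the index is 0. A
  signal whose binarization is a single repeated symbol carries no
  information at this quantization, and PCI is defined as 0 for it (with
  a warning), mirroring the degenerate-binning rule for Φ. Because short
  windows are intrinsically less compressible per symbol, PCI here is
  typically ≤ 0 on real signals; its absolute scale is not comparable to
  published PCI magnitudes, whose windowing convention is not public.
* **Integration score**: mean zero-lag Pearson correlation of consecutive
  windows over the $N-1$ pairs (the divisor is configurable to $N$;
  pairs is the default since only $N-1$ correlations exist).
* **Integrated information**
  $\Phi = H(X) - \overline{MI}(X_i, X_{i+1})$ in bits: the Shannon
  entropy of the whole-signal histogram (`bins` equal-width bins over the
  data range) minus the mean plug-in mutual information of consecutive
  windows (2-D histogram, same global edges on both axes). A constant
  signal gives $\Phi = 0$. Negative estimates are reported with a
  warning, never clipped.

Defaults `n_windows = 10`, `bins = 16` are explicit arguments of every
entry point: reported Φ magnitudes depend on both, and no windowing
convention is canonical, so absolute Φ values should only be compared
within a fixed configuration. With these defaults the three synthetic
system analogs score Φ in the 1.9–2.5 bit range, the same regime reported
for the laboratory systems.

# The synthetic-data module

`gen_spike_trace()` draws Poisson spike times (optionally thinned by a
refractory interval) with Normal-truncated-at-zero amplitudes, renders
each spike as an instantaneous rise with exponential decay (default 30 s,
matching the asymmetric spike shapes seen in these systems), and adds
Gaussian noise to a per-phase baseline. `gen_voltammogram()` renders
triangular sweeps with Gaussian redox peaks whose amplitudes decay as
$e^{-\alpha(n-1)}$, making the per-cycle charge exactly geometric at zero
noise. `gen_spectrum()` evaluates the R(RC)(RC) model on a log-spaced
grid (11 decades at 12.3 points/decade gives the standard 136-point
sweep) with multiplicative complex Gaussian noise. `gen_burst_trace()`
realises burst-like oscillations as a sinusoid between `v_min` and
`v_max` under a logistic onset envelope with characteristic time `tau`;
the published burst parameters (τ = 200 s, f = 1.8 min⁻¹, 4–16 mV range)
are honoured as contracts on the output rather than through any specific
closed form, which is not public.

`gen_system_trace()` builds P/PS/PSP analogs as baseline oscillation +
Poisson spikes + AR(1) background noise, with per-system parameters fixed
from the reported values: oscillation periods 600/150/300 s (median
inter-event periods 563.6/158.4/310.0 s, rounded so analysis windows hold
integer cycle counts), oscillation amplitudes from the reported potential
ranges (the PS system's 40–45 mV oscillations give half-amplitude 20 mV),
spike rates 0.5 / 1.2 / (0.2→1.8 phased) per minute, spike amplitudes
from the tabulated means and SDs, and backgrounds chosen to match the
described character of each recording — a slow, low-RMS drift for the
stable pristine baseline, rapid high-RMS fluctuation for PS, and an
intermediate level for PSP. Under the default complexity configuration
these analogs reproduce the reported qualitative hierarchies
$C_{LZW}(P) < C_{LZW}(PSP) < C_{LZW}(PS)$ and the matching integration
ordering.

**What the generator does not emulate:** electrode drift and 1/f
instrument noise, the heavy-tailed period outliers behind the very large
reported period kurtosis, amplitude–period dependence, and any
mechanistic (ODE) membrane model. Passing tests therefore demonstrate
correctness of the *analyses* under controlled statistical structure, not
fidelity of the generator to every feature of laboratory recordings.

# Numerical choices and degenerate inputs

* Charge decay is fitted only for strictly positive charges (log fit);
  non-positive charges are an error, not silently dropped.
* `find_redox_peaks()` signals peaks-not-found (NA with warning) when the
  current's peak-to-peak range does not exceed the configured noise floor.
* `peak_ratio`, `reversibility_index` and `transfer_efficiency` return NA
  with a warning at zero denominators; `efficiency_enhancement` errors on
  a non-positive reference.
* Zero-variance windows contribute correlation 0 (with warning) to the
  integration score.
* KS p-values below the $\lambda < 0.2$ regime of the Kolmogorov series
  are reported as exactly 1.
* All generators take an explicit integer seed and are fully
  deterministic given it.

# Problem sizes used in the test and acceptance runs

The shipped test suite and acceptance script exercise the pipeline at
sizes chosen to keep every statistical check well-powered while running in
seconds: 100-cycle voltammograms at 200 points per half-sweep; 136-point
impedance spectra with 50 noisy replicates; $10^4$–$2\times10^4$ s spike
traces at 0.5–1 s sampling; 1000 replicate pairs of n = 500 Normal
samples for the KS size check; and 30,000 s system analogs for the
complexity orderings.

# Limitations

* The CV feature set assumes a single dominant redox couple per sweep;
  multi-peak voltammograms would need peak deconvolution, which is out of
  scope (as are semi-integration, Randles–Ševčík analysis and IR-drop
  correction).
* The impedance model has no constant-phase elements or Warburg
  diffusion; spectra with depressed arcs will fit with biased
  capacitances.
* The complexity metrics are windowing- and binning-dependent by
  construction; only orderings under a fixed configuration are
  meaningful.
* The KS p-value is asymptotic; for very small samples an exact test
  should be preferred.
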