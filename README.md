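# protoneuro

Quantitative analysis of the electrical behaviour of proteinoid
protocells — thermal-protein microspheres that spike, oscillate and carry
redox chemistry — and of their serotonin- and paroxetine-modified
variants.

Proteinoid microspheres doped with the neurotransmitter serotonin (PS) and
further with the SSRI paroxetine (PSP) show markedly different
electrochemistry and spontaneous electrical activity from the pristine
polymer (P). Characterising those differences takes four analysis
families, all implemented here:

* **Cyclic voltammetry** — per-cycle redox features: peak potentials and
  currents, peak separation ΔE_p = E_pa − E_pc, ratio |i_pa/i_pc|,
  integrated charge Q = ∫|i| dt with exponential decay fit
  Q(n) = Q₀e^(−αn), reversibility index η = |i_pa/i_pc|/ΔE_p,
  electron-transfer efficiency ε = |i_pa·i_pc|/ΔE_p, zero crossings
  (E_zc, I_zc) and hysteresis (loop) area.
* **Spike-train statistics** — prominence-based spike detection,
  inter-spike periods, windowed spike frequency, RMS phase segmentation,
  and distribution summaries with type-7 quartiles, skewness and Pearson
  kurtosis.
* **Impedance spectroscopy** — magnitude/phase and Nyquist/Bode
  summaries, and complex nonlinear least-squares fitting of the
  R(RC)(RC) equivalent circuit
  Z(ω) = R₁ + R₂/(1+jωR₂C₁) + R₃/(1+jωR₃C₂)
  with modulus weighting and log-space positivity.
* **Comparison and complexity** — exact two-sample Kolmogorov–Smirnov
  statistic with asymptotic p, Cohen's d (equal-weight pooled SD), and
  four information-theoretic metrics of binarized traces: LZW
  complexity, a perturbational complexity index, a window integration
  score, and integrated information Φ = H(X) − mean MI(Xᵢ, Xᵢ₊₁) in bits.

A synthetic-signal module (`gen_spike_trace`, `gen_voltammogram`,
`gen_spectrum`, `gen_burst_trace`, `gen_system_trace`) generates all
signal types with the statistical structure the analyses assume, so the
entire pipeline runs and is tested without instrument data.

## Worked example

Simulate a 100-cycle voltammogram with 1%/cycle charge decay, extract
per-cycle features and recover the decay constant:

```r
library(protoneuro)

vg <- gen_voltammogram(cv_spec(n_cycles = 100, alpha = 0.01,
                               noise_sd = 0.05), seed = 7)
fx <- cv_features(vg)
summarize_cv(fx)[c(5, 6), ]
#>    feature  mean      sd
#> 5 delta_ep 0.167 0.01413
#> 6    ratio 0.204 0.00444

fit_charge_decay(fx$q)$alpha
#> [1] 0.0094
```

The mean peak separation (0.167 V) recovers the generator's 0.166 V gap
between the anodic (0.30 V) and cathodic (0.134 V) peaks; the decay
constant comes back near the programmed 0.01 (biased slightly low because
noise enters the |i| integral as a positive offset).

Fit the R(RC)(RC) circuit to a noisy synthetic spectrum:

```r
p  <- circuit_params(590.2, 715.9, 0.436e-9, 13.12e6, 3426e-9)
sp <- gen_spectrum(p, 1e-5, 1e6, 12.3, noise_frac = 0.01, seed = 7)
fit_circuit(sp)
#> <circuit_fit> R(RC)(RC)
#>   r1  594.802 Ohm (1.04% err)
#>   r2  712.097 Ohm (0.847% err)
#>   c1  4.36876e-10 F (1.99% err)
#>   r3  1.3162e+07 Ohm (0.174% err)
#>   c2  3.42237e-06 F (0.14% err)
#>   chi2 = 9.591e-05, 7 iterations, converged: TRUE
```

All five parameters come back within ~1% under 1% multiplicative noise
over the 136-point, 11-decade sweep.

Score a serotonin-system analog trace:

```r
tr <- gen_system_trace("PS", seed = 7)
consciousness_report(tr)
#>   label c_lzw     pci integration  phi n_windows bins
#> 1    PS 0.032 -0.0286       0.818 2.42        10   16
```

Here `c_lzw` is the compressibility of the median-binarized trace,
`integration` the mean correlation of consecutive windows, and `phi` the
whole-signal entropy minus the mean mutual information between
consecutive windows (bits). Under the default configuration the three
system analogs rank P < PSP < PS on both LZW complexity and integration.

A thin command-line front end over the same functions lives at
`inst/cli/protoneuro.R`:

```sh
Rscript inst/cli/protoneuro.R simulate cv --seed 3 --out out/
Rscript inst/cli/protoneuro.R cv --in out/cv.csv --scan-rate 0.1 --out out/
Rscript inst/cli/protoneuro.R eis --in spectrum.csv --out out/
```

## Vignette

`vignettes/protoneuro-methods.Rmd` documents the models and their
assumptions, the tunable parameters with units and defaults, what the
synthetic generators do and do not emulate, numerical choices and
degenerate-input behaviour, and known limitations.
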