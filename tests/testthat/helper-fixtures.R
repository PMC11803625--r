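# Shared fixture builders (everything is generated in code; no data files).

# Write a small delimited file to a tempfile and return its path.
write_fixture <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# One synthetic triangular CV cycle with Gaussian redox peaks; returns
# list(e, i) ordered forward sweep then reverse sweep.
gaussian_cycle <- function(e_min = -1.5, e_max = 1.5, epa = 0.3, epc = 0.134,
                           ipa = 3.53, ipc = -17.6, width = 0.1, m = 400) {
  fwd <- seq(e_min, e_max, length.out = m)
  bwd <- rev(fwd)[-1]
  e <- c(fwd, bwd)
  i <- c(ipa * exp(-(fwd - epa)^2 / (2 * width^2)),
         ipc * exp(-(bwd - epc)^2 / (2 * width^2)))
  list(e = e, i = i)
}

# Reference circuit: the magnitudes reported for the fitted R(RC)(RC) model
# (series 590.2 Ohm, 715.9 Ohm // 0.436 nF, 13.12 MOhm // 3426 nF).
ref_circuit <- function() {
  circuit_params(r1 = 590.2, r2 = 715.9, c1 = 0.436e-9,
                 r3 = 13.12e6, c2 = 3426e-9)
}
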