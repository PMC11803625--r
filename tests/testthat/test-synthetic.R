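test_that("generators are deterministic given a seed and vary across seeds", {
  ph <- phase_spec(0, 1000, 1, 10, 2, noise_sd = 0.5)
  a <- gen_spike_trace(ph, dt = 1, seed = 3)
  b <- gen_spike_trace(ph, dt = 1, seed = 3)
  c <- gen_spike_trace(ph, dt = 1, seed = 4)
  expect_identical(a$v, b$v)
  expect_false(identical(a$v, c$v))

  sp1 <- gen_spectrum(ref_circuit(), 1e-2, 1e4, 10, 0.05, seed = 1)
  sp2 <- gen_spectrum(ref_circuit(), 1e-2, 1e4, 10, 0.05, seed = 1)
  expect_identical(sp1$z_re, sp2$z_re)
})

test_that("zero-rate phase yields pure baseline with no detectable spikes", {
  tr <- gen_spike_trace(phase_spec(0, 500, 0, 10, 2, baseline = 3), dt = 1,
                        seed = 1)
  expect_true(all(tr$v == 3))
  expect_length(detect_spikes(tr)$times, 0)
})

test_that("Poisson spike counts and per-phase rates match specification", {
  # single phase at 1.8/min over 10,000 s: mean 300, check within 3 sigma
  tr <- gen_spike_trace(phase_spec(0, 1e4, 1.8, 10, 2), dt = 1, seed = 11)
  n_true <- nrow(attr(tr, "spikes"))
  expect_lt(abs(n_true - 300), 3 * sqrt(300))

  # three phases, rates 0.2 / 1.0 / 1.8: each within 3 sigma Poisson bounds
  phs <- list(phase_spec(0, 1e4, 0.2, 10, 2),
              phase_spec(1e4, 2e4, 1.0, 10, 2),
              phase_spec(2e4, 3e4, 1.8, 10, 2))
  tr3 <- gen_spike_trace(phs, dt = 1, seed = 21)
  truth <- attr(tr3, "spikes")
  for (k in 1:3) {
    lam <- c(0.2, 1.0, 1.8)[k] / 60 * 1e4
    n_k <- sum(truth$time >= (k - 1) * 1e4 & truth$time < k * 1e4)
    expect_lt(abs(n_k - lam), 3 * sqrt(lam))
  }
  expect_error(gen_spike_trace(list(phase_spec(0, 10, 1, 5),
                                    phase_spec(5, 20, 1, 5)), dt = 1),
               "overlap")
})

test_that("spike amplitude moments converge to the specified distribution", {
  # ~1700 spikes: sample mean within 3 standard errors of amp_mean
  tr <- gen_spike_trace(phase_spec(0, 1e5, 1.0, 12, 2), dt = 10, seed = 5)
  a <- attr(tr, "spikes")$amplitude
  expect_gt(length(a), 1000)
  expect_lt(abs(mean(a) - 12), 3 * 2 / sqrt(length(a)))
  expect_lt(abs(sd(a) - 2), 3 * 2 / sqrt(2 * length(a)))
  expect_true(all(a > 0))
})

test_that("burst trace honours range, envelope and dominant period", {
  bs <- burst_spec(v_max = 16.2, v_min = 5.8, tau = 200, freq = 1.8,
                   duration = 4000)
  tr <- gen_burst_trace(bs, dt = 0.5)
  expect_gte(min(tr$v), 5.8 - 1e-9)
  expect_lte(max(tr$v), 16.2 + 1e-9)
  expect_gt(max(tr$v), 16.1)          # peaks reach v_max once the burst is on
  # dominant period ~ 60 / 1.8 = 33.3 s from the spectrum of the active part
  late <- tr$v[tr$t > 1500]
  sp <- Mod(stats::fft(late - mean(late)))[2:(length(late) %/% 2)]
  f_dom <- which.max(sp) / (length(late) * 0.5)
  expect_equal(1 / f_dom, 60 / 1.8, tolerance = 0.05)

  # freq = 0: constant baseline
  flat <- gen_burst_trace(burst_spec(16.2, 5.8, 200, 0, 1000), dt = 1)
  expect_true(all(flat$v == 5.8))

  # doubling v_max - v_min doubles the realized amplitude range
  tr2 <- gen_burst_trace(burst_spec(5.8 + 2 * (16.2 - 5.8), 5.8, 200, 1.8,
                                    4000), dt = 0.5)
  expect_equal(diff(range(tr2$v)), 2 * diff(range(tr$v)), tolerance = 1e-9)
})

test_that("synthetic voltammograms decay geometrically and place peaks", {
  # alpha = 0, no noise: all cycles identical
  vg0 <- gen_voltammogram(cv_spec(alpha = 0, n_cycles = 5, noise_sd = 0))
  per <- length(vg0$e) / 5
  expect_identical(vg0$i[1:per], vg0$i[per + 1:per])

  # charge sequence exactly geometric with ratio exp(-alpha) at zero noise
  vg <- gen_voltammogram(cv_spec(alpha = 0.02, n_cycles = 20, noise_sd = 0))
  fx <- cv_features(vg)
  expect_equal(fx$q[-1] / fx$q[-20], rep(exp(-0.02), 19), tolerance = 1e-10)

  # peak positions: epa 0.3, epc 0.134 recovered within grid resolution
  de <- (1.5 - (-1.5)) / 199
  expect_lt(abs(fx$epa[1] - 0.3), de)
  expect_lt(abs(fx$epc[1] - 0.134), de)
  expect_error(gen_voltammogram(cv_spec(epa0 = 2)), "inside")
})

test_that("spectrum generator spaces frequencies and matches the model", {
  sp <- gen_spectrum(ref_circuit(), 1e-5, 1e6, 12.3, 0)
  expect_length(sp$f, 136)  # 11 decades at 12.3 points/decade
  z <- circuit_impedance(ref_circuit(), sp$f)
  expect_equal(sp$z_re, Re(z))
  expect_equal(sp$z_im, Im(z))
})
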