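test_that("segment_cycles finds triangles and rejects monotone ramps", {
  cyc <- gaussian_cycle(m = 60)
  e3 <- rep(cyc$e[-length(cyc$e)], 3)
  i3 <- rep(cyc$i[-length(cyc$i)], 3)
  vg <- voltammogram(e3, i3, NULL, scan_rate = 0.1)
  seg <- segment_cycles(vg)
  expect_equal(max(seg$cycle), 3)
  expect_equal(length(seg$e), length(e3))

  ramp <- voltammogram(seq(0, 1, length.out = 50), rep(1, 50), NULL, 0.1)
  expect_error(segment_cycles(ramp), "full cycle")
  flat <- voltammogram(rep(c(0, 0), 25), rnorm(50), NULL, 0.1)
  expect_error(segment_cycles(flat), "constant")

  # generator ground truth: a 100-cycle synthetic input gives 100 cycles
  vg100 <- gen_voltammogram(cv_spec(n_cycles = 100, noise_sd = 0),
                            points_per_sweep = 60)
  reseg <- segment_cycles(voltammogram(vg100$e, vg100$i, NULL, 0.1))
  expect_equal(max(reseg$cycle), 100)
})

test_that("find_redox_peaks locates Gaussian peaks and flags flat cycles", {
  cyc <- gaussian_cycle(m = 400)
  pk <- find_redox_peaks(cyc$e, cyc$i)
  de <- 3 / 399
  expect_lt(abs(pk$epa - 0.3), de)
  expect_lt(abs(pk$epc - 0.134), de)
  expect_gt(pk$ipa, 0)
  expect_lt(pk$ipc, 0)

  expect_warning(flat <- find_redox_peaks(cyc$e, rep(0, length(cyc$e))),
                 "flat")
  expect_true(is.na(flat$epa))

  # adding a constant offset current shifts ipa by exactly that offset
  pk2 <- find_redox_peaks(cyc$e, cyc$i + 1.25)
  expect_equal(pk2$ipa, pk$ipa + 1.25)
  expect_equal(pk2$epa, pk$epa)
})

test_that("peak separation and ratio follow their defining arithmetic", {
  expect_equal(peak_separation(0.6, -0.358), 0.958)
  expect_equal(peak_separation(0.3, 0.134), 0.166)
  expect_equal(peak_separation(0.2, 0.2), 0)

  expect_equal(peak_ratio(2.58, -5.86), 2.58 / 5.86)
  expect_equal(peak_ratio(1, 1), 1)
  expect_equal(peak_ratio(3, -4), peak_ratio(3, 4))  # sign irrelevant
  expect_warning(r0 <- peak_ratio(1, 0), "undefined")
  expect_true(is.na(r0))
})

test_that("integrated charge matches rectangle and Gaussian oracles", {
  # constant |i| = 1 uA over a 1 V sweep at 0.1 V/s: 10 s -> 10 uC
  e <- seq(0, 1, length.out = 101)
  expect_equal(integrated_charge(e, rep(1, 101), 0.1), 10)
  expect_equal(integrated_charge(e, rep(0, 101), 0.1), 0)

  # Gaussian peaks: closed-form area |ip| * width * sqrt(2*pi) / scan_rate
  cyc <- gaussian_cycle(m = 2000)
  q_exp <- (3.53 + 17.6) * 0.1 * sqrt(2 * pi) / 0.1
  expect_equal(integrated_charge(cyc$e, cyc$i, 0.1), q_exp,
               tolerance = 0.01)
})

test_that("charge-decay fit recovers exponential parameters", {
  expect_equal(fit_charge_decay(rep(7, 10))$alpha, 0)
  n <- 1:100
  fd <- fit_charge_decay(10 * exp(-0.02 * n), n)
  expect_equal(fd$alpha, 0.02, tolerance = 1e-10)
  expect_equal(fd$q0, 10, tolerance = 1e-8)
  expect_error(fit_charge_decay(c(1, 2, -1, 4, 5)), "positive")
  expect_error(fit_charge_decay(c(1, 2, 3)), "5 cycles")
})

test_that("decay rate is the per-cycle relative change in percent", {
  expect_equal(decay_rate(rep(4, 5)), c(NA, 0, 0, 0, 0))
  expect_equal(decay_rate(c(10, 5)), c(NA, -50))
  r <- 0.9
  g <- 10 * r^(0:9)
  expect_equal(decay_rate(g)[-1], rep((r - 1) * 100, 9))
})

test_that("reversibility, efficiency and enhancement match printed values", {
  # eta = |ipa/ipc| / dEp reproduces the reported system means
  expect_equal(reversibility_index(1.04, -1, 0.947), 1.04 / 0.947)
  expect_equal(round(reversibility_index(1.04, -1, 0.947), 2), 1.10)
  expect_equal(round(reversibility_index(0.44, -1, 0.958), 2), 0.46)
  expect_equal(reversibility_index(2, -1, 0.5), 2 * reversibility_index(1, -1, 0.5))
  expect_warning(e0 <- reversibility_index(1, -1, 0), "undefined")
  expect_true(is.na(e0))

  # epsilon = |ipa*ipc| / dEp in uA^2/V, quadratic in a common current scale
  expect_equal(transfer_efficiency(3.53, -17.6, 0.166), 3.53 * 17.6 / 0.166)
  expect_equal(transfer_efficiency(0, -5, 0.2), 0)
  expect_equal(transfer_efficiency(2 * 3, 2 * -4, 0.5),
               4 * transfer_efficiency(3, -4, 0.5))

  expect_equal(efficiency_enhancement(10, 10), 0)
  expect_equal(efficiency_enhancement(16.23, 373.86), 2203.5, tolerance = 1e-3)
  expect_error(efficiency_enhancement(0, 10), "positive")
})

test_that("zero crossings are interpolated on the forward sweep", {
  # forward i = e - 1.2, retraced on reverse: ezc = 1.2 V, izc = 0
  e <- c(seq(0, 2, length.out = 100), seq(2, 0, length.out = 100)[-1])
  i_sym <- c(seq(0, 2, length.out = 100) - 1.2,
             seq(2, 0, length.out = 100)[-1] - 1.2)
  zc <- zero_crossings(e, i_sym)
  expect_equal(zc$ezc, 1.2, tolerance = 1e-9)
  expect_equal(zc$izc, 0, tolerance = 1e-9)

  # hysteretic loop: reverse branch offset, izc nonzero
  i_hyst <- c(seq(0, 2, length.out = 100) - 1.2,
              seq(2, 0, length.out = 100)[-1] - 1.0)
  zc2 <- zero_crossings(e, i_hyst)
  expect_equal(zc2$ezc, 1.2, tolerance = 1e-9)
  expect_equal(zc2$izc, 0.2, tolerance = 1e-9)

  expect_warning(nozc <- zero_crossings(e, abs(i_sym) + 1), "no zero")
  expect_true(is.na(nozc$ezc))
})

test_that("hysteresis area matches polygon oracles", {
  # retraced line encloses nothing
  e <- c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50))
  expect_equal(hysteresis_area(e, e * 2), 0)
  # 1 V x 2 uA rectangle (closed)
  er <- c(0, 1, 1, 0, 0)
  ir <- c(0, 0, 2, 2, 0)
  expect_equal(hysteresis_area(er, ir), 2)
  # an open loop is closed by joining the endpoints, with a warning
  expect_warning(a_open <- hysteresis_area(er[-5], ir[-5]), "open")
  expect_equal(a_open, 2)
  # ellipse with semi-axes a, b: area pi*a*b within 0.1%
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  expect_equal(hysteresis_area(3 * cos(th), 2 * sin(th)), pi * 6,
               tolerance = 1e-3)
  # area is invariant under a current-axis offset
  expect_equal(hysteresis_area(er, ir + 5), 2)
})

test_that("feature extraction is offset-invariant and deterministic", {
  vg <- gen_voltammogram(cv_spec(n_cycles = 5, noise_sd = 0))
  fx <- cv_features(vg)
  # potential-axis offset leaves dEp unchanged
  vg_off <- voltammogram(vg$e + 0.4, vg$i, vg$cycle, vg$scan_rate)
  fx_off <- cv_features(vg_off)
  expect_equal(fx_off$delta_ep, fx$delta_ep)
  expect_equal(fx_off$hyst_area, fx$hyst_area)
  # bit-identical repeat run
  expect_identical(cv_features(vg), fx)
})

test_that("summaries use sample SD over cycles", {
  vg <- gen_voltammogram(cv_spec(alpha = 0, n_cycles = 4, noise_sd = 0))
  sm <- summarize_cv(cv_features(vg))
  expect_true(all(sm$sd[sm$feature == "delta_ep"] == 0))
  expect_equal(attr(sm, "n_cycles"), 4)

  two <- data.frame(cycle = 1:2, delta_ep = c(0.1, 0.2))
  sm2 <- summarize_cv(two)
  expect_equal(sm2$mean, 0.15)
  expect_equal(sm2$sd, sd(c(0.1, 0.2)))
  expect_error(summarize_cv(two[0, ]), "no cycles")
})
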