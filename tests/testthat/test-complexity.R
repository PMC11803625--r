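test_that("binarization thresholds on data-relative statistics", {
  expect_equal(binarize(voltage_trace(1:4, c(1, 2, 3, 4))), "0011")
  expect_equal(binarize(voltage_trace(1:3, rep(2, 3))), "000")
  v <- rnorm(50)
  expect_equal(binarize(v), binarize(v + 10))       # offset invariance
  expect_equal(binarize(v), binarize(3 * v))        # positive rescale
  expect_equal(binarize(c(1, 2, 3, 10), method = "mean"), "0001")
})

test_that("LZW complexity matches the hand-traced oracle", {
  # "00000000": phrases 0 | 00 | 000 | 00 -> 4 codes over 8 symbols
  expect_equal(lzw_complexity("00000000"), 0.5)
  expect_equal(lzw_complexity("0"), 1)

  # an incompressible string scores above a constant one of equal length
  set.seed(14)
  rand <- paste(sample(c("0", "1"), 1e4, TRUE), collapse = "")
  const <- strrep("0", 1e4)
  expect_gt(lzw_complexity(rand), lzw_complexity(const))

  # constant-string complexity decays with length (phrase growth ~ sqrt(n))
  expect_gt(lzw_complexity(strrep("0", 10)), lzw_complexity(strrep("0", 100)))
  expect_gt(lzw_complexity(strrep("0", 100)),
            lzw_complexity(strrep("0", 1000)))
  # and is exactly non-increasing along the triangular lengths n = m(m+1)/2
  tri <- cumsum(1:20)
  cs <- sapply(tri, function(n) lzw_complexity(strrep("0", n)))
  expect_true(all(diff(cs) <= 0))
})

test_that("PCI is zero for degenerate traces and separates noise from tone", {
  const <- voltage_trace(1:1000, rep(1, 1000))
  expect_warning(p0 <- pci(const), "degenerate")
  expect_equal(p0, 0)

  # concatenation of identical windows: all window complexities equal
  w <- sin(seq(0, 4 * pi, length.out = 200))
  v <- rep(w, 10)
  cw <- sapply(protoneuro:::cut_windows(v, 10),
               function(x) lzw_complexity(binarize(x)))
  expect_true(all(cw == cw[1]))

  # white noise carries higher whole-signal complexity than a sinusoid
  set.seed(15)
  noise <- voltage_trace(1:4000, rnorm(4000))
  tone <- voltage_trace(1:4000, sin((1:4000) / 20))
  expect_gt(lzw_complexity(binarize(noise)), lzw_complexity(binarize(tone)))
})

test_that("integration score reflects window-to-window correlation", {
  # window length equal to the period: consecutive windows identical
  t <- 1:1000
  per <- voltage_trace(t, sin(2 * pi * t / 100))
  expect_equal(integration_score(per, n_windows = 10), 1, tolerance = 1e-9)

  # alternating v / -v windows
  w <- rnorm(100)
  alt <- voltage_trace(1:1000, rep(c(w, -w), 5))
  expect_equal(integration_score(alt, n_windows = 10), -1, tolerance = 1e-9)

  # independent white-noise windows: near zero within 3 SE
  set.seed(16)
  wn <- voltage_trace(1:10000, rnorm(10000))
  expect_lt(abs(integration_score(wn, n_windows = 10)), 3 / sqrt(9 * 1000))

  # zero-variance windows contribute 0 with a warning
  expect_warning(z <- integration_score(rep(1, 100), n_windows = 2),
                 "zero-variance")
  expect_equal(z, 0)
  expect_equal(suppressWarnings(integration_score(rep(1, 100), 5)), 0)
  expect_error(integration_score(per, n_windows = 600), "fewer than 2")
})

test_that("integrated information is zero for constants, ~H for iid noise", {
  expect_warning(phi0 <- integrated_information(rep(2, 400)), "degenerate")
  expect_equal(phi0, 0)

  # iid uniform, 16 bins: H ~ 4 bits and MI between windows ~ 0
  set.seed(17)
  u <- voltage_trace(1:16000, runif(16000))
  phi <- integrated_information(u, n_windows = 10, bins = 16)
  expect_equal(phi, 4, tolerance = 0.3)

  # plug-in MI term is within its information-theoretic bounds on any input
  v <- rnorm(2000)
  wins <- protoneuro:::cut_windows(v, 4)
  edges <- seq(min(v), max(v), length.out = 17)
  bin_of <- function(x) pmin(pmax(findInterval(x, edges, all.inside = TRUE), 1L), 16L)
  for (k in 1:3) {
    a <- bin_of(wins[[k]]); b <- bin_of(wins[[k + 1]])
    ha <- protoneuro:::entropy_bits(tabulate(a, 16))
    hb <- protoneuro:::entropy_bits(tabulate(b, 16))
    hab <- protoneuro:::entropy_bits(tabulate((a - 1L) * 16L + b, 256))
    mi <- ha + hb - hab
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(ha, hb) + 1e-12)
  }
})

test_that("all four metrics are invariant under positive affine transforms", {
  set.seed(18)
  tr <- gen_system_trace("PSP", duration = 5000, dt = 1, seed = 18)
  tr2 <- voltage_trace(tr$t, 2.5 * tr$v + 7, tr$label)
  r1 <- consciousness_report(tr)
  r2 <- consciousness_report(tr2)
  expect_equal(r1$c_lzw, r2$c_lzw)
  expect_equal(r1$pci, r2$pci)
  expect_equal(r1$integration, r2$integration, tolerance = 1e-12)
  expect_equal(r1$phi, r2$phi, tolerance = 1e-9)
})

test_that("reports are deterministic and round-trip through CSV", {
  tr <- gen_system_trace("PS", duration = 5000, dt = 1, seed = 19)
  r1 <- consciousness_report(tr)
  r2 <- consciousness_report(tr)
  expect_identical(r1, r2)

  path <- tempfile(fileext = ".csv")
  write_report(r1, path)
  back <- read_report(path)
  expect_equal(back$phi, r1$phi, tolerance = 1e-9)
  expect_equal(back$c_lzw, r1$c_lzw, tolerance = 1e-9)
})
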