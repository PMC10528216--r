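test_that("chromatogram construction validates its invariants", {
  v <- seq(6, 7, by = 0.1)
  ch <- chromatogram(v, rep(1, length(v)), rep(2, length(v)))
  expect_s3_class(ch, "chromatogram")
  expect_error(chromatogram(c(1, 1, 2), 1:3, 1:3), class = "secmp_domain_error")
  expect_error(chromatogram(c(1, 2, 3), 1:2, 1:3), class = "secmp_domain_error")
  expect_error(chromatogram(c(1, 2, 3), c(1, NaN, 3), 1:3),
               class = "secmp_domain_error")
})

test_that("delimited chromatogram files load, reject and round-trip", {
  f <- write_temp_csv(c("volume_mL,a280_mAU,a260_mAU",
                        "1.0,0.1,0.2", "1.1,0.3,0.4", "1.2,0.5,0.6",
                        "1.3,0.7,0.8", "1.4,0.9,1.0"))
  ch <- load_chromatogram(f)
  expect_length(ch$volume, 5L)
  expect_equal(ch$a260, c(0.2, 0.4, 0.6, 0.8, 1.0))

  # repeated volume value -> invariant rejection
  f2 <- write_temp_csv(c("volume_mL,a280_mAU,a260_mAU",
                         "1.0,0,0", "1.0,0,0"))
  expect_error(load_chromatogram(f2), class = "secmp_domain_error")

  # missing channel named in the error
  f3 <- write_temp_csv(c("volume_mL,a280_mAU", "1.0,0", "1.1,0"))
  expect_error(load_chromatogram(f3), "a260_mAU", class = "secmp_format_error")

  # non-numeric row -> parse error carrying the file line number
  f4 <- write_temp_csv(c("volume_mL,a280_mAU,a260_mAU",
                         "1.0,0,0", "1.1,oops,0"))
  expect_error(load_chromatogram(f4), "line 3", class = "secmp_parse_error")

  # write-then-read equality through the simulator writer
  sim <- gaussian_chrom()
  fp <- tempfile(fileext = ".csv")
  write_chromatogram(sim, fp)
  back <- load_chromatogram(fp)
  expect_equal(back$volume, sim$volume, tolerance = 1e-12)
  expect_equal(back$a280, sim$a280, tolerance = 1e-12)
  expect_equal(back$a260, sim$a260, tolerance = 1e-12)
})

test_that("baseline subtraction is exact, linear, and anchor-checked", {
  ch <- gaussian_chrom()
  # constant zero baseline is the identity
  expect_equal(subtract_baseline(ch, baseline_spec())$a280, ch$a280)

  # a trace that IS the anchor line maps to zero
  v <- seq(6, 10, by = 0.01)
  line <- 2 + 0.5 * (v - 6)
  ch2 <- chromatogram(v, line, line)
  spec <- baseline_spec(a280 = c(6.5, 2 + 0.5 * 0.5, 9.5, 2 + 0.5 * 3.5),
                        a260 = c(6.5, 2 + 0.5 * 0.5, 9.5, 2 + 0.5 * 3.5))
  out <- subtract_baseline(ch2, spec)
  expect_equal(max(abs(out$a280)), 0, tolerance = 1e-12)
  expect_equal(max(abs(out$a260)), 0, tolerance = 1e-12)

  # drift-laden Gaussian: anchors on the drift recover the drift-free area
  area <- 10
  clean <- gaussian_chrom(area280 = area, area260 = area, drift = 0)
  drifted <- gaussian_chrom(area280 = area, area260 = area, drift = 0.7)
  anchors <- c(6.4, 0.7 * 0.4, 10.6, 0.7 * 4.6)
  corr <- subtract_baseline(drifted, baseline_spec(a280 = anchors, a260 = anchors))
  win <- peak_window(8.6 - 0.5, 8.6 + 0.5)
  expect_equal(integrate_peak(corr, win)$A280_int,
               integrate_peak(clean, win)$A280_int, tolerance = 1e-9)

  # linearity: spec1 then spec2 == pointwise-summed spec
  s1 <- baseline_spec(a280 = c(6.5, 1, 9.5, 2), a260 = 0.5)
  s2 <- baseline_spec(a280 = c(6.5, -0.5, 9.5, 1), a260 = c(6.5, 0, 9.5, 1))
  seq_ch <- subtract_baseline(subtract_baseline(ch2, s1), s2)
  sum_spec <- baseline_spec(a280 = c(6.5, 0.5, 9.5, 3),
                            a260 = c(6.5, 0.5, 9.5, 1.5))
  one_ch <- subtract_baseline(ch2, sum_spec)
  expect_equal(seq_ch$a280, one_ch$a280, tolerance = 1e-12)
  expect_equal(seq_ch$a260, one_ch$a260, tolerance = 1e-12)

  # anchors outside the grid are a domain error
  expect_error(subtract_baseline(ch2, baseline_spec(a280 = c(5, 0, 9, 0))),
               class = "secmp_domain_error")
})

test_that("estimate_baseline recovers a linear drift from signal-free regions", {
  ch <- gaussian_chrom(drift = 0.5)
  clean <- gaussian_chrom(drift = 0)
  spec <- estimate_baseline(ch, 6.4, 10.6)
  corr <- subtract_baseline(ch, spec)
  win <- peak_window(8.1, 9.1)
  expect_equal(integrate_peak(corr, win)$A280_int,
               integrate_peak(clean, win)$A280_int, tolerance = 1e-7)
})

test_that("peak integration matches closed-form oracles", {
  # zero trace -> (0, 0)
  v <- seq(6, 10, by = 0.01)
  z <- chromatogram(v, rep(0, length(v)), rep(0, length(v)))
  pk0 <- integrate_peak(z, peak_window(7, 8))
  expect_identical(c(pk0$A280_int, pk0$A260_int), c(0, 0))

  # constant 2 mAU over 1.5 mL -> 3.0 mAU*mL (rectangle)
  const <- chromatogram(v, rep(2, length(v)), rep(2, length(v)))
  pk1 <- suppressWarnings(integrate_peak(const, peak_window(7, 8.5)))
  expect_equal(pk1$A280_int, 3.0, tolerance = 1e-12)

  # Gaussian peak of known area, apex +/- 5 sigma window, 0.002 mL grid
  g <- gaussian_chrom(area280 = 10, area260 = 10, sigma = 0.1, by = 0.002)
  pk2 <- integrate_peak(g, peak_window(8.6 - 0.5, 8.6 + 0.5))
  expect_equal(pk2$A280_int, 10, tolerance = 1e-4)

  # window edges between grid points are interpolated, not snapped
  pk3 <- suppressWarnings(integrate_peak(const, peak_window(7.0051, 8.0051)))
  expect_equal(pk3$A280_int, 2.0, tolerance = 1e-9)

  # window fully outside the grid is a domain error
  expect_error(integrate_peak(const, peak_window(11, 12)),
               class = "secmp_domain_error")
})

test_that("integration is additive over adjacent windows", {
  g <- gaussian_chrom(area280 = 7, area260 = 3)
  # splitting at the apex triggers the edge-residual warning by design
  a <- suppressWarnings(integrate_peak(g, peak_window(7.9, 8.6)))
  b <- suppressWarnings(integrate_peak(g, peak_window(8.6, 9.3)))
  whole <- integrate_peak(g, peak_window(7.9, 9.3))
  expect_equal(a$A280_int + b$A280_int, whole$A280_int, tolerance = 1e-12)
  expect_equal(a$A260_int + b$A260_int, whole$A260_int, tolerance = 1e-12)
})

test_that("trapezoid error shrinks under grid refinement", {
  err_at <- function(by) {
    g <- gaussian_chrom(area280 = 10, area260 = 10, sigma = 0.1, by = by)
    abs(integrate_peak(g, peak_window(8.6 - 0.5, 8.6 + 0.5))$A280_int - 10)
  }
  expect_lt(err_at(0.002), err_at(0.02))
})

test_that("integration warns when the trace is not at baseline at the edges", {
  v <- seq(6, 10, by = 0.01)
  const <- chromatogram(v, rep(2, length(v)), rep(0, length(v)))
  expect_warning(integrate_peak(const, peak_window(7, 8)),
                 class = "secmp_integration_warning")
  expect_silent(integrate_peak(const, peak_window(7, 8), edge_tol = 5))
})

test_that("suggest_boundaries brackets isolated peaks and rejects monotone traces", {
  # single isolated Gaussian: suggested window holds >= 99% of its area
  g <- gaussian_chrom(area280 = 10, area260 = 0, sigma = 0.1)
  win <- suggest_boundaries(g, peak_window(7, 10))
  pk <- integrate_peak(g, win)
  expect_gte(pk$A280_int, 0.99 * 10)

  # two separated Gaussians: window over the taller excludes >= 95% of the other
  v <- seq(6, 11, by = 0.002)
  tall <- 10 * dnorm(v, 8.5, 0.1); small <- 5 * dnorm(v, 9.3, 0.1)
  two <- chromatogram(v, tall + small, rep(0, length(v)))
  win2 <- suggest_boundaries(two, peak_window(8, 9.6))
  other_inside <- integrate_peak(
    chromatogram(v, small, rep(0, length(v))), win2)$A280_int
  expect_lte(other_inside, 0.05 * 5)

  # monotone trace has no apex
  mono <- chromatogram(v, v, v)
  expect_error(suggest_boundaries(mono, peak_window(7, 10)),
               class = "secmp_not_found_error")
})
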