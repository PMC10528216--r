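test_that("MP event files load, convert units and report parse errors", {
  f <- write_temp_csv(c("mass_kDa", as.character(seq(3500, 5300, by = 200))))
  run <- load_mp_events(f)
  expect_s3_class(run, "mp_run")
  expect_length(run$masses, 10L)

  # MDa column converts to kDa on load
  f2 <- write_temp_csv(c("mass_MDa", "3.76", "4.60"))
  expect_equal(load_mp_events(f2)$masses, c(3760, 4600))

  # header but no events
  f3 <- write_temp_csv("mass_kDa")
  expect_error(load_mp_events(f3), class = "secmp_format_error")

  # non-numeric row carries its line number
  f4 <- write_temp_csv(c("mass_kDa", "3500", "n/a"))
  expect_error(load_mp_events(f4), "line 3", class = "secmp_parse_error")

  # round trip through the simulator writer
  run2 <- mp_run(c(3500.25, 4600.5, 5100.75))
  fp <- tempfile(fileext = ".csv")
  write_mp_events(run2, fp)
  expect_equal(load_mp_events(fp)$masses, run2$masses, tolerance = 1e-12)
})

test_that("histogram counts are conservative and bin edges unambiguous", {
  # empty range overlap -> all-zero bins
  run <- mp_run(c(100, 200))
  h0 <- mp_histogram(run, 25, mass_window(3000, 6000))
  expect_true(all(h0$counts == 0))

  # conservation against direct enumeration on random runs
  set.seed(11)
  for (i in 1:20) {
    r <- mp_run(runif(500, 2000, 7000))
    h <- mp_histogram(r, 25, mass_window(3000, 6000))
    expect_identical(sum(h$counts),
                     sum(r$masses >= 3000 & r$masses <= 6000))
  }

  # an event exactly on an interior bin edge lands in exactly one bin
  r2 <- mp_run(3050)  # edge between bins [3025,3050) and [3050,3075)
  h2 <- mp_histogram(r2, 25, mass_window(3000, 6000))
  expect_identical(sum(h2$counts), 1L)
  expect_identical(h2$counts[h2$mids == 3062.5], 1L)
})

test_that("Gaussian peak fitting recovers single and mixed populations", {
  nm <- noise_model(mp_sd = 135, seed = 101)
  one <- simulate_mp_events(
    species_mix("empty", TRUE, 3760, 0, 1e12, 8.6, 0.2), 10000, nm)
  fits <- detect_and_fit_peaks(one)
  expect_length(fits, 1L)
  se <- 135 / sqrt(10000)
  expect_lt(abs(fits[[1L]]$mu - 3760), 3 * se)
  expect_lt(abs(fits[[1L]]$sigma - 135), 0.1 * 135)
  expect_true(is_homogeneous(fits[[1L]]))

  # 50/50 mixture of the empty (3.76 MDa) and full (4.60 MDa) populations
  mix <- species_mix(c("empty", "full"), TRUE, c(3760, 4600), c(0, 8.4e5),
                     c(1e12, 1e12), 8.6, 0.2)
  nm2 <- noise_model(mp_sd = 120, seed = 102)
  two <- simulate_mp_events(mix, 10000, nm2)
  fits2 <- detect_and_fit_peaks(two)
  expect_length(fits2, 2L)
  se2 <- 120 / sqrt(5000)
  expect_lt(abs(fits2[[1L]]$mu - 3760), 3 * se2)
  expect_lt(abs(fits2[[2L]]$mu - 4600), 3 * se2)

  # uniform mass distribution yields no accepted peak
  set.seed(103)
  flat <- mp_run(runif(10000, 3000, 6000))
  expect_length(detect_and_fit_peaks(flat), 0L)

  # too few events in the search window
  expect_error(detect_and_fit_peaks(mp_run(rep(4000, 10))),
               class = "secmp_insufficient_data_error")
})

test_that("fitted parameters converge toward truth with event count", {
  err <- function(n, seed) {
    r <- simulate_mp_events(species_mix("s", TRUE, 4600, 8.4e5, 1e12, 8.6, 0.2),
                            n, noise_model(mp_sd = 110, seed = seed))
    f <- detect_and_fit_peaks(r)[[1L]]
    c(abs(f$mu - 4600), abs(f$sigma - 110))
  }
  e1k <- rowMeans(vapply(1:10, function(s) err(1000, s), numeric(2L)))
  e10k <- rowMeans(vapply(1:10, function(s) err(10000, 100 + s), numeric(2L)))
  expect_lt(e10k[1L], e1k[1L])
  expect_lt(e10k[2L], e1k[2L])
})

test_that("homogeneity threshold is inclusive at its boundary", {
  f <- function(s) list(mu = 4600, sigma = s, converged = TRUE)
  expect_true(is_homogeneous(f(135)))
  expect_true(is_homogeneous(f(110)))
  expect_true(is_homogeneous(f(150)))
  expect_false(is_homogeneous(f(150.1)))
  expect_false(is_homogeneous(list(mu = 1, sigma = 50, converged = FALSE)))
})

test_that("windowed counting matches hand enumeration and brute force", {
  masses <- c(3500, 4000, 5200, 5300, 5350, 6500, 2000, 5000, 4900, 5120)
  run <- mp_run(masses)
  expect_identical(count_in_window(run, mass_window(5100, 5400)), 4L)
  expect_identical(count_in_window(run, mass_window(3000, 6000)), 8L)
  expect_identical(count_in_window(mp_run(c(1, 2)), mass_window(5100, 5400)), 0L)

  # oracle equivalence on random runs: loop-based enumeration
  set.seed(7)
  for (i in 1:50) {
    m <- runif(200, 1000, 8000)
    lo <- runif(1, 2000, 5000); hi <- lo + runif(1, 100, 2000)
    brute <- 0L
    for (x in m) if (x >= lo && x <= hi) brute <- brute + 1L
    expect_identical(count_in_window(mp_run(m), mass_window(lo, hi)), brute)
  }
})

test_that("fraction_full builds the theoretical-mass window and is count-exact", {
  masses <- c(3500, 4000, 5200, 5300, 5350, 6500, 2000, 5000, 4900, 5120)
  run <- mp_run(masses)
  ff <- fraction_full(run, m_theory = 5250)
  expect_equal(ff$fraction, 4 / 8)
  # theoretical mass 5.25 MDa with the default 150 kDa half-width
  expect_equal(ff$counts$full_window$lo, 5100)
  expect_equal(ff$counts$full_window$hi, 5400)
  expect_identical(ff$counts$n_full, 4L)
  expect_identical(ff$counts$n_total, 8L)

  # all events at the theoretical mass
  expect_equal(fraction_full(mp_run(rep(5250, 20)), 5250)$fraction, 1.0)

  # invariant under shuffling and under events outside the total window
  set.seed(9)
  shuffled <- mp_run(sample(masses))
  expect_equal(fraction_full(shuffled, 5250)$fraction, 0.5)
  padded <- mp_run(c(masses, 100, 250, 9000, 15000))
  expect_equal(fraction_full(padded, 5250)$fraction, 0.5)

  # errors: no events in total window; full window not nested
  expect_error(fraction_full(mp_run(c(100, 200)), 5250),
               class = "secmp_insufficient_data_error")
  expect_error(fraction_full(run, 5950, half_width = 150),
               class = "secmp_domain_error")
})

test_that("replicate summaries use the sample (n-1) standard deviation", {
  expect_equal(replicate_summary(c(0.5, 0.5, 0.5)),
               list(mean = 0.5, sd = 0.0, n = 3L))
  rs <- replicate_summary(c(0.1, 0.2))
  expect_equal(rs$mean, 0.15)
  expect_equal(rs$sd, 0.07071068, tolerance = 1e-6)
  one <- replicate_summary(0.3)
  expect_equal(one$mean, 0.3)
  expect_true(is.na(one$sd))
  expect_error(replicate_summary(numeric()), class = "secmp_domain_error")
})

test_that("genome mass from the MP peak separation matches the sequence value", {
  full <- list(mu = 4600, sigma = 110, converged = TRUE)
  empty <- list(mu = 3760, sigma = 135, converged = TRUE)
  expect_equal(genome_mass_from_peaks(full, empty), 840000)
  # consistent with the 2763 nt sequence-derived mass at display precision
  expect_equal(signif(genome_mass_from_peaks(full, empty) / 1e6, 2),
               signif(ssdna_mass(2763) / 1e6, 2))
  expect_error(genome_mass_from_peaks(empty, empty), class = "secmp_domain_error")

  # recovery from a simulated two-species sample within 3 SE of each mean
  mix <- species_mix(c("e", "f"), TRUE, c(3760, 4600), c(0, 8.4e5),
                     c(1e12, 1e12), 8.6, 0.2)
  run <- simulate_mp_events(mix, 10000, noise_model(mp_sd = 120, seed = 77))
  fits <- detect_and_fit_peaks(run)
  est <- genome_mass_from_peaks(fits[[2L]], fits[[1L]])
  se <- 120 / sqrt(5000) * sqrt(2) * 1000  # Da
  expect_lt(abs(est - 840000), 3 * se)
})
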