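#' Mass-photometry single-particle run
#'
#' One MP acquisition reduced to its per-particle mass estimates (kDa), one
#' entry per landing event. The instrument's working range for AAV analysis
#' is roughly 3-6 MDa; masses outside 0-20 MDa are retained (filtering is
#' the counters' job) but flagged in `meta$n_outlandish`.
#'
#' @param masses Numeric vector of event masses (kDa); must be finite and
#'   non-empty.
#' @param meta Optional named list of acquisition annotations.
#' @return An object of class `"mp_run"`.
#' @export
mp_run <- function(masses, meta = list()) {
  masses <- as.numeric(masses)
  if (!length(masses))
    secmp_stop("insufficient_data", "an MP run must contain at least one event")
  if (any(!is.finite(masses)))
    secmp_stop("domain", "event masses must be finite")
  n_out <- sum(masses < 0 | masses > 20000)
  meta <- as.list(meta)
  if (n_out > 0) {
    message(n_out, " event(s) outside 0-20 MDa kept but flagged")
    meta$n_outlandish <- n_out
  }
  structure(list(masses = masses, meta = meta), class = "mp_run")
}

#' @export
print.mp_run <- function(x, ...) {
  cat(sprintf("MP run: %d events, median mass %.3g kDa\n",
              length(x$masses), stats::median(x$masses)))
  invisible(x)
}

#' @export
plot.mp_run <- function(x, bin_width = 25, range = mass_window(3000, 6000),
                        fits = NULL, ...) {
  h <- mp_histogram(x, bin_width = bin_width, range = range)
  graphics::plot(h$mids, h$counts, type = "h", lwd = 2, col = "grey40",
                 xlab = "mass (kDa)", ylab = "particle count", ...)
  if (!is.null(fits)) {
    xs <- seq(range$lo, range$hi, length.out = 400L)
    for (f in fits) {
      if (!isTRUE(f$converged)) next
      graphics::lines(xs, f$count * bin_width *
                        stats::dnorm(xs, f$mu, f$sigma), col = "blue")
    }
  }
  invisible(x)
}

#' Closed mass window (kDa)
#'
#' Mass windows are closed intervals `[lo, hi]`: an event sitting exactly on
#' a boundary (e.g. at 5.40 MDa for the 5.10-5.40 MDa full-particle window)
#' counts as inside.
#'
#' @param lo,hi Window bounds in kDa, `lo < hi`.
#' @return An object of class `"mass_window"`.
#' @export
mass_window <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    secmp_stop("domain", "mass window requires lo < hi (got %.4g, %.4g)", lo, hi)
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)), class = "mass_window")
}

#' Load MP events from a delimited text file
#'
#' One measured mass per row under a single mass column; the unit is read
#' from the column name (`mass_kDa` or `mass_MDa`; MDa values are converted
#' to kDa on load). `#` lines are comments.
#'
#' @param path Path to the file.
#' @param column Mass column name; `NULL` accepts `mass_kDa` or `mass_MDa`.
#' @return A validated [mp_run()].
#' @export
load_mp_events <- function(path, column = NULL) {
  tab <- read_delim_chr(path, sep = NULL)
  if (!length(tab$rows))
    secmp_stop("format", "'%s' contains a header but no events", path)
  col <- column %||% intersect(c("mass_kDa", "mass_MDa"), tab$header)[1L]
  if (is.na(col) || is.null(col) || !col %in% tab$header)
    secmp_stop("format", "'%s' has no recognised mass column (mass_kDa or mass_MDa)",
               path)
  masses <- num_col(tab, col, path)
  if (identical(col, "mass_MDa")) masses <- masses * 1000
  mp_run(masses, meta = list(source = path, unit_column = col))
}

#' Histogram of an MP run
#'
#' Bins of width `bin_width` spanning `range`; interior bins are half-open
#' `[b_i, b_{i+1})` and the final bin is closed so that the total count
#' equals the number of events inside the (closed) range.
#'
#' @param run An [mp_run()].
#' @param bin_width Bin width in kDa.
#' @param range A [mass_window()].
#' @return List with `breaks`, `mids`, `counts`.
#' @export
mp_histogram <- function(run, bin_width = 25, range = mass_window(3000, 6000)) {
  stopifnot(inherits(run, "mp_run"), inherits(range, "mass_window"))
  stopifnot_scalar_pos(bin_width, "bin_width")
  nb <- max(1L, ceiling((range$hi - range$lo) / bin_width - 1e-9))
  breaks <- range$lo + (0:nb) * bin_width
  m <- run$masses[run$masses >= range$lo & run$masses <= range$hi]
  idx <- pmin(nb, floor((m - range$lo) / bin_width) + 1L)
  counts <- tabulate(idx, nbins = nb)
  list(breaks = breaks, mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
       counts = counts)
}

# Topographic prominence of local maxima in a numeric series.
local_modes <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  idx <- which(vapply(2:(n - 1L), function(i)
    y[i] > y[i - 1L] && y[i] >= y[i + 1L], logical(1L))) + 1L
  idx
}

mode_prominence <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    higher_l <- which(y[seq_len(i - 1L)] > h)
    lo_l <- if (length(higher_l)) min(y[(max(higher_l) + 1L):(i - 1L)]) else min(y[seq_len(i)])
    after <- if (i < length(y)) y[(i + 1L):length(y)] else numeric()
    higher_r <- which(after > h)
    lo_r <- if (length(higher_r)) min(after[seq_len(min(higher_r) - 1L)]) else min(c(h, after))
    h - max(lo_l, lo_r)
  }, numeric(1L))
}

#' Detect and fit Gaussian peaks in an MP mass distribution
#'
#' Mode detection runs on a histogram (default 25 kDa bins, resolving the
#' 110-150 kDa widths typical of homogeneous AAV peaks with >= 4 bins per
#' sigma) smoothed by a 3-bin moving average; a mode is accepted when its
#' topographic prominence exceeds both a fraction of the tallest mode and a
#' Poisson-scale floor, so a flat (uniform) distribution yields no peaks.
#' Each accepted mode is then fit by least squares with a single Gaussian on
#' the *unsmoothed* histogram within mode +/- 3 provisional sigmas
#' (provisional sigma from the smoothed half-maximum width). Fits that fail
#' to converge are returned flagged, not dropped silently, and never crash
#' the caller.
#'
#' @param run An [mp_run()].
#' @param search A [mass_window()] to analyse (default 3-6 MDa).
#' @param max_peaks Keep at most this many modes, by decreasing prominence
#'   (prominence ties break toward lower mass).
#' @param bin_width Histogram bin width (kDa).
#' @param min_events Minimum events inside `search` (insufficient-data error
#'   below this floor).
#' @param prominence_frac,prominence_sds Acceptance thresholds: prominence
#'   must exceed `max(prominence_frac * tallest, prominence_sds * sqrt(tallest))`.
#' @return An object of class `"mp_peakfit"`: a list of per-peak fits
#'   (fields `mu`, `sigma`, `count`, `fit_window`, `goodness`, `converged`),
#'   sorted by `mu`, with the event count and search window as attributes.
#' @export
detect_and_fit_peaks <- function(run, search = mass_window(3000, 6000),
                                 max_peaks = 6L, bin_width = 25,
                                 min_events = 50L,
                                 prominence_frac = 0.10, prominence_sds = 4) {
  stopifnot(inherits(run, "mp_run"), inherits(search, "mass_window"))
  n_in <- count_in_window(run, search)
  if (n_in < min_events)
    secmp_stop("insufficient_data",
               "only %d events in %.0f-%.0f kDa (floor %d)",
               n_in, search$lo, search$hi, min_events)
  h <- mp_histogram(run, bin_width = bin_width, range = search)
  sm <- stats::filter(h$counts, rep(1 / 3, 3L), sides = 2L)
  sm <- ifelse(is.na(sm), h$counts, as.numeric(sm))
  modes <- local_modes(sm)
  fits <- list()
  if (length(modes)) {
    prom <- mode_prominence(sm, modes)
    thr <- max(prominence_frac * max(sm), prominence_sds * sqrt(max(sm)))
    keep <- prom >= thr
    modes <- modes[keep]; prom <- prom[keep]
    if (length(modes) > max_peaks) {
      ord <- order(-prom, h$mids[modes])  # ties toward lower mass
      modes <- sort(modes[ord[seq_len(max_peaks)]])
    }
    fits <- lapply(modes, function(i)
      fit_one_gaussian(h, i, search, bin_width))
    fits <- fits[order(vapply(fits, `[[`, numeric(1L), "mu"))]
  }
  structure(fits, class = "mp_peakfit", n_events = n_in, search = search,
            bin_width = bin_width, histogram = h)
}

# Provisional sigma from the half-maximum width around mode index i.
provisional_sigma <- function(y, mids, i, bin_width) {
  half <- y[i] / 2
  l <- i; while (l > 1L && y[l] > half) l <- l - 1L
  r <- i; while (r < length(y) && y[r] > half) r <- r + 1L
  s <- (mids[r] - mids[l]) / 2.355
  max(s, bin_width)
}

fit_one_gaussian <- function(h, i, search, bin_width) {
  s0 <- provisional_sigma(h$counts, h$mids, i, bin_width)
  mu0 <- h$mids[i]
  sel <- h$mids >= mu0 - 3 * s0 & h$mids <= mu0 + 3 * s0
  df <- data.frame(x = h$mids[sel], y = h$counts[sel])
  win <- mass_window(max(search$lo, mu0 - 3 * s0), min(search$hi, mu0 + 3 * s0))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                      start = list(a = max(df$y), mu = mu0, s = s0),
                      lower = c(a = 0, mu = win$lo, s = bin_width / 4),
                      upper = c(a = Inf, mu = win$hi, s = (search$hi - search$lo))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(mu = mu0, sigma = s0, count = NA_real_, fit_window = win,
                goodness = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(mu = unname(cf[["mu"]]), sigma = unname(cf[["s"]]),
       count = unname(cf[["a"]] * cf[["s"]] * sqrt(2 * pi) / bin_width),
       fit_window = win,
       goodness = sqrt(mean(stats::residuals(fit)^2)) / max(df$y),
       converged = TRUE)
}

#' @export
print.mp_peakfit <- function(x, sigma_max = 150, ...) {
  cat(sprintf("MP peak fits (%d events in %.0f-%.0f kDa):\n",
              attr(x, "n_events"), attr(x, "search")$lo, attr(x, "search")$hi))
  if (!length(x)) cat("  no accepted peaks (flat or featureless distribution)\n")
  for (f in x) {
    if (isTRUE(f$converged))
      cat(sprintf("  mu = %.0f kDa, sigma = %.0f kDa, ~%.0f particles%s\n",
                  f$mu, f$sigma, f$count,
                  if (is_homogeneous(f, sigma_max)) " [homogeneous]" else ""))
    else
      cat(sprintf("  mode near %.0f kDa: fit did not converge\n", f$mu))
  }
  invisible(x)
}

#' Is a fitted MP peak homogeneous?
#'
#' A population is called homogeneous (single well-packaged species) when
#' the fitted mass standard deviation does not exceed `sigma_max`; the
#' boundary value itself passes (<=, not <).
#'
#' @param fit A single peak fit from [detect_and_fit_peaks()].
#' @param sigma_max Homogeneity threshold in kDa (default 150).
#' @return Logical.
#' @export
is_homogeneous <- function(fit, sigma_max = 150) {
  if (!is.list(fit) || is.null(fit$sigma))
    secmp_stop("domain", "fit must be a single peak fit with a sigma field")
  isTRUE(fit$converged) && fit$sigma <= sigma_max
}

#' Count events inside a closed mass window
#'
#' @param run An [mp_run()].
#' @param window A [mass_window()].
#' @return Integer count of events with `lo <= mass <= hi`.
#' @export
count_in_window <- function(run, window) {
  stopifnot(inherits(run, "mp_run"), inherits(window, "mass_window"))
  sum(run$masses >= window$lo & run$masses <= window$hi)
}

#' Fraction of fully packaged particles by windowed counting
#'
#' Counts events within `m_theory +/- half_width` (the expected full-virion
#' mass, e.g. 5.25 MDa giving the 5.10-5.40 MDa window at the default
#' half-width) against all events in the `total` window (default 3-6 MDa,
#' the AAV monomer range), and returns their ratio — the counting estimate
#' of %full used when the population is heterogeneous.
#'
#' @param run An [mp_run()].
#' @param m_theory Theoretical full-particle mass (kDa).
#' @param half_width Half-width of the full window (kDa, default 150).
#' @param total Total-particle [mass_window()].
#' @return List with `fraction` and `counts` (class `"window_counts"`:
#'   `n_full`, `n_total`, `full_window`, `total_window`).
#' @export
fraction_full <- function(run, m_theory, half_width = 150,
                          total = mass_window(3000, 6000)) {
  stopifnot(inherits(run, "mp_run"), inherits(total, "mass_window"))
  stopifnot_scalar_pos(m_theory, "m_theory")
  stopifnot_scalar_pos(half_width, "half_width")
  full <- mass_window(m_theory - half_width, m_theory + half_width)
  if (full$lo < total$lo || full$hi > total$hi)
    secmp_stop("domain",
               "full window [%.0f, %.0f] is not nested in total window [%.0f, %.0f] kDa",
               full$lo, full$hi, total$lo, total$hi)
  n_total <- count_in_window(run, total)
  if (n_total < 1L)
    secmp_stop("insufficient_data", "no events in the total window %.0f-%.0f kDa",
               total$lo, total$hi)
  n_full <- count_in_window(run, full)
  counts <- structure(list(n_full = n_full, n_total = n_total,
                           full_window = full, total_window = total),
                      class = "window_counts")
  list(fraction = n_full / n_total, counts = counts)
}

#' Mean and SD of replicate %full measurements
#'
#' @param fractions Numeric vector of replicate fractions (>= 1).
#' @return List with `mean`, `sd` (sample SD, n-1 denominator; `NA` for a
#'   single replicate) and `n`.
#' @export
replicate_summary <- function(fractions) {
  fractions <- as.numeric(fractions)
  if (!length(fractions))
    secmp_stop("domain", "at least one replicate is required")
  if (any(!is.finite(fractions)))
    secmp_stop("domain", "replicate fractions must be finite")
  list(mean = mean(fractions),
       sd = if (length(fractions) >= 2L) stats::sd(fractions) else NA_real_,
       n = length(fractions))
}

#' Genome mass from the full-empty MP peak separation
#'
#' The mass difference between the fully packaged and the empty capsid peak
#' is the encapsidated genome mass, providing an MP-only route to M_genome
#' that can be cross-checked against the vector-sequence value.
#'
#' @param full_fit,empty_fit Peak fits from [detect_and_fit_peaks()];
#'   `full_fit$mu` must exceed `empty_fit$mu`.
#' @return Genome mass in Da.
#' @export
genome_mass_from_peaks <- function(full_fit, empty_fit) {
  if (is.null(full_fit$mu) || is.null(empty_fit$mu))
    secmp_stop("domain", "peak fits must carry a mu field")
  d <- full_fit$mu - empty_fit$mu
  if (d <= 0)
    secmp_stop("domain",
               "full peak (%.0f kDa) must be heavier than empty peak (%.0f kDa)",
               full_fit$mu, empty_fit$mu)
  d * 1000
}
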