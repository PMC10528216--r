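#' Dual-wavelength SEC-UV chromatogram
#'
#' Container for a size-exclusion chromatogram recorded simultaneously at
#' 280 nm and 260 nm. The elution axis is in millilitres; both absorbance
#' traces are in milli-absorbance units (mAU). Only the 280/260 nm channel
#' pair is represented: those two wavelengths carry the protein- and
#' DNA-dominated signals on which the capsid/DNA deconvolution rests.
#'
#' @param volume Strictly increasing numeric vector of elution volumes (mL).
#' @param a280,a260 Absorbance traces (mAU), same length as `volume`.
#' @param meta Optional named list of acquisition annotations (column id,
#'   flow rate, seed of a simulation, ...).
#'
#' @return An object of class `"chromatogram"`: a list with elements
#'   `volume`, `a280`, `a260`, `meta`.
#' @examples
#' v <- seq(6, 12, by = 0.01)
#' ch <- chromatogram(v, a280 = exp(-(v - 8.6)^2 / 0.05),
#'                    a260 = 0.7 * exp(-(v - 8.6)^2 / 0.05))
#' ch
#' @export
chromatogram <- function(volume, a280, a260, meta = list()) {
  volume <- as.numeric(volume); a280 <- as.numeric(a280); a260 <- as.numeric(a260)
  if (length(volume) < 2L)
    secmp_stop("domain", "a chromatogram needs at least 2 points")
  if (anyNA(volume) || any(!is.finite(volume)))
    secmp_stop("domain", "elution volumes must be finite")
  if (any(diff(volume) <= 0))
    secmp_stop("domain", "elution volume grid must be strictly increasing")
  if (length(a280) != length(volume) || length(a260) != length(volume))
    secmp_stop("domain", "absorbance traces must match the volume grid length")
  if (any(!is.finite(a280)) || any(!is.finite(a260)))
    secmp_stop("domain", "absorbance traces must be finite")
  structure(list(volume = volume, a280 = a280, a260 = a260,
                 meta = as.list(meta)),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("SEC-UV chromatogram: %d points, %.3f-%.3f mL\n",
              length(x$volume), min(x$volume), max(x$volume)))
  cat(sprintf("  max A280 %.3g mAU, max A260 %.3g mAU\n",
              max(x$a280), max(x$a260)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, window = NULL, ...) {
  graphics::plot(x$volume, x$a280, type = "l", col = "blue",
                 xlab = "elution volume (mL)", ylab = "absorbance (mAU)",
                 ylim = range(c(x$a280, x$a260)), ...)
  graphics::lines(x$volume, x$a260, col = "purple")
  if (!is.null(window))
    graphics::abline(v = c(window$v_start, window$v_end), col = "darkgreen")
  graphics::legend("topright", c("280 nm", "260 nm"),
                   col = c("blue", "purple"), lty = 1, bty = "n")
  invisible(x)
}

#' Column-mapping dialect for delimited chromatogram files
#'
#' @param volume,a280,a260 Column names in the file header.
#' @param sep Field separator; `NULL` auto-detects comma vs tab vs whitespace
#'   from the header line.
#' @return A list used as the `dialect` argument of [load_chromatogram()].
#' @export
chrom_dialect <- function(volume = "volume_mL", a280 = "a280_mAU",
                          a260 = "a260_mAU", sep = NULL) {
  list(volume = volume, a280 = a280, a260 = a260, sep = sep)
}

detect_sep <- function(path) {
  ln <- readLines(path, n = 50L, warn = FALSE)
  ln <- ln[!startsWith(trimws(ln), "#")]
  if (!length(ln)) secmp_stop("format", "'%s' contains no data", path)
  h <- ln[[1L]]
  if (grepl("\t", h)) "\t" else if (grepl(",", h)) "," else ""
}

# Read a delimited table as character, tracking original file line numbers.
read_delim_chr <- function(path, sep) {
  if (!file.exists(path)) secmp_stop("format", "file '%s' does not exist", path)
  if (is.null(sep)) sep <- detect_sep(path)
  raw <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(raw), "#") & nzchar(trimws(raw))
  lines <- raw[keep]
  if (length(lines) < 1L) secmp_stop("format", "'%s' contains no data", path)
  lineno <- which(keep)
  split1 <- function(s) {
    out <- if (sep == "") strsplit(trimws(s), "[[:space:]]+")[[1L]]
           else strsplit(s, sep, fixed = TRUE)[[1L]]
    trimws(out)
  }
  header <- split1(lines[[1L]])
  rows <- lapply(lines[-1L], split1)
  list(header = header, rows = rows, lineno = lineno[-1L], sep = sep)
}

num_col <- function(tab, colname, path) {
  j <- match(colname, tab$header)
  if (is.na(j))
    secmp_stop("format", "'%s' is missing required column '%s'", path, colname)
  vals <- vapply(tab$rows, function(r) if (length(r) >= j) r[[j]] else NA_character_,
                 character(1L))
  num <- suppressWarnings(as.numeric(vals))
  bad <- which(is.na(num))
  if (length(bad))
    secmp_stop("parse", "non-numeric value '%s' in column '%s' of '%s' (line %d)",
               vals[bad[1L]], colname, path, tab$lineno[bad[1L]])
  num
}

#' Load a chromatogram from a delimited text file
#'
#' Reads a comma-, tab- or whitespace-separated table with a header row and
#' (at least) an elution-volume column plus the 280 nm and 260 nm absorbance
#' channels. Lines starting with `#` are treated as comments; simulator
#' outputs carry their seed there. Proprietary instrument binaries are not
#' supported — export to text first.
#'
#' @param path Path to the file.
#' @param dialect Column mapping, see [chrom_dialect()].
#' @return A validated [chromatogram()].
#' @export
load_chromatogram <- function(path, dialect = chrom_dialect()) {
  tab <- read_delim_chr(path, dialect$sep)
  extra <- setdiff(tab$header, c(dialect$volume, dialect$a280, dialect$a260))
  if (length(extra))
    message("ignoring extra channel column(s): ", paste(extra, collapse = ", "))
  chromatogram(num_col(tab, dialect$volume, path),
               num_col(tab, dialect$a280, path),
               num_col(tab, dialect$a260, path),
               meta = list(source = path))
}

#' Straight-line (or constant) baseline specification
#'
#' Mirrors the manual baseline-setting step of the chromatogram analysis:
#' per channel, either a constant offset or the straight line through two
#' user-chosen anchor points `(volume, absorbance)` placed on signal-free
#' stretches of the trace.
#'
#' @param a280,a260 Either a single number (constant baseline, mAU) or a
#'   numeric vector `c(v_left, a_left, v_right, a_right)` defining the two
#'   anchors (mL, mAU).
#' @return An object of class `"baseline_spec"`.
#' @seealso [estimate_baseline()] for deriving anchors from the trace itself.
#' @export
baseline_spec <- function(a280 = 0, a260 = 0) {
  chk <- function(x, nm) {
    x <- as.numeric(x)
    if (!length(x) %in% c(1L, 4L) || any(!is.finite(x)))
      secmp_stop("domain",
                 "baseline for %s must be a constant or c(v1, a1, v2, a2)", nm)
    if (length(x) == 4L && x[1L] >= x[3L])
      secmp_stop("domain", "left anchor volume must be below right anchor (%s)", nm)
    x
  }
  structure(list(a280 = chk(a280, "a280"), a260 = chk(a260, "a260")),
            class = "baseline_spec")
}

baseline_values <- function(spec_ch, volume) {
  if (length(spec_ch) == 1L) return(rep(spec_ch, length(volume)))
  v1 <- spec_ch[1L]; a1 <- spec_ch[2L]; v2 <- spec_ch[3L]; a2 <- spec_ch[4L]
  if (v1 < min(volume) || v2 > max(volume))
    secmp_stop("domain",
               "baseline anchors (%.3f, %.3f mL) fall outside the %.3f-%.3f mL grid",
               v1, v2, min(volume), max(volume))
  a1 + (volume - v1) * (a2 - a1) / (v2 - v1)
}

#' Subtract a per-channel baseline from a chromatogram
#'
#' @param chrom A [chromatogram()].
#' @param spec A [baseline_spec()].
#' @return A chromatogram on the identical volume grid with the baseline
#'   removed pointwise from each channel.
#' @export
subtract_baseline <- function(chrom, spec) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(spec, "baseline_spec"))
  chromatogram(chrom$volume,
               chrom$a280 - baseline_values(spec$a280, chrom$volume),
               chrom$a260 - baseline_values(spec$a260, chrom$volume),
               meta = c(chrom$meta, list(baseline_subtracted = TRUE)))
}

#' Estimate straight-line baseline anchors from signal-free regions
#'
#' Convenience replacement for the manual anchor placement: the anchor
#' absorbance at each of two volumes is the median of the trace within
#' `halfwidth` of that volume, per channel.
#'
#' @param chrom A [chromatogram()].
#' @param v_left,v_right Anchor volumes (mL), chosen on signal-free baseline.
#' @param halfwidth Half-width (mL) of the neighbourhood used for the median.
#' @return A [baseline_spec()].
#' @export
estimate_baseline <- function(chrom, v_left, v_right, halfwidth = 0.08) {
  stopifnot(inherits(chrom, "chromatogram"))
  stopifnot_scalar_pos(halfwidth, "halfwidth")
  if (v_left >= v_right)
    secmp_stop("domain", "v_left must be below v_right")
  anchor <- function(tr, v) {
    sel <- abs(chrom$volume - v) <= halfwidth
    if (!any(sel))
      secmp_stop("domain", "no grid points within %.3f mL of anchor %.3f mL",
                 halfwidth, v)
    stats::median(tr[sel])
  }
  baseline_spec(
    a280 = c(v_left, anchor(chrom$a280, v_left), v_right, anchor(chrom$a280, v_right)),
    a260 = c(v_left, anchor(chrom$a260, v_left), v_right, anchor(chrom$a260, v_right)))
}

#' Elution-volume integration window
#'
#' Windows are half-open in volume, `[v_start, v_end)`; this convention is
#' used by every volume-domain operation in the package.
#'
#' @param v_start,v_end Window bounds (mL), `v_start < v_end`.
#' @return An object of class `"peak_window"`.
#' @export
peak_window <- function(v_start, v_end) {
  stopifnot(is.numeric(v_start), is.numeric(v_end))
  if (!is.finite(v_start) || !is.finite(v_end) || v_start >= v_end)
    secmp_stop("domain", "peak window requires v_start < v_end (got %.4g, %.4g)",
               v_start, v_end)
  structure(list(v_start = as.numeric(v_start), v_end = as.numeric(v_end)),
            class = "peak_window")
}

# Trapezoid over the native grid, with linear interpolation at the window
# edges when they fall between grid points.
trapz_window <- function(v, y, v1, v2) {
  lo <- max(v1, min(v)); hi <- min(v2, max(v))
  if (lo >= hi) return(0)
  inside <- v > lo & v < hi
  xs <- c(lo, v[inside], hi)
  ys <- c(stats::approx(v, y, xout = lo)$y, y[inside],
          stats::approx(v, y, xout = hi)$y)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2)
}

#' Integrate both absorbance channels over a peak window
#'
#' Trapezoidal integration on the native volume grid, linearly interpolating
#' at window edges that fall between grid points. The caller is responsible
#' for having subtracted the baseline first; a warning is emitted if either
#' trace exceeds `edge_tol` (in absolute value) at the window edges, which
#' usually signals a badly placed baseline or window.
#'
#' @param chrom A baseline-corrected [chromatogram()].
#' @param window A [peak_window()]; must overlap the volume grid.
#' @param edge_tol Absolute edge-residual threshold (mAU) for the warning.
#' @return An object of class `"integrated_peak"` with integrated absorbances
#'   `A280_int` and `A260_int` (mAU·mL) and the window used. Strongly
#'   negative integrals indicate a bad baseline.
#' @export
integrate_peak <- function(chrom, window, edge_tol = 0.5) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(window, "peak_window"))
  v <- chrom$volume
  if (window$v_end <= min(v) || window$v_start >= max(v))
    secmp_stop("domain", "window [%.3f, %.3f) lies outside the %.3f-%.3f mL grid",
               window$v_start, window$v_end, min(v), max(v))
  edges <- c(max(window$v_start, min(v)), min(window$v_end, max(v)))
  ev <- c(stats::approx(v, chrom$a280, xout = edges)$y,
          stats::approx(v, chrom$a260, xout = edges)$y)
  if (any(abs(ev) > edge_tol))
    secmp_warn("integration",
               "trace is %.3g mAU at a window edge (tolerance %.3g); check baseline/window placement",
               max(abs(ev)), edge_tol)
  structure(list(A280_int = trapz_window(v, chrom$a280, window$v_start, window$v_end),
                 A260_int = trapz_window(v, chrom$a260, window$v_start, window$v_end),
                 window = window),
            class = "integrated_peak")
}

#' Suggest monomer-peak boundaries from the trace itself
#'
#' Advisory helper for the manual boundary-placement step. On the summed
#' (280 + 260 nm) trace, lightly smoothed, it locates the tallest interior
#' local maximum inside `search_window` and walks outward to the nearest
#' flanking local minima (or the search-window edges if the trace keeps
#' falling). Boundary placement remains the analyst's call; this only
#' automates the common case of a well-isolated peak.
#'
#' @param chrom A baseline-corrected [chromatogram()].
#' @param search_window A [peak_window()] to search within.
#' @param smooth Odd moving-average width (points) applied before the search.
#' @return A [peak_window()] spanning the flanking valleys.
#' @export
suggest_boundaries <- function(chrom, search_window, smooth = 5L) {
  stopifnot(inherits(chrom, "chromatogram"), inherits(search_window, "peak_window"))
  v <- chrom$volume
  sel <- which(v >= search_window$v_start & v < search_window$v_end)
  if (length(sel) < 5L)
    secmp_stop("domain", "search window overlaps fewer than 5 grid points")
  y <- chrom$a280[sel] + chrom$a260[sel]
  if (smooth > 1L) {
    k <- as.integer(smooth); if (k %% 2L == 0L) k <- k + 1L
    f <- stats::filter(y, rep(1 / k, k), sides = 2L)
    y <- ifelse(is.na(f), y, as.numeric(f))
  }
  n <- length(y)
  apex <- which.max(y)
  is_interior_max <- apex > 1L && apex < n
  if (!is_interior_max || all(y == y[apex]))
    secmp_stop("not_found", "no local maximum inside the search window")
  i <- apex
  while (i > 1L && y[i - 1L] <= y[i]) i <- i - 1L
  j <- apex
  while (j < n && y[j + 1L] <= y[j]) j <- j + 1L
  peak_window(v[sel[i]], v[sel[j]])
}
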