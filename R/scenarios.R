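#' Genome specification
#'
#' Describes the expected vector genome, either by nucleotide count (from
#' the vector sequence) or directly by mass. At least one of the two is
#' required wherever a theoretical genome or full-virion mass is needed
#' (scenarios 2 and 3); the mass can alternatively be measured from the MP
#' full/empty peak separation via [genome_mass_from_peaks()].
#'
#' @param n_nt Expected nucleotide count (optional).
#' @param m_genome_da Genome mass in Da (optional; derived from `n_nt` via
#'   [ssdna_mass()] when absent).
#' @param capsid_shell_kda Mass of the empty capsid shell (kDa), used to
#'   build the theoretical full-virion mass `shell + genome`.
#' @return An object of class `"genome_spec"`.
#' @export
genome_spec <- function(n_nt = NULL, m_genome_da = NULL,
                        capsid_shell_kda = 3760) {
  if (is.null(m_genome_da) && !is.null(n_nt)) m_genome_da <- ssdna_mass(n_nt)
  if (!is.null(m_genome_da)) stopifnot_scalar_pos(m_genome_da, "m_genome_da")
  stopifnot_scalar_pos(capsid_shell_kda, "capsid_shell_kda")
  structure(list(n_nt = n_nt, m_genome_da = m_genome_da,
                 capsid_shell_kda = capsid_shell_kda),
            class = "genome_spec")
}

genome_mass_required <- function(genome) {
  if (is.null(genome) || is.null(genome$m_genome_da))
    secmp_stop("configuration",
               "a genome specification (n_nt or m_genome_da) is required for this scenario")
  genome$m_genome_da
}

#' Full-virion theoretical mass (kDa) from a genome spec
#'
#' @param genome A [genome_spec()].
#' @return Shell mass plus genome mass, in kDa.
#' @export
full_virion_mass <- function(genome) {
  genome$capsid_shell_kda + genome_mass_required(genome) / 1000
}

#' Classify the MP mass distribution into one of three analysis scenarios
#'
#' Scenario 1: exactly one accepted peak, homogeneous (sigma <= `sigma_max`)
#' — a single well-defined species; titer and genome size come from the
#' chromatogram alone. Scenario 2: exactly two accepted peaks, both
#' homogeneous — an empty + full mixture; %full comes from the DNA mass
#' balance. Scenario 3: anything else (broad, multimodal, or featureless
#' distributions with events present) — %full must be counted from the mass
#' histogram.
#'
#' @param fits An `"mp_peakfit"` object from [detect_and_fit_peaks()], or a
#'   plain list of peak fits.
#' @param sigma_max Homogeneity threshold (kDa).
#' @param n_events Number of events behind the fits; taken from the
#'   `"mp_peakfit"` attribute when available. Zero events is an error, not a
#'   scenario.
#' @return An object of class `"scenario_call"`: `scenario` (1, 2 or 3),
#'   `evidence` (per-peak sigma and homogeneity), `n_events`.
#' @export
classify_scenario <- function(fits, sigma_max = 150,
                              n_events = attr(fits, "n_events")) {
  if (is.null(n_events)) n_events <- NA_integer_
  if (!is.na(n_events) && n_events < 1L)
    secmp_stop("insufficient_data", "no MP events to classify")
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  homog <- vapply(ok, is_homogeneous, logical(1L), sigma_max = sigma_max)
  scenario <- if (length(ok) == 1L && all(homog)) 1L
              else if (length(ok) == 2L && all(homog)) 2L
              else 3L
  structure(list(scenario = scenario,
                 evidence = list(
                   n_peaks = length(ok),
                   sigmas = vapply(ok, `[[`, numeric(1L), "sigma"),
                   mus = vapply(ok, `[[`, numeric(1L), "mu"),
                   homogeneous = homog,
                   sigma_max = sigma_max),
                 n_events = n_events),
            class = "scenario_call")
}

#' @export
print.scenario_call <- function(x, ...) {
  cat(sprintf("Scenario %d (%d accepted peak(s)%s)\n", x$scenario,
              x$evidence$n_peaks,
              if (length(x$evidence$sigmas))
                paste0("; sigma = ",
                       paste(sprintf("%.0f", x$evidence$sigmas), collapse = ", "),
                       " kDa") else ""))
  invisible(x)
}

new_titer_report <- function(scenario, uv, percent_full, genome_size_knt,
                             effective_titer, notes = character(),
                             counts = NULL, replicate = NULL,
                             provenance = list()) {
  flags <- uv$flags %||% character()
  if (!is.null(percent_full) && is.finite(percent_full) && percent_full > 1)
    flags <- c(flags, "percent_full_exceeds_100")
  structure(list(scenario = scenario,
                 c_cap = uv$c_cap,
                 w_dna = uv$w_dna,
                 cp_per_ml = uv$cp_per_ml,
                 percent_full = percent_full,
                 genome_size_knt = genome_size_knt,
                 effective_titer = effective_titer,
                 counts = counts,
                 replicate = replicate,
                 warnings = flags,
                 notes = notes,
                 provenance = provenance),
            class = "titer_report")
}

#' Scenario 1: single homogeneous species
#'
#' The titer and genome size come directly from the chromatogram: the
#' capsid number concentration is the total titer, and the genome size is
#' `w_DNA / c_cap` converted to knt. For a genome-bearing species the
#' effective (fully packaged) titer equals the total capsid titer; an empty
#' preparation (genome size 0) has an effective titer of 0.
#'
#' @param uv A `"uv_quant"` result.
#' @param genome Optional [genome_spec()]; when supplied, the measured
#'   genome size is compared to the expected one within `tol_knt`.
#' @param tol_knt Agreement tolerance in knt for that comparison.
#' @param provenance Optional provenance list echoed into the report.
#' @return A `"titer_report"`.
#' @export
analyze_scenario1 <- function(uv, genome = NULL, tol_knt = 0.1,
                              provenance = list()) {
  stopifnot(inherits(uv, "uv_quant"))
  if (uv$c_cap <= 0)
    secmp_stop("domain", "no capsids detected (c_cap = 0); nothing to titer")
  notes <- character()
  empty <- uv$genome_size_knt <= 0
  if (empty) notes <- c(notes, "empty capsid preparation: effective titer is 0")
  if (!is.null(genome) && !is.null(genome$m_genome_da)) {
    expected_knt <- as.numeric(genome_size_from_mass(genome$m_genome_da))
    if (abs(uv$genome_size_knt - expected_knt) > tol_knt)
      notes <- c(notes, sprintf(
        "measured genome size %.2f knt differs from expected %.2f knt by more than %.2f knt",
        uv$genome_size_knt, expected_knt, tol_knt))
  }
  new_titer_report(1L, uv,
                   percent_full = NULL,
                   genome_size_knt = uv$genome_size_knt,
                   effective_titer = if (empty) 0 else uv$cp_per_ml,
                   notes = notes, provenance = provenance)
}

#' Scenario 2: empty + full two-species mixture
#'
#' With both species homogeneous, the DNA mass balance gives
#' `%full = w_DNA / (c_cap * M_genome)`: the measured DNA per capsid as a
#' fraction of a full genome. Values above 100% are retained and flagged
#' (they diagnose integration error), never clamped. Effective titer is
#' `cp_per_ml * %full`.
#'
#' @param uv A `"uv_quant"` result.
#' @param genome A [genome_spec()] resolving `M_genome` (from sequence or
#'   from the MP peak separation).
#' @param provenance Optional provenance list.
#' @return A `"titer_report"`.
#' @export
analyze_scenario2 <- function(uv, genome, provenance = list()) {
  stopifnot(inherits(uv, "uv_quant"))
  if (uv$c_cap <= 0)
    secmp_stop("domain", "no capsids detected (c_cap = 0); nothing to titer")
  m_genome <- genome_mass_required(genome)
  pf <- uv$w_dna / (uv$c_cap * m_genome)  # both numerator terms in Da
  new_titer_report(2L, uv,
                   percent_full = pf,
                   genome_size_knt = uv$genome_size_knt,
                   effective_titer = uv$cp_per_ml * pf,
                   provenance = provenance)
}

#' Scenario 3: heterogeneous population, counting-based %full
#'
#' %full is the windowed particle-count fraction from MP; the effective
#' titer is `cp_per_ml * fraction`. When a genome mass is available the
#' DNA-mass-based ratio is additionally reported as "DNA occupancy" — it
#' assumes the DNA is spread uniformly over all capsids and therefore has no
#' direct interpretation as a particle fraction in heterogeneous samples; it
#' is included for transparency only.
#'
#' @param uv A `"uv_quant"` result.
#' @param mp_fraction Counting fraction from [fraction_full()].
#' @param counts The associated `"window_counts"`.
#' @param genome Optional [genome_spec()] for the occupancy diagnostic.
#' @param provenance Optional provenance list.
#' @return A `"titer_report"` (with `dna_occupancy` when computable).
#' @export
analyze_scenario3 <- function(uv, mp_fraction, counts, genome = NULL,
                              provenance = list()) {
  stopifnot(inherits(uv, "uv_quant"))
  if (uv$c_cap <= 0)
    secmp_stop("domain", "no capsids detected (c_cap = 0); nothing to titer")
  if (!inherits(counts, "window_counts"))
    secmp_stop("domain", "counts must be the window_counts from fraction_full()")
  if (counts$n_total < 1L)
    secmp_stop("insufficient_data", "zero particles in the total window")
  if (!is.finite(mp_fraction) || mp_fraction < 0 || mp_fraction > 1)
    secmp_stop("domain", "mp_fraction must lie in [0, 1]")
  notes <- character()
  occupancy <- NULL
  if (!is.null(genome) && !is.null(genome$m_genome_da)) {
    occupancy <- uv$w_dna / (uv$c_cap * genome$m_genome_da)
    notes <- c(notes, paste(
      "DNA occupancy assumes uniform DNA distribution over all capsids;",
      "it is not interpretable as a particle fraction for heterogeneous samples"))
  }
  rep <- new_titer_report(3L, uv,
                          percent_full = mp_fraction,
                          genome_size_knt = uv$genome_size_knt,
                          effective_titer = uv$cp_per_ml * mp_fraction,
                          notes = notes, counts = counts,
                          provenance = provenance)
  rep$dna_occupancy <- occupancy
  rep
}

#' Expected concentration and %full of a volume mixture
#'
#' For components mixed by volume, the expected total capsid concentration
#' is the volume-fraction-weighted sum of the component concentrations, and
#' the expected %full is the concentration contributed by full components
#' over the total.
#'
#' @param components A data frame (or list of lists) with columns/fields
#'   `cp_per_ml`, `volume_fraction`, `is_full`.
#' @return List with `cp_per_ml` and `percent_full` (fraction in 0-1).
#' @export
mixture_expectation <- function(components) {
  if (is.data.frame(components)) {
    cp <- components$cp_per_ml; f <- components$volume_fraction
    full <- components$is_full
  } else {
    cp <- vapply(components, `[[`, numeric(1L), "cp_per_ml")
    f <- vapply(components, `[[`, numeric(1L), "volume_fraction")
    full <- vapply(components, `[[`, logical(1L), "is_full")
  }
  if (any(!is.finite(cp)) || any(cp < 0) || any(!is.finite(f)) || any(f < 0))
    secmp_stop("domain", "component concentrations and fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9)
    secmp_stop("domain", "volume fractions must sum to 1 (got %.12g)", sum(f))
  total <- sum(f * cp)
  if (total <= 0)
    secmp_stop("domain", "mixture contains no capsids")
  list(cp_per_ml = total, percent_full = sum(f[full] * cp[full]) / total)
}

#' @export
print.titer_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable titer report block
#'
#' @param report A `"titer_report"`.
#' @return Character vector of report lines (one per element).
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "titer_report"))
  ln <- c(
    "== SEC-MP titer report ==",
    sprintf("scenario           : %d", report$scenario),
    sprintf("total capsids      : %.3g Cp/mL (c_cap = %.3g mol/L)",
            report$cp_per_ml, report$c_cap),
    sprintf("DNA concentration  : %.3g mg/mL", report$w_dna))
  if (!is.null(report$genome_size_knt) && !is.na(report$genome_size_knt))
    ln <- c(ln, sprintf("genome size        : %.2g knt", report$genome_size_knt))
  if (!is.null(report$percent_full))
    ln <- c(ln, sprintf("percent full       : %.3g%%", 100 * report$percent_full))
  if (!is.null(report$dna_occupancy))
    ln <- c(ln, sprintf("DNA occupancy      : %.3g%% (diagnostic only)",
                        100 * report$dna_occupancy))
  ln <- c(ln, sprintf("effective titer    : %.3g Vg/mL", report$effective_titer))
  if (!is.null(report$counts))
    ln <- c(ln, sprintf("counting           : %d full / %d total in [%.2f, %.2f] MDa",
                        report$counts$n_full, report$counts$n_total,
                        report$counts$total_window$lo / 1000,
                        report$counts$total_window$hi / 1000))
  if (!is.null(report$replicate) && !is.null(report$replicate$mean))
    ln <- c(ln, sprintf("replicates         : %%full %.3g%% +/- %.2g%% (n = %d)",
                        100 * report$replicate$mean, 100 * report$replicate$sd,
                        report$replicate$n))
  if (length(report$warnings))
    ln <- c(ln, paste("warning            :", report$warnings))
  if (length(report$notes))
    ln <- c(ln, paste("note               :", report$notes))
  ln
}

#' Serialize a titer report (plus provenance) to JSON
#'
#' @param report A `"titer_report"`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "titer_report"))
  x <- unclass(report)
  x$counts <- if (!is.null(x$counts)) {
    list(n_full = x$counts$n_full, n_total = x$counts$n_total,
         full_window_kDa = c(x$counts$full_window$lo, x$counts$full_window$hi),
         total_window_kDa = c(x$counts$total_window$lo, x$counts$total_window$hi))
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
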