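#' Run configuration
#'
#' Collects every knob of the SEC-MP analysis in one structure so that all
#' manual steps of the bench procedure (baseline anchors, peak boundaries,
#' mass windows) are explicit, reproducible values. Dimensioned keys carry
#' their unit in the key name. The resolved configuration is echoed into
#' every report (provenance), so each reported number is recomputable from
#' its inputs.
#'
#' @param extinction An [extinction_set()].
#' @param geometry An [acquisition_geometry()].
#' @param baseline A [baseline_spec()], or `NULL` to estimate anchors from
#'   `baseline_anchors_ml` via [estimate_baseline()].
#' @param baseline_anchors_ml Two volumes (mL) on signal-free baseline used
#'   when `baseline` is `NULL`.
#' @param window A [peak_window()] for the monomer peak.
#' @param mp_total_window A [mass_window()] tallying all monomeric AAVs.
#' @param mp_half_width_kda Half-width of the full-particle window (kDa).
#' @param mp_sigma_max_kda Homogeneity threshold on fitted sigma (kDa).
#' @param mp_bin_width_kda Histogram bin width (kDa).
#' @param mp_min_events Minimum events required for peak fitting.
#' @param genome A [genome_spec()] or `NULL`.
#' @param scenario_override Force scenario 1, 2 or 3 (`NULL` = classify).
#' @param seed Seed echoed to simulator calls made through this config.
#' @return An object of class `"secmp_config"`.
#' @export
secmp_config <- function(extinction = extinction_set(),
                         geometry = acquisition_geometry(),
                         baseline = NULL,
                         baseline_anchors_ml = c(7.85, 9.55),
                         window = peak_window(8.1, 9.1),
                         mp_total_window = mass_window(3000, 6000),
                         mp_half_width_kda = 150,
                         mp_sigma_max_kda = 150,
                         mp_bin_width_kda = 25,
                         mp_min_events = 50L,
                         genome = NULL,
                         scenario_override = NULL,
                         seed = NULL) {
  stopifnot(inherits(extinction, "extinction_set"),
            inherits(geometry, "acquisition_geometry"),
            inherits(window, "peak_window"),
            inherits(mp_total_window, "mass_window"))
  if (!is.null(baseline) && !inherits(baseline, "baseline_spec"))
    secmp_stop("configuration", "baseline must be a baseline_spec or NULL")
  if (!is.null(scenario_override) && !scenario_override %in% 1:3)
    secmp_stop("configuration", "scenario_override must be 1, 2 or 3")
  if (!is.null(genome) && !inherits(genome, "genome_spec"))
    secmp_stop("configuration", "genome must be a genome_spec or NULL")
  structure(list(extinction = extinction, geometry = geometry,
                 baseline = baseline, baseline_anchors_ml = baseline_anchors_ml,
                 window = window, mp_total_window = mp_total_window,
                 mp_half_width_kda = mp_half_width_kda,
                 mp_sigma_max_kda = mp_sigma_max_kda,
                 mp_bin_width_kda = mp_bin_width_kda,
                 mp_min_events = as.integer(mp_min_events),
                 genome = genome, scenario_override = scenario_override,
                 seed = seed),
            class = "secmp_config")
}

cfg_need <- function(block, key, where) {
  if (is.null(block[[key]]))
    secmp_stop("configuration", "missing config key '%s.%s'", where, key)
  block[[key]]
}

# YAML scalars like "6.35e6" (no sign in the exponent) parse as strings;
# coerce dimensioned config values defensively.
cfg_num <- function(x, key) {
  v <- suppressWarnings(as.numeric(x))
  if (!length(v) || anyNA(v))
    secmp_stop("configuration", "config key '%s' is not numeric (got '%s')",
               key, paste(x, collapse = ", "))
  v
}

#' Read a run configuration from a YAML file
#'
#' See `inst/extdata/demo-config.yaml` for the schema: blocks `extinction`,
#' `geometry`, `peak_window` are required; `baseline`, `mp`, `genome`,
#' `scenario_override` and `seed` are optional. Unit suffixes are part of
#' the key names.
#'
#' @param path Path to a YAML file.
#' @return A [secmp_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    secmp_stop("configuration", "config file '%s' does not exist", path)
  y <- yaml::read_yaml(path)
  ext_b <- cfg_need(y, "extinction", "")
  geo_b <- cfg_need(y, "geometry", "")
  win_b <- cfg_need(y, "peak_window", "")
  ncfg <- function(block, key, where)
    cfg_num(cfg_need(block, key, where), paste(where, key, sep = "."))
  ext <- extinction_set(
    eps_cap280 = ncfg(ext_b, "eps_cap280_per_M_per_cm", "extinction"),
    eps_cap260 = ncfg(ext_b, "eps_cap260_per_M_per_cm", "extinction"),
    eps_dna280 = ncfg(ext_b, "eps_dna280_mL_per_mg_per_cm", "extinction"),
    eps_dna260 = ncfg(ext_b, "eps_dna260_mL_per_mg_per_cm", "extinction"),
    cap_mass_kda = cfg_num(ext_b$cap_mass_kDa %||% 3736, "extinction.cap_mass_kDa"))
  geom <- acquisition_geometry(
    path_length = ncfg(geo_b, "path_length_cm", "geometry"),
    injection_volume = ncfg(geo_b, "injection_volume_mL", "geometry"))
  window <- peak_window(ncfg(win_b, "v_start_mL", "peak_window"),
                        ncfg(win_b, "v_end_mL", "peak_window"))
  baseline <- NULL
  anchors <- c(7.85, 9.55)
  if (!is.null(y$baseline)) {
    b <- y$baseline
    if (!is.null(b$anchors_mL)) anchors <- as.numeric(b$anchors_mL)
    if (!is.null(b$a280) || !is.null(b$a260))
      baseline <- baseline_spec(a280 = b$a280 %||% 0, a260 = b$a260 %||% 0)
  }
  mp <- y$mp %||% list()
  tw <- cfg_num(mp$total_window_kDa %||% c(3000, 6000), "mp.total_window_kDa")
  genome <- NULL
  if (!is.null(y$genome))
    genome <- genome_spec(
      n_nt = if (!is.null(y$genome$n_nt)) cfg_num(y$genome$n_nt, "genome.n_nt"),
      m_genome_da = if (!is.null(y$genome$m_genome_Da))
        cfg_num(y$genome$m_genome_Da, "genome.m_genome_Da"),
      capsid_shell_kda = cfg_num(y$genome$capsid_shell_kDa %||% 3760,
                                 "genome.capsid_shell_kDa"))
  secmp_config(extinction = ext, geometry = geom, baseline = baseline,
               baseline_anchors_ml = anchors, window = window,
               mp_total_window = mass_window(tw[1L], tw[2L]),
               mp_half_width_kda = cfg_num(mp$half_width_kDa %||% 150,
                                           "mp.half_width_kDa"),
               mp_sigma_max_kda = cfg_num(mp$sigma_max_kDa %||% 150,
                                          "mp.sigma_max_kDa"),
               mp_bin_width_kda = cfg_num(mp$bin_width_kDa %||% 25,
                                          "mp.bin_width_kDa"),
               mp_min_events = cfg_num(mp$min_events %||% 50L, "mp.min_events"),
               genome = genome,
               scenario_override = y$scenario_override,
               seed = y$seed)
}

config_echo <- function(config) {
  list(extinction = unclass(config$extinction),
       geometry = unclass(config$geometry),
       peak_window = unclass(config$window),
       mp = list(total_window_kDa = c(config$mp_total_window$lo,
                                      config$mp_total_window$hi),
                 half_width_kDa = config$mp_half_width_kda,
                 sigma_max_kDa = config$mp_sigma_max_kda,
                 bin_width_kDa = config$mp_bin_width_kda),
       genome = if (!is.null(config$genome)) unclass(config$genome),
       seed = config$seed)
}

#' SEC-MP quantitation of an AAV sample
#'
#' The central estimator: runs the full analysis on one chromatogram and one
#' MP event list — baseline subtraction, monomer-peak integration,
#' two-wavelength capsid/DNA deconvolution, MP peak fitting and homogeneity
#' classification, scenario selection, and scenario-specific titer
#' assembly.
#'
#' @param chrom A [chromatogram()] or a path to a chromatogram file.
#' @param mp An [mp_run()] or a path to an MP event file.
#' @param config A [secmp_config()].
#' @return An object of class `"secmp"`: components `report` (the
#'   `"titer_report"`), `uv`, `fits`, `call_info` (the scenario call),
#'   `chrom` (baseline-corrected), `mp`, `config`. Methods: `print`,
#'   `summary`, `coef`, `plot`.
#' @examples
#' mix <- mix_single_full()
#' nm <- noise_model(seed = 1)
#' fit <- secmp(simulate_chromatogram(mix, extinction_set(),
#'                                    acquisition_geometry(), nm),
#'              simulate_mp_events(mix, 2000, nm),
#'              secmp_config(genome = genome_spec(n_nt = 2763)))
#' fit
#' @export
secmp <- function(chrom, mp, config = secmp_config()) {
  stopifnot(inherits(config, "secmp_config"))
  if (is.character(chrom)) chrom <- load_chromatogram(chrom)
  if (is.character(mp)) mp <- load_mp_events(mp)
  stopifnot(inherits(chrom, "chromatogram"), inherits(mp, "mp_run"))

  baseline <- config$baseline %||%
    estimate_baseline(chrom, config$baseline_anchors_ml[1L],
                      config$baseline_anchors_ml[2L])
  corrected <- subtract_baseline(chrom, baseline)
  peak <- integrate_peak(corrected, config$window)
  uv <- uv_quantify(peak, config$extinction, config$geometry)

  fits <- detect_and_fit_peaks(mp, search = config$mp_total_window,
                               bin_width = config$mp_bin_width_kda,
                               min_events = config$mp_min_events)
  call_info <- classify_scenario(fits, sigma_max = config$mp_sigma_max_kda)
  scenario <- config$scenario_override %||% call_info$scenario

  genome <- config$genome
  provenance <- config_echo(config)
  report <- switch(as.character(scenario),
    "1" = analyze_scenario1(uv, genome = genome, provenance = provenance),
    "2" = {
      if (is.null(genome) || is.null(genome$m_genome_da)) {
        # fall back to the MP full/empty peak separation
        ok <- Filter(function(f) isTRUE(f$converged), fits)
        if (length(ok) < 2L)
          secmp_stop("configuration",
                     "scenario 2 needs a genome spec or two MP peaks to derive M_genome")
        m <- genome_mass_from_peaks(ok[[length(ok)]], ok[[1L]])
        genome <- genome_spec(m_genome_da = m,
                              capsid_shell_kda = ok[[1L]]$mu)
      }
      analyze_scenario2(uv, genome, provenance = provenance)
    },
    "3" = {
      m_full <- if (!is.null(genome)) full_virion_mass(genome)
                else secmp_stop("configuration",
                                "scenario 3 needs a genome spec to place the full-particle window")
      ff <- fraction_full(mp, m_theory = m_full,
                          half_width = config$mp_half_width_kda,
                          total = config$mp_total_window)
      analyze_scenario3(uv, ff$fraction, ff$counts, genome = genome,
                        provenance = provenance)
    })
  structure(list(report = report, uv = uv, fits = fits,
                 call_info = call_info, chrom = corrected, mp = mp,
                 config = config),
            class = "secmp")
}

#' @export
print.secmp <- function(x, ...) {
  print(x$call_info)
  print(x$report)
  invisible(x)
}

#' @export
summary.secmp <- function(object, ...) {
  print(object$call_info)
  print(object$fits, sigma_max = object$config$mp_sigma_max_kda)
  print(object$uv)
  print(object$report)
  invisible(object)
}

#' @export
coef.secmp <- function(object, ...) {
  r <- object$report
  c(c_cap = r$c_cap, w_dna = r$w_dna, cp_per_ml = r$cp_per_ml,
    percent_full = if (is.null(r$percent_full)) NA_real_ else r$percent_full,
    genome_size_knt = if (is.null(r$genome_size_knt)) NA_real_ else r$genome_size_knt,
    effective_titer = r$effective_titer)
}

#' @export
plot.secmp <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$chrom, window = x$config$window, main = "SEC-UV (corrected)")
  plot(x$mp, bin_width = x$config$mp_bin_width_kda,
       range = x$config$mp_total_window, fits = x$fits, main = "MP distribution")
  invisible(x)
}

#' Write the JSON and plain-text reports of a fitted analysis
#'
#' @param fit A `"secmp"` object.
#' @param dir Output directory (created if needed).
#' @param stem Base file name.
#' @return Paths of the two files written, invisibly.
#' @export
write_reports <- function(fit, dir, stem = "titer_report") {
  stopifnot(inherits(fit, "secmp"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, paste0(stem, ".json"))
  tpath <- file.path(dir, paste0(stem, ".txt"))
  report_json(fit$report, jpath)
  writeLines(format_report(fit$report), tpath)
  invisible(c(json = jpath, text = tpath))
}
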