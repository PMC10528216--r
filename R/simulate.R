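#' Ground-truth species mixture for the forward simulator
#'
#' Each row describes one species in the loaded sample: a capsid-bearing
#' particle (empty, partially or fully packaged monomer, or aggregate), a
#' free DNA fragment, or a free protein contaminant. Chromatographic
#' behaviour is an idealised Gaussian elution peak (apex, sigma); mass
#' photometry sees only capsid-bearing species, in proportion to their
#' number concentrations.
#'
#' @param label Character species labels.
#' @param capsid Logical: is the species a capsid-bearing particle?
#' @param mass_kda Particle mass (kDa); for free DNA/protein, the molecule
#'   mass.
#' @param genome_da DNA mass carried per particle (Da); 0 for empty capsids
#'   and protein species, the full fragment mass for free DNA.
#' @param conc_per_ml Number concentration in the loaded sample
#'   (particles/mL).
#' @param apex_ml,sigma_ml Elution peak apex and width (mL).
#' @return An object of class `"species_mix"` (a validated data frame).
#' @export
species_mix <- function(label, capsid, mass_kda, genome_da, conc_per_ml,
                        apex_ml, sigma_ml) {
  df <- data.frame(label = as.character(label), capsid = as.logical(capsid),
                   mass_kda = as.numeric(mass_kda),
                   genome_da = as.numeric(genome_da),
                   conc_per_ml = as.numeric(conc_per_ml),
                   apex_ml = as.numeric(apex_ml),
                   sigma_ml = as.numeric(sigma_ml),
                   stringsAsFactors = FALSE)
  if (!nrow(df)) secmp_stop("domain", "a species mix needs at least one species")
  with(df, {
    if (any(!is.finite(mass_kda)) || any(mass_kda <= 0))
      secmp_stop("domain", "species masses must be positive")
    if (any(!is.finite(genome_da)) || any(genome_da < 0))
      secmp_stop("domain", "genome masses must be non-negative")
    if (any(!is.finite(conc_per_ml)) || any(conc_per_ml < 0))
      secmp_stop("domain", "concentrations must be non-negative")
    if (any(!is.finite(sigma_ml)) || any(sigma_ml <= 0))
      secmp_stop("domain", "elution sigmas must be positive")
  })
  structure(df, class = c("species_mix", "data.frame"))
}

#' Noise model for the forward simulator
#'
#' Defaults reflect a modern HPLC UV detector (short-term noise ~0.05 mAU,
#' drift ~0.3 mAU/mL) and an MP instrument whose per-event mass error SD of
#' 120 kDa reproduces the 110-135 kDa fitted peak widths observed for
#' homogeneous AAV preparations.
#'
#' @param chrom_sd Additive chromatogram noise SD (mAU).
#' @param drift_slope Linear baseline drift (mAU/mL).
#' @param mp_sd Per-event MP mass error SD (kDa).
#' @param seed Integer RNG seed, recorded in all simulator outputs; `NULL`
#'   uses the caller's RNG stream.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(chrom_sd = 0.05, drift_slope = 0.3, mp_sd = 120,
                        seed = NULL) {
  stopifnot_scalar_pos(chrom_sd, "chrom_sd", strict = FALSE)
  stopifnot_scalar_pos(mp_sd, "mp_sd", strict = FALSE)
  if (!is.numeric(drift_slope) || !is.finite(drift_slope))
    secmp_stop("domain", "drift_slope must be a finite number")
  structure(list(chrom_sd = chrom_sd, drift_slope = drift_slope,
                 mp_sd = mp_sd, seed = seed),
            class = "noise_model")
}

# Per-species integrated channel areas (mAU*mL) implied by the two-channel
# extinction model: capsid species absorb through both the protein shell and
# their cargo DNA; free DNA only through the DNA coefficients; free protein
# through the capsid coefficients scaled by mass relative to the reference
# shell.
species_areas <- function(mix, ext, geom) {
  scale <- 1000 * geom$path_length * geom$injection_volume
  c_mol <- mix$conc_per_ml * 1000 / N_AVOGADRO     # mol/L
  w_dna <- c_mol * mix$genome_da                   # g/L = mg/mL
  cap_mol <- ifelse(mix$capsid, c_mol, 0)
  prot_mol <- ifelse(!mix$capsid & mix$genome_da == 0,
                     c_mol * mix$mass_kda / ext$cap_mass_kda, 0)
  dna_w <- ifelse(mix$capsid | mix$genome_da > 0, w_dna, 0)
  list(a280 = scale * ((cap_mol + prot_mol) * ext$eps_cap280 + dna_w * ext$eps_dna280),
       a260 = scale * ((cap_mol + prot_mol) * ext$eps_cap260 + dna_w * ext$eps_dna260))
}

#' Simulate a dual-wavelength SEC-UV chromatogram
#'
#' Each species contributes a Gaussian elution peak whose integrated area in
#' each channel equals `1000 * path_length * injection_volume` times the
#' channel absorbance its concentrations would produce under the two-channel
#' extinction model — so integrating the simulated monomer peak and
#' inverting recovers the injected concentrations exactly at zero noise.
#' Linear drift and white noise are added last, under the model's seed.
#'
#' @param mix A [species_mix()].
#' @param ext An [extinction_set()].
#' @param geom An [acquisition_geometry()].
#' @param noise A [noise_model()].
#' @param grid Elution-volume grid (mL); must cover every apex +/- 5 sigma.
#' @return A [chromatogram()] with the seed in `meta`.
#' @export
simulate_chromatogram <- function(mix, ext, geom, noise = noise_model(),
                                  grid = seq(6, 12.5, by = 0.002)) {
  stopifnot(inherits(mix, "species_mix"), inherits(ext, "extinction_set"),
            inherits(geom, "acquisition_geometry"), inherits(noise, "noise_model"))
  if (any(mix$apex_ml - 5 * mix$sigma_ml < min(grid)) ||
      any(mix$apex_ml + 5 * mix$sigma_ml > max(grid)))
    secmp_stop("domain", "grid must cover every species apex +/- 5 sigma")
  ar <- species_areas(mix, ext, geom)
  a280 <- numeric(length(grid)); a260 <- numeric(length(grid))
  for (i in seq_len(nrow(mix))) {
    shape <- stats::dnorm(grid, mix$apex_ml[i], mix$sigma_ml[i])
    a280 <- a280 + ar$a280[i] * shape
    a260 <- a260 + ar$a260[i] * shape
  }
  drift <- noise$drift_slope * (grid - grid[1L])
  with_seed(noise$seed, {
    a280 <- a280 + drift + stats::rnorm(length(grid), 0, noise$chrom_sd)
    a260 <- a260 + drift + stats::rnorm(length(grid), 0, noise$chrom_sd)
    chromatogram(grid, a280, a260,
                 meta = list(simulated = TRUE, seed = noise$seed))
  })
}

#' Simulate a mass-photometry event list
#'
#' Events are drawn from the capsid-bearing species with probabilities
#' proportional to their number concentrations (MP dilutes every sample to
#' its working concentration, so only proportions matter, not absolute
#' concentration), and each event mass is the species mass plus
#' `Normal(0, mp_sd)` measurement error. Free DNA and protein contaminants
#' are far below the instrument's AAV mass range and generate no events.
#'
#' @param mix A [species_mix()] with at least one capsid species.
#' @param n_events Number of landing events to draw (>= 1).
#' @param noise A [noise_model()] (supplies `mp_sd` and the seed).
#' @return An [mp_run()] with the seed in `meta`.
#' @export
simulate_mp_events <- function(mix, n_events, noise = noise_model()) {
  stopifnot(inherits(mix, "species_mix"), inherits(noise, "noise_model"))
  if (!is.numeric(n_events) || n_events < 1)
    secmp_stop("domain", "n_events must be >= 1")
  caps <- mix[mix$capsid & mix$conc_per_ml > 0, , drop = FALSE]
  if (!nrow(caps))
    secmp_stop("domain", "mix contains no capsid-bearing species with positive concentration")
  with_seed(noise$seed, {
    idx <- sample.int(nrow(caps), size = n_events, replace = TRUE,
                      prob = caps$conc_per_ml)
    masses <- caps$mass_kda[idx] + stats::rnorm(n_events, 0, noise$mp_sd)
    mp_run(masses, meta = list(simulated = TRUE, seed = noise$seed))
  })
}

#' Exact ground truth of a species mixture
#'
#' Computes, by exact arithmetic over the species table, the quantities the
#' analysis pipeline estimates, under the same definitions: total capsids
#' are the capsid species whose true mass lies in `total_window` (which
#' excludes aggregates, as SEC and the MP mass window do); full species are
#' those within `half_width` of `full_mass_kda` (default: the capsid species
#' carrying the largest genome); genome occupancy is total encapsidated DNA
#' relative to all-capsids-full.
#'
#' @param mix A [species_mix()].
#' @param full_mass_kda Theoretical full-virion mass (kDa); default taken
#'   from the largest-genome capsid species.
#' @param half_width Full-window half-width (kDa).
#' @param total_window Monomer [mass_window()] (kDa).
#' @return List with `total_cp_per_ml`, `percent_full` (count fraction),
#'   `occupancy`, `effective_titer`, `full_mass_kda`.
#' @export
ground_truth <- function(mix, full_mass_kda = NULL, half_width = 150,
                         total_window = mass_window(3000, 6000)) {
  stopifnot(inherits(mix, "species_mix"))
  caps <- mix[mix$capsid, , drop = FALSE]
  if (!nrow(caps)) secmp_stop("domain", "mix contains no capsid species")
  mono <- caps[caps$mass_kda >= total_window$lo & caps$mass_kda <= total_window$hi, ,
               drop = FALSE]
  if (!nrow(mono))
    secmp_stop("domain", "no monomeric capsid species inside the total window")
  if (is.null(full_mass_kda)) {
    full_mass_kda <- if (max(mono$genome_da) > 0)
      mono$mass_kda[which.max(mono$genome_da)] else NA_real_
  }
  total <- sum(mono$conc_per_ml)
  is_full <- !is.na(full_mass_kda) &
    abs(mono$mass_kda - full_mass_kda) <= half_width
  pf <- if (total > 0) sum(mono$conc_per_ml[is_full]) / total else 0
  m_genome_full <- max(mono$genome_da)
  occupancy <- if (total > 0 && m_genome_full > 0)
    sum(mono$conc_per_ml * mono$genome_da) / (total * m_genome_full) else 0
  list(total_cp_per_ml = total, percent_full = pf, occupancy = occupancy,
       effective_titer = total * pf, full_mass_kda = full_mass_kda)
}

#' Write a chromatogram to the delimited format the loader consumes
#'
#' @param chrom A [chromatogram()].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path, sep = ",") {
  stopifnot(inherits(chrom, "chromatogram"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(chrom$meta$seed))
    writeLines(sprintf("# seed: %d", as.integer(chrom$meta$seed)), con)
  df <- data.frame(volume_mL = chrom$volume, a280_mAU = chrom$a280,
                   a260_mAU = chrom$a260)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an MP event list to the delimited format the loader consumes
#'
#' @param run An [mp_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mp_events <- function(run, path) {
  stopifnot(inherits(run, "mp_run"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(run$meta$seed))
    writeLines(sprintf("# seed: %d", as.integer(run$meta$seed)), con)
  utils::write.table(data.frame(mass_kDa = run$masses), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Demonstration mixtures
#'
#' Ready-made [species_mix()] tables emulating the canonical AAV sample
#' types, with monomers eluting at 8.6 mL, aggregates at 7 mL and small
#' contaminants after 10 mL:
#'
#' * `mix_single_full()`: one homogeneous fully packaged species (2763 nt
#'   genome, shell 3760 kDa, hence 4.60 MDa virions at 1.14e13 Cp/mL) plus
#'   an aggregate and late-eluting free DNA and protein contaminants.
#' * `mix_single_empty()`: the empty counterpart (3.76 MDa, 2.40e12 Cp/mL).
#' * `mix_empty_full()`: their 1:1 volume mixture (each component halved).
#' * `mix_heterogeneous()`: a low-genome-purity sample — empty capsids, two
#'   partially packaged species (the heavier one prominent just below the
#'   full mass), ~10% fully packaged virions carrying a 4787 nt genome, an
#'   aggregate, and free DNA/protein contaminants.
#'
#' @param conc_full,conc_empty Number concentrations (Cp/mL) of the full and
#'   empty monomer species.
#' @param shell_kda Empty shell mass (kDa).
#' @return A [species_mix()].
#' @name demo_mixes
NULL

contaminant_rows <- function() {
  species_mix(label = c("free_dna", "free_protein"),
              capsid = c(FALSE, FALSE),
              mass_kda = c(50, 100),
              genome_da = c(5e4, 0),
              conc_per_ml = c(5e12, 1e13),
              apex_ml = c(10.6, 11.2),
              sigma_ml = c(0.15, 0.2))
}

rbind_mix <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  structure(df, class = c("species_mix", "data.frame"))
}

#' @rdname demo_mixes
#' @export
mix_single_full <- function(conc_full = 1.14e13, shell_kda = 3760) {
  g <- ssdna_mass(2763)
  rbind_mix(
    species_mix("full", TRUE, shell_kda + g / 1000, g, conc_full, 8.6, 0.18),
    species_mix("aggregate", TRUE, 2 * (shell_kda + g / 1000), 2 * g,
                0.03 * conc_full, 7.0, 0.15),
    contaminant_rows())
}

#' @rdname demo_mixes
#' @export
mix_single_empty <- function(conc_empty = 2.40e12, shell_kda = 3760) {
  rbind_mix(
    species_mix("empty", TRUE, shell_kda, 0, conc_empty, 8.6, 0.18),
    species_mix("aggregate", TRUE, 2 * shell_kda, 0, 0.03 * conc_empty, 7.0, 0.15),
    contaminant_rows())
}

#' @rdname demo_mixes
#' @export
mix_empty_full <- function(conc_empty = 2.40e12, conc_full = 1.14e13,
                           shell_kda = 3760) {
  g <- ssdna_mass(2763)
  rbind_mix(
    species_mix(c("empty", "full"), c(TRUE, TRUE),
                c(shell_kda, shell_kda + g / 1000), c(0, g),
                c(conc_empty / 2, conc_full / 2), c(8.6, 8.6), c(0.18, 0.18)),
    contaminant_rows())
}

#' @rdname demo_mixes
#' @export
mix_heterogeneous <- function(shell_kda = 3760) {
  g <- ssdna_mass(4787)
  full_mass <- shell_kda + g / 1000
  rbind_mix(
    species_mix(
      label = c("empty", "partial_low", "partial_high", "full", "aggregate"),
      capsid = TRUE,
      mass_kda = c(shell_kda, shell_kda + 540, shell_kda + 1140,
                   full_mass, 2 * full_mass),
      genome_da = c(0, 5.4e5, 1.14e6, g, 2 * g),
      conc_per_ml = c(1.2e12, 1.0e12, 0.8e12, 3.5e11, 1.5e11),
      apex_ml = c(8.6, 8.6, 8.6, 8.6, 7.0),
      sigma_ml = c(0.18, 0.18, 0.18, 0.18, 0.15)),
    contaminant_rows())
}
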