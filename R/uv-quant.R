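#' Extinction-coefficient set for the two-wavelength deconvolution
#'
#' The 280/260 nm absorbance of a monomeric AAV peak is modelled as the sum
#' of a capsid-protein term and an encapsidated-DNA term at each wavelength:
#' \deqn{A_{280} = \epsilon_{cap,280} c_{cap} + \epsilon_{DNA,280} w_{DNA}}
#' \deqn{A_{260} = \epsilon_{cap,260} c_{cap} + \epsilon_{DNA,260} w_{DNA}}
#' with the capsid coefficients per-particle molar (M\eqn{^{-1}}cm\eqn{^{-1}})
#' and the DNA coefficients per-mass (mL·mg\eqn{^{-1}}·cm\eqn{^{-1}}). DNA UV
#' absorptivity is sequence-independent and capsid absorptivity varies little
#' across serotypes, so one set serves most AAV products; the set used is
#' echoed into every report.
#'
#' The defaults are built from standard UV absorptivities: capsid specific
#' absorbance 1.7 mL·mg\eqn{^{-1}}·cm\eqn{^{-1}} at 280 nm with a protein
#' A260/A280 ratio of 0.59, scaled to a 3.736 MDa shell; ssDNA
#' 27 mL·mg\eqn{^{-1}}·cm\eqn{^{-1}} at 260 nm with A280/A260 = 0.55.
#'
#' @param eps_cap280,eps_cap260 Capsid molar extinction coefficients
#'   (M^-1 cm^-1).
#' @param eps_dna280,eps_dna260 ssDNA mass extinction coefficients
#'   (mL mg^-1 cm^-1).
#' @param cap_mass_kda Reference shell mass (kDa) the capsid coefficients
#'   refer to; used by the simulator to scale free-protein contaminants.
#' @param max_condition Reject sets whose 2x2 coefficient matrix has a
#'   condition number above this cap (near-singular systems cannot separate
#'   protein from DNA).
#' @return An object of class `"extinction_set"`.
#' @export
extinction_set <- function(eps_cap280 = 6.35e6, eps_cap260 = 3.75e6,
                           eps_dna280 = 14.85, eps_dna260 = 27,
                           cap_mass_kda = 3736, max_condition = 1e6) {
  for (nm in c("eps_cap280", "eps_cap260", "eps_dna280", "eps_dna260",
               "cap_mass_kda"))
    stopifnot_scalar_pos(get(nm), nm)
  m <- matrix(c(eps_cap280, eps_dna280, eps_cap260, eps_dna260),
              nrow = 2L, byrow = TRUE)
  kap <- kappa(m, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    secmp_stop("conditioning",
               "extinction matrix condition number %.3g exceeds cap %.3g; the 280/260 system cannot be inverted reliably",
               kap, max_condition)
  structure(list(eps_cap280 = eps_cap280, eps_cap260 = eps_cap260,
                 eps_dna280 = eps_dna280, eps_dna260 = eps_dna260,
                 cap_mass_kda = cap_mass_kda, condition = kap),
            class = "extinction_set")
}

ext_matrix <- function(ext) {
  matrix(c(ext$eps_cap280, ext$eps_dna280, ext$eps_cap260, ext$eps_dna260),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("A280", "A260"), c("cap", "dna")))
}

#' Acquisition geometry linking peak area to loaded-sample concentration
#'
#' An integrated peak area (mAU·mL) is turned into an absorbance referenced
#' to the injected sample by \eqn{A = S / (1000\, l\, V_{inj})}: the factor
#' 1000 converts mAU to AU, `path_length` is the flow-cell path (cm) and
#' `injection_volume` the loaded volume (mL). Without this normalisation the
#' two-wavelength system would yield flow-cell concentrations rather than
#' sample titers.
#'
#' @param path_length Flow-cell path length (cm).
#' @param injection_volume Injected sample volume (mL).
#' @return An object of class `"acquisition_geometry"`.
#' @export
acquisition_geometry <- function(path_length = 1, injection_volume = 0.01) {
  stopifnot_scalar_pos(path_length, "path_length")
  stopifnot_scalar_pos(injection_volume, "injection_volume")
  structure(list(path_length = path_length, injection_volume = injection_volume),
            class = "acquisition_geometry")
}

#' Effective absorbances of the loaded sample
#'
#' @param peak An `integrated_peak` from [integrate_peak()].
#' @param geom An [acquisition_geometry()].
#' @return Named numeric vector `c(A280 =, A260 =)` in AU, referenced to the
#'   injected sample. Negative values (bad baseline) are passed through with
#'   a warning.
#' @export
effective_absorbance <- function(peak, geom) {
  stopifnot(inherits(peak, "integrated_peak"), inherits(geom, "acquisition_geometry"))
  a <- c(A280 = peak$A280_int, A260 = peak$A260_int) /
    (1000 * geom$path_length * geom$injection_volume)
  if (any(a < 0))
    secmp_warn("integration", "negative effective absorbance (%.3g AU); check baseline",
               min(a))
  a
}

#' Solve the two-wavelength system for capsid and DNA concentrations
#'
#' Inverts the 2x2 linear system documented in [extinction_set()] to obtain
#' the capsid molar concentration `c_cap` (mol/L) and the DNA mass
#' concentration `w_dna` (mg/mL) of the loaded sample.
#'
#' Small negative solutions are a normal consequence of baseline noise on a
#' species that genuinely lacks one component (e.g. empty capsids carry no
#' DNA). A negative `c_cap` or `w_dna` within `-tol` of zero is clamped to 0
#' and flagged; `tol` is `clamp_rel` times a magnitude reference (for
#' `c_cap`, the concentration that would explain the full A280 alone; for
#' `w_dna`, the DNA that would explain an A260 of 0.6·A280 alone). Larger
#' negatives raise an inconsistency error naming both channels.
#'
#' @param A280,A260 Effective absorbances (AU), see [effective_absorbance()].
#' @param ext An [extinction_set()].
#' @param clamp_rel Relative clamp tolerance (default 2%).
#' @return List with `c_cap` (mol/L), `w_dna` (mg/mL) and a character vector
#'   `flags`.
#' @export
solve_capsid_dna <- function(A280, A260, ext, clamp_rel = 0.02) {
  stopifnot(inherits(ext, "extinction_set"))
  if (!is.finite(A280) || !is.finite(A260))
    secmp_stop("domain", "absorbances must be finite")
  # Column-equilibrated solve with one iterative-refinement step: the molar
  # capsid and per-mass DNA coefficients differ by ~5 orders of magnitude,
  # and equilibration keeps the inversion accurate to near machine precision.
  m <- ext_matrix(ext)
  b <- c(A280, A260)
  d <- sqrt(colSums(m^2))
  ms <- sweep(m, 2L, d, "/")
  x <- solve(ms, b) / d
  x <- x + solve(ms, b - as.numeric(m %*% x)) / d
  c_cap <- x[[1L]]; w_dna <- x[[2L]]
  flags <- character()
  scale_a <- max(abs(A280), abs(A260))
  tol_c <- clamp_rel * scale_a / ext$eps_cap280
  tol_w <- clamp_rel * 0.6 * scale_a / ext$eps_dna260
  if (c_cap < 0) {
    if (c_cap >= -tol_c) {
      c_cap <- 0
      flags <- c(flags, "c_cap_clamped_to_zero")
    } else {
      secmp_stop("inconsistency",
                 "c_cap solves to %.3g mol/L (< -%.3g): A280 = %.4g and A260 = %.4g AU are inconsistent with the extinction set",
                 c_cap, tol_c, A280, A260)
    }
  }
  if (w_dna < 0) {
    if (w_dna >= -tol_w) {
      w_dna <- 0
      flags <- c(flags, "w_dna_clamped_to_zero")
    } else {
      secmp_stop("inconsistency",
                 "w_dna solves to %.3g mg/mL (< -%.3g): A280 = %.4g and A260 = %.4g AU are inconsistent with the extinction set",
                 w_dna, tol_w, A280, A260)
    }
  }
  list(c_cap = unname(c_cap), w_dna = unname(w_dna), flags = flags)
}

#' Molecular mass of a single-stranded DNA genome
#'
#' `n_nt * 303.7 + 79.0` daltons: the average ssDNA nucleotide contributes
#' 303.7 Da and the 79.0 Da term accounts for the terminal phosphate/hydroxyl
#' ends.
#'
#' @param n_nt Nucleotide count (>= 0).
#' @return Mass in Da.
#' @examples
#' ssdna_mass(2763) / 1e6  # MDa of a 2763 nt vector genome
#' @export
ssdna_mass <- function(n_nt) {
  if (any(!is.finite(n_nt)) || any(n_nt < 0))
    secmp_stop("domain", "nucleotide count must be non-negative")
  n_nt * 303.7 + 79.0
}

#' Genome size (kilo-nucleotides) from an encapsidated DNA mass
#'
#' Inverse of [ssdna_mass()], clamped at zero: masses below the 79 Da end
#' -group term (in particular the exact 0 reported for empty capsids) map to
#' a genome size of 0.
#'
#' @param genome_mass Mass in Da (>= 0).
#' @return Genome size in knt. Carries a `"flags"` attribute when the clamp
#'   was applied to a positive sub-threshold mass.
#' @export
genome_size_from_mass <- function(genome_mass) {
  if (any(!is.finite(genome_mass)) || any(genome_mass < 0))
    secmp_stop("domain", "genome mass must be non-negative")
  knt <- pmax(0, (genome_mass - 79.0) / 303.7) / 1000
  if (any(genome_mass > 0 & genome_mass < 79.0))
    attr(knt, "flags") <- "mass_below_end_group_clamped"
  knt
}

#' Capsid number concentration from molar concentration
#'
#' `c_cap * N_A / 1000` particles per mL (N_A = 6.02214076e23 / mol).
#'
#' @param c_cap Capsid molar concentration (mol/L), >= 0.
#' @return Number concentration in Cp/mL.
#' @export
capsid_number_concentration <- function(c_cap) {
  if (any(!is.finite(c_cap)) || any(c_cap < 0))
    secmp_stop("domain", "c_cap must be non-negative")
  c_cap * N_AVOGADRO / 1000
}

#' Total particles loaded on the column
#'
#' @param cp_per_ml Capsid number concentration (Cp/mL).
#' @param volume_ml Loaded volume (mL).
#' @return Particle count.
#' @export
loaded_particles <- function(cp_per_ml, volume_ml) {
  stopifnot_scalar_pos(volume_ml, "volume_ml")
  if (cp_per_ml < 0) secmp_stop("domain", "cp_per_ml must be non-negative")
  cp_per_ml * volume_ml
}

#' Full UV quantitation of an integrated monomer peak
#'
#' Chains [effective_absorbance()], [solve_capsid_dna()],
#' [capsid_number_concentration()] and [genome_size_from_mass()] into the
#' quantities reported for the loaded sample.
#'
#' @param peak An `integrated_peak`.
#' @param ext An [extinction_set()].
#' @param geom An [acquisition_geometry()].
#' @param clamp_rel Passed to [solve_capsid_dna()].
#' @return An object of class `"uv_quant"`: `c_cap` (mol/L), `w_dna` (mg/mL),
#'   `cp_per_ml` (Cp/mL), `genome_mass` (Da, `w_dna/c_cap`), `genome_size_knt`,
#'   `A280`, `A260` (AU) and `flags`.
#' @export
uv_quantify <- function(peak, ext, geom, clamp_rel = 0.02) {
  a <- effective_absorbance(peak, geom)
  sol <- solve_capsid_dna(a[["A280"]], a[["A260"]], ext, clamp_rel = clamp_rel)
  cp <- capsid_number_concentration(sol$c_cap)
  # w_dna is mg/mL = g/L, so w_dna / c_cap has units g/mol = Da directly
  gm <- if (sol$c_cap > 0) sol$w_dna / sol$c_cap else NA_real_
  knt <- if (is.na(gm)) NA_real_ else as.numeric(genome_size_from_mass(gm))
  structure(list(c_cap = sol$c_cap, w_dna = sol$w_dna, cp_per_ml = cp,
                 genome_mass = gm, genome_size_knt = knt,
                 A280 = unname(a[["A280"]]), A260 = unname(a[["A260"]]),
                 flags = sol$flags),
            class = "uv_quant")
}

#' @export
print.uv_quant <- function(x, ...) {
  cat("UV peak quantitation (loaded sample)\n")
  cat(sprintf("  c_cap      %.4g mol/L\n", x$c_cap))
  cat(sprintf("  w_DNA      %.4g mg/mL\n", x$w_dna))
  cat(sprintf("  capsids    %.4g Cp/mL\n", x$cp_per_ml))
  if (!is.na(x$genome_mass))
    cat(sprintf("  genome     %.4g Da (%.2g knt)\n", x$genome_mass,
                x$genome_size_knt))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
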