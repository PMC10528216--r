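# Shared fixtures, built in code at test time.

# A clean Gaussian-peak chromatogram: area `area` mAU*mL per channel factor,
# apex and sigma in mL, on a uniform grid.
gaussian_chrom <- function(area280 = 10, area260 = 6, apex = 8.6, sigma = 0.1,
                           from = 6, to = 11, by = 0.002, drift = 0) {
  v <- seq(from, to, by = by)
  shape <- dnorm(v, apex, sigma)
  chromatogram(v, area280 * shape + drift * (v - from),
               a260 = area260 * shape + drift * (v - from))
}

# Random well-conditioned extinction sets for property tests. Conditioning
# is judged on the column-equilibrated matrix (the angle between the protein
# and DNA spectral signatures), which is scale-free: the raw matrix always
# has a large condition number because molar capsid coefficients (~1e6) and
# per-mass DNA coefficients (~1e1) live on different scales.
random_extinction <- function() {
  repeat {
    cap <- c(runif(1, 1e6, 1e7), runif(1, 5e5, 8e6))
    dna <- c(runif(1, 5, 30), runif(1, 10, 60))
    m_eq <- cbind(cap / sqrt(sum(cap^2)), dna / sqrt(sum(dna^2)))
    if (kappa(m_eq, exact = TRUE) >= 1e4) next
    e <- try(extinction_set(eps_cap280 = cap[1L], eps_cap260 = cap[2L],
                            eps_dna280 = dna[1L], eps_dna260 = dna[2L],
                            max_condition = 1e8),
             silent = TRUE)
    if (!inherits(e, "try-error")) return(e)
  }
}

demo_config <- function(...) {
  secmp_config(...)
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
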