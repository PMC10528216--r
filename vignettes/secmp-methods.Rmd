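---
title: "Quantifying AAV products from SEC-UV and mass photometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AAV products from SEC-UV and mass photometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secmp)
```

## The measurement problem

Adeno-associated virus (AAV) preparations are never a single species. Along
with the desired fully packaged vector they contain empty capsids, partially
packaged capsids carrying genome fragments, aggregates, and free protein or
DNA. The quantity that matters for dosing is the *effective titer*: the
concentration of capsids that carry the complete genome. `secmp` estimates
it by combining two orthogonal measurements of the same sample:

* a **size-exclusion chromatogram** recorded at 280 nm and 260 nm, which
  after baseline correction and integration of the monomeric-AAV peak gives
  the *total* capsid concentration and the *total* encapsidated DNA; and
* a **mass-photometry (MP) event list**, one mass per detected particle,
  which resolves how that DNA is distributed over particles — empty, partial
  and full capsids differ by their cargo mass, not their size, so SEC alone
  cannot separate them.

## The two-wavelength deconvolution

Proteins absorb predominantly at 280 nm, nucleic acids at 260 nm. Writing
$c_\mathrm{cap}$ for the capsid molar concentration (mol/L) and
$w_\mathrm{DNA}$ for the DNA mass concentration (mg/mL) of the loaded
sample, the integrated monomer-peak absorbances obey

$$A_{280} = \varepsilon_{cap,280}\, c_\mathrm{cap} + \varepsilon_{DNA,280}\, w_\mathrm{DNA},
\qquad
A_{260} = \varepsilon_{cap,260}\, c_\mathrm{cap} + \varepsilon_{DNA,260}\, w_\mathrm{DNA},$$

a 2×2 linear system solved exactly by `solve_capsid_dna()`. The capsid
coefficients are per-particle molar (M⁻¹cm⁻¹), the DNA coefficients
per-mass (mL·mg⁻¹·cm⁻¹); DNA UV absorptivity is sequence-independent and
capsid absorptivity varies only slightly across serotypes, so one
`extinction_set()` serves most products. The packaged defaults derive from
standard absorptivities (capsid 1.7 mL·mg⁻¹·cm⁻¹ at 280 nm with a protein
A260/A280 ratio of 0.59 on a 3.736 MDa shell; ssDNA 27 mL·mg⁻¹·cm⁻¹ at
260 nm with A280/A260 = 0.55). They are configuration, not constants — the
set used is echoed into every report, and all quantitative validation in
this package is closed-loop: the simulator and the inversion share one set,
so correctness never hinges on the default values.

Derived quantities:

* capsid number concentration $N_A c_\mathrm{cap} / 1000$ in Cp/mL
  (`capsid_number_concentration()`);
* encapsidated genome mass $w_\mathrm{DNA}/c_\mathrm{cap}$ in Da (mg/mL
  over mol/L is g/mol directly);
* genome size in kilonucleotides through the inverse of the ssDNA mass
  formula $M = 303.7\,n_{nt} + 79.0$ Da (`ssdna_mass()`,
  `genome_size_from_mass()`).

**Area normalisation.** An integrated area $S$ (mAU·mL) refers to material
passing the flow cell; `effective_absorbance()` converts it to an
absorbance referenced to the injected sample via
$A = S / (1000\, l\, V_{inj})$ with path length $l$ (cm) and injection
volume $V_{inj}$ (mL). Making this explicit (as `acquisition_geometry()`)
is what lets the same equations report sample titers rather than flow-cell
concentrations.

**Negative solutions.** Baseline noise pushes the DNA estimate of a truly
empty preparation slightly negative about half the time. Solutions within
2% of a magnitude reference (for $c_\mathrm{cap}$, the concentration that
would explain all of $A_{280}$; for $w_\mathrm{DNA}$, the DNA that would
explain an $A_{260}$ of $0.6 A_{280}$) are clamped to zero and flagged —
this is what makes an empty sample report a genome size of exactly 0.
Larger negatives indicate a genuinely inconsistent channel pair and raise
an error instead of being silently repaired.

## Chromatogram handling conventions

* **Baseline** is a straight line through two user-chosen anchors per
  channel (or a constant): the simplest model consistent with how baselines
  are drawn in practice, and linear in the trace, so corrections compose.
  `estimate_baseline()` automates anchor placement as the median of the
  trace within ±0.08 mL of each anchor volume.
* **Integration** is trapezoidal on the native volume grid with linear
  interpolation at window edges — no resampling, and refinement of the grid
  provably reduces the error (tested). Volume windows are half-open
  `[v_start, v_end)` everywhere.
* **Boundaries** are explicit configuration. `suggest_boundaries()` is
  advisory only: it brackets the tallest apex between its flanking valleys,
  the common case of a well-isolated monomer peak. Boundary placement is a
  recognised error source when impurity peaks shoulder the monomer peak,
  which is why the choice stays with the analyst and is echoed into the
  report.

## MP analysis and the three scenarios

`detect_and_fit_peaks()` histograms the events (25 kDa bins over the 3–6
MDa AAV monomer range), smooths with a 3-bin moving average for mode
detection, and accepts modes whose topographic prominence exceeds both 10%
of the tallest mode and a Poisson-scale floor ($4\sqrt{h_{max}}$) — a flat
distribution therefore yields no peaks. Accepted modes get a least-squares
Gaussian fit on the *unsmoothed* histogram within ±3 provisional sigmas
(Levenberg–Marquardt via `minpack.lm`). A peak is *homogeneous* when its
fitted σ ≤ 150 kDa; the threshold is inclusive at the boundary, fixing by
decision the ambiguity between a strict and non-strict reading.

The fitted distribution selects one of three analysis branches
(`classify_scenario()`):

1. **One homogeneous peak** — a single species. Titer and genome size come
   from the chromatogram alone; the effective titer equals the total capsid
   titer (or 0 for an empty preparation, genome size 0).
2. **Two homogeneous peaks** — an empty + full mixture. %full is the DNA
   mass balance $w_\mathrm{DNA} / (c_\mathrm{cap} M_{genome})$, with
   $M_{genome}$ from the vector sequence or from the MP peak separation
   (`genome_mass_from_peaks()`). Values above 100% are *retained and
   flagged*, never clamped: they diagnose integration error.
3. **Anything else** — heterogeneous population. %full is counted: events
   within ±150 kDa of the theoretical full-virion mass (shell + genome,
   e.g. 5.25 MDa giving the 5.10–5.40 MDa window) over all events in 3–6
   MDa. Mass windows are closed intervals, so an event exactly on a
   boundary counts. Counting operates on raw events, not fitted areas —
   the histogram directly enumerates particles, which is the more reliable
   estimate when species overlap. The DNA-balance ratio is still reported,
   labelled *DNA occupancy*, with the caveat that it assumes uniform DNA
   distribution and is not interpretable as a particle fraction here.

## The forward simulator

`simulate_chromatogram()` and `simulate_mp_events()` generate both data
types from a ground-truth `species_mix()` so every stage is testable
without instrument data, with `ground_truth()` as the exact answer key
(same window definitions as the analysis side). The signal model:

* each species elutes as a Gaussian peak whose integrated channel areas are
  exactly what the two-wavelength model predicts from its concentrations —
  so at zero noise, analysis inverts simulation to quadrature precision
  (verified to 1e-4 relative; the residual is trapezoid error plus the
  5-sigma window truncation);
* capsid-bearing species produce MP events in proportion to their number
  concentrations (the instrument dilutes every sample to its working
  concentration, so only proportions matter), each event blurred by
  Gaussian mass error;
* free DNA and protein contaminants contribute UV signal (260- and
  280-dominant respectively, protein scaled within the capsid coefficient
  family by mass relative to the reference shell) but never MP events in
  the AAV range; aggregates elute early (~7 mL) with masses above 6 MDa,
  so they perturb UV integration if windows are set badly but never the
  counting.

**Noise defaults, chosen once:** chromatogram white noise 0.05 mAU and
drift 0.3 mAU/mL (typical short-term noise and drift of a modern HPLC UV
detector); MP per-event mass error SD 120 kDa, which reproduces the
110–135 kDa fitted widths characteristic of homogeneous AAV preparations.

**Demo mixtures.** `mix_single_full()` / `mix_single_empty()` model
high-purity preparations (4.60 and 3.76 MDa monomers at 1.14×10¹³ and
2.40×10¹² Cp/mL, the canonical single-species examples);
`mix_empty_full()` their 1:1 volume mixture (expected 6.9×10¹² Cp/mL, 83%
full). `mix_heterogeneous()` models a low-genome-purity product: empty
capsids, two partial species — the heavier one prominent just below the
full mass, the morphology typical of heterogeneous samples — ~10% full
virions carrying a 4787 nt genome (5.21 MDa), a dimer aggregate and late
contaminants. Monomers co-elute at 8.6 mL regardless of cargo (SEC
separates by size, and cargo does not change size), which is precisely why
MP is needed.

What the simulator deliberately does **not** model: chromatographic
physics (plate theory, tailing, species-dependent elution of monomers),
MP optics and contrast-to-mass calibration, detection-efficiency variation
across 3–6 MDa (assumed uniform), and co-eluting impurity shoulders.
Passing closed-loop tests therefore demonstrates the correctness of the
arithmetic and the estimators under the stated signal model, not
robustness to every real-chromatography artifact.

## Numerical and design choices

* Window conventions: volume windows half-open, mass windows closed; fixed
  once, used everywhere.
* Whether the instrument integrates in time or volume is not observable
  from exported traces; integration here is volume-based (flow rate
  constant), and a constant factor converts if needed.
* Scenario-1 reports compare the measured genome size against an expected
  value (when given) within ±0.1 knt, a tolerance configurable per run.
* Display rounding (2 significant figures for knt and MDa) is a reporting
  concern; internal values keep full precision. Reported values use
  round-half-even via `signif()`.
* Degenerate inputs are errors with stable categories (parse, domain,
  configuration, insufficient data), which the command-line driver maps to
  distinct exit codes.

## Known limitations

* **Window-truncation bias of counting.** With event noise σ ≈ 120 kDa, a
  ±150 kDa full window captures only ~79% of genuinely full particles, so
  the counting %full underestimates by ~0.21·p(full) minus whatever leaks
  in from nearby partial species. At the low full fractions where the
  counting branch is actually deployed (heterogeneous samples, a few
  percent full) this bias is fractions of a percentage point; for
  predominantly full samples the DNA-balance route (scenario 2) is the
  appropriate one. The cross-method consistency test exercises exactly the
  low-fraction regime for this reason.
* Boundary placement (both chromatographic and mass windows) remains the
  dominant real-world error source and is arbitrary by nature; the package
  makes it explicit and reproducible rather than pretending to solve it.
* Partially packaged species adjacent to the full mass can contribute
  several-fold errors to the counted full fraction when abundant — the
  fixed-width window cannot distinguish a full virion from a partial one
  120 kDa lighter.

## Problem sizes used in validation

The shipped tests run the closed loop at 10,000 MP events per run (the
scale of a typical MP acquisition), chromatograms of ~3,300 points at
0.002 mL spacing, 20 seeded replicates for the parameter-recovery check,
40 seeds per injection volume for the loading-volume trend, and 1,000
randomized extinction sets for the inversion property — sizes at which the
binomial counting error (±0.4 points at 10% full) and quadrature error
(≪ 1e-4) are well below the tolerances being asserted.
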