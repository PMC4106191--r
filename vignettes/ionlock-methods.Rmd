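---
title: "Models and methods behind ionlock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ionlock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionlock)
```

`ionlock` analyses surfactant protein C (SP-C) peptide mimics in which an
engineered Glu⁻⋯Lys⁺ pair at *i*, *i*+4 spacing ("ion-lock") substitutes for
the helix-stabilizing palmitoyl groups of the native protein. This vignette
documents the models, the tunable parameters and their defaults, the
numerical decisions, and the limits of what the test suite establishes.

## Sequence model and fixtures

Peptides are 1-based strings over the 20 standard residues, 10–60 residues
long. The bundled fixture table carries the native human/dog/pig SP-C
sequences and the mimic suite (rSP-C; SP-Css/SP-Cff; SP-C33 UCLA; ion-lock
variants). Fixture sequences were transcribed from the canonical published
sequences and verified against every stated residue anchor (rSP-C Phe-4/
Phe-5/Ile-32; E20/K24 and K15/E19 in the ion-locks) and against the
hydropathy worked examples below; the rSP-C fixture is 34 residues, the only
length consistent with all of those anchors simultaneously. The dog SP-C
entry is a clearly-labelled synthetic stand-in (human scaffold with one
Cys→Phe, reflecting its known single palmitoyl substitution): the exact
sequence was not recoverable offline, and nothing downstream depends on it.
`apply_ion_lock()` substitutes E at the anion and K at the cation position of
each pair; pairs must be spaced exactly 4 and non-overlapping.

## Windowed hydropathy with salt bridges

The transfer free energy of a residue from water to *n*-octanol
(ΔG<sub>res</sub>, kcal/mol, whole-residue scale including the backbone;
charged forms for D/E/K/R, neutral His at pH 7) is summed over a sliding
window and negated, so positive totals mean favorable bilayer partitioning:

$$H(w) = -\sum_{i \in w} \Delta G_{res}(i)$$

- **Window length** default 19 residues — the span of a bilayer-crossing
  α-helix. The quantity is a window *sum*, not a mean: totals near
  +11 kcal/mol for a 19-mer cannot be per-residue averages.
- **Salt-bridge engagement**: if an ion-lock pair falls entirely inside a
  window and is flagged engaged, its two charged-residue terms
  (ΔG(E⁻) = 3.63, ΔG(K⁺) = 2.80) are replaced by one joint term
  `salt_bridge_pair_dg`, default **+0.1 kcal/mol** — the electrostatically
  neutral ion pair costs almost nothing to transfer. A pair straddling the
  window boundary counts as disengaged for that window: a bridge cannot be
  half-counted.
- Ties in the best window break to the smallest start (rSP-C has a genuine
  two-way tie; the convention picks 12–30).

With these defaults the package computes rSP-C (no locks) best window 12–30
at **11.31 kcal/mol**, and SP-Css ion-lock 1 window 12–30 at **10.29**
(engaged) and **3.96 kcal/mol** (disengaged) — the calibration surface for
the constants. The engagement delta, 6.33 kcal/mol, is the thermodynamic
value of closing one bridge inside the window.

## β-sheet pairing energies

Candidate aggregation is scored by summing a 20×20 pairwise energy table
over residues facing one another in a two-strand β-sheet, for every pair of
equal-length segments (≥ `min_len`, default 4), both orientations
(antiparallel reverses one segment) and all registers, keeping the
`max_results` (default 100) most stable. The classifier flags a sequence as
amyloid-like when the best energy is strictly below −29.0, the operating
point quoted for the published propensity tables. **Those tables are not
redistributed**: the package ships only a labelled toy table, so absolute
energies here are not comparable to published values — the algorithm, its
ordering contract (energy, then smaller first-segment start, parallel before
antiparallel) and the threshold logic are what the tests pin down, by
exhaustive brute-force comparison on sequences ≤ 15 residues. Ordering keys
round energies to 10⁻⁹ so exact ties break by the documented keys rather
than floating-point accumulation order. Salt bridges deliberately do *not*
enter the pairing score (the upstream algorithm has the same caveat);
E/K substitutions act only through their per-residue propensities.

## Amide-I deconvolution

A spectrum region (default 1600–1715 cm⁻¹) is modelled as a linear baseline
plus Gaussian–Lorentzian (pseudo-Voigt) bands
$A\,[f G(x) + (1{-}f) L(x)]$ sharing center and FWHM.

- **Band picking**: local minima of a Savitzky–Golay (local quadratic,
  7-point) second derivative, thresholded at `sensitivity` (default 4) times
  the noise level propagated from the second difference of the signal;
  adjacent flat-top minima within 6 cm⁻¹ merge. This replaces proprietary
  Fourier self-deconvolution: both are initializers for the same fit, and
  the second derivative is reproducible.
- **Fitting**: box-constrained least squares (analytic gradients) with
  centers within ±8 cm⁻¹ of initials, widths in **[6, 30] cm⁻¹**, Gaussian
  fraction in **[0.25, 0.75]**, amplitudes ≥ 0. The width and mix-fraction
  boxes are deliberately tighter than "anything positive"/[0, 1]: with
  overlapped bands the mix fraction is weakly identified, and a
  near-pure-Lorentzian component carries ~50% more area at equal amplitude —
  unconstrained fits silently reallocated area between neighbouring classes
  (measured: mean class-fraction error 0.050 → 0.031 on the random-spectrum
  benchmark after constraining). `fit_shape = FALSE` freezes the mix
  entirely, the usual practice when software fits are compared across
  samples.
- **Band count**: after fitting the picked candidates (plus a template band
  seeded at the midpoint of any conformational class window lacking a
  candidate — standard amide-I practice), bands with amplitude < 3% of the
  maximum are pruned, then single bands are added at the largest positive
  residual while the BIC improves, to at most 7.
- **Identifiability limit**: at a signal-to-noise ratio of 50, per-band
  *areas* of neighbouring bands recover only to ~5–8% even with the mix
  frozen (fitted residuals at or below the noise floor, so this is a
  statistical limit, not an optimizer failure). Class *fractions* are much
  better behaved because within-class leakage cancels.
- **Class windows** (half-open partition by fitted center): sheet
  [1613, 1637), disordered [1637, 1645), helix [1645, 1662], turn
  (1662, 1682], sheet (1682, 1710]. The conventional literature limits
  overlap between 1645–1650 (helix vs disordered); the partition above is a
  decision that reproduces every class call those limits are used for
  (1630 → sheet, 1653–1657 → helix, 1691 → sheet). A center at exactly 1662
  is helix; at 1637, disordered. Centers in no window count as turn inside
  1600–1715 and are excluded (with a warning) outside.
- **β polymorph**: a low-frequency sheet band with a high-frequency
  companion below 10% of its amplitude (config-exposed) is called a parallel
  in-register fibril signature; a significant companion (the ~1/5-intensity
  regime) is called antiparallel oligomer.

## Polarized-ATR orientation

The thick-film model maps a helix tilt Θ (from the membrane normal) to the
dichroic ratio via $S_{helix} = (3\cos^2\Theta - 1)/2$,
$S_{dipole} = S_{helix} \cdot (3\cos^2\alpha - 1)/2$,
$K_z = (2 S_{dipole} + 1)/3$ and
$$R = \frac{E_x^2 (1-K_z)/2 + E_z^2 K_z}{E_y^2 (1-K_z)/2}.$$
Defaults: E<sub>x</sub> = 1.398, E<sub>y</sub> = 1.516, E<sub>z</sub> = 1.625,
α = 39° (amide-I transition dipole to helix axis). The printed source
equation for the inversion contains a typo (identical numerator and
denominator); the corrected inversion
$S_{dipole} = (E_x^2 - R E_y^2 + E_z^2)/(E_x^2 - R E_y^2 - 2 E_z^2)$
is adopted — it reproduces the isotropic limit
R = (E<sub>x</sub>² + E<sub>z</sub>²)/E<sub>y</sub>² ≈ 2.00 and round-trips
the forward model to 10⁻⁹. R is strictly decreasing in Θ (attainable range
≈ [1.418, 4.357] with defaults), so inversion is unique; out-of-range R
errors by default, or clamps to the limiting tilt with a warning
(`clamp = TRUE`) since multilayer disorder biases R downward. All results
are *maximum* tilt angles for the same reason. Degrees at the interface,
radians internally.

## H/D exchange kinetics

The amide II (1525–1565 cm⁻¹) to amide I (1600–1700 cm⁻¹) area ratio,
normalized to its t = 0 value, gives percent unexchanged amide protons. The
fit is
$$y(t) = \text{plateau} + \sum_i a_i\, 2^{-t/t_{1/2,i}}$$
with a<sub>i</sub> ≥ 0 and the sum-to-100 constraint enforced exactly by
parameterizing plateau = 100 − Σa. Decisions that matter:

- **Half-life parameterization** (t½, rate = ln2/t½), reported ascending.
- **Profiled amplitudes**: for fixed half-lives the model is linear in the
  amplitudes; the small constrained least-squares problem is solved exactly
  by active-set enumeration, and the outer search runs over log half-lives
  only, from a deterministic multi-start grid ({3, 10, 30, 120, 480} min
  pairs, capped) — reproducible without a seed.
- **Compartment half-life bound, 150 min**: the compartment model describes
  fast and intermediate exchange (t½ between 10 and 120 min); the fit bounds
  half-lives at that regime plus 25% margin and assigns slower decay to the
  plateau. Without the bound, a slow exponential is statistically confounded
  with the plateau on a 0–6 h window: unbounded fits reached plateau errors
  of 10–18 percentage points *with better residuals than the truth*, an
  identifiability failure no optimizer can fix. The bound is configurable
  (`half_life_max`) for longer experiments.
- **Weighting** 1/y², the maximum-likelihood weighting for the
  multiplicative area noise the generator (and instrument) produce.
- **Rounding of residue counts**: one decimal below 10 (a ~3.5-residue core
  is meaningfully not 4), nearest integer above.

## Synthetic data: what it does and does not establish

Generators emit a truth record beside every dataset; recovery tests compare
pipeline output to truth, never to transcribed constants. Noise models:
additive Gaussian on absorbance (spectra); multiplicative Gaussian, 2%
default, on band areas (polarized pairs, H/D ratios). All randomness flows
through an explicit seed and the caller's RNG state is restored.

Stated-world choices: random test spectra draw 3–5 bands, at most one per
conformational class, centers inside slightly shrunk class windows with
≥ 12 cm⁻¹ separation (resolvable at the 2 cm⁻¹ instrument resolution),
widths 12–22 cm⁻¹, amplitudes 0.3–1.0, mix 0.3–0.7; H/D series use 14 time
points over 0–360 min with the compartment parameters in the 10–120 min
regime; polarized pairs use the default field constants. Real spectra add
things the generator does not emulate: water-vapor lines, imperfect lipid
subtraction, sloping scattering backgrounds, correlated detector noise,
band asymmetry, and isotropic (unoriented) peptide fractions that bias R
low. A green recovery test therefore establishes that the *algorithms*
invert their own stated forward models at realistic noise — not that any
particular laboratory spectrum will deconvolve to ±5%.

## Pipeline and topology call

`run_pipeline()` runs every stage whose inputs exist, records per-stage
errors per peptide without aborting the rest, and writes a combined table
plus a hydropathy-vs-pairing-energy table (the plane separating
membrane-partitioning helix formers from β-aggregators). The topology call
is: **not-helical** below 33% helix; otherwise **transmembrane** when the
helical residue count ≥ 17 (the low end of the 17–25-residue span of known
transmembrane helices) and the maximum tilt ≤ 30°; otherwise
**single-leaflet**. The 30° cutoff is a package decision separating the
observed ~22–23° transmembrane regime from the ~34° single-leaflet regime;
both thresholds are config-exposed and logged in the report header.

## Known limitations

- Hydropathy uses the octanol (transmembrane) scale only; no interfacial
  scale mode or folding-partitioning cycles.
- β-pairing ships no trained propensities; absolute amyloid classification
  requires the published tables as TSV input.
- FTIR: no Fourier self-deconvolution pre-filter parameters, no
  ¹³C-isotope-edited analysis, no lipid-band order parameters.
- Orientation: thick-film fields only; the isotropic-fraction contribution
  is handled only through the "maximum tilt" caveat.
- HDX: no per-residue protection factors or intrinsic-rate corrections.
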