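---
title: "Exact-mass PFAS quantitation and replicate-calibration validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact-mass PFAS quantitation and replicate-calibration validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasq)
```

## The problem

Per- and polyfluoroalkyl substances (PFAS) are quantified in drinking water
at low ng/L (parts-per-trillion) levels. On high-resolution accurate-mass
(HRAM) instruments the quantitative signal is the exact-mass precursor
(MS1) peak area, extracted in a narrow ppm window around the theoretical
ion m/z and referenced to a stable-isotope-labeled internal standard (IS);
the isotope envelope and the MS2 fragmentation pattern are qualitative
identity checks rather than the quantitative channel. `pfasq` implements
this workflow together with the replicate-calibration validation
statistics recommended by EPA Method 537.1, and ships a synthetic-data
generator so the entire pipeline can be exercised and tested without an
instrument.

This vignette records the package's own account of the model, its
conventions, the knobs that matter, and the places where a genuine design
choice had to be made.

## Exact-mass conventions

Ion m/z values are computed from Hill-formula element counts using a
packaged snapshot of IUPAC monoisotopic atomic masses. Three singly
charged species cover the panel:

- `[M-H]-` — deprotonation, the default for the acids and sulfonates;
- `[M+H]+` — protonation, used by the three zwitterionic sulfonamides,
  which are only observed in positive mode;
- `[M-CO2-H]-` — deprotonation after in-source decarboxylation. Two ether
  acids (HFPO-DA and PEPA) lose their carboxyl so efficiently in the source
  that the decarboxylated ion is the reproducible quantitation channel, and
  the registry marks them accordingly.

**The hydrogen convention.** The default adds or removes a *neutral
hydrogen atom* and ignores the electron mass. Published PFAS method tables
print masses under this convention — 6:2 FTS deprotonated is 426.9674 —
whereas the physically complete proton convention gives 426.9679. Since the
package's purpose includes reproducing printed method tables, neutral-H is
the default and `electron_correction = TRUE` switches every computation to
the proton convention. The difference (one electron mass, 0.000549 Da,
about 1.3 ppm at m/z 427) matters exactly at the margins where ppm windows
decide interference questions, which is why it is a single global switch
rather than a silent choice.

**Labeled standards.** Isotope labels are carried as separate counts
(`n13C`, `n2H`), never embedded in the formula string: a label substitutes
the heavy-isotope mass and freezes that position out of the predicted
isotope envelope. For decarboxylated labeled species the removed CO2 carbon
is taken to be unlabeled whenever any unlabeled carbon remains — the
labeled positions of the commercial standards sit on the retained backbone
— and only a fully labeled formula loses a 13C.

**Isotope patterns** are computed by per-element multinomial expansion and
pairwise convolution, merging peaks closer than 0.01 Da. The merge width
sits far below the profile peak width at 60k resolving power (~7 mDa FWHM
at m/z 427 would not be resolved from a 10 mDa neighbor) and far above the
fine-structure splittings (13C vs 33S differs by 4 mDa) that this
instrument class cannot resolve; tests verify the convolution against a
brute-force isotopologue enumeration oracle to 1e-4 relative abundance.

**The near-isobar pair.** Hydro-EVE (deprotonated m/z 426.9657) sits 3.98
ppm below 6:2 FTS and has no public molecular formula, so it ships in the
registry as a mass-only `interference` row; nothing in the package invents
a formula for it. A 3 ppm XIC window excludes it from the 6:2 FTS trace, a
5 ppm window does not — this directionality is asserted in tests.

## The packaged registry

The default registry holds 45 analytes across eight chemical classes
(sulfonates, carboxylates, fluorotelomer sulfonates, sulfonamides,
sulfonamidoacetic acids, ether acids, zwitterions, other) and 23 labeled
internal standards. Molecular formulas were compiled from the compound
names. Retention times and MS2 fragment templates are synthetic defaults —
plausible values for a 20-minute reversed-phase gradient and
class-characteristic fragments — intended for simulation and testing, not
measured values; they are flagged as such in the registry documentation.
Surrogate assignments for analytes without a matched label minimize the
fluorine-count difference, with chemical class as the tie-break, following
the observation that fluorine count is a good surrogate-selection
indicator.

## The validation statistics

From `N` replicate back-calculated concentrations at a level with nominal
("actual") value `A`:

$$\mathrm{HR}_{PIR} = s \cdot t_{N-1,\,1-\alpha/2} \cdot \sqrt{1 + 1/N},
\qquad \alpha = 0.01$$

with `s` the sample standard deviation. A level passes when both
recoveries are inside the band (bounds inclusive):

$$\frac{\bar{x} + \mathrm{HR}_{PIR}}{A} \times 100\% \le 150\%,\qquad
\frac{\bar{x} - \mathrm{HR}_{PIR}}{A} \times 100\% \ge 50\%.$$

The **MRL** is the lowest passing level; the **DL** applies
$s \cdot t_{N-1,\,1-\alpha/2}$ to the MRL level's replicates; **IDP** and
**IDA** are the RSD and mean recovery at the 500 ng/L mid level. `DL ≤
MRL` is *not* asserted anywhere: it is empirically typical but not
guaranteed by the formulas.

**Sidedness.** The DL formula is rendered two-tailed here (quantile
`1 − α/2`), consistent with the HR_PIR rendering, which makes
`DL = HR_PIR / sqrt(1 + 1/N)` an algebraic identity on the same replicate
set. EPA 537.1's own DL uses the one-sided Student t; `sided = "one"` is
provided, and neither reading is asserted as uniquely correct. The
discrepancy is surfaced as a documented switch rather than silently
resolved.

**Replicate selection.** Method practice requires "at least seven" of the
QC replicates without printing a selection rule. The default uses all
available QC replicates (no outlier rejection); `trim_to = 7` enables an
explicit rule (repeatedly drop the farthest-from-mean value) for users who
want the minimal set. The replicate serving as the calibration curve
defaults to replicate 1.

Both t-based statistics are tested against an independent quantile oracle
(t density integrated numerically, inverted by root finding — no shared
code with `qt`) to 1e-6 across df 2–30, and HR_PIR monotonicity in `s`,
`alpha`, and `N` is property-tested.

## Quantitation choices

Quantitation is on MS1 area ratios by default; MS2-based areas flow
through the same interface if an area table is built from MS2 traces.
Defaults that matter:

- **XIC tolerance** 5 ppm: generous against the 2–3 ppm mass accuracy an
  orbitrap achieves in practice, yet tight enough to exclude nothing in
  the panel except the deliberate Hydro-EVE confusion case.
- **Calibration weighting** `1/x`: the calibration spans 2–2000 ng/L
  (three decades); unweighted least squares would let the top standard
  dominate. `none` and `1/x^2` are available; weighted R² is computed on
  the weighted fit and verified against independent matrix algebra.
- **Integration**: apex within ±0.5 min of the expected RT, boundaries
  extended until intensity falls below 2% of apex (`boundary_fraction`),
  trapezoidal area. A bimodal breakthrough peak whose inter-mode valley
  stays above the threshold integrates as one peak — the desired behavior
  for minimally retained early eluters. A zero apex returns a flagged
  zero-area non-detect rather than an error, so validation statistics
  always see a complete replicate grid.
- **dotp** uses the square-root-intensity cosine (the spectral-library
  convention in proteomics tooling); plain-intensity cosine is a config
  option. **idotp** is the plain cosine of the observed vs predicted
  isotope envelope. Both are scale-invariant and live in [0, 1].

Back-calculated concentrations may legitimately be negative at
noise-dominated levels; they are reported as-is and judged by the PIR
recovery criteria, not clipped.

## What the synthetic generator emulates

`simulate_replicate_study` produces the peak-area table of a replicate
calibration study under the sample-preparation arithmetic of the method:
calibrator and IS working solution mixed 900:100 (calibrator dilution
factor 0.9, IS factor 0.1), 100 µL injected, so a 10 ng/L calibrator puts
0.9 pg on column and the 10 000 ng/L IS a constant 100 pg. Areas are
response factor × pg on column, times mean-one lognormal noise, plus an
optional additive baseline term. Noise may be level-dependent (a
level-named CV vector), which is how constructed MRL scenarios are built.

The default calibration levels {2, 5, 10, 50, 100, 500, 1000, 2000} ng/L
span the MRL range reported for panels of this type and include the
500 ng/L IDP/IDA level; ten replicates are prepared, one serving as the
calibration curve. These defaults are configurable but deliberately fixed
— they are the study conditions, not tuning knobs.

**Correlated noise.** Analyte and IS log-noise share a latent normal
factor: in ordinary studies each analyte correlates with its assigned IS
(coefficient ρ, default 1 — the idealization of a co-varying matched
label); `rho = 0` models a surrogate that shares nothing. The ratio then
cancels noise exactly at ρ = 1 and inflates it by √2 at ρ = 0, both
verified by Monte Carlo. In the *surrogate scenario*
(`make_surrogate_scenario`) the structure inverts: every IS correlates
with one focal analyte with coefficient `exp(−rate · ΔF)`, ΔF the
fluorine-count difference — a jointly consistent correlation structure
that gives the surrogate scan a recoverable trend (calibration R² decays
with fluorine mismatch; Spearman ΔF-vs-R² negative in ≥ 45/50 seeded
runs under the default rate 0.2 and CV 8%).

`simulate_scan_stream` generates centroided MS1/MS2 scans for one
injection: isotope envelopes riding Gaussian, exponentially modified
Gaussian, or bimodal breakthrough elution profiles (breakthrough assigned
to early-eluter registry rows; default split 0.3, mode separation
0.15 min), ppm-scale mass jitter, Poisson baseline centroids,
inclusion-list MS2 triggering above an intensity threshold with optional
dynamic exclusion, positive-mode scan events confined to the 9.5–11.5 min
window, and MS1 mass ranges acting as visibility filters (the dual-range
acquisition is modeled as visibility only, not as a sensitivity scaling).
MS2 fragment abundances are concentration-independent (times noise), as
they are on the instrument within the linear range.

**Deliberately not emulated:** realistic noise spectra, mass-calibration
drift, matrix suppression, carryover, chromatographic misalignment across
runs, coeluting-isomer deconvolution. Passing tests on this generator
demonstrate the correctness of the *computations* — mass arithmetic,
integration, calibration algebra, validation statistics, acquisition
logic — not instrument-level performance claims; the generator's noise is
exactly the idealization the statistics assume, which is what makes exact
identities (noiseless IDA = 100.00%) usable as structural checks.

## Numerical and degenerate cases

- CV = 0 yields *exactly* `rf × pg` areas (the lognormal multiplier is
  identically 1), so the noiseless pipeline identity holds to floating
  point, not approximately.
- `s = 0` replicate sets give HR_PIR = DL = 0 and pass PIR at 100%.
- PIR bounds are inclusive (`≤ 150`, `≥ 50`), matching the printed
  criteria; tests pin the boundary at machine precision.
- Fewer than `min_replicates` (default 7) replicates at a level excludes
  the level from the MRL search with a warning; an all-failing compound
  yields a flagged undefined-MRL row, not an error.
- A zero-slope curve refuses to back-calculate; pairs with non-finite
  ratios (zero IS area) are dropped from calibration with a warning.
- Calibration with fewer than two distinct levels is an error.

**The constructed MRL scenario** used in testing designates level 10 ng/L
by giving levels 2 and 5 a 35% area CV (their PIR half-ranges then exceed
the level several-fold, failing the lower criterion with overwhelming
probability) while keeping 10 ng/L and above at 2%. The bad-level CV is
deliberately moderate: the calibration curve is fit on one replicate that
includes the noisy low levels, and a much larger CV lets their lognormal
tails perturb the fitted intercept enough to bias all back-calculations.
At 35%/2% the designated level is recovered as the MRL, in agreement with
an independently coded per-level criterion check, across the test's 20
seeds.

## Problem sizes in the test-suite

The suite exercises the full 45-compound panel wherever the computation is
cheap (replicate-study simulation, validation reports, surrogate scans:
50-seed and 20-seed Monte Carlo loops) and a 7-compound mini registry with
short acquisition spans (~2 min of simulated gradient at a 0.01 min scan
period) for scan-stream work, which keeps the whole suite under a minute
on one core while still covering every acquisition feature. These sizes
were chosen as the smallest that leave every mechanism visible — e.g.
enough scans across a peak for the trapezoid-vs-Gaussian 0.5% closed-form
check.

## Known limitations

- The registry's retention times and fragment templates are synthetic;
  users with real acquisitions should supply their own registry CSV.
- Scan streams serialize to a documented JSON-lines dialect; mzML is not
  written. External peak-area tables (e.g. Skyline exports) can bypass the
  scan-stream layer entirely via `read_area_table`'s column mapping.
- Coeluting isomers ("mixed isomers" entries) are treated as single summed
  peaks; no deconvolution is attempted.
- The MRL search assumes the level grid is the candidate set; it does not
  interpolate between levels.
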