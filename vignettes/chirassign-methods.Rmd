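---
title: "Assigning absolute configuration from computed NMR and ECD evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning absolute configuration from computed NMR and ECD evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirassign)
```

## The problem

Many natural products carry *isolated blocks of chirality*: groups of
stereocenters whose relative configuration within each block is fixed by
ROE correlations and coupling constants, but which share no NOE or J
connectivity with the other blocks, so the blocks cannot be correlated with
each other by NMR geometry arguments alone. The sulfur-containing
alkaloids this package was built around are a textbook case: an
octahydronaphthalene block with five stereocenters and a fused
pyrrolothiazinone block with two (C-19 and C-24). Once relative
configuration is known inside each block, the full assignment reduces to a
small candidate set — here the four stereoisomers obtained by flipping
C-19 and C-24 — that can be discriminated by comparing quantum-chemically
predicted observables with experiment:

1. **DFT-NMR**: computed ¹³C isotropic shieldings, Boltzmann-averaged over
   a conformer ensemble and linearly scaled, ranked against the
   experimental shift table. NMR is blind to mirror reflection, so this
   stage can only pin the *relative* configuration of the varied block.
2. **TDDFT-ECD**: rotational strengths broadened into Δε curves and
   compared with the measured circular dichroism spectrum. ECD is
   sign-sensitive, and in favourable cases distinct wavelength regions are
   governed by distinct stereocenters, so a region-wise comparison reads
   out the *absolute* configuration of one block at a time.

`chirassign` implements everything downstream of the quantum-chemistry
engines: the ensemble bookkeeping, the spectral arithmetic, the scoring,
and the evidence logic that merges the two stages (plus HRESIMS formula
arithmetic and a blind-docking pose filter used in the same study design).
The electronic-structure and docking computations themselves are out of
scope; their outputs enter as tabular interchange files, and seeded
generators emulate them so the whole pipeline is testable offline.

## Boltzmann machinery

Conformer populations follow $p_i \propto \exp(-E_i / RT)$ with
$R = 8.31446\ \mathrm{J\,mol^{-1}K^{-1}}$ and a default $T = 298.15$ K
(the source protocols do not state a temperature; room temperature is the
universal default in this field). Energies are exchanged in kJ/mol
relative to the ensemble minimum; absolute hartree energies can be
converted with `hartree_to_rel_kjmol()` (1 hartree = 2625.4996 kJ/mol).
Two filters reproduce the standard protocol:

* `apply_energy_window()` keeps conformers with relative energy ≤ 21
  kJ/mol by default — the conformational-search window. The boundary is
  inclusive (the protocols are silent; inclusivity is the conservative
  reading and is asserted in tests).
* `apply_population_floor()` then drops conformers below 1 % Boltzmann
  population and renormalizes. Because Boltzmann weights renormalize
  multiplicatively, recomputing weights over the survivors is identical to
  renormalizing the retained populations; tests assert this commutation.
  A floor exceeding every population would empty the ensemble and raises
  an explicit `AmbiguousFloor` error instead.

## NMR scaling and ranking

Computed shieldings map to shifts through the affine correction
$\sigma = I + S\,\delta$, inverted as $\delta = (\sigma - I)/S$. The
built-in constants are the published multi-standard pairs for the
mPW1PW91/6-311+G(2d,p) level: $I = 185.6277$, $S = -1.0175$ (methanol) and
$I = 185.2853$, $S = -1.0267$ (DMSO). `fit_correction()` re-derives a pair
from reference data by ordinary least squares when users work at another
level of theory.

Because the correction is affine, Boltzmann-averaging shieldings and then
converting is *exactly* the same as converting per conformer and then
averaging; the package averages shieldings first and a property test
asserts the equivalence to 10⁻¹⁰. This also makes the (unstated) order of
operations in published protocols irrelevant.

Agreement with experiment is summarized by MAE (the field's default for
shielding-scaling protocols), RMSD, maximum deviation, and CMAE — the MAE
after re-fitting a least-squares line of observed on predicted shifts,
which absorbs residual systematic slope/offset error. One caution: CMAE is
conventionally described as "always ≤ MAE", but under a least-squares
(not least-absolute-deviation) re-fit this is a strong tendency, not a
theorem; with nearly unbiased predictions CMAE can exceed MAE by a hair.
The package implements the conventional least-squares form and tests the
inequality in the regime it is meant for, systematic affine distortion.

`rank_stereoisomers_nmr()` orders candidates by ascending error over ¹³C
shifts only (¹H shifts are exposed but do not drive the default ranking —
proton shifts are more solvent- and conformation-sensitive and the
discrimination here rests on carbons). Ties within 10⁻⁹ are reported as
ties, never silently broken. Diastereotopic protons (H-25a/H-25b) are
matched by label string; no automatic pairing swap is attempted.

## ECD broadening and comparison

A calculated ECD curve is a sum of Gaussians over transitions $i$:

$$\Delta\varepsilon(\tilde\nu) \;=\; \sum_i
  \frac{\tilde\nu_i R_i}{22.97\,\sqrt{\pi}\,\sigma}\,
  \exp\!\left(-\left(\frac{\tilde\nu-\tilde\nu_i}{\sigma}\right)^{\!2}\right)$$

with wavenumbers in cm⁻¹, dipole-velocity rotational strengths $R_i$ in
10⁻⁴⁰ cgs units, and the prefactor's 22.97 arising from the cgs constant
2.297 × 10⁻³⁹ once $R$ is expressed in 10⁻⁴⁰ units. The prefactor uses the
transition's own wavenumber $\tilde\nu_i$, not the evaluation point. The
band width is printed as "3000 cm⁻¹ at half height" in the protocols this
reproduces; the package reads that as a FWHM and converts to the 1/e
half-width in the exponent, $\sigma = \mathrm{FWHM}/(2\sqrt{\ln 2})$. Some
programs exponentiate the printed number directly; the
`width_convention = "1/e"` switch reproduces that behaviour. The default
grid is 180–450 nm in 1 nm steps, covering the usual 200–400 nm
measurement range with margin.

Calculated-versus-experimental agreement is quantified as the cosine
similarity (normalized inner product) of the two curves on their common
grid: +1 for identical shape, −1 for an exact mirror image (the
enantiomer), with intensity scaling irrelevant by construction. A rigid
integer-nm shift scan is available as a crude systematic-energy-offset
correction; the best least-squares scale factor is reported for plotting
but never affects the score. Published assignments of this kind are argued
visually ("reproduced equally well" / "gave a mismatch"); the cosine score
is this package's quantification of that judgement and is not claimed to
reproduce any printed number.

`region_ranking()` applies the score per wavelength region, because the
physics that makes this workflow work is that different regions can be
governed by different stereocenters (here: the region above 240 nm reports
C-19; the intense negative Cotton effect below 240 nm reports the fixed
C-4 block). Its tie tolerance defaults to 0.05 cosine units: differences
smaller than typical band-shape noise are not evidence, and this is what
lets two epimers that genuinely "reproduce the spectrum equally well" tie
for first place so that downstream logic draws no conclusion about the
center the region does not report. The region boundary is a parameter, not
a constant — it is compound-specific.

## Evidence combination

`enumerate_candidates()` builds the candidate set (Cartesian R/S flips
over the undetermined centers); `combine_evidence()` filters it with two
kinds of items:

* **relative** patterns (from ROE or from the NMR ranking) match a
  candidate up to global inversion of the referenced centers;
* **absolute** patterns (from region-wise ECD) match exactly, and may list
  several accepted alternatives.

Filtering has set semantics — order-independent, monotone — and zero
survivors are flagged as contradictory evidence rather than silently
returned. `assign_configuration()` wires the upstream results in: the
top-ranked NMR pattern (with ties) enters as relative evidence; each
block's reporter-region winners (with ties) enter as absolute evidence on
that block's varied centers. When evidence underdetermines the answer the
full ambiguity set is returned; the two-stage narrative — NMR alone leaves
a two-candidate ambiguity, region-wise ECD resolves it — falls out of this
logic. Where NMR and ROE conflict (as happens for one of the compounds
this was modelled on), the package reports the contradiction; it encodes
no fixed trust hierarchy, leaving precedence to the analyst.

ROESY interpretation itself is expert geometric reasoning and stays
outside the package: ROE-derived relative configurations enter as
user-supplied evidence items. Stereodescriptors are opaque R/S labels; no
CIP perception from 3D structures is performed.

## Formula arithmetic

`monoisotopic_mass()` sums embedded most-abundant-isotope masses (IUPAC
2021 values, cross-checked against independent calculators) and subtracts
one electron mass (0.000549 Da) per positive charge, so `adduct_mz()`
reproduces "calcd for" values exactly as mass spectrometrists print them.
RDBE uses the standard valence contributions (C,Si +1; H,halogens −½;
N,P +½; O,S 0) plus 1. `formula_search()` is a brute-force enumeration
over per-element ranges, filtered by ppm tolerance and RDBE ≥ 0 and ranked
by absolute error — small ranges keep it exhaustive and exact.

## Docking pose filter

Pose-pose RMSD uses the identity atom mapping with no superposition —
docking poses live in the receptor frame, so rigid-body differences are
real. Clustering is the classic greedy leader scheme: visit poses best
score first (ties by id, so results are deterministic), join the first
cluster whose leader is within the 2.0 Å cutoff, else seed a new cluster.
A binding mode is *valid* iff the largest cluster holds at least 20 % of
all poses (inclusive) **and** its leader sits in the binding pocket. The
pocket test — no formal definition exists in the protocols this models —
is operationalized as: any ligand heavy atom within 4.0 Å (inclusive) of
any pocket reference atom, or inside a user-supplied centroid sphere. All
thresholds are arguments with these defaults. Hydrogens are ignored
throughout; symmetry-aware RMSD is out of scope.

## What the synthetic generators emulate — and what they don't

The generators produce data with the *statistical shape* of the real
inputs at the study's scale (4 candidate stereoisomers, a handful of
conformers each, energies inside a 21 kJ/mol window), with planted truth
so every downstream step is a parameter-recovery experiment:

* `gen_nmr_ensembles()`: shieldings built as $I + S(\delta_{true} +
  \varepsilon)$ with Gaussian $\varepsilon$ (default SD 0.5 ppm, a typical
  ¹³C residual for scaled GIAO protocols) and planted inter-isomer
  differences of 3 ppm on 3 carbons — the order of the real C-17/C-19
  differences between epimers here. The default "distinct" mode gives
  every candidate its own shifts (unique recovery); "relative" mode makes
  mirror-block candidates share shifts, reproducing NMR's physical
  blindness to reflection for end-to-end tests.
* `gen_ecd_ensembles()`: sticks in two well-separated regions; the
  epimer at the reporter center flips signs only inside the reporter
  region, an enantiomer would flip all. Sticks are placed ≥ 40 nm inside
  the reporter region so that 3000 cm⁻¹ bands (σ ≈ 1800 cm⁻¹) do not bleed
  across the boundary, emulating the well-separated chromophores (a ~310
  nm band versus a < 240 nm Cotton effect) that make region logic valid at
  all.
* `gen_pose_cloud()`: Gaussian blobs of translated copies of one rigid
  ligand template (no rotational noise), scores correlated with blob rank.
* `gen_experimental_shift_table()`: seeded Gaussian perturbation of the
  packaged experimental tables.

All randomness is Gaussian and conformers are statistically independent —
deliberately non-physical simplifications. Passing the recovery suites
therefore shows that the *pipeline arithmetic and decision logic* are
correct under the stated noise model; it does not validate DFT shielding
accuracy, TDDFT band shapes, vibronic structure, or docking score
realism on real molecules. Every generator is a pure function of its seed
(asserted by tests), and generation runs inside a protected RNG scope so
callers' seeds are untouched.

## Numerical choices and degenerate inputs

* Boltzmann weights exponentiate energies relative to the running minimum,
  so large absolute energies cannot overflow.
* Zero transitions broaden to an all-zero spectrum (not an error); the
  cosine score of an all-zero curve is defined as 0.
* Spectra are resampled by linear interpolation onto the experimental grid
  restricted to the overlap; non-overlapping grids are an error.
* Energy-window and population-floor boundaries, the 20 % occupancy rule,
  and the 4.0 Å contact rule are all inclusive, each asserted by a
  boundary test.
* Ranking ties: NMR at 10⁻⁹ (exact duplicates), ECD at 0.05 (band-noise
  scale), clustering by pose id — all deterministic and documented above.

## Problem sizes used in the shipped experiments

The packaged test-and-acceptance experiments run at the study's own scale:
4 candidates × 8 conformers × 24 carbons for NMR recovery (200 seeded
replicates for the ≥ 95 % recovery rate), 3 conformers × 7 transitions for
ECD, and 200 poses in two blobs (0.7/0.3) for the docking filter. These
sizes mirror the real workflow's magnitudes while keeping each experiment
in the seconds range.

## Known limitations

No DP4-style probabilistic scoring; no velocity↔length gauge handling; no
vibronic or solvent-shift modelling beyond the rigid shift scan; no
symmetry-corrected RMSD; no CIP perception; no isotope fine structure.
The printed conformer counts of the original study depend on the external
conformational-search and DFT engines and are treated as narrative
context, not reproduction targets.
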