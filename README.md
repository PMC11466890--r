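# chirassign

Assignment of absolute configuration in natural products from computed
NMR and ECD evidence, for molecules with **isolated blocks of
chirality** — groups of stereocenters whose relative configuration is
known within each block (from ROE/J data) but which cannot be correlated
with one another by NMR geometry arguments.

The package implements everything *downstream* of the quantum-chemistry
and docking engines in the standard workflow:

* **Formula arithmetic** — Hill-notation parsing, monoisotopic and adduct
  masses with electron-mass correction, ring-plus-double-bond equivalents,
  brute-force formula search for HRESIMS verification.
* **Conformer ensembles** — Boltzmann populations
  (p&#7522; ∝ exp(−E&#7522;/RT)), the 21 kJ/mol energy-window and 1 %
  population-floor filters.
* **DFT-NMR scoring** — linear shielding→shift scaling δ = (σ − I)/S with
  the published solvent pairs (I = 185.6277, S = −1.0175 for MeOH;
  I = 185.2853, S = −1.0267 for DMSO), Boltzmann-averaged shift
  prediction, MAE/CMAE/RMSD against experimental tables, stereoisomer
  ranking.
* **TDDFT-ECD spectra** — Gaussian broadening of dipole-velocity
  rotational strengths (3000 cm⁻¹ width at half height by default),
  Δε(ν̃) = Σ ν̃ᵢRᵢ/(22.97√π σ)·exp(−((ν̃−ν̃ᵢ)/σ)²), cosine similarity
  against experimental curves globally and per wavelength region.
* **Evidence combination** — candidate enumeration over undetermined
  centers, relative (mirror-invariant) and absolute evidence items,
  monotone filtering with a first-class ambiguity result.
* **Docking pose filter** — in-place RMSD, greedy leader clustering at
  2.0 Å, and the validity rule *largest cluster ≥ 20 % of poses and
  located in the binding pocket*.
* **Seeded synthetic generators** that emulate quantum-chemistry and
  docking outputs with planted truth, so the full pipeline is testable
  with no external software.

Experimental ¹H/¹³C shift tables for the three sulfur-containing
alkaloids the workflow was built around (aplospojaveedins A–C, DMSO-d6)
ship as packaged fixtures (`load_compound_shifts(1:3)`).

## Worked example

HRESIMS arithmetic for the neutral composition C26H35O5N3S:

```r
library(chirassign)
adduct_mz("C26H35O5N3S", "[M+H]+")   # 502.2370  (observed: 502.2366)
rdbe("C26H35O5N3S")                  # 11 degrees of unsaturation
```

The two-stage configurational assignment on a synthetic analogue of the
compound-1 problem (octahydronaphthalene block fixed as 3R,4S,5R,8R,10S;
C-19/C-24 undetermined). Stage 1, NMR ranking:

```r
sim <- gen_nmr_ensembles(seed = 11, mode = "relative")
rk  <- rank_stereoisomers_nmr(sim$ensembles, sim$observed,
                              builtin_correction("meoh"))
rk
#>                stereo_label   mae  cmae  rmsd rank  tied
#> 1 (3R,4S,5R,8R,10S,19R,24R) 0.200 0.196 0.238    1 FALSE
#> 2 (3R,4S,5R,8R,10S,19S,24S) 0.203 0.193 0.268    2 FALSE
#> 3 (3R,4S,5R,8R,10S,19S,24R) 0.581 0.623 1.122    3 FALSE
#> 4 (3R,4S,5R,8R,10S,19R,24S) 0.633 0.686 1.095    4 FALSE
```

The two mirror-block candidates (19R,24R) and (19S,24S) score equally
well (MAE ≈ 0.20 ppm): NMR pins the *relative* configuration of the
block but cannot orient it absolutely.

```r
blocks <- list(
  block_definition("octahydronaphthalene", c("3","4","5","8","10"),
                   reporter_region = c(190, 239)),
  block_definition("thiazinone", c("19","24"),
                   reporter_region = c(240, 450)))
cands <- enumerate_candidates(blocks,
  c("3"="R","4"="S","5"="R","8"="R","10"="S"), vary = c("19","24"))

assign_configuration(blocks, cands, nmr_result = rk)
#> <assignment_report> ambiguous between:
#>   (3R,4S,5R,8R,10S,19R,24R), (3R,4S,5R,8R,10S,19S,24S)
```

Stage 2, region-wise ECD. Above 240 nm the spectrum is governed by C-19:
the 19S epimers mirror the band (cosine ≈ −1) while below 240 nm all four
candidates reproduce the curve and tie:

```r
sime    <- gen_ecd_ensembles(seed = 11)
spectra <- lapply(sime$ensembles, ensemble_ecd_spectrum)
rr <- region_ranking(spectra, sime$exp_spectrum,
                     list(c(240, 450), c(190, 239)))
rr
#>      region              stereo_label  score rank tied
#> 1 240-450nm (3R,4S,5R,8R,10S,19R,24R)  0.999    1 TRUE
#> 2 240-450nm (3R,4S,5R,8R,10S,19R,24S)  0.999    1 TRUE
#> 3 240-450nm (3R,4S,5R,8R,10S,19S,24R) -0.998    2 TRUE
#> 4 240-450nm (3R,4S,5R,8R,10S,19S,24S) -0.999    2 TRUE
#> 5 190-239nm (3R,4S,5R,8R,10S,19R,24R)  1.000    1 TRUE
#> ...

assign_configuration(blocks, cands, nmr_result = rk, ecd_region_result = rr)
#> <assignment_report> assigned configuration: (3R,4S,5R,8R,10S,19R,24R)
```

Combining the NMR relative pattern with the ECD verdict on C-19 leaves a
unique stereodescriptor — the planted truth of the simulation.

Docking post-processing on a synthetic pose cloud:

```r
simp <- gen_pose_cloud(seed = 11)
validate_binding_mode(simp$poses, simp$pocket)
#> <binding_verdict> VALID - largest cluster meets the occupancy threshold
#>   and sits in the pocket
```

A thin command-line front end over the same functions lives at
`system.file("cli", "chirassign.R", package = "chirassign")` with
subcommands `formula`, `boltzmann`, `nmr-assign`, `ecd`, `dock-filter`
and `simulate`.

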