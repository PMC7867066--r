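---
title: "Fractional 13C labeling: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional 13C labeling: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracnmr)
```

# The labeling model

When cells grow on a mixture of U-¹³C₆ glucose (molar fraction *f*) and
unlabeled glucose, every glucose-derived metabolic precursor molecule is
either fully ¹³C (an "intact" unit) or carries ¹³C only at natural
abundance. `fracnmr` models each precursor molecule instance as:

* fully labeled with probability *q = f · purity*;
* otherwise each carbon independently ¹³C at the natural abundance *a*.

Amino-acid carbons are mapped to precursor molecules by a curated table
(`inst/extdata/precursor_map.tsv`, standard E. coli biosynthesis). Two
bonded carbons from one precursor are co-labeled — the bond contributes a
¹³C–¹³C coupling whenever the unit is labeled — while carbons from two
different precursors are labeled independently. Hence, with *a* = 0:

* intact bond: P(both ¹³C) = *q*, and P(partner | reference) ≈ 1;
* across-precursor bond: P(both) = *q*², i.e. **4% at *f* = 0.2** — the
  canonical Val/Leu/Ile Cα–Cβ case, since branched-chain biosynthesis
  assembles Cα and Cβ from two different pyruvate molecules.

All higher-level quantities (`p_joint_label()`,
`conditional_partner_label()`, `predict_cbca_ratio()`,
`methyl_multiplet()`) marginalize this model; `enumerate_isotopomers()`
is the brute-force reference that the closed forms are tested against
for every bond of all 20 residue types.

## TCA scrambling

Residues built from oxaloacetate or 2-oxoglutarate (Asp, Asn, Thr, Met,
Lys, Glu, Gln, Pro, Arg backbones) pass through the citric-acid cycle,
where cycling and the symmetry of fumarate break precursor bonds to a
degree that depends on aeration during expression. This is not
quantifiable from the scheme alone, so it is exposed as a single
parameter `scramble` *s* ∈ [0, 1]: with probability *s* a TCA-derived
unit splits into independent single-carbon units. The joint probability
of a TCA intact bond interpolates linearly between the intact (*q*) and
independent (*q*²-like) limits. The default *s* = 0.5 places the TCA
group between the intact and broken groups, reproducing the observed
ordering without pretending more knowledge than exists; it is a modeling
choice, not a measured value.

## Attenuation: from probabilities to peak ratios

Observed CBᵢ/CAᵢ intensity ratios sit below the pure conditional
probability because the CA→CB transfer also pays for transverse
relaxation, passive couplings and transfer delays. These losses are
collapsed into one multiplicative constant per group
(`default_attenuation()`): 0.825 (intact-high), 0.55 (intermediate-TCA),
0.5 (broken-low). The defaults are a calibration chosen once so that, at
*f* = 0.2 with default natural abundance and purity, the intact group
lands in the experimentally reported 0.75–0.90 band and the broken group
near 0.10; they are configurable and documented as calibration, not
prediction. With attenuation set to 1 the ratios are pure labeling
probabilities (e.g. ratio(Val)/ratio(Ala) = *f*).

## Stereospecific methyls

Ketol-acid reductoisomerase migrates one methyl during Val/Leu
biosynthesis. The retained methyl (named Cγ1/Cδ1 here) keeps an intact
bond to its attached carbon and is pro-R: its ¹³C signal is a doublet
whenever observed. The migrated methyl (Cγ2/Cδ2, pro-S) sits across a
precursor boundary and is a singlet in ~(1 − *f*) of the labeled
molecules. `stereo_assign_methyls()` inverts this rule on annotated
ct-HSQC multiplets and refuses to guess when both methyls carry the same
annotation. The pro-R/pro-S keys are the API; the atom-name convention
is cosmetic.

# Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `f_labeled` | molar fraction | — (0.2 typical) | the isotope dilution itself |
| `nat_abund` | fraction | 0.011 | ¹³C natural abundance |
| `isotopic_purity` | fraction | 0.99 | vendor enrichment of U-¹³C₆ glucose |
| `scramble` | fraction | 0.5 | aeration-dependent TCA bond loss (see above) |
| overlap tolerances | ppm | 0.03 (¹H), 0.3 (¹⁵N), 0.3 (¹³C) | typical linewidth-scale separations |
| NOE cutoff | — | 0.65 | excludes flexible residues from τ_c averaging |
| CSP ¹⁵N weight | — | 0.154 | standard amide-CSP weighting |
| CSP threshold | ppm | 0.01 | strict inequality; a CSP exactly at threshold is not called |
| γ(¹⁵N)/γ(¹H) | — | 0.101329 | fixed constant, sign ignored |

# Numerical choices

* **Exponential fits** use `stats::nls` with the `"port"` algorithm (the
  default Gauss–Newton cannot handle zero-residual, i.e. noiseless,
  data) and a log-linear regression start. Two points are solved
  exactly; non-decaying or constant data yield a per-residue failure
  flag so batch pipelines continue. Fits are unweighted by default;
  under multiplicative noise the reported standard errors are therefore
  approximate.
* **τ_c closed form**: τ_c = √(6·T₁/T₂ − 7)/(4π·ν_N), defined only for
  T₁/T₂ > 7/6 and documented as a rigid-rotor single-field
  approximation. Against a full ¹⁵N spectral-density oracle (dipolar
  r_NH = 1.02 Å plus −160 ppm CSA) it agrees within ~1% over 3–15 ns at
  850 MHz; the test budget allows 5%.
* **Empirical τ_c from MW** uses Stokes–Einstein–Debye with v̄ = 0.73
  cm³/g and a 3.2 Å hydration shell; for a 10 kDa protein at 303 K it
  gives ≈ 4.2 ns. Literature "empirical" values can run ~20% higher
  depending on the hydration convention, so no exact match is asserted.
* **Kabsch superposition** uses the SVD construction with the
  determinant sign fixed, so reflections are never applied; collinear or
  <3-atom selections are errors. Mean structures are raw iterative
  coordinate averages (superpose → re-average until the mean moves
  < 1e-6 Å), not energy-minimized.
* **RMSD matrices** reproduce the asymmetric mean-vs-bundle convention:
  diagonal = pairwise within-bundle mean ± sd, off-diagonal (row A,
  column B) = RMSD of mean(A) to each member of B. The matrix is
  reported asymmetric, not symmetrized. Note a statistical consequence
  checked by the tests: for bundles scattered around a common base with
  per-coordinate σ, pairwise RMSD ≈ σ√6 while mean-vs-member RMSD is
  smaller by √((1 + 1/n)/2); the two conventions are *not*
  interchangeable.
* **Tie-breaks**: group inference scores are ranked with a stable sort
  in the declared order intact-high, intermediate-TCA, broken-low, so a
  ratio equidistant from two bands resolves deterministically.

# What the synthetic generators emulate — and what they do not

Each generator is seeded (identical arguments ⇒ bit-identical output,
including written files) and emits its generating truth.

* `gen_peaklist()` emulates intra-residual CA/CB peak heights: a
  log-normal base intensity per residue times the model-predicted ratio
  for CB, with multiplicative log-normal noise (default sdlog 0.1,
  ~10% scatter typical of 3D peak heights). Gly rows lack CB, Pro rows
  are absent. It does **not** simulate sequential peaks' J-transfer
  physics, lineshapes, or realistic chemical shifts — positions are
  uniform draws in typical ppm ranges, enough to exercise overlap logic.
* `gen_decay()` produces mono-exponential decays at the standard delay
  lists (T₁: 10–2000 ms; T₂: 16–256 ms) with per-residue true constants
  drawn around 694 ± 17 / 104 ± 7 ms and 2% multiplicative noise. No
  cross-correlated relaxation, no offset/baseline effects.
* `gen_titration()` uses exact two-state 1:1 fast-exchange binding (the
  binding quadratic) with defaults mimicking a weak millimolar
  interaction probed up to 25:1 ligand excess; non-binders get 0.001 ppm
  jitter. Intermediate/slow exchange and lineshape effects are out of
  scope.
* `gen_ensemble()` scatters an ideal helical backbone by isotropic
  per-atom Gaussian noise and hides it behind random rigid motions.
  Real NMR bundles have correlated, restraint-shaped variance; a green
  recovery test establishes that the estimators undo rigid motions and
  average isotropic noise correctly, not that they reproduce any
  deposited ensemble.

# Known limitations

* The precursor map is E. coli-centric; other expression hosts (yeast,
  cell-free) have different scrambling patterns.
* Aromatic ring fine structure is limited to bond-intactness flags; no
  multi-carbon multiplet prediction for rings.
* Only single-field τ_c estimation; no model-free (Lipari–Szabo)
  analysis, no anisotropic diffusion.
* No Kd fitting from titrations (the generator's binding model would
  support adding it); no automated free↔bound assignment transfer
  beyond nearest-neighbor matching.
* Cost arithmetic is static input prices; note the reported
  "twice the cost of a ¹⁵N-only sample" comparison is not reproducible
  from the printed prices (60/20 = 3); the package reports recipe
  arithmetic only and takes no position.
* PDB reading is the fixed-column text format (ATOM/MODEL/ENDMDL,
  altloc by occupancy); no mmCIF.
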