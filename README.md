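# fracnmr

Planning and analysis toolkit for **biosynthetically directed fractional
¹³C labeling** of proteins: NMR samples grown on a mixture of U-¹³C₆ and
unlabeled glucose (typically 20% labeled), uniformly ¹⁵N labeled. Such
samples cost a fraction of a uniformly ¹³C-labeled preparation yet still
support full backbone assignment and structure determination — provided
you know which ¹³C–¹³C connectivities survive biosynthesis.

The package is aimed at protein NMR spectroscopists planning or analyzing
fractional-labeling experiments. It covers:

* **Isotopomer prediction** — per amino-acid ¹³C labeling statistics from
  a curated precursor map of E. coli biosynthesis. For a bond whose
  carbons come from one precursor molecule ("intact"), P(both ¹³C) ≈ f,
  the labeled-glucose fraction; for a bond spanning two precursors it
  falls to f² (4% at f = 0.2). TCA-derived residues interpolate via a
  scramble parameter.
* **CB/CA peak statistics** — the CBᵢ/CAᵢ intensity ratio from assigned
  HNCACB-type peak lists, with Gly/Pro/overlap exclusions, per-type
  aggregation, amino-acid-type group inference, and stereospecific
  pro-R/pro-S methyl calls for Val/Leu from ct-HSQC singlet/doublet
  patterns.
* **¹⁵N relaxation** — mono-exponential T₁/T₂ fits (I(t) = I₀·e^(−t/T)),
  heteronuclear NOE ratios, and the rotational correlation time from the
  single-field closed form τ_c = √(6·T₁/T₂ − 7)/(4π·ν_N).
* **CSP titrations** — peak tracking across a ligand series and the
  weighted perturbation Δδ_av = √(Δδ_H² + (0.154·Δδ_N)²) with a strict
  0.01 ppm significance threshold.
* **Ensemble comparison** — Kabsch superposition, iterative mean
  structures, asymmetric mean-vs-bundle RMSD matrices over residue
  ranges and backbone/heavy atom sets, per-residue global displacement.
* **Cost planning** — per-litre isotope costs, scheme cost ratios, and
  the molar-mass-corrected effective ¹³C fraction of a glucose mix.
* **Synthetic data** — seeded generators for every input type (peak
  lists, decay series, titrations, multi-model PDB ensembles), each
  emitting its generating truth for recovery tests.

## Worked example

Predicted CBᵢ/CAᵢ ratios at 20% labeling (defaults: natural abundance
0.011, glucose purity 0.99, TCA scramble 0.5):

```r
library(fracnmr)
predict_cbca_table(labeling_scheme(0.2))
#>    residue            group  ratio
#> 1      ALA      intact-high 0.7902
#> 2      ARG intermediate-TCA 0.3203
#> ...
#> 13     PHE      intact-high 0.7902
#> 18     VAL       broken-low 0.1034
```

The intact-bond group (Phe, Tyr, Ala, His) keeps ~80% of the CA
intensity on CB — the bond survives glycolysis intact — while Val, Leu
and Ile drop to ~0.10 because branched-chain biosynthesis assembles Cα
and Cβ from two different pyruvate molecules. That is also why the pro-S
methyl of Val shows a mostly-singlet ¹³C pattern at f = 0.2:

```r
methyl_multiplet("VAL", "pro-S",
                 labeling_scheme(0.2, nat_abund = 0, isotopic_purity = 1))
#> singlet doublet
#>     0.8     0.2
```

Relaxation, fitted from synthetic decays generated at the standard delay
lists (true T₁ = 694 ± 17 ms, T₂ = 104 ± 7 ms, 2% noise):

```r
t1 <- gen_decay(experiment = "T1", seed = 1)
t2 <- gen_decay(experiment = "T2", seed = 2)
s <- summarize_relaxation(fit_decay_table(t1$decays),
                          fit_decay_table(t2$decays), field_1H = 850)
s$summary
#>   quantity    mean      sd
#> 1    T1_ms 696.672 18.5951
#> 2    T2_ms 103.973  7.9939
#> 3    T1/T2   6.742  0.5772
s$tau_c$from_ratio_of_means
#> <tauc_estimate> tau_c = 5.32 ns (T1/T2 = 6.7 at 850 MHz)
```

A T₁/T₂ of 6.7 at 850 MHz corresponds to τ_c ≈ 5.3 ns — a ~10 kDa
monomer tumbling freely.

Costs of the two schemes per litre of M9 (0.4 vs 2.0 g ¹³C-glucose at
100 EUR/g plus 0.8 g ¹⁵NH₄Cl at 25 EUR/g):

```r
r <- example_recipes()
scheme_cost(r$frac20); scheme_cost(r$uniform); cost_ratio(r$frac20, r$uniform)
#> [1] 60
#> [1] 220
#> [1] 0.2727273      # "about one-fourth"
effective_13c_fraction(r$frac20_prep)
#> [1] 0.2026204      # 0.42 g labeled + 1.6 g unlabeled glucose -> ~20%
```

## Command line

```sh
inst/cli/fracnmr simulate --what peaks --seed 1 --out-dir demo
inst/cli/fracnmr ratios demo/peaks.csv --out demo/ratios.csv
inst/cli/fracnmr relax t1.csv t2.csv --field-mhz 850 --noe-cutoff 0.65
inst/cli/fracnmr csp titration_manifest.json --threshold 0.01
inst/cli/fracnmr compare bundleA.pdb bundleB.pdb --range 459-541 --atoms backbone
inst/cli/fracnmr cost
```

Exit codes: 0 success, 2 input error, 3 numerical failure.

## Documentation

The methods vignette (`vignettes/fractional-labeling.Rmd`) describes the
labeling model and its assumptions, the parameter defaults, what the
synthetic generators do and do not emulate, and known limitations.
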