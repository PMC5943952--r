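# groupadd

Atom-group additivity models for two liquid-phase descriptors at opposite
ends of dilution: the **liquid viscosity coefficient** at 293.15 K,
modelled as log₁₀(η/cP), and the **activity coefficient at infinite
dilution in water** at 298.15 K, modelled as log₁₀ γ∞.  The method covers
ordinary organic molecules (H, B, C, N, O, P, S, Si, halogens) and ionic
liquids, whose charged moieties are handled by dedicated atom groups.

The package is aimed at property-prediction and QSPR work in
cheminformatics: given a 2D structure (SDF V2000 or SMILES), it performs
the complete "radical breakdown" of the molecule into atom-centered
groups, looks the groups up in the published parameter tables, and sums
their contributions

    Y = Σᵢ aᵢ Aᵢ + Σⱼ bⱼ Bⱼ + C

where `Aᵢ` are atom-group counts, `Bⱼ` special-group counts (per-carbon
alkane / unsaturated-hydrocarbon terms and an intramolecular
hydrogen-bond term, log γ∞ only) and `C` a constant (viscosity only,
−0.70).  A hard eligibility gate ensures that a number is produced only
when every group of the molecule is present in the table and *valid*
(supported by at least three training molecules); otherwise a structured
verdict lists the offending groups.  Beyond prediction, the package
contains the full training machinery — sparse design matrices,
Gauss–Seidel least squares on the normal equations, ten-fold
cross-validation with per-fold validity recomputation, and iterative
outlier exclusion against three times the cross-validated standard error
— so the parameter tables can be re-derived or extended from new
experimental data.

## Worked example

```r
library(groupadd)
visc <- load_packaged("log_eta_293K")

predict_property(read_smiles("CCO", id = "ethanol"), visc)
#> <prediction> ethanol: log_eta_293K = 0.3300 (linear 2.138)
```

The value 0.33 is the hand sum over the packaged viscosity table —
constant −0.70, methyl group `C sp3 | H3C` −0.06, methylene-to-oxygen
group `C sp3 | H2CO` 0.51, hydroxyl oxygen `O | HC` 0.58 — and 2.138 is
the back-transformed viscosity in cP.  Ionic liquids work the same way;
both ions of one record are perceived together, and the imidazolium
cation is automatically rewritten into its calculation form (positive
charge on C2, aromatic C2–N bonds):

```r
il <- read_smiles("CCCCn1cc[n+](C)c1.[B-](F)(F)(F)F", id = "[BMIM][BF4]")
p <- predict_property(il, visc)
print(p$breakdown, row.names = FALSE)
#>           signature count contribution product
#>             B(-)|F4     1         1.50    1.50
#>          C sp2|H=CN     2         0.48    0.96
#>          C sp3|H2C2     2         0.09    0.18
#>          C sp3|H2CN     1         0.63    0.63
#>           C sp3|H3C     1        -0.06   -0.06
#>           C sp3|H3N     1         0.54    0.54
#>  C(+) aromatic|H:N2     1         0.40    0.40
#>  N aromatic|C2:C(+)     2        -0.05   -0.10
#>               CONST     1        -0.70   -0.70
p$value
#> [1] 3.35
```

Each breakdown row is one atom group (center type | canonical neighbour
string) with its count, tabulated contribution and product; the
prediction is their sum in log₁₀(η/cP).  An ineligible molecule instead
reports `missing`/`invalid` signatures and no value.

Training works on any set of perceived molecules (or synthetic count
matrices):

```r
tr  <- training_set(lapply(mols, perceive), values)      # values in log units
fit <- fit_with_outlier_removal(tr, uses_constant = TRUE)  # viscosity-style model
cv  <- cross_validate(tr, k = 10)
```

A command-line front end is installed at
`system.file("scripts/groupadd", package = "groupadd")` with subcommands
`perceive`, `predict`, `fit`, `cv` and `synth`.

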