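---
title: "Atom-group additivity for liquid viscosity and aqueous infinite-dilution activity coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-group additivity for liquid viscosity and aqueous infinite-dilution activity coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupadd)
```

## The model

`groupadd` implements an atom-centered group-contribution model for two
molecular descriptors at opposite ends of dilution: the decimal logarithm
of the liquid viscosity coefficient at 293.15 K, log(η/cP), and the decimal
logarithm of the activity coefficient of a solute at infinite dilution in
water at 298.15 K, log γ∞.  A descriptor Y of a molecule is the linear
combination

$$ Y \;=\; \sum_i a_i A_i \;+\; \sum_j b_j B_j \;+\; C $$

where $A_i$ counts how often atom group $i$ occurs in the molecule, $a_i$
is that group's tabulated contribution, $B_j$ are special-group counts
with contributions $b_j$, and $C$ is a constant.  The viscosity model uses
the constant ($C = -0.70$) and no special groups; the activity-coefficient
model uses no constant ($C = 0$) and three special groups: a per-carbon
alkane term, a per-carbon unsaturated-hydrocarbon term, and an
intramolecular hydrogen-bond term.

An *atom group* is one heavy atom (the center) classified by element,
formal charge and hybridisation, together with a canonical string encoding
its immediate bonded neighbourhood.  This "radical breakdown" is total:
every heavy atom becomes a center except hydrogens, halogens, terminal
O/N/S atoms attached through a multiple bond (carbonyl and sulfonyl
oxygens, nitrile nitrogens, thiocarbonyl sulfurs) and terminal negatively
charged oxygens (carboxylate, sulfonate, nitro) — all of which appear only
inside the neighbour strings of their attached centers.  Acetic acid, for
example, decomposes into three groups, not four:

```{r}
print(perceive(read_smiles("CC(=O)O", id = "acetic acid")))
```

## The group grammar

The center label combines element, charge mark and hybridisation class
derived purely from the bond pattern (never from geometry): aromatic if
the atom carries an aromatic bond; sp for a triple bond or two doubles;
sp2 for one double; sp3 otherwise.  Sulfur is split by coordination into
S2/S4, neutral four-coordinate phosphorus is P4, and charged P and B drop
the coordination digit: `P(+)`, `P(-)`, `B(-)`.  Oxygen is one class `O`
whose context lives entirely in the neighbour string.

The neighbour string is built deterministically:

1. implicit hydrogens first (`H`, `H2`, `H3`);
2. one token per heavy neighbour, a bond marker (`=`, `#`, `:`, nothing
   for single) followed by the element symbol, iodine written `J`;
   identical tokens aggregate with a count (`F4`, `=O2`);
3. tokens are ordered element-major — B, C, N, O, P, S, Si, then the
   halogens F, Cl, Br, J — and within one element by bond marker
   (single < `=` < `#` < `:`);
4. formal charges of neighbours are appended as `(+)`/`(-)` markers at the
   very end of the string;
5. for centers of type `N sp3`, `O` and `S2` the bond markers are dropped
   and a trailing `(pi)`/`(2pi)` records how many neighbours are aromatic
   or multiply bonded (a carbonyl carbon counts as a pi neighbour).

Rule 4 deserves a note: the published tables write the charge mark in
different positions relative to the token it belongs to (`H:C:N(+)`,
`CO=O(-)`, `CN=O2(-)`, `CPF2(-)`).  Placing every charge mark at the end
of the string is the single rule that regenerates all of these strings
verbatim — including the sulfonamide string `CN=O2(-)`, where the charge
belongs to the nitrogen, and the perfluoroalkylphosphate string
`CPF2(-)`, where it belongs to the phosphorus.  A per-token placement
cannot produce either.  Rule 5's pi counts make phenol's oxygen `HC(pi)`,
an ester oxygen `C2(pi)` and diphenyl ether's oxygen `C2(2pi)`.

## Aromaticity and the amidinium convention

The parameter tables imply a deliberately narrow aromaticity model, which
this package adopts as its fixed convention:

* six-membered rings made of carbon and nitrogen are aromatic (benzene,
  pyridine, pyridinium, fused carbo-/azaarenes);
* five-membered heteroaromatics are treated in their Kekulé form — the
  tables describe thiophene and furan α-carbons as `C sp2` groups such as
  `H=CS` and `H=CO`, and contain no `:S`/`:O` neighbour tokens;
* cations in which a carbon sits between nitrogens (imidazolium,
  amidinium, guanidinium) are represented with the positive charge on the
  central carbon and aromatic bonds from that carbon to the motif
  nitrogens, reflecting where the charge actually resides.  The rest of an
  imidazolium ring keeps its Kekulé pattern, so its C4/C5 atoms are
  ordinary `C sp2 H=CN` groups.

Structure input is normalised into this convention regardless of drawing
style: readers kekulise any input aromatic bonds (a backtracking matching
in which neutral carbons must receive exactly one double bond and
heteroatoms may contribute a lone pair), materialise implicit hydrogens
from a standard valence model, apply the amidinium rewrite
(`normalize_amidinium()`, automatic but switchable off), and re-aromatise
six-membered C/N rings.  The rewrite is idempotent and never changes the
molecular formula or the net charge.  Because the guanidinium cation has
three *acyclic* aromatic C–N bonds in this representation, aromatic bonds
are permitted outside rings exactly for such motifs.

One numerical consequence is handled explicitly: for a charged amidinium
carbon the aromatic C–N bonds count as formal single bonds when implicit
hydrogens are derived, so an imidazolium C2 with two ring bonds still
carries its hydrogen; in all other contexts an aromatic bond counts 1.5
and the atom's bond-order sum is rounded down.

```{r}
mim <- read_smiles("Cn1cc[nH+]c1", id = "1-methylimidazolium")
print(perceive(mim))
```

## The parameter tables and validity

`load_packaged()` returns the two published tables exactly as printed
(two-decimal contributions, occurrence and molecule counts): 126 entries
for viscosity including the constant, 116 for log γ∞ of which three are
special groups.  Checksums guard the packaged files.  The printed summary
lines (goodness of fit, deviations, cross-validation statistics) are
exposed as metadata, not entries.

A group is *valid* for prediction when it is represented by at least three
distinct molecules of the training collection; molecules containing any
missing or invalid group get a structured verdict instead of a number.
Applying this rule to the printed molecule counts flags 80 entries per
table as valid, slightly more than the printed "valid groups" lines (76
and 75) — the original work evidently applied an additional unstated
criterion of molecule independence.  We store the rule-derived flags and
keep the printed numbers as metadata; `recompute_validity()` re-derives
flags from any user dataset.

## Fitting, cross-validation and outliers

Training solves the least-squares problem for the contributions on a
sparse design matrix (one row per compound, one column per group, plus an
all-ones column when the constant is fitted).  The solver is Gauss–Seidel
iteration on the normal equations $X^TX\,a = X^Ty$ from a zero start,
stopping when the largest relative coordinate change falls below 1e-12
(at most 1e5 sweeps; each sweep is one triangular solve).  Groups with
fewer than three supporting molecules are still fitted — they are merely
flagged invalid for prediction and kept for future data.

Reported statistics follow the conventions: R² is the squared Pearson
correlation of experimental versus fitted values, the *average deviation*
is the mean absolute residual and the *standard deviation* the
root-mean-square residual (the published work does not define these; this
interpretation is recorded here).  When predictions are constant the
correlation is undefined and R² is reported as 0.

Ten-fold cross-validation (`cross_validate()`) assigns compounds to
near-equal folds by a seeded permutation (default seed 20171221) and
refits on each complement, *recomputing validity on that complement*: a
test compound whose group falls below three supporters in the training
complement is excluded from Q² with a reason.  This per-fold gate is what
thins the predictable set in cross-validation relative to the training
fit.  Q² is the squared correlation over the predictable out-of-fold
pairs.

Outlier exclusion (`fit_with_outlier_removal()`) alternates fit →
cross-validation → exclusion: compounds whose experimental value deviates
from the fit by more than three times the cross-validated standard error
are removed and the model refitted, until no new exclusion occurs (cap 10
rounds).  The cross-validation runs inside each round because the
threshold is defined against the cross-validated error.  A deviation
floor of 1e-8 prevents the rule from flagging floating-point residuals
when a model fits exactly.  Two open protocol details are resolved as
follows: outlier exclusion wraps cross-validation (not vice versa), and
the Gauss–Seidel fixed point is taken to be the least-squares solution,
which every release verifies against a direct solver.

## The synthetic generator

`synth_spec()`/`make_design()` emulate the statistical structure the
additivity model assumes: a sparse non-negative integer count matrix
(each group present in a compound with probability 0.3, count uniform on
1..4 when present), true contributions uniform on (−1, 1), optional
constant, and homoscedastic Gaussian noise, all reproducible from one
seed.  The default noise σ = 0.10 matches the magnitude of the
cross-validated standard error of the viscosity model, and 500 compounds
× 40 groups gives a support per group (~150 compounds) comparable to the
well-populated table entries.  Columns that come out empty are resampled
so every parameter is estimable.

What the generator deliberately does *not* emulate: correlated group
co-occurrence (real substituent patterns are far from independent),
heteroscedastic experimental error, the long tail of rare groups, or any
molecular-graph structure.  Passing the recovery and cross-validation
checks on synthetic data therefore validates the estimation machinery,
not the chemistry; the chemistry is pinned by the fixture molecules —
eighteen species with hand-derived decompositions, including the nine
worked ionic-liquid examples (tetrafluoroborate through methylsulfonate)
— which the test suite compares byte-for-byte against perception.

Test problem sizes were chosen to exercise each property at comfortable
margins: 100 random systems up to 200×50 for the solver check, 500×40 for
parameter recovery, 12 compounds for the leave-one-out oracle and 120 for
the outlier rule.

## Degenerate inputs and edge cases

* Zero variance in the response is an explicit error (R² undefined).
* A group absent from every training compound yields a zero diagonal in
  the normal equations and an explicit error naming the column.
* Ineligible molecules (unsupported elements, missing or invalid groups)
  never produce a number.
* Charge-separated drawing conventions are expected where applicable:
  nitro groups as N(+)(=O)O(−); hypervalent neutral drawings (e.g.
  pentavalent nitro) are not rewritten and will generally produce labels
  outside the table vocabulary, caught by `perceive(strict = TRUE)` or by
  the eligibility gate.
* SDF records that cannot be parsed are reported per record with the
  record index; the remaining records are returned.

## Known limitations

* Both tables are single-temperature; no temperature extrapolation.
* The printed contributions have two decimals, so hand sums match
  predictions exactly, but refitting on new data reproduces the printed
  values only to that precision.
* The hydrogen-bond detector is deliberately simple (topological distance
  3–5 between donor and acceptor heavy atoms, each unordered pair counted
  once) and off by default: only six molecules supported the parameter in
  the original data, and the original detector is not specified.
* The narrow aromaticity convention means exotic aromatics (7-membered
  rings, fused ionic heteroaromatics beyond the amidinium motif) fall
  back to their Kekulé forms; their groups will usually be missing from
  the tables and gated out rather than mispredicted.
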