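# nppu — Net Primary Production Use characterization factors for feed ingredients

`nppu` computes the **Net Primary Production Use** (NPPU, also called Biotic
Resource Use, BRU) midpoint indicator used in life-cycle assessment of
aquaculture and livestock feeds: the mass of primary-production carbon
appropriated per kilogram of a feed ingredient, in kg C/kg. It is aimed at LCA
practitioners who need characterization factors for fish-based, plant-based,
other-animal-based and milk-based feed ingredients, and at anyone who wants to
recompute or extend such reference tables with their own data.

## The model

For a fresh organism at trophic level `TL` in a food web with trophic transfer
efficiency `TE`, the indicator amplifies the organism's carbon content
geometrically up the web (Pauly–Christensen):

```
NPPU = C_content * (1 / TE)^(TL - 1)        [g C per kg fresh mass]
```

Carbon content comes either from a generic whole-fish constant
(111.1 g C/kg fresh) or from the proximate composition via the carbon mass
fractions of its organic fractions:

```
C_content = 0.531 * protein + 0.774 * lipid + 0.444 * carbohydrate   [g C/kg]
```

with coefficients derived stoichiometrically from the empirical formulas
C5H7O2N (protein), C57H104O6 (triglyceride) and the anhydroglucose unit
C6H10O5 with integer molar masses (C 12, H 1, O 16, N 14).

Class-specific rules: plants sit at `TL = 1` (NPPU equals carbon content),
milk ingredients are fixed at `TL = 2`, fish classes get tiered parameter
policies (generic `TE = 10 %` and generic carbon vs ecosystem-/species-specific
values: marine tiers T1–T3, freshwater T1–T2, other animals a single tier).
Fresh-fish NPPU is distributed to fishmeal and fish oil by mass, energy, or
user-supplied (e.g. economic) weights:

```
NPPU_meal = (NPPU_fresh / Y_meal) * Y_meal*E_meal / (Y_meal*E_meal + Y_oil*E_oil)
```

and symmetrically for oil; mass allocation gives `NPPU_fresh / (Y_meal+Y_oil)`
for both coproducts. Uncertainty is propagated by a first-order Taylor
expansion in `(C_content, TE, TL)` with a Monte-Carlo cross-check.

## Worked example

An anchovy-like fish: 70.5 % moisture, 18 % protein, 6 % lipid, 3.5 % ash,
carbohydrate by difference; upwelling-ecosystem transfer efficiency 11.9 %,
trophic level 3.2 ± 0.2.

```r
library(nppu)

comp <- proximate_composition(protein = 180, lipid = 60, ash = 35, moisture = 705)
cc <- carbon_content(comp)
cc
#> [1] 150.9

v <- nppu_fresh(cc, TE = 0.119, TL = 3.2)
v
#> NPPU [fresh, tier -, allocation none]: 1.631e+04 g C/kg = 16.31 kg C/kg

spec <- coproduct_spec(yield_meal = 0.225, yield_oil = 0.05,
                       energy_meal = 18.5, energy_oil = 39)
allocate_energy(v, spec)
#> NPPU energy allocation (factors 0.6810 meal / 0.3190 oil):
#>   meal: 49.37 kg C/kg
#>   oil:  104.1 kg C/kg

allocate_mass(v, spec)
#> NPPU mass allocation (factors 0.8182 meal / 0.1818 oil):
#>   meal: 59.31 kg C/kg
#>   oil:  59.31 kg C/kg

nppu_sd(cc, 0.119, 3.2, sigma_TL = 0.2)
#> [1] 6944.108
```

Reading: producing 1 kg of this fresh fish appropriates about 16.3 kg of
primary-production carbon; concentrating it into meal and oil raises the
per-kg burden of the coproducts (49–104 kg C/kg under energy allocation,
59.3 kg C/kg for both under mass allocation — the two columns of the
reference ingredient tables). The ±0.2 trophic-level spread alone propagates
to a standard deviation of about 6.9 kg C/kg on the fresh value — NPPU
uncertainty grows with trophic level, which is why the reference tables ship
an SD file. The full tier-by-yield variant table for a species is one call:

```r
rec <- species_record("Engraulis ringens",
                      trophic_parameters(TL = 3.2, TL_SD = 0.2, TE = 0.119),
                      C_specific = 105)
tier_yield_matrix(rec,
                  coproduct_spec(0.225, 0.05, 18.5, 39, "generic"),
                  coproduct_spec(0.20, 0.08, 18.5, 39, "specific"),
                  method = "energy")
#>   label tier yield_source nppu_fresh_kg nppu_meal_kg nppu_oil_kg ...
#> 1   T11   T1      generic         17.61        53.29      112.35
#> 2   T12   T1     specific         17.61        47.76      100.69
#> 3   T21   T2      generic         12.01        36.35       76.62
#> ...
```

Tables following the published CSV layouts are handled by
`read_nppu_table()`, `write_nppu_table()` and `validate_nppu_table()`
(schemas: `schema_ids()`); `generate_species()` produces synthetic tables
with the statistical structure the method assumes.

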