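---
title: "NPPU characterization factors: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NPPU characterization factors: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nppu)
```

## The indicator

Net Primary Production Use (NPPU, synonym Biotic Resource Use) measures the
mass of primary-production carbon appropriated per kilogram of a feed
ingredient. For an organism at trophic level $TL$ in a food web where a
fraction $TE$ of production passes between successive trophic levels, each
trophic step divides the available production by $TE$, so

$$\mathrm{NPPU} = C \cdot \left(\frac{1}{TE}\right)^{TL - 1}
\quad [\mathrm{g\,C\,per\,kg}],$$

where $C$ is the carbon content of one kilogram of the fresh organism in
g C/kg. The model assumes a single scalar transfer efficiency per organism —
constant across the trophic levels below it — and a well-defined (possibly
fractional) trophic level. Primary producers have $TL = 1$ and an
amplification of exactly 1.

```{r}
amplification_factor(TE = 0.10, TL = 3.5)
nppu_fresh(111.1, TE = 0.10, TL = 3.5)
```

## Carbon stoichiometry

Where composition data exist, carbon content is a linear combination of the
organic fractions with the carbon mass fractions of their representative
empirical formulas:

```{r}
carbon_mass_fraction(empirical_formula(C = 5, H = 7, O = 2, N = 1))   # protein
carbon_mass_fraction(empirical_formula(C = 57, H = 104, O = 6))       # lipid
carbon_mass_fraction(empirical_formula(C = 6, H = 10, O = 5))         # carbohydrate
```

The molar masses default to integers (C 12, H 1, O 16, N 14) so the
reference coefficients 0.531 / 0.774 / 0.444 reproduce exactly;
`molar_mass_table()` accepts IUPAC values for users who prefer them.

Two carbohydrate formulas circulate for this coefficient: C5H8O4, whose
carbon fraction with integer masses is 0.4545, and the anhydroglucose repeat
unit C6H10O5 of polysaccharides, whose fraction is $72/162 = 0.444$. The
coefficient actually used in the reference coefficient set is 0.444, which
matches anhydroglucose; `default_carbon_coefficients()` therefore returns
the constant triple verbatim, and `carbon_mass_fraction()` is exposed
separately so either formula can be recomputed explicitly.

Compositions are handled internally in g per kg **as-fed**; percent columns
in files are converted on read (×10). When a carbohydrate value is absent it
is filled by difference, `max(0, 1000 - protein - lipid - ash - moisture)`:
the only closure consistent with treating carbohydrate as the residual
organic fraction. Closure is validated to 1 g/kg. Animal carbon contents are
treated on the fresh (wet) basis throughout, consistent with the generic
constant of 111.1 g C per kg fresh fish; dry-matter inputs must be converted
before entry, and the freshwater/other-animal table layouts carry an
explicit dry-matter column to make the basis visible.

## Ingredient classes and tiers

Parameter provenance is a declared contract, encoded in `tier_policy()`:

| class | tier | TE | carbon content | TL |
|---|---|---|---|---|
| marine | T1 | generic 0.10 | generic 111.1 | species |
| marine | T2 | ecosystem-specific | generic 111.1 | species |
| marine | T3 | ecosystem-specific | species-specific | species |
| freshwater | T1 | generic 0.10 | generic 111.1 | species |
| freshwater | T2 | generic 0.10 | species-specific | species |
| other animal | single | generic 0.10 | species-specific | species |
| milk | single | generic 0.10 | from composition | fixed 2 |
| plant | single | — | from composition | fixed 1 |

The generic transfer efficiency is 10 %; across ecosystems it plausibly
ranges from 3.51 % to 38.1 % (mean 11.9 %), and those bounds drive the
synthetic generator and the test grids. A policy that demands a specific
value the record does not carry fails with an error naming the field rather
than silently downgrading the tier — a silently downgraded tier would
mislabel the output's provenance. Specific TEs are taken as constant across
trophic levels within an ecosystem (a known simplification of the method).

For milk the trophic level is fixed at 2 (one step above primary
production). No tier text exists for milk's TE, so the generic 0.10 is used
unless the record supplies one; carbon content comes from the ingredient's
own composition, since milk ingredients — like plant ingredients — are
characterized directly at the ingredient level rather than via a fresh
organism plus allocation (upstream dairy value chains are too entangled to
allocate reliably).

## Coproduct allocation

Fresh-fish NPPU is distributed over fishmeal and fish oil yields
$Y_m, Y_o$ (fractions of fresh mass):

* **energy**: $\mathrm{NPPU}_{meal} = \frac{\mathrm{NPPU}_{fresh}}{Y_m}\cdot
  \frac{Y_m E_m}{Y_m E_m + Y_o E_o}$, symmetrically for oil, with $E$ the
  energy densities in MJ/kg;
* **mass**: the same algebra with equal weights, which collapses to
  $\mathrm{NPPU}_{fresh} / (Y_m + Y_o)$ for both coproducts — the unique
  mass-proportional rule satisfying the same mass balance (the explicit
  mass-allocation formula is not printed anywhere authoritative, so this is
  a design choice);
* **custom**: the same algebra with user-supplied positive weights, the hook
  intended for economic allocation — no price table is shipped because
  prices are volatile across years and species.

Every method satisfies $Y_m \mathrm{NPPU}_{meal} + Y_o \mathrm{NPPU}_{oil}
= \mathrm{NPPU}_{fresh}$ to 1e-9 relative; the residual fraction
$1 - Y_m - Y_o$ carries no burden, since the allocation normalizes over meal
and oil only. The "densities" columns of the ingredient table layouts are
read as energy densities (MJ/kg): the allocation formulas consume energy
terms. `tier_yield_matrix()` crosses the class's tiers with generic and
specific yields into the labelled variant set (`T11` … `T32` for marine,
a 2×2 block for freshwater).

## Uncertainty propagation

`nppu_sd()` applies a first-order Taylor expansion with independent inputs:

$$\sigma^2_{\mathrm{NPPU}} =
\left(\frac{\partial \mathrm{NPPU}}{\partial C}\sigma_C\right)^2 +
\left(\frac{\partial \mathrm{NPPU}}{\partial TE}\sigma_{TE}\right)^2 +
\left(\frac{\partial \mathrm{NPPU}}{\partial TL}\sigma_{TL}\right)^2$$

with analytic partials $(1/TE)^{TL-1}$, $-C(TL-1)TE^{-TL}$ and
$C (1/TE)^{TL-1}\ln(1/TE)$ (unit-tested against central finite differences
at relative tolerance 1e-5). Reference tables supply a standard deviation
for the trophic level only, so $\sigma_C$ and $\sigma_{TE}$ default to 0;
independence is assumed because no covariances are available.

`monte_carlo_sd()` cross-checks the expansion by sampling independent
normals truncated to the valid domains ($C \ge 0$, $0 < TE \le 1$,
$TL \ge 1$; out-of-domain draws are rejected and redrawn, with a warning
when any input's rejection rate exceeds 50 %). The two estimates agree
within Monte-Carlo error when NPPU is linear in the perturbed input
($\sigma_C$ only) and within a few percent when all coefficients of
variation are small. The agreement degrades predictably with amplification:
the TL term acts like a lognormal with log-scale
$s = \ln(1/TE)\,\sigma_{TL}$, whose true SD exceeds the linearization by a
factor $\approx \sqrt{e^{s^2}-1}\,e^{s^2/2}/s$ — about 4 % at
$s \approx 0.23$ but already ~10 % at $TE = 0.119$, $TL = 3$ with a 5 % CV
on every input. Taylor SDs at high trophic levels should therefore be read
as first-order approximations; this is the regime behind the very large
SDs reported for high-TL species.

## Table I/O and validation

Nine schemas (`schema_ids()`) cover the published file layouts; the three
marine fresh-fish tier files share one schema, as do the two freshwater
files. The reader sniffs comma-vs-semicolon delimiters and dot-vs-comma
decimals (the source files are French-origin), maps headers by name
order-insensitively and whitespace-tolerantly, converts percent columns to
g/kg, and normalizes transfer efficiencies written as percentages (values
above 1) to fractions. The writer always emits canonical comma/dot/UTF-8
with verbatim published header names (including `%` and `/`), re-derives the
kg-column from the g-column so the two NPPU unit columns can never drift,
and writes absent values as empty cells, never sentinel numbers.
`validate_nppu_table()` returns row-level findings (unit consistency within
0.5 g/kg, $TE \in (0,1]$, $TL \ge 1$, composition percentages in $[0,100]$
summing to ≤ 101, non-negative SDs) instead of raising, so a whole file can
be triaged in one pass. For the ingredient-level layouts whose published
column names are only described as grouped counts, this package fixes its
own explicit header spellings; bit-compatibility with the deposited files is
not claimed.

## Synthetic fixtures and what they do (not) show

`generate_species()` draws records with uniform $TL \in [2, 4.5]$,
$TE \in [0.0351, 0.381]$, $TL_{SD} \in [0, 0.5]$, moisture 600–800 g/kg and
protein/lipid/ash/carbohydrate partitioning the dry remainder with exact
closure to 1000 g/kg (so carbohydrate-by-difference is exercised at its
boundary). Uniform sampling over these plausible ranges is deliberate: the
ranges are stated, the distributions are not. Yields (meal 0.15–0.30, oil
0.02–0.12) and energy densities (meal 16–22, oil 35–42 MJ/kg) reflect
reduction-industry practice. These fixtures have the *structural* properties
real tables must have — valid ranges, unit consistency, closure — but not
the empirical correlations of real species (e.g. lipid–TL covariance), so
green tests certify the calculation machinery and schemas, not the
published per-species values, which depend on third-party compilations
(FishBase trophic levels, feed-table compositions) that are out of scope
here. Tests use tables of 3–8 records and 100 seeds for round-trip checks,
and $10^5$ Monte-Carlo draws for the Taylor cross-check; these sizes make
the full suite run in well under a minute while leaving the estimators'
errors far below the asserted tolerances.

## Known limitations

* No economic allocation values are shipped; `allocate_custom()` is the hook.
* TL–TE covariance and ecosystem-resolved TE profiles are out of scope.
* Trophic levels are species averages; catch location and size are ignored.
* First-order SDs are biased low at high trophic levels (see above).
* Milk coproduct chains are not allocated upstream of the ingredient.
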