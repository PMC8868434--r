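---
title: "Fatty-acid nutritional quality indices and bioassay evaluation with lipidqi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fatty-acid nutritional quality indices and bioassay evaluation with lipidqi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidqi)
```

## Scope and model

`lipidqi` evaluates the nutritional quality of a fatty-acid (FA) composition
as delivered by GC-MS FAME analysis: a list of shorthand-coded FA species
with their percentages of total FA. Everything downstream of the identified
composition table is in scope — shorthand parsing, class aggregation, the
eight standard nutritional indices, and colorimetric bioassay readouts
(radical scavenging, ACE inhibition, IC50 estimation). Chromatography,
spectral identification, uncertainty propagation and molecular docking are
not.

### Shorthand nomenclature

Codes follow the `C<carbons>:<double bonds>[n<position>][c|t]` grammar:
`C16:0` (palmitic), `C20:5n3` (EPA), `C18:1n9t` (elaidic). The parser
enforces chemical representability (`double_bonds <= (carbons - 2) / 2`),
forbids unsaturation suffixes on saturated codes, and canonicalizes on
output, so `format_fa(parse_fa(x))` is the identity on valid codes. Three
deliberate reading rules:

* **Geometry defaults to non-trans.** Only an explicit `t` suffix counts
  toward total trans FAs. In the packaged reference data the TFA index
  equals exactly the elaidic-acid (C18:1n9t) entry of each strain, which is
  the behaviour that reproduces the published values; treating
  suffix-less MUFAs or PUFAs as cis-or-trans-unknown-but-counted would not.
* **Codes outrank trivial names.** Common names are opaque metadata.
  Reference datasets in this field carry naming irregularities (the
  packaged table lists "Ginkgolic acid" against code C17:1, chemically a
  salicylic-acid derivative rather than a C17 monoene); the shorthand code
  is arithmetically consistent and is what every formula consumes.
* **Omega positions other than n3/n6/n9** parse but carry no class tag (a
  warning is emitted); they never enter the omega sums.

### Aggregation

`aggregate_profile()` produces every quantity the index formulas consume.
The choices that matter, each forced by reproduction of the published
reference values rather than free:

* N.D. ("not detected") entries are exactly 0 in every sum.
* ΣUFA = ΣMUFA + ΣPUFA **includes trans isomers** (the atherogenicity
  denominator only reproduces with elaidic acid inside ΣUFA).
* The omega-3/omega-6 sums are restricted to PUFAs (`double_bonds >= 2`);
  an `n9` tag on a MUFA never enters them.
* `cis-C18:1` means explicitly-cis C18:1 entries only (oleic acid); the
  trans isomer is excluded from the h/H numerator.
* Totals are **not renormalized** to 100%: printed composition tables sum
  to ≈100 only up to rounding, and renormalization would silently shift
  every index. A total outside [95, 105] raises a warning, not an error.

### The eight indices

With all quantities in percent of total FA:

| Index | Formula | Reading |
|---|---|---|
| PS | PUFA / SFA | higher = better |
| IA | (C12:0 + 4·C14:0 + C16:0) / ΣUFA | lower = better |
| IT | (C14:0 + C16:0 + C18:0) / (0.5·ΣMUFA + 0.5·Σn6 + 3·Σn3 + Σn3/Σn6) | lower = better |
| h/H | (cis-C18:1 + ΣPUFA) / (C12:0 + C14:0 + C16:0) | higher = better |
| HPI | ΣUFA / (C12:0 + 4·C14:0 + C16:0) | reciprocal of IA |
| UI | Σₖ k · (% of FAs with k double bonds), k = 1..6 | unsaturation mass |
| SED | EPA (C20:5n3) + DHA (C22:6n3) | omega-3 payload |
| TFA | Σ explicitly-trans entries | lower = better |

The final IT denominator term is read as the *ratio* Σn−3/Σn−6, not a
subtraction chain — the only reading that reproduces the published IT
values (1.15 and 1.11) from the reference compositions.

A consequence worth stating: **IT is not scale-invariant.** Its denominator
adds the dimensionless n3/n6 ratio to percent-scaled terms, so multiplying
a composition by a constant changes IT. That is a property of the published
formula, not an implementation artifact; the package implements it
faithfully and the property-test suite asserts scale invariance for PS, IA,
h/H and HPI only.

Single-index functions (`index_ps()` through `index_tfa()`) raise a classed
`undefined-index` error when a denominator is zero; `nutritional_indices()`
instead records the flagged index as `NA` in `undefined`, so batch
processing never dies on a degenerate sample (all-saturated, all-zero,
omega-6-free).

### Worked reference example

```{r}
ref <- diatom_reference_profiles()
nutritional_indices(ref$Ano)
nutritional_indices(ref$Rho)
```

These two profiles (benthic diatoms *Anomoeoneis* sp. AARL D039 and
*Rhopalodia* sp. AARL D020, 24 FA species each) are bundled as a plain-CSV
transcription of the published GC-MS means, with triplicate SDs carried as
metadata. The published index values reproduce at 2-decimal precision for
all eight indices and both strains; the acceptance suite asserts all 16
cells. Display rounding is round-half-even (base `round()`), full precision
is kept internally, and SDs are never propagated — the published index SDs
derive from biological triplicates, for which no propagation rule exists at
the composition-table level.

## Bioassay readouts

Radical-scavenging activity (the same expression serves DPPH at 517 nm and
ABTS at 734 nm):

$$\mathrm{activity}\,(\%) = 100 \cdot \frac{A_c - (A_s - A_{sc})}{A_c}$$

ACE inhibition, with enzyme-free (Bi) and substrate-free (Bs) blanks, uses
the standard enzymatic-inhibition form
$100\,[(C - B_i) - (S - B_s)]/(C - B_i)$. The printed source formula is
typographically ambiguous in its bracketing; the standard form is adopted
because it matches the scavenging equations' structure and the assay
literature, and no raw absorbances exist to discriminate empirically.
Activities outside [0, 100] are preserved with a warning, never clipped —
clipping would bias any downstream fit.

### IC50 estimation

No estimation method is stated alongside the published IC50 values, so the
package adopts the field standard and records which route produced each
estimate:

1. **Four-parameter logistic (4PL)** on log-concentration,
   $y = b + (t - b)/(1 + (\mathrm{IC50}/x)^{h})$, by least squares
   (`stats::nls`, Gauss-Newton with `scaleOffset = 1` so the convergence
   criterion stays defined on noise-free data; a direct Nelder-Mead + BFGS
   least-squares minimisation backs it up, since Gauss-Newton's known
   failure mode on near-zero-residual data is a singular gradient). The
   fitted midpoint is the IC50. A fit whose midpoint falls more than a
   log-decade outside the dosed range is rejected as implausible.
2. **Log-linear interpolation** between the two doses bracketing 50%
   activity — the fallback when the fit fails, and the only route for
   3-point series. Decreasing (inverted) series are handled by sign
   detection in both routes.

If activity never crosses 50% and no fit converges, a diagnostic
`no-estimate` error is raised. Concentration units are an explicit tag
(`mg/mL` or `ug/mL`), never converted, and mixing units in one series is an
error.

The published assay IC50s (DPPH 3.65/4.49, ABTS 4.83/11.26, ACE 0.22/0.20
mg/mL) cannot be recomputed: the underlying dose-response points were never
tabulated. They serve as plausibility anchors only. The testable surface is
parameter recovery on synthetic curves: noise-free 4PL series are recovered
to 1e-6 relative, and at additive Gaussian noise of 3 percentage points the
median relative error over 100 seeded replicates stays below 10%.

## Synthetic data: what it emulates, what it does not

`simulate_fa_profile()` draws a composition from a Dirichlet distribution
(independent gamma draws normalised to 100%), then zeroes species
independently with `nd_probability` to emulate not-detected calls. Defaults
are anchored to the reference dataset: the species list is its 24 FAs (ten
SFAs, seven MUFAs including one trans isomer, seven PUFAs including EPA and
DHA), and `nd_probability = 0.15` matches its observed N.D. rate (7 of 48
cells). Weight 1 per species gives a flat composition prior — the indices
need valid compositions, not diatom physiology; the generator deliberately
does **not** emulate the strong C16 dominance, inter-FA correlations or
growth-condition effects of real profiles. A green property test therefore
establishes arithmetic correctness over the composition simplex, not
biological realism.

`simulate_dose_response()` evaluates the 4PL curve exactly (bottom 0, top
100 by default — a full-range assay) and adds optional i.i.d. Gaussian
noise in percentage points; `noise_sd = 3` in the recovery suite reflects
typical plate-reader replicate scatter. Seeds are mandatory everywhere;
there is no global-random-state mode, and the simulators restore the
caller's RNG stream on exit.

## Command-line interface

`run_cli()` (wrapped by `exec/lipidqi`) exposes `indices`, `bioassay` and
`simulate` subcommands; any flag can come from a JSON `--config` file
(command line wins, unknown keys are rejected). JSON is the canonical
machine output — fixed key order, 10 significant digits — so identical
inputs give byte-identical files. Errors surface as one structured line on
stderr and distinct exit codes (2 usage, 3 load, 4 parse, 5 assay/index).
The config format is JSON rather than YAML to keep the dependency set to
`jsonlite` alone.

## Known limitations

* No mg/g or mol% unit conversion, no renormalization, no multi-sample
  statistics; one profile at a time.
* Index uncertainty is out of scope (SDs are metadata only).
* Nomenclature covers straight-chain shorthand only — no Δ-position lists,
  branched, hydroxy or otherwise substituted FAs; FAs with more than six
  double bonds are rejected by the unsaturation-index path.
* The IC50 estimator assumes a monotone sigmoidal response; biphasic
  curves will fit poorly and may silently fall back to interpolation (the
  `method` field discloses this).
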