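---
title: "Methods: stoichiometry and energetics of methanogenic alkane disproportionation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stoichiometry and energetics of methanogenic alkane disproportionation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkanogen)
```

## The model

`alkanogen` analyses the thermodynamic feasibility of anaerobic n-alkane
degradation by archaea that carry both an alkane-activating (divergent)
and a canonical methyl-coenzyme M reductase, and are therefore proposed
to disproportionate alkanes to CH4 and CO2 inside a single cell — no
syntrophic partner, no external electron acceptor. Three questions are
made computable:

1. **Stoichiometry.** What balanced reaction does each catabolic fate of
   CnH2n+2 imply?
2. **Electron bookkeeping.** How are the reducing equivalents of the
   oxidation half-step partitioned between methyl reduction and CO2
   reduction?
3. **Energetics.** Is each fate exergonic under standard, pH-transformed
   and realistic in-situ conditions, and how does the yield scale with
   chain length?

### Closed-form stoichiometries

For chain length n the package emits closed forms (all verified in the
test suite against a generic element/charge null-space balancer, and
exactly balanced by construction):

* complete oxidation to H2 (1-alkane basis):
  `CnH2n+2 + 2n H2O -> n CO2 + (3n+1) H2`
* acetogenic oxidation (1-alkane basis; 2-alkane basis for odd n so the
  acetate and proton coefficients stay integral):
  `CnH2n+2 + n H2O -> (n/2) CH3COO- + (n/2) H+ + (n+1) H2`
* methanogenic disproportionation (4-alkane basis):
  `4 CnH2n+2 + (2n-2) H2O -> (3n+1) CH4 + (n-1) CO2`

The methanogenic fate is deliberately *not* reduced by the gcd of its
coefficients: the 4-alkane basis is the convention in which the pathway's
half-steps are integral for every n, and it is the basis the per-mol
normalization metadata records. `normalize_reaction()` performs the gcd
reduction as a separate, explicit step. For n = 1 the "disproportionation
of methane to methane" nets to zero; the reaction is emitted empty with a
`degenerate` flag rather than raising an error, so chain scans over
n >= 1 are total.

The half-steps are written with the H4MPT methyl carrier as a
carrier-phase species pair `R-H`/`R-CH3` differing by {C:1, H:2}, and
with a formal electron species (empty composition, charge −1). Modelling
the carrier as a pseudo-element keeps one balancing engine for full and
half reactions; carrier formation energies are never needed because the
pair cancels in `compose_half_steps()`, and `energy_report()` refuses the
half-step fates with a not-applicable error.

### The electron ledger

Per 4 alkanes, oxidation of the alkane carbon skeleton to 2n
methyl-H4MPT plus 2n CO2 releases `12n + 8` electrons; reducing the 2n
methyl groups to CH4 consumes `4n`, and the remaining `8n + 8` reduce
`n + 1` CO2 to CH4. Conservation (`12n + 8 = 4n + (8n + 8)`), the methane
total `3n + 1` and the net CO2 `n - 1` are asserted for all n in 1..40,
and the ledger is cross-checked against the electron coefficients of the
balanced half-reactions. The ledger is defined for the disproportionation
fate only; for the H2-producing fates the package reports electrons as
2 × (H2 produced), which is unambiguous and testable.

## Thermodynamic conventions

Energies are evaluated as ΔG = ΔG° + RT ln Q with
R = 8.31446 J mol⁻¹ K⁻¹, from the shipped table of standard Gibbs
energies of formation at 298.15 K (`default_species_table()`).

**Standard states and the CO2 convention.** Gases are referenced to
1 bar, aqueous solutes to 1 M, water and the n-alkane (a bulk oil phase)
to unit activity. CH4 and H2 default to their gaseous species; **CO2
defaults to the dissolved species** (`co2_aq`, ΔGf° ≈ −386.0 kJ/mol). In
cold, anoxic marine sediments CO2 produced by catabolism joins the
porewater DIC pool rather than a gas phase, and this is the convention of
the hydrocarbon-degradation bioenergetics literature whose hexadecane
reference values the package reproduces; with gaseous CO2 the
complete-oxidation value would shift by 16 × 8.34 ≈ 133 kJ per mol
alkane, far outside the spread among published compilations. Both CO2
(and CH4, H2) variants are shipped, and every fate generator takes
`ch4=`, `co2=`, `h2=` species arguments, so the convention is a default,
not a constraint.

**Alkane formation energies.** Gas-phase values for C1–C4, liquid values
for C5–C20 (CRC-style anchors for C5–C10, extended at +5.4 kJ/mol per CH2
— the fitted group-additivity slope — beyond C10). `alkane_gf_estimate()`
returns tabulated values verbatim and extrapolates the least-squares line
`dGf0(n) = a + b·n` over the liquid rows for n > 20; the fit is only
trusted in the liquid regime (n ≥ 5).

**pH transformation.** `delta_g_prime()` adds
`nu_net(H+) · RT · ln(10^-pH)` and nothing else; at pH 0, or for
reactions with no net protons (the disproportionation), ΔG°′ = ΔG°. At
298.15 K and pH 7 each produced proton contributes −39.95 kJ/mol.

**Temperature.** The default is the isothermal approximation: ΔG° is
taken at its 298.15 K value and only the RT ln Q term varies with
temperature. This is the usual choice when only 25 °C formation energies
are trusted, and over the 275–298 K scenario range the neglected ΔS°
correction is small relative to the hundreds of kJ separating the fates.
An optional Gibbs–Helmholtz extrapolation
(`temperature_model = "gibbs_helmholtz"`) uses the shipped ΔHf° values
where present.

**Pressure.** Hydrostatic pressure at a ~2,900 m seep (~30 MPa) is *not*
corrected for; molar-volume corrections for condensed-phase reactions of
this size are of order a few kJ and the `pressure_corrected = FALSE`
flag in every report makes the omission explicit.

**Normalizations.** Per-mol-alkane values divide the per-reaction value
by the alkane coefficient magnitude (4 for the disproportionation);
per-electron values divide by the ledger's released electrons (12n + 8)
for the disproportionation and by 2 × H2 for the other fates.

**Exactness.** Stoichiometric arithmetic is exact: coefficients are
integers (rationals internally), the null-space oracle uses exact
rational Gaussian elimination on the integer element/charge matrix, and
balance residuals are compared to zero, not to a tolerance. Floating
point enters only in energy evaluation. The Hess-law identity —
methanogenic (per 4 alkanes) = 4 × complete oxidation + (3n+1) ×
(CO2(aq) + 4 H2 → CH4 + 2 H2O) — is therefore asserted to 1e-9 kJ, since
it is a linear identity on one table.

## Reference values and tolerances

With the shipped table, the hexadecane fates at pH 7 and 298.15 K give
+1363.6, +470.2 and −340.2 kJ per mol alkane. Published calculations for
the same three reactions give +1365.1, +471.8 and −339.2; the package's
tests accept agreement within max(5%, 15 kJ per mol alkane), the spread
attributable to choosing a different (unnamed in the source literature)
formation-energy compilation. The *signs* — the first two fates
endergonic, disproportionation exergonic — are asserted exactly, as is
the strict monotone increase of the energy yield with chain length over
n = 6..20 (about −21 kJ per additional CH2 per mol alkane on this table).

## The scenario generator

`scenario_spec()` / `generate_scenarios()` produce synthetic in-situ
condition sets standing in for porewater measurements from a cold,
sulfate-depleted, oil-rich deep-sea seep. Defaults (a packaged YAML file,
`extdata/scenario_ranges.yaml`, so measured values can be substituted):

| axis | range | sampling |
|---|---|---|
| temperature | 275–298 K | uniform |
| pH | 6.5–8.5 | uniform |
| p(CH4) | 10⁻³–1 bar | uniform in log10 |
| a(CO2, dissolved) | 10⁻³–1 | uniform in log10 |
| alkane | fixed 1 (pure oil phase) | — |

The lower bounds are deliberately *adverse* to methanogenesis only in the
direction that matters (product activities up to standard state); the
temperature floor reflects bottom water near 2–3 °C. Designs: latin
hypercube (default, via the `lhs` package), uniform random, and full
factorial grid; all use R's Mersenne-Twister with an explicit integer
seed, so scenario sets are bit-reproducible. What the generator does
**not** emulate: ionic-strength/activity-coefficient effects, sulfide and
DIC speciation, hydrostatic pressure, or gradients with sediment depth —
so a 100% exergonic screen shows robustness of the sign over plausible
activity ranges, not a transport-resolved in-situ energy budget.

`feasibility_screen()` counts scenarios with per-mol-alkane ΔG below a
strict 0 threshold by default; a "biological energy quantum" (e.g.
−20 kJ/mol) can be supplied instead, which is reported, not silently
applied. With the defaults, seed 42 and 1,000 scenarios the hexadecane
disproportionation is exergonic in all scenarios (ΔG between about −600
and −350 kJ per mol alkane), while complete oxidation to H2 at 1 bar H2
is exergonic in none.

## CARD-FISH enumeration arithmetic

`cells_per_ml()` implements the standard filter-count conversion
(mean signals per grid × filter/grid area ratio × dilution ÷ filtered
volume, protocol defaults: 20 grids, 1.3 µl sediment per filter) and
`aggregate_cells()` the spherical-aggregate estimate
packing × (D/d)³ for coccoid cells of d = 1 µm. The naive packing of 1.0
matches the plain volume-ratio assumption of the enumeration protocol;
random close packing (0.64) is a named preset. Because the underlying
raw counts and filter geometry of the motivating study are unpublished,
the shipped example setups (`extdata/fish_counts_synthetic.tsv`) are
synthetic and the module asserts only arithmetic identities (linearity,
monotonicity, the cubed-ratio law), never absolute abundances.

## Problem sizes and design notes

* Property tests sweep n = 1..40 (oracle equivalence at n = 2..40), the
  range over which closed forms, ledger identities and the Hess identity
  are asserted; 40 carbons comfortably covers the saturated fraction of
  a biodegraded crude oil.
* The feasibility screen is exercised at 1,000 latin-hypercube scenarios
  (seed 42); summaries are exact counts, so the fraction reported is not
  an estimate with sampling error *given* the scenario set.
* The generic balancer requires a unique solution: one pinned
  coefficient suffices for the overall fates (1-dimensional null space);
  the half-reaction species sets have a second degree of freedom (the
  carrier pair), resolved by pinning the carrier coefficient too.
* Ties/degeneracies: duplicated-species reactions collapse by summation;
  the n = 1 disproportionation is the only degenerate fate and is
  flagged, not erroneous.
* CLI output is locale-independent ('.' decimals, tabs, LF), full
  precision in JSON and 4 significant digits in TSV display columns,
  with a metadata block (version, species-table MD5, seed) for
  provenance.

## Known limitations

* No activity-coefficient model (Debye–Hückel or otherwise): activities
  are taken at face value.
* No speciation: CO2(aq) is used as the DIC proxy; carbonate equilibria
  are not resolved, so pH affects only reactions with net protons.
* No pressure correction (flagged in output).
* Formation energies beyond C20 are a linear extrapolation; branched and
  substituted alkanes are out of scope, as are kinetics, flux models and
  any genome-derived constraints.
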