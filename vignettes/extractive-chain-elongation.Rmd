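---
title: "Electron and carbon bookkeeping for extractive chain elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron and carbon bookkeeping for extractive chain elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caproext)
```

## The process and the accounting problem

Chain-elongating reactor microbiomes convert an electron donor (here
l-lactate) and short-chain acceptors (acetate, n-butyrate) into
medium-chain carboxylates (MCC, C6–C12), chiefly n-caproate (nC6) and
n-caprylate (nC8), via reverse β-oxidation. In *extractive* chain
elongation a solvent — here food-grade sunflower oil laid as a static
layer on the broth — continuously strips the protonated (undissociated)
acids out of the aqueous phase. This relieves product toxicity, raises
conversion rates and yields an MCC-enriched oil that can be harvested
directly.

Comparing such campaigns requires consistent bookkeeping across three
bases:

* **mass** (g/L, what chromatographs report),
* **electron equivalents** (degree of reduction, `4C + H − 2O` per mol;
  1 e⁻ eq ≡ 8 g COD), the natural currency for selectivity and balance
  closure in anaerobic systems, and
* **carbon mol**, the currency of carbon-flux (Sankey) reconciliation.

`caproext` implements this algebra on a compound registry, plus the
two-phase extraction metrics, acid speciation, period-level CSTR
accounting and a process simulator that generates synthetic campaigns
with known ground truth.

## The compound registry

The registry (`default_registry()`, a TSV users can extend) stores each
compound's C/H/O formula, molar mass, carbon count, electron
equivalents, pKa and extractability. Two invariants are enforced on
load: the electron equivalents must equal `4C + H − 2O`, and the molar
mass must agree with the formula to 0.5%. Carboxylates are represented
by the free acid's formula; a "carboxylate" concentration always means
the dissociated + undissociated sum.

Molar masses are the standard values (lactic 90.08, acetic 60.05, …
n-caproic 116.16, n-caprylic 144.21 g/mol). Conversion between printed
e⁻ meq and g/L figures in the extractive chain-elongation literature
reproduces to within one unit of the last printed decimal; exact
agreement cannot be expected because published rate pairs are rounded
independently on each basis.

## Acid speciation and extraction metrics

Speciation is Henderson–Hasselbalch:
$f_{HA} = (1 + 10^{\,pH - pK_a})^{-1}$. The pKa defaults (lactic 3.86,
acetic 4.76, propionic 4.87, n-butyric 4.82, n-valeric 4.84, n-caproic
4.88, n-heptanoic/n-caprylic 4.89) are standard handbook values; with
them the package reproduces both the published partition-coefficient
columns and the mM ↔ g/L threshold pairs for undissociated n-caproic
acid, which is how they were validated. No activity-coefficient or
temperature corrections are applied (out of scope).

Per-compound extraction metrics:

* `distribution_ratio()` — $K_D = C_{org}/C_{aq}$ at sampling pH.
* `partition_coefficient()` — $P = f_{HA}/K_D$. The quantity ratios the
  extractable (protonated) aqueous pool against the solvent load; small
  P means efficient capture. This definition was chosen because it
  reproduces the four published food-waste values (nC4 2.6, nC5 0.9,
  nC6 0.2, nC8 0.5 at pH 4.8) with the default pKa table; it is
  documented here precisely because other definitions of "partition
  coefficient" circulate, and users comparing against another
  convention should apply their own formula to `undissociated_fraction()`
  and `distribution_ratio()` outputs.
* `recovery()` — percent of a compound's measured mass in the solvent.
  It deliberately never derives from $K_D$ and nominal volumes:
  sampling changes phase volumes during a campaign, and published batch
  recoveries are visibly inconsistent with the closed-system identity
  $100\,K_D r/(1+K_D r)$ (r = solvent ratio). Measured amounts are the
  ground truth.
* `specificity()` — each compound's share of the solvent's carboxylate
  load. The basis is mass (g), a documented choice; a molar basis would
  shift values by the molar-mass ratios.

`oil_composition_report()` expresses solvent concentrations as the
composition measures used for MCC-enriched oil products, assuming
carboxylic acids are a fraction `f_ca` (default 0.97) of the oil by
weight and a default density of 0.902 kg/L. The identity
`wt% MCC = (Σ %-of-carboxylic-acids over MCC) × f_ca` holds exactly.
Back-extraction (`back_extraction_conc()`) assumes complete transfer of
carboxylates into the alkaline phase and neglects the oil volume's
contribution to the back-extract.

## Period-level CSTR accounting

The net production rate of compound *i* over a period is

$$r_i = D\,(\bar C_{aq,i} - C_{feed,i}) + \frac{\Delta M_{org,i}}{V_{aq}\,\Delta t},$$

computed per sampling interval and averaged arithmetically over the
period (the first timepoint is the baseline). Periods are user input:
which samples constitute "steady state" is an operational judgement the
package does not make. Negative organic increments (re-solubilisation
from the oil when production declines) keep their sign.

Electron selectivity divides each *net-produced* species' e⁻ meq rate
by the total over net products — carboxylates with positive net rate
plus H2 and CH4. Net-consumed species are substrates and are excluded;
acetate can legitimately appear on either side. Carbon selectivity
includes CO2 in the product pool: measured when a gas column is
present, otherwise estimated as one CO2 per lactate consumed (the
oxidation stoichiometry of the elongation steps) and flagged
`co2_estimated` in the output, since both conventions exist. Balance
closure reports the relative gap on both bases; positive gaps are
conventionally read as biomass assimilation (the missing-carbon
convention of Sankey reconciliations), and negative gaps are reported
with sign as a data-quality flag.

Acid-dose metrics convert a dosing rate (mmol H⁺/L/d) to mol H⁺ per mol
MCC using each MCC's own electron equivalents — an nC6-equivalent lump
would bias the molar rate where nC8 is significant.

The areal extraction flux uses the vessel cross-section
(`π d²/4`; 8.66×10⁻³ m² for the default 10.5-cm reactor) as the
broth–solvent interface, matching how static-overlay fluxes are
reported.

## The process simulator

The generator exists so that every analysis stage can be exercised
against data with known ground truth. It is a deliberately small
mechanistic model, not a microbiome simulator.

**Stoichiometry.** Five reactions, each elementally and electronically
balanced (per mol extent):

1. lactate + acetate → n-butyrate + CO2 + H2O
2. lactate + n-butyrate → n-caproate + CO2 + H2O
3. lactate + n-caproate → n-caprylate + CO2 + H2O
4. 2 lactate → n-butyrate + 2 CO2 + 2 H2
5. 3 lactate → 2 propionate + acetate + CO2 + H2O

plus an anabolic flux that routes a fraction `y_x` (default 0.07) of
all consumed substrate electrons into a biomass ledger. Because every
reaction conserves e⁻ eq exactly, a noise-free simulation closes its
electron ledger to integrator tolerance — the test suite asserts
< 10⁻⁶ relative. n-Valerate and n-heptylate formation are not
modelled; they are minor (~1% selectivity) side products in the systems
this package targets.

**Kinetics.** Each reaction is Monod in lactate (Ks 0.5 g/L) and its
acceptor (Ks 0.2 g/L), proportional to biomass, and attenuated by
undissociated n-caproic acid through a linear ramp from no effect at
26 mM to complete arrest at 37 mM — the published threshold and
full-inhibition concentrations for lactate-fed systems; only the two
endpoints are constrained by observation, the linear form between them
is a modelling choice. The specific-rate defaults
(`q_max = c(6, 12, 0.35, 3, 0.5)` e⁻ meq substrate per e⁻ meq biomass
per day) were chosen once so that the default 1.2-L, HRT-2-d campaign
fed 40 g/L lactate + 5 g/L acetate at pH 5.0 lands in the observed
operating envelope — nC6 ≈ 9 g/L aqueous at the inhibition ceiling,
~18 g/L residual lactate, nC6 electron selectivity ~80%, acid dose
~2.6 mol H⁺/mol MCC, yield ~0.32 mol nC6/mol lactate. None of the
consistency tests depend on these magnitudes.

**Extraction.** A two-film linear-driving-force term
$J_i = kA_i (C_{aq,i} - C_{org,i}/K_{D,i})$ moves extractable acids
into the static oil. $K_D$ is treated as the *effective* distribution
ratio at operating pH rather than decomposed into speciation ×
intrinsic partitioning, matching how distribution ratios are measured.
CSTR defaults ($K_D$ 11 for nC6, 38 for nC8; others 0) reflect the
enrichment factors a static oil layer reaches over an acidic broth,
where only the MCC partition appreciably; batch-equilibration scenarios
should pass the directly measured batch values (e.g. nC6 2.5 at
pH 4.8). `kA` defaults (0.5 L/d) give pre-saturation fluxes of
~1–2 g nC6/L_broth/d, the observed magnitude for an unstirred overlay.

**pH and the acid ledger.** pH follows the setpoint or a user profile;
it is not mechanistic. The acid ledger integrates the proportional
controller action implied by charge bookkeeping: converting
mostly-dissociated lactate (pKa 3.86) into partly-undissociated product
acids (pKa ≈ 4.85) at pH 5 leaves excess alkalinity that the controller
neutralises. This reproduces realistic dose metrics (~2.5–2.6 mol
H⁺/mol MCC) without simulating titration chemistry.

**Numerics.** `deSolve::lsoda` with rtol 10⁻⁸/atol 10⁻¹⁰; output on a
fixed grid (default 0.5 d, the every-other-day sampling cadence of the
campaigns emulated, halved to keep interval-based rate estimates
smooth). Instantaneous acid/gas rates are evaluated from the derivative
at output times, not by differencing, so the observation table is free
of discretisation artefacts. A 120-d campaign integrates in well under
a second. Non-finite states abort with a diagnostic. An optional
exponential `activity_decay` hook (default off) can emulate the
progressive rate loss sometimes seen after prolonged solvent exposure;
it is not calibrated, merely available.

**Noise.** `add_measurement_noise()` applies seeded multiplicative
lognormal noise with unit mean and CV equal to the requested `sd`
(meanlog = −sdlog²/2), per measurement column. The generator state of
the calling session is restored afterwards.

**What the generator does and does not emulate.** It reproduces the
*structure* of two-phase campaign data — substrate depletion, product
spectra, inhibition-limited steady states, selective MCC extraction,
acid dosing, gas ledgers — with exact conservation, which is what the
analysis modules need for closed-loop validation. It does not emulate
community dynamics, adaptation, pH excursions, solvent losses, sampling
volume changes, or analytical biases such as back-extraction recovery
< 100%. Passing the closed-loop tests therefore demonstrates
correctness of the accounting, not fidelity of any kinetic parameter to
a particular reactor.

## Degenerate inputs and tie-breaks

* `distribution_ratio()` is undefined at zero aqueous concentration and
  says so rather than returning `Inf`.
* `recovery()` requires the compound in at least one phase;
  `specificity()` requires a non-empty organic phase.
* Selectivity requires at least one net product; an all-consuming
  period is an error, not a zero.
* `stoichiometric_summary()` warns and returns `NA` for the
  lactate:acetate ratio when acetate is not net-consumed (extractive
  operation can halve acetate consumption, and near-zero denominators
  would otherwise print absurd ratios).
* Balance gaps are computed only when feed inflow is positive.
* Unknown compounds — in registry lookups, series columns, feed or
  initial conditions — fail loudly with the offending name.

## Problem sizes

The shipped tests simulate 60-d campaigns at 0.5-d cadence
(121 output points) for the closed-loop checks and a single 120-d
campaign for the long-run contract; the acceptance script runs two 60-d
campaigns, one 30-d batch equilibration and the worked-example
arithmetic. Everything completes in seconds on one CPU.

## Known limitations

* $K_D$ is concentration-independent; real isotherms can curve at high
  oil loadings.
* The acid ledger ignores the buffering of medium components other than
  the carboxylates themselves.
* Back-extraction is assumed complete; incomplete recovery in practice
  would make measured oil concentrations lower bounds.
* The inhibition ramp attenuates all catabolic steps equally; no
  step-specific toxicity is modelled.
* Periods are closed intervals on sampling times; a sample on a period
  boundary belongs to both adjacent periods.
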