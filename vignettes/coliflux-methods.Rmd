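---
title: "Flux, carbon-balance and ATP-spilling analysis of E. coli continuous cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux, carbon-balance and ATP-spilling analysis of E. coli continuous cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coliflux)
```

# The problem

Glucose-limited *Escherichia coli* K-12 MG1655 changes its physiology
markedly as the specific growth rate $\mu$ rises: above a critical growth
rate acetate overflow sets in, TCA-cycle throughput per glucose declines,
the pentose phosphate pathway is induced, and a family of further
by-products — lactate, the pyrimidine-pathway intermediates
carbamoyl-aspartate (CBASP), dihydroorotate (DHO) and orotate, and
N-acetyl-aspartate (NAA) — is excreted in growth-rate-dependent phases.
(The pyrimidine intermediates accumulate in this strain because its *rph*
frameshift depresses *pyrE* expression, bottlenecking orotate conversion.)
Quantifying what this costs the cell requires three calculations done
consistently on the same cultivation: biomass-specific conversion rates
from the culture time series, a metabolic flux analysis (MFA) that respects
the measured by-products and the $\mu$-dependent biomass composition, and
carbon-balance / ATP bookkeeping on the resulting flux vector. This package
implements that chain for chemostat, A-stat (accelerostat, dilution rate
rising at constant acceleration so the culture tracks a quasi steady state)
and D-stat (constant dilution rate, acetate co-feeding) regimes.

# The flux model

The network is a deliberately small, fully determined stoichiometric model:
lumped glycolysis, the oxidative and non-oxidative pentose phosphate
pathway, the TCA cycle with the glyoxylate shunt, PEP carboxylase
anaplerosis (lumped with the gluconeogenic carboxykinase into one
reversible flux), PTS glucose uptake consuming one PEP per glucose, the
acetate excretion branch (Pta/Ack, yielding one substrate-level ATP) and
the acetyl-CoA synthetase re-assimilation branch (costing two ATP
equivalents) that together form the futile PTA-ACS cycle, a pyrimidine
branch aspartate $\to$ CBASP $\to$ DHO $\to$ orotate with an excretion flux
at each intermediate, an NAA synthesis-and-excretion flux, lactate
excretion, a generic excess-carbon outflow from oxaloacetate (`Vprod`),
CO2 transport, lumped oxidative phosphorylation at a configurable P/O
ratio (default 2 mol ATP per mol NADH), and an explicit ATP dissipation
reaction.

Balanced species: 19 carbon branch-point metabolites plus the three
cofactor pools ATP, NADH and NADPH — 22 in total, balanced across 50
fluxes. The fluxes partition into 1 measured inflow (glucose via PTS), 7
outflows fixed from broth measurements (acetate, lactate, CBASP, DHO,
orotate, NAA, `Vprod`), 18 biomass-drain fluxes computed from the biomass
composition, and 24 dependent fluxes solved from the balances. FADH2 from
succinate dehydrogenase is folded into the NADH pool at a configurable
discount (default 1.0). Carbamoyl-phosphate is modelled as a one-carbon
unit drawn from CO2 plus two ATP inside the lumped CBASP synthesis step.

Every reaction — transport and biomass drains included — conserves carbon
exactly once boundary species are counted: drains deposit their net carbon
into an explicit biomass-carbon sink species, which is also how the biomass
carbon content (mmol C per g DCW) used by the carbon balance is derived
from the composition. With the default composition this gives
`r round(biomass_carbon(composition_at_mu(default_composition_table(), 0.3)), 1)`
mmol C/g DCW, i.e. ~45 % carbon by mass, inside the 35–55 % envelope
expected for bacterial biomass.

## Determinacy: why the glyoxylate shunt needs a rule

With the 26 fixed fluxes removed, 24 dependent fluxes face 22 balance
equations. Two further constraints close the system:

1. **The acetate-branch switch.** Excretion (Pta/Ack) and re-assimilation
   (Acs) cannot both be identified from extracellular data — their
   difference is all the balances see. The branch opposing the sign of the
   measured net acetate rate is constrained to zero (Acs active when
   acetate is consumed or zero, Pta active when it is excreted).
2. **The glyoxylate regime rule.** The remaining degree of freedom is a
   loop through the glyoxylate shunt, TCA cycle, anaplerosis and glycolysis
   that conserves *every* balanced species including CO2 and NADPH (we
   verified this numerically: the loop lies exactly in the nullspace).
   Consequently the measured CO2 evolution rate carries **no** information
   about the shunt, and no choice of measurement can determine it — the
   classic identifiability limit that normally requires 13C labelling. The
   package therefore constrains the shunt by regime: zero during growth on
   glucose alone (the shunt is repressed), and a configurable fraction
   (default 0.3) of the acetate assimilation flux during co-utilisation.

With both rules the system is square (22 unknowns, 22 balances) and
generically nonsingular; the CO2 transport flux, the oxidative
phosphorylation flux and the ATP dissipation flux close the carbon, NADH
and ATP nodes respectively. The measured CO2 rate is then naturally a
*redundant* measurement. Two solver modes expose this:

* `mode = "constraint"` (default): the CO2 transport flux is fixed to the
  measurement; the system is overdetermined by one and solved by least
  squares with per-metabolite residuals reported. A measured CO2 rate that
  deviates from the carbon-bookkeeping prediction by more than half the
  predicted rate is a gross inconsistency and raises an error rather than
  being absorbed — a least-squares residual alone can hide such a mismatch
  by silently redistributing carbon fluxes.
* `mode = "redundancy"`: the square system is solved exactly and the
  predicted-minus-measured CO2 rate is reported as `co2_residual`.

The NADPH balance is kept as a hard constraint in both modes because it is
what pins the glycolysis/PPP split (PPP induction supplies NADPH); without
it the split is undetermined. This choice makes the PPP response to rising
biosynthetic NADPH demand an emergent property of the solve.

## Numerical structure of the solve

The energy closure is block-triangular: oxidative phosphorylation appears
only in the NADH and ATP rows, and the dissipation flux only in the ATP
row. The solver exploits this — the carbon + NADPH core is solved first
(QR), then the two energy fluxes follow by exact back-substitution. Besides
matching how the balances determine each other, this makes the P/O ratio
invariance *exact*: changing `po_ratio` alters only the ATP row, so every
carbon flux is bit-identical and only the oxidative ATP term rescales.
Stoichiometric coefficients are exact in binary (integers and halves);
balance and rank checks use a 1e-9 tolerance. Irreversible fluxes are not
imposed as inequality constraints (the system is determined, not an
optimisation); negative values on irreversible reactions are flagged in
`sign_violations` instead.

# Biomass composition and the 18 drains

The 18 calculated drain fluxes are monomer-class drains — six protein
amino-acid families (keyed to their central-metabolism precursors:
pyruvate, 3-phosphoglycerate, aspartate, 2-oxoglutarate, E4P + PEP, R5P),
purine and pyrimidine nucleotides for RNA and DNA (pyrimidines drawing on
orotate through the bottlenecked pathway), lipid, LPS, murein, glycogen and
a soluble pool, plus three growth-associated cofactor demands (ATP, NADPH,
net NADH production). Each drain flux is demand (mmol/g DCW) times $\mu$,
so drains are exactly linear in both.

The shipped composition table is **surrogate data**: literature-typical
*E. coli* values with the RNA mass fraction rising with $\mu$ and levelling
off near 0.40 1/h, protein declining slightly, and structural fractions
constant. It is not a measurement of any particular cultivation and is
meant to be overridden from a user file (`read_composition_table()`) when
measured compositions exist. Using a fixed low-$\mu$ composition at high
$\mu$ shifts dependent fluxes by more than 5 % on the reference scenario,
which is why the $\mu$-dependence is carried through the whole chain.

# Specific rates

Chemostat windows use the steady-state balances
$\mu = D$, $q_S = D(S_{feed}-S)/X$, $q_P = DP/X$, $r_{CO_2} = CER/X$, with
stationarity asserted per species (relative drift beyond 5 % by default is
an error naming the species). A-stat time points keep the accumulation
terms, $\mu = D + \dot X/X$, $q_P = (\dot P + D(P - P_{feed}))/X$, with
derivatives from a centred local linear regression (11 samples by
default); near the series edges the window widens and gains a quadratic
term, the standard local-polynomial boundary correction, because a
one-sided linear fit is biased for curved signals. On stationary data the
A-stat formulas reduce exactly to the chemostat ones. Units are fixed
throughout: concentrations mM, biomass g DCW/L, rates mmol/(g DCW h).

Overflow onset is the smallest $\mu$ at which the acetate excretion rate
exceeds a threshold (default 0.05 mmol/(g DCW h)) and stays above it; since
the threshold crossing overestimates a gradual onset by threshold/slope,
the estimate is refined by back-extrapolating a linear fit over the first
five post-crossing snapshots to its zero crossing, falling back to the
crossing point for step-like profiles.

# Energy ledger and carbon balance

ATP production sums substrate-level phosphorylation and
`po_ratio` × the respiratory NADH oxidation flux; growth-associated
consumption is read off the drains; **ATP spilling** is the explicit
dissipation flux that closes the ATP node — production minus all
stoichiometric consumption, a first-class member of the flux vector rather
than a post-hoc subtraction. The ledger reports the spilling rate
(mmol/(g DCW h)) and the per-biomass view (rate/$\mu$, mmol/g DCW). The
per-biomass view is the one in which spilling *declines* after overflow
onset under a constant biomass yield: with yield constant, rates scale
roughly with $\mu$, so a declining energy waste is a per-biomass statement
(less ATP dissipated per gram of cells formed), driven by the falling
ATP-per-glucose as carbon is diverted from full oxidation into excreted
by-products. The ledger also reports the TCA-cycle share of CO2 and NADH
production and the glycolytic share of ATP production.

The carbon balance divides each measured carbon flow by the carbon fed
(6 $q_{glc}$ plus twice any acetate uptake — consumed species enter the
denominator, never as negative recoveries): fractions to biomass, CO2 and
each by-product, with the unclosed remainder reported as `gap`, never
redistributed. The identity recoveries + gap = 1 is arranged to hold
exactly in floating point.

# The synthetic-data generator

No cultivation data are deposited for this kind of experiment, so the
generator is a first-class module that emulates the study conditions:
A-stat acceleration 0.01 1/h², $\mu$ from 0.10 to 0.48 1/h, feed glucose
25 mM (4.5 g/L), constant biomass yield 0.45 g/g (a mid-range aerobic
glucose yield, chosen once), acetate onset at $\mu = 0.27$ 1/h with a
second, faster accumulation phase after 0.46 1/h, pyrimidine-intermediate
excretion in three phases (CBASP and DHO rising to onset; DHO declining
after it while orotate and CBASP plateau; orotate and CBASP rising again
past 0.46), NAA appearing above ~0.22 1/h, total by-product carbon wasting
growing from 3 % to 11 % across the ramp, `Vprod` peaking near the PDH
saturation growth rate 0.42 1/h, and D-stat acetate co-utilisation whose
capacity is repressed linearly with dilution rate and scaled by a
capability parameter, with the summed non-acetate wasting pinned at 5.5 %.
Profiles are piecewise-smooth parametric curves (smoothed hinges and
logistic transitions at the named breakpoints), not mechanistic kinetics —
only breakpoint locations and monotone phases are modelled.

At every time point the generator fixes the inflow (from the yield),
outflows (from the profiles), drains (composition × $\mu$) and the regime
rules, solves the square system, and keeps the exactly balanced flux
vector as ground truth; concentrations follow by integrating the broth
balances $\dot P = q_P X - D(P - P_{feed})$ (deSolve) along the ramp, or
by the stationary algebra for chemostat/D-stat, with biomass from the
glucose balance. Observation noise is multiplicative log-normal (CV 2 % by
default), seeded; the D-stat acetate uptake is computed self-consistently
with the biomass it produces so the observed concentrations invert to the
true rates.

What passing tests on this generator shows: the estimators and solver
recover exactly what was put in, at realistic noise, through the full
file-format round trip. What it does not show: anything about real
measurement error structure (autocorrelated drift, calibration bias,
sampling dead volumes), real biological variance between replicates, or
the truth of the emulated breakpoints themselves — those are inputs, not
findings. Parameter-recovery checks average over triplicate generated
cultivations, mirroring the triplicate-experiment design such studies use.

# The counterfactual

`reroute_counterfactual()` asks what a study that had *not* measured
lactate, CBASP, DHO, orotate and NAA would have concluded: those outflows
are removed and their carbon placed as a generic pyruvate outflow, and the
system re-solved. On the reference scenario at $\mu = 0.47$ 1/h the
anaplerotic flux is distorted far more than the TCA cycle, which is
distorted more than pyruvate dehydrogenase — the ordering expected when
oxaloacetate-adjacent drains are misattributed to pyruvate, and the reason
measuring "minor" by-products matters for MFA even when they are a few
percent of carbon.

# Problem sizes and runtime choices

The reference ramp is sampled every 0.25 h (153 points over 38 h);
snapshot grids use $\Delta\mu$ = 0.01 1/h; parameter-recovery and
Monte-Carlo assertions use triplicate scenarios and ~100 randomised
solves. These sizes keep the full suite near ten seconds while leaving
every estimate's sampling error well below the tolerances tested.

# Known limitations

* The glyoxylate shunt is set by rule, not estimated; resolving it needs
  isotope labelling, outside scope.
* The NADPH balance is closed exactly; transhydrogenase activity would
  reallocate it between pools and is not modelled.
* The composition table is surrogate; conclusions about composition
  sensitivity are qualitative until measured compositions are supplied.
* The spilling magnitudes depend on the P/O ratio choice (default 2); the
  ratio rescales the oxidative ATP term only, so relative statements
  (declines, ratios to total production) are unaffected.
* Irreversibility is diagnosed, not enforced; grossly infeasible inputs
  error out, mildly noisy ones are reconciled by least squares.

# Worked example

```{r example, eval = FALSE}
net <- build_default_network()
ct <- default_composition_table()
sc <- generate_scenario(scenario_config("astat", seed = 1))
bundle <- run_pipeline(sc, mu_grid = c(0.15, 0.30, 0.45), regime = "astat",
                       network = net, comp_table = ct)
ledger_table(bundle)
balance_table(bundle)
```
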