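---
title: "Models and methods behind chemostoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemostoich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemostoich)
```

This vignette documents the scientific models the package implements, the
conventions and numerical choices behind them, and what the test suite
does and does not demonstrate.

## The zero-growth stoichiometric model

### Scope and structure

The built-in network (`build_default_network()`) is a compartmented model
of *S. cerevisiae* central carbon metabolism, curated to the minimum that
determines product yields and ATP costs: glycolysis (with the
GAPDH–PGK–PGM–ENO stretch lumped into one NADH- and ATP-forming step),
the oxidative and non-oxidative pentose phosphate pathway, the cytosolic
route to acetyl-CoA (pyruvate decarboxylase, acetaldehyde dehydrogenase,
AMP-forming acetyl-CoA synthetase), acetyl-CoA carboxylase, mitochondrial
pyruvate dehydrogenase with a lumped TCA cycle, respiration at a
configurable P/O ratio, a lumped shikimate pathway
(E4P + 2 PEP + ATP + NADPH → chorismate), chorismate mutase/prephenate
dehydratase, transamination against a glutamate/2-oxoglutarate couple
closed by glutamate dehydrogenase, and the five heterologous steps of the
resveratrol pathway (PAL2, the C4H monooxygenase, 4CL, STS, and the
ATP-dependent Snq2 exporter), plus passive export of coumaric, cinnamic
and phloretic acid. The shikimate pathway is lumped because none of its
internal branch points is used elsewhere in the model; likewise the TCA
cycle. Growth-coupled flux balance (a biomass equation) is out of scope:
the maximum biomass yield used by the physiology side is a regression
estimate, not a network property.

Two choices are deliberately configurable:

* **P/O ratio** (default 1.0, the in vivo value for glucose-grown
  *S. cerevisiae*): mol ATP per electron pair respired. Cytosolic and
  mitochondrial NADH respire at the same P/O (external NADH
  dehydrogenase assumption), as does FADH2.
* **Phloretic acid formation** (default NADPH): the reduction of
  coumarate to phloretate has no characterised enzyme, so its cofactor
  is a parameter.

### Element bookkeeping conventions

Only C, H, O and N are balanced. Protons and phosphate groups are not
tracked: sugar phosphates carry their parent-sugar formula, ATP, ADP and
AMP share one formula (so phosphoryl transfers are element-neutral), and
NAD(P)H and FADH2 carry two hydrogens more than their oxidized partners.
Coenzyme A is tracked without its sulfur. Water is explicit wherever
these conventions require it, which makes every reaction over balanced
metabolites conserve C, H, O and N *exactly* — and therefore forces the
water and CO2 coefficients of the net overall conversion. The
degree-of-reduction balance (electrons at C = 4, H = 1, O = −2, N = −3)
is checked independently on every overall reaction: electrons in glucose
must equal electrons in the product plus four per O2 consumed.

### Cofactor scenarios

Yeast has NADP- and NAD-dependent isoenzymes of both acetaldehyde
dehydrogenase (Ald6 vs Ald2/3) and glutamate dehydrogenase (Gdh1/3 vs
Gdh2), so the NADPH books can close four different ways. Per mole of
resveratrol the pathway demands 3 NADPH (shikimate lump, C4H, and the
glutamate dehydrogenase that re-assimilates the ammonia released by PAL)
and produces 3 reduced cofactors at the acetaldehyde-dehydrogenase step.
With NADP-ALD and NADP-GDH the books close exactly; with NAD-ALD the
oxidative PPP must supply NADPH at a carbon cost (1.5 or 1.0 G6P per
product, depending on the GDH); with NADP-ALD and NAD-GDH one NADPH per
product is surplus. The model reoxidizes that surplus through a
non-phosphorylating NADPH oxidase (O2-consuming, no ATP): routing it
through the phosphorylating chain instead would change the ATP breakdown
of that scenario into a copy of the NADP/NADP case, which contradicts
the scenario's distinct ATP accounting. This is also why the yield we
report for the NADP-ALD/NAD-GDH scenario is 0.277 rather than the 0.284
sometimes quoted for it: 0.284 is not consistent with that scenario's own
ATP breakdown (2.875/0.875/9.25), which the model reproduces exactly, and
which implies a glucose requirement of 3.604 mol/mol.

### The linear program

`solve_min_substrate()` fixes product export at 1, imposes steady state
on every balanced metabolite and non-negativity on irreversible
reactions, and minimizes glucose uptake. A linear program (rather than a
square solve) is needed because the NADPH oxidase plus the oxidative PPP
form a one-dimensional carbon-wasting cycle: minimization selects the
carbon-optimal flux the yield concept requires. The optimal objective is
unique; the flux vector can still be degenerate, so a second stage
minimizes the L1 norm at the fixed optimal glucose uptake, making the
reported vector reproducible (and keeping reversible reactions from
running in both directions at once).

The solver is a dense two-phase simplex with Bland's anti-cycling rule,
written for this package: the flux problems are small (about sixty
variables) but heavily degenerate — conserved cofactor moieties make
balance rows linearly dependent (an independent row subset is selected by
QR factorisation, and the full system is re-verified on every returned
solution) — and Bland's rule guarantees termination where
largest-coefficient pivoting can cycle or crash. Balances are accepted at
|residual| < 1e-9; yields are conventionally reported to 3 decimals.

ATP accounting sums net ATP formation by reaction category: glycolytic
substrate-level phosphorylation (PGK-lump + pyruvate kinase net of the
hexokinase and phosphofructokinase investments), TCA substrate-level
phosphorylation (succinyl-CoA-level GTP, funnelled into the ATP pool by a
nucleoside-diphosphate kinase), and oxidative phosphorylation (P/O times
the respired cofactors). AMP-forming activations (acetyl-CoA synthetase,
4CL) count as 2 ATP equivalents — ATP → AMP + PPi with the pyrophosphate
hydrolysed — which is what makes the pathway demand come to 13 mol ATP
per mol exported resveratrol (1 shikimate kinase + 6 ACS + 3 ACC + 2 4CL
+ 1 export). An explicit ATP-dissipation reaction is part of the network;
it carries zero flux in every minimum-substrate optimum and serves as the
objective of `atp_per_glucose()`, which recovers the respiratory ATP
yield of glucose (16 at P/O 1.0) from the network rather than from a
constant.

## Chemostat physiology

All rates are computed on total dry biomass and indexed by dilution rate
D, matching how steady-state data tables are reported;
`viable_growth_rate()` (μ = D / viability) is available separately for
the low-D regime where viability drops and the growing fraction must
turn over faster than D. Unit conventions: product concentrations in µM,
residual glucose in mM, feed and biomass in g/l, rates in mmol per g dry
weight per h, glucose at 180.16 g/mol, gas volumes at 24.06 l/mol (20 °C,
1 atm) — all centralized in `cs_constants()`. Uptake rates are stored
negative (uptake) but every formula uses magnitudes.

Carbon recovery needs a biomass composition; the package fixes
CH1.8O0.5N0.2 at 26.4 g/Cmol (ash included), a standard value for
glucose-grown yeast. The maintenance regression is unweighted OLS — no
weighting scheme is implied by the underlying linear relation — with a
`weights` argument for sensitivity analysis. In the Herbert–Pirt
decomposition, growth is the *residual* term (1 − maintenance − product),
so the three fractions sum to one by construction; a record whose
maintenance-plus-product terms exceed its measured uptake is flagged as
inconsistent rather than silently truncated.

The steady-state criterion follows standard chemostat practice: after at
least 6 volume changes, dry weight and q_CO2 must each change by less
than 3 % over 2 consecutive volume changes (linear interpolation between
observations).

## The synthetic-data generator

`generate_dataset()` emulates glucose-limited steady states that obey the
package's own model relations exactly before noise: μ = D, a linear
pooled-product model q_p(μ) split over the four products by fixed
composition fractions, the Herbert–Pirt relation for q_s, Monod kinetics
for residual glucose, the reactor glucose balance for the biomass
concentration, and carbon plus degree-of-reduction closure for q_CO2 and
q_O2 (so noiseless records have exactly 100 % carbon recovery and RQ ≈ 1).
Measurement noise is multiplicative log-normal with mean one —
concentrations and rates are positive, and reported reproducibility for
such cultures is a few percent, which motivates the default CV of 2 % —
applied per observable from its own random substream, so silencing or
adding an observable never perturbs the draws of the others at a fixed
seed.

The presets encode two study designs: a non-producing reference strain
(Y_X/S^max 0.52 g/g, m_s 0.10 mmol/gX/h, duplicates at D = 0.025–0.15 1/h)
and a producer (m_s 0.12, μ_max 0.25 1/h, K_s 0.247 mM, pooled
productivity reaching 0.024 mmol/gX/h at D = 0.15, viability declining
linearly below D = 0.075 to 0.76 at 0.025). The producer's K_s comes from
inverting Monod at the observed operating point (μ = 0.15, C_s = 0.37 mM);
the reference Monod parameters (μ_max 0.40 1/h, K_s 0.30 mM) are chosen
as typical for a wild-type strain under these conditions, since only the
producer's kinetics are constrained by data. Composition fractions
(0.659/0.130/0.181/0.030) are the effluent concentration ratios of the
producer at D = 0.10.

What the generator does *not* emulate: replicate-to-replicate biological
variation beyond measurement noise, evolutionary drift over long runs,
the growth-rate *independence* of phloretic acid formation (all four
products share the linear μ-dependence for simplicity), weak-acid
uncoupling, or any transcriptional response. Passing parameter-recovery
tests on synthetic data therefore shows the estimators are correct and
unbiased under the stated error model, not that real cultures satisfy
the model.

## Problem sizes and determinism

The test suite and the acceptance script run the flux LP a few dozen
times (milliseconds each), one 200-seed parameter-recovery study on
8-record datasets, and 25-seed carbon-recovery sampling; the whole suite
completes in well under a minute. All stochastic steps are seeded; the
synthetic reference dataset used for the headline maintenance-recovery
number is generated at seed 42, the seed fixed in the study design.

## Known limitations

* The network is a curated minimum, not a genome-scale reconstruction;
  SBML import, thermodynamics and kinetics are out of scope.
* Yields are zero-growth, zero-maintenance ceilings; they say nothing
  about attainable rates.
* The Herbert–Pirt product term uses model-derived maximum yields, so a
  bias in the stoichiometric model propagates into the decomposition.
* Carbon recovery requires measured q_CO2; records without off-gas data
  get `NA` rather than an imputed recovery.
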