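---
title: "From production to health: tracing mercury through trade, transport and diet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From production to health: tracing mercury through trade, transport and diet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtrade)
```

## The problem

Anthropogenic mercury (Hg) is emitted where goods are produced, but through
international trade those goods are often consumed elsewhere. Because the
locally deposited fraction of emitted Hg varies with latitude, relocating
production changes not only *who* is responsible for emissions but also *how
much* Hg is deposited globally, how much methylmercury (MeHg) accumulates in
seafood, freshwater fish and rice, and ultimately the IQ losses in newborns
and fatal heart attacks (FHA) in adults that dietary MeHg causes.

`hgtrade` implements that full chain as composable, tested pieces:

1. **Consumption-based accounting** — attribute sectoral emissions to the
   countries that finally consume the associated goods (environmentally
   extended MRIO analysis).
2. **A "no trade" counterfactual** — rescale each country's gridded
   emissions from production-based to consumption-based totals, holding the
   global total fixed.
3. **A linear transport surrogate** — map either gridded inventory to
   atmospheric deposition, ocean plankton MeHg and soil Hg.
4. **Proxy-scaled dietary exposure** — scale each country's with-trade food
   MeHg exposure to the counterfactual using three environmental proxies.
5. **Health impacts and valuation** — linear IQ and log-linear FHA
   dose–response, monetized with earnings losses and the value of a
   statistical life (VSL).
6. **Monte Carlo uncertainty** — systematic multiplicative errors on four
   input components, propagated through the whole health computation.

Real-world applications of this chain require licensed trade databases,
gridded emission inventories and a coupled Earth-system simulation. The
package therefore ships a **synthetic world generator** with the same
statistical structure, so every equation is exercised, every invariant is
testable, and nothing needs downloading.

## Consumption-based accounting

For an economy of $R$ regions and $S$ sectors, let $Z$ be the
interindustry flow matrix, $Y$ final demand (one column per consuming
region), and $x$ gross output. With technical coefficients
$A_{ij} = Z_{ij}/x_j$ and Leontief inverse $L = (I - A)^{-1}$, the
emissions produced in region $r$ attributable to final consumption of
region $s$ are

$$\mathrm{EE}_{rs} = e^{(r)} \, L \, Y_s,$$

where $e^{(r)}$ is the emission-coefficient row vector (emissions per unit
output) restricted to region $r$'s sectors and zero elsewhere. The package
computes the **full** $R \times R$ matrix including the domestic diagonal,
because that makes the two conservation identities testable — row sums are
production-based (PBA) totals and column sums consumption-based (CBA)
totals — and the scenario module needs CBA totals. The off-diagonal
restriction appears only in `embodied_trade_share()`. Emission-inventory
sources are mapped to MRIO sectors by a user-supplied many-to-one
concordance (`aggregate_sources()`); no concordance is hard-coded, and
sources without monetary output of their own (artisanal gold mining is the
canonical case) are carried by whichever sector the user maps them to.

Numerically, $L$ is obtained by a dense factorization (`solve`), with an
explicit spectral-radius diagnostic before the solve and a residual check
(tolerance $10^{-10}$) after it. The test suite cross-checks the whole
accounting against an independent truncated power-series oracle
$\sum_{k \le 60} A^k$.

## The "no trade" counterfactual

The counterfactual assumes each country would produce domestically, with
its own technology and spatial pattern, what it currently consumes: within
each country's masked cells the gridded inventory is multiplied by
$\mathrm{CBA}_c/\mathrm{PBA}_c$, so the global total is unchanged while
national totals switch from production to consumption accounting.
Fractional border cells are scaled by their mask weight, which makes
double-counting impossible. A country with zero production but positive
consumption has no pattern to scale; its CBA total is spread uniformly over
its masked cells, with a warning. Rescaling is applied to the country's
total inventory (a per-sector-layer variant would be a straightforward
extension but is not needed by the chain). No economic re-equilibration
(prices, substitution) is attempted — the counterfactual is deliberately
mechanical.

The pipeline feeds this step PBA and CBA totals taken as the row and column
sums of the embodied-flow matrix itself. This is a self-consistency choice:
in an autarky world (`trade_share = 0`) the flow matrix is exactly
diagonal, the scaling ratio is exactly 1, and the entire downstream chain
is bitwise identical across scenarios — the "no effect under no trade" null
holds exactly, not merely to tolerance.

## The linear transport surrogate

A coupled atmosphere–ocean–land simulation is out of scope; what the
downstream equations actually need is the *scenario difference* of three
environmental fields, and the dominant mechanism — a latitude-dependent
deposited fraction — is linear. The surrogate therefore gives each source
cell a deposition budget:

* a **local fraction** $\alpha(\varphi)$, interpolating linearly in
  $|\varphi|$ from `local_fraction_min` at the equator (default 0.2) to
  `local_fraction_peak` (default 0.6) at `peak_latitude` (default 40°),
  constant poleward of the peak. The shape is an artifact choice; only the
  ordering $\alpha(40°) > \alpha(0°)$ — faster oxidation of atmospheric Hg
  in the mid-latitude band, and the readier deposition of oxidized Hg — is
  load-bearing, and the monotone clamped ramp is the simplest shape with
  that property.
* an **advected share** `advection_fraction` (default 0.1) deposited over
  `advection_cells` cells eastward (westerlies), with exponentially
  decaying weights (ratio 1/2), wrapping in longitude;
* a **well-mixed share** `global_mixing` (default 0.1) deposited uniformly;
* an explicit **undeposited remainder**, reported in the mass ledger rather
  than silently lost.

Plankton MeHg responds linearly to the deposition anomaly on ocean cells
(`plankton_gain`), since oceanic inorganic Hg — the methylation substrate —
derives mainly from deposition. Soil Hg responds by `soil_gain` (default
0.005, capped below 0.01) times the *relative* deposition anomaly,
reflecting the enormous mass and slow turnover of the soil pool: under the
default backgrounds, halving or doubling emissions moves soil Hg by well
under 1%. Backgrounds (natural plus legacy re-emission, the majority of the
modern Hg cycle) are held identical across scenarios; `background_D` must
be positive because the soil response is defined relative to it.
Superposition holds to $10^{-10}$ and is tested.

## Exposure and health

With-trade exposure is the intake-weighted sum over food categories
(µg/day):

$$E_{\mathrm{WT}} = I_{\mathrm{seafood}} C_{\mathrm{seafood}} +
  I_{\mathrm{fwfish}} C_{\mathrm{fwfish}} + I_{\mathrm{rice}} C_{\mathrm{rice}}.$$

The counterfactual exposure scales each pathway by the ratio of its proxy
between scenarios — fish-catch-weighted plankton MeHg ($P$) for seafood,
population-weighted deposition ($D$) for freshwater fish, mean soil Hg
($S$) for rice:

$$E_{\mathrm{NT}} = \tfrac{P_{\mathrm{NT}}}{P_{\mathrm{WT}}} I_s C_s +
  \tfrac{D_{\mathrm{NT}}}{D_{\mathrm{WT}}} I_f C_f +
  \tfrac{S_{\mathrm{NT}}}{S_{\mathrm{WT}}} I_r C_r,$$

with consumption patterns held fixed. Proxies are evaluated within national
boundaries only (no transboundary watershed logic); countries with no
marine catch get a *missing* plankton proxy, never zero, and a pathway with
zero intake skips its ratio entirely, so no 0/0 ever arises.

Health endpoints use the standard coefficient chain: $\beta$ (intake →
blood), $\lambda$ (blood → hair), then $\gamma$ (hair → IQ points,
linear, no threshold) and $\varphi$ (hair → FHA risk, log-linear with
causality probability $\omega$):

$$\Delta IQ = \gamma\lambda\beta \cdot (E \odot BW), \qquad
  \Delta CF = \sum_g POP_g \, Cf_g \, \omega
  \left(1 - e^{-\varphi\lambda\beta (E \odot BW)}\right),$$

$$H = EL \times \Delta IQ_{\mathrm{total}} + VSL \times \Delta CF.$$

Two deliberate exposures of ambiguity:

* **`bw_mode`** — the published form multiplies exposure by body weight,
  while the conventional intake→blood chain is stated per kg. The default
  follows the literal form (`multiply`); `divide` is available and the two
  differ by $BW^2$, so the choice is flagged prominently.
* **Per-scenario vs differenced dose** — impacts are computed under each
  scenario's absolute exposure and then differenced (net = with − no),
  matching a per-scenario summary table; at the small doses involved the
  log-linear form is nearly linear (the linearization error is second
  order, `small_dose_limit_check()`), so the alternative reading changes
  little.

$\gamma, \lambda, \beta, \varphi, \omega$ and $BW$ carry **no defaults**:
they are study inputs. The example configuration ships illustrative values
($\gamma\lambda\beta = 10^{-4}$, $\varphi\lambda\beta = 10^{-5}$ per
µg/day·kg, $\omega = 0.5$, $BW = 70$ kg) chosen to give per-fetus IQ
decrements of order $10^{-2}$ points and national FHA burdens of order
$10^2$ deaths/yr — plausible magnitudes, not calibrated estimates. $EL$
defaults to \$18,832 per IQ point (2008 USD) and $VSL$ to \$6.3 million
(2005 USD), converted to 2020 USD by user-supplied deflators (none are
hard-coded; the example uses 1.24 and 1.35). An optional income-elasticity
scaling of VSL by GDP per capita reduces exactly to the flat-VSL case at
elasticity 0.

Countries missing demographics are flagged and excluded from global sums
with a reported count — never silently zeroed. Global per-fetus IQ
decrement is the births-weighted mean.

## Monte Carlo uncertainty

Four multiplicative error components — food intake, food MeHg
concentration, dose-response, valuation — are drawn once per iteration and
applied *systematically* (shared across countries), because the literature
ranges they encode are systematic biases, not independent national noise.
Asymmetric 95% ranges are fitted to log-normal factors by matching both
quantiles (`lognormal_from_bounds()`); the default spec uses ranges typical
of global Hg assessments: intake (−47%, +42%), concentration (−37%, +63%),
dose–response (−59%, +147%), valuation (−70%, +26%). The health computation
is repeated 1,000 times by default and the 2.5/97.5 percentiles reported
next to the unperturbed point value (which the percentile interval need not
contain, though in practice it does). Draws that error are recorded; more
than 1% failures aborts with diagnostics, preventing silent selection bias.
`nrmsd()` provides the model-evaluation statistic (RMSD over the observed
range, switchable to mean normalization).

## The synthetic world

`generate_world()` emulates the *shapes* of the real inputs:

* **Economy** — built from the demand side: log-normal final demand,
  random technical coefficients with column sums in (0.3, 0.6) so the
  Leontief system is invertible by construction (a rescale-and-retry guard
  divides $A$ by 1.1× its spectral radius in the never-observed case
  $\rho \ge 1$), gross output solved for exact balance. Exactly
  `trade_share` of every region's demand is sourced abroad, so the
  parameter is recoverable to machine precision.
* **Emission intensities** — log-normal per (region, sector) around a
  shared sectoral base, multiplied by `intensity_gap` for developing
  regions: the embodied-trade mechanism requires a vast intensity gap
  between industrialized and emerging economies, and the gap is recoverable
  from the generated account within sampling error.
* **Geography** — each country owns a contiguous longitude strip and a
  latitude band: developed countries near 40°, developing near the
  equator, the rest ocean. Country totals are spread over land cells with
  Gamma-jittered weights, so per-country grid sums equal the account
  exactly (tested at $10^{-6}$ relative).
* **Diets** — coastal countries eat ~80 g/day seafood and little rice;
  inland countries eat no marine seafood, more freshwater fish and ~300
  g/day rice. Concentration medians (0.08, 0.04, 0.004 µg/g) make seafood
  the dominant global pathway, followed by freshwater fish, then rice —
  the observed global ordering.
* **Demographics** — populations, births, baseline FHA incidence by
  gender, and a developed/developing GDP-per-capita contrast.

What it does **not** emulate: real sector magnitudes or price structure,
within-country heterogeneity, food trade (fish eaten where caught vs
consumed, beyond catch weighting), seasonality, atmospheric chemistry or
ocean circulation, and the correlation structure of real national
statistics. Passing tests therefore demonstrate the *correctness of the
computations and the qualitative mechanism*, not calibrated real-world
magnitudes — the headline numbers of any real application still require the
real databases and transport simulation.

The **three-country world** (`three_country_world()`) is the designed
minimal case for the sign of the global effect: two coastal seafood-eating
importers in the high-deposition band, one inland rice-eating exporter on
the equator. Trade moves emission-intensive production to the low-
deposition band, so deposition, exposure and total loss all fall relative
to autarky while the exporter's own burden rises. Every intermediate
quantity is hand-computed in the test suite.

## Reproducibility and problem sizes

A single global seed fans out to per-module seeds through a documented
integer hash (`fanout_seed()`), keeping every stage's stream independent
and each seed below $2^{31}$. Identical configurations reproduce
byte-identical output files.

The analysis scripts and tests use a 10-region × 4-sector economy on a
36 × 72 (5°) grid with 1,000 Monte Carlo repeats (200 in the acceptance
script) — comfortably sized for a laptop while leaving the sampling error
of every tested statistic far below its assertion tolerance. Key
tolerances: accounting conservation and scenario conservation $10^{-6}$
relative; Leontief residual $10^{-10}$; superposition $10^{-10}$;
oracle-vs-implementation $10^{-6}$; Monte Carlo quantiles within 3×
standard error at $n = 1000$.

## Known limitations

* The counterfactual ignores relative prices, substitution and capacity
  constraints under autarky.
* The transport surrogate has no chemistry, no Hg speciation beyond the
  latitude proxy, no seasonality, and a single fixed advection direction.
* Exposure ignores within-country heterogeneity and international food
  trade.
* The FHA endpoint uses a single causality probability rather than a
  cohort life table; IQ valuation uses one lifetime-earnings constant with
  no discounting schedule.
* The four Monte Carlo components are treated as independent and
  uncorrelated; no variance decomposition is attempted.

```{r demo}
res <- run_three_country()
res$table1
```
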