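---
title: "Models and methods behind fishrtk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fishrtk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishrtk)
```

fishrtk compares physiologically based toxicokinetic (PBTK) models of a
teleost fish at three levels of architectural fidelity, and studies how that
choice propagates into reverse toxicokinetics (rTK): inferring the waterborne
exposure concentration that would produce an observed internal concentration.
This vignette is the package's own account of the models, the numerical
choices, and the design decisions that were genuinely open.

## The three architectures

All models share the same physical picture: a fish in water with a constant
chemical concentration $C_\mathrm{env}$ (µM), exchanging chemical across the
gills, distributing it through the blood to flow-limited tissue compartments,
and destroying it by first-order metabolism. Units are seconds, mL and µM
throughout; flows are mL/s.

* **7C** — arterial and venous blood, brain, gonads, liver, poorly perfused
  tissue (ppt) and richly perfused tissue (rpt). Arterial blood feeds every
  tissue; the gonads' and rpt's effluents drain *into the liver* before
  reaching the venous blood; brain, liver and ppt drain to the venous blood.
  The liver is the only metabolizing compartment. The gill interface carries
  an assimilation factor $\varphi$.
* **6C** — arterial and venous blood, brain, gonads, liver and a lumped
  "other" tissue; every tissue drains directly to the venous blood. The
  liver metabolizes ($k_\mathrm{met}$) and the "other" tissue can excrete
  ($k_\mathrm{exc}$; zero for the preset chemicals, see below).
* **1C** — a single well-mixed body compartment with gills; metabolism acts
  on the whole body.

Two structural variants of the 6C model isolate architecture from
parameterization: `collapse_gonads_other()` merges gonads and "other" into
one compartment (volumes and flows add, composition mixes by volume), and
`rewire_gonads_to_liver()` sends the gonads' effluent through the liver, as
in the 7C.

### Tissue exchange and partitioning

Each tissue is flow-limited: $V_i\,\dot C_i = Q_i\,(C_\mathrm{art} - C_i/P_i)
- \text{sinks}$, where the tissue–water partition ratio uses a linear
lipid/water mixing rule

$$P_i = f_{\mathrm{lipid},i}\,10^{\log K_\mathrm{ow}} + f_{\mathrm{water},i},$$

with the octanol–water ratio standing in for the lipid phase. Blood is
parameterized as pure water phase ($P = 1$): in the absence of measured
plasma binding, blood is assumed not to accumulate chemical, and the carried
`kd_plasma` descriptor field is inert. This choice affects absolute
magnitudes identically in all architectures, so relative comparisons between
models are unaffected.

### The gill interface

The gills are treated as an instantaneous-equilibrium interface rather than
a state variable. On the venous-to-arterial pass, an effective
water-equilibrating flow

$$Q_\mathrm{ex} = \varphi \, \min(Q_w, Q_c)$$

leaves the gills at the water concentration, so arterial blood is the
mixture $C_\mathrm{art}^{eq} = \big[(Q_c - Q_\mathrm{ex})\,C_\mathrm{ven} +
Q_\mathrm{ex}\,C_\mathrm{env}\big]/Q_c$. Uptake is therefore bounded by
$Q_\mathrm{ex} C_\mathrm{env} \le Q_w C_\mathrm{env}$ — the gills cannot
extract more chemical than the respiratory water delivers — and elimination
is the mirror-image term $Q_\mathrm{ex} C_\mathrm{ven}$ (the assimilation
factor applies symmetrically to uptake and elimination; the alternative,
uptake-only placement would depress all 7C steady states by the factor
$\varphi$ uniformly, which is not what the architecture comparison is
about). The 1C model has no cardiac output, so it exchanges directly at
$Q_w$ against its free water-phase concentration $C_b/P_b$, giving the
single-compartment balance $\dot C_b = (Q_w/V)\,C_\mathrm{env} -
\big(Q_w/(V P_b) + k_\mathrm{met}\big)\,C_b$.

### Kinetics

First-order kinetics makes every model a linear system $\dot C = A C + b\,
C_\mathrm{env}$ with strictly stable $A$, which is what licenses the exact
rTK inversion. Saturable clearance is available as a Michaelis term
$v_\mathrm{max} C/(K_m + C)$ in the metabolizing compartment; in the regime
$K_m \gtrsim 100\times$ the peak concentration it is numerically
indistinguishable from first order (the test suite bounds the whole-body
difference below 1%), which is why the package's inversion layer restricts
itself to first-order kinetics — the Michaelis inversion would be neither
linear nor unique.

## Default physiology fixtures

The package is self-contained: it ships one default parameter set per
architecture (`default_physiology()`), loadable and overridable from CSV.
**All values are assumed**, chosen once at design time on a zebrafish scale
from literature-plausible ranges, and flagged as such in the `provenance`
field — they are not measurements:

| quantity | value | rationale |
|---|---|---|
| body volume | 0.65 mL (0.65 g) | adult female zebrafish scale |
| cardiac output $Q_c$ | 0.002 mL/s (~0.12 mL/min) | small-teleost cardiac output |
| respiratory flow $Q_w$ | 0.008 mL/s | ventilation:perfusion ≈ 4 |
| assimilation factor $\varphi$ | 0.5 (7C only) | mid-range gill uptake efficiency; also the smallest value consistent with arterial blood relaxing on the order of seconds (see below) |
| gonad volume / flow | 0.05 mL / 1% of $Q_c$ | vitellogenic ovary ≈ 8% of body, weakly perfused |
| gonad lipid fraction | 0.15 | lipid-rich eggs |
| ppt (muscle, skin) | 0.45 mL, 66% of $Q_c$, 2% lipid | bulk of the body |

The 6C set reuses these body-centric values where the interpretation is
analogous, merging ppt and rpt into "other" by volume-weighted mixing; the
1C set lumps everything, so its partition ratio is exactly the
volume-weighted mean of the multicompartment ratios. The assimilation
factor deserves one note: with the gill model above, arterial blood can only
relax faster than the slow venous pool if the gill-equilibrated fraction of
cardiac output exceeds half the arterial relaxation amplitude, which
requires $\varphi \gtrsim 0.5$; the observation that arterial blood should
re-equilibrate within seconds after an exposure step fixes the default at
0.5 rather than lower.

Preset chemicals: diazinon ($\log K_\mathrm{ow} = 3.81$) and
1,2-dichloroethane ($\log K_\mathrm{ow} = 1.48$), a lipophilic/hydrophilic
contrast. Their default clearance $k_\mathrm{met} = 10^{-4}\,\mathrm{s}^{-1}$
is an assumed mid-range value (the midpoint of the default clearance grid),
identical for both so that comparisons between them isolate lipophilicity.
`k_exc = 0` by default: the rTK layer's chemical parameterization is a
single hepatic clearance plus $K_\mathrm{ow}$.

## Exact exposure reconstruction

At steady state, $C_\mathrm{ss} = -A^{-1} b \, C_\mathrm{env}$, so each
observable carries a dimensionless *response coefficient*
$s = C_\mathrm{obs,ss}/C_\mathrm{env}$ independent of the exposure level
(the whole-body coefficient is the volume-weighted mean over all
compartments, blood included — blood has $P = 1$, so its inclusion is
conservative). The predicted exposure concentration is then simply
$\mathrm{PEC} = C_\mathrm{obs}/s$. The inversion is computed from the linear
system rather than from hand-transcribed closed forms: one code path, no
transcription errors, and the forward model itself provides the round-trip
test (forward-simulate at $E$, invert, recover $E$ to $10^{-6}$ relative).
With no sinks at all, $s_i = P_i$ exactly — thermodynamic equilibrium with
the water — which is a second closed-form anchor for the linear algebra.

## The structural-variant analysis

Collapsing gonads and "other" is *exactly* invisible to the remaining
compartments whenever neither merged compartment carries a distributed sink:
at steady state a sink-free flow-limited tissue equilibrates
($C_i/P_i = C_\mathrm{art}$), so its venous effluent flux is $Q_i
C_\mathrm{art}$ and any flow-preserving merge returns the same total flux.
With a distributed excretion rate in "other" the merge changes the aggregate
excretory clearance and the invariance becomes approximate — a documented
limitation; the package's variant analysis therefore uses hepatic-only
clearance.

Rewiring the gonads through the liver is *not* neutral, and the direction is
forced by mass balance: the liver's steady-state throughput as a function of
its perfusion $Q$ is $T(Q) = Q/(Q + k_\mathrm{met} V_l P_l)$, and
$\mathrm{d}\,[Q\,T(Q)]/\mathrm{d}Q < 1$, so routing the sink-free gonads'
effluent through the liver strictly *lowers* the total venous return flux.
Consequently the rewired model's liver concentration rises (it receives more
inflow) while the venous concentration falls, and with it everything
downstream of the gills; when the full cardiac output equilibrates at the
gills ($Q_\mathrm{ex} = Q_c$) the arterial blood is pinned at
$C_\mathrm{env}$ and the arterial and brain differences are exactly zero.
The package reports these signed differences per compartment
(`steady_state_difference()`, the `variant_analysis` experiment) rather than
a single verdict, because the sign pattern itself is the scientific content.

## Relaxation protocol

`relaxation_half_life()` implements a step-perturbation protocol:
equilibrate at $C_\mathrm{env}$, step to $C_\mathrm{env}(1+\delta)$,
re-equilibrate, step back, and record for each compartment and for the whole
body the first time its concentration drops halfway back to baseline.
Choices that matter:

* $\delta = 0.10$ by default. "Slightly increased" needs a number; for a
  linear system the relaxation shape — hence the half-life — is exactly
  independent of $\delta$ (the tests bound the spread over
  $\delta \in \{0.05, 0.1, 0.2\}$ below 0.5%), so the choice is
  inconsequential in the first-order regime and mild in the saturable one.
* Both equilibrations use the exact linear solve under first-order kinetics,
  avoiding compounded integration error, and the decay is evaluated with the
  eigendecomposition propagator of $A$ on a log-spaced grid (half-lives span
  roughly $10^1$–$10^6$ s across compartments), with each crossing refined
  by root finding on the exact solution. For Michaelis kinetics the package
  falls back to stiff integration (deSolve `lsoda`, rtol $10^{-8}$, atol
  $10^{-12}$) and monotone interpolation in log-time.
* Crossings not reached by the time cap ($10^8$ s by default) are reported
  as censored, never silently truncated.
* Steady-state detection by integration (needed only for saturable
  kinetics) replaces eyeballing with an explicit criterion: the maximum
  relative change of every compartment over a sliding one-hour window must
  fall below $10^{-8}$.

## Population variability

`sample_physiology()` draws compartment volumes, tissue flows, cardiac
output, respiratory flow and body mass independently from log-normal
distributions whose *arithmetic* mean equals the base value
($\mu_{\log} = \ln(\mathrm{base}) - \sigma^2/2$, $\sigma = \ln(\mathrm{gsd})$;
geometric centring is available since either reading of "mean equal to the
base values" is defensible). The default geometric standard deviation is
$\sqrt 2$ ($\sigma_{\log_2} = 1/2$): draws rarely stray beyond two-fold,
which keeps the ensemble spread of steady-state concentrations modest
(coefficient of variation well below 1) — a deliberate small-variation
regime; it is configurable. After sampling, tissue flows are rescaled so
they sum exactly to the drawn cardiac output, keeping every draw a valid
physiology. Chemical parameters never vary. Sampling is seeded and
reproducible, and does not disturb the caller's RNG stream.

## Synthetic assay tables

`generate_chemical_table()` emulates the *structure* of a high-throughput
estrogenic-activity dataset matched to whole-organism effect thresholds: by
default 36 chemicals, AC10s log-uniform over $10^{-3}$–$10\ \mu$M,
$\log K_\mathrm{ow}$ uniform over 0.5–6, clearances log-uniform over
$10^{-6}$–$10^{-3}\,\mathrm{s}^{-1}$, and LOECs tied to the AC10s through
$\mathrm{LOEC} = \mathrm{AC10}\cdot 10^\eta$ with
$\eta \sim \mathcal N(1, 1)$ — loosely correlated, typically an order of
magnitude higher, scattered over about two more. These are synthetic
stand-ins: passing tests demonstrate that the pipeline's statistics behave
correctly on data of this shape, not that any real chemical's exposure is
predicted accurately. Real assay tables can be supplied as CSV with the same
columns.

## IVIVE statistics

The comparison layer maps each chemical's AC10 to a PEC per model (treating
the AC10 as a whole-body or gonad steady-state concentration), then:

* counts under-predictions against the matched LOECs and tests the count
  with the *exact* two-sided binomial test at null probability 1/2
  (`stats::binom.test`; an independent integer tail-enumeration oracle in
  the test suite confirms every count at $n = 36$). Ties count as not-below
  and are reported.
* compares models' log10 PEC/LOEC ratios pairwise with Welch's t-test by
  default — the unequal-variance-robust choice; the classic pooled test is a
  flag away — and returns Gaussian kernel density estimates with the
  Silverman-type default bandwidth.
* the tangent-based point of departure: expanding a logistic
  concentration–response curve about its inflection on the semi-log scale
  and intersecting that tangent with the lower asymptote lands two log-units
  below the inflection, where the response is exactly $1/(1+e^2) \approx
  11.9\%$ — the rationale for treating an AC10-like concentration as an
  approximate 12%-response point of departure.

The prediction-ratio grids evaluate $\log_{10}(\mathrm{PEC}_A/
\mathrm{PEC}_B)$ for a shared whole-body concentration over a default
$50\times50$ grid of $\log_{10} k_\mathrm{met} \in [-7, -1]$ and
$\log_{10} K_\mathrm{ow} \in [0, 8]$ (configurable; the biologically
plausible clearance range is the lower half of that axis). Linearity makes
the grid independent of the chosen body concentration, which is asserted at
run time. One regime note: because the 1C model applies clearance to its
entire partitioned body volume, its response coefficient falls like
$1/k_\mathrm{met}$ once $k_\mathrm{met} V P \gg Q_w$, so at the extreme
high-clearance edge of the default grid the 1C denominator — not
architecture — dominates the ratios; clearance-insensitivity of the ratios
at low $K_\mathrm{ow}$ holds in the slow-clearance regime
($k_\mathrm{met} \lesssim 10^{-5}\,\mathrm{s}^{-1}$), and the grid's
low-$K_\mathrm{ow}$ column always varies far less than its
high-$K_\mathrm{ow}$ column.

## Problem sizes and runtime

The test suite and the acceptance script are sized for a single CPU:
population protocols use 1000 draws for the 1C model and 100 draws for the
multicompartment models (the linear propagator makes each draw a few
milliseconds), round-trip and variant properties use 100–210 random
parameter/chemical draws, and the ratio grids are $50\times50$. All
quantities stabilize well below these sizes; the sizes are chosen for
statistical comfort, and every seed is explicit.

## Known limitations

* Constant (piecewise-constant) exposure only; no dietary or dermal routes,
  no temperature or growth scaling, no mixtures.
* The rTK inversion is first-order only; saturable kinetics is simulated
  forward but not inverted.
* Parameter values are assumed defaults, not calibrated to any measured
  fish; conclusions supported by the package are *relative* (architecture
  effects), not absolute exposure predictions.
* Collapse invariance is exact only under hepatic-only clearance (above).
* Population draws are independent across parameters; no correlation
  structure, and no global sensitivity indices — the sensitivity module is
  one-at-a-time by design.
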