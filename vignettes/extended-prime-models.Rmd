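---
title: "Models behind edisim: vaccine dosing kinetics and the germinal center response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models behind edisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edisim)
```

# Why model dosing regimens?

Splitting a fixed vaccine dose over time — rather than injecting it all
at once — can dramatically amplify humoral immune responses. Two
regimens of particular interest are the seven-dose exponentially
escalating series given every other day over 12 days ("7-ED"), and the
far more practical two-dose extended prime ("2-ED"): 20% of the dose at
day 0 and the remaining 80% at day 7. `edisim` implements two
complementary models that together explain why these schedules work and
let users explore new ones in silico:

1. a **deterministic kinetic model of T-cell priming** — adjuvant- and
   antigen-driven dendritic cell (DC) recruitment, activation and
   antigen loading in the draining lymph node, leading to T follicular
   helper (Tfh) cell expansion; and
2. a **stochastic germinal center (GC) model** — agent-based B-cell
   competition for antigen held on follicular dendritic cells (FDCs),
   coupled to deterministic antigen degradation/capture kinetics and
   antibody production.

Both take a `regimen` object (module `regimens`) as input, so any
schedule — bolus, n-dose escalating, two-dose splits, zero-order
extended release — can be pushed through either model.

# Dosing regimens

A regimen is an ordered set of dose events, each an impulse or a
constant-rate release window, carrying a fraction of the total dose and
tagged with the component it delivers (antigen, adjuvant, or both).
Within each component the fractions sum to 1, so different schedules
always deliver the same total dose — the central experimental control.

The escalating series uses amounts proportional to $e^k$ for injection
index $k = 0, \dots, n-1$. For $n = 7$ this puts
$e^6 / \sum_k e^k = 63\%$ of the dose into the final injection — the
defining feature of the schedule. With $n$ doses the series spans the
same 12-day window (interval $12/(n-1)$); the alternative fixed 2-day
spacing is also constructible via `make_exponential_ed(n, 2)`.

```{r regimen-example}
reg <- make_exponential_ed(7, 2)
round(reg$events$amount, 3)
```

# The priming model

State variables: adjuvant and antigen at the injection site/lymph node
(dose fractions), an activated innate-cell proxy (which absorbs the
cytokine/chemokine intermediary), total DCs, activated antigen-loaded
DCs (aDC-Ag+), antigen-specific T cells, and Tfh cells. The equations:

$$
\begin{aligned}
\dot A_{dj} &= u_{adj}(t) - \delta_{adj} A_{dj}, \qquad
\dot A_g = u_{ag}(t) - \delta_{ag} A_g \\
\dot I &= k_{innate} A_{dj} - \delta_{innate} I \\
\dot D &= k_{dc} I - \delta_{dc}(D - D_0) \\
\dot D^* &= k_{up} \frac{A_{dj}}{A_{dj}+K_{adj}}
               \frac{A_g}{A_g+K_{ag}} D - \delta_{adc} D^* \\
\dot T &= \rho \frac{D^*}{D^*+K_T} T - \delta_T (T - T_0) \\
\dot F &= k_{tfh} T - \delta_{tfh} F
\end{aligned}
$$

Impulse doses are state jumps at event times (the integrator restarts
there); release events enter through $u(t)$. The product saturation in
the $D^*$ equation encodes that DC activation and antigen loading need
adjuvant *and* antigen simultaneously — the mechanistic core: a bolus
wastes most of its antigen because it decays before DCs have been
recruited, while escalating schedules deliver their largest doses into
a DC-rich, antigen-experienced lymph node. It also predicts that
mismatched schedules (bolus adjuvant with escalating antigen) prime
poorly: late antigen arrives after the adjuvant, and hence the DC
response, has waned.

Tfh differentiation is modelled as a constant per-cell rate that does
not drain the proliferating pool (the pool is interpreted as
phenotype-indexed, not conserved); a depleting variant is available via
`priming_params(tfh_depletes = TRUE)`.

## Parameters and defaults

Clearance half-lives for adjuvant and antigen at the site are about one
day; the innate proxy relaxes in hours-to-a-day; DCs live a few days.
The saturation constants ($K_{adj} = K_{ag} = 0.01$ dose units) make
even percent-scale doses immunologically visible, which is what lets
the small early injections of the escalating series contribute. T-cell
proliferation tops out at $\rho = 2.5$/day with half-saturation
$K_T = 3\times10^4$ aDC-Ag+, placing the response in the regime where
the *magnitude and duration* of the aDC-Ag+ wave both matter. These
order-of-magnitude choices were fixed once so that the canonical
qualitative behaviour holds — DC peak within ~1 day of a bolus, DC
return to baseline before the day-7 dose of the two-dose extended
prime, aDC-Ag+ maximum after the final escalating dose, and peak Tfh
ordered bolus < 2-ED < 7-ED — and are not adjusted thereafter. A known
caveat: with these dynamics the 7-ED Tfh wave peaks a few days after
day 14, so at exactly day 14 the model ranks 2-ED above 7-ED even
though the peak ordering is the reverse.

Two parameters are deliberately left to data: the DC recruitment rate
`k_dc` and the baseline antigen-specific T-cell count `T_baseline`.
`fit_priming_params()` fits them to per-animal day-14 Tfh counts across
regimens by least squares on log counts. Because the T/Tfh equations
are linear conditional on the aDC-Ag+ trajectory, the model's day-14
Tfh count is exactly proportional to `T_baseline`; the fit exploits
this by profiling `T_baseline` out in closed form and scanning/refining
the one remaining dimension (`log k_dc`). This avoids multi-start local
optimization entirely and makes non-convergence detectable as a
boundary solution.

# The germinal center model

## Antigen: native, non-native, soluble, FDC-bound

Antigen arrives in its native (intact) conformation and converts to a
non-native (partially degraded) form at
$k_{deg} = \ln 2 / 6.2\,\mathrm{h} \approx 2.68$/day — the measured
half-life of intact antigen in the lymph node. Both soluble forms are
cleared nonspecifically ($\delta_{sol} = 1$/day) and can be deposited
onto FDCs as immune complexes (ICs) by circulating antibody of the
matching specificity, at rate $k_{dep} \times$ titer. FDC-bound antigen
is protected from degradation (no $k_{deg}$ term) and decays only
slowly by consumption ($\delta_{ic}$). Within an agent step the titers
are constant, so the antigen system is linear; it is advanced with the
exact matrix exponential of the augmented system including cumulative
input/clearance/decay accumulators, which keeps the pools non-negative
and conserves the mass balance (input = pools + cleared + consumed) to
round-off at any step size.

## B cells, selection, and the help rule

Each of `n_gc = 20` GCs holds agents with an epitope target (native or
non-native), an affinity ($-\log_{10} K_d$, germline around 6.2–6.6,
capped at 10), a lineage id and a mutation count. Per step of
`dt = 0.04` day a cell captures antigen $c = q/(1+q)$ with

$$ q = \frac{\mathrm{IC}_{e}}{1 + n_{e}/n_{compete}}
       \cdot 10^{aff - a_{cap}}, $$

where $n_e$ is the number of GC cells already targeting epitope $e$:
clones of one specificity crowd each other's access to their own FDC
antigen. This intra-epitope competition is essential to the biology
the model exists to capture — a rare specificity with a well-stocked
antigen pool (native antigen arriving during an extended release) can
out-compete an established immunodominant response whose thousands of
cells are dividing a fixed antigen supply. T-cell help is then

$$ h = \min\!\left(1,\ \frac{c}{\lambda\,\bar c + K_{help}}\right), $$

a competitive share (partially normalized by the GC mean $\bar c$,
$\lambda = 0.3$) damped by a scarcity constant. The damping matters: a
pure ratio $c/\bar c$ would let the best cell of an antigen-starved GC
divide at the maximal rate, so bolus GCs would flourish on vanishing
FDC antigen. Together these give the regimes seen experimentally:
scarce antigen → strong affinity discrimination *and* small GCs;
abundant antigen → help near 1 for most cells, weakening the
immunodominance hierarchy so initially low-affinity (native-targeting)
cells are activated, proliferate, and mature. Cells divide with
probability $\beta_{max} h\,dt$, die at $\mu\,dt$, and exit to the
plasma compartment at $p_{exit}\,dt$; births beyond
`gc_capacity = 2000` are rejected. Daughters of selection-phase
divisions mutate: silent/lethal/affinity-changing with probabilities
0.5/0.3/0.2, the affinity change drawn as
$2\,(0.6 - \mathrm{lognormal}(0, 0.45))$ (mostly deleterious, a
modest beneficial tail), clamped to the affinity bounds.

Non-native immunodominance is encoded twice, as a higher precursor
frequency (0.7 vs 0.3) and a higher mean germline affinity (6.6 vs
6.2); both are plain parameters.

## Seeding and the founder burst

Naive cells enter each GC at `seed_rate` × a saturating function of
the total available antigen (soluble + FDC-bound) — GCs can therefore
form after a bolus even though almost nothing reaches the FDCs — but
each GC admits at most `n_founders = 200` founders. The budget
reflects GC biology (founder influx wanes once GCs are established)
and has two consequences the data demand: early GC size does not
simply scale with the size of the first injection, and late GC
composition is set by selection rather than by a perpetual trickle of
naive entrants. Each founder additionally performs
`burst_divisions = 4` programmed divisions — gated on antigen being
present at all, but independent of FDC capture — before its progeny
become selection-dependent, mirroring the clonal burst of activated B
cells. The burst is what makes day-7 GC sizes comparable between
bolus and split-dose priming (as observed experimentally) even though
the first injections differ five-fold in antigen.

## Antibody and the feedback loop

Exiting cells accumulate as plasma cells; concentrations follow
$\dot C_i = k_{ab} N_i - \delta_{ab} C_i$ and titers follow the same
kinetics with counts weighted by $10^{aff - a_{ref}}$ ($a_{ref} = 8$:
a clone at affinity 8 has weight 1). Early antibody therefore comes
from pre-GC exiting cells at germline-like affinity — weak, but enough
to begin IC deposition — and affinity maturation feeds back
exponentially into the capture rate. This loop is what converts dosing
kinetics into antigen geography: by day 7 of the two-dose extended
prime a modest titer exists, so the large second dose is efficiently
captured; during a 10-day extended release of the second dose most
antigen arrives *after* titers are high, is captured while still
native, and the day-21 native share of FDC-held antigen roughly
doubles (about 40% to about 87% under the shipped defaults, as
recomputed by `scripts/acceptance.R` and the test suite).

## Calibration and what the defaults mean

The parent-model details (selection functional forms, mutation
distribution, GC counts) are reconstructions; `n_gc = 20` ×
`gc_capacity = 2000` is a desk-scale stand-in for the lymph node's GC
ensemble. The free kinetic constants ($k_{dep}$, $k_{ab}$,
$\delta_{ab}$, $\delta_{ic}$, $\delta_{sol}$, $p_{exit}$, $\mu$,
$\beta_{max}$, $K_{help}$, $\lambda$, $n_{compete}$, $a_{cap}$,
founder and burst counts, germline means/frequencies,
mutation scale) were calibrated jointly in a single documented pass
against two intact-IC anchor values (day-21 native IC share near 38%
for the all-impulse two-dose prime, near 92% with the 10-day
slow-release second dose) together with the qualitative orderings
(day-21 FDC antigen and native GC fraction each bolus < 2-ED < 7-ED;
GC sizes similar at day 7 but diverged by day 14), then frozen; the
shipped defaults reproduce the anchors to within a few percentage
points (about 40% and 87%). All remain user-overridable through
`gc_params()`.

The day-21 evaluation point for the native IC share is the simulation
end; use `native_ic_fraction(out, day)` to sweep other days.

# The synthetic cohort generator

`gen_cohort()` emulates per-animal flow-cytometry readouts (default:
day-14 Tfh counts, n = 5 animals/group): model group mean × lognormal
noise with `meanlog = -sdlog^2/2`, so the noise is mean-unbiased and
its coefficient of variation equals `noise_cv` exactly. The default CV
of 0.5 reflects typical inter-animal spread of such counts. What the
generator does *not* emulate: gating error, detection floors, batch
effects, or any correlation structure between readouts — so passing
recovery tests demonstrates the fitting machinery, not robustness to
real-world measurement pathology.

# Numerical choices

* Priming ODEs: `deSolve::lsoda`, rtol 1e-8/atol 1e-10, impulses as
  additive events; halving tolerances moves outputs well below 0.1%.
* GC agent step `dt = 0.04` day keeps every per-step probability below
  0.15 (the scheme requires < 0.3) while the antigen/antibody layer is
  advanced exactly, so the agent clock is the only discretization.
* Stochastic replicates: 10 per lymph node by default (replicate means
  are reported); per-replicate seeds derive deterministically from the
  user seed, so identical seeds give identical outputs bit-for-bit.
* Problem sizes in the shipped tests and the acceptance script (10
  replicates, 21-day horizons, 20-repeat recovery studies at 5
  animals/group) were chosen as the smallest sizes at which the
  replicate-mean metrics are stable to a few percent.

# Known limitations

* The priming model has no spatial structure, no DC subsets, and no
  TCR repertoire; cell-count scales are per-lymph-node
  order-of-magnitude conventions, and `k_dc`/`T_baseline` absorb the
  units when fitted.
* The GC model does not cover memory recall, epitope masking by serum
  antibody, extrafollicular plasmablast surges, or sequence-level
  receptor evolution.
* The two models are run independently (the GC model's Tfh help
  capacity is constant); coupling priming-model Tfh output into the GC
  birth budget is a natural extension but is deliberately off by
  default because the two models address separate questions.
* All "non-native" antigen is a single pooled species; real degradation
  produces a spectrum of fragments with heterogeneous immunogenicity.
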