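# edisim

Simulation tools for comparing vaccine dosing regimens — bolus,
multi-dose exponentially escalating ("escalating-dose immunization",
EDI), two-dose extended prime, and extended-release variants — through
two coupled questions:

1. **T-cell priming.** How do the kinetics of adjuvant and antigen
   arrival shape dendritic cell (DC) recruitment, DC activation and
   antigen loading, and ultimately T follicular helper (Tfh) cell
   expansion in the draining lymph node?
2. **Germinal center (GC) output.** How much antigen ends up displayed
   on follicular dendritic cells (FDCs) as immune complexes, in intact
   (native) versus degraded (non-native) form, and how does that shift
   the GC response toward B cells that recognize the intact immunogen?

The package is aimed at vaccinologists and systems immunologists who
want to explore dosing schedules in silico before committing to animal
studies.

## The models in brief

**Priming model** (deterministic ODEs, `simulate_priming()`): adjuvant
and antigen clear at constant rates; adjuvant activates an innate
compartment that recruits DCs; DCs become activated and antigen-loaded
(aDC-Ag+) at a rate saturating in both adjuvant and antigen
(`u · [Adj/(Adj+K_adj)] · [Ag/(Ag+K_ag)] · DC`); aDC-Ag+ drive
saturating T-cell proliferation (`rho · aDC/(aDC+K_T)`), and T cells
differentiate into Tfh at a constant rate. Two parameters — the DC
recruitment rate and the baseline antigen-specific T-cell count — are
designed to be fitted to day-14 Tfh counts across regimens
(`fit_priming_params()`, log-scale least squares with the second
parameter profiled out in closed form).

**GC model** (stochastic agents over a deterministic antigen/antibody
layer, `simulate_gc()`): antigen arrives native and converts to a
non-native form with a 6.2-hour half-life; antibody deposits soluble
antigen of its own specificity onto FDCs, where it is protected from
degradation. Agent-based B cells in 20 GCs per lymph node target
either form, capture FDC antigen in proportion to affinity (with
clones of the same specificity crowding each other's access), compete
for birth signals, mutate, and export plasma cells whose
affinity-weighted output closes the antibody–capture feedback loop.

See the methods vignette (`vignettes/extended-prime-models.Rmd`) for
the full equations, parameter meanings, calibration notes and
limitations.

## Worked example

```r
library(edisim)

# the optimized two-dose extended prime: 20% day 0, 80% day 7
reg <- make_two_dose(0.2, 7)

# Tfh priming compared to bolus
p <- priming_params()
peak_bolus <- priming_peak(simulate_priming(p, make_bolus()), "tfh")
peak_2ed   <- priming_peak(simulate_priming(p, reg), "tfh")
round(c(bolus = peak_bolus, two_dose = peak_2ed))
#>    bolus two_dose
#>     7421    57429

# GC response with both doses as injections...
gp <- gc_params()
out_imp <- simulate_gc(gp, reg, t_end = 21, n_replicates = 10, seed = 1)
# ...and with the second dose released over 10 days
out_ext <- simulate_gc(gp, with_extended_release(reg, 2, 10),
                       t_end = 21, n_replicates = 10, seed = 2)
round(100 * c(impulse = native_ic_fraction(out_imp, 21),
              extended = native_ic_fraction(out_ext, 21)), 1)
#>  impulse extended
#>     40.3     87.2
```

The two Tfh peaks say that splitting the dose 20/80 a week apart
yields roughly an eight-fold larger peak Tfh response than a bolus
under the default parameters. The last two numbers are the day-21
percentage of FDC-held immune-complexed antigen that is still in its
native conformation: with two bolus injections most of the large
second dose degrades before antibody can capture it (~40% native),
whereas releasing the second dose over 10 days lets antigen arrive
after affinity-matured antibody titers have risen, so the FDC display
becomes predominantly native (~87%) — the rationale for
extended-release second doses.

Regimens can also be named on the command line through the thin
wrapper in `inst/scripts/edisim.R`:

```sh
Rscript inst/scripts/edisim.R gc --regimen 2ed-ext:10 --reps 10 --seed 42 --out out/
Rscript inst/scripts/edisim.R experiment --name release_sweep --out out/
```

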