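# isctsim

**In-silico clinical trials for closed-loop drug-infusion devices.**

`isctsim` is for engineers and scientists evaluating *physiological
closed-loop controllers* — infusion pumps that adjust drug delivery from
sensed physiology — before the sensor or device exists in hardware. It
simulates the whole trial: a virtual patient cohort drawn from a population
pharmacokinetic (PK) model, a noisy/periodic/delayed plasma-concentration
sensor, an actuator with device limits and alarms, and two competing control
strategies, compared on cohort-level concentration–time statistics. The
package is instantiated for intravenous anesthetic (propofol) delivery.

## The models at the core

*Disposition* is the linear three-compartment mammillary model with a
massless effect-site compartment:

    dA1/dt = A2·k21 + A3·k31 − A1·(k10 + k12 + k13) + U(t)
    dA2/dt = A1·k12 − A2·k21
    dA3/dt = A1·k13 − A3·k31
    dC4/dt = (C1 − C4)·ke0,          C1 = A1/V1

with `k10 = CL/V1`, `k12 = Q2/V1`, `k21 = Q2/V2`, `k13 = Q3/V1`,
`k31 = Q3/V3`, `k41 = ke0`, `k14 = ke0/10⁴`.

*Between-subject variability* is log-normal per parameter,
`PARᵏⱼ = PARᵏ·exp(ηᵏⱼ)`, `ηᵏⱼ ~ N(0, ωₖ²)`; *measurement error* is the
combined model `Y = C + sqrt(prop²·C² + add²)·ε`, `ε ~ N(0,1)`.

*Open-loop TCI* computes a reach-and-hold schedule from the population model
(full-rate loading, a trimmed pulse so the predicted effect-site peak
touches the target exactly, then maintenance). The *closed-loop controller*
personalizes the same planner: it MAP-estimates each subject's η from the
delayed noisy measurements (penalized weighted least squares under the
log-normal prior, quasi-Newton with warm starts) and replans rates against
the individualized model. Trials are summarized by median profiles, 95%
prediction intervals (PI95) and the band area around the target.

## Worked example

The shipped scenario (`inst/extdata/propofol_reference.yaml`) is a cohort of
demographically identical adults (36 y, 70 kg, 170 cm, female) with
representative published propofol population values, an effect-site target
of 6 mg/L, a sensor sampling every 30 s with a 15 s delay, and a
200 mg/min pump ceiling. Here scaled to 50 subjects:

```r
library(isctsim)
cfg <- load_config(system.file("extdata", "propofol_reference.yaml",
                               package = "isctsim"))
cfg$n <- 50L                              # scaled-down cohort for the example
res <- run_trial(cfg)

open   <- accuracy_metrics(res$arms$open_loop,   cfg$tci$target,
                           reference = res$reference)
closed <- accuracy_metrics(res$arms$closed_loop, cfg$tci$target,
                           reference = res$reference)

round(c(open = open$band_area, closed = closed$band_area), 1)
#>   open closed
#>   46.2   21.0
round(c(open = open$within_10pct_fraction,
        closed = closed$within_10pct_fraction), 2)
#>   open closed
#>   0.14   0.34
round(open$max_rel_deviation, 2)
#> [1] 0.95
```

The PI95 band area over the equilibrated half of the trial shrinks from
46.2 to 21.0 mg/L·min when the loop is closed: personalization cuts the
cohort's spread around the 6 mg/L setpoint by more than half, and the
fraction of subjects held within ±10% of target throughout the window
rises from 14% to 34%. Under the open-loop schedule individual plasma
concentrations deviate from the population prediction by up to 95% even in
this 50-subject cohort (≥100% at the full 1,000-subject scenario). The
effect-site summary of the closed-loop arm:

```r
s <- summarize_ct_profiles(res$arms$closed_loop, "C4")
round(s[s$time %in% c(1, 5, 10, 15), ], 2)
#>     time lo95 median hi95
#> 11     1 0.52   1.65 3.97
#> 51     5 5.37   6.18 8.27
#> 101   10 4.83   5.83 7.35
#> 151   15 3.00   5.56 6.25
```

A command-line surface wraps the same functions
(`inst/scripts/isctsim`): `simulate`, `tci`, `generate-cohort`, `run-trial`
and `summarize` subcommands emit CSV trajectories, summaries, event logs,
a JSON metrics report and a checksummed run manifest.

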