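# impactcurves

Simulation models of how the ecological impact of an invasive
suspension-feeding bivalve (*Dreissena*, the zebra and quagga mussels)
depends jointly on its **abundance** and on the **ecosystem it invades** —
so that one species carries multiple, non-interchangeable abundance–impact
curves rather than a single one. The package is aimed at invasion ecologists
and managers who fit or use density–impact functions, and at anyone studying
how space-for-time (horizontal) sampling designs distort such curves.

## The models

**Shell accumulation (cumulative impact).** Spent shell ("shell hash") on
the sediments follows first-order loss under production forcing,

```
dS/dt = P(t) − k S,
```

with standing stock `S` (kg/m²), shell production `P` (kg/m²·yr) and
instantaneous dissolution rate `k` (/yr). At equilibrium `S* = P/k`, so the
within-ecosystem abundance–impact curve is linear through the origin with
slope `1/k`; the time to reach a fraction `f` of equilibrium is
`−ln(1 − f)/k`. Three canonical ecosystems (`k` = 0.05, 0.3 and 2 /yr) span
the waters where dense dreissenid populations occur. Piecewise-constant
forcing is advanced with the exact exponential update per interval, so
trajectories carry no truncation error.

**Macrophyte habitat (instantaneous impact).** Population filtration rate
`DFR` (% of the water column/day) is chained through

```
chl_post = 0.2 chl_pre + 0.8 chl_pre e^(−0.0347 DFR)
log10(Secchi) = −0.473 log10(chl) + 0.803
η = 1.7 / Secchi,   z* = −ln(0.05)/η,
```

and a lake's hypsographic curve converts the colonization depth `z*` (the
5 %-light depth) into the fraction of lake bottom available to submersed
macrophytes. Six canonical lakes (shallow 5 m, deep 50 m, shelf 15 m basins
× pre-invasion chlorophyll 3 or 30 µg/L) produce qualitatively different
curves — including a lake where the invader has no effect at any density,
and a shelf lake with a steep nonlinear response.

**Sampling designs.** `within_system_curve()`, `snapshot_sample()` and
`long_term_sample()` build the three curve formulations on synthetic
landscapes of lakes (seeded lognormal AR(1) abundance trajectories with
order-of-magnitude interannual variation); `fit_linear()`,
`per_capita_effects()` and `compare_designs()` quantify how pooled
cross-system fits diverge from the within-system truth, including
constructed sign reversals and Jensen (nonlinear-averaging) gaps.

## Worked example

```r
library(impactcurves)

river <- shell_params(2, "moderately hardwater river")
lake  <- shell_params(0.05, "hardwater lake")
equilibrium_stock(1, river)            # 0.5  kg/m2 at P = 1 kg/m2/yr
equilibrium_stock(1, lake)             # 20   kg/m2: same invader, 40x impact
round(time_to_fraction(river, 0.95), 2)  # 1.5  yr to 95% of equilibrium
round(time_to_fraction(lake, 0.95), 1)   # 59.9 yr

series <- generate_trajectory(hudson_trajectory(n_years = 150, seed = 1))
production_stock_coupling(series, river)
#> Production-stock coupling (k = 2): Pearson r = 0.992 over 140 years (burn-in 10 yr)
production_stock_coupling(series, lake)
#> Production-stock coupling (k = 0.05): Pearson r = 0.403 over 50 years (burn-in 100 yr)
```

The fast-dissolving river tracks its population almost perfectly (r =
0.992): a yearly snapshot recovers the abundance–impact curve. The
hardwater lake integrates decades of history, so current impact is nearly
decoupled from current abundance (r = 0.403).

```r
preset <- design_presets()[["equal-even"]]
compare_designs(preset$landscape, seed = 1, abundances = preset$abundances)
#> Sampling-design comparison
#>   within-system slopes: high-slope = 3, moderate-slope = 1, low-slope = 0.2
#>   pooled snapshot slope:  1.4 (r^2 = 0.232)
#>   pooled long-term slope: 0.7559 (r^2 = 0.015)
```

Every lake in this landscape has a clean linear response, yet the pooled
cross-system regressions (slopes 1.4 and 0.76, low r²) match none of the
three true slopes — the central caution about horizontal designs.

A thin command-line wrapper ships in `inst/cli/impactcurves.R`:

```sh
Rscript inst/cli/impactcurves.R macrophyte --preset shelf-productive --out runs/shelf
```

writes the habitat-gain table plus a `manifest.json` that records every
parameter and seed needed to re-run the stage exactly.

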