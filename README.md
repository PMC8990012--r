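# lpsim — agent-based lost-person movement on terrain grids

Wilderness search and rescue (SAR) planning hinges on predicting where a
lost person (LP) is likely to be, starting from the initial planning point
(IPP) — the last place they were known to be. `lpsim` implements a
discrete-time agent-based model of LP movement for this problem, aimed at
SAR researchers and modelers: an agent walks on a layered terrain grid
(elevation, linear features such as trails and shorelines, inaccessible
water interiors) and at every time step draws one of six reorientation
strategies from its *behavioral profile* — random walking (RW), route
traveling (RT), direction traveling (DT), staying put (SP), view enhancing
(VE), backtracking (BT). The profile is a PMF **p** over
`[RW, RT, DT, SP, VE, BT]`.

Motion uses one step of velocity memory: with smoothing factor α (default
0.55), the strategy's provisional cell x̂(t+1) updates the position as

    x(t+1) = (2 − α) x(t) + (α − 1) x(t−1) + α v(t),    v(t) = x̂(t+1) − x(t)

and the agent stays put whenever the rounded target is inaccessible.
Profiles are fitted to incident endpoints with the two-sample **energy
statistic**: for each candidate profile, the closest points x₁…xₙ of n
Monte Carlo replicate trajectories to the find location y are scored by

    E(X, Y) = 2A − B − C,   A = (1/nm) Σᵢⱼ‖xᵢ − yⱼ‖,  B = (1/n²) Σᵢⱼ‖xᵢ − xⱼ‖,

with C ≡ 0 for a single find (m = 1). The lowest-energy profile wins per
incident; incidents combine through weights wᵢ = (dᵢ/Eᵢ)^L (L = ½, dᵢ the
IPP-to-find distance) into the normalized weighted average profile, which
is then evaluated by leave-one-out cross-validation (LOOCV) and an
effective-speed regression diagnostic. A synthetic terrain and incident
generator supports end-to-end parameter-recovery testing. See the methods
vignette (`vignettes/lost-person-model.Rmd`) for the full model account.

## Worked example

Build a synthetic 2 km map, generate an incident from a known
route/direction-traveling truth, and fit a profile lattice to it:

```r
library(lpsim)

map <- generate_synthetic_map(synthetic_map_config(seed = 11))
map
#> <grid_map> 300 x 300 cells, 6.67 m/cell (2.0 x 2.0 km)
#>   elevation: 301.3..407.2 m | feature cells: 2115 | inaccessible: 360

truth <- behavior_pmf(c(0, 1/3, 2/3, 0, 0, 0))     # 1/3 RT, 2/3 DT
cfg   <- sim_config(hours = 2, steps_per_hour = 850, replicates = 50,
                    seed = 101)
excl  <- exclusion_config(min_distance_m = 200, boundary_margin_cells = 10)
inc   <- generate_synthetic_incident(map, truth, mobile_hours = 0.5, cfg,
                                     seed = 501, exclusion = excl)$incident

fit <- best_lpt_for_incident(inc, enumerate_lpts(6, 1/3), map, cfg)
fit
#> <lp_fit> incident syn-1: E = 303.9 m, d = 507.7 m, w = 1.292
#> <behavior_pmf>  RW=0.333 RT=0.000 DT=0.667 SP=0.000 VE=0.000 BT=0.000
```

The fitted profile for this single incident is DT-dominant, as the truth
is: the replicate closest points of the 2/3-DT candidate spread around the
find location with energy 303.9 m over a 507.7 m IPP-to-find distance,
giving weight (507.7/303.9)^½ ≈ 1.29. The full 15-incident recovery study
(fit + LOOCV over the 56-profile step-1/3 lattice) runs in under a minute:

```r
study <- synthetic_recovery_study()
study$fit_report$average_profile
#> <behavior_pmf>  RW=0.263 RT=0.309 DT=0.320 SP=0.054 VE=0.054 BT=0.000
```

The two largest components of the averaged profile, DT and RT, are exactly
the strategies present in the generating truth; the vignette discusses why
the RT/RW split is the hardest part of the recovery (away from a linear
feature, route traveling *is* a random walk).

A thin command-line front end over the same pipeline lives at
`inst/scripts/lpsim` (`lpsim fit|loocv --config run.json`).

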