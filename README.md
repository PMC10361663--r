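# spindleflux

Quantitative kinetics of fluorescent reporters on the metaphase spindle,
for cell biologists analysing FRAP (fluorescence recovery after
photobleaching) and photoactivation time-lapse experiments on
spindle-bound proteins such as HURP — and for anyone who needs a
ground-truthed stochastic simulator of such experiments to validate an
analysis pipeline end to end.

## What it computes

**FRAP.** After half-spindle photobleaching, each region of interest
(whole spindle, bleached/unbleached half, and six axial zones —
pole / intermediate / chromosome per half) is background-subtracted and
double-normalized against the whole spindle,

```
I_norm(t) = [I_ref(t_pre) / I_ref(t)] * [I_roi(t) / I_roi(t_pre)]
```

so acquisition fade cancels and the pre-bleach value is 1. Bleached ROIs
are then full-scale normalized,

```
I_fs(t) = [I_norm(t) - I_norm(t0)] / [1 - I_norm(t0)]
```

(0 at the first post-bleach frame t0, 1 at the pre-bleach level), and
fitted with a one-phase association `y = P (1 - e^{-k (t - t0)})`;
unbleached ROIs are fitted with a one-phase decay
`y = P + A e^{-k (t - t0)}`. Half-lives are `t1/2 = ln 2 / k`.

**Photoactivation.** A 2-µm stripe of photoactivated reporter is tracked
by fitting a Gaussian to each frame's pole-to-pole intensity profile. The
centre trajectory µ(t) is fitted with a second-order polynomial giving
the initial velocity `u0` and acceleration `a`, and the velocity is
extrapolated with the constant-acceleration equations of motion

```
x = x0 + u0 t + a t^2 / 2        u_c = u0 + a t
```

to the moment the pulse centre would cross a reference landmark (the
chromosome edge, located from the gap of microtubule staining, or the
pole) at distance `x0`, yielding the reference-point velocity `u_c` that
is comparable across cells.

**Statistics.** Two-tailed Mann-Whitney comparisons (exact for small
tie-free samples), Spearman rank correlation, and spindle-size-normalized
profile averaging with 95% confidence bands.

**Simulator.** `simulate_spindle()` renders two-channel stacks from a
stochastic transport model — diffusing unbound molecules, binding with a
chromosome-proximal on-rate boost (a Ran-GTP-gradient stand-in),
unbinding, poleward lattice flux, optional poleward/equatorward motor
states, commanded bleach/activation events, Poisson + read noise — and
returns the ground truth (e.g. expected recovery half-life `ln 2 /
k_off`) so every stage of the pipeline can be checked against known
kinetics.

## Worked example

Simulate a half-spindle FRAP experiment with a known off-rate
(`k_off = 0.0277 /s`, so the true recovery half-life is 25 s), then run
the full analysis:

```r
library(spindleflux)

bleach <- photo_event("bleach", frame_index = 3, region = "half",
                      side = "left", efficiency = 0.9)
cfg <- simulation_config(n_molecules = 20000, k_off = 0.0277,
                         photo_events = list(bleach), rng_seed = 42)
sim <- simulate_spindle(cfg)
sim$stack
#> <spindle_stack> 25 frames x 2 channels, 91 x 141 px (0.1 um/px)
#>   time 0 .. 120 s; channels: reporter=1, reference=2
sim$truth$expected_recovery_halflife
#> [1] 25.02336

fits <- frap_experiment(sim$stack, bleach)
dplyr::select(fits, roi, kind, k_per_s, halflife_s, r_squared)
#> # A tibble: 8 × 5
#>   roi                     kind        k_per_s halflife_s r_squared
#>   <chr>                   <chr>         <dbl>      <dbl>     <dbl>
#> 1 bleached_half           association  0.0267       25.9     0.996
#> 2 bleached_pole           association  0.0239       29.0     0.994
#> 3 bleached_intermediate   association  0.0267       25.9     0.993
#> 4 bleached_chromosome     association  0.0294       23.6     0.992
#> 5 unbleached_half         decay        0.0245       28.3     0.998
#> 6 unbleached_pole         decay        0.0236       29.3     0.999
#> 7 unbleached_intermediate decay        0.0272       25.5     0.990
#> 8 unbleached_chromosome   decay        0.0230       30.2     0.996
```

The bleached-half association fit recovers the configured 25-s half-life
within a few percent (25.9 s here), the unbleached half shows the
mirror-image decay of the same exchange process, and per-zone rows expose
the axial kinetics. `autoplot()` on a fit, `plot_recovery_curves()`, and
`plot_center_track()` draw the standard figures; `tidy()`/`glance()`
return fit tables.

The photoactivation side works the same way: simulate a stripe
activation with a configured poleward flux, then
`pa_experiment(stack, event, landmark = "chrom_edge")` returns `x0`,
`u0`, `a`, the crossing time `t*`, and the reference-point velocity
`u_c` for that cell.

A thin command-line wrapper ships in `inst/exec/spindletools`
(`simulate`, `frap`, `pa`, `report` subcommands) for scripted use; all
outputs are tidy CSV.

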