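# chainmig

Agent-based simulation of collective neuroblast migration through a field
of deformable astrocyte obstacles, with an evaluation layer that measures
when moving in a collective is faster than moving alone.

## The problem

Adult-born neuroblasts travel long distances through brain tissue densely
packed with astrocytes. They migrate *saltatorily* — extend a leading
process, then translocate the soma — and *collectively*, in adherent
chain-like clusters, while shrinking nearby astrocyte processes through
Slit–Robo signalling. Tracking individual cells inside a chain for days
is infeasible in tissue, so this package provides the in-silico
counterpart: a minimal mechanical model whose long-term migration
efficiency can be measured exactly, swept over conditions, and analysed
statistically.

`chainmig` is aimed at computational cell-biology users who want to
re-run, perturb or extend the model: every model constant, schedule and
condition flag is a config value, every trial is seeded and
bit-reproducible, and all outputs are tidy tables.

## The model in brief

A neuroblast is a dumbbell of two circles (soma, radius 5 µm; tip, 3 µm)
joined by a spring-like process. Overdamped dynamics with an oscillating
spring target and an anchoring friction switch produce saltatory
locomotion:

- target length: ℓ̄(t) = L + A_sal(t)·sin(ω_sal·t + φ_i), with L = 40 µm,
  a 20-min cycle, and amplitude A_sal either constant (10 µm), slowly
  periodic, or randomly redrawn (inconstant behaviour);
- friction: (μ_S, μ_T) = (μ_high, μ_low) while ℓ̄ grows (process
  extension, soma anchored) and (μ_low, μ_high) while it shrinks (somal
  translocation, tip anchored).

An astrocyte is three overlapping circular units that passively move
under contact forces and shrink when neuroblasts are near: unit radius
relaxes (time constant τ) toward max(r_max − ρ_A·B, r_min), where B
counts neuroblasts within d_slit = 15 µm of the unit surface. Contacts
between circles combine overlap-proportional repulsion (k_R·δ) with
constant-magnitude adhesion H per pair type (H_N = 2.22 nN between
neuroblasts); a circle touching a process is repelled with the reaction
split between soma and tip by lever arms.

Migration efficiency: forward speed v_i(t) = ê_ST·Δx_S/60 min (soma
displacement projected on the cell axis) is regressed on collectivity
n_i(t) (other neuroblasts within 20 µm of the surface), pooled over all
trials of a condition:

v ~ α·n + β

A positive slope α means collectives outpace solitary cells.

## Worked example

```r
library(chainmig)

cfg <- run_config(n_astrocytes = 40, duration = 3000, n_trials = 3,
                  base_seed = 100)
traj <- run_condition(cfg)
samples <- collect_samples(traj, window = c(900, 3000))
fit <- fit_speed_collectivity(samples)
print(fit)
#> Forward speed ~ collectivity (pooled OLS)
#>   slope alpha:       0.0035 um/min per neighbour (SE 0.0022)
#>   intercept beta:    0.0326 um/min (SE 0.0032)
#>   n samples:       2592
```

Among 40 reactive-shrinking astrocytes, solitary cells strand against
obstacles (intercept β ≈ 0.03 µm/min, far below the ~0.8 µm/min free
speed) and cells with more neighbours move faster (positive α):
collectives shrink astrocytes cooperatively and open routes. The same
call with `n_astrocytes = 0` gives a negative slope — in an empty field a
collective only gets in its own way. `autoplot(fit)` draws the binned
means with 95% intervals and the regression line; `tidy(fit)` and
`glance(fit)` return the coefficients as tibbles.

Condition sweeps (astrocyte density, reactive vs mismatched shrinkage,
constant/periodic/random amplitude or adhesion schedules, adhesion
strength, morphology variants):

```r
grid <- condition_grid(n_astrocytes = c(0, 40),
                       amplitude_schedule = c("constant", "periodic"),
                       duration = 3000, n_trials = 3, base_seed = 100)
res <- run_sweep(grid)
sweep_table(res)
plot_slope_grid(res)
```

A thin command-line wrapper with `run`, `sweep`, `evaluate`, `summarize`
and `fixture` subcommands is installed at `inst/cli/sim.R`; configs are
YAML (`read_run_config()` / `write_run_config()`) and every run can
write a JSON manifest of all switches and seeds (`write_manifest()`).

## Package layout

- `R/geometry.R` — periodic field, minimal image, circle/segment contacts
- `R/schedule.R`, `R/astrocyte.R`, `R/forces.R` — model laws (R reference)
- `src/engine.cpp` — compiled all-pairs force assembly + Euler integrator
- `R/simulate.R` — initialization, seeded trials, condition sweeps
- `R/evaluate.R` — forward speed, collectivity, pooled OLS, binned means
- `R/io.R`, `inst/cli/sim.R` — configs, manifests, CSV tables, CLI
- `vignettes/neuroblast-migration-model.Rmd` — model description, design
  decisions, limitations
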