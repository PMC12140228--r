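---
title: "An agent-based model of neuroblast chain migration among astrocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of neuroblast chain migration among astrocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(chainmig)
```

## The biological question

Adult-born neuroblasts migrate long distances through brain tissue packed
with astrocytes, and they do so collectively, in chain-like clusters held
together by transient adhesion. Two observations motivate this model:
neuroblasts shrink nearby astrocyte processes through Slit–Robo
signalling, clearing their own path, and their motile behaviour is not
constant over time. `chainmig` implements a deliberately minimal physical
model of this system so that long-term migration efficiency can be
measured under controlled, repeatable conditions: how fast does a cell
move forward, and does having neighbours help or hurt?

## The model

### Neuroblasts

A neuroblast is a dumbbell: a soma circle (radius $r_S = 5\,\mu m$) and a
tip circle ($r_T = 3\,\mu m$) joined by a rectangular process of
half-width $w = 2\,\mu m$. The two circle centres $x_S, x_T$ obey
overdamped dynamics (inertia is irrelevant at cell scale):

$$\mu_S(t)\,\dot x_S = k_P\big(|x_S - x_T| - \bar\ell(t)\big)\,\hat e_{ST} + F_S,
\qquad
\mu_T(t)\,\dot x_T = -k_P\big(|x_S - x_T| - \bar\ell(t)\big)\,\hat e_{ST} + F_T,$$

where $\hat e_{ST}$ is the unit vector from soma to tip and $F_{S,T}$
collect contact interactions. Saltatory locomotion is produced by an
oscillating spring target,

$$\bar\ell(t) = L + A_{sal}(t)\,\sin(\omega_{sal} t + \phi_i),$$

with $L = 40\,\mu m$, a 20-min cycle ($\omega_{sal} = 2\pi/20$ rad/min)
and per-cell phases $\phi_i$ drawn uniformly on $[0, 2\pi)$, combined
with an anchoring switch: while the target length grows (the *resting*
phase) the soma has high friction $\mu_{high}$ and the tip low friction
$\mu_{low}$, and vice versa while it shrinks (the *moving* phase). A
derivative of exactly zero counts as resting; this tie-break also covers
the degenerate amplitude-free schedule. For a stiff spring the
displacement per cycle has the closed form

$$\Delta = 2 A_{sal}\,\frac{\mu_{high} - \mu_{low}}{\mu_{high} + \mu_{low}},$$

which the test suite verifies against the full integrator to within 5%.
An isolated cell never rotates or backs up; turning arises only from
contact.

The amplitude $A_{sal}(t)$ follows one of three schedules:

* **constant** — $A_{sal} = A_{mid} = 10\,\mu m$;
* **periodic** — $A_{sal}(t) = A_{mid} + A_{act}\sin(\omega_{act}t + \phi_{act})$
  with $A_{act} = 5\,\mu m$, $\omega_{act} = \omega_{sal}/36$ (a 12-h
  activity cycle) and $\phi_{act} = 3\pi/2$ so the activity starts at its
  minimum;
* **random** — redrawn from $\mathcal N(A_{mid}, \sigma_A)$ with
  $\sigma_A = 5\,\mu m$, clamped into $[0, 20]\,\mu m$, every $u = 3$
  saltation cycles.

All three have the same mean target length $L$ — exactly for constant and
periodic (over whole cycles), and in expectation for random, because
clamping a distribution symmetric about the midpoint of the interval
preserves its mean. Random redraws are applied when the saltation phase
argument crosses a multiple of $2\pi u$, i.e. at the start of a resting
phase where $\sin(\cdot) = 0$, so the target length is continuous across
a redraw and the spring never teleports. Clamping (rather than
resampling) was chosen because it is deterministic given the draw; both
preserve the mean.

### Astrocytes

An astrocyte is three overlapping "astrocytic units" — circles at the
vertices of an equilateral triangle (circumradius $0.8\,r_{max}$) — held
together by strong intracellular adhesion. Units move only passively
($\mu_A \dot x = F$) and deform by a radius law that abstracts
Slit–Robo-induced process retraction: unit $j$ counts the neuroblasts
$B_j(t)$ whose soma or tip surface lies within $d_{slit} = 15\,\mu m$ of
its surface (each cell at most once), targets

$$\bar r_j(t) = \max\big(r_{max} - \rho_A B_j(t),\; r_{min}\big),$$

and relaxes toward the target with time constant $\tau$:
$\tau \dot r_j = \bar r_j - r_j$. Counting is surface-to-surface and
uses only the soma and tip circles; a config switch (`count_process`)
can include the process rectangle, but the default keeps the signal
source at the cell bodies.

In the **mismatched shrinkage** control, the multiset of counts
$\{B_j\}$ is redistributed over all units by a uniformly random
permutation, refreshed once per saltation period (20 min). Permuting
(rather than re-rolling counts independently) conserves the total shrink
signal, which is the property that makes the control comparable to the
reactive case; the refresh interval avoids per-step flicker and is
exposed in the config.

### Contact mechanics

Every pair of circles in contact (soma, tip, unit — excluding the
soma–tip pair of one cell, whose only coupling is the spring) feels a
repulsion proportional to the overlap, $k_R\,\delta$, opposed by an
adhesion of constant magnitude $H$ while the contact lasts:

$$f = (k_R\,\delta - H)\,\hat n .$$

Two adhering circles therefore relax to a stable overlap $H/k_R$. $H$
depends on the pair: $H_N = 2.22$ nN between neuroblasts, $H_a \gg H_A$
between units of one astrocyte versus different astrocytes, and zero for
neuroblast–astrocyte contacts (repulsion only). The constant-magnitude
adhesion law makes the nN values of $H$ literal forces; an alternative
overlap-proportional law is available (`adhesion_law = "proportional"`)
for sensitivity checks. $H_N$ can itself follow constant, periodic or
random schedules (inconstant adhesion), clamped at zero from below and —
in random mode — at $2 H_{mid}$ from above; the schedule is global, since
it models a common, slowly varying physiological influence rather than
pair-specific noise.

A circle touching a *process* is pushed away from the closest point of
the soma–tip segment with force $k_R\,\delta$; the reaction is split
between soma and tip with lever weights $(1-s, s)$, where $s \in [0,1]$
is the contact parameter along the segment. Contacts whose closest point
clamps to an endpoint are left entirely to the circle–circle term, which
prevents double counting at the process ends. Process–process contacts
do not occur for in-range parameters and are not computed. Coincident
circle centres (a measure-zero event) get a repulsion direction from the
trial's RNG rather than crashing the run.

## Parameters and their defaults

| parameter | default | units | why |
|---|---|---|---|
| $L$, $A_{mid}$, $r_S$, $r_T$, $w$ | 40, 10, 5, 3, 2 | µm | neuroblast morphology and saltation geometry |
| $\omega_{sal}$ | $2\pi/20$ | rad/min | 20-min saltation cycle |
| $d_{slit}$ | 15 | µm | short reach of the Slit signal |
| $H_N$ | 2.22 | nN | baseline neuroblast adhesion; swept 0–3.33 nN |
| $\mu_{low}, \mu_{high}$ | 1, 100 | nN·min/µm | anchoring contrast: per-cycle efficiency $(\mu_h-\mu_l)/(\mu_h+\mu_l) \approx 0.98$ |
| $k_P$ | 0.5 | nN/µm | see below |
| $k_R$ | 10 | nN/µm | sub-µm penetration at the force scales above; units do not split |
| $r_{max}, r_{min}, \rho_A$ | 28, 14, 2.8 | µm | three-unit territory ≈ 100 µm wide; floor at half size; five cells reach the floor |
| $\tau$ | 30 | min | protrusion retraction over tens of minutes |
| $\mu_A$ | 1000 | nN·min/µm | astrocytes are effectively stationary obstacles |
| $H_a$, $H_A$ | 22.2, 0.56 | nN | units of one astrocyte never separate; astrocytes barely adhere to each other |

The friction, stiffness and astrocyte constants are not measurable
directly and were fixed once by the qualitative constraints the system
must satisfy. The spring constant deserves a note: the maximal force a
blocked cell can exert through its spring is $k_P \cdot 2A_{mid}$. At
$k_P = 0.5$ this is 10 nN, which a pair of astrocytic units resists with
sub-micron overlap, so a blocked cell genuinely strands until the
environment deforms — while the spring still tracks its target well
within a phase ($\mu_{low}/k_P = 2$ min against a 10-min half-cycle). A
much stiffer spring would let single cells bulldoze through any gap (and
slowly plough astrocytes aside), erasing the distinction between
confined and open environments that the model exists to study.

## Numerical scheme

The coupled system is integrated by explicit Euler — the equations are
first-order and friction-dominated, so no stiffness beyond the spring
and contact rates arises. The default step $dt = 0.02$ min is validated
against the bound $dt \le \min(\mu_{low}/k_P, \tau)/10$ at construction
time, and a Richardson test in the suite confirms first-order
convergence of whole trajectories. Positions are stored wrapped into the
periodic $600 \times 600\,\mu m$ square; every geometric query uses the
minimal-image convention (valid because all interaction ranges are far
below half the field). Each soma additionally accumulates an *unwrapped*
displacement, which is what the forward-speed measure differences —
correctness does not depend on a cell staying within half a field per
hour. Force assembly is the plain all-pairs $O(n^2)$ loop (at most ~170
circles in scope); the compiled engine is checked against an independent
R implementation of the same ledger to $10^{-9}$ nN, and the ledger sums
to zero at every step because all interactions are equal and opposite.

One RNG stream per trial (seed = `base_seed + trial`), with fixed
substream offsets for initialization, amplitude redraws, adhesion
redraws, mismatched permutations and degenerate contacts, so toggling
one stochastic feature does not shift the draws of the others, and every
trial is bit-reproducible.

### Initialization

Scattered mode draws uniform positions and orientations, rejecting any
placement that overlaps a previously placed circle with a neuroblast
circle; astrocyte units start at $r_{max}$. Astrocyte–astrocyte overlap
is permitted at $t = 0$: at 40 astrocytes the nominal packing fraction
exceeds 80%, so full mutual exclusion is geometrically infeasible — their
own repulsion relaxes residual overlap within the first simulated hours,
and the evaluation window starts at 900 min. Clustered mode packs all
somas into a central disc (radius 60 µm) and keeps astrocyte units
outside it. Rejection sampling failing $10^5$ times is reported as a
configuration error ("field too crowded").

## Evaluation

Forward speed at time $t$ is

$$v_i(t) = \hat e_{ST,i}(t) \cdot \frac{x_{S,i}(t) - x_{S,i}(t - t_{eval})}{t_{eval}},
\qquad t_{eval} = 60 \text{ min},$$

using the orientation at the window *end* (as the definition is
written), with no averaging over the window. Collectivity $n_i(t)$
counts other neuroblasts whose nearest surface-to-surface distance (over
the four soma/tip circle pairs, boundary inclusive) is within
$d_{near} = 20\,\mu m$; processes are excluded from this distance, a
choice exposed as a config switch. Samples are taken every 60 min from
900 to 9000 min — 136 time points per trial, 24 cells each — and pooled
over all trials of a condition into a single OLS regression
$v \sim \alpha n + \beta$. Binned means per collectivity value carry
normal-approximation 95% intervals ($\pm 1.96\,SE$); at thousands of
samples the distinction from t-based intervals is immaterial.

```{r example, eval = FALSE}
cfg <- run_config(n_astrocytes = 40, duration = 9000, n_trials = 10)
traj <- run_condition(cfg)
samples <- collect_samples(traj)
fit <- fit_speed_collectivity(samples)
glance(fit)
autoplot(fit)
```

A positive slope $\alpha$ means cells in collectives outrun solitary
cells; the package's condition grids (astrocyte density 0–40, reactive
vs mismatched shrinkage, the three amplitude and adhesion schedules,
adhesion 0–3.33 nN, smooth-morphology variants, clustered
initialization) reproduce the model's full condition system, and
`run_sweep()`/`sweep_table()` emit the slope tables behind the condition
heat maps.

## What the synthetic conditions do and do not show

Everything in this package is simulation: the generator's defaults *are*
the study conditions (24 cells on a 600-µm periodic square, 10 trials of
9000 min each). The desk-scale test suite necessarily runs reduced
problems — the condition-contrast checks use 3 trials of 3000 min with
the evaluation window starting at 900 min — which the vignette states as
the package's own choice of test scale; slope *magnitudes* at reduced
scale are noisier than at full scale, so those checks assert the
qualitative contrast (signs and ordering), not printed magnitudes.
Passing tests show the mechanics, bookkeeping and statistics are
implemented as specified, and that the qualitative phenomenology
(stranding of solitary cells among dense reactive astrocytes, chain
formation, the collectivity contrast between dense and empty fields)
emerges under the package defaults. They do not show that the defaults
match any particular biological tissue quantitatively: the friction,
stiffness and astrocyte constants are order-of-magnitude choices
constrained only qualitatively, and real neuroblasts steer, branch and
respond to guidance cues that the model deliberately omits.

## Known limitations

* No chemotaxis, steering, branching or backward crawling; all turning
  is contact-induced.
* Astrocytes neither proliferate nor migrate actively; the Slit signal
  is a contact-range count, not a diffusing field.
* The regression is descriptive pooled OLS, as defined — no mixed
  effects, no per-trial weighting.
* The adhesion-inconstancy amplitudes (`A_H = 8`, `sigma_H = 4`) are
  larger than the mean `H_N = 2.22` nN if read in nN; whether they were
  meant in nN or internal model units is ambiguous, so both readings are
  possible through the config (set them directly in nN), and the
  schedule clamps at zero either way.
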