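---
title: "The evosoc society model: dynamics, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The evosoc society model: dynamics, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evosoc)
```

## The model

A society is a set of `n` potential *occupations* linked by a binary
directed support matrix `C`: `c_ij = 1` means occupation `j` supports
occupation `i`. Occupation `i` holds a nonnegative productivity `x_i`
(the inhabitants it feeds); the society's total is `X = sum(x_i)`. Two
forces act on every occupation:

* **competing strength** `Cs_i = a * (C x)_i` — supporting inflow from the
  occupations that back it (only active occupations contribute; support
  coefficients are equal across links);
* **environmental restriction** `Ce = b * X` — a pressure shared by every
  occupation that grows linearly with the total population.

The canonical change rate divides the inflow by the occupation's own size,

```
dx_i/dt = a (Cx)_i / x_i - b X ,
```

so growth saturates as an occupation gets large, and the restriction term
is a common pressure rather than a dilution flux — the system can expand.
At a fixed point every active occupation satisfies
`a (Cx)_i / x_i = b X`, i.e. `x` is a nonnegative eigenvector of `C`. On
an irreducible active structure the Perron–Frobenius theorem gives a
unique positive eigenvector with eigenvalue `lambda_pf` (the spectral
radius), and matching the stationarity condition fixes the norm:
`X* = (a/b) * lambda_pf`. For binary `C`, `lambda_pf >= 1`; only the ratio
`a/b` matters for equilibria, so the package uses `b = 1` internally and
exposes `a_over_b`.

An alternative mass-action form `dx_i/dt = a (Cx)_i - b X x_i` shares the
same fixed points; it is available as `rate_form = "mass"` and the test
suite checks both relax to the same Perron equilibrium. The canonical
ratio form is the default.

Two discrete mechanisms drive structural change:

* **Elimination.** An occupation needs at least `limina` productivity to
  function. Whenever `x_i` drops below limina it is eliminated: `x_i`
  becomes 0, it stops supporting others, and the loss may cascade.
* **Mutation.** At each phase boundary, the active occupations are visited
  in a uniformly random order; each holding strictly more than `2*limina`
  fires with probability `p_m`, transferring exactly one limina quantum to
  a target drawn among the occupations currently supported by the active
  network (a society remembers its occupations, so destroyed ones can be
  regenerated, and entirely new ones created). Targets in the source's own
  society carry weight 1; targets in another society carry `cross_weight`.
  Mutation conserves total productivity exactly.

A simulation alternates *developing* phases (relax to the attractor, with
eliminations) and *mutating* phases.

## Parameters

| name | meaning | default / study value |
|---|---|---|
| `a_over_b` | support-to-restriction ratio; sets the equilibrium scale `X* = (a/b) lambda_pf` | 60–120 |
| `limina` | minimum functioning productivity, and the mutation quantum | 1.0 (the unit all productivities are measured in) |
| `p_m` | per-occupation mutation probability per phase | 0.01–0.04 |
| `p_c`, `p_c_xy` | support probability within / between society blocks | 0.075–0.4 |
| `cross_weight` | relative weight of other-society mutation targets | 0.1 |
| `r_d` | pulse severity: `b` is amplified to `r_d * b` for one developing phase | 4–25 |

`cross_weight` has no stated value in the source material beyond being
"lower" than within-society flow; 0.1 is the package's fixed choice and is
exposed as a knob. It controls how quickly a derived society forms
relative to the original society's own dynamics, not the equilibrium the
pair eventually reaches.

## Numerics

**Developing phase.** Explicit Euler stepping with base step
`dt = 1e-3 / b`, run until the stationarity residual
`max_i |a (Cx)_i / x_i - b X|` falls below `tol = 1e-8 * (a/b)`, with a cap
of `1e7` steps. Eliminations are checked after every step, so cascades
resolve within one phase. Two per-step guards matter:

* *Elimination resolution.* The step is shrunk so no occupation moves more
  than `0.2 * limina` per step. During violent transients (a severe pulse
  makes every rate of order `r_d * b * X`) a plain Euler step would sweep
  the entire society below limina in one stroke, making elimination order —
  and hence who survives a collapse — an artifact of the step size. With
  the limiter, the weakest occupations are eliminated first, the
  restriction `b X` falls as they go, and compact self-supporting cores can
  stabilise; halving the limiter factor again changes no outcome in the
  ensembles the tests run, so 0.2 is resolution-converged.
* *Stiffness of the mass form.* `rate_form = "mass"` has Jacobian norm of
  order `a * deg + b X`, so its step is additionally bounded by a per-step
  estimate of that scale.

The fixed points of the scheme are exactly the fixed points of the ODE, so
the tight residual tolerance — not the step size — controls the accuracy of
reported equilibria (the suite verifies 1e-6 relative agreement with the
eigenvector oracle).

**Perron pair.** Power iteration on the shifted matrix `C + I`, tolerance
`1e-12` on the iterate, cap `1e5` iterations. The unit shift makes every
irreducible matrix primitive (pure cycles would otherwise oscillate) and
adds exactly 1 to the dominant eigenvalue without moving its eigenvector;
the shift is subtracted from the reported value. `eigen()` serves as an
independent oracle in the tests, never as the implementation.

**Degenerate inputs.** A 1×1 matrix is irreducible iff its entry is 1 (a
self-supporting singleton is a legal seed society). Reducible matrices are
rejected by `equilibrium_productivity()` — their attractors are found by
`develop()`, which handles slaved (parasitic) structures naturally. An
extinct state passes through `develop()`/`step()` unchanged. Probabilities
above 1 in configurations are capped at 1 with a warning.

## Scenario procedures

All scenario events are scheduled, not detected: societies that start at
their equilibrium are steady from phase 1, so the event phase (default 51,
i.e. after a 50-phase steady stretch) plays the role of "after the society
has stabilised".

* **boot** — one self-supporting occupation at `x = limina`
  (`ensure_self_supporter` guarantees such a seed exists); mutation
  gradually populates the rest. The active count climbs to (nearly) `n`
  and `X` fluctuates around `(a/b) lambda_pf`.
* **supporting** (parasitism, `p_c_do = 0` enforced) — by default
  (`origin_state = "boot"`) the original society self-boots *while*
  cross-society mutation is live, so the run races society formation
  against the parasitic load: the derived society contributes nothing to
  the total, and if it grabs too much share before/after the host is fully
  formed, host occupations fall below limina and the collapse can be
  total — in which case a non-self-supporting parasite follows its host.
  `origin_state = "equilibrium"` starts the host fully formed instead;
  coexistence is then markedly more stable, which is the main sensitivity
  of this scenario to procedure.
* **disturbing** — the society starts at its equilibrium; the developing
  phase at `event_phase` runs under `b' = r_d * b` (the pulse lasts exactly
  one phase). Surviving occupations scale as `1/r_d` at the disturbed
  attractor; `wipeout_threshold(X, n0, limina) = X / (n0 * limina)` is the
  severity that kills a uniformly distributed society outright.
* **invading** — original society at equilibrium; at `event_phase` the
  intact invader block enters. The default entry productivity is the
  invader's home-environment equilibrium (`invader_entry = "equilibrium"`):
  the squad is a functioning society, and a squad landed at bare limina is
  structurally incapable of invading — any below-average member is
  eliminated in the first developing step and the block unravels, so the
  limina option (kept for exploration) makes invasion always fail. With
  equilibrium entry the block with the larger spectral radius wins and the
  other goes extinct; exact ties are resolved in favour of the larger
  established mass.
* **mutual** — as `supporting` but with back-support (`p_c_do > 0`); the
  merged irreducible matrix has a larger spectral radius than the original
  block alone, so the fused society settles at a strictly higher total.

## Replication harness

`replicate_scenario()` runs seeds `base_seed + 0..n_reps-1` and aggregates
statistics per phase index (all replicates share `n_phases`; no time
warping). Extinction of a society means zero active occupations with its
label at the end of the run. Normality of the steady-state productivity
distribution is tested per surviving replicate on the final active
productivities (Shapiro–Wilk via `stats::shapiro.test`), the summary
reporting per-replicate `W` and `p` plus their means. The "steady state"
sampled is the final phase of the run.

## What the generator does and does not emulate

Support structures are Erdős–Rényi digraphs: every potential support link
is an independent Bernoulli draw, block-wise between societies. This
captures the one structural statistic the model's equilibria depend on
(`lambda_pf ≈ n * p_c` with bell-shaped Perron weights) but none of the
degree correlation, clustering or specialisation hierarchy of real
occupation networks. Productivity is a single scalar per occupation;
inhabitants are not modelled as agents, interactions carry no delays, and
support coefficients are all equal. Passing ensembles therefore validate
the *mechanism* — eigenvector equilibria, threshold cascades, formation
races — not any calibrated claim about a real society.

## Problem sizes

The study configurations use societies of 100 potential occupations
(derived blocks up to 200, invader blocks of 100), 50 replicates for
ensemble counts, and runs of 300–2000 phases chosen so that every reported
ensemble is flat over its final quarter; the directional boot comparisons
use 10 replicates. On an ordinary single core the whole suite and the
acceptance script each finish in a few minutes.

## Known limitations

* The supporting-scenario extinction count depends visibly on the origin
  procedure (formation race vs. equilibrated host) and on `cross_weight`;
  both are exposed rather than hidden, and the package's defaults are
  stated above.
* Power iteration rejects (by error) matrices whose dominant eigenvalue is
  defective — these do not arise for the generated structures but can be
  constructed by hand.
* Trajectories record per-society totals and counts once per phase;
  within-phase cascade detail is not logged.
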