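# stemgame

Evolutionary-game analysis of stem-cell injection therapy against cancer.

`stemgame` is for modellers studying tumour–immune dynamics who want a small,
fully analyzable system: the competition between cancerous (C) and healthy
(H) cells is a two-strategy evolutionary game, its dynamics are the
replicator equations, and a stem-cell therapy enters as a feedback
compartment whose equilibrium effect is governed by a single composite
control parameter. The package computes equilibria and stability in closed
form, classifies the parameter space into dynamical regimes, integrates
trajectories to steady state, and designs therapies that drive the system to
states with few or no cancerous cells.

## The model

With payoff matrix entries `a` (C vs C), `b` (C vs H), `c` (H vs C),
`d` (H vs H) and `x` the cancerous-cell frequency (`y = 1 - x`), the
replicator dynamics on the simplex reduce to

```
dx/dt = x (1 - x) (t2 - (t1 + t2) x),   t1 = c - a,  t2 = b - d
```

with fixed points `0`, `1` and `x3 = t2/(t1+t2)`. Stem-cell injection adds a
compartment `z` (`dz/dt = x j - z l`) that depresses cancerous growth by
`z w`; the nonzero equilibria become the roots of

```
(t1 + t2) x^2 - (t1 + 2 t2 + e) x + t2 = 0,   e = w j / l,
```

each paired with `z = (j/l) x`. The root product `t2/(t1+t2)` is invariant
in `e` while the root sum is linear in it, so therapy slides the two roots
along a fixed-product hyperbola — the lever behind every design strategy.
In the bistable regime (`t1 < 0`, `t2 < 0`) the quadratic loses its interior
roots once `e` exceeds `-2 sqrt(t2 (t1+t2)) - (t1 + 2 t2)`, after which the
whole interval drains to the cancer-free state.

## Worked example

```r
library(stemgame)

t <- t_params(-1, 2)          # or derive_t_params(payoff_matrix(a, b, c, d))
classify_case(t)
#> Case A1 (t1<0, t2>0); x3 = 2 (above one)
```

Case A1: without therapy the all-cancer state `x = 1` attracts the whole
interior. Adding therapy with composite parameter `e = 18` creates a small
attracting equilibrium:

```r
therapy_equilibria(t, therapy = 18)
#> Equilibria for t1 = -1, t2 = 2, e = 18:
#>            x           z stability            source
#>   0.00000000  0.00000000    saddle            origin
#>   0.09567398  0.09567398    stable therapy_quadratic
#>  20.90432602 20.90432602    saddle therapy_quadratic
#> Vieta: root product P = 2, root sum S = 21
```

The residual cancerous fraction at the attractor is 0.096; the root product
(2) is the same as at `e = 0`, where the roots are 1 and 2. To target a
specific residual level instead, invert the quadratic and verify stability:

```r
rec <- recommend_therapy(t, x_target = 0.1)
#> Therapy recommendation for case A1:
#>   strategy: increase_positive
#>   e = 17.1 (w = 17.1 with j = 1, l = 1)
#>   predicted steady-state x = 0.1

traj <- simulate_game(0.5, t, therapy = therapy_params(w = rec$w))
steady_state_value(traj)
#>        x        y        z        t
#>  0.10000  0.90000  0.10000 26.62337
```

The simulated steady state lands on the designed equilibrium, with the
stem-cell level at its quasi-steady state `z = (j/l) x`.

A command-line wrapper over the same functions is installed at
`inst/scripts/stemgame` (subcommands `classify`, `analyze`, `simulate`,
`design`, `sweep`, `reftable`, with JSON/YAML config support).

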