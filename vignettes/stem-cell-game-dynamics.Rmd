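---
title: "Replicator dynamics of cancer-healthy cell competition under stem-cell injection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicator dynamics of cancer-healthy cell competition under stem-cell injection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemgame)
```

## The model

The package treats the competition between cancerous (C) and healthy (H)
cells as a two-strategy evolutionary game with payoff matrix

$$\begin{pmatrix} a & b \\ c & d \end{pmatrix},$$

where $a$ is the payoff of a C cell meeting another C cell, $b$ of C meeting
H, $c$ of H meeting C and $d$ of H meeting H. The payoffs absorb, among other
things, the strength of the patient's immune response; they are treated as
free parameters rather than estimated from data. With $x$ and $y = 1 - x$
the frequencies of cancerous and healthy cells, the replicator equations

$$\dot x = x\,(f_C - f_{CH}), \qquad \dot y = y\,(f_H - f_{CH})$$

with fitnesses $f_C = xa + yb$, $f_H = xc + yd$, $f_{CH} = x f_C + y f_H$
drive each strategy at a rate proportional to its fitness advantage over the
population mean. On the simplex the dynamics reduce to a single cubic in $x$,

$$\dot x = x\,(1 - x)\,\bigl(t_2 - (t_1 + t_2)\,x\bigr),
\qquad t_1 = c - a, \quad t_2 = b - d,$$

so everything depends on the payoffs only through the two reduced
parameters. The fixed points are $x = 0$ (cancer-free), $x = 1$ (all-cancer)
and the coexistence point $x_3 = t_2/(t_1 + t_2)$, which may lie outside
$[0, 1]$.

### Case taxonomy

`classify_case()` partitions the $(t_1, t_2)$ plane by the sign of
$t_1 + t_2$ (family A positive, family B negative) and the location of
$x_3$:

| label | $x_3$ | behaviour on $(0,1)$ |
|---|---|---|
| A1 | $> 1$ | all-cancer state attracts |
| A2 | $< 0$ | cancer-free state attracts |
| A3 | $(0,1)$ | stable coexistence at $x_3$ |
| B1 | $< 0$ | all-cancer state attracts |
| B2 | $> 1$ | cancer-free state attracts |
| B3 | $(0,1)$ | bistable; $x_3$ separates the basins |

The sub-case is assigned from the location of $x_3$, with the implied sign
pattern of $(t_1, t_2)$ recorded alongside: in family B the sign pattern is
*derived* from the $x_3$ location ($x_3 < 0$ forces $t_2 > 0$ when
$t_1 + t_2 < 0$, and so on), since the two descriptions are equivalent only
when stated this way. Boundary sets ($t_1 + t_2 = 0$, $t_1 = 0$ or
$t_2 = 0$, i.e. $x_3$ undefined or exactly at $0$/$1$) are labelled
`DEGENERATE`: the dynamics there are non-hyperbolic and any sub-case label
would be arbitrary. Classification uses exact sign tests — the inputs are
user-chosen parameters, not measurements, so no floating tolerance is
appropriate.

## The therapy model

Stem-cell injection is modelled as a feedback compartment $z$ coupled to the
game:

$$\dot x = x\,(f_C - f_{CH} - z w), \qquad
  \dot y = y\,(f_H - f_{CH}) + (1 - y)\,z w, \qquad
  \dot z = x j - z l.$$

Injection is driven by the cancerous fraction (rate $j$ per unit $x$),
cleared at rate $l$, and each unit of $z$ depresses the cancerous growth
rate by $w$. The third equation is integrated as a differential equation:
its quasi-steady state $z_{eq} = (j/l)\,x_{eq}$ is what makes the
equilibrium analysis closed-form. At equilibrium the nonzero $x$ values
solve the quadratic

$$(t_1 + t_2)\,x^2 - (t_1 + 2 t_2 + e)\,x + t_2 = 0,
\qquad e = \frac{w j}{l},$$

so the three therapy rates act on the equilibrium structure only through the
composite control parameter $e$. By Vieta's formulas the root *product*
$t_2/(t_1+t_2)$ is independent of $e$ while the root *sum*
$(t_1 + 2t_2 + e)/(t_1+t_2)$ is linear in it: therapy slides the two roots
along a fixed-product hyperbola, which is the lever every design strategy in
the package uses. The origin keeps linearization coefficient $t_2$ for every
$e$ — therapy can never change the local stability of the cancer-free state,
only reshape the basin that feeds it.

### Therapy design

`recommend_therapy()` implements one strategy per case:

* **A2, B2** — the cancer-free state already attracts the whole interior;
  no therapy (`e = 0`).
* **A1, A3, B1** — the origin is unstable ($t_2 > 0$), so the best
  achievable outcome is a *small* stable residual equilibrium. Driving
  $e \to \infty$ would push the stable root to $0^+$; the package instead
  inverts the quadratic (`e_for_target()`) for a finite $e$ that places the
  root exactly at the requested residual frequency, then verifies with the
  full 2-D Jacobian that the root is attracting. Moderate finite values
  suffice in practice: for $t_1 = -1, t_2 = 2$ a residual of $0.1$ needs
  only $e = 17.1$.
* **B3** — the origin is already stable but shares the interval with the
  stable all-cancer state. Above the exclusion threshold
  $e^\star = -2\sqrt{t_2 (t_1+t_2)} - (t_1 + 2 t_2)$ the quadratic has no
  root inside $(0, 1)$, the separatrix disappears, and the whole interval
  drains to $x = 0$. The recommendation uses $1.1\,e^\star$: the condition
  is a strict inequality, and the 10% margin both gives floating-point
  headroom and keeps the slow passage near the vanished root pair short.
  $e^\star > 0$ throughout the B3 region (it equals
  $(\sqrt{|t_1|+|t_2|} - \sqrt{|t_2|})^2$ there), so the margin always
  moves $e$ in the right direction.

In case B1 an attracting small-$x$ equilibrium requires $e > 0$, the same
direction as A1/A3: *decreasing* the root sum with negative $e$ moves the
feasible root toward 1 and the negative root further negative, and the
reference scenario tabulated at $e = -12$ is in fact reproduced by
$e = +12$ (see `reference_equilibrium_table()`, which flags that row rather
than silently matching it). Because prescriptions with the opposite sign
circulate, the recommendation carries a `discrepancy_flags` note.

The exclusion condition is exposed as printed — a lower bound on $e$ only.
Large $e$ also produces *real* roots outside $(0,1)$ (the discriminant
argument gives a band of complex pairs, after which the real roots re-enter
outside the unit interval); since either way no equilibrium blocks the
interior, the package reports the root locations alongside the boolean so
the full picture is visible.

## Stability: when the composite parameter is not enough

Equilibrium *positions* depend on the rates only through $e$; stability does
not quite. With $y$ eliminated, the $(x, z)$ Jacobian at a nonzero
equilibrium satisfies $\det J = -l\,h'(x^\ast)$, where
$h(x) = x[(1-x)(t_2 - (t_1+t_2)x) - e x]$ is the reduced
(quasi-steady-state) flow. So $h'(x^\ast) > 0$ is always a saddle, exactly as
the 1-D picture predicts. But when $h'(x^\ast) < 0$ the equilibrium can
still lose stability through a positive trace,
$\operatorname{tr} J = f_x - l$: if the stem-cell compartment relaxes slowly
relative to the game (small $l$) the feedback loop overshoots and the
equilibrium is an unstable focus. Even at the default $j = l = 1$ this
happens in corners of the sampled parameter box (for example
$t_1 = -10, t_2 = 0.3$ with the root placed at $x = 0.3$). For this reason
`therapy_equilibria()` always classifies with the eigenvalues of the full
2-D Jacobian, `recommend_therapy()` only certifies targets whose root the
Jacobian calls stable, and the corresponding property test asserts the
determinant identity plus the saddle correspondence and requires every
reduced-map disagreement to be explained by a positive trace. Non-hyperbolic
equilibria (an eigenvalue at zero within 1e-10 of the Jacobian scale) are
reported as `"marginal"`, never silently as stable.

## Numerical choices

* **Quadratic roots** use the cancellation-safe formulation (sign-matched
  numerator, companion root via $c/q$), because therapy design routinely
  places one root within $10^{-2}$ of zero while the other is of order
  $e/(t_1+t_2)$.
* **Integration** (`simulate_game()`) uses `deSolve::lsodar` — adaptive,
  stiff-capable, with root-based stopping — at `rtol = 1e-9`,
  `atol = 1e-11`. Convergence is declared when the max-norm of the
  right-hand side falls below `1e-8`; with these tolerances simulated steady
  states agree with the closed-form equilibria to ~1e-4 or better, which is
  what the tests assert.
* **Horizon**: the model has no intrinsic time scale, so the default horizon
  is 500 time units with up to 4 automatic doublings when the convergence
  criterion has not fired (slow passages occur just above the B3 exclusion
  threshold, where an almost-root pair throttles the flow).
* **Feasibility is monitored, not enforced**: states are never clipped.
  Negative excursions beyond $-10^{-10}$ warn, beyond $-10^{-6}$ error —
  the boundary faces are invariant manifolds of the exact flow, so anything
  larger than round-off indicates a genuine problem. The stem-cell level is
  a level, not a frequency: its quasi-steady state $(j/l)x$ can exceed 1,
  which is allowed but warned about. $z_0 = 0$ by default (therapy starts
  with no stem cells present).
* **Parameter sampling** for the property tests draws uniformly from
  $t_1, t_2 \in [-10, 10]$ restricted to each case region, excluding
  $|t_1 + t_2| < 0.05$ so sampled systems stay comfortably hyperbolic.

## Problem sizes used by the test suite

The property suites run 500-instance sweeps for the root-solver-vs-bracketing
oracle (sign scan at $10^{-4}$ resolution over $[-50, 50]$, bisection-refined)
and for target-inversion consistency, 200 sampled B3 parameter sets with five
interior initial conditions each for the exclusion-threshold suite, and
1000-draw loops for the classification and polynomial-equivalence
invariants. These sizes exercise every case region densely while keeping the
whole suite in the low minutes on a single core.

## What the model does and does not cover

The simulator and analyzer are exact to their contracts, but the model is a
deliberately minimal caricature of tumour-immune dynamics: two well-mixed
cell strategies, constant payoffs, deterministic infinite-population
dynamics, and a single lumped stem-cell compartment. It contains no
finite-population noise, no spatial structure, no time-varying or
state-dependent dosing, and no pharmacokinetics behind $w, j, l$; payoffs
are not estimated from patient data. Passing tests therefore demonstrate
faithfulness to the mathematical model, not clinical validity. Within the
model, the practical reading of the analysis is that moderate finite values
of $e$ — reachable by raising the injection gain $j$ or lowering the
clearance $l$ — already drive the system to states with few or no cancerous
cells; the limiting prescriptions ($e \to \infty$) are idealizations the
package replaces with verified finite targets.

## A worked session

```{r example}
t <- t_params(-1, 2)
classify_case(t)

baseline_equilibria(t)

therapy_equilibria(t, therapy = 18)

rec <- recommend_therapy(t, x_target = 0.1)
rec

traj <- simulate_game(0.5, t, therapy = therapy_params(w = rec$w))
steady_state_value(traj)
```
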