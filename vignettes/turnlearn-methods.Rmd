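---
title: "Cultural evolution under population turnover: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cultural evolution under population turnover: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnlearn)
```

## The model

A group of constant size faces a task with two solutions, one more
efficient than the other. At time $t$ a fraction $n(t)$ of the group is
naive (knows neither solution), $i(t)$ uses the inefficient solution and
$e(t)$ the efficient one, with $n + i + e = 1$. Three processes move
individuals between these compartments in continuous time:

* **Innovation.** Inefficient individuals independently discover the
  efficient solution at per-capita rate $\mu$.
* **Turnover.** Individuals of any compartment are replaced by naive
  newcomers (immigrants, or deaths balanced by naive recruits) at
  per-capita rate $m$.
* **Social learning.** Pairs meet under mass action, at a rate equal to
  the product of their compartment frequencies. Naive individuals always
  attempt to learn from a knowledgeable partner; knowledgeable individuals
  are behaviorally conservative and attempt to learn only with probability
  $1 - c$. An attempt on an efficient partner succeeds at rate $s_e$, on
  an inefficient partner at rate $s_i$, with the standing assumption
  $s_e > s_i$ (the efficient solution, once seen, is the more attractive
  one to copy). Encounters with naive partners teach nothing, and there is
  no cultural loss: efficient individuals never revert spontaneously.

The mean-field dynamics are

$$
\begin{aligned}
n' &= m\,i + m\,e - n\,e\,s_e - n\,i\,s_i \\
i' &= -\mu i - m\,i + n\,i\,s_i + (1-c)\,e\,i\,s_i - (1-c)\,i\,e\,s_e \\
e' &= \mu i - m\,e + n\,e\,s_e - (1-c)\,e\,i\,s_i + (1-c)\,i\,e\,s_e ,
\end{aligned}
$$

implemented verbatim in `culture_rhs()`; `flow_decomposition()` exposes
the seven directed flows whose signed sums reconstruct it. The derivatives
sum to zero identically, which the package asserts rather than enforcing
by renormalization (see *Numerical choices*).

The question the model answers: when does replacing experienced members
with naive ones *speed up* the spread of the efficient solution? It can,
because newcomers, unlike conservative incumbents, always try to learn.

## Parameters

| symbol | meaning | unit | default |
|---|---|---|---|
| `mu` | innovation rate of inefficient individuals | 1/time | 0.01 |
| `m` | population turnover rate | 1/time | (varied) |
| `c` | behavioral conservatism probability | – | (varied) |
| `se` | learning success rate from an efficient partner | 1/time per encounter | (varied; required) |
| `si` | learning success rate from an inefficient partner | 1/time per encounter | 0.1 |

Time units are periods in which a single social-learning event can occur
— days or weeks rather than generations — so realistic turnover per
timestep is small ($m \ll 0.1$). The defaults `mu = 0.01`, `si = 0.1` and
the all-inefficient start `simplex_state(0, 1, 0)` are the reference
configuration for every analysis in the package; `se` has no default
anywhere because it is a primary swept parameter. `se <= si` is accepted
with a warning rather than rejected: the boundary `se = si` is needed for
the exchange-symmetry checks in the test suite, and probing it is
legitimate, but none of the persistence/extinction results below are
guaranteed there (see *Limitations*).

## Trajectories and the time to half-adoption

`integrate_culture()` solves the system with an adaptive stiff-capable
solver (`deSolve::lsoda`, rtol 1e-8, atol 1e-10). `time_to_threshold()`
finds the first time $t_h$ with $e(t_h)$ equal to a threshold (default
one half) by the solver's own root detection, which locates the crossing
far below the 1e-6 time tolerance required of it — crossing-time error
must stay well under the finite-difference scales used by the sensitivity
analysis downstream.

```{r th}
t_still <- time_to_threshold(model_params(m = 0,   c = 0.75, se = 0.5))
t_turn  <- time_to_threshold(model_params(m = 0.1, c = 0.75, se = 0.5))
c(no_turnover = t_still$t_h, turnover = t_turn$t_h)
```

Turnover at $m = 0.1$ *shortens* the time to half-adoption despite
removing knowledgeable individuals, because at $c = 0.75$ incumbents
rarely attempt to learn while their naive replacements always do.

A threshold can be genuinely unattainable: the equilibrium efficient
fraction (next section) bounds $e(t)$ from above in the long run. The
package distinguishes "unreachable" (equilibrium at or below the
threshold: `reached = FALSE`) from "horizon too small" (equilibrium
strictly above it but `t_max` expired: an error), using the closed form
rather than guessing from the trajectory. The knife-edge where the
equilibrium *equals* the threshold is classified unreachable: the
approach is asymptotic, so no finite crossing time exists, and growing
the horizon would never terminate.

## Equilibrium and regimes

With $\mu > 0$ the inefficient solution always goes extinct (no cultural
loss means $i$ has no permanent source), so equilibria have $i = 0$ —
encoded structurally, not solved for. Balancing turnover against social
learning in the remaining two compartments gives

$$
e^* = 1 - m / s_e \quad (0 < m < s_e), \qquad
e^* = 1 \; (m = 0), \qquad
e^* = 0 \; (m \ge s_e).
$$

When $m \ge s_e$ naive newcomers arrive faster than they adopt, the pool
of experience erodes, and only naive individuals remain. The boundary
$m = s_e$ is assigned to the extinction regime: the formula gives exactly
0 there, and the long-run dynamics for every $m \ge s_e$ end all-naive. A
direct corollary is the majority condition: efficient individuals can be
half or more of the population at equilibrium only when $m \le s_e/2$,
i.e. when social learning runs more than twice as fast as turnover
(`critical_ratio()` recovers the factor 2 by bisection over long-horizon
integrations, without using the closed form).

`equilibrium_analytic()` returns the closed form after verifying it by
substitution (residual under 1e-12); `equilibrium_numeric()` integrates
with an adaptive horizon (doubling from 1e3, capped at 1e7) until
$\max|{\rm rhs}| < 10^{-9}$ at the endpoint, and reports non-convergence
as an error instead of truncating silently. With $\mu = 0$ the system has
a continuum of equilibria, so the analytic branch refuses $\mu = 0$ with
an explanatory message.

Two degenerate facts shape the robustness analysis: the all-naive state
is an exact fixed point (nothing to learn from, nothing to innovate
from), and every other start converges to the same equilibrium.
`robustness_to_initial_conditions()` verifies this from uniform random
simplex starts (symmetric Dirichlet(1,1,1), rejecting draws with
$i_0 + e_0 < 0.01$), asserting both the spread across starts and the
deviation from the closed form stay below 1e-4.

## The critical curve and parameter sweeps

`sweep_th()` maps $t_h$ over an $(m, c)$ grid; `th_sensitivity()`
differentiates it in $m$ (central difference, step `dm = 1e-3` — far
above the crossing-time tolerance, far below typical grid spacings;
forward difference at $m < dm$). A negative sensitivity means turnover
accelerates cultural evolution. `critical_curve()` locates, for each
$m$, the conservatism $c(m)$ at which the sensitivity vanishes, by
scanning $c \in [0, 1]$ for a sign change and bisecting to 1e-4. Above
the curve turnover accelerates adoption; below it, it slows it. For the
reference configuration the curve exists for small $m$ and exits $c > 1$
near $m \approx 0.13$; turnover rates without a sign change are omitted
from the curve with a log message rather than raised, and when several
brackets appear the root nearest the previous turnover rate's root is
kept so the curve stays continuous. Raising $s_e$ pushes the curve down,
enlarging the acceleration region.

```{r curve, eval = FALSE}
critical_curve(c(0.02, 0.05, 0.08, 0.12), fixed = list(se = 0.5))
#>      m         c
#> 1 0.02 0.5202637
#> 2 0.05 0.5978027
#> 3 0.08 0.7014160
#> 4 0.12 0.9057129
```

Grid cells are pure functions of their coordinates: recomputing any
single cell reproduces the stored value bit-for-bit, and results are
independent of evaluation order. Unreachable cells carry an explicit
marker in memory and an empty value plus `reachable=false` in CSV —
never NaN-as-data.

## The stochastic counterpart

`simulate_ctmc()` is an exact (Gillespie direct-method) simulation of a
finite population of $N$ agents moving through the same three states via
seven event channels. Channel rates are scaled so that the expected drift
of the count fractions equals `culture_rhs()` *exactly* (a pairwise
channel between classes at fractions $x, y$ with success rate $s$ fires
at total rate $N x y s$; no $N/(N-1)$ correction, no self-encounter
term). This drift-exactness is what qualifies the chain as an independent
oracle for the ODE: any systematic disagreement beyond finite-size
effects indicates a bug on one side. Continuous time is deliberate — the
model does not assume innovation, turnover and learning occur in any
particular order.

Finite populations differ from the mean field in two documented ways:

* The ensemble mean carries an $O(1/N)$ correction. At $N = 1000$, on
  the reference configuration, it is about $-0.006$ in $e$ at the
  steepest part of the transition — comparable to the Monte-Carlo
  standard error of a 200-replicate ensemble, so a 3-SE agreement check
  at that size is near its resolution limit and tightens only as $N$
  grows.
* Drift can extinguish the efficient trait even when $m < s_e$: at
  $N = 20$ on the reference configuration roughly a tenth of replicates
  are absorbed all-naive by $t = 400$, while at $N = 2000$ none are.

## Numerical choices

* State is stored as all three fractions, not two plus a complement, so
  conservation is an assertable invariant; trajectories are checked for
  simplex-sum drift (tolerance 1e-7) and never renormalized —
  renormalization would mask solver bugs.
* Simplex tolerances: sum within 1e-9; components within
  $[-10^{-12}, 1+10^{-12}]$ for solver output, exact $[0,1]$ for user
  input. Chosen to sit well above double-precision noise and well below
  any model-scale quantity.
* The fixed-step Euler and RK4 integrators exist purely as brute-force
  cross-checks. At step 1e-4 on $[0, 100]$ the fourth-order reference
  agrees with the adaptive solution to ~1e-8; forward Euler is
  first-order, so its own truncation error caps the achievable agreement
  near 1e-4 for fast-learning parameter draws — tests bound it there,
  and the solver's 1e-5 validation rests on the RK4 reference.
* Equilibrium grids respect the standing assumption: the $(m, s_e)$
  validation grid keeps $s_e > s_i$ and offsets its axes so no cell sits
  on the $m = s_e$ diagonal, where convergence slows as $|s_e - m| \to 0$.
  With $s_e < s_i$ the model genuinely admits a coexistence equilibrium
  with $i > 0$ (e.g. $m = 0.05$, $s_e = 0.075$, $s_i = 0.1$ settles at
  $i \approx 0.174$), outside the persistence/extinction dichotomy.
* Problem sizes used by the shipped checks: a 20×20 equilibrium grid,
  ten random parameter draws for oracle equivalence, 200 replicates of
  $N = 1000$ agents for the mean-field comparison, 20 random starts for
  robustness. Together they run in well under a minute.

## Limitations

The model has exactly two trait variants with a fixed efficiency gap; no
age structure, no increase of conservatism with age, no heterogeneity in
learning rates, no distinction between vertical and horizontal
transmission, and mass-action (well-mixed) encounters with no spatial or
network structure. The stochastic counterpart inherits all of these: it
validates the mean-field mathematics, not the realism of mass action.
Passing checks therefore show internal consistency of the model family,
not that any particular animal population follows it.
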