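---
title: "Adaptive two-type SIS epidemics: model, moment closure, and thresholds"
author: "adaptivesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive two-type SIS epidemics: model, moment closure, and thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptivesis)
```

## The model

`adaptivesis` studies a susceptible–infected–susceptible (SIS) epidemic on
a contact network of $N$ agents and $K$ bidirectional links in which the
agents differ in an *intrinsic, immutable* susceptibility and *rewire*
their contacts away from infected neighbours.  Two types are
distinguished: type A (fraction $p_a$, susceptibility multiplier
$\psi_a$) and type B (fraction $p_b = 1 - p_a$, multiplier $\psi_b$), with
$\psi_a \ge \psi_b > 0$ so that A-agents are the more susceptible ones.
Three continuous-time Markov processes drive the dynamics:

* **recovery** — every infected node returns to the susceptible state at
  rate $\mu$;
* **contact avoidance** — every link joining a susceptible to an infected
  node ("active link") is rewired at rate $\omega$: the susceptible end
  cuts the link and reconnects to a randomly chosen other susceptible
  node;
* **contagion** — along every active link the disease is transmitted at
  rate $\beta\,\psi_i$, where $i$ is the type of the susceptible end.

Because rewiring responds to the epidemic state while the epidemic spreads
over the rewired structure, a feedback loop couples topology and dynamics:
an *adaptive network*.  The phenomena of interest are (i) bistability
between extinct and endemic states, bounded by a *persistence threshold*
$\beta_{per}$ (a fold bifurcation) and an *invasion threshold*
$\beta_{inv}$ (a transcritical bifurcation); (ii) the dependence of the
invasion threshold on the link configuration left behind by a previous
epidemic, which splits it into an *initial* (random-mixing) and an
*adapted* value; and (iii) the self-organization of degree heterogeneity:
resistant agents accumulate links until the degree ratio $k_b/k_a$
approaches $\sqrt{\psi_a/\psi_b}$.

### Parameters, units, defaults

All rates are per unit time in arbitrary but consistent units; `beta` is
per active link, `mu` per infected node, `omega` per active link.  The
working parameter set used throughout the documentation and tests is

```{r}
p <- model_params(beta = 0.032, psi_a = 0.65, psi_b = 0.05, p_a = 0.75,
                  mu = 0.002, omega = 0.2, n_nodes = 1e5, n_links = 1e6)
p
```

i.e. slow recovery, fast rewiring, mean degree $\langle k \rangle = 2K/N =
20$, and a strongly heterogeneous population whose *mean* susceptibility
is $\langle\psi\rangle = p_a\psi_a + p_b\psi_b = 0.5$.  When comparing
populations of different heterogeneity we hold $\langle\psi\rangle$ fixed
and solve the composition from it
(`solve_pa_for_mean_susceptibility()`); $\langle\psi\rangle = 0.5$ is the
package's default balance point, chosen because the parameter set above
realizes it, and it is a free input everywhere.

## Conventions: ordered pair densities

Pair approximations are conventionally written in *unordered* link
densities where same-class pairs such as $[S_aS_a]$ count each link once;
that convention drags symmetry bookkeeping factors through every equation,
and for palindromic triplet chains (equal outer classes, distinct middle)
the factor assignment is ambiguous.  Internally this package therefore
uses the *ordered* convention: every undirected link contributes two
ordered pairs, so the twelve state variables are the infected fractions
$[I_a], [I_b]$ and ten ordered link densities (`SS_aa`, `SS_ab`, `SS_bb`,
`SI_aa`, `SI_ab`, `SI_ba`, `SI_bb` with the susceptible end first,
`II_aa`, `II_ab`, `II_bb`), normalized per node.  In this convention all
symmetry factors are absorbed; the unordered presentation remains
available as an I/O view through `to_paper_convention()` /
`from_paper_convention()` (same-class densities are exactly halved /
doubled, and the two views round-trip bit-exactly).

Two conservation laws hold: $[I_u] + [S_u] = p_u$ per type, and the
ordered link total equals $\langle k\rangle$, so 11 of the 12 stored
numbers are independent.

## The moment-closure system

Writing $S_u = p_u - I_u$, $G_u = \sum_v SI_{uv}$ (active links anchored
on type-$u$ susceptibles), $W_u = G_u / S_u$ (mean infected pressure per
type-$u$ susceptible), and $S = S_a + S_b$, the right-hand side
implemented in `moment_rhs()` is, for $u, v \in \{a, b\}$:

$$\dot I_u = -\mu I_u + \beta \psi_u G_u$$
$$\dot{SS}_{uv} = \mu (SI_{uv} + SI_{vu})
  - \beta \psi_v SS_{uv} W_v - \beta \psi_u SS_{uv} W_u
  + \omega \frac{G_u S_v + G_v S_u}{S}$$
$$\dot{SI}_{uv} = \mu II_{uv} - (\mu + \beta\psi_u + \omega) SI_{uv}
  + \beta \psi_v SS_{uv} W_v - \beta \psi_u SI_{uv} W_u$$
$$\dot{II}_{uv} = -2\mu II_{uv}
  + \beta(\psi_u SI_{uv} + \psi_v SI_{vu})
  + \beta \psi_u SI_{uv} W_u + \beta \psi_v SI_{vu} W_v$$

Term by term: recovery converts active links into susceptible–susceptible
links and infected–infected links into active ones; transmission *inside*
an active link converts it into an infected pair; transmission from a node
*external* to a pair is a triplet-chain effect, closed at the pair level
by `closure_triplet()`, $[X_u Y_v Z_w] = [X_uY_v][Y_vZ_w]/[Y_v]$ (the
standard pair approximation; the focal link is not subtracted from the
neighbour sum); rewiring destroys active links and creates
susceptible–susceptible links whose new partner is type $v$ with
probability $S_v/S$.  The closure is what truncates the moment hierarchy:
it assumes neighbours of a shared middle node are uncorrelated beyond
pair statistics.

Summing the ordered link derivatives with multiplicities gives zero
identically, so link conservation is exact in the algebra, not just in the
integrator; the tests verify both.

### Numerical choices

* **Denominator guards.**  Whenever $S_u < 10^{-12}$ every term carrying
  $1/S_u$ is set to zero.  The numerators vanish at least as fast, and the
  guard makes the extinct plane *exactly* invariant in floating point
  (`moment_rhs(disease_free_state(p), p)` is identically zero).
* **Independent coordinates.**  Newton and continuation run in 11
  coordinates with `SS_bb` reconstructed from link conservation, so every
  iterate satisfies the constraint exactly instead of drifting and being
  projected back.  The integrator (`integrate_moments()`, lsoda via
  deSolve, `rtol = 1e-10`) runs in the full 12 and its conservation drift
  is monitored against `10 * rtol * <k>`; undershoots below zero but above
  `-atol` are clipped and counted.
* **Derivatives.**  Jacobians come from complex-step differentiation of
  the purely arithmetic right-hand side (step $10^{-20}$): machine-precision
  derivatives with no subtractive cancellation, validated against central
  finite differences in the tests.
* **Rank-deficient limits.**  Without rewiring ($\omega = 0$) the
  per-type-pair link totals are individually conserved and the reduced
  Jacobian is structurally singular; Newton then falls back to a
  minimum-norm (pseudoinverse) step, which converges to the steady state
  on the conserved leaf of the initial guess.

## Thresholds and continuation

With no infected, *any* susceptible–susceptible configuration is
stationary: the extinct states form a two-parameter plane, and the full
Jacobian always has neutral directions there.  Invasion is therefore
decided by the 7-dimensional linear subsystem of the infected link classes
(4 `SI` + 3 `II`) assembled by `infected_subsystem_matrix()`; the
infectivity at which its leading eigenvalue crosses zero is found by
bisection to a relative tolerance of $10^{-8}$
(`invasion_threshold_at()`).  In the homogeneous limit
$\psi_a = \psi_b = \bar\psi$ at the random-mixing configuration the
aggregated $2\times2$ determinant condition collapses to the closed form
$\beta^* = (\mu + \omega) / (\bar\psi \langle k\rangle)$ — with
$\mu = 0.002$, $\omega = 0.2$, $\bar\psi = 0.5$, $\langle k\rangle = 20$
this is $0.0202$, which the package reproduces to $10^{-6}$ relative and
uses as an oracle in its tests.

`continue_branch()` is a pseudo-arclength predictor–corrector: secant
predictor, bordered-system Newton corrector, adaptive step halving and
growth, with link densities normalized by $\langle k\rangle$ and $\beta$
by its starting value.  The endemic branch is continued downward from a
relaxed-and-polished endemic state; the *persistence threshold* is the
fold, detected by the sign change of the $\beta$ increments along
arclength and refined by a parabolic fit of $\beta$ against local
arclength (`persistence_threshold()`).  Past the fold the unstable branch
is followed toward vanishing prevalence by natural continuation in the
total prevalence $c = I_a + I_b$ (solving the 11 equilibrium equations
plus $I_a + I_b = c$ for the state *and* $\beta$, halving $c$ to
$10^{-6}$), and the landing configuration on the extinct plane is obtained
by linear extrapolation in $c$ — near a transcritical crossing $\beta(c)$
is smooth, so the extrapolation error is $O(c^2)$.  The *adapted invasion
threshold* is then re-derived as the linearized threshold of the landing
configuration; agreement between the extrapolated and re-derived values
(typically within $10^{-8}$ relative) is a mandatory self-consistency
check (`adapted_invasion_threshold()`).

At the working parameter set the pipeline gives
$\beta_{per} \approx 0.0125 < \beta_{inv}^{initial} = 0.0202 <
\beta_{inv}^{adapted} \approx 0.0427$ (all three recomputed by
`threshold_report()` and by `scripts/acceptance.R`): adaptation roughly
doubles the invasion threshold, and in the homogeneous limit the two
invasion thresholds coincide because the extinct state is unique at pair
level.

## Mean-field predictions

On the population level, rewiring drains links from frequently infected
types and hands them to susceptible ones.  Two balance relations pin the
stationary degree ratio $q = k_b/k_a$: per-type rewiring balance makes
$[I_i]/[S_i]$ a common multiple of $1/k_i$, and mean-field epidemic
balance makes it a common multiple of $\psi_i k_i$.  Eliminating the
common factors across types yields $\psi_a k_a^2 = \psi_b k_b^2$, i.e.

$$\frac{k_b}{k_a} = \sqrt{\frac{\psi_a}{\psi_b}}$$

(`predict_degree_ratio()`), strictly between the homogeneous value 1 and
the equal-risk value $\psi_a/\psi_b$ whenever $\psi_a > \psi_b$.  For the
working set this is $\sqrt{13} \approx 3.606$; the endemic fixed point of
the full moment system gives $3.646$, within 1.2%.

The *link reproductive number* $Z_0(q)$ estimates the expected number of
secondary active links created by transmission along one focal active
link in the low-prevalence limit: the link ends on a type-$i$ susceptible
with probability $\propto p_i k_i$, infection proceeds at rate
$\propto \psi_i$, and the fresh infected contributes $\propto k_i$ new
active links, under the constraint $\langle k \rangle = p_a k_a + p_b
k_b$ fixed.  The package fixes the overall prefactor as
$\beta/(\mu+\omega)$ — transmission relative to the two rates that
deactivate a link — and treats it as a convention: every shipped
conclusion (the minimizer, the orderings) is prefactor-invariant, which
the tests assert directly.  Minimizing over $q$ (log-grid scan, Brent,
and a final exact parabolic polish in $\log q$) yields $q^* =
\psi_a/\psi_b$, the Lagrange point $\psi_a k_a = \psi_b k_b$ where both
types are infected at the same rate.  Note that at fixed mean degree
$Z_0$ does not diverge as $q \to \infty$: $k_b$ saturates at
$\langle k\rangle / p_b$, so $Z_0$ grows monotonically beyond $q^*$
toward a finite ceiling.  Since $\sqrt{\psi_a/\psi_b} < \psi_a/\psi_b$,
the self-organized network always sits below the most robust ratio, in
the regime where extra degree heterogeneity is still stabilizing.

## The stochastic simulator and what it emulates

`gillespie_run()` is an exact event-driven simulation (compiled core) of
the three channels, with category-level rate sums and uniform selection
within categories, an incrementally maintained active-link registry
(auditable at every sample time against a full rescan via
`debug_check = TRUE`), and R's own RNG so that `set.seed()` governs
reproducibility.  Networks are initialized as Erdős–Rényi $G(N, K)$
graphs — exactly $K$ distinct edges, Poissonian degrees — with types and
epidemic states assigned uniformly and independently
(`generate_er_network()`, `assign_initial_condition()`).  This generator
*is* the study condition: a maximally random, uncorrelated contact
structure.  It deliberately lacks features of real contact networks —
clustering, communities, broad intrinsic degree distributions,
assortativity — so passing tests certify the model's internal
consistency, not realism of any particular epidemic.

Design choices the process description leaves open are resolved as
follows and exposed as arguments:

* **Rewiring targets** are drawn uniformly from susceptibles excluding
  the rewiring node and its current neighbours (the graph stays simple);
  an event with no eligible target is a no-op that leaves the link
  intact.  A lone susceptible therefore cannot rewire.
* **Stationarity** (`run_to_stationarity()`): prevalence means of two
  consecutive windows of $50/\mu$ time units must agree within two
  batch-means standard errors; one further window is then averaged for
  the summary.  The criterion is scale-free in $\mu$ and detects drift;
  a configurable hard cap ($10^5$ time units) bounds the cost.
* **Simulated invasion thresholds**
  (`estimate_invasion_threshold_sim()`): "the epidemic can no longer be
  stopped" is operationalized as the extinction probability over `n_runs`
  independent runs dropping below `p_cut` (default 0.05, configurable,
  since any sharp cut is a convention), located by bisection.  Runs are
  simulated until extinct or clearly established (prevalence above 5%).
  The reported bracket spans from the largest probed infectivity at which
  *every* run died out to the smallest at which the criterion held —
  below the transcritical point establishment is impossible, so any
  establishment certifies the threshold has been passed.

Exact validation: on graphs small enough to enumerate ($N \le 4$), the
simulator's outcome distributions are checked against a brute-force
master equation over all (edge set, epidemic state) pairs — including
rewiring — built independently in the test helpers and exponentiated with
`Matrix::expm`.

## Problem sizes used in the tests

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each claim is meaningfully testable: exact
oracles at $N \le 4$; protocol and property checks at $N = 10^3$–$2\cdot
10^3$; quantitative ODE–simulation comparisons at $N = 5\,000$–$10^4$
with $\langle k\rangle = 20$ (the endemic-prevalence comparison passes
within 10% already at $N = 10^4$).  The study-scale configuration
($N = 10^5$, $K = 10^6$) is fully supported and is the default of
`model_params()` documentation examples, just not exercised routinely.

## Known limitations

* **Finite-size suppression of self-organized heterogeneity.**  At the
  working rates the endemic branch lives above 93% prevalence, so the
  susceptible pool is a few percent of $N$.  For $N \lesssim 10^4$ the
  simple-graph constraint saturates the susceptible–susceptible
  neighbourhood of the resistant hubs and throttles their link
  accumulation: at $N = 5\,000$ the stationary simulated degree ratio
  plateaus near 2.4, versus 3.65 for the moment system; at $N = 2\cdot
  10^4$ it reaches ≈ 3.3 and at $N = 4\cdot 10^4$ ≈ 3.5, consistent with
  the $\sqrt{13}$ prediction at $N = 10^5$.  Consequently the *measured*
  invasion threshold of a small adapted network sits below the
  moment-system landing value (≈ 0.031 vs 0.0427 at $N = 5\,000$).
  Quantitative degree-ratio and adapted-threshold comparisons therefore
  need $N \gtrsim$ a few $10^4$; the package reports both sides honestly
  rather than hiding the gap.
* **Pair approximation.**  The closure neglects correlations beyond
  pairs; it captures the fold/transcritical structure here but is known
  to fail for fragmentation-type transitions, and its accuracy degrades
  in the very-high-prevalence regime where the susceptible subgraph is
  tiny and strongly correlated.
* **Two types only.**  The implementation is strictly two-type; the
  moment system generalizes mechanically but nothing in the API does.
* **No oscillation analysis.**  Fold and transcritical points are
  detected; Hopf bifurcations and epidemic cycles are out of scope, as is
  any model variant with per-node rewiring rates.
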