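---
title: "Methods: a discrete-time individual-based model of growth and diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a discrete-time individual-based model of growth and diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fkibm)
```

## The model

`fkibm` simulates a population of discrete individuals on a lattice in
discrete time.  At every time step of length $\tau$, **every individual
simultaneously and independently** decides on three actions, based only on
the state of the system at the start of the step:

* **movement** — with probability $P_{move}$ the individual steps to a
  uniformly chosen neighbour slot (2 on a line, 4 on a rectangular grid, 6
  on a hexagonal grid).  A slot that is masked as inhabitable or lies
  outside the confined domain makes the individual stay, so the
  per-open-direction probability is always $P_{move}/n_{neighbors}$;
* **birth** — with probability
  $\beta(N) = b_0 - (b_0 - \theta)\,N/K$, where $N$ is the count in the
  individual's cell, a newborn appears in that cell;
* **death** — with probability
  $\delta(N) = d_0 + (\theta - d_0)\,N/K$ the individual is removed.

At $N = K$ both rates equal the turnover $\theta$, so $K$ is the
deterministic carrying capacity while $\theta$ fixes how much birth-death
churn (and hence demographic noise) persists at equilibrium.  Because the
update is synchronous and based on the start-of-step state, the expected
one-step change of the pure growth term is exactly one Forward-Euler step
of the logistic equation with $r = (b_0 - d_0)/\tau$, and the expected
change of the pure movement term is one Euler step of the diffusion
equation with

$$D = P_{move}\,\frac{\langle \Delta x_{axis}^2\rangle}{2\tau},$$

the per-axis second moment of a single hop.  On the line and the square
grid this reduces to the familiar $D = P_{move}\,\Delta x^2 /
(n_{neighbors}\,\tau)$; on the hexagonal grid the mean of $\cos^2$ over the
six directions gives $D = P_{move}\,\Delta x^2/(4\tau)$.  We use the
variance-based form throughout because it is the one under which the
hexagonal parameter sets of the large-scale dispersal scenario
($P_{move} = 0.2$, $\Delta x = 60$ km, $\tau = 1$ yr, and its
rescaled variants) all reconcile to the same $D \approx 180$ km²/yr; the
naive $1/6$ direction factor does not.

Combining the two terms yields a stochastic Fisher–Kolmogorov (FK)
growth-diffusion model whose continuum limit
($\tau \to 0$, $\Delta x \to 0$, $K \to \infty$) is

$$\partial_t \rho = D \nabla^2 \rho + r \rho (1 - \rho/K),$$

with travelling-wave solutions of minimal deterministic speed
$v_{det} = 2\sqrt{D r}$.

## Exact structure of the growth update

With independent per-individual Bernoulli decisions, the number of births
and deaths in a cell are independent binomials over the $N$ start-of-step
individuals, so the one-step transition kernel is the convolution

$$T(M\mid N) = \sum_{b - d = M - N} \binom{N}{b}\beta^b(1-\beta)^{N-b}
\binom{N}{d}\delta^d(1-\delta)^{N-d},$$

supported on $M \in [0, 2N]$ — no more than $N$ individuals can be born
because each individual spawns at most once per step.
`transition_kernel()` implements this exactly and `master_equation_step()`
iterates the induced distribution over $N$ (truncated at $N_{max} = 4K$ by
default, with the leaked mass monitored and reported).

Two conventions make the kernel well defined where the linear rates leave
the unit interval:

* when the raw $\beta$ turns negative (possible for
  $N > b_0 K/(b_0 - \theta)$), the excess is folded into mortality,
  $\delta^* = |\beta| + \delta$ with $\beta^* = 0$, which preserves the
  expected change $(\beta - \delta)N$ and hence the logistic limit;
* $\delta^*$ is clamped to 1 (and $\beta^*$ to 0); both clamps are only
  reachable far above $K$.

Two further conventions pin down the individual-level bookkeeping, which
the aggregate description leaves open:

* deaths are drawn among the $N$ original individuals only — newborns can
  neither die nor reproduce in their birth step (this is what makes the
  death binomial a $\binom{N}{d}$ term);
* a dying individual can still produce a newborn in the same step: the
  birth and death draws are independent.

## The effective carrying capacity

The mean steady-state population of the stochastic model sits *below* $K$:
fluctuations interact with the concavity of the logistic map.  A
Renshaw-style second-order estimate for the binomial update gives

$$\langle N\rangle \approx K - \frac{2\theta(1-\theta)}{2r - r^2},$$

implemented in `effective_K_approx()`.  Written in terms of
$\alpha = \theta/b_0$ (with $d_0 = 0$) the deviation is
$f = 2\alpha(1-\alpha b_0)/(2 - b_0)$ (`deviation_term()`): every curve
over $b_0$ passes through $f = 1/2$ at $\alpha = 1/2$ — so at
$\theta = b_0/2$ the deviation is exactly half an individual regardless of
the update frequency — and for $b_0 > 0.5$ the deviation is maximal where
$\alpha b_0 = 1/2$, because a binomial is noisiest at success probability
one half.  This is why *slowing the clock down* (reducing $b_0$ and
$\theta$ at fixed ratio) can either increase or decrease the noise
depending on which side of that maximum the system sits.

`estimate_effective_K()` measures $\langle N\rangle$ by simulation: 100
realizations (50 in the scaled presets) of 500 steps from $N_0 = K$,
discarding a 100-step burn-in, averaging over time and realizations.  The
burn-in length is our choice (the transient decays on a $1/r$ timescale,
and 100 steps cover it for every default parameter set); sensitivity to it
is exposed as an argument.  Realizations that hit the absorbing state
$N = 0$ are excluded from the average and their number is reported — a
quasi-stationary reading; with $d_0 = 0$ and $K \ge 10$ exclusions are
rare, and whether the reference results conditioned on non-extinction is
not stated, so the exclusion rule is a documented package choice.

## Front speeds

The wave experiments track the front position $x_{K/2}$, the rightmost
point where the ($y$-averaged, in 2-D) profile crosses $K/2$, linearly
interpolated between the bracketing cells.  The speed is the least-squares
slope of $x_{K/2}(t)$ after discarding the first half of the trace (the
stabilisation window is configurable; the transient before linear motion
has no sharp endpoint, and discarding 50% is conservative for runs stopped
when the population reaches $x \approx 300$).

For an exponential front profile $e^{-\gamma x}$ the synchronous update
has the dispersion relation

$$v(\gamma) = \frac{1}{\gamma\tau}\,
\ln\!\left[1 + D'(e^{-\gamma\Delta x} - 1) + D'(e^{\gamma\Delta x} - 1)
+ (b_0 - d_0)\right],\qquad D' = \frac{P_{move}}{n_{neighbors}},$$

and the realised ("pulled") front travels at its minimum over $\gamma$.
`minimal_dispersion_speed()` finds $\gamma_0$ by bracketed scalar
minimisation (tolerance $10^{-10}$) and the curvature $v''(\gamma_0)$ by
Richardson-extrapolated central differences (base step $10^{-4}$, checked
against the doubled step).  Two limit behaviours are worth stating because
they differ from continuum intuition:

* $v(\gamma) \to \Delta x/\tau$ (the lattice speed limit) as
  $\gamma \to \infty$ — it does not diverge; the interior minimum exists
  whenever $v_{min} < \Delta x/\tau$;
* $\min_\gamma v(\gamma) \to v_{det}$ when the growth probability is
  decreased *at fixed movement*, since then $\gamma_0 \to 0$ and the
  lattice corrections vanish.  Halving $b_0$ and $P_{move}$ *jointly*
  keeps $\gamma_0 \Delta x$ fixed, so a small discreteness offset survives
  in that limit; the convergence tests therefore decrease $b_0$ alone.

For finite $K$ the leading edge of the wave is made of few individuals and
the front is slowed.  The package uses the standard second-order cutoff
correction

$$v = v(\gamma_0) - \frac{\pi^2 v''(\gamma_0)}{2 L^2},
\qquad L = \frac{\ln K}{\gamma_0}\ \text{by default},$$

where only the logarithmic dependence of $L$ on $K$ is established; the
prefactor form is declared, not derived, and is kept configurable.  The
correction decays like $1/(\ln K)^2$ — slowly — and for very small $K$ the
expansion can undershoot (even below zero); there it is indicative only.

## The simulator step and its mean field

One growth-diffusion step (`step_growth_diffusion()`) applies, per cell:
births and deaths drawn from the start-of-step count; the survivors move
with per-direction probability $P_{move}/n_{neighbors}$ (blocked
directions stay); newborns remain in the natal cell until the next step.
The movement split across directions is drawn as a sequence of conditional
binomials, cell-major, so runs are bit-reproducible given the seed.

Replacing every draw by its expectation (`deterministic = TRUE`) yields an
explicit finite-difference scheme for the FK equation in which transported
mass carries the survival factor $(1-\delta)$:

$$N_i' = \beta_i N_i + (1 - P_{move}) S_i +
\frac{P_{move}}{n}\sum_{j \sim i} S_j,\qquad S_i = (1-\delta_i) N_i.$$

The decoupled limits are the textbook Euler schemes exactly: with
$P_{move} = 0$ the map is Forward-Euler logistic growth, and with growth
switched off it is Forward-Euler diffusion.  In the combined step the
survival-weighted transport differs from the naive additive Euler scheme
by an $O(P_{move}\,\delta)$ flux term; this is a property of the
individual-level protocol (an individual cannot both die and survive to
move), and the package's tests verify the mean field against an
independently coded integrator of the survival-weighted scheme to
$10^{-9}$, rather than pretending the additive scheme is reproduced
exactly.

## Habitability masks and anisotropy

Masked cells and off-domain slots are treated identically ("confined"
boundary): a single blocked-slot mechanism covers geography and domain
edges, which is also what the per-open-direction invariance requires.  The
resulting effective movement probability near blocked cells is

$$P_{move}^{\,eff} = P_{move}\,\frac{N_{tot} - N_{inaccess}}{N_{tot}},$$

(`effective_move_probability()`), the unique linear rescaling that leaves
the per-open-direction probability — and hence the diffusion coefficient
along open directions — unchanged.  `run_masked_demo()` exercises this on
a synthetic corridor mask (a wall with a one-cell gap) and records
per-cell first-colonisation times; it is a demonstration of the mechanism
on synthetic geography, not a geographic reconstruction (no spherical
grid, no paleo-topography; the 12 pentagonal cells of an icosahedral
tessellation are out of scope, and the hexagonal lattice here is planar).

## What the experiments emulate — and what they do not

The experiment drivers regenerate the idealised, desk-scale study
conditions:

* `run_table1()`: 3000 independent 1-D walkers, 500 steps,
  $\Delta x = \tau = 1$, $P_{move} \in \{1, 2/5, 1/5\}$ — the
  variance-slope estimate of $D$ against the microscopic value;
* `run_growth_sweep()`: single-cell growth at
  $K \in \{10, 50, 100, 500\}$, $b_0 \in \{0.8, 0.3\}$ with turnovers
  $\{0.7, 0.4, 0.08, 0.008\}$ and $\{0.2625, 0.15, 0.03, 0.003\}$,
  $d_0 = 0$, $N_0 = K$, 500 steps — the effective-carrying-capacity
  surface;
* `run_speed_sweep()`: waves at $D = 0.2$, $\theta = 0.1\,b_0$, $d_0 = 0$,
  point seed (1-D, domain 1000 cells) or line seed (2-D, 1000×100,
  $N_0 = K$ per seeded cell), stopped when the population reaches
  $x \approx 300$, ten repetitions per set (five or fewer in the scaled
  presets, with correspondingly wider Monte-Carlo error).

All inputs are synthetic; nothing is fitted to field data.  Passing tests
therefore show internal consistency of the stochastic model, its exact
kernel, and its analytic approximations — they do not validate the model
against real population data, where age/sex structure, non-linear density
dependence, group living and environment-dependent parameters (all out of
scope here) matter.

## Numerical choices

* Degenerate inputs: an empty cell is absorbing for growth
  ($T(0\mid 0)=1$); a fully blocked neighbourhood freezes a walker;
  an all-zero profile has no front (reported as missing, not an error).
* Walker-cloud runs intended as free diffusion use domains wide enough
  that no walker can reach the edge within the simulated horizon
  (width $2\,n_{steps}+$ margin); reaching the boundary raises a warning.
* Master-equation truncation at $N_{max} = 4K$; per-step leak monitored
  against $10^{-10}$ and warned about with its magnitude.
* Seeding: each experiment takes one master seed; per-realization streams
  are derived with a fixed counter hash (`derive_seed()`), so realization
  $i$ is reproducible in isolation and all results are bit-identical for
  identical (config, seed).
* Problem sizes in the shipped tests are scaled to desk hardware: 50–60
  growth realizations, 3–5 wave repetitions, the reduced speed grid
  $K \in \{10, 50, 100, 500\}$, $b_0 \in \{0.8, 0.1\}$.  The package's own
  statistical allowances (3–4 standard errors, chi-square at
  $\alpha = 0.01$) reflect those sizes.

## Known limitations

* The effective-carrying-capacity formula is a second-order estimate; at
  very small $K$ (≈10) with violent turnover it deviates from the exact
  master-equation mean by more than its nominal accuracy, which is why the
  tests compare simulation, master equation and formula at matched
  parameters instead of trusting any single route.
* The cutoff form $L = \ln K / \gamma_0$ is one defensible choice; only
  the $\ln K$ dependence is established, and predicted absolute speeds at
  small $K$ should be read qualitatively.
* Strong-noise regimes (kink-like fronts at very small $K$ and large
  $b_0$) are simulated faithfully but not analysed further here.
* Time-varying masks are possible mechanically (rebuild the lattice
  between steps) but no loader or scheduler for environmental time series
  is provided.
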