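---
title: "Fractional-order network dynamics of amyloid, tau, astrocytes and neuronal damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional-order network dynamics of amyloid, tau, astrocytes and neuronal damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadnet)
```

## The model

`fadnet` simulates the joint dynamics of five fields at each location of the
brain: healthy amyloid-beta $u$, toxic amyloid-beta $\tilde u$, healthy tau
$v$, toxic tau $\tilde v$, and activated astrocytes $w$, together with a
neuronal damage index $q \in [0, 1]$.  The reaction kinetics follow a
heterodimer scheme — a toxic protein converts its healthy counterpart on
contact — with logistic growth for the healthy pools and an astrocyte
compartment that can either clear or amplify toxic amyloid:

$$
\begin{aligned}
u_t &= u(a_0 - a_1 u) - a_2 u \tilde u, \\
\tilde u_t &= -\tilde a_1 \tilde u + a_2 u \tilde u - \mu \tilde u (w - \tilde u), \\
v_t &= v(b_0 - b_1 v) - b_2 v \tilde v - b_3 \tilde u v \tilde v, \\
\tilde v_t &= -\tilde b_1 \tilde v + b_2 v \tilde v + b_3 \tilde u v \tilde v, \\
w_t &= w(c_0 - w / c_1),
\end{aligned}
$$

and damage accumulates irreversibly from the toxic loads,

$$
q_t = (1 - q)\,(k_1 \tilde u + k_2 \tilde v + k_3 \tilde u \tilde v + k_4 q).
$$

The $\mu\tilde u(w - \tilde u)$ term carries the astrocytes' dual role: when
astrocytes outnumber toxic amyloid ($w > \tilde u$) the term clears
$\tilde u$; when toxic amyloid dominates, the same interaction amplifies it.
All quantities are nondimensional; there is no unit-conversion layer.

Non-Markovian "memory" enters by replacing the time derivative with the
Caputo fractional derivative of order $\alpha \in (0, 1]$,
$$
D^\alpha_t z(t) = \frac{1}{\Gamma(1-\alpha)} \int_0^t
  \frac{z'(s)}{(t-s)^\alpha}\, ds,
$$
which weights the whole past of the state with a power-law kernel.
$\alpha = 1$ recovers the ordinary (memoryless) system.  The damage equation
uses the same order $\alpha$ as the concentration equations.

### Default parameters

`ad_params()` returns the synthetic secondary-tauopathy parameter set used
throughout ($a_0 = 1.035$, $a_1 = a_2 = 1.38$, $\tilde a_1 = 0.828$,
$b_0 = 0.69$, $b_1 = 1.38$, $b_2 = 1.035$, $\tilde b_1 = 0.552$,
$b_3 = 4.14$, $c_0 = 1$, $c_1 = 0.1$, $\mu = 0.1$, $k_1 = 10^{-4}$,
$k_2 = 10^{-2}$, $k_3 = 0.1$, $k_4 = 10^{-3}$, diffusivities
$\rho_u = 1.38$, $\rho_{\tilde u} = 0.138$, $\rho_v = 1.38$,
$\rho_{\tilde v} = 0.014$).  The four diffusivities are assigned to
$(u, \tilde u, v, \tilde v)$ in listing order; the assignment is
configurable should a different convention be needed.  With these values
toxic tau cannot invade on its own ($b_2 b_0 / b_1 = 0.5175 < \tilde b_1$),
so the set is *secondary* tauopathy: tau toxicity is driven by the amyloid
coupling $b_3$.  `classify_tauopathy()` applies exactly this invasion
condition, with the boundary case classified as secondary.

## Equilibria and stability

Because the system factorizes, its equilibria are enumerated exactly by a
branch cascade rather than multistart root finding: $u$ is zero or on the
logistic branch; $\tilde u$ is zero or solves
$a_2 u - \mu(w - \tilde u) = \tilde a_1$; $w$ is $0$ or $c_0 c_1$; and
$(v, \tilde v)$ is $(0,0)$, $(b_0/b_1, 0)$, or the interior pair.  Every
nonnegative candidate is polished by damped Newton iteration on the analytic
Jacobian to a residual below $10^{-10}$ and deduplicated at $10^{-8}$;
branch roots with negative components are excluded and reported separately.
For the default parameters the cascade yields the unique all-positive point
$(0.596094, 0.153906, 0.330110, 0.140206, 0.1)$, and long seeded
integrations converge to the same point, which serves as an independent
dynamical cross-check in the tests.

Stability uses the analytic $5 \times 5$ Jacobian (verified against centered
finite differences).  At $\alpha = 1$ a point is stable iff all eigenvalues
have negative real part; for $\alpha < 1$ the argument (Matignon-type)
condition $|\arg \lambda_i| > \alpha \pi / 2$ applies.  The reported margin
is $-\max \mathrm{Re}\,\lambda$ or $\min |\arg \lambda| - \alpha\pi/2$;
margins within $10^{-9}$ of zero are labelled *marginal* rather than stable,
since the numerical eigenproblem cannot certify strict inequality there.
The argument condition is monotone in $\alpha$, so stability at some
$\alpha_1$ implies stability at every smaller order.

## Time integration

Two integrators are provided, with transparent R reference implementations
(`solve_rk4`, `solve_caputo_pc`) and compiled fast paths used by
`simulate_local`, `simulate_damage` and `simulate_network`:

* **RK4** (classical fourth order, fixed step) for $\alpha = 1$.  The default
  step is $dt = 0.01$; results are step-size-converged at this value for the
  default parameter set, and the suite verifies fourth-order error decay.
* **Caputo Adams–Bashforth–Moulton predictor–corrector** for
  $0 < \alpha < 1$: a fractional Adams–Bashforth predictor with convolution
  weights $(n+1-j)^\alpha - (n-j)^\alpha$ followed by one Adams–Moulton
  corrector pass with weights
  $(n-j+2)^{\alpha+1} + (n-j)^{\alpha+1} - 2(n-j+1)^{\alpha+1}$, scaled by
  $dt^\alpha/\Gamma(\alpha + 1)$ and $dt^\alpha/\Gamma(\alpha+2)$
  respectively.  The initial condition sits at $t = 0$ with no pre-history.
  The full memory kernel is retained — no short-memory truncation — so cost
  grows as $O(M^2)$ in the number of steps; the compiled path stores the
  reversed kernels so each step is a single BLAS matrix–vector product.
  $\alpha = 1$ dispatches to RK4 exactly.

The solver is validated against the Mittag-Leffler function
$E_\alpha(-t^\alpha)$, the exact solution of the linear Caputo relaxation
problem, evaluated by `mittag_leffler()` via machine-precision series
summation and cross-checked against the closed form
$E_{1/2}(-x) = e^{x^2}\mathrm{erfc}(x)$.

**Step sizes for fractional runs.**  The predictor–corrector is explicit in
character, so its stable step shrinks with both the Laplacian spectral
radius and the order $\alpha$.  On the synthetic 200-node connectome the
package's studies use $dt = 0.05$ for $\alpha \in \{0.9, 0.8\}$ (halving
the step changes the state by about $4\times10^{-6}$ sup-norm, while
$dt = 0.1$ is unstable at $\alpha = 0.8$), and $dt = 0.01$ for the RK4
baseline.  The slowly relaxing driven damage equation uses larger steps
($dt = 0.25$) over its very long horizons; the dynamics there evolve on
time scales of hundreds, and halving the step changes the endpoint by
under $10^{-8}$.

A note on horizons: at $\alpha = 1$ the damage variable approaches its
absorbing state $q = 1$ exponentially (within 0.01 by $t \approx 1100$ under
equilibrium toxic loads), but for $\alpha < 1$ the approach is algebraic,
$1 - q \sim t^{-\alpha}$, so reaching the same neighbourhood at
$\alpha = 0.8$ takes a horizon of order $10^4$–$10^5$.  The tests integrate
to $t = 6 \times 10^4$ for that check; this tail behaviour is an intrinsic
feature of Caputo relaxation, not a solver artifact.

## The connectome model

A connectome couples the nodes through graph-Laplacian diffusion.  From the
edge fiber statistics the adjacency is $A_{ij} = n_{ij} / l_{ij}^2$ (mean
fiber count over squared mean fiber length; with a single length per edge
the two readings of "mean length squared" coincide).  Each diffusing
species gets its own operator $L^{(s)} = \rho_s (D - A)$ with
$D = \mathrm{diag}(A\mathbf{1})$.  Two deliberate readings of the printed
network equations are made here, both verified by conservation properties:

* the diffusivity scales the whole operator, $L = \rho(D - A)$, because
  $\rho D - A$ has nonzero row sums for $\rho \neq 1$ and would create or
  destroy mass under pure diffusion;
* the coupling is the matrix–vector product $-(L^{(s)} y_s)_j$, since the
  alternative literal reading $-\sum_k L_{jk} y_j$ is not a diffusion
  operator and would not make homogeneous states stationary.

With these choices, reaction-free dynamics conserve each species total to
$10^{-10}$ and any homogeneous equilibrium of the local model is a network
fixed point — both are asserted in the test suite.  The astrocyte and
damage fields do not diffuse.

**Seeding.**  Runs start from the healthy baseline $u = 0.75$, $v = 0.5$
(the disease-free carrying capacities $a_0/a_1$ and $b_0/b_1$), astrocytes
$w = 0.1$ ($= c_0 c_1$), $q = 0$.  Toxic protein is introduced only at the
named seed territories: toxic amyloid (0.38% of the local healthy amyloid)
at temporobasal and frontomedial nodes, toxic tau (0.25% of local healthy
tau) at transentorhinal and brain-stem-associated nodes.  The percentages
are interpreted *relative* to the local healthy baseline — consistent with
the 1% convention of the sensitivity initial condition — with an absolute
mode available (`mode = "absolute"`).  Seed sets travel with the
`connectome` object and are serialized in its CSV form.

**Mixed tauopathy.**  `mixed_tauopathy_overrides()` expands a brain-ID
level specification of $(b_2, b_3)$ into per-node parameter overrides.  The
published heterogeneous values are deferred to external references and not
printed, so the package ships a documented synthetic default in its
examples: raising $b_2$ to 1.6 in the overridden territory, which flips
those nodes across the invasion threshold into primary tauopathy while the
rest of the graph stays secondary.  Because the toxic-tau diffusivity is
small ($\rho_{\tilde v} = 0.014$), regional identity dominates and the
overridden region settles at a visibly higher toxic-tau plateau.

## The synthetic connectome generator

The published whole-brain dataset (1015 nodes, 16,280 edges) is not
bundled; `generate_connectome()` produces graphs that emulate its summary
statistics so every pipeline stage is testable offline: edge density near
16 edges per node, fiber counts from a log-normal (meanlog
$\log 39.33 - \sigma^2/2$, $\sigma = 1.4$) clipped to $[1, 4966.5]$ — the
heavy tail is consistent with a maximum two orders of magnitude above the
mean — and lengths from a gamma (shape 9, mean 30.089 mm) clipped to
$[10.270, 83.003]$ mm.  Node geometry is cosmetic (region-clustered
Gaussian blobs on an ellipsoidal layout; edge probability decays with
distance on a 30 mm scale): the dynamics depend only on $(n_{ij}, l_{ij})$.
Graphs are augmented to connectivity by joining components at their closest
cross pair, and generation is byte-reproducible given the seed.

What the generator does *not* emulate: the true degree and weight
correlations of diffusion-MRI connectomes (hub structure, hemispheric
symmetry, community structure), realistic region adjacency, or the
empirical coupling between fiber length and Euclidean distance.  Passing
tests on synthetic graphs therefore demonstrate correctness of the
dynamics, seeding, averaging and ordering machinery — not quantitative
reproduction of trajectories on the real connectome, whose exact curves
require the real data loaded through `read_connectome()`.

## Sensitivity analysis

`run_sensitivity()` draws $n = 1000$ i.i.d. uniform samples within
$\pm 10\%$ of the nominal values, integrates the memoryless temporal model
(RK4, $dt = 0.01$) from $u_0 = 0.75$, $\tilde u_0 = 0.0075$, $v_0 = 0.5$,
$\tilde v_0 = 0.005$, $q_0 = 0$ to $t = 200$, and Pearson-correlates each
sampled parameter with each of the six outputs at that single time point.
Two configuration gaps are resolved as follows: the sampled set is the 16
local reaction/damage parameters (the diffusivities do not enter the
temporal model), and the astrocyte initial value, absent from the stated
condition, is $w_0 = 0.1$, its equilibrium.  Correlations are reported with
an explicit `NA` marker when an output has zero variance.  The sign of the
production-to-damage correlation ($a_0$ vs $q$) is positive and stable
across seeds, which the acceptance suite checks; correlation *magnitudes*
are seed-dependent at $n = 1000$ and are not asserted.

## Problem sizes used by the test suite

The suite exercises the full pipeline at desk scale: fixture graphs of 2–12
nodes for exactness checks (equilibrium preservation to $10^{-9}$ over
$t \in [0, 100]$; dual-role steady states matched to the closed form
$\tilde u^* = (a_2 a_0/a_1 - \tilde a_1 - \mu c_0 c_1)/(a_2^2/a_1 - \mu)$
to $10^{-6}$), and a 200-node synthetic connectome for the memory-effect
study ($\alpha = 1, 0.9, 0.8$; horizons 400–1000 chosen so the average
damage crosses one half within the window at every order).  The half-rise
times of average toxic tau and average damage increase strictly as $\alpha$
decreases — the memory effect delays propagation — with crossing times
interpolated linearly between stored samples.

## Known limitations

* The continuous-space PDE with diffusion tensors is out of scope; only its
  network discretization is implemented.
* Uniform time grids only; no adaptive or graded meshes, and no
  short-memory acceleration for the fractional kernel (cost is $O(M^2)$).
* The plain Mittag-Leffler series is restricted to $|z| \le 10$; it is a
  test oracle, not a general special-function implementation.
* Equilibrium enumeration is exhaustive for this system's factorized
  structure but is not a general-purpose polynomial solver.
* No fitting to patient data; parameters are the synthetic literature set.
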