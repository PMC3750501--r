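---
title: "Inverse circuit design by linearized specification maps: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse circuit design by linearized specification maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(specmap)
```

`specmap` turns a quantitative behavioral specification for a gene circuit
into a region of kinetic design parameters that realizes it. This vignette
is the package's own account of the underlying model and algorithm: the
assumptions it makes, the tunable parameters that matter and why their
defaults are what they are, the numerical choices, and what the shipped
case study does and does not demonstrate.

## The forward model

Dynamics are deterministic mass-action kinetics,
$\dot x = N\,v(x, k, u(t))$ with $x(0) = x_0 \ge 0$: $N \in \mathbb{Z}^{n
\times q}$ is the stoichiometric matrix, $v \ge 0$ the reaction flux
vector, $k \ge 0$ the rate parameters, and $u(t)$ a scalar,
piecewise-constant external input. This description presumes copy numbers
large enough that concentrations are meaningful — for transcriptional
circuits that means several gene copies, which is why the sensor fixture
defaults to a total promoter concentration of 10 nM rather than a single
gene. Stochasticity (intrinsic noise, plasmid copy-number variation) is
out of scope: the map from parameters to behavior is deterministic here.

Behavior is scored by a specification functional
$\psi(x) = \int_0^T g(s, x(s))\,ds \in \mathbb{R}^m$. The only smoothness
demanded of the kernel $g$ is once-differentiability in the state — enough
for the sensitivity calculus below, and deliberately weaker than what
temporal-logic specifications would require to be made differentiable.
Two families are built in:

* **weighted squared deviations** (`weighted_deviation_kernel()`):
  $\psi_i = \int w_i(s)\,[x_{j(i)}(s) - x^*_i(s)]^2\,ds$ with indicator
  windows $w_i$ and piecewise-constant targets $x^*_i$. Note the square:
  an integrated *absolute* deviation would express the same intent but is
  not differentiable where the trajectory crosses the target, so the
  squared form is the one the method can linearize. Units are nM²·s.
* **convolutions** (`convolution_kernel()`): $g = h(T-t)\,x$, one feature
  per species; $h \equiv 1$ gives time integrals, a narrow box near $t=T$
  approximates endpoint evaluation.

The composition $F = \psi \circ \varphi$ (simulate, then score) maps a
designated subset of design parameters — the rates an experimenter can
actually engineer — to features, with all other rates frozen at nominal
values.

## Linearization by variational integration

$L = \partial F/\partial k|_{k^0}$ is computed by forward sensitivity
analysis: the variational equation
$\frac{d}{dt}\frac{\partial x}{\partial k} = N\frac{\partial v}{\partial
x}\frac{\partial x}{\partial k} + N\frac{\partial v}{\partial k}$, with
zero initial sensitivity, is integrated jointly with the state equation,
the running matrix $L(t)$ (integrand $(\partial g/\partial x)(\partial
x/\partial k)$, $L(0)=0$) and the running features. One stiff solve of
$n + n\,p_\text{design} + m\,p_\text{design} + m$ equations yields both
$L$ and $f^0 = F(k^0)$. Forward (not adjoint) sensitivities are the right
tool at this scale — $m$ and $p_\text{design}$ are small (2 × 2 in the
case study); adjoint methods would pay off only for many parameters and
few features.

Two consequences of the zero initial condition deserve emphasis:

* the initial state is *fixed* across design-parameter values. The
  case-study default computes $x_0$ once, as the inhibitor-free steady
  state at nominal rates, and holds it fixed thereafter; recomputing a
  steady state per parameter value would add an $x_0(k)$ dependence the
  variational equation does not track.
* the flux Jacobians $\partial v/\partial x$ and $\partial v/\partial k$
  must be exact; they are supplied analytically for the sensor fixture and
  assembled symbolically from monomial exponents by
  `mass_action_network()`, and the test suite checks both against central
  finite differences (relative 1e-6) at random states.

Numerical settings: the stiff-capable `lsoda` integrator at `rtol = 1e-8`,
`atol = 1e-10` by default; integration restarts at every input breakpoint
*and* every feature-window edge, with the solver forbidden (via `tcrit`)
from stepping past a segment end. The right-hand side is discontinuous at
those times, and a solver allowed to straddle them collapses its step size
(we observed 4×10⁵ right-hand-side evaluations for a segment that takes
~900 once split properly). Features are evaluated by adaptive quadrature
on the dense per-segment spline interpolant, restarted at every
non-smoothness; an independent route appends the features as extra ODE
states, and the two agree to relative 1e-6 in the tests.

## Local inversion and its error

The pseudoinverse $L^+$ is computed from the SVD with singular values
below $10^{-12}\sigma_{\max}$ treated as zero. The ridge-regularized form
$(L^\top L + \lambda I)^{-1}L^\top$ is implemented separately
(`pinv_limit()`) purely as a cross-check: its $\lambda \to 0$ limit is the
pseudoinverse, and the tests verify monotone convergence. One numerical
caveat found while testing: for matrices that are rank-deficient only up
to floating-point noise (a random low-rank product has a spurious singular
value near 1e-16), the ridge form re-amplifies that noise once $\lambda$
drops below about 1e-8, so the deep-sweep comparison uses exactly
representable singular values.

A feature ball $B_{f^0}(\delta)$ back-maps to the parameter ellipsoid
$\{k^0 + L^+(f - f^0)\}$ with semi-axes $\delta/\sigma_i(L)$ along the
right-singular directions. Sampling it uniformly in the *ball* (Gaussian
direction, radius $\propto U^{1/m}$) and pushing through $L^+$ gives
member parameter sets by construction; draws with a negative rate are
rejected and redrawn, and a rejection rate above 90% raises an error
(the ellipsoid has essentially left the positive orthant).

The inversion error is quantified by the reverse-forward map: request $f$,
back-map, re-simulate, measure $\|F(k^0 + L^+(f-f^0)) - f\|$. Writing
$F(k^0 + \Delta k) - f^0 = \tilde L \Delta k$ with the secant (rank-one)
update $\tilde L$, the robust-least-squares bound gives, for full-row-rank
$L$, error $\le \rho(\delta)\,\|L^+(f-f^0)\|$ where $\rho(\delta)$ bounds
$\|\tilde L - L\|_F$ locally. If $L$ lacks full row rank the package falls
back to the two-term bound $\|(LL^+ - I)(f-f^0)\| +
\rho(\delta)\|L^+(f-f^0)\|$; how the method should behave in that regime
is genuinely open, and the fallback is this package's conservative choice.

$\rho(\delta)$ cannot be computed exactly (it is a nonconvex supremum), so
it is *estimated*: draw feature points in the $\delta$-ball, back-map them
(that is the neighborhood the bound actually ranges over — the pulled-back
ellipsoid, not a parameter ball of radius $\delta$), evaluate $F$ exactly,
form $\tilde L$, take the maximum of $\|\tilde L - L\|_F$, and enforce
monotonicity across the radius grid by a running maximum. Between grid
points the estimate is interpolated linearly through the origin
($\rho \to 0$ as $\delta \to 0$ for a smooth map) and held constant beyond
the last grid point. Defaults: 4 grid radii (geometric, up to the cap), 20
samples per radius. Because a sampled maximum underestimates a supremum,
every downstream guarantee is statistical, not certified; the package's
own tests require the reverse-forward error to respect $\varepsilon$ in at
least 95% of fresh draws, and 20 samples per radius is the smallest count
at which that margin held robustly in the case study (10 was visibly too
optimistic). The maximal radius solves $\rho(\delta)\,\sigma_{\max}(L^+)
\,\delta \le \varepsilon$ — worst case over the ball, attained along the
top right-singular direction — by bisection, returning the lower bracket.

## Covering a specification region

A rectangular region $S$ in feature space is covered ball by ball:

1. The first center is the feature image of the nominal design (clamped
   into $S$ if outside). Later centers come from a ball walk: uniform
   proposals in a step-ball (step = current radius, so consecutive balls
   overlap) around the current center, accepted if inside $S$; after 20
   consecutive proposals landing in covered territory the walk restarts
   from a random uncovered Monte-Carlo point.
2. Each proposed center is pulled back to parameter space by damped
   Gauss–Newton (step $L^+ r$, step-halving on the residual, at most 25
   iterations, convergence at $10^{-3}\,\mathrm{diam}(S)$), relinearizing
   at every iterate; the final linearization is reused as the ball's
   expansion point, so the pull-back costs no extra solve.
3. $\rho$ is estimated at the new expansion point, the radius chosen as
   above (cap: half the box diagonal), and balls smaller than
   $10^{-3}\,\mathrm{diam}(S)$ are skipped — a center in a pathological
   corner would otherwise stall the loop.
4. Coverage is the fraction of a *fixed* set of uniform points of $S$
   (default $10^5$, drawn once per run) inside the ball union — fixed so
   the estimate is monotone in the number of balls and the whole run is
   deterministic given one seed. The run stops at 98% coverage, at the
   ball budget (default 50), or when no uncovered point remains.

The Monte-Carlo estimator and the stopping target are this package's
concrete choices; a coverage metric is needed and none is canonical. The
standard error is at most $0.5/\sqrt{n_\text{mc}} \approx 0.0016$ at the
default size.

## The shipped case study

The fixture is a five-state transcriptional sensor: mRNA, monomer, dimer,
inhibitor-bound dimer, and activator-bound promoter, with the dimer as its
own transcriptional activator and an external inhibitor input that
sequesters it. Rates are the construct's nominal values (basal
transcription 0.02/s through degradation 0.2/s; see `?sensor_network`);
designable rates are the two binding rates an experimenter can plausibly
mutate, inhibitor–dimer (`k7`) and dimer–promoter (`k9`).

The remaining study conditions are this package's reconstructions, chosen
once from the nominal model's behavior and fixed in
`inst/extdata/sensor_case_study.yaml`:

* **input**: a 100 nM inhibitor pulse on $[100, 300)$ s of a 600 s
  horizon — long enough for the inhibited quasi-steady state to establish
  and for full recovery after washout (nominal dimer: 81 nM → 20 nM →
  81 nM);
* **initial state**: the inhibitor-free steady state at nominal rates;
* **windows and targets**: the monomer is constrained to 10 nM over two
  50 s windows ($[180,230]$ and $[400,450]$); the dimer to 5 nM during
  inhibition and 100 nM after washout over two *brief* 5 s checkpoints
  ($[180,185]$, $[400,405]$). The asymmetry is deliberate in two ways: a
  checkpoint is the natural reading of "drops quickly / recovers quickly",
  and short dimer windows keep the two features on commensurate scales
  (nominal $f^0 = (1093, 2923)$ nM²·s). With 50 s dimer windows the dimer
  row of $L$ is ~2000× the monomer row, and the error bound — which
  multiplies the worst-case Frobenius nonlinearity by the worst-case
  back-map gain — becomes so conservative that admissible radii collapse
  to a few feature units;
* **specification region and tolerance**: $S = [1040, 1160] \times
  [2500, 3500]$ nM²·s around $f^0$, $\varepsilon = 150$ nM²·s (about 5% of
  the dimer feature scale). These were fixed from radius probes at four
  candidate expansion points — chosen so that admissible radii vary
  noticeably across $S$ (≈95 in its most nonlinear corner to ≈270 in its
  most linear one) — before any coverage experiment was run.

Problem sizes throughout (chosen as a balance of accuracy against the
cost of the many re-simulations the method requires): 400 output grid
points per trajectory, `rtol = 1e-8`, 4 × 20 secant samples per ball,
$10^5$ coverage points, 50-ball budget. A covering run of the shipped
configuration takes on the order of a minute on one CPU and reaches ≥98%
coverage with fewer than ten balls.

## What the tests do and do not show

All quantitative guarantees are exercised on two kinds of system: toy
networks with closed-form solutions (linear decay, constant-source,
quadratic-rate, and a two-species chain checked against the matrix
exponential), where the oracles are exact; and the sensor fixture, where
oracles are high-accuracy finite differences and re-simulation. Passing
them shows the machinery is correct *for deterministic mass-action models
whose Jacobians are exact and whose forward map is smooth on the region
explored*. It does not show that a real construct's behavior is captured:
measurement noise, extrinsic variability, model misspecification, and
discreteness at low copy number are all outside the model class, and a
specification met by the ODE model may still fail in vivo.

## Known limitations

* The method is local: it assumes the specification region and its
  preimage are connected, and balls are expanded around points reached by
  continuation from the nominal design. Regions split by bifurcations will
  at best be covered partially, at worst make Gauss–Newton fail (which is
  reported, with the probed feature points).
* $\rho(\delta)$ is a sampled lower bound on a supremum; guarantees are
  statistical (the suite checks a 95% margin), never certificates.
* The worst-case coupling $\rho \cdot \sigma_{\max}(L^+)$ makes the radius
  selection conservative under feature-scale anisotropy; specifications
  whose features differ by orders of magnitude will produce needlessly
  small balls. Scale features comparably (window lengths are an effective
  lever) rather than relying on the bound to cope.
* Parameters are handled in linear space, and back-mapped sets with
  negative rates are rejected; ellipsoids hugging the positive orthant
  boundary therefore carry sampling bias toward the interior.
* Squared-deviation features are nonnegative, so specification boxes far
  below the reachable feature set are empty requests; the covering reports
  such regions as unreachable rather than guessing.
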