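---
title: "Geometric identifiability analysis of spheroid growth models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric identifiability analysis of spheroid growth models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidgeom)
```

## The problem

Tumour-spheroid experiments usually yield one cheap observable: the outer
radius $R(t)$ at a handful of times, corrupted by measurement noise.
Mechanistic growth models — which encode nutrient diffusion, proliferation
thresholds and necrosis — carry the parameters an experimentalist actually
cares about, but radius data alone rarely constrain them: the models are
*practically non-identifiable*. Simple phenomenological models (logistic,
Gompertz) are identifiable from the same data but say nothing about
mechanism.

This package operationalises a geometric way out: treat the identifiable
simple model as a *surrogate*, define the least-squares map
$f_{ij}$ from the complex model's parameters $p_i$ to the surrogate's
parameters $p_j$,

$$ f_{ij}(p_i) = \arg\min_{p_j} \lVert m_i(p_i) - m_j(p_j)\rVert, $$

and study the geometry of that map — its Jacobian, its dimensionless
relative-sensitivity matrix, the manifolds in $p_i$-space on which a
surrogate *feature* (growth rate $\lambda$, maximum size $R_\max$) is
constant, and how those manifolds relate to the sloppy directions of the
Fisher information matrix (FIM). The surrogate parameters act as
interpretable features of the data, inserted between the raw parameters
and the scalar likelihood that classical identifiability analysis stares
at.

## The model hierarchy

All models describe the spheroid radius with the initial size
$R(0) = R_0 = 10\,\mu$m treated as known (it is directly measurable;
every solver exposes it as an argument). The volumetric growth rate
$\lambda$ (units d$^{-1}$) appears in every model; the factor $1/3$ in the
radius equations converts volumetric to radial growth.

* **Logistic** ($k=2$): $dR/dt = (\lambda/3)R(1 - R/R_\max)$. Closed form.
* **Bounded Gompertz** ($k=2$):
  $dR/dt = (\lambda/3)R\,\min(\log(R_\max/R), 1)$ — exactly exponential
  while $R < R_\max/e$, Gompertzian after. Piecewise closed form, joined
  continuously at the switch.
* **Richards** ($k=3$): $dR/dt = (\lambda/3)R(1 - (R/R_\max)^\beta)$;
  $\beta = 1$ recovers the logistic model. Solved in closed form through
  the substitution $u = (R/R_\max)^\beta$. Note that at *fixed* $\lambda$
  the right-hand side degenerates to zero growth as $\beta \to 0^+$; the
  familiar "Gompertz limit" of the Richards family holds under the
  conventional rate rescaling $\lambda \to \lambda/\beta$, which is how
  the package tests it.
* **Radial-death** ($k=3$): nutrient is assumed to penetrate a fixed
  distance $R_d$ from the periphery; the volume balance
  $dV/dt = \lambda V_1 - \zeta N$ with necrotic volume
  $N = (4\pi/3)\max(0, R - R_d)^3$ reduces to a single radius ODE.
  Exponential phase in closed form, necrotic phase integrated adaptively.
* **Greenspan** ($k=4$, parameters $Q \in (0,1)$, $R_d$, $\gamma =
  \zeta/\lambda$, $\lambda$): the classical three-phase nutrient model.
  The inhibited radius $R_i$ and necrotic radius $R_n$ solve an algebraic
  system derived from the quasi-steady nutrient profile of a sphere with
  an inert core. In phase 3 the package solves
  $0 = R^3 - R_d^2 R - 3RR_n^2 + 2R_n^3$ for $R_n$ and the corresponding
  quartic line for $R_i$, by guaranteed-bracketing root finding
  (relative tolerance $10^{-12}$); inside the ODE right-hand side a
  warm-started Newton iteration on the same equations is used for speed,
  falling back to bracketing whenever it strays. The sign of the $2R_n^3$
  term follows from re-deriving the nutrient profile; it is the unique
  choice under which the model's long-time plateau at the reference
  parameters equals the 320 um the rest of the analysis assumes.
* **Ward–King** ($k=8$): a simplified multiphase moving-boundary PDE for
  cell density $n(r,t)$, cellular material $p = 1 - n$ (no voids),
  quasi-steady nutrient $c(r,t)$ and velocity $v(r,t)$, with Hill-type
  (exponent 10) nutrient switches for growth and death. The no-voids
  volume balance implies $v = -D_p\,\partial n/\partial r$, so the
  boundary flux condition becomes the law of motion of the outer radius.

For every non-PDE model the *crowding function*
$f(R) = \tfrac{3}{\lambda R}\,dR/dt$ is available in closed form
(`crowding_function()`); for Ward–King it is estimated from a solved
trajectory by centred differences (`wk_empirical_crowding()`).

Reference parameters ("the study conditions") are the Greenspan vector
$p_1 = (Q, R_d, \gamma, \lambda) = (0.8, 150\,\mu\text{m}, 1, 1\,
\text{d}^{-1})$ with daily observations on $0 \le t \le 21$ d.

### Ward–King numerics and defaults

The solver applies the Landau transformation $\rho = r/R(t)$ to a fixed
unit domain, central differences in $\rho$ (first-order upwinding for the
advective term, symmetry limits at $\rho = 0$), re-solves the nutrient
two-point boundary-value problem by damped Newton (Thomas tridiagonal
solves) at every right-hand-side evaluation, and steps in time with
`lsoda`. Default grid: 101 nodes; tests use 31–62 nodes, where doubling
the mesh moves the radius by less than 0.5%.

The quantitative parameter set the original analysis fitted is not
recoverable: its printed initial guess has nine entries for eight
parameters, and two Table-1 entries are blank. The `wk_params()` defaults
are therefore a documented *synthetic* reference set, chosen once so that
growth is sigmoid from 10 um to a few hundred um over three weeks with
nutrient-limited saturation: $\lambda = 1$, $\delta = 1.5$ d$^{-1}$,
$c_1 = 0.4$, $c_2 = 0.3$, $\alpha = 5\times10^{-5}$ d um$^{-2}$
(with the radial coordinate kept dimensional, $\alpha$ carries units),
$D_p = 3\times10^4$ um$^2$ d$^{-1}$, $Q_p = 300$ um d$^{-1}$,
$p_0 = 0.1$, $n_0 = 1$. Ward–King-dependent conclusions in the package
are therefore qualitative (spectral gap structure, steering behaviour),
never digit-level.

## Noise model and inference

Observations are $y^{(k)} = m^{(k)}(p) + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$ i.i.d., with $\sigma$ known (20 um in
the main scenario, 2 um in the early-time scenario). The synthetic-data
generator (`generate_dataset()`) draws exactly this; negative radii that
large noise can produce at small $R(t)$ are deliberately kept — clipping
would bias the noise model. Named scenarios: `"main"` (Greenspan $p_1$,
$t = 0,\dots,21$ d, $\sigma = 20$), `"noise_sweep"`
($\sigma \in \{5, 10, 20, 40\}$, 100 replicates — the source grid is not
printed, so the span is a package choice), `"early_time"` (22 equally
spaced times on $[0, 5]$ d, $\sigma = 2$).

Maximum-likelihood fitting (`fit_mle()`) minimises the sum of squared
errors by multi-start Nelder–Mead on transformed parameters — log scale
for positive parameters, logit for $(0,1)$-bounded ones — so that the
search spans several orders of magnitude, followed by a quasi-Newton
polish that only sharpens the simplex result. Ties among starts break by
best likelihood, then smallest parameter norm. The full $n$-term Gaussian
log-likelihood is used, so AIC $= 2k - 2\ell(\hat p)$ is comparable
across models.

Profile likelihoods (`profile_parameter()`) fix one parameter on a grid
(default 41 log-spaced points over $[\hat p/100, 100\hat p]$, clipped to
the registry bounds — the grid is a package default, not a source fact)
and maximise over the rest, moving outward from the MLE with three inner
starts per point: the MLE, the previous profiled point, and the default
initial guess. The 95% threshold is $-\chi^2_1(0.95)/2 \approx -1.92$;
crossings on both sides of the maximiser classify a parameter
`identifiable`, one crossing `one_sided`, none `non_identifiable`.
`profile_error_function()` applies the same machinery to the raw error
function of noise-free data, which is how theoretical (noise-free)
identifiability is probed.

## Information geometry

For additive Gaussian noise the FIM is $F = J^\top J/\sigma^2$ with $J$
the $n \times k$ sensitivity Jacobian of the predictions
(`model_jacobian()`, central differences, relative step $10^{-4}$).
The $1/\sigma^2$ factor is a deliberate scaling of the plain $J^\top J$:
it makes $F$ the actual information matrix while leaving everything the
analysis interprets — normalised spectrum, eigenvectors, rank, condition
number — unchanged. Eigenvalues are reported scaled so the spectral
radius is one; a "sloppy" eigenvalue group is any group separated from
the leading cluster by a configurable spectral gap (default 3 decades).
At $p_1$, the Greenspan FIM is full rank yet has condition number of
order $10^9$: one direction in parameter space is essentially
uninformative.

`sloppy_path()` follows that direction, integrating $dp/ds = v_1(p)$
(the unit eigenvector of the smallest FIM eigenvalue) with fixed-step
RK4. Because the arclength parameterisation is arbitrary, stepping is
done in scaled coordinates $p/p_{\text{start}}$ (step 0.01); sign
continuity is enforced by flipping $v_1$ whenever it reverses against
the previous direction, with the initial sign fixed by the first
sizeable component.

## The model map and its geometry

`fit_map()` computes $f_{ij}$ by the same multi-start-plus-polish
optimiser on noise-free source predictions and reports
$R^2 = 1 - \lVert m_i - m_j(f_{ij})\rVert^2 / \lVert m_i - \bar
m_i\rVert^2$. `map_jacobian()` differentiates the map by warm-started
central differences with Richardson extrapolation: each column starts at
relative step $10^{-3}$ and the step is halved until two Richardson
levels agree to a column-norm-relative $2\times10^{-3}$ — warm-starting
every inner fit from the anchor's fitted surrogate parameters is what
keeps the columns smooth enough to differentiate through an optimiser.
Agreement is measured against the column norm on purpose: the smallest
entries sit at the optimiser-noise floor and would otherwise force
useless step shrinkage.

The relative sensitivity matrix rescales the Jacobian into %-per-%
units, $S^{(k_1 k_2)} = (p_i^{(k_2)}/p_j^{(k_1)})\,J^{(k_1 k_2)}$ — an
entry of $-0.016$ in row $\lambda$, column $Q$ means a 1% increase in
$Q$ decreases the surrogate $\lambda$ by 0.016%. The printed matrix
equation in the source swaps that scaling relative to its own prose
interpretation; the package follows the prose, with
`convention = "printed"` available for the transposed reading.

Three geometric tools build on the map:

* `feature_manifold()` traces constant-feature level sets over a 2-D or
  3-D slice of source-parameter space by per-gridline bracketed root
  finding on the feature residual, so every returned point carries a
  residual certificate (default 0.5% — a package tolerance; the source
  does not state one). The map inside the tracer reuses the anchor's
  surrogate fit as a warm start and the $t = 0..21$ d grid (the grid the
  map is defined on; also a package assumption). The final-time Greenspan
  necrotic radius is exposed as the extra feature `"necrotic_final"`, so
  the three-manifold point-intersection argument (radius features plus
  one inner-structure measurement identify the parameters) can be run.
* `tangent_normal_check()` verifies, in a 3-parameter slice, that the
  cross product of the two map-Jacobian rows — the intersection of the
  two tangent planes of the constant-feature manifolds — aligns with the
  sloppiest FIM eigenvector. At $p_1$ in the $(Q, R_d, \gamma)$ slice the
  absolute cosine exceeds 0.99.
* `steer()` uses rows of $S$ as multiplicative update directions
  $p \leftarrow p(1 + d)$, scaled so the linearised prediction of the
  targeted feature change matches the request; with
  `orthogonalize = TRUE` the direction is first projected orthogonal to
  the other feature's row, changing (say) $\lambda$ while approximately
  holding $R_\max$. The linearisation is local: requested relative
  changes beyond ~20% are not expected to be achieved accurately.

## Numerical choices, in one place

* ODE integration: `lsoda`, rtol $10^{-8}$, atol $10^{-10}$. The
  nonsmooth right-hand sides (the `max(0, .)` kinks of the bounded
  Gompertz and radial-death models, the Greenspan phase switches) never
  meet the adaptive stepper: the exponential pre-switch phase is closed
  form and integration starts exactly at the switch radius.
* Algebraic roots: bracketed Brent solves at relative tolerance
  $10^{-12}$ (bracketing guarantees convergence on the monotone
  cubic/quartic); the ODE-internal Newton fast path falls back to
  bracketing on any misstep and its residuals are asserted in tests.
* Optimisation: Nelder–Mead reltol $10^{-8}$ (map fits $10^{-12}$) with
  one restart and a BFGS polish kept only when it improves; 1-D inner
  problems use bracketed Brent search. Box constraints are enforced by a
  large finite penalty outside the registry bounds.
* Degenerate inputs are rejected at the domain boundary (`Q` outside
  $(0,1)$, non-increasing time grids, non-positive radii), and solver
  failures inside likelihood evaluations surface as $-\infty$ with a
  warning rather than as errors, so profiling and sweeps continue past
  pathological grid points.

## Scaled-down study sizes

The package's tests reproduce the stochastic experiments at reduced
size, a deliberate design choice to keep the suite fast and
deterministic: AIC comparisons use 2–3 replicates instead of 100,
profile grids use 9–21 points instead of 41, manifold slices use 3–4
gridlines, and Ward–King runs use 31–62 radial nodes over shorter
horizons. The deterministic headline quantities (the Greenspan-to-
surrogate maps, the plateau, the sensitivity entries) are computed at
full precision; only replicate counts and grid resolutions are scaled.

## What the synthetic generator does and does not emulate

It reproduces additive, homoscedastic Gaussian noise on a deterministic
growth curve — the stated observation model. Real spheroid data also
carry biological replicate variability (parameters differing between
spheroids), size-dependent measurement error, and inner-structure
observables with their own noise; none of these are modelled. Passing
tests therefore certify the inference and geometry machinery under the
stated noise model, not robustness to misspecified noise.

## Known limitations

* The map, its Jacobian and the sensitivity matrix are local objects;
  at distant points on the near-constant-likelihood curve the
  sensitivities can differ substantially.
* The two smallest $\lambda$-row sensitivities of the Greenspan-to-
  logistic map sit near the FD-through-optimiser noise floor; the
  package reports converged central-difference values, which for the
  $(\lambda, Q)$ entry is 0.0180 — close to, but not matching, the
  0.0156 reported elsewhere, while the remaining entries agree to
  printed precision.
* The Ward–King reference parameter set is synthetic (see above), so
  all Ward–King conclusions are qualitative.
* Nelder–Mead multi-start is deterministic by design; a genuinely
  multimodal likelihood could require user-supplied starts.

## A worked example

```{r example, eval = FALSE}
grid <- time_grid(0:21)
p1 <- greenspan_params()              # (0.8, 150, 1, 1)

fit_map("greenspan", p1, "logistic", grid)
#> <sg_map> greenspan -> logistic  (R^2 = 0.99844)
#>     lam    Rmax
#>   1.208 315.900

solve_greenspan(p1, 10, c(0, 200))$radius[2]   # long-time plateau, um
#> [1] 319.7902

J <- map_jacobian("greenspan", p1, "logistic", grid)
sensitivity_matrix(J)
#>             Q       Rd   gamma     lam
#> lam  -0.01797 -0.05243  0.1051 0.98910
#> Rmax  0.90100  1.00600 -0.3041 0.01447
```

The surrogate growth rate responds one-to-one to the Greenspan growth
rate (0.989) and barely at all to $(Q, R_d)$; the surrogate maximum size
responds strongly to $(Q, R_d, \gamma)$. That is the geometric
explanation of the practical non-identifiability of $(Q, R_d, \gamma)$
from radius data: they move the data only through one identifiable
feature, $R_\max$.
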