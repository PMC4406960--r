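---
title: "Estimating stochastic differential mixed-effects models with sdmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating stochastic differential mixed-effects models with sdmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Longitudinal data $y_{ij}$ (subject $i$, observation $j$) are described by a
nonlinear mixed-effects model whose within-subject dynamics are a stochastic
differential equation:

$$
d x_i = f(x_i, u_i, t, \phi_i)\,dt + \Sigma(\hat x_i, u_i, t, \phi_i)\,dW_i,
\qquad x_i(0) = x_0(\phi_i),
$$
$$
y_{ij} = h(x_i, u_i, t_{ij}, \phi_i) + e_{ij}, \qquad
e_{ij} \sim N\{0, S(\cdot)\},
$$

with individual parameters $\phi_i = g(\theta, Z_i, \eta_i)$, random effects
$\eta_i \sim N(0, \Omega)$ and $\Omega = U U^\top$ for an upper-triangular
factor $U$ (which keeps $\Omega$ positive semidefinite for any real entries).
Compared with the usual ODE-based mixed-effects model, the diffusion term
$\Sigma\,dW$ — the *system noise* — is a third source of variability next to
measurement error and inter-individual variability.  It represents
uncertainty in the dynamics themselves: misspecified or oversimplified
kinetics show up as system noise rather than being absorbed into an inflated
measurement error.

A practical subtlety: the extended Kalman filter used below cannot handle
diffusion coefficients that depend on the *latent* state.  Proportional
system noise is therefore expressed through the filter's own state estimate
($\sigma \hat C$ rather than $\sigma C$).  The diffusion function of a
`dynamic_model` receives the conditional mean by convention; during
simulation, where no filter runs, the simulator substitutes the current
simulated state into the same function.

### Shipped structural models

**One-compartment PK with first-order absorption and Michaelis–Menten
elimination** (`one_compartment_pk_model()`): states $A$ (amount in the GI
tract, mg) and $C$ (plasma concentration, mg/L),

$$
\frac{dA_i}{dt} = -k_{ai} A_i, \quad A_i(0) = 20; \qquad
V\,dC_i = \Big(k_{ai}A_i - \frac{V_{mi} C_i}{K_m + C_i}\Big)dt
          + \sigma \hat C_i \, dW_i, \quad C_i(0) = 0,
$$

with $y = C + e$, $e \sim N(0, s^2)$, and log-normal variability
$k_{ai} = k_a e^{\eta_{1}}$, $V_{mi} = V_m e^{\eta_{2}}$.  Units:
$k_a$ (1/min), $V_m$ (mg/min), $K_m$ (mg/L), $V$ (L), $s$ (mg/L), $\sigma$
(L/min).  The system noise enters only the concentration equation — it
models uncertainty in the elimination process, so no mass-balance pairing is
applied (an optional `mass_balance` switch adds the opposite-signed term to
the absorption equation).

**Nicotinic-acid (NiAc) disposition** (`niac_model()`): one state $c$
(plasma NiAc, µmol/L) with endogenous synthesis `Synt`, a piecewise-constant
infusion $u(t)$ and capacity-limited elimination,

$$
V_c\,dc_i = \Big(u + Synt - \frac{V_{mi} c_i}{K_m + c_i}\Big)dt
            + \sigma \hat c_i\,dW_i, \qquad
c_i(0) = \frac{Synt\,K_m}{V_{mi} - Synt},
$$

started at the drug-free steady state (requiring $V_m > Synt$), with
proportional residual error $S = (s\,\hat c)^2$ and log-normal variability
on $V_m$ only.  Time is minutes throughout; no unit conversion layer exists.

## Likelihood machinery

### Continuous-discrete extended Kalman filter

Between observations the conditional mean and covariance of the state are
propagated by

$$
\frac{d\hat x}{dt} = f(\hat x, u, t, \phi), \qquad
\frac{dP}{dt} = A P + P A^\top + \Sigma\Sigma^\top,
\qquad A = \partial f/\partial x \big|_{\hat x},
$$

with $A$ and $\Sigma$ re-evaluated continuously along $\hat x$ (so the
state-estimate-proportional diffusion is genuinely time-varying).  At an
observation, with $C = \partial h/\partial x$ at the predicted mean,

$$
R = C P C^\top + S, \quad K = P C^\top R^{-1}, \quad
\epsilon = y - h(\hat x), \quad
\hat x^+ = \hat x + K\epsilon, \quad P^+ = P - K R K^\top,
$$

and $P^+$ is re-symmetrised.  The per-observation residuals $\epsilon_j$ and
output covariances $R_j$ are exactly the ingredients the likelihood needs.
The covariance propagation uses the symmetry-preserving Lyapunov form
$AP + PA^\top + \Sigma\Sigma^\top$.

The initial covariance defaults to $P_0 = 0$: both shipped models define the
initial state exactly given $\phi$ (a known dose; a steady state), so there
is no initial-state uncertainty to encode.  $P_0$ is an argument everywhere
for models where that is not true.  The first observation is handled by
predicting from $(x_0(\phi), P_0)$ at $t = 0$ to $t_1$.

### FOCE/FOCEI Laplace approximation

The marginal likelihood integrates over the random effects; the integral is
approximated by Laplace's method around each subject's posterior mode
$\eta_i^\ast = \arg\max_\eta l_i(\eta)$ of

$$
l_i(\eta) = -\tfrac12\sum_j\big(\epsilon_j^\top R_j^{-1}\epsilon_j
  + \log|2\pi R_j|\big)
  - \tfrac12 \eta^\top\Omega^{-1}\eta - \tfrac12\log|2\pi\Omega|,
$$

giving
$-\log L(\theta) \approx \sum_i\big[-l_i(\eta_i^\ast)
 + \tfrac12\log|-\Delta l_i(\eta_i^\ast)/(2\pi)|\big]$.
The curvature $\Delta l_i$ is approximated using first-order sensitivities
only.  Dropping the dependence of $R$ on $\eta$ gives the FOCE form
$\Delta l = -\sum_j \partial\epsilon_j^\top R_j^{-1}\partial\epsilon_j
- \Omega^{-1}$; retaining all first-order $\partial R/\partial\eta$ terms
(including the $\tfrac12\mathrm{tr}(R^{-1}\partial R R^{-1}\partial R)$
term) gives FOCEI, which reduces exactly to FOCE when
$\partial R/\partial\eta \equiv 0$ — a property the test suite checks
exhaustively on randomised instances.  In an SDE model the interaction is
always present (the Kalman gain, and hence $R$, depends on the individual
parameters), which is why FOCEI is the default for the PK study; FOCE
guarantees a positive-definite curvature and is the default for
NiAc-structure fits.  If a FOCEI curvature fails to be negative definite at
the mode, its spectrum is floored at $10^{-8}$ before the log-determinant,
keeping the outer objective finite near boundary fits; occurrences are rare
and confined to excursions of the outer optimizer.

## Gradients without finite differences of the objective

Finite differences of an adaptively-solved objective are noisy at exactly
the scale an optimizer cares about.  Two design choices remove that noise:

1. **Fixed-grid integration.**  All prediction ODEs are integrated with
   classical RK4 on a grid determined only by the observation times, input
   breakpoints and a time-graded step bound — never by the parameters.  The
   discrete objective is therefore a smooth function of the parameters.
   The base step is `h_max = 0.1` min on $[0, 10)$, tripled on $[10, 30)$
   and sextupled beyond, reflecting the relaxation of the kinetics after
   the initial transient; refining this grid changes the objective by about
   one part in $10^8$ (checked by a grid-insertion invariance test).

2. **Exact discrete sensitivities.**  For the compiled models the forward
   variational equations of $\hat x$ and $P$ (with the chain-rule terms
   through $\partial A/\partial x$, $\partial A/\partial\phi$,
   $\partial(\Sigma\Sigma^\top)/\partial x$,
   $\partial(\Sigma\Sigma^\top)/\partial\phi$) are integrated with the same
   RK4 stages, and the measurement update is differentiated exactly as
   algebra.  The returned $\partial\epsilon/\partial\phi$,
   $\partial R/\partial\phi$ are thus the *exact* derivatives of the
   discretized filter outputs, verified against central finite differences
   to ~$10^{-8}$ relative.  User-declared R models fall back to central
   finite differences of the whole (fixed-grid, hence smooth) filter.

The inner gradient
$\partial(-l)/\partial\eta = \sum_j[\partial\epsilon_j^\top R_j^{-1}\epsilon_j
- \tfrac12\epsilon_j^\top R_j^{-1}\partial R_j R_j^{-1}\epsilon_j
+ \tfrac12\mathrm{tr}(R_j^{-1}\partial R_j)] + \Omega^{-1}\eta$
is assembled exactly from those sensitivities.

The outer gradient differentiates each subject's Laplace contribution with
the implicit-function treatment of the inner optimum,
$d\eta^\ast/d\theta = -[\partial^2 l/\partial\eta^2]^{-1}
\partial^2 l/\partial\eta\,\partial\theta$.  First-order pieces are exact;
the second-order pieces ($\partial^2 l/\partial\eta\partial\theta$, the
$\theta$- and $\eta$-derivatives of $\Delta l$ inside the log-determinant,
and the exact $\eta$-Hessian used in the implicit term) are formed by
central finite differences *of sensitivity-computed first-order quantities*
with a relative step of $10^{-4}$.  Each such quantity is a smooth
deterministic function on the fixed grid, so these differences carry none
of the step-acceptance noise that plagues finite differences of the
objective.  The assembled gradient matches central finite differences of
the implemented objective to ~$10^{-6}$ relative, and the derivatives of
$\Omega$-terms are analytic throughout.  The log-determinant term keeps the
same first-order-only approximation as the curvature itself; no third-order
sensitivities are ever formed.

## Optimization

The inner (per-subject) problem is solved by a damped Newton method with
the always-positive-definite FOCE information matrix as metric, the exact
sensitivity gradient, and Armijo backtracking; warm starts at the previous
outer iteration's optimum make 2–5 iterations typical.  Convergence:
gradient $\infty$-norm $\le 10^{-6}$, or an objective change at the
floating-point floor with gradient $\le 10^{-4}$ (cap 100 iterations,
flagged if hit).

The outer problem runs BFGS on a transformed scale — $\log$ for all
positive parameters (structural, $s$, $\sigma$, $\omega_{11}$,
$\omega_{22}$), natural scale for the sign-free $\omega_{12}$ — with an
Armijo line search, per-iteration direction capping (no transformed
coordinate moves more than 2 per step), and a safeguarded restart of the
metric when a direction fails.  Convergence is declared at gradient
$\infty$-norm $\le 10^{-4}$ (transformed scale); if the line search
exhausts at a point where the gradient is below $10^{-2}$, the fit is
reported converged at the numerical floor (criterion `"gfloor"`), since no
further decrease is representable — with objective values of order $10^2$,
both stopping rules locate the optimum far below the Monte-Carlo precision
of a simulation study.  Accepted iterations decrease the objective
monotonically, and the trace (iteration, objective, gradient norm) is kept
on the fit object for convergence plots.

Relative standard errors are obtained from the Hessian of the outer
objective at the optimum — central finite differences of the
sensitivity-equation gradient on the transformed scale — inverted and
delta-method-mapped to the natural scale:
$\mathrm{RSE\%} = 100\,\mathrm{se}(\hat\theta)/|\hat\theta|$.  A
non-positive-definite Hessian triggers a warning and a pseudo-inverse.
In replicate studies the spread of the replicate estimates
($100\,\mathrm{sd}/\mathrm{mean}$) is reported instead.

## The synthetic-data generator and the study conditions

`simulate_population_dataset()` draws $\eta_i \sim N(0, UU^\top)$, maps to
$\phi_i$, and integrates each subject's SDE by Euler–Maruyama with step
0.01 min (grid refined to include all observation times and input
breakpoints), adding measurement noise drawn from $S$ at the observation
times.  Euler–Maruyama is the simplest strong-order-0.5 scheme; at this
step the deterministic error is ~0.5% and first-order in the step
(verified against a high-accuracy ODE solve), and the stationary variance
of an Ornstein–Uhlenbeck test process is reproduced within Monte-Carlo
error.  Latent states are never clipped inside the integration — the
proportional noise vanishes with the concentration, which already keeps
paths nonnegative in practice — so the simulated moments are unbiased.

The default simulated study mirrors the validation design: 20 subjects,
observations at $t = 1, 9, \dots, 97$ min, truth
$(k_a, V_m, K_m, V, s, \omega_{11}, \omega_{12}, \omega_{22}, \sigma) =
(0.1, 0.5, 3, 1, 0.1, 0.5, 0.1, 0.3, 0.05)$, estimation started from
$(0.2, 1, 1, 2, 0.5, 0.1, 0, 0.1, 0.01)$, FOCEI, with the SDE fit (all
nine parameters free) compared against the ODE fit ($\sigma$ pinned at
zero).  Replicate seeds derive from the master seed by a counter, so a
study is reproducible end to end.  The package's own checks run 8
replicates in the test suite and 20 in the acceptance script — sizes chosen
so the replicate-mean Monte-Carlo error is a few percent per parameter,
which is the resolution at which the study's conclusions (unbiased
SDE-mode recovery; ODE-mode bias with roughly six-fold inflation of the
measurement-error standard deviation) are assessed.  Non-converged
replicates are excluded from summaries and counted; a study with more than
20% exclusions is flagged invalid rather than silently reported.

No real NiAc concentrations are distributed with the package, so the NiAc
disposition model is exercised entirely on synthetic data: 15 subjects
split as 8 on a 0.67 µmol/min/kg × 30 min infusion and 7 on 0.17 × 300 min
(mirroring the two analyzed infusion groups), with observation times chosen
once to cover the infusion, the post-infusion decline and the return toward
the endogenous steady state.  Recovery is assessed against the generating
values with replicate-based standard errors.  What passing these checks
shows is that the estimation machinery is consistent under the model's own
assumptions (Gaussian noise, log-normal variability, correctly specified
structure); it does not certify behaviour under the misspecification,
irregular sampling, censoring or covariate effects of real datasets.

## Individual fits and uncertainty bands

Given population estimates, per-subject posterior modes are re-optimized
and the model is run as a state estimator.  `ekf_filter()` keeps a dense
inter-observation prediction grid; `filter_band()` turns it into an output
mean ± one standard deviation band (state uncertainty plus measurement
covariance), which with system noise present narrows at each observation
and widens between them.  `rts_smooth()` runs the fixed-interval
(Rauch–Tung–Striebel-type) backward pass over the linearized system,
conditioning every state on *all* of the subject's observations — this is
what individual fit plots should use.  The backward gain uses a
pseudo-inverse of the predicted covariance so that the deterministic limit
($\Sigma = 0$, $P_0 = 0$) degrades gracefully to the ODE solution instead
of failing on a singular matrix; the smoother is verified against exact
joint-Gaussian conditioning on a linear toy.

## Numerical choices, in one place

| Choice | Value | Why |
|---|---|---|
| Prediction integrator | RK4, fixed graded grid, base step 0.1 min | smooth objective; exact discrete sensitivities |
| Grid grading | ×1 before 10 min, ×3 to 30 min, ×6 after | kinetics relax after the transient; ~$10^{-8}$ relative objective effect |
| Simulation scheme | Euler–Maruyama, step 0.01 min | simplest strong scheme; verified by OU oracle |
| $P_0$ | 0 (configurable) | both shipped models fix $x(0)$ exactly |
| Inner tolerance | $\lVert g\rVert_\infty \le 10^{-6}$ | posterior mode accuracy far below objective noise |
| Outer tolerance | $\lVert g\rVert_\infty \le 10^{-4}$ (transformed) | parameter precision ≪ Monte-Carlo spread |
| Curvature floor | eigenvalues of $-\Delta l$ floored at $10^{-8}$ | finite objective near boundary fits |
| Second-order FD step | $10^{-4}$ relative, central | smooth quantities; truncation ~$10^{-8}$ |
| Transforms | log for positive parameters, identity for $\omega_{12}$ | unconstrained smooth optimization |

## Known limitations

- The likelihood machinery assumes a scalar measurement per time point (the
  filter itself is multivariate-ready).
- Compiled high-speed paths exist for the two shipped structural models;
  user-declared `dynamic_model`s run through the generic R filter with
  finite-difference sensitivities, which is accurate but slower and
  restricts their practical use to small models.
- The Laplace/FOCE/FOCEI approximations are exact only for models linear in
  $\eta$ with Gaussian errors (the test suite proves this on such toys);
  elsewhere they carry the usual conditional-estimation approximation
  error.
- No adjoint sensitivities: the forward approach scales with the number of
  parameters and states, which is fine at $n_x \le 2$ but would not be the
  right design for large systems.
- No dosing-record dialects (ADDL/SS/EVID), no censoring/BQL handling, no
  covariate model building.
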