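---
title: "Step-response theory of skin-plus-sensor systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-response theory of skin-plus-sensor systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermadiff)
```

## The physical model and its assumptions

A wearable transdermal sensor reads an analyte that has diffused from the
capillary bed across the stratum corneum, the outermost and rate-limiting
skin layer. `dermadiff` models that layer as a single homogeneous slab of
thickness $L$ with constant diffusion coefficient $D$:

$$\frac{\partial c}{\partial t} = D \frac{\partial^2 c}{\partial x^2},
\qquad c(x,0)=0, \qquad c(0,t)=C_0 \ \ (t \ge 0),$$

i.e. a step change of the blood-side concentration at $t=0$. The key
assumptions are: one-dimensional transport (no lateral heterogeneity, no
sweat-gland shunt pathways), unit partition coefficient at both faces, no
metabolism inside the layer, and constant $D$ (no hydration or temperature
dependence). The blood side is an ideal reservoir — the step is held
exactly.

What distinguishes sensor classes is the boundary condition at the
skin/sensor interface $x=L$:

* **concentration-type** (Neumann, $\partial c/\partial x|_L = 0$): the
  sensor measures reversibly and consumes nothing;
* **ideal flux-type** (Dirichlet, $c(L,t)=0$): the sensor irreversibly
  consumes every arriving molecule and measures the influx;
* **Robin-type** ($D\,\partial c/\partial x|_L = -\alpha\, c(L,t)$): a
  finite-sensitivity flux sensor whose uptake rate constant $\alpha$ (cm/s)
  is proportional to the electrode's heterogeneous rate constant.

All computations are done in dimensionless variables $\bar x = x/L$,
$\bar t = tD/L^2$, $\bar c = c/C_0$; responses are normalized by their
steady states so that different output units (mol cm$^{-3}$ versus
mol cm$^{-2}$ s$^{-1}$) can be compared on one axis. The single
dimensionless parameter of the Robin family is
$\bar\alpha = \alpha/(D/L) = \alpha/k_\mathrm{skin}$, the sensor
sensitivity relative to skin permeability.

## Series solutions and their conventions

The Neumann and Dirichlet problems have classical separation-of-variables
solutions; their normalized sensor-face responses are

$$\bar m_\mathrm{Conc}(\bar t) = 1 + \frac{4}{\pi}\sum_{i\ge1}
\frac{(-1)^i}{2i-1} e^{-\pi^2(2i-1)^2 \bar t/4}, \qquad
\bar m_\mathrm{Flux}(\bar t) = 1 + 2\sum_{i\ge1} (-1)^i e^{-\pi^2 i^2 \bar t}.$$

Two numerical conventions matter:

* **Truncation.** Terms decay like $e^{-a k^2 \bar t}$, so the number of
  retained terms is chosen from the smallest evaluated time so that the term
  envelope falls below `tol` (default $10^{-12}$), capped at 10 000 terms.
  Doubling the retained terms changes nothing beyond `tol` (tested).
* **The $\bar t = 0$ limit.** The series converge non-uniformly at
  $\bar t = 0$ (the flux series does not converge pointwise there at all),
  so for $\bar t < 10^{-4}$ the exact initial/boundary values are returned
  instead of summing: profiles are 0 inside the slab and 1 at the blood
  face, responses are 0. Physically nothing has crossed the skin yet; the
  value $10^{-4}$ is far below any time at which these kernels are
  informative ($\bar t \sim 0.01$ and later).

The alternating signs are implemented as explicit $(-1)^i =
\cos(\pi i)$ factors, and the identity $\bar m_\mathrm{Conc}(\bar t) =
\bar c_\mathrm{Neumann}(1, \bar t)$ is a unit test, which pins the sign
conventions.

## The Robin eigenproblem

Separation of variables with the Robin condition gives mode shapes
$\sin(\mu_n \bar x)$ whose eigenvalues solve

$$\mu\cos\mu + \bar\alpha \sin\mu = 0,$$

with exactly one root per interval $((n-\tfrac12)\pi,\, n\pi)$. Writing the
condition in this product form (rather than $\tan\mu = -\mu/\bar\alpha$)
avoids the tangent's poles, so every root can be bracketed and found by a
guaranteed bracketing root finder; two Newton polish steps push the residual
to rounding level (tested below $10^{-10}$). As $\bar\alpha \to \infty$ the
roots slide to the Dirichlet modes $n\pi$; as $\bar\alpha \to 0$, to the
Neumann modes $(n-\tfrac12)\pi$.

The steady profile is linear, $\bar c_{ss}(\bar x) = 1 -
\beta\bar x$ with $\beta = \bar\alpha/(1+\bar\alpha)$, fixed by the blood
boundary value and the flux balance $D c'(L) = -\alpha c(L)$; the sensor-face
value is $1/(1+\bar\alpha)$. The transient coefficients are the unique
$L^2$ projection of the negated steady profile onto the eigenmodes,

$$b_n = -\frac{\langle \bar c_{ss}, \sin(\mu_n\bar x)\rangle}
{\langle \sin(\mu_n\bar x), \sin(\mu_n\bar x)\rangle},$$

evaluated in closed form (numerator $(1-\cos\mu)/\mu -
\beta(\sin\mu - \mu\cos\mu)/\mu^2$, denominator $1/2 - \sin 2\mu/(4\mu)$)
and cross-checked against numerical quadrature to $10^{-10}$ and against
the finite-difference solver to $10^{-5}$. Projection is the only expansion
consistent with the zero initial condition and Sturm–Liouville
orthogonality, so no other normalization convention can change the summed
solution.

One caveat documented deliberately: the eigenmodes all vanish at
$\bar x = 0$ while the function being expanded equals $-1$ there, so the
partial sums of the $t=0$ reconstruction carry a Gibbs tail of size
$\approx 1/(\pi N d)$ at distance $d$ from the blood face. This affects
only the reconstruction diagnostic at exactly $\bar t = 0$; for any
$\bar t > 0$ the $e^{-\mu_n^2 \bar t}$ factors restore spectral
convergence, which is why profile evaluations default to 200 modes and
response evaluations to 50 (ample for $\bar t \ge 0.01$; both
configurable).

## Timescale metrics

Two metrics are computed side by side, with no claim that either is
preferable:

* **Leading-exponential timescale**: the reciprocal decay rate of the
  slowest series mode, read from the implemented mode table rather than
  hard-coded. This gives $\tau_\mathrm{Flux} = L^2/(\pi^2 D)$,
  $\tau_\mathrm{Conc} = 4L^2/(\pi^2 D)$ (ratio exactly 4), and
  $\tau_\mathrm{Robin} = L^2/(D\mu_1^2)$ strictly between them.
* **Integrated intercept**: $\bar t^* = \int_0^\infty (1-\bar m)\,d\bar t$,
  the x-intercept of the asymptote of the integrated response. Every series
  term integrates in closed form, so $\bar t^*$ is a term-wise sum: $1/6$
  (flux), $1/2$ (concentration) — ratio 3 — and
  $-(1+\bar\alpha)\sum_n b_n \sin\mu_n/\mu_n^2$ for Robin, which decreases
  monotonically from $1/2$ to $1/6$ as $\bar\alpha$ grows. The alternating
  tails are summed to their own error bound ($10^{-12}$, which for the flux
  intercept means $\sim 4.5\times10^5$ vectorized terms — these sums are not
  subject to the profile series' 10 000-term cap), smallest terms first,
  and verified against adaptive quadrature of $1-\bar m$ to $10^{-8}$.

By either metric, an ideal flux-type sensor is three to four times faster
than a concentration-type sensor on the same skin, and raising $\bar\alpha$
always speeds the system up, to the flux-type limit.

## The finite-difference oracle

Every analytic solution is verified against an independent Crank–Nicolson
solver: second-order central differences on a uniform grid, the blood node
pinned at 1 from the first step (the idealized step input), Neumann/Robin
conditions imposed through a ghost node (second-order boundary flux),
Dirichlet imposed directly. The sensor-face flux is reconstructed with a
one-sided third-order stencil.

Grid defaults were chosen by measuring the error against the closed-form
Dirichlet solution: the step discontinuity at $(x,t)=(0,0)$ produces a
steep front whose spatial error saturates near $3\times10^{-5}$ on a
201-node grid at $\bar t = 0.01$. The shipped defaults — 401 nodes,
$\Delta\bar t = 10^{-5}$ until $\bar t = 0.01$ and $10^{-4}$ after, with
four backward-Euler startup steps (Rannacher smoothing) to damp the
Crank–Nicolson oscillations the discontinuity would otherwise excite —
hold the measured error below $10^{-5}$ over $\bar t \in [0.01, 3]$ for
all three boundary conditions, which is the agreement level the test suite
asserts (`verify_series_vs_oracle()`). A convergence study confirms the
observed spatial order $\approx 2$. Requested output times are snapped to
the nearest time step (multiples of $\Delta\bar t$ are hit exactly).

The oracle and the series implementations share no code: the eigensolver
never informs the difference scheme and vice versa, so agreement to
$10^{-5}$ is meaningful evidence that both are correct.

## The ethanol case study and its presets

The amperometric arithmetic $\alpha = i/(C\,n\,A\,F)$ converts a sensor's
electrical calibration into a mass-transport coefficient comparable with
skin permeability. The bundled presets reproduce published parameter
chains verbatim, including their internal tensions, rather than
editorializing:

* two diffusion coefficients for ethanol in stratum corneum circulate
  (3×10⁻¹¹ cm²/s in timescale estimates, 5×10⁻¹⁰ cm²/s in the permeability
  chain, both traced to the same 1971 measurement study); they ship as
  separate presets `ethanol-timescale` and `ethanol-kskin`;
* two permeability values likewise (3.3×10⁻⁷ cm/s in recent modelling
  work, 5.3×10⁻⁷ cm/s implied by a device patent's flux-at-concentration
  figure); case-study rows carry both, tagged by source;
* the Faraday constant is kept at the two-digit engineering value
  9.64×10⁴ s A/mol used in those chains, not the CODATA value, so printed
  numbers reproduce exactly;
* the WrisTAS-style chain assumes $n = 4$ electrons per ethanol molecule
  as published, although oxidation stoichiometry varies by sensor
  chemistry (noted in the report output).

Classification thresholds are a package choice: the theory says only
"$\bar\alpha \gg 1$ behaves flux-like, $\bar\alpha \ll 1$
concentration-like". The defaults 10 and 0.1 encode "an order of magnitude
away from 1" and are arguments of `classify_sensor()`, not constants.

```{r}
case_study_report()[, c("preset", "alpha_bar", "classification")]
```

## Problem sizes used in the tests

The oracle-equivalence checks compare all three solutions on the full
401-node grid at six times spanning $\bar t \in [0.01, 3]$, with Robin
sensitivities $\bar\alpha \in \{0.2, 1, 5\}$ (the three values used in the
response-comparison figure); monotonicity and dominance properties are
asserted on grids of a few hundred times. These sizes keep the full suite
around a minute on one core while exercising every regime boundary
(early-time front, mid-transient, steady state).

## Limitations

The model is deliberately minimal. It does not represent: multi-layer skin
or the brick-and-mortar microstructure of the stratum corneum; partition
coefficients different from 1; shunt pathways (sweat glands, follicles);
a gas headspace between skin and sensor; time-varying blood concentration
(responses to arbitrary $C_0(t)$ would follow by convolution with the step
response, but no deconvolution tooling is provided); hydration- or
temperature-dependent $D$; or concentration-dependent sensor kinetics.
Passing the verification suite shows the mathematics is implemented
correctly under these idealizations — it does not validate the
idealizations themselves against real skin, where permeability varies by
individual, site and time.
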