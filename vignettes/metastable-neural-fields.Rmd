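---
title: "Constructing metastable dynamics in heterogeneous neural fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing metastable dynamics in heterogeneous neural fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofield)
```

## The model

Neural fields describe the mesoscopic activity $u(x, t)$ of cortical
tissue over a spatial continuum $\Omega$. The starting point is the Amari
equation,
$$\frac{\partial u(x,t)}{\partial t} = -u(x,t)
  + \int_\Omega w(x,y)\, f(u(y,t))\, dy,$$
with a synaptic kernel $w(x,y)$. This package works with its polynomial
expansion truncated at second order,
$$\frac{\partial u}{\partial t} = -u
  + \int_\Omega w_1(x,y)\, u(y,t)\, dy
  + \iint_\Omega w_2(x,y,z)\, u(y,t)\, u(z,t)\, dy\, dz,$$
because for this form the kernels can be **constructed in closed form**
from a prescribed set of patterns and a prescribed temporal dynamics — no
supervised training. Given $n$ linearly independent spatial modes
$v_k(x)$ with biorthogonal adjoints $v_k^+(x)$
($\int v_j^+ v_k = \delta_{jk}$), and a Lotka-Volterra system
$$\dot\xi_k = \xi_k\Big(\sigma_k - \sum_j \rho_{kj}\,\xi_j\Big),
\qquad \sigma_k > 0,\ \rho_{kk} = 1,$$
the Pincherle-Goursat (finite-rank) kernels
$$w_1(x,y) = \sum_k (\sigma_k + 1)\, v_k(x) v_k^+(y), \qquad
  w_2(x,y,z) = -\sum_{kj} \sigma_j \rho_{kj}\, v_k(x) v_k^+(y) v_j^+(z)$$
make the field dynamics carry the population dynamics exactly on the span
of the modes: writing $u = \sum_k \alpha_k(t) v_k(x)$ with amplitudes
$\alpha_k = \xi_k / \sigma_k$, the projections of the field equation
reproduce the Lotka-Volterra flow, every mode $v_k$ is a stationary state,
and any component of $u$ outside the mode span decays at unit rate. The
package tests assert all three properties directly (`field_rhs`,
`project_onto_modes`, and the complement-decay check in
`test-field.R`).

When the Lotka-Volterra parameters realize *winnerless competition* — a
closed chain of saddles $S_k = \sigma_k e_k$, each with exactly one
unstable direction pointing at its successor — the field visits the
patterns $v_1, v_2, \ldots, v_n, v_1, \ldots$ in sequence, dwelling near
each for a while: a model of metastable transient activity such as EEG
microstates or ERP components.

## Designing the contour

`build_contour_matrix()` specifies $\rho$ through the eigenvalues of the
linearization at each saddle. At $S_k$ the transverse eigenvalues are
$\lambda_j = \sigma_j - \rho_{jk}\sigma_k$ ($j \ne k$) and the
longitudinal one is $-\sigma_k$, so prescribing eigenvalues and solving
for $\rho$ is immediate. Two choices matter:

**Escape rates proportional to growth rates.** The unstable eigenvalue at
$S_k$ is set to $+\varepsilon_u \sigma_k$ (default
$\varepsilon_u = 0.3$). Since the dwell time near a saddle is inversely
proportional to its escape rate, dwell times are ordered as
$T_k \propto 1/\sigma_k$: with $\sigma = (1, 2, 3)$ the first pattern
lives longest and the third shortest, in the ratio
$1 : \tfrac12 : \tfrac13$. Positivity of all interaction weights requires
$\varepsilon_u < \min_k \sigma_{succ(k)}/\sigma_k$ (equal to $1/3$ for
the default growth rates), which the builder enforces with an error
naming the offending entry.

**Dwell-map slopes.** A deterministic attracting heteroclinic cycle has
dwell times that grow from passage to passage: the dwell at the next
saddle obeys approximately
$T_{succ(k)} \approx a_k T_k + \text{const}$ with slope
$a_k = s_k / \lambda_u(succ(k))$, where $s_k$ is the contraction rate of
the future-unstable direction while the orbit waits near $S_k$. If all
$a_k \ge 1$ the dwells grow monotonically *within* each cycle (so the
dwell ordering above is destroyed); if $\prod_k a_k < 1$ the contour
loses its attraction and the orbit falls into the interior coexistence
equilibrium — both regimes were mapped numerically while designing the
default. The builder therefore sets $a_k = 0.65$ for $k < n$ and
$a_n = \text{growth}/0.65^{\,n-1}$ with growth $= 1.05$: successive
dwells *shrink* inside a cycle (preserving
$T_1 > T_2 > \cdots > T_n$ from the second cycle on) while the whole
cycle lengthens by about five percent per revolution, keeping the contour
attracting. Explicit per-saddle contraction rates can be supplied through
`eps_stable` to override this design.

`verify_contour()` recomputes the closed-form eigenvalues and checks the
one-unstable-direction property saddle by saddle; the test suite compares
them against the eigenvalues of a numerically differentiated Jacobian.

With the defaults, the first dwell lasts about 17 ticks
($\log(1/\delta)/0.3$ for the default displacement $\delta = 10^{-3}$)
and the second cycle dwells are roughly $32$, $18$, and $11$ ticks. The
default run length `t_end = 160` covers two complete cycles plus the
beginning of the third; this problem size keeps each 1D field simulation
well under a second.

## Discretization and numerics

* **Grid convention.** The 1D domain $[0, 2\pi)$ is sampled half-open and
  uniformly, $x_i = i\,L/N_x$, with rectangle-rule weights $L/N_x$
  (default $N_x = 100$). On this grid the discrete orthogonality of the
  sine modes $v_k(x) = \sin kx$ is *exact*:
  $\sum_i \sin(j x_i)\sin(k x_i)\, w_i = \pi\,\delta_{jk}$ for
  $j, k < N_x/2$, so the analytic adjoints $v_k^+ = \sin(kx)/\pi$ are
  biorthogonal to machine precision. Including the right endpoint would
  break this identity — the half-open convention is what makes the
  orthogonality test a $10^{-12}$ assertion instead of a quadrature
  approximation.
* **Quadrature everywhere.** Integrals are weighted sums throughout, and
  the pseudoinverse adjoints solve the *weighted* biorthogonality
  $A\,W\,V^\top = I$ via $A = (V W V^\top)^{-1} V$, which also gives each
  adjoint row the minimum-norm (in-span) property. On the 2D pixel grid
  all weights are 1 and this reduces to the ordinary Moore-Penrose
  pseudoinverse.
* **Kernels are kept factored.** The dense three-point tensor has $N_x^3$
  entries ($4^3$ GB-scale at the 2D size of $N_x = 400$), but the
  Pincherle-Goursat structure makes the factored evaluation — project,
  apply the $n \times n$ coefficient matrices, expand — algebraically
  identical. Dense tensors are built only on request and refused above
  $N_x = 150$; equivalence of the two paths to $10^{-10}$ is asserted on
  random states.
* **Integration.** Both the population system and the field equation are
  integrated with a variable-order backward-differentiation method
  (`deSolve::ode(method = "bdf")`), relative tolerance $10^{-8}$,
  absolute tolerance $10^{-10}$, output every $0.05$ ticks, with the
  analytic Jacobian supplied (the factored kernel structure makes it a
  sum of outer products). Solver failures are never silent: trajectories
  carry a diagnostics record and the partial solution, which the ensemble
  driver uses to flag rejected trials.
* **Rank checks.** Linear independence of modes is decided by the
  singular values of the weight-scaled mode matrix, with threshold
  $10^{-10}$ relative to the largest singular value.
* **Comparisons.** `trajectory_error()` resamples mismatched time grids
  by per-node linear interpolation onto the coarser grid and reports the
  relative space-time $L_2$ distance
  $\|a - b\| / \max(\|a\|, \|b\|)$ with quadrature weights in space.

## The synthetic ERP ensemble

The ensemble experiment emulates trial-to-trial variability in
event-related potentials: 60 trials start from randomized initial
conditions in the vicinity of the first saddle, are recorded at four
probe nodes (3, 21, 47, 88 — 1-based, matching the grid's natural
indexing), and receive additive Gaussian observational noise of standard
deviation 0.005 on the recordings only.

Randomized starts are drawn *in-span*,
$u_0 = v_1 + \sum_k \eta_k v_k$, so the order-parameter picture remains
exact. The resident coefficient is perturbed symmetrically
($\eta_1 \sim N(0, 0.05)$); the transverse coefficients use the
magnitude $|N(0, 0.05)|$. The sign restriction is a property of the
dynamics, not a convenience: a negative transverse coefficient places the
orbit outside the positive orthant in which winnerless competition
operates, and such orbits either blow up in finite time or converge to
spurious mixed-sign equilibria of the polynomial field equation — they do
not emulate ERP trials. Trials are rejected when the solver fails or the
field magnitude exceeds ten times the largest saddle amplitude; with
in-span nonnegative starts the default run typically rejects none (a
correct outcome — rejection here exists to catch genuine numerical
escapes, and the machinery is exercised in the tests by tightening the
bound).

Three quantitative signatures are checked: (i) the across-trial standard
deviation of the clean traces (the *decoherence index*) grows from the
first tenth of the run to the final third at every probe — trials start
coherent and desynchronize because their initial distances from the
saddle translate into different passage times; (ii) the grand average
(mean of accepted noisy recordings) consequently decays, its RMS over the
final third falling below the first third, while remaining smoother than
any single noisy trial; (iii) pooling the residuals noisy − clean over
all probes, times, and trials recovers the injected noise level. The
ensemble default `t_end = 60` spans the first two pattern transitions,
which is where the dispersion builds up; 60 trials at this length run in
seconds.

## The two-dimensional experiment

The 2D study uses three grayscale digit patterns ("1", "2", "3") as
modes on a $20 \times 20$ pixel grid ($N_x = 400$). Since no canonical
bitmaps exist, the package renders them deterministically: fixed polyline
strokes in the unit square, stroke width one eighth of the image height,
anti-aliased over one pixel, rasterized at $100 \times 100$ and
block-mean downsampled to $20 \times 20$. The rendering is a pure
function of (label, resolution) — no fonts, no randomness. Patterns are
centered to zero mean before use as modes because the shared background
level otherwise makes the three bitmaps nearly collinear; the raw
$[0, 1]$ bitmaps are preserved for image export. Adjoints come from the
pseudoinverse; the temporal dynamics is the same heteroclinic contour as
in 1D.

Measurement at single pixels illustrates distributed representations:
`select_probe_points()` picks, for each pattern, the pixel maximizing the
contrast ratio $|v_k(i)| / \max_{j \ne k} |v_j(i)|$ (falling back, with a
warning, to the pattern's own maximum if no pixel exceeds ratio 1). The
recorded activity at probe $k$, normalized by $v_k$ at that pixel, then
rises toward 1 exactly while pattern $k$ dominates. The package
quantifies the visual alignment of probe activity with pattern emergence
as a Jaccard overlap between the thresholded probe trace and the
winner-take-all dwell intervals of the projected amplitudes; the
acceptance suite requires overlap above 0.8 for every pattern, and the
default configuration achieves about 0.97–0.99.

## What the generated data do and do not show

All inputs are synthetic and generated in code: analytic sine modes,
stroke-rendered digits, and in-span Gaussian perturbations. Passing tests
therefore demonstrate the *mechanism* — kernels constructed from patterns
reproduce the prescribed metastable itinerary, with realistic-looking
trial variability arising purely from initial-condition spread — not that
the model fits any particular recording. Observational noise is white,
Gaussian, and independent across probes; real EEG noise is colored and
spatially correlated. The dynamics here are noiseless between
measurements (dynamical noise is out of scope), dwell times grow slowly
across cycles rather than being exactly periodic, and absolute transition
times depend on the unpublished interaction weights of the original
study, so they are treated as qualitative throughout.

## Known limitations

* Only closed contours (cyclic successor maps) are exercised; open
  heteroclinic sequences fit the data model but are untested.
* Homogeneous (translation-invariant) kernels and Fourier solvers are out
  of scope — the point of the construction is heterogeneity.
* The sigmoidal activation of the general Amari equation is never
  evaluated; the simulated equation is exactly the quadratic expansion.
* Dense kernels are a small-grid debugging device; the factored path is
  the production representation.
* The threshold-based dwell detector reports the time above the
  dominance level 0.9 (on the amplitude scale where a saddle sits at 1),
  which includes part of each rise and fall; alternative definitions
  shift dwell times by a tick or two.
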