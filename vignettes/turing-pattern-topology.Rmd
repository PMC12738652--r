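---
title: "Classifying Turing-pattern topology with persistent homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Turing-pattern topology with persistent homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turingtda)
```

## The scientific problem

Two-species reaction-diffusion systems with a diffusion-driven (Turing)
instability settle, from near-homogeneous initial states, into stable spatial
patterns — spots, stripes, labyrinths. Linear theory predicts *when* the
homogeneous state destabilises and which Fourier modes grow first, but the
final pattern is selected by nonlinear dynamics and by the random initial
condition, so the relation between kinetic parameters and long-time pattern
*topology* is not analytically accessible except in special regimes. This
package implements a numerical pipeline that makes that relation measurable:
simulate the PDEs across a discretised Turing space, summarise each stable
pattern by the persistent homology of star filtrations of the two
concentration fields, and cluster parameter points under composite Wasserstein
metrics between the resulting persistence diagrams.

Two kinetic models are built in:

* **CIMA** (chlorite–iodide–malonic acid, Lengyel–Epstein reduction), in
  nondimensional form
  $$u_\tau = \nabla^2 u + \alpha - u - \tfrac{4uv}{1+u^2},\qquad
    v_\tau = \sigma\bigl(\delta\,\nabla^2 v + \beta u - \tfrac{\beta uv}{1+u^2}\bigr),$$
  with feed $\alpha$, kinetic rate $\beta$, diffusivity ratio $\delta$ and
  starch factor $\sigma$ (all positive, dimensionless). These are *pure*
  kinetics: in a stable pattern the extrema of $u$ and $v$ are aligned.
* **Schnakenberg**,
  $$u_\tau = \nabla^2 u + \alpha - u + u^2 v,\qquad
    v_\tau = \delta\,\nabla^2 v + \beta - u^2 v,$$
  *cross* kinetics: the two species pattern in anti-phase.

All analysis happens on the closed rectangle $[0,L_x]\times[0,L_y]$ with
zero-flux (Neumann) boundaries.

## Linear and weakly nonlinear layer

`linearise()` evaluates the Jacobian of the kinetics at the uniform steady
state — for CIMA, $(u_s,v_s) = (\alpha/5,\,1+\alpha^2/25)$ with the closed-form
matrix $\tfrac{1}{\alpha^2+25}\begin{pmatrix}3\alpha^2-125 & -20\alpha\\
2\alpha^2\beta\sigma & -5\alpha\beta\sigma\end{pmatrix}$; for Schnakenberg the
derivatives of the kinetics at $(\alpha+\beta,\ \beta/(\alpha+\beta)^2)$ — and
the effective diffusivities $(d_u, d_v) = (1, \sigma\delta)$ (CIMA) or
$(1,\delta)$ (Schnakenberg). `turing_conditions()` evaluates the four
classical inequalities (stability without diffusion, positivity of the kinetic
determinant, and the two cross-diffusion conditions); all four strict, so the
Hopf boundary $f_u+g_v = 0$ is excluded.

`dispersion()` returns $h(k^2) = d_ud_vk^4 - (d_vf_u + d_ug_v)k^2 +
\det J$ — the determinant of the $k^2$-shifted Jacobian — and $\lambda(k^2)$,
the largest real part of its eigenvalues. We take the real part because
complex pairs occur near the Hopf boundary; whenever $h<0$ the eigenvalues are
real with opposite signs, so $h(k^2) < 0 \Leftrightarrow$ the mode grows.
`enumerate_modes()` walks the Neumann cosine modes
$k^2_{m,n} = \pi^2(m^2/L_x^2 + n^2/L_y^2)$, $(m,n)$ nonnegative and not both
zero, counting $(m,n)$ and $(n,m)$ separately. `dominant_mode()` reports the
unstable mode maximising $\lambda$ and the percentage gap
$100(\lambda_1-\lambda_2)/\lambda_1$ between the two largest growth rates over
*distinct* $k^2$ (so symmetric twins on a square do not register a spurious
zero gap; the gap formula itself is this package's definition).

For pattern selection at onset on small squares, `ermentrout()` evaluates the
amplitude-equation scalars $a(\alpha)$ and $b(\alpha)$ for the CIMA kinetics
(stripes stable iff $b<a<0$, spots stable iff $a<-|b|<0$). Since the only
$\delta,\sigma$-dependence is a common positive prefactor, the classification
depends on $\alpha$ alone. `critical_alphas()` locates the three boundaries of
the classification on $(0,20)$ — `2.501, 11.581, 12.630` to three decimals —
by a dense scan (step 0.01) plus bisection to $10^{-5}$. We deliberately
locate *classification changes* rather than solving $a=0$, $a=b$, $a=-b$
individually, because the three boundaries are defined by different equalities
and the scan-and-bisect formulation needs no case analysis.

## Simulation layer

`build_grid()` demands that the side lengths be integer multiples of the
stepsize — a misfit errors rather than silently remeshing. The method-of-lines
discretisation uses the 5-point Laplacian with mirrored ghost nodes
(second-order, zero-flux). Under this stencil the conserved quantity of pure
diffusion is the trapezoid-rule integral (boundary vertices weighted 1/2),
which is what `field_mean()` computes and what the conservation test checks to
$10^{-8}$.

Two integrators are provided. The default (`method = "imex"`) is a
Peaceman–Rachford alternating-direction-implicit scheme for the diffusion
operator — unconditionally stable, one tridiagonal sweep per axis per
half-step with precomputed factorisations — with the reaction terms advanced
explicitly inside the half-steps; the time step (default 0.02) is additionally
capped at half the reciprocal of the reaction Jacobian's largest entry at the
steady state, keeping the explicit part well inside its stability region. The
alternative (`method = "rk45"`) is an adaptive Dormand–Prince 5(4) pair on
the full system; it is step-size-limited by the diffusion stiffness
($\Delta t \lesssim h^2/4d_{\max}$) and therefore roughly fifty times slower
at stepsize 0.5, but free of splitting error. The IMEX default is this
package's choice for parameter sweeps; the two integrators agree to
$O(10^{-3})$ on pattern trajectories, and the explicit pair is used in the
tests that need high temporal accuracy (the linear growth-rate check, where a
seeded single-mode perturbation must grow at $\lambda(k^2)$ to within 10%).

Initial conditions are independent Gaussian $N(0, 0.1^2)$ perturbations of the
steady state at every vertex — white noise that excites all modes, which is
what makes the final pattern seed-dependent wherever several modes are
unstable. Integration runs to $\tau = 250$ by default, stopping earlier when
the sup-norm of the time derivative falls below `steady_tol` ($10^{-5}$; the
"numerically steady" notion of convergence — some near-boundary parameter
points have arbitrarily slow transients, so convergence here is computational,
checked by the doubling-the-horizon robustness test rather than by an
asymptotic guarantee). Blow-up (non-finite or $>10^8$ values) raises an error
with the integration time reached.

The mesh must resolve the finest unstable wavelength.
`max_unstable_wavenumber()` scans the restricted Turing space — for CIMA,
$\alpha$ and $\sigma$ on a 0.1 grid with $\beta$ scanned at 0.01 over its
feasible interval, which is available in closed form from the first and third
Turing conditions — and reports the unstable Neumann mode of largest $k^2$.
Over $\alpha\in[0,20]$, $\sigma\in[1,20]$, $\delta=1.5$ on the $20\times20$
square this is the $(9,3)$ mode, found in a thin sliver near the
high-$\alpha$, high-$\sigma$ Hopf corner; its finest axis variation, like that
of the more commonly quoted $(9,0)$ mode, is $m=9$ half-periods across the
domain. `nyquist_stepsize()` converts the mode to the sampling bound
$\tfrac12\min(L_x/m, L_y/n)$ — the cosine half-period convention, under which
the bound is $10/9 \approx 1.11$, so the production stepsize 0.5 resolves the
band comfortably. We use the half-period convention (not $2\pi/k$) because the
bound is about resolving sign changes of the eigenfunction along an axis.

## Persistence layer

`triangulate_grid()` splits every cell along the lower-left-to-upper-right
diagonal — a fixed, documented convention; any consistent diagonal gives a
triangulated disk ($V - E + F = 1$), and fixing one keeps runs reproducible.

`star_filtration()` builds the 20-level lower- or upper-star filtration: with
thresholds dividing $[\min u, \max u]$ evenly, a vertex enters at the first
threshold it passes and a simplex enters when its last vertex does. Levels are
indexed $1..20$; bar lengths are measured in these level units, and the
default cleaning cutoff 5 is in the same units. Because thresholds are tied to
each field's own range, the filtration normalises amplitude away — diagrams
from parameter points with very different pattern amplitudes are directly
comparable (the trade-off: amplitude information is lost, so a separate
amplitude diagnostic $\max u - \min u$ is carried through the pipeline). A
constant field is placed entirely at level 1, keeping the filtration
exhaustive. With `n_levels = "exact"` no quantisation is applied — each
distinct vertex value becomes a level — which is the exact star filtration of
the piecewise-linear field and the object for which the stability theorem
holds verbatim.

`compute_barcodes()` runs the standard column reduction of the level-sorted
boundary matrix over $\mathbb{F}_p$ (default $p=2$; configurable prime — on
these 2-complexes no torsion arises and $\mathbb{F}_2$ and $\mathbb{F}_{11}$
agree, which is tested). Simplices are ordered by (level, dimension,
construction index); zero-persistence pairs are dropped; unpaired creators
become essential bars with death $\infty$. The implementation is validated on
random small complexes against an independent oracle that computes persistent
Betti numbers from ranks of boundary operators and recovers bar multiplicities
by inclusion-exclusion.

The filtration convention per model follows the kinetics: for CIMA (pure),
lower-star of $u$ and upper-star of $v$; for Schnakenberg (cross), upper-star
of both. `clean_barcode_set()` applies per-channel cutoffs, default
$(B_0^u, B_1^u, B_0^v, B_1^v) = (5, 0, 5, 5)$: every bar of the degree-1
$u$ channel is kept because its long bars sit too close to its noise bars for
any useful cutoff, while the other channels show a clear bimodal length
density whose valley `length_histogram()` locates (the suggested cutoff is the
argmin of the smoothed density between the two lowest-length modes; a
unimodal density yields none).

## Metrics and clustering

`wasserstein_distance()` implements $W_{p,q}$ between diagrams with diagonal
matching: point-to-point cost $\|x-y\|_p$, point-to-diagonal cost
$(d-b)\,2^{1/p-1}$, outer $\ell_q$ aggregation, $q=\infty$ giving the
bottleneck distance. Infinite bars match only each other (the
$\infty-\infty=0$ convention makes their cost the birth difference, and the
one-dimensional matching of sorted births is optimal); diagrams with different
essential counts are infinitely far apart. The finite part is solved exactly
by a Hungarian assignment on the diagonal-augmented bipartite problem, the
bottleneck case by a feasibility binary search over candidate costs. Both are
validated against exhaustive matching enumeration on small diagrams.

`node_distance()` combines the four channel-wise $W_{2,2}$ values: `d1` (sum,
the default pipeline metric), `d2` ($\sqrt{\sum W^2}$) and `dinf` (max). The
channel-wise reading $\sum\sqrt{W^2}$ of `d2` is algebraically identical to
`d1`; we implement the root-sum-square as the intended second metric and keep
the literal reading behind `literal_d2 = TRUE` rather than silently guessing.
Distances are taken in level units on cleaned barcodes by default
(`use_cleaned = FALSE` restores raw diagrams; whether full-scale clustering is
better served by cleaned or raw barcodes is a genuinely open choice, so both
are first-class).

Clustering is agglomerative on the precomputed matrix (`stats::hclust`;
single, complete and average linkage — Ward and centroid require a Euclidean
embedding that a general diagram metric does not provide).
`silhouette_score()` is the mean silhouette width (singletons contribute 0)
and `select_clustering()` grid-searches linkage × k (default $k\in 2..12$),
breaking ties towards smaller k, then earlier linkage.

## Synthetic patterns: what they do and do not show

`make_pattern()` generates the three archetypes from Neumann cosine
eigenfunctions: spots ($\cos\frac{m\pi x}{L_x}\cos\frac{n\pi y}{L_y}$),
stripes ($\cos\frac{m\pi x}{L_x}$), and labyrinths (a seeded random-sign
superposition of at least 14 eigenfunctions with $m^2+n^2$ in a narrow band,
rescaled to the requested amplitude). Equal mode magnitudes with random signs
— rather than random Gaussian weights — keep the topological statistics of
the labyrinth family stable across seeds, which is what lets the three planted
classes separate perfectly under `d1` with silhouette selection; this is a
design choice of the fixture, made so the clustering contract is testable,
not a claim about PDE labyrinths. Ground truth is computed on the noiseless
field by direct grid search: strict local minima (8-neighbourhood) below the
mid-range $(\max+\min)/2$ for spots, connected components (4-neighbourhood) of
the sub-mid-range set for stripes and labyrinths. The mid-range threshold is
arbitrary but fixed. For reference, the $m=n=4$ spot field on the
$20\times20$ grid has 12 strict minima (3 peak positions × 2 trough positions
per axis, both orientations), and the $m=6$ stripe field has 3 troughs.

These fixtures exercise the persistence, metric and clustering layers against
known topology without PDE runs. They do *not* emulate PDE amplitude
profiles, mode competition, or the amplitude collapse near the Turing
boundary; passing fixture tests therefore validates the topological pipeline,
not the solver (which has its own fixed-point, conservation, growth-rate and
cross-integrator tests).

`perturb_field()` adds seeded uniform noise on $[-\varepsilon,\varepsilon]$,
so the sup-norm hypothesis of the stability theorem holds by construction; the
stability tests then assert the bottleneck distance (exact filtration, field
units) is at most $\varepsilon$ in every trial.

## The sweep pipeline

`discretize_turing_space()` rejection-samples a Halton sequence over the
configured box, for CIMA warping the third coordinate onto the feasible
$\beta$ interval at each $(\alpha,\sigma)$ so nodes concentrate where patterns
exist; every accepted node satisfies all four Turing conditions strictly, and
placement is deterministic in the master seed. The default CIMA box is
$\alpha\in[0,20]$, $\sigma\in[1,20]$, $\delta=1.5$; for Schnakenberg we fix
$\delta\in[25,45]$ and chose $\alpha\in[0.01,0.3]$, $\beta\in[0.5,1.8]$ as a
box with a substantial Turing region (the literature gives no canonical
bounds; both are configurable). The production node count default is 549;
desk-scale runs use ~30.

`run_sweep()` simulates each node (per-node seed = master seed + node index),
builds the model's filtration pair, reduces, and stores four barcodes plus the
amplitude diagnostic; results are cached keyed by a configuration hash, failed
nodes are flagged and skipped rather than interpolated. `cluster_sweep()` and
`sweep_report()` finish the job (distance matrix, silhouette selection, CSV +
JSON outputs).

Problem sizes used by the shipped tests, chosen as desk-scale study
conditions: synthetic fixtures on the $41\times41$ grid ($L=20$, stepsize
0.5, the production mesh); stability checks on $13\times13$ grids; the
end-to-end sweep on 30 CIMA nodes (28 quasi-uniform plus the spotted exemplar
at $\alpha=9.74,\beta=0.27,\sigma=12.5$ and the striped exemplar at
$\alpha=20,\beta=1.35,\sigma=11$) at $\tau=250$. At this sample size the
silhouette typically selects two or three clusters — the full seven-cluster
structure of a 549-node study needs the full node budget — but the spotted and
striped exemplars separate reliably, which is the property the acceptance test
asserts.

## Numerical choices and degenerate inputs

* Level quantisation ties: a vertex exactly on a threshold joins the lower
  level (with a $10^{-9}$ relative guard against floating-point noise).
* Constant fields: all simplices at level 1; diagrams are a single essential
  component.
* `wasserstein_distance` on two empty diagrams is 0; against one empty
  diagram, every point pays its diagonal cost.
* Mode enumeration errors out (rather than truncating) when the unstable band
  extends beyond the enumerated indices, and `integrate_rd` warns when the
  grid stepsize violates the sampling bound.
* Steady-state residual tolerance $10^{-12}$ (relative) at construction;
  singular prefactors in the weakly nonlinear scalars
  ($\alpha^2 = 75$ or $\alpha^2(2\delta\sigma-3)+225 = 0$) are rejected.

## Known limitations

* Domains are rectangles with uniform grids; no curved or heterogeneous
  domains, no spatially varying parameters.
* Homology is computed in degrees 0 and 1 only (the domain is a disk).
* The labyrinth fixture is a topological stand-in, not a PDE surrogate.
* Cluster counts at desk scale are not comparable to full-scale sweeps;
  only the relative separations are.
* The Wasserstein solver is exact but $O(n^3)$ in diagram size; it is sized
  for cleaned diagrams (tens of points), not for raw diagrams of very noisy
  fields at scale.
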