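---
title: "Neural fields on flat and curved triangulated domains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural fields on flat and curved triangulated domains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurofield)
```

## The model

`neurofield` solves a two-variable neural field model on a spatial domain
$\Omega$ that may be a flat periodic square or a closed curved surface:

$$
\frac{\partial u}{\partial t} = -u - a +
  A \int_\Omega w\big(d(\mathbf{x}, \mathbf{x}')\big)\,
  S\big(u(\mathbf{x}', t) - h\big)\, d\Omega(\mathbf{x}'),
\qquad
\tau \frac{\partial a}{\partial t} = B u - a .
$$

Here $u(\mathbf{x},t)$ is the mean activity of the neuronal population at
$\mathbf{x}$, and $a$ is a slow recovery (negative-feedback) field that
repolarises active regions; without it, localized activity is stationary,
with it, bumps of activity can travel. The connectivity kernel is a
mexican hat in the *intrinsic* (geodesic) distance $d$,

$$ w(d) = e^{-d^2} - c_2\, e^{-\gamma d^2}, \qquad c_2 = 0.17,\ \gamma = 0.2, $$

short-range excitation with a weaker, wider inhibitory surround; the sign
change sits at $d^\ast = \sqrt{\log(1/c_2)/(1-\gamma)} \approx 1.488$. The
firing rate is the sigmoid $S(v) = 1/(1+e^{-\beta v})$ evaluated at
$v = u - h$. Model constants default to $A=2$, $B=0.4$, $h=0.8$, $\tau=3$,
$\beta=5$ (`nf_params()`); all are dimensionless except $\tau$ (time units of
the ODE clock).

The distance function is what couples the dynamics to geometry: on the flat
periodic square $[-L,L]^2$ it is the minimal-image Euclidean distance (the
translation-invariant metric consistent with solving the convolution form of
the integral with periodic boundary conditions), and on a surface it is the
geodesic distance of the induced metric.

## Spatial discretisation

The domain is a conforming triangulation (`nf_mesh`). The unknowns are nodal
values; within each triangle $u$ is the linear interpolant, and the nonlocal
integral is evaluated triangle by triangle after the affine map
$T_k(r,s) = (1-r-s)\mathbf v_{k,1} + s\,\mathbf v_{k,2} + r\,\mathbf v_{k,3}$
from the unit simplex, whose Jacobian contributes the factor
$2\,\mathrm{Area}(\triangle_k)$. With the three-point vertex quadrature rule
$\int_\sigma G \approx \tfrac16[G(0,0)+G(0,1)+G(1,0)]$ (exact for linears)
the assembled interaction collapses to a lumped form: node $j$ carries the
weight $A_j = \sum_{k \ni j} \mathrm{Area}(\triangle_k)/3$, and enforcing the
equation at the nodes yields the ODE system

$$
\dot u_i = -u_i - a_i + A \sum_j w(d_{ij})\, A_j\, S(u_j - h), \qquad
\dot a_i = (B u_i - a_i)/\tau .
$$

On the regular periodic Cartesian grid every distinct node touches exactly
six triangles of area $\Delta x^2/2$, so $A_j = \Delta x^2$: vertex-rule
collocation *is* the composite trapezoidal rule there, which is why it
inherits the trapezoidal rule's super-algebraic (geometric) convergence on
smooth periodic integrands, and why the package can cross-validate the
collocation path against the trapezoidal and FFT-convolution paths to
machine precision (`trapezoid_integral_plane()`, `fft_integral_plane()`).
On the torus the parametric trapezoidal rule with the exact area element
$r(R + r\cos\theta')\,d\theta' d\phi'$ is available as a reference
(`trapezoid_integral_torus()`); the integral there is not a convolution, so
no FFT shortcut exists.

A degree-2 simplex rule (`simplex_rule("midpoint")`) is supported behind the
same interface, with kernel values at non-vertex points obtained by
barycentric interpolation of vertex distances. It is experimental: the
interpolation reintroduces an $O(h^2)$ error floor, so it does not raise the
asymptotic order and is excluded from the operator assembly path.

Time integration uses the adaptive Dormand–Prince 4(5) pair (`deSolve`'s
`ode45`) with absolute and relative tolerances $10^{-6}$ and dense output at
stride 1 (`nf_integrate()`).

## Geodesic distances

Three interchangeable distance layers stand behind one contract
(`all_pairs_distances()`):

* **`analytic`** — the minimal-image closed form on the periodic plane.
* **`fmm`** (default for general meshes) — first-order fast marching on the
  triangulation. Three standard accuracy devices are built in: corners wider
  than 75° are split by unfolding into virtual support pairs (the classical
  obtuse-angle remedy, applied early because it also tightens the error
  constant of right-angled grids); relaxation is allowed along virtual
  (unfolded) support edges; and each source is initialised with *exact*
  polyhedral distances inside a metric radius of 1.5 length units (the
  excitatory range of the kernel), computed by a depth-limited
  continuous-Dijkstra unfolding with visibility-cone pruning. The patch
  radius is resolution-independent, so the near field — where the kernel is
  largest — is exact at every mesh size. Worst-case error against the
  analytic metric on a fine flat periodic mesh is ≈1.2%.
* **`parametric`** (regular torus grids) — the eikonal equation
  $ (\partial_\theta d / r)^2 + (\partial_\phi d / (R + r\cos\theta))^2 = 1 $
  solved by Godunov upwind fast sweeping on a fine periodic reference grid
  (an exact multiple of the simulation grid, one solve per $\theta$ row),
  evaluated by $C^1$ periodic bicubic interpolation. This is the most
  accurate layer for the torus and plays the role that exact polyhedral
  geodesics play for general meshes.

The `dijkstra` backend (edge-graph shortest paths) is kept as an upper-bound
baseline: graph distances always overestimate geodesics, which the tests
assert pointwise.

Backend outputs are symmetrised by averaging $d_{ij}$ and $d_{ji}$; the raw
asymmetry is recorded as a diagnostic. A practical lesson learned while
validating the torus dynamics is recorded here deliberately: the travelling
bump is sensitive to *asymmetric* components of the distance error. A
reflection-asymmetric error of magnitude ~0.1 visibly bends the trajectory
off the equator, while symmetric errors of the same size merely perturb the
speed. This is why the torus simulations default to the parametric backend
(symmetric to ~1e-11) and why the reference grid is constrained to be an
exact multiple of the mesh grid.

## Convergence protocol

Grid convergence is measured exactly as the refinement studies report it:
the nonlocal integral $I$ is evaluated at the node nearest the domain
origin with $u = w(d(\text{origin},\cdot))$ (a smooth field qualitatively
similar to a bump), meshes are refined stage by stage, and the error proxy
is $|I_{m+1} - I_m|$. The plane uses the schedule $N_m = (2^m\cdot 8 + 1)^2$;
irregular meshes and the torus triangulation are refined by quadrisection
(edge midpoints; on the torus, midpoints are reprojected onto the analytic
surface, keeping planar elements with vertices on the torus).

Orders are least-squares slopes of $\log$ error against $\log h$ with
$h \propto N^{-1/2}$. Two regimes are excluded from the fitted slope, both
decided once and applied uniformly:

* *pre-asymptotic stages*, where the consecutive relative change exceeds 5%
  of the converged value — the coarsest grids (spacing larger than the
  kernel width) do not resolve the integrand at all, and slopes fitted
  through them exceed the theoretical maximum order of every scheme;
* *saturated stages*, where the consecutive relative change falls below
  $\sqrt{\varepsilon_{\text{mach}}}$ — differences this small no longer
  measure discretisation error. On the regular plane the decay bottoms out
  near $5\times10^{-9}$ relative: the cut-locus kink of the minimal-image
  metric (the kernel tail is ~$2\times10^{-6}$ at the half-period) caps the
  otherwise geometric decay. The geometric-decay flag (strictly increasing
  local order estimates) is therefore evaluated on the unsaturated stages.

Both torus studies evaluate the *fixed* parametric distance field, so the
consecutive differences isolate the convergence of the integral
discretisation; recomputing first-order fast-marching distances on every
mesh adds distance-error noise of order $10^{-3}$ that dominates and
scrambles the differences (the option `per_mesh_distances = TRUE` exposes
that variant). Measured this way, the trapezoidal rule on the torus
converges at order ≈1.8 and collocation at ≈1.7 (both capped at 2 by the
cut-locus kink of $d$ and, for collocation, by the vertex rule's $O(h^2)$
composite error); irregular planar collocation measures ≈2 as quadrature
theory predicts for a rule exact on linears. We note expressly that these
measured orders are what the implementation produces under cross-validated
conditions; reports of *first*-order behaviour for such discretisations
correspond to slopes against node count $N$ (where slope 1 equals order 2 in
$h$) or to pre-asymptotic ranges.

## Travelling bumps and tracking

The standard experiments initialise $u$ at a raised level in a rectangular
patch and $a$ at 1.5 in an equally sized patch offset in the propagation
direction; the bump then travels *away* from the recovery patch. Patch
geometry is a package decision (the underlying studies do not specify it):
on the plane, $u = 1$ on a $2\times2$ patch at the origin with the $a$ patch
shifted $+2$ in $x$; on the torus, the same geometry transplanted in arc
length at the outer equator — $u = 2$ on a patch of 1.0 rad in $\theta$
($\approx 2$ length units) by 0.31 rad in $\phi$, $a$ shifted $+0.31$ rad in
$\phi$. Two cautions discovered while fixing these defaults: patches much
smaller than the kernel scale (e.g. 0.6 rad square) let the transient wrap
the tube into a ring state instead of a localized spot, and grids coarser
than about $48\times96$ on the $R=4.5, r=2$ torus pin the slow bump
(speed ≈ 0.11) to the lattice — it advances one cell and stops. The package
therefore uses $48\times96$ (4608 nodes) as its torus study size, and
$33^2$ nodes with $T=250$ on the plane; full-size runs remain available
through the same functions.

`track_bump()` reduces each output sample to a centroid: nodes with
$u \ge \tfrac12\max u$ weighted by vertex area times the *soft* excess
$(u - \tfrac12\max u)_+$. The soft weight makes the centroid continuous in
the field, which matters for speed estimates: with a hard membership cut,
support changes dominate the per-step speed (relative SD 0.33 on the torus
demo versus 0.037 with the soft weight). Plane centroids use circular means
per coordinate (period $2L$); surface centroids are reprojected onto the
torus or, for general meshes, to the nearest vertex. Speeds are consecutive
centroid distances per unit time — minimal-image on the plane, ambient chord
on surfaces (consecutive centroids are ~0.1–0.2 length units apart, so the
chord–geodesic gap is $O(K d^3) \approx 10^{-4}$). Curvature along the path
is the analytic $K(\theta) = \cos\theta / (r(R + r\cos\theta))$ when a torus
domain is attached and the angle-defect estimate otherwise (single-vertex
angle defects are noisy, which is the other reason centroids, not raw
maxima, are tracked). "Constant speed" is operationalised as relative SD
≤ 5% after discarding the first 10% of samples.

On the regular plane grid the mesh (and hence the discrete dynamics) is
exactly symmetric about the launch line, so the measured drift is zero to
rounding; on irregular meshes the drift is finite and shrinks under
refinement, which `drift_metric()` quantifies.

## Synthetic geometry and what the tests do (and do not) show

All test geometries are generated in code: the periodic Cartesian grid, a
seeded irregular mesh (jittered lattice, boundary-constrained Delaunay,
Laplacian smoothing — boundary nodes fixed and mirrored so periodic
identification is exact), the regular torus grid, and a synthetic "bumpy"
closed surface (`bumpy_torus_mesh()`, a torus with harmonically modulated
minor radius) standing in for folded cortical sheets. Passing tests
demonstrate the numerics — convergence orders, machine-precision agreement
of independent discretisations, geodesic accuracy contracts, and the
qualitative bump phenomenology (leftward planar bumps, constant-speed
equatorial bumps, variable-speed non-geodesic trajectories over variable
curvature). They do not certify behaviour on real cortical meshes, whose
element quality, topology noise, and scale differ; the general-mesh pathway
(OFF/PLY input, fast-marching distances, node-fraction initial conditions)
is the supported route for such data.

## Degenerate inputs and numerical choices

Meshes are validated on construction (index ranges, no zero-area triangles);
closedness is determined from edge incidence and gates the curvature and
distance layers. The sigmoid is evaluated overflow-safely. Zero consecutive
errors are excluded from order fits with a warning. The dense
$n \times n$ interaction operator is guarded by an explicit size check
(default cap 20000 nodes). Distance caches are keyed by a mesh content hash
and the backend name; mismatches trigger recomputation with a warning rather
than silent reuse. Configuration files are validated — unknown keys
rejected, $\tau > 0$, $\beta > 0$, $T > 0$ — before any computation, and
each `nf_run()` writes its config, package version, seed, and stage log next
to its outputs so every artefact is attributable.
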