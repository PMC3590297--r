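---
title: "hyperview: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hyperview: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperview)
```

`hyperview` is a headless re-implementation of the computations behind
GPU molecular viewers: bond perception, Gaussian surfaces, ray-cast
quadric primitives with lit-sphere shading and cut planes,
electrostatic field-line animation, 3D network layout, and a spring
network. This vignette records the models it implements, why each
default is what it is, and the numerical decisions a maintainer would
want written down.

## Bond perception

Bonds are perceived from geometry alone: atoms $i,j$ are bonded when

$$d_{\min} < d(i,j) \le r_i^{\mathrm{cov}} + r_j^{\mathrm{cov}} + t,$$

with single-bond covalent radii from the Cordero (2008) compilation
(shipped in `inst/extdata/elements.tsv` together with van der Waals
radii, masses and CPK-like display colors; unknown symbols fall back to
a generic 0.77 Å row with a warning, never an error). The slack
$t = 0.4$ Å and floor $d_{\min} = 0.4$ Å are the long-standing
viewer heuristics; both are exposed through `bond_params()` because the
right calibration depends on which hydrogens, waters and alternate
locations a parse policy admits — `pdb_policy()` keeps those switches
in one object for the same reason. Two refinements reflect viewer
convention rather than chemistry: a hydrogen is assigned at most its
single nearest eligible heavy partner (without this, the 0.4 Å slack
lets one H bridge two donors), and water residues only bond internally.

Candidate pairs come from a uniform spatial hash with cell size equal
to the largest possible cutoff, so detection is near-linear in atom
count; the test suite pins the hash against a brute-force all-pairs
oracle on random 500-atom clouds (exact set equality).

## Gaussian density and marching cubes

The density is a sum of truncated atom-centered Gaussians

$$\rho(\mathbf{x}) = \sum_i \exp\!\Big(B\big(\tfrac{d_i^2}{r_i^2} - 1\big)\Big),$$

with blobbiness $B = -2$, iso level $\tau = 1$, grid spacing
$h = 0.5$ Å and padding 3 Å by default. This particular normalization
is chosen so an *isolated* atom has density exactly 1 at distance
$r_i$: the $\tau = 1$ surface of a single atom is exactly its sphere,
which turns surface accuracy into a measurable quantity (the RMS radial
error of the extracted sphere) instead of a visual judgement. $B$
controls how much neighboring atoms blend; more negative is tighter.
Contributions are truncated at $3 r_i$ (`cutoff_mult`) and accumulated
into the local block of cells only, keeping the build
$O(\text{atoms} \times \text{cutoff volume})$.

Marching cubes is the classic 256-case algorithm, with one
implementation decision worth recording: the per-configuration triangle
table is *derived constructively at load time* rather than transcribed.
For each corner-sign pattern, intersected cube edges are linked into
polygons by pairing them on each face; on the ambiguous face (4
intersected edges) the pairing isolates the inside corners — a rule
that depends only on the face's own corner signs, so both cells sharing
a face always agree, which makes meshes watertight by construction.
Polygons are oriented by their Newell normal against the inside-corner
centroid and fan-triangulated. Two geometric cleanups follow at
assembly: vertices that coincide (which happens exactly when a grid
node sits on the iso level, making several edges interpolate onto the
same node) are welded and zero-area triangles dropped; and each face's
winding is checked against the density gradient at its centroid, since
a strongly skewed 5–6-gon can make a naive fan triangle flip even when
the polygon as a whole is oriented correctly. The exported convention:
triangle normals point toward decreasing density (outward for a blob),
and per-vertex normals are the normalized negative gradient.

Vertices are placed by linear interpolation
$t = (\tau - v_a)/(v_b - v_a)$ along straddling edges; "inside" is
strictly $v > \tau$. An iso level outside the grid's value range yields
an empty mesh, not an error. On a fixed 32³ single-atom grid this
implementation produces the same vertex and face counts (642 / 1280) as
an independent reference implementation, frozen into the tests.

## HyperBalls quadrics

Atoms are sphere quadrics; bonds are one-sheeted hyperboloids of
revolution, in the bond frame

$$\rho^2 = a^2 + c\,(x - x_w)^2, \qquad a = (1 - s)\min(r_i, r_j),$$

with shrink $s \in [0, 1)$. At $s = 0$ and equal radii the surface
degenerates to a cylinder ($c = 0$); as $s \to 1$ the waist pinches
toward the cone/two-sheet limit. The free parameters $(c, x_w)$ are
determined by requiring tangency to both atom spheres. Substituting
$u = c/(1+c)$ makes the two tangency conditions linear in $u$, which
gives a closed-form elimination used as the starting point of a damped
two-unknown Newton iteration (residual tolerance $10^{-10}$, $c$ kept
nonnegative); the closed form alone would suffice in exact arithmetic,
but the Newton polish pins the residual regardless of conditioning. The
quadric is clipped to the slab between the tangency abscissae
$x_i^t = u x_w$ and $x_j^t = u x_w + (1-u) D$, leaving each sphere to
cap its own end. Configurations with one sphere inside the other, or
too close for the requested shrink (no external tangency), are
rejected with an explicit error — for bonded atoms drawn at covalent
scale this does not arise at moderate shrink, but heavily overlapping
spheres with a tiny waist genuinely admit no tangent one-sheet surface.
All quadrics use the inside-negative sign convention; whether the
original shrink parameter of GPU implementations maps linearly to the
waist is not recoverable from published descriptions, so the mapping
above is defined (and documented) as this toolkit's semantics.

Ray intersection substitutes $\mathbf{p}(t)$ into
$\tilde{\mathbf p}^\top Q \tilde{\mathbf p} = 0$ and solves the
quadratic with the numerically stable form of the root pair; the
nearest root with $t > 0$ passing the clip slab wins, falling through
to the far root when the near one is clipped. Normals are
$2 Q \tilde{\mathbf p}$ truncated to 3 components, oriented toward the
ray origin. An independent bracketing-plus-bisection sampler along the
ray serves as the oracle in tests (agreement to $10^{-6}$ in $t$).

## Renderer

The camera is right-handed with view direction $-z$ and $y$ up on
screen; normals are stored in camera space so lit-sphere shading is the
literal matcap lookup $(u, v) = ((n_x+1)/2,\; 1-(n_y+1)/2)$ with the
$v$ axis flipped so texture "up" is screen "up". Sphere primitives are
rendered as exact analytic impostors: per-pixel ray-sphere tests
restricted to the projected bounding box — the same visual contract as
point-sprite particles, with no GPU. The particle representation
processes its primitive list in chunks of at most 16,000 (the
per-system limit of the particle engines it models); chunking is an
implementation policy and is asserted pixel-identical to the unchunked
render (this toolkit has no transparency, where per-chunk ordering
could show).

One sample per pixel, no anti-aliasing: this keeps analytic coverage
oracles (disk areas, cap areas) exact up to quantization, which is how
the renderer is tested. Shading is either a headlight Lambert term with
a 0.15 ambient floor, or the lit-sphere lookup blended with the flat
base color by `litsphere_blend`. The cut plane keeps
$(\mathbf p - \mathbf p_0)\cdot\mathbf n \le 0$; when a ray's near hit
is discarded by the cut and the same primitive's far hit survives, that
far point is painted with the flat cap color (normal = plane normal) —
the uniform-interior fill that makes the object read as solid. Meshes
rasterize through a z-buffer with barycentric normal interpolation;
back faces exposed by a cut are painted the cap color.

`write_png()` quantizes to 8-bit and is byte-deterministic.

## Electrostatic field lines

Lines are streamlines of $\mathbf E = -\nabla\phi$ on a trilinearly
interpolated grid, integrated by classical RK4 on the *unit* direction
field (arclength parameterization) with fixed step
$h_t = 0.25\,\min(\text{spacing})$: normalizing removes stiffness near
charges and makes the step a geometric quantity. Gradients are central
differences of the trilinear interpolant with step = half the local
spacing, so the differentiable domain ends half a cell inside the grid.

Stopping rules are a design decision (published descriptions of the
animated-line technique do not fix integrator or stopping): domain
exit, $|\mathbf E| < 10^{-6}$, step/length caps, plus two guards this
toolkit adds for critical points. A sharp reversal of the advected
direction between consecutive steps, or a relative change of
$|\mathbf E|$ exceeding 15% within one step (`max_grad_ratio`), both
signal a source/sink the grid cannot resolve — near a point charge
$|\mathbf E| \sim 1/d^2$ changes by $\approx 2h_t/d$ per step, so the
15% guard halts tracing about three grid cells from the singularity,
which is where trilinear interpolation of a Coulomb field stops being
directionally trustworthy (about 1° error at that distance, growing
fast inside). Consequences worth knowing: traced lines end a few cells
short of point charges, and the endpoint of a charge-terminated branch
moves with the step size (the domain-exit endpoint converges normally,
which is what the convergence test measures).

Seeds are surface vertices ranked by $|\phi|$ descending, greedily
thinned so no two kept seeds are closer than twice the mean grid
spacing (an invented but simple rule for "some representative lines"),
then truncated. The dash mask at arclength $d$ and time $t$ is
$\mathrm{phase} = \mathrm{frac}(d/\lambda - f t)$ with carrier
$\tfrac12(1+\sin 2\pi\,\mathrm{phase})$ shown where
$\mathrm{phase} < \mathrm{duty}$: a dash of length
$\mathrm{duty}\cdot\lambda$ per wavelength advancing at $f\lambda$ Å/s.
Defaults $\lambda = 5$ Å, duty 0.3, $f = 1$ cycle/s.

## Networks and springs

XGMML import takes node radius as half the graphics width (then height,
then 1.0), colors from the hex fill, and negates the imported $y$
because the Cytoscape axis grows downward. The depth layout is the
simplest rule with the stated behavior: a linear min-max normalization
$z = \mathrm{depth}\cdot(r - r_{\min})/(r_{\max} - r_{\min})$, zero for
equal radii, idempotent, and invariant under rescaling all radii. The
package's network camera sits on the negative-$z$ side, so a positive
depth factor pushes large nodes into the background. Nodes become
sphere quadrics, edges become low-shrink hyperboloids through the same
constructors as molecular bonds; labels are carried in the model and
exported as a TSV sidecar (text rasterization is out of scope).

The spring network puts one spring on every bond with rest length equal
to the current distance — the loaded conformation is the equilibrium —
and integrates semi-implicit Euler: forces update velocities, new
velocities update positions, pinned atoms never move. The integrator
matches game-physics practice, is stable for
$\mathrm{dt} < 0.2\sqrt{m/k}$, and conserves a shadow energy: the true
energy oscillates within an $O(\mathrm{dt}\,\omega)$ band without
secular drift, which is exactly what the conservation test measures
(time-averaged energy at the start vs the end of $10^4$ steps).
Per-atom energies split each spring's $\tfrac12 k (\ell - \ell_0)^2$
half to each endpoint; coloring maps zero energy to white and the frame
maximum to black (frame-max normalization chosen for visibility; a
fixed reference scale is available for comparable frames). Interactive
dragging is modeled headlessly as `external_force` and `pinned` sets.

## Synthetic data

The fixture generators make every stage testable without downloads or
external solvers, and they define the conditions under which the
package's checks run: two-atom and chain structures at covalent-like
spacings (1.5 Å); analytic Coulomb potentials — point charge and dipole
— sampled on 32³–64³ grids over 20 Å domains, with charges snapped to
cell centers so no node touches a singularity and the dipole grid is
exactly antisymmetric; seeded G(n, m) networks with degree-proportional
radii (mimicking connectivity-based sizing) serializable to XGMML; and
three procedural lit-sphere textures (vertical gradient, polar checker,
Lambert-lit hemisphere). All randomized generators are pure functions
of (parameters, seed) and restore the global RNG state.

What they deliberately do not emulate: real proteins' element mix,
alternate locations and disorder; solver-grade electrostatics (APBS
potentials include dielectric boundaries the analytic Coulomb grids do
not); and Cytoscape's actual size/color conventions beyond the fields
the parser reads. Passing tests therefore demonstrate the geometry and
numerics are right, not that any biological conclusion follows;
structure-level calibration (atom and bond counts of published PDB
entries) lives in two network-dependent tests that skip cleanly
offline.

## Problem sizes and interfaces

The test suite and the verification script use sizes chosen to make
every check complete in seconds on one CPU: 256² frames for the render
oracles, 64³ grids for field-line accuracy, 32³ for the marching-cubes
reference comparison, 500-atom clouds for the spatial-hash oracle,
$10^4$ steps for energy-conservation runs. All are ordinary parameters;
nothing in the implementation is specific to these sizes.

R-facing conventions adapted from the language: bond and face indices
are 1-based; colors are numeric RGB in $[0,1]$; the out-of-domain
signal from grid sampling is `NA`; chunk ranges are reported 0-based
half-open, matching how they are consumed. The command line
(`exec/hyperview`, a thin wrapper over `hv_run()`) mirrors the R
functions one-to-one; the R API is the primary interface.

## Known limitations

- Marching cubes uses the classic tables without ambiguity resolution;
  pathological saddle grids can produce topologically debatable (still
  watertight) connectivity.
- The renderer has no transparency, anti-aliasing, shadows or
  screen-space effects, by design.
- Field-line tracing is only as good as the grid near its sources; see
  the stopping-rule discussion above.
- `fetch_pdb()` is a convenience; nothing else touches the network.
- Bond perception ignores CONECT records, bond orders and aromaticity.
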