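---
title: "Methods: tract-embedded axonal strain and injury metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tract-embedded axonal strain and injury metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axtract)
```

## The problem

Finite element (FE) head models predict brain tissue strain during impacts,
but concussion pathology is organized along axonal fiber tracts, not along
mesh elements. `axtract` post-processes FE kinematics at the tract level: a
tractography-derived fiber bundle is embedded as chains of massless beam
elements inside the hexahedral mesh of the brain parenchyma, each beam node
kinematically slaved to its host element. Because every beam follows the
interpolated displacement field through time, the axial strain of a beam is
the axonal strain *along the instantaneous fiber direction* — unlike
post-hoc projection of the element strain tensor onto a fixed axis, which
cannot follow element-scale rotation of the fiber during the impact.

The package deliberately stops short of FE solving: it consumes nodal
displacement histories from any solver (or from its own closed-form
generators) and produces strain histories, injury metrics, validation
scores and outcome statistics.

## Kinematics

Solid elements are 8-node trilinear hexahedra. For an element with
reference nodal coordinates $X_i$ and displacements $u_i(t)$, the
deformation gradient at a natural coordinate $\xi$ is

$$F = I + \sum_i u_i \otimes \nabla_X N_i(\xi), \qquad
E = \tfrac12 (F^\top F - I),$$

with $E$ the Green–Lagrange tensor and MPS its largest eigenvalue. $F$ is
exact for affine displacement fields on any (non-degenerate) hexahedron,
which provides the package's strongest oracle: rigid motions must give
$E = 0$ to machine precision, and any homogeneous deformation must be
reproduced exactly, independent of mesh resolution.

**Evaluation point.** Strain is evaluated at the element centroid by
default; an 8-point Gauss average is available via
`element_strain_history(eval_rule = "gauss")`. Solvers differ in where they
sample strain and the choice is not standardized, so it is a configuration
flag rather than an assumption; the two rules coincide for homogeneous
fields.

**Point location.** The inverse isoparametric map is solved by Newton
iteration from $\xi = 0$ (tolerance $10^{-10}$ in natural coordinates, at
most 50 iterations), with candidate elements pre-filtered by an
axis-aligned bounding-box grid. An element claims a point only if the
converged $\xi$ lies in $[-1, 1]^3$ (within tolerance) *and* the forward
map reproduces the query point; the residual guard matters because Newton
can stall inside a strongly distorted element for exterior points. Points
on shared faces are assigned to the containing element with the lowest
index, which makes embeddings deterministic.

## Fibers, beams and embedding

Streamlines (TRK/TCK, world mm) are resampled by arc length at a 1.0 mm
step — the tracking step of the source tractography, so one beam element
corresponds to one tracking step. A trailing remainder shorter than half a
step is merged into the last beam; a longer one is kept as a short final
beam. The merge rule avoids near-zero-length beams whose strain ratios
would be numerically fragile.

Embedding maps every beam node to a host element and natural coordinates.
The beams are pure kinematic trackers (the null-beam convention: negligible
density and cross-section); they never feed forces back. Beam nodes that
fall outside the mesh but within 0.5 mm of the boundary are snapped to the
nearest element surface and counted — tract-to-mesh registration slop of
this size is unavoidable in practice — while fibers with nodes farther out
are dropped and reported, never silently.

**Strain measure.** The default axonal strain is the axial Green–Lagrange
value $\tfrac12(\lambda^2 - 1)$ with $\lambda$ the beam stretch, consistent
with the solid-side measure and exact under the affine oracle
(`axonal_strain_dynamic` then equals $a^\top E a$ for every beam, which the
acceptance checks verify to $10^{-10}$). Engineering ($\lambda - 1$) and
logarithmic ($\ln\lambda$) measures are selectable because beam "axial
strain" conventions differ between solvers; no single convention is
asserted.

## Material axes

For transversely isotropic constitutive use, each solid element's material
axis is the renormalized average of the unit direction vectors of beam
elements passing through it, with "passing through" decided by segment
midpoint containment (deterministic and cheap; exact segment–hexahedron
clipping would change very little at a 1 mm step but costs far more).
Because fiber start/end is arbitrary, directions are sign-unified first:
a vector $v$ is kept if the product of its three components is
non-negative and flipped to $-v$ otherwise. The product rule alone leaves
axis-aligned vectors (zero product) un-unified, so opposite traversals of
an axis-aligned fiber would cancel; the default `"robust"` mode therefore
adds a first-nonzero-component-positive tie-break, while `"strict"` mode
implements the bare product rule for fidelity comparisons. Averaging is
unweighted by default, with a length-weighted option (`length_weighted`),
since segment-length weighting is a plausible but unconfirmed variant.
Elements whose canonicalized directions still cancel are flagged degenerate
with a warning record, and skipped by the keyword writer.

The `*ELEMENT_SOLID_ORTHO` export completes the orthotropic frame with the
component of global $z$ orthogonal to the axis (global $y$ fallback when
nearly parallel); any completion is valid for a transversely isotropic
material, so the rule is chosen for reproducibility, not physics.

## Injury metrics

* **Fiber damage weight** $w$: the fraction of a fiber's beams whose peak
  axonal strain strictly exceeds `eps_thresh` (default 0.10, the
  established functional-impairment optimum for axonal strain). "Exceeds"
  is a strict inequality; boundary values do not count (configurable).
* **Tract susceptibility index** $\phi$: the mean of $w$ over the tract's
  fibers. This two-level structure is deliberate: pooling all beams of a
  tract weights long fibers more and gives a different number whenever
  fiber lengths differ — a regression test pins the distinction.
* **AxS95**: the 95th percentile of per-beam peak axonal strain in a
  tract, used instead of the maximum to limit the influence of a few
  numerically unstable beams. Percentiles use linear interpolation between
  closest ranks at position $p(n-1)$ (the type-7 convention); the
  convention is stated because tools disagree and it changes the value at
  small $n$. The percentile is taken over per-beam *peaks* by default;
  a pooled time-by-beam variant can be fed in explicitly.
* **MPS95 / CSDM**: the same percentile of per-element peak MPS, and the
  fraction of the element set whose peak MPS strictly exceeds
  `csdm_threshold` (default 0.25). CSDM is volume-weighted by default (the
  classic definition); an element-count mode exists because the quantity is
  sometimes described as an element ratio. The element set is a named
  configuration choice (part-label filter), defaulting to all elements
  provided.

$\phi$ and CSDM are monotone non-increasing in their thresholds, AxS95 and
MPS95 monotone non-decreasing under pointwise strain increase; both
properties are tested.

## Cluster validation and CORA

Cadaveric validation campaigns track radio-opaque markers (NDTs) in the
brain; strain is estimated over clusters of markers triangulated into
tetrahedra. `cluster_strain` uses the constant-strain tetrahedron — exact
for affine fields — and averages, over the included tetrahedra, the maximum
principal strain and the maximum shear $(E_1 - E_3)/2$. Tetrahedra can be
excluded (the standard situation when one marker of a sub-cluster was not
recorded). The connectivity is an input, never hard-coded, because
published marker sets differ; the synthetic fixture uses a
centre-plus-octahedron layout whose eight face tetrahedra cover the volume.

`cora_score` implements the correlation sub-method of the CORA rating
(corridor rating intentionally not implemented): the shape sub-rating is
the maximal normalized cross-correlation over an allowed shift window
(raised to a configurable power, default 1), the phase sub-rating falls
linearly from 1 at zero shift to 0 at the window edge (window default 20%
of the evaluation interval), and the size sub-rating is the min/max ratio
of the two curves' L2 magnitudes. The total is the weighted mean (defaults
0.5 / 0.25 / 0.25 for shape / size / phase). Published applications of
CORA typically cite "optimized settings" without printing the constants,
so every constant here is an explicit configuration field; the defaults
are the manual-style choices above, not a reconstruction of any particular
study's setting. Ratings map onto the standard sliding scale —
Unacceptable [0, 0.26), Marginal [0.26, 0.44), Fair [0.44, 0.65),
Good [0.65, 0.86), Excellent [0.86, 1] — with shared edges assigned to the
upper band, matching the overlapping notation these bands are usually
printed with.

## Outcome statistics

Cases carry a three-level ordinal outcome code (0 none, 1 prolonged
symptoms without acute signs, 2 concussion/acute signs); the bundled
`case_outcomes.csv` manifest records the coding of the eight reconstructed
impact cases and is editable for sensitivity variants. The per-case
representative value of a tract metric is the mean of the top five tract
values (ties at the fifth rank broken lexicographically). Rank association
uses Spearman's $\rho$ on average ranks and Kendall's $\tau_b$; the
two-sided p-value for $\rho$ is exact by full enumeration of all $n!$
permutations up to $n = 9$ (40320 permutations at $n = 8$), with an
asymptotic fallback above.

The rotation-axis contribution analysis correlates, per tract, case-wise
metric values with case-wise peak angular accelerations about X, Y and Z,
and normalizes the absolute correlation magnitudes to sum to 1 per tract.
Pearson correlation is the default and Spearman a flag, and negative
correlations enter through their absolute value — both choices are recorded
in the output metadata, because the published convention for this analysis
is not stated anywhere we could verify. Tracts with constant metrics
(e.g. zero in every case) are reported missing rather than zero.

## The synthetic generator

`make_box_mesh`, `make_perturbed_mesh`, `make_bundle`, `make_history`,
`make_cluster_fixture` and `make_cora_pair` generate every input the
pipeline needs with known ground truth. Amplitudes follow a haversine
pulse (smooth, zero-start, the conventional impact shape). Deformation
kinds: affine blends $F(t) = I + a(t)(M - I)$, simple shear, rigid
rotation+translation, and an inhomogeneous twist. Homogeneous kinds carry
closed-form $F$, $E$ and axonal-strain oracles; the twist ships an
independent dense finite-difference oracle (step $10^{-6}$ of the domain
scale) rather than reusing package kinematics, so the cross-check is
genuine.

What the generator does *not* emulate: brain-shaped geometry, heterogeneous
material response, solver integration error, contact, and measured head
kinematics of real cases. Passing the affine/rigid/shear oracles therefore
demonstrates the correctness of the kinematic post-processing chain, not
the predictive accuracy of any FE model; validation against experimental
curves is what the CORA machinery is for.

## Problem sizes and numerical choices

The bundled checks run at desk scale, chosen to finish in seconds while
still exercising every code path: a $5^3$ box with a 50-fiber random bundle
(~1200 beams) for the affine-equivalence sweep over 100 random histories; a
$6^3$ perturbed mesh with $10^4$ random interior points for the inverse-map
round trip (tolerance $10^{-8}$ mm); $10^5$ random vectors for
canonicalization properties; 1000 random fiber configurations for the
metric formulas; and a 15-fiber shear-box scenario for the end-to-end
threshold crossing, where the bundle is aligned with the stretched diagonal
of the shear so its peak axial strain $\gamma/2 + \gamma^2/4$ crosses the
0.10 damage threshold between $\gamma = 0.15$ and $\gamma = 0.30$.

Other numerical choices, in one place: internal units are mm and seconds
(`ms` inputs converted at ingest); indices are 1-based in R and in CSV
interchange, 1-based in keyword export as LS-DYNA requires, 0-based only in
VTK connectivity as that format requires; report files pin their float
formatting so identical runs are byte-identical; and all generator
randomness sits behind a single integer seed.

## Known limitations

* No force coupling or beam constitutive response: beams are trackers, so
  damage evolution and axon–matrix interaction are out of scope.
* Midpoint membership can mis-assign a beam that merely clips an element
  corner; at a 1 mm step against multi-mm elements the effect is small.
* The CORA defaults are a documented, configurable choice — scores are
  comparable within this package but not automatically against other CORA
  implementations with different constants.
* Exact permutation p-values are limited to $n \le 9$; beyond that the
  asymptotic approximation is used and flagged in the result.
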