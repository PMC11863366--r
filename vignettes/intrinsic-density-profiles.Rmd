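---
title: "Intrinsic density profiles at hull and alpha-shape interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic density profiles at hull and alpha-shape interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hullprof)
```

## The problem

Radial density profiles measured from an aggregate's center of mass are
the standard way to describe the internal structure of nanoparticles and
micelles in molecular dynamics (MD) simulations. They are adequate only
for spherical assemblies: for an elongated, bent or hollow particle, a
sphere of fixed radius around the center simultaneously samples core and
solvent, so the apparent density smears across the interface and remains
nonzero far beyond it. hullprof instead measures densities *relative to
the particle's own surface*: every frame, an explicit interface is built
over the structure-forming atoms, and each analyte atom (or grid cell) is
characterized by its signed Euclidean distance $r$ to that surface —
negative inside the core, zero on the surface, positive in the solvent.
Profiles from assemblies of any shape then become directly comparable: a
lattice cylinder and a lattice sphere of equal construction density yield
the same interior plateau.

## Interface models

**Convex hull.** The default interface is the convex hull of the
structure selection — the smallest convex set containing the points. It
is cheap and adequate for convex or mildly aspherical particles.

**Alpha shape.** For bent, branched or hollow particles the hull
overestimates the enclosed region. The alpha shape generalizes the hull:
starting from the Delaunay tetrahedralization of the points, only
tetrahedra whose circumscribed sphere has radius at most $\alpha$ are
kept ("scooping out" any void a ball of radius $\alpha$ can roll
through). The boundary consists of the triangular faces incident to
exactly one interior tetrahedron; it may have several components and may
enclose cavities, which is what makes hollow shells representable. As
$\alpha \to \infty$ every tetrahedron qualifies and the alpha shape *is*
the convex hull — in this implementation exactly, because both are read
off one shared tetrahedralization.

**Optimal alpha.** When no $\alpha$ is given, the package selects the
smallest critical value (tetrahedron circumradius) for which (i) every
input point lies in the closure of the shape and (ii) the interior forms
a single face-connected solid. Both conditions are monotone enough to be
found by one sweep over the sorted circumradii; if no critical value
satisfies them the hull-equivalent alpha is used with a warning. For a
cubic lattice of spacing $s$ the sweep selects $\sqrt{3}s/2$ — the
circumradius of a lattice cell — which is the smallest ball that leaves
no interior holes.

**Signed distance.** $|r|$ is the exact minimum distance to the boundary
triangles (facet interior, edge or vertex, computed per facet in
constant time, $O(mN)$ overall for $m$ facets and $N$ query points). The
sign comes from half-space tests against the outward facet planes (hull)
or point location in the tetrahedralization (alpha shapes). Points on
the boundary have $r = 0$ and count as inside; hull vertices are
structure atoms and must never register as outside.

## Density estimation

The box is discretized into $n^3$ rectangular cells (`n` is the
`norm_bin_count`; cells of roughly 10 Å work well, e.g. $n = 8$ for an
80 Å box), and each cell center receives a signed distance to the
current frame's interface. Distance bins (default width 1 Å, edges
aligned at zero) then accumulate, over frames:

* **cell mode** (default): analyte atoms are assigned to grid cells;
  a bin receives the atoms and the free volume (cell count × cell
  volume) of the cells whose *centers* fall in it. This is the literal
  grid scheme, and it is what `norm_bin_count` was designed for.
* **atom mode**: exact per-atom signed distances are histogrammed. The
  free volume is still estimated by counting cell centers per bin, but
  on a grid refined until the cell edge is at most one bin width —
  counts resolved at Å resolution must not be normalized by volumes
  sampled at 10 Å resolution, or the ratio acquires a systematic bias
  (several percent for a ~30 Å particle).

The final density of a bin is (summed counts)/(summed free volume).
Bins with no free volume have *undefined* density and are reported as
`NA`, never as zero. The two modes bracket the method's resolution
trade-off: cell mode matches the coarse normalization grid exactly but
aliases against structured (lattice-like) analyte positions — with 10 Å
cells over a 2.988 Å lattice each cell edge covers 3 or 4 lattice
planes, and the acceptance runs show the resulting deviation staying
within about ±4% of the constructed density. Atom mode is free of that
aliasing and is the better default for plateau quantification; both are
computed by the acceptance script.

A plateau is estimated by pooling counts and free volume over all bins
in a window (`profile_mean_density()`), which is independent of the bin
width. The validation suite uses the window $-25 \le r \le -10$ Å for
the 29 Å reference assemblies — far enough from the surface to avoid
boundary depletion and from the center to avoid small-volume noise.

`count_inside()` reports solubilized molecules — target entities with
$r \le 0$, at atom or residue granularity (a residue counts if any of
its atoms is inside). `volume_series()` reports the enclosed volume
(sum of interior tetrahedron volumes, which for hulls equals the
divergence-theorem volume of the oriented boundary) and boundary area
per frame.

## Periodic boundaries: clusters, making whole, centering

Aggregates are identified by single-linkage clustering of the selected
atoms: two residues join a cluster when a chain of atom pairs, each
within a cutoff (default 3.5 Å, a common heavy-atom contact criterion)
under the minimum-image convention, connects them. The implementation
uses a periodic cell list with union-find; membership is determined at
one chosen frame and held fixed, matching the usual workflow of
identifying a micelle once and analyzing the whole trajectory.

`make_whole()` first reassembles each residue around its first atom by
integer box-vector shifts, then stitches the residues of a cluster by
breadth-first traversal of their contact graph, placing each residue at
the minimum image of its already-placed neighbour. Because neighbours
are within the cutoff, each placement is unambiguous even when the whole
aggregate is wider than half a box length — a seed-relative minimum
image would fail there. `center_cluster()` then translates the cluster's
center of geometry to the box center and wraps all other atoms back into
the box. Analyzing a wrapped-then-centered trajectory reproduces the
never-wrapped profiles bin for bin, which is the property that makes the
whole pipeline free of PBC artifacts.

## The synthetic assemblies

`make_fixture()` generates the validation systems: a lattice-filled
sphere and cylinder (the shapes of known density and volume used to
validate the method — radius and half-height 2.9 nm at spacing
2.988 Å give exactly $0.0375$ atoms/Å$^3$ by construction), a hollow
shell, a bent rod around a circular arc, and a solvent bath filling the
box outside an exclusion interface (spacing 3.104 Å reproduces the bulk
water number density, ~0.0334 Å$^{-3}$). Lattice placement is the
default precisely because it realizes the target density exactly and
deterministically; seeded uniform-random placement exists for property
tests. Structure lattices are anchored at the box center; the solvent
lattice at a half-spacing offset from the origin. The box for the
reference assemblies is an 80 Å cube, consistent with an $n = 8$
normalization grid of 10 Å cells.

What the fixtures deliberately do *not* emulate: thermal disorder,
molecular connectivity (each generated atom is its own single-atom
residue), force-field chemistry, and trajectory dynamics (frames
replicate static coordinates). Passing tests on these fixtures validates the geometry and
bookkeeping of the method — interface construction, distances,
normalization, PBC handling — not its behaviour on thermally
fluctuating interfaces, where per-frame hull rebuilding is the relevant
mechanism and is exercised only mechanically here.

Two quantified fixture facts worth knowing (both verified in the test
suite against independent geometry oracles): the achieved global density
of the 29 Å/2.988 Å sphere is ~1.5% above $s^{-3}$ because the counting
sphere clips the lattice at the surface shell (the interior is exact);
and the hull of a lattice sphere is smaller than the analytic ball — at
spacing 1.2 Å by ~1.7%, at 1.5 Å by ~2.7% (the exact value cross-checked
against an independent hull implementation) — because the outermost
lattice plane sits below the nominal radius.

## Numerical choices

* **Degeneracy joggle.** Lattice fixtures are *exactly* degenerate:
  thousands of cospherical and coplanar point groups that
  double-precision insphere/orientation predicates cannot order.
  All combinatorial decisions are therefore made on deterministically
  joggled coordinates (amplitude $10^{-4}$ Å by default — far below the
  $10^{-2}$–$10^{-3}$ Å precision of GRO/PDB coordinates, far above
  predicate round-off). Every metric quantity (volume, area, distance)
  is evaluated on the original coordinates. The joggle is a fixed hash
  of the point index, so results are bit-reproducible and independent of
  R's RNG state. The amplitude also keeps the circumradii of
  degeneracy-broken sliver tetrahedra around $10^5$ Å, so an alpha of
  $10^6$ Å is exactly hull-equivalent even on lattices.
* **Self-verification.** Every triangulation is checked for
  watertightness (summed tetrahedron volume against the
  divergence-theorem volume of its boundary, relative $10^{-9}$); on
  failure the joggle escalates ×100 and the build repeats.
* **Conventions.** Bins are half-open $[lo, hi)$ with $r = 0$ assigned
  to the interior side; boundary points are inside; cluster output is
  ordered by descending size, ties by smallest residue id; frames are
  indexed from 0 with a half-open range, as in MD tooling.
* **Degenerate input.** Fewer than 4 points, or (nearly) collinear or
  coplanar selections, raise errors naming the degeneracy; a degenerate
  structure selection in a trajectory names the frame.
* **Parallelism.** Frames are distributed over forked workers and
  reduced in frame order, so results are identical for any worker
  count; the tests assert bit-identity for 1, 2 and 4 workers.

## Problem sizes

The test and acceptance runs use the 80 Å reference assemblies (3 887
sphere atoms, 5 567 cylinder atoms, 13 250 solvent atoms, and a
59 085-point dense sphere for the hull-volume check); a single-frame
density profile at $n = 8$ including the Å-resolution normalization grid
takes a few seconds on one core, and the complete acceptance script
about half a minute. These sizes were chosen to match the reference
assemblies while keeping a full validation run interactive.

## Known limitations

* Orthorhombic boxes only; triclinic input is rejected explicitly.
* The interface is rebuilt from scratch every frame; there is no
  temporal smoothing or stride-based reuse.
* Weighted alpha shapes, periodic (box-spanning) interfaces and
  sub-voxel partial-volume corrections to the free-volume grid are out
  of scope; the free-volume estimate converges only at the rate of the
  grid refinement.
* Cluster membership is static over the analysis range; aggregation
  kinetics need a different tool.
* Cell-mode profiles inherit the normalization grid's aliasing against
  highly ordered analyte positions (see above); atom mode avoids it.
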