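---
title: "Building and analysing curvature-restrained membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing curvature-restrained membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcurv)
```

## The model

A membrane patch held between two soft repulsive walls adopts the walls'
shape while its lipids remain laterally mobile. `memcurv` models the
membrane mid-surface as either a plane or a circular cylinder whose axis is
the laboratory Y axis — the direction in which the bicelle is periodic — so
the whole geometry lives in the XZ plane. Every analysis is formulated in
the *signed depth* coordinate: zero on the mid-surface, positive toward the
outer leaflet. For a cylinder with radius $R$, centre $\mathbf{c}$ and
orientation sign $s$,

$$\mathrm{depth}(\mathbf{p}) = s\,(\lVert \mathbf{p}_{XZ} - \mathbf{c}\rVert - R),
\qquad c = s/R ,$$

and the local outer normal is the gradient of this depth. The sign
convention is fixed once: $c > 0$ means the outer monolayer is convex. The
surface object stores which side is "outer" explicitly; no caller ever
infers it from the data.

`fit_surface()` recovers these models from point clouds (lipid head groups,
wall anchors): an algebraic Kåsa circle fit in the XZ projection provides
the initial centre, refined by geometric least squares on the radial
residuals (relative tolerance $10^{-14}$ on the profiled objective, which
comfortably reaches the $10^{-10}$ residual regime on clean data). Collinear
XZ projections raise a degenerate-fit error rather than returning a
meaningless huge radius; in `kind = "auto"` mode a cylinder is only accepted
if its radius is below 1000 nm and it halves the plane's residual.

## The walls

Each wall bead is an *anchor* (a dummy particle fixed in absolute
coordinates, interacting with nothing) plus a *shell* bound to it by a
zero-length harmonic bond with force constant $k = 10$ kJ mol⁻¹ nm⁻².
Shells repel only the acyl-tail carbons, through a Lennard-Jones potential
with $\sigma = 0.85$ nm. Because the LJ minimum sits at $r_\min = 2^{1/6}
\sigma \approx 0.954$ nm, the force is strictly repulsive for all $r <
r_\min$, i.e. everywhere inside the 0.8 nm short-range cutoff —
`check_repulsive()` exposes this bound, and `wall_spec()` refuses parameter
combinations that break it. The walls sit $D = 5$ nm apart (about the
hydrophobic-core thickness plus clearance) with beads on a grid of spacing
$d = 0.51$ nm, fine enough that tails cannot slip between shells.

Two layout decisions are worth recording:

* **Arc-length mapping.** Curved walls reuse the flat x-grid, mapping each
  bead's in-plane coordinate to arc length on the wall's own circle (radius
  $1/|c| \pm D/2$). Bead spacing *along the arc* therefore stays exactly
  $d$ on both walls at any curvature, the walls' normal separation is $D$
  everywhere, and bead counts never change — which also makes
  `generate_walls(c)` coincide with the final step of every bending plan.
  The two walls consequently subtend slightly different angles; the wall
  extent defaults to covering the declared box in the bending plane, which
  is the conservative choice when the literature leaves cap coverage
  unspecified.
* **Bending schedule.** `plan_bending()` interpolates linearly in
  *curvature*, regenerating the geometry at each intermediate value rather
  than interpolating Cartesian coordinates (which would shrink the grid
  spacing mid-plan). "Gradual" is quantified by a per-step anchor
  displacement cap, default 0.05 nm — about a tenth of the bead spacing.
  When the caller requests an explicit step count the plan honours it and
  only warns if the cap is exceeded, because a one-step plan (flat →
  target) is a legitimate object to inspect; with `n_steps = NULL` the
  smallest compliant count is found iteratively.

The ITP fragment writes the anchor type as a non-interacting dummy and
emits both immobilization options (a freeze-group note and an
`#ifdef`-guarded stiff position-restraint block), since either realizes
"fixed in absolute coordinates". Energy-like parameters are passed through
numerically unchanged in the engine's topology units.

## The bilayer and the selective repulsion

`build_bicelle()` lays the phospholipids of each monolayer on an
`nx × ny` grid (default 17 × 6 = 102 sites) with the species order shuffled
by the seed, and intercalates cholesterol at random in-plane positions. The
default composition table is the asymmetric erythrocyte-like loading:
SM 42 / PC 46 / PE 14 / PS 0 outside, SM 12 / PC 14 / PE 46 / PS 30 inside,
51 cholesterol per leaflet. Phosphatidylinositol is omitted (its
physiological abundance would amount to roughly one molecule at this system
size). The in-plane grid spacing is a free parameter (default 0.8 nm,
i.e. 0.64 nm² per site, a typical fluid-phase area per lipid).

The lipids are minimal single-conformer pseudo-molecules — phosphorus head
reference, chain carbons C2–C18 with explicit hydrogen pairs, and for
cholesterol the hydroxyl oxygen (O3), the tail-branching carbon (C17,
configurable, since sterol numbering conventions differ on the branching
atom) and one tail carbon. These are the atoms the builders and analyses
actually touch; building full force-field topologies is the simulation
engine's job, and the atom-name mapping to a production lipid set is a
config entry.

The selective repulsion that keeps the leaflets from mixing in bicelle caps
acts between *heavy* atoms of phospholipids of opposite leaflets only, with
$\sigma = 0.8$ nm and a tiny $\varepsilon = 10^{-7}$. Distal tail carbons —
index ≥ 10, i.e. below the oleoyl 9–10 double bond — are excluded so tail
ends still interdigitate; the same index boundary is applied to
sphingomyelin's saturated chain by default (configurable, as no boundary is
standard there). Cholesterol is excluded entirely so it can flip between
leaflets through the caps.

## Analyses

**Density profiles** histogram the signed depth of mass-weighted atom
groups (mass weighting is the membrane-density convention; number
weighting is available), divide by the per-bin volume — constant for
planes, proportional to the local radius $|R + s\,t|$ for cylinders — and
normalize each group to unit integral. Default bin width 0.01 nm.

**Order parameters** compute, per tail carbon $i$,
$S_{CD}(i) = \langle (3\cos^2\theta_i - 1)/2 \rangle$ with $\theta_i$ the
angle between each C–H bond and the local outer normal at the lipid's head
position (the normal's sign cancels in $\cos^2$). Explicit hydrogens are
required; united-atom reconstruction is out of scope. The geometric limits
— $-0.5$ for an all-trans chain along the normal, 0 for isotropic or
magic-angle (54.74°) orientations — are exact test anchors.

**Areas per lipid** follow the tangent-plane Voronoi construction: the
tangent plane at each head group is taken from the *fitted global* surface
normal (not local PCA — the global shape is restrained by construction, so
the global fit is the better-conditioned estimate), same-leaflet neighbor
heads within 1.5 nm are projected onto it, and the target's Voronoi cell
area is computed (tessellation by `deldir`). Cells not closed by neighbor
data — edge lipids, or fewer than three projected neighbors — are flagged
and excluded from means rather than treated as errors. Cholesterol heads
compete for area in the tessellation whenever they are present in the
leaflet, which is physically right but means lattice-exact area recovery is
only expected on cholesterol-free fixtures.

**Cholesterol metrics** define the molecular long axis from the
tail-branching carbon to the hydroxyl group; inclination is the angle to
the molecule's leaflet outward normal at the hydroxyl position. Depth is
measured from the leaflet's *head-group surface*, taken as the smoothed
peak of the phosphorus depth distribution recomputed from the data (an
explicit per-leaflet override exists for head-free fixtures). Molecules
whose hydroxyl lies within 0.5 nm of the mid-surface form the horizontal
interleaflet "minor" population; the half-width is a declared default —
the mid-membrane peak is well separated from the leaflet peaks, so the
classification is insensitive to it over a wide range. Histogram bins are
2° (angles) and 0.025 nm (depths) with mode-after-smoothing peak picking
(Gaussian kernel, bandwidth two bins).

**Sectors.** All analyses accept a sector restriction — an arc of ±30°
around the bicelle symmetry plane on cylinders, or a slab of ±30% of the
X extent on planes, both configurable — to keep cap lipids out of the
statistics. The extents are package defaults, chosen to stay well clear of
the caps while retaining most of the bilayer region.

## Synthetic fixtures and what they show

`make_membrane_fixture()` builds configurations whose ground truth is known
by construction: head groups on a lattice whose spacing realizes the target
area per lipid on each leaflet's own head surface; C–H bonds placed at the
fixed polar angle $\theta_i = \arccos\sqrt{(2 S_i + 1)/3}$ with random
azimuth, which realizes any imposed $S_{CD}$ profile in $[-0.5, 1]$ exactly;
cholesterol split into vertical leaflet-bound molecules and an exactly
counted horizontal mid-surface population. Defaults describe the study
conditions: the asymmetric composition table, head surface at 2.0 nm,
0.62 nm² per lipid, an $S_{CD}$ profile of 0.20 over the proximal carbons
falling linearly to 0.05 at C18 (the proximal/distal ordering split of
oleoyl chains), and a 1.7% minor cholesterol fraction — the flat-membrane
value of that quantity.

For curved fixtures two lattice modes exist: `per_leaflet_apl` realizes the
target area on both leaflets (they subtend different angles), while
`fixed_angle` gives both leaflets the same angular lattice, so equal lipid
counts cover the same arc and the realized areas scale with the leaflet
radius — the geometry behind the convex > flat > concave ordering of areas
per lipid, which the test suite verifies as a direction-of-effect property.

Trajectory fixtures are independent Gaussian-jittered replicas (no
dynamics); multi-frame GRO — a valid GROMACS trajectory format, and a text
format — is the trajectory carrier, with the analysis API taking plain
lists of frames so any reader can feed it.

What passing fixtures do *not* show: the fixtures have no thermal
conformational disorder, no lipid–lipid correlations, no undulations and no
genuine cap regions, so round-trip tests validate the *estimators* (their
geometry, conventions and numerics), not the biological findings of any
particular simulation. Quantities that only emerge from equilibrated
dynamics — hydrophobic thinning, curvature-dependent area redistribution
magnitudes, equilibrium minor-cholesterol fractions — must come from actual
simulations; this package only makes those measurements well-defined and
reproducible.

## Problem sizes and determinism

The shipped tests run on patches of 24–144 lipids and trajectories of up to
40 frames — sizes where every closed form is exact and Monte-Carlo
tolerances (APL within 1%, $S_{CD}$ within 0.02 at $10^4$ samples per
carbon) are comfortably resolved. All randomness (species shuffling,
cholesterol placement, azimuths, jitter) flows through one explicit seed
per builder call, with the caller's RNG state restored afterwards; fixed
seed means byte-identical output files.

## Known limitations

* Cylindrical and planar mid-surfaces only; spherical or saddle restraints
  and per-lipid instantaneous curvature fields are out of scope.
* The GROMACS dialect is the only topology target; the wall concept is
  engine-agnostic but no other writer is provided.
* Order parameters need explicit hydrogens.
* Binary trajectory formats (XTC/TRR) are not read; convert to multi-frame
  GRO/PDB first.
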