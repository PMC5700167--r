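# memcurv

Membrane curvature is transient in free molecular-dynamics simulations, which
makes its structural effects hard to measure. One way around this is to hold
the *global* shape of a membrane at a prescribed curvature with a pair of
soft repulsive walls made of dummy particles, while leaving the lateral
dynamics of individual lipids untouched. `memcurv` implements that setup and
the analyses that go with it:

* **Wall builder** — grids of anchor/shell bead pairs forming two surfaces a
  distance *D* apart (default 5 nm, spacing *d* = 0.51 nm). The anchor is
  fixed in space and interacts with nothing; the shell is tied to it by a
  zero-length harmonic bond (*k* = 10 kJ mol⁻¹ nm⁻²) and repels the lipid
  acyl-tail carbons through a Lennard-Jones potential (σ = 0.85 nm) chosen so
  that it is purely repulsive within the short-range cutoff:
  2^(1/6) σ ≥ r_c. GROMACS-compatible GRO/ITP fragments are emitted, plus a
  gradual bending schedule that moves the anchors from a flat wall to the
  target curvature while conserving bead spacing and wall separation.
* **System builder** — an asymmetric bilayer assembled from a leaflet
  composition table (default: SM/PC-rich outer, PE/PS-rich inner leaflet,
  102 phospholipids + 51 cholesterol per monolayer on a 17 × 6 grid), with
  the selective inter-monolayer repulsion (σ = 0.8 nm, ε = 1·10⁻⁷) that
  prevents leaflet mixing in bicelle caps while excluding hydrogens, distal
  tail carbons and cholesterol.
* **Curvature-aware analyses** — signed-depth density profiles, deuterium
  order parameters S_CD(i) = ⟨(3 cos²θᵢ − 1)/2⟩ against the local membrane
  normal, tangent-plane Voronoi areas per lipid, and cholesterol
  inclination / depth / interleaflet ("minor") fraction statistics, all
  restricted to an analysis sector that excludes bicelle caps.
* **Synthetic fixtures** — flat and cylindrically curved asymmetric
  configurations with *known* ground truth (target area per lipid, imposed
  S_CD profile, exact minor-cholesterol count), so every analysis can be
  validated end-to-end without simulation output.

The sign convention throughout: curvature *c* = ±1/R (nm⁻¹), positive when
the outer monolayer is convex.

## Worked example

```r
library(memcurv)

# walls restraining a membrane at c = +0.2 nm^-1
g <- generate_walls(wall_spec(curvature = 0.2))
g
#> wall_geometry: c = +0.2000 nm^-1, D = 5.000 nm, d = 0.510 nm, 140 beads/wall
fo <- fit_surface(g$outer$anchors, "cylinder")
fi <- fit_surface(g$inner$anchors, "cylinder")
c(fo$radius, fi$radius, 2 / (fo$radius + fi$radius))
#> [1] 7.5 2.5 0.2                    # radii 1/c ± D/2; mid-surface c recovered

check_repulsive(wall_spec())
#> [1] 0.9540927                      # 2^(1/6)*0.85 >= 0.8: purely repulsive
#> attr(,"holds") TRUE

# the asymmetric bilayer with the default composition table
frame <- build_bicelle(composition(), seed = 1)
frame
#> membrane_frame: 21318 atoms, 306 residues, box 17.60 x 4.80 x 8.00 nm

# a curved synthetic fixture: equal leaflet loading over the same arc
fx <- make_membrane_fixture(fixture_spec(
  curvature = 0.2, comp = composition(outer = c(PC = 72), inner = c(PC = 72)),
  chol_minor_frac = 0, arc_mode = "fixed_angle", seed = 7))
aggregate_apl(areas_per_lipid(fx$frame, fx$surface))
#>   species leaflet mean_area sd_area  n
#> 1      PC   inner  0.370464       0 40   # concave leaflet: compressed
#> 2      PC   outer  0.864417       0 40   # convex leaflet: expanded
```

The area-per-lipid ratio 0.864/0.370 ≈ (R + t)/(R − t) with R = 5 nm and
head-surface offset t = 2 nm: with equal lipid counts over the same angular
extent, the convex leaflet dilutes and the concave leaflet compresses —
the direction of the curvature effect the restrained simulations probe.

A cholesterol-bearing fixture reports the minor fraction exactly:

```r
fc <- make_membrane_fixture(fixture_spec(
  curvature = 0.2, chol_minor_frac = 2.5, seed = 7,
  comp = composition(outer = c(PC = 48, CHL = 40), inner = c(PC = 48, CHL = 40))))
cholesterol_metrics(fc$frame, fc$surface)
#> cholesterol report
#>   molecules (frame-pooled): outer 39, inner 39, central 2
#>   minor (interleaflet) fraction: 2.50%
#>   outer: inclination peak 1.0 deg, depth peak 0.512 nm
```

## Command line

```sh
Rscript inst/scripts/memcurv build-walls --curvature 0.2 --out wall
Rscript inst/scripts/memcurv bend-plan --target-curvature 0.2 --out bend
Rscript inst/scripts/memcurv build-bicelle --seed 1 --out bicelle.gro
Rscript inst/scripts/memcurv fixtures --preset curved --seed 3 --out fx
Rscript inst/scripts/memcurv analyze apl --traj fx.gro --curvature 0.2 --out apl.tsv
```

## Scope

The package builds inputs for, and analyses outputs of, curvature-restrained
simulations; it does not run molecular dynamics, solvate, or equilibrate
systems, and force-field content beyond the wall/repulsion parameters is
config metadata only. See `vignettes/curved-membranes.Rmd` for the model,
its assumptions and the numerical choices.
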