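#' Parameters of the repulsive dummy-particle walls
#'
#' Each wall bead is a pair of particles: an *anchor*, fixed in absolute
#' coordinates and interacting with nothing, and a *shell* tied to it by a
#' zero-length harmonic bond. Shells interact only with the lipid acyl-tail
#' carbons through a soft Lennard-Jones potential chosen to be purely
#' repulsive within the force field's short-range cutoff, so the two walls
#' cage the membrane's hydrophobic core without perturbing head groups,
#' cholesterol, water or ions.
#'
#' @param curvature Target signed curvature of the mid-surface (nm^-1).
#' @param separation Normal distance between the two walls (nm). Default 5.0.
#' @param spacing Bead grid spacing within a wall (nm). Default 0.51.
#' @param extent Wall extent `c(Lx, Ly)` (nm): length along the bending
#'   direction (arc length for curved walls) and along Y.
#' @param sigma,epsilon Shell-tail Lennard-Jones parameters (nm, energy in
#'   the simulation engine's units). Defaults 0.85 and 1e-5.
#' @param k_bond Anchor-shell harmonic bond force constant
#'   (kJ mol^-1 nm^-2). Default 10. Bond length is always 0.
#' @param cutoff Short-range cutoff r_c (nm) used by the repulsivity
#'   guarantee: `2^(1/6) * sigma >= cutoff` must hold. Default 0.8.
#' @param anchor Point on the mid-surface (nm).
#' @param max_step_disp Largest allowed per-step anchor displacement in a
#'   bending plan (nm). Default 0.05.
#' @return A `wall_spec` object.
#' @export
wall_spec <- function(curvature = 0, separation = 5.0, spacing = 0.51,
                      extent = c(10, 3.06), sigma = 0.85, epsilon = 1e-5,
                      k_bond = 10, cutoff = 0.8, anchor = c(0, 0, 0),
                      max_step_disp = 0.05) {
  if (separation <= 0) abort("wall separation must be > 0",
                             class = "memcurv_invalid_parameter")
  if (spacing <= 0) abort("grid spacing must be > 0",
                          class = "memcurv_invalid_parameter")
  if (sigma <= 0 || epsilon <= 0) abort("sigma and epsilon must be > 0",
                                        class = "memcurv_invalid_parameter")
  if (length(extent) != 2L || any(extent <= 0)) {
    abort("extent must be two positive lengths (nm)",
          class = "memcurv_invalid_parameter")
  }
  if (abs(curvature) >= 1) abort("|curvature| must be < 1 nm^-1",
                                 class = "memcurv_invalid_parameter")
  rmin <- 2^(1 / 6) * sigma
  if (rmin < cutoff - 1e-12) {
    abort(sprintf(
      "wall potential is attractive inside the cutoff: 2^(1/6)*sigma = %.4f nm < r_c = %.4f nm",
      rmin, cutoff), class = "memcurv_validation_error")
  }
  structure(list(curvature = curvature, separation = separation,
                 spacing = spacing, extent = as.numeric(extent),
                 sigma = sigma, epsilon = epsilon, k_bond = k_bond,
                 cutoff = cutoff, anchor = drop(as_points(anchor)),
                 max_step_disp = max_step_disp),
            class = "wall_spec")
}

#' Lennard-Jones potential
#'
#' `V(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6)`, used by the wall shells and
#' by the repulsivity check.
#'
#' @param r Distance(s), nm.
#' @param sigma,epsilon LJ parameters.
#' @return Potential values (same units as `epsilon`).
#' @export
lj_potential <- function(r, sigma, epsilon) {
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}

#' Largest distance with a strictly repulsive wall potential
#'
#' The shell-tail Lennard-Jones potential has `dV/dr < 0` strictly for
#' `r < r_min = 2^(1/6) sigma`; the wall is therefore purely repulsive within
#' the short-range cutoff if and only if `r_min >= r_c`.
#'
#' @param spec A [wall_spec()] (or a single sigma value, nm).
#' @return `r_min` in nm, with attributes `cutoff` and `holds` (logical:
#'   whether the purely-repulsive-within-cutoff guarantee holds).
#' @examples
#' check_repulsive(wall_spec())   # 2^(1/6) * 0.85 = 0.954 nm >= 0.8 nm
#' @export
check_repulsive <- function(spec) {
  if (inherits(spec, "wall_spec")) {
    sigma <- spec$sigma
    cutoff <- spec$cutoff
  } else {
    sigma <- as.numeric(spec)
    cutoff <- NA_real_
  }
  if (sigma <= 0) abort("sigma must be > 0", class = "memcurv_invalid_parameter")
  rmin <- 2^(1 / 6) * sigma
  structure(rmin, cutoff = cutoff,
            holds = if (is.na(cutoff)) NA else rmin >= cutoff - 1e-12)
}

# Wall offsets in signed depth: the "outer" wall sits at +separation/2, the
# "inner" wall at -separation/2. On a cylinder a depth offset t corresponds
# to radius R + s*t.
wall_radius <- function(spec, side) {
  t <- if (side == "outer") spec$separation / 2 else -spec$separation / 2
  R <- 1 / abs(spec$curvature)
  R + sign(spec$curvature) * t
}

# Bead grid coordinates for one wall at a given curvature. The x-grid is the
# flat grid; for curved walls each x becomes an arc length on the wall's own
# circle, so the along-arc spacing stays exactly `spacing` at any curvature.
wall_bead_coords <- function(spec, side, curvature = spec$curvature,
                             xs = NULL, ys = NULL) {
  d <- spec$spacing
  if (is.null(xs)) {
    nx <- floor(spec$extent[1] / d + 1e-9) + 1L
    if (spec$extent[1] < d) {
      abort("grid spacing exceeds the wall extent: no beads fit",
            class = "memcurv_empty_wall")
    }
    xs <- (seq_len(nx) - (nx + 1) / 2) * d
  }
  if (is.null(ys)) {
    ny <- floor(spec$extent[2] / d + 1e-9) + 1L
    if (spec$extent[2] < d) {
      abort("grid spacing exceeds the wall extent: no beads fit",
            class = "memcurv_empty_wall")
    }
    ys <- (seq_len(ny) - (ny + 1) / 2) * d
  }
  a <- spec$anchor
  t <- if (side == "outer") spec$separation / 2 else -spec$separation / 2
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  if (curvature == 0) {
    pos <- cbind(a[1] + g$x, a[2] + g$y, a[3] + t)
  } else {
    s <- sign(curvature)
    R <- 1 / abs(curvature)
    rw <- R + s * t
    center <- c(a[1], a[3] - s * R)
    # direction from center to the mid-surface anchor
    u0 <- c(a[1] - center[1], a[3] - center[2]) / R
    phi <- g$x / rw  # arc-length-preserving mapping
    # rotate u0 by phi in the XZ plane
    ux <- u0[1] * cos(phi) + u0[2] * sin(phi)
    uz <- -u0[1] * sin(phi) + u0[2] * cos(phi)
    pos <- cbind(center[1] + rw * ux, a[2] + g$y, center[2] + rw * uz)
  }
  colnames(pos) <- c("x", "y", "z")
  list(pos = pos, xs = xs, ys = ys)
}

#' Generate the anchor/shell wall bead grids
#'
#' Builds the two restraining walls for the curvature declared in the spec:
#' two parallel planes `separation` nm apart for a flat membrane, or two
#' coaxial cylindrical arcs at radii `1/|c| +/- separation/2` for a curved
#' one. Beads are laid on a rectangular grid with spacing `spacing` (exact in
#' the flat case, exact *along the arc* in the curved case). At generation
#' time every shell coincides with its anchor.
#'
#' @param spec A [wall_spec()].
#' @return A `wall_geometry`: per wall (`outer`, `inner`) the anchor and
#'   shell coordinate matrices, plus the mid-surface `surface_model` and the
#'   flat x/y grids used (kept so bending plans preserve bead identity).
#' @export
generate_walls <- function(spec) {
  stopifnot(inherits(spec, "wall_spec"))
  outer <- wall_bead_coords(spec, "outer")
  inner <- wall_bead_coords(spec, "inner", xs = outer$xs, ys = outer$ys)
  mid <- make_surface(spec$curvature, anchor = spec$anchor)
  structure(list(
    spec = spec,
    outer = list(anchors = outer$pos, shells = outer$pos),
    inner = list(anchors = inner$pos, shells = inner$pos),
    xs = outer$xs, ys = outer$ys,
    mid_surface = mid
  ), class = "wall_geometry")
}

#' @export
print.wall_geometry <- function(x, ...) {
  cat(sprintf(
    "wall_geometry: c = %+.4f nm^-1, D = %.3f nm, d = %.3f nm, %d beads/wall\n",
    x$spec$curvature, x$spec$separation, x$spec$spacing,
    nrow(x$outer$anchors)))
  invisible(x)
}

#' Plan a gradual bending schedule
#'
#' Maps the flat wall anchors onto walls of increasing curvature,
#' interpolating linearly in curvature. Each bead keeps its grid identity:
#' its in-plane x coordinate becomes arc length on the target circle, so the
#' along-arc bead spacing and the wall separation are conserved at every
#' step. Step 0 is the flat input, step N the target-curvature walls.
#'
#' @param flat_geom A flat [generate_walls()] geometry.
#' @param c_target Target signed curvature (nm^-1).
#' @param n_steps Number of bending steps (>= 1), or `NULL` to pick the
#'   smallest count keeping every per-step anchor displacement below the
#'   spec's `max_step_disp` (a warning is issued if an explicit `n_steps`
#'   violates that cap).
#' @return A `bending_plan`: list of per-step wall geometries, the per-step
#'   curvatures and the largest per-step anchor displacement.
#' @export
plan_bending <- function(flat_geom, c_target, n_steps = NULL) {
  stopifnot(inherits(flat_geom, "wall_geometry"))
  if (flat_geom$spec$curvature != 0) {
    abort("bending plans start from a flat (planar) wall geometry",
          class = "memcurv_invalid_parameter")
  }
  if (abs(c_target) >= 1) abort("|c_target| must be < 1 nm^-1",
                                class = "memcurv_invalid_parameter")
  if (!is.null(n_steps) && (length(n_steps) != 1L || n_steps < 1)) {
    abort("n_steps must be >= 1", class = "memcurv_invalid_parameter")
  }
  spec <- flat_geom$spec
  geom_at <- function(ck) {
    o <- wall_bead_coords(spec, "outer", curvature = ck,
                          xs = flat_geom$xs, ys = flat_geom$ys)
    i <- wall_bead_coords(spec, "inner", curvature = ck,
                          xs = flat_geom$xs, ys = flat_geom$ys)
    sp <- spec
    sp$curvature <- ck
    structure(list(spec = sp,
                   outer = list(anchors = o$pos, shells = o$pos),
                   inner = list(anchors = i$pos, shells = i$pos),
                   xs = flat_geom$xs, ys = flat_geom$ys,
                   mid_surface = make_surface(ck, anchor = spec$anchor)),
              class = "wall_geometry")
  }
  max_disp_between <- function(g1, g2) {
    max(sqrt(rowSums((g2$outer$anchors - g1$outer$anchors)^2)),
        sqrt(rowSums((g2$inner$anchors - g1$inner$anchors)^2)))
  }
  if (is.null(n_steps)) {
    # total anchor displacement flat -> target bounds the step count
    total <- max_disp_between(flat_geom, geom_at(c_target))
    n_steps <- max(1L, ceiling(total / spec$max_step_disp))
    # linear-in-curvature steps are not exactly linear in displacement;
    # refine upward until the cap actually holds
    repeat {
      cs <- c_target * seq(0, 1, length.out = n_steps + 1L)
      gs <- lapply(cs, geom_at)
      disp <- max(vapply(seq_len(n_steps), function(k)
        max_disp_between(gs[[k]], gs[[k + 1L]]), numeric(1)))
      if (disp <= spec$max_step_disp + 1e-12) break
      n_steps <- n_steps + 1L
    }
  } else {
    n_steps <- as.integer(n_steps)
    cs <- c_target * seq(0, 1, length.out = n_steps + 1L)
    gs <- lapply(cs, geom_at)
    disp <- if (n_steps >= 1) max(vapply(seq_len(n_steps), function(k)
      max_disp_between(gs[[k]], gs[[k + 1L]]), numeric(1))) else 0
    if (disp > spec$max_step_disp + 1e-12) {
      warning(sprintf(
        "largest per-step anchor displacement %.4f nm exceeds the cap %.3f nm",
        disp, spec$max_step_disp))
    }
  }
  gs[[1L]] <- flat_geom
  structure(list(steps = gs, curvatures = cs, max_step_disp = disp,
                 n_steps = n_steps), class = "bending_plan")
}

#' @export
print.bending_plan <- function(x, ...) {
  cat(sprintf(
    "bending_plan: %d steps, c 0 -> %+.4f nm^-1, max per-step displacement %.4f nm\n",
    x$n_steps, x$curvatures[length(x$curvatures)], x$max_step_disp))
  invisible(x)
}
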