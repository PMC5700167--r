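# Synthetic membrane configurations with known ground truth. These emulate
# flat and cylindrically curved asymmetric bilayers with cholesterol —
# including a controllable horizontally-lying interleaflet cholesterol
# population — so every builder and analysis operation is testable without
# any simulation output.

#' Default imposed order-parameter profile
#'
#' A plateau of 0.20 over the proximal carbons (2-9) falling linearly to
#' 0.05 at C18, mimicking the proximal/distal ordering split of oleoyl
#' chains.
#'
#' @return Named numeric vector, names = carbon indices 2..18.
#' @export
default_scd_profile <- function() {
  i <- 2:18
  s <- ifelse(i <= 9, 0.20, 0.20 - (i - 9) * (0.15 / 9))
  stats::setNames(s, i)
}

#' Specification of a synthetic membrane fixture
#'
#' @param curvature Signed mid-surface curvature (nm^-1).
#' @param comp A [composition()]; default the asymmetric plasma-membrane
#'   table.
#' @param apl Target area per lipid `c(outer =, inner =)` (nm^2), realized
#'   by the head-group lattice spacing. Default 0.62 both.
#' @param scd Imposed S_CD per carbon (named vector, carbon index names);
#'   default [default_scd_profile()].
#' @param chol_minor_frac Percentage of all cholesterol placed horizontally
#'   at the mid-surface (the minor fraction). Default 1.7.
#' @param chol_tilt Tilt (degrees) of the leaflet-bound cholesterol long
#'   axis away from the normal. Default 0.
#' @param noise Isotropic Gaussian positional noise sigma (nm). Default 0.
#' @param head_depth Head-group surface depth (nm). Default 2.0.
#' @param chol_head_depth Depth of vertical cholesterol hydroxyls (nm).
#' @param ny Lattice rows along Y; the phospholipid count of each leaflet
#'   must be divisible by it. Default 6.
#' @param arc_mode For curved fixtures: `"per_leaflet_apl"` places each
#'   leaflet at its own arc spacing realizing `apl` (leaflets subtend
#'   different angles); `"fixed_angle"` gives both leaflets the same angular
#'   lattice so equal counts cover the same arc and the realized areas scale
#'   with the leaflet radius (convex > concave).
#' @param seed Mandatory integer seed.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(curvature = 0, comp = composition(),
                         apl = c(outer = 0.62, inner = 0.62),
                         scd = default_scd_profile(),
                         chol_minor_frac = 1.7, chol_tilt = 0, noise = 0,
                         head_depth = 2.0, chol_head_depth = 1.5, ny = 6,
                         arc_mode = c("per_leaflet_apl", "fixed_angle"),
                         seed) {
  arc_mode <- match.arg(arc_mode)
  if (missing(seed)) abort("fixtures require an explicit seed",
                           class = "memcurv_invalid_parameter")
  if (abs(curvature) >= 1) abort("|curvature| must be < 1 nm^-1",
                                 class = "memcurv_invalid_parameter")
  if (any(apl <= 0)) abort("target areas per lipid must be > 0",
                           class = "memcurv_validation_error")
  if (chol_minor_frac < 0 || chol_minor_frac > 100) {
    abort("chol_minor_frac is a percentage in [0, 100]",
          class = "memcurv_validation_error")
  }
  if (any(scd < -0.5 | scd > 1)) {
    abort("imposed S_CD values must lie in [-0.5, 1]",
          class = "memcurv_validation_error")
  }
  if (curvature != 0 && head_depth >= 1 / abs(curvature)) {
    abort("head_depth must be smaller than the radius of curvature",
          class = "memcurv_validation_error")
  }
  structure(list(curvature = curvature, comp = comp, apl = apl, scd = scd,
                 chol_minor_frac = chol_minor_frac, chol_tilt = chol_tilt,
                 noise = noise, head_depth = head_depth,
                 chol_head_depth = chol_head_depth, ny = as.integer(ny),
                 arc_mode = arc_mode, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Map lattice coordinates (u = arc length / in-plane x, v = y) at a depth
# offset t onto 3D positions, together with the local "up" direction
# (toward the leaflet's head side).
lattice_points <- function(surface, u, v, t, up_sign) {
  if (surface$kind == "plane") {
    pos <- cbind(u, v, surface$z0 + t)
    up <- matrix(rep(c(0, 0, surface$nsign * up_sign), each = length(u)),
                 ncol = 3L)
  } else {
    s <- surface$s
    R <- surface$radius
    r <- R + s * t
    a <- surface$anchor
    center <- surface$center
    u0 <- c(a[1] - center[1], a[3] - center[2]) / R
    phi <- u / r
    ux <- u0[1] * cos(phi) + u0[2] * sin(phi)
    uz <- -u0[1] * sin(phi) + u0[2] * cos(phi)
    pos <- cbind(center[1] + r * ux, v, center[2] + r * uz)
    up <- cbind(s * up_sign * ux, 0, s * up_sign * uz)
  }
  list(pos = pos, up = up)
}

build_fixture_lipid <- function(species, origin, up, scd, head_depth) {
  basis <- tangent_basis(up)
  if (species == CHOL_RESNAME) {
    tmpl <- lipid_template(CHOL_RESNAME)
    pos <- place_template(tmpl, origin, up, basis$e1, basis$e2)
    return(data.frame(name = tmpl$name, element = tmpl$element,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      stringsAsFactors = FALSE))
  }
  carbons <- as.integer(names(scd))
  rows <- list(data.frame(name = "P", element = "P", x = origin[1],
                          y = origin[2], z = origin[3],
                          stringsAsFactors = FALSE))
  for (ch in c("A", "B")) {
    xoff <- if (ch == "A") -0.15 else 0.15
    for (j in seq_along(carbons)) {
      i <- carbons[j]
      cpos <- origin + basis$e1 * xoff - up * (0.30 + 0.10 * (i - 2))
      # sample C-H directions at the fixed polar angle realizing S_CD(i)
      costh <- sqrt((2 * scd[j] + 1) / 3)
      sinth <- sqrt(1 - costh^2)
      phi <- stats::runif(2, 0, 2 * pi)
      hdir <- t(vapply(phi, function(p)
        costh * up + sinth * (cos(p) * basis$e1 + sin(p) * basis$e2),
        numeric(3)))
      hpos <- sweep(0.109 * hdir, 2, cpos, `+`)
      rows[[length(rows) + 1L]] <- data.frame(
        name = c(sprintf("C%d%s", i, ch),
                 sprintf("H%d%s1", i, ch), sprintf("H%d%s2", i, ch)),
        element = c("C", "H", "H"),
        x = c(cpos[1], hpos[, 1]), y = c(cpos[2], hpos[, 2]),
        z = c(cpos[3], hpos[, 3]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic membrane configuration with known ground truth
#'
#' Phospholipid head groups are placed on a lattice realizing the target
#' area per lipid on each leaflet's head surface (plane or cylinder arc);
#' pseudo-tails carry C-H pairs whose orientations realize the imposed
#' S_CD profile exactly in expectation; cholesterol is split into vertical
#' leaflet-bound molecules and a horizontally-lying mid-surface population
#' realizing the requested minor fraction. Fully deterministic per seed.
#'
#' @param spec A [fixture_spec()].
#' @return A `membrane_fixture`: list with `frame` (a [membrane_frame()]),
#'   `surface` (the generating [make_surface()] model) and `truth` (the
#'   ground-truth record: realized per-leaflet APL, imposed S_CD profile,
#'   minor counts/fraction, depths, seed).
#' @export
make_membrane_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  surface <- make_surface(spec$curvature)
  with_seed(spec$seed, {
    pieces <- list()
    resid <- 0L
    apl_truth <- c(outer = NA_real_, inner = NA_real_)
    extents <- c()
    emit <- function(df, species, lf) {
      resid <<- resid + 1L
      df$resname <- species
      df$resid <- resid
      df$leaflet <- lf
      pieces[[length(pieces) + 1L]] <<- df
    }
    for (lf in c("outer", "inner")) {
      t <- if (lf == "outer") spec$head_depth else -spec$head_depth
      counts <- comp_counts(spec$comp, lf)
      npl <- sum(counts)
      if (npl %% spec$ny != 0L) {
        abort(sprintf(
          "%s leaflet phospholipid count %d is not divisible by ny = %d",
          lf, npl, spec$ny), class = "memcurv_validation_error")
      }
      nx <- npl %/% spec$ny
      if (spec$arc_mode == "fixed_angle" && surface$kind == "cylinder") {
        # same angular lattice for both leaflets: spacing apl[1]^(1/2) on
        # the mid-surface, scaled by r/R on each leaflet
        a0 <- sqrt(spec$apl[[1]])
        r <- surface$radius + surface$s * t
        au <- a0 * r / surface$radius
        av <- a0
      } else {
        au <- av <- sqrt(spec$apl[[lf]])
      }
      apl_truth[lf] <- au * av
      us <- (seq_len(nx) - (nx + 1) / 2) * au
      vs <- (seq_len(spec$ny) - (spec$ny + 1) / 2) * av
      g <- expand.grid(u = us, v = vs, KEEP.OUT.ATTRS = FALSE)
      lp <- lattice_points(surface, g$u, g$v, t, up_sign = sign(t))
      species <- sample(rep(names(counts), counts))
      for (k in seq_along(species)) {
        emit(build_fixture_lipid(species[k], lp$pos[k, ], lp$up[k, ],
                                 spec$scd, spec$head_depth),
             species[k], lf)
      }
      extents <- rbind(extents, c(max(abs(us)) + au, max(abs(vs)) + av))
    }
    # cholesterol: minor (horizontal, mid-surface) + vertical leaflet-bound
    chol_counts <- c(outer = sum(comp_counts(spec$comp, "outer", "chol")),
                     inner = sum(comp_counts(spec$comp, "inner", "chol")))
    total_chol <- sum(chol_counts)
    n_minor <- round(spec$chol_minor_frac / 100 * total_chol)
    take <- c(outer = n_minor %/% 2 + n_minor %% 2, inner = n_minor %/% 2)
    take <- pmin(take, chol_counts)
    umax <- min(extents[, 1]) * 0.8
    vmax <- min(extents[, 2]) * 0.8
    for (lf in c("outer", "inner")) {
      t_o3 <- if (lf == "outer") spec$chol_head_depth else -spec$chol_head_depth
      nvert <- chol_counts[[lf]] - take[[lf]]
      if (nvert > 0) {
        u <- stats::runif(nvert, -umax, umax)
        v <- stats::runif(nvert, -vmax, vmax)
        lp <- lattice_points(surface, u, v, t_o3, up_sign = sign(t_o3))
        for (k in seq_len(nvert)) {
          up <- lp$up[k, ]
          if (spec$chol_tilt != 0) {
            b <- tangent_basis(up)
            th <- deg2rad(spec$chol_tilt)
            ph <- stats::runif(1, 0, 2 * pi)
            up <- cos(th) * up + sin(th) * (cos(ph) * b$e1 + sin(ph) * b$e2)
          }
          emit(build_fixture_lipid(CHOL_RESNAME, lp$pos[k, ], up, spec$scd,
                                   spec$head_depth), CHOL_RESNAME, lf)
        }
      }
    }
    if (n_minor > 0) {
      u <- stats::runif(n_minor, -umax, umax)
      v <- stats::runif(n_minor, -vmax, vmax)
      lp <- lattice_points(surface, u, v, 0, up_sign = 1)
      for (k in seq_len(n_minor)) {
        # long axis along Y: exactly perpendicular to any local normal
        emit(build_fixture_lipid(CHOL_RESNAME, lp$pos[k, ], c(0, 1, 0),
                                 spec$scd, spec$head_depth),
             CHOL_RESNAME, "central")
      }
    }
    atoms <- do.call(rbind, pieces)
    if (spec$noise > 0) {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, spec$noise)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, spec$noise)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, spec$noise)
    }
    span <- apply(atoms[, c("x", "y", "z")], 2, function(x) diff(range(x)))
    frame <- membrane_frame(atoms, pmax(span + 2, 1))
    truth <- list(curvature = spec$curvature, apl = apl_truth,
                  scd = spec$scd, minor_fraction = 100 * n_minor / total_chol,
                  n_minor = n_minor, n_chol = total_chol,
                  head_depth = spec$head_depth,
                  chol_head_depth = spec$chol_head_depth, seed = spec$seed)
    structure(list(frame = frame, surface = surface, truth = truth),
              class = "membrane_fixture")
  })
}

#' Generate a jittered multi-frame trajectory fixture
#'
#' Independent Gaussian-jittered replicas of the base fixture; the ground
#' truth is unchanged in expectation. With `jitter = 0` every frame equals
#' the base frame.
#'
#' @param spec A [fixture_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param jitter Per-frame isotropic positional jitter sigma (nm).
#' @param file Optional path: frames are written as a multi-frame GRO
#'   trajectory.
#' @return List with `frames` (list of [membrane_frame()]), `surface`,
#'   `truth`.
#' @export
make_trajectory_fixture <- function(spec, n_frames, jitter = 0, file = NULL) {
  if (n_frames < 1) abort("n_frames must be >= 1",
                          class = "memcurv_invalid_parameter")
  base <- make_membrane_fixture(spec)
  frames <- with_seed(spec$seed + 1L, lapply(seq_len(n_frames), function(k) {
    f <- base$frame
    if (jitter > 0) {
      n <- nrow(f$atoms)
      f$atoms$x <- f$atoms$x + stats::rnorm(n, 0, jitter)
      f$atoms$y <- f$atoms$y + stats::rnorm(n, 0, jitter)
      f$atoms$z <- f$atoms$z + stats::rnorm(n, 0, jitter)
    }
    f
  }))
  if (!is.null(file)) write_gro(frames, file, title = "memcurv fixture")
  list(frames = frames, surface = base$surface, truth = base$truth)
}

#' Write a fixture's ground truth as a key-value sidecar file
#'
#' @param fixture A `membrane_fixture` (or the `truth` list itself).
#' @param file Output path (YAML key-value text).
#' @return `file`, invisibly.
#' @export
write_ground_truth <- function(fixture, file) {
  truth <- if (inherits(fixture, "membrane_fixture")) fixture$truth
           else fixture
  truth$scd <- as.list(stats::setNames(unname(truth$scd), names(truth$scd)))
  truth$apl <- as.list(truth$apl)
  yaml::write_yaml(truth, file)
  invisible(file)
}
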