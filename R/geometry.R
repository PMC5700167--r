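#' Construct a membrane mid-surface model at a prescribed curvature
#'
#' The mid-surface of a globally curved membrane is modelled as either a plane
#' (curvature zero) or a circular cylinder whose axis is the laboratory Y axis
#' (the direction in which the bicelle is periodic). The signed curvature
#' follows the convention that positive curvature means the outer monolayer is
#' convex: `curvature = s / R` where `s = +1` when the outer side faces away
#' from the cylinder axis.
#'
#' @param curvature Signed curvature in nm^-1. `0` gives a plane; `|c|` must be
#'   below 1 nm^-1 (radii under 1 nm are outside the model's regime).
#' @param anchor A 3D point (nm) lying on the desired mid-surface. For a
#'   cylinder it also fixes the angular origin used by [sector_mask()].
#' @param outer For a plane, which side the outer leaflet faces: `"+z"`
#'   (default) or `"-z"`. Ignored for cylinders, where the side is implied by
#'   the sign of `curvature`.
#' @return A `surface_model` object.
#' @examples
#' s <- make_surface(0.2)            # cylinder, R = 5 nm, outer side convex
#' p <- make_surface(0)              # plane through the origin
#' @seealso [fit_surface()], [signed_depth()], [outer_normal()]
#' @export
make_surface <- function(curvature, anchor = c(0, 0, 0), outer = c("+z", "-z")) {
  outer <- match.arg(outer)
  anchor <- drop(as_points(anchor))
  if (!is.numeric(curvature) || length(curvature) != 1L || !is.finite(curvature)) {
    abort("curvature must be a single finite number (nm^-1)",
          class = "memcurv_invalid_parameter")
  }
  if (abs(curvature) >= 1) {
    abort("|curvature| must be < 1 nm^-1", class = "memcurv_invalid_parameter")
  }
  nsign <- if (outer == "+z") 1 else -1
  if (curvature == 0) {
    out <- list(kind = "plane", z0 = anchor[3], nsign = nsign, anchor = anchor)
  } else {
    s <- sign(curvature)
    R <- 1 / abs(curvature)
    # Center placed so that the outer normal at the anchor points along +Z
    # for either sign of the curvature.
    center <- c(anchor[1], anchor[3] - s * R)
    out <- list(kind = "cylinder", center = center, radius = R, s = s,
                axis = c(0, 1, 0), anchor = anchor)
  }
  class(out) <- "surface_model"
  out
}

#' @export
print.surface_model <- function(x, ...) {
  if (x$kind == "plane") {
    cat(sprintf("surface_model: plane z0 = %.4f nm, outer normal %sZ\n",
                x$z0, if (x$nsign > 0) "+" else "-"))
  } else {
    cat(sprintf(
      "surface_model: cylinder (axis Y), R = %.4f nm, c = %+.6f nm^-1, center XZ = (%.4f, %.4f)\n",
      x$radius, surface_curvature(x), x$center[1], x$center[2]))
  }
  invisible(x)
}

#' Signed curvature of a surface model
#'
#' @param surface A `surface_model`.
#' @return Signed curvature in nm^-1 (0 for a plane).
#' @export
surface_curvature <- function(surface) {
  stopifnot(inherits(surface, "surface_model"))
  if (surface$kind == "plane") 0 else surface$s / surface$radius
}

#' Signed depth of points relative to the mid-surface
#'
#' Zero on the mid-surface, positive toward the outer leaflet, negative toward
#' the inner leaflet. For a cylinder this is `s * (||p_xz - center|| - R)`; for
#' a plane it is the signed height above `z0` along the outer normal.
#'
#' @param surface A `surface_model`.
#' @param points A 3-vector or n x 3 matrix of positions (nm).
#' @return Numeric vector of signed depths (nm).
#' @export
signed_depth <- function(surface, points) {
  stopifnot(inherits(surface, "surface_model"))
  p <- as_points(points)
  if (surface$kind == "plane") {
    surface$nsign * (p[, 3] - surface$z0)
  } else {
    r <- sqrt((p[, 1] - surface$center[1])^2 + (p[, 3] - surface$center[2])^2)
    surface$s * (r - surface$radius)
  }
}

#' Local outer (or inner) leaflet normal
#'
#' Unit vector pointing away from the mid-surface on the outer side (the
#' gradient of [signed_depth()]); the inner-leaflet normal is its negation.
#'
#' @inheritParams signed_depth
#' @param leaflet `"outer"` (default) or `"inner"`.
#' @return An n x 3 matrix of unit vectors.
#' @export
outer_normal <- function(surface, points, leaflet = c("outer", "inner")) {
  stopifnot(inherits(surface, "surface_model"))
  leaflet <- match.arg(leaflet)
  p <- as_points(points)
  if (surface$kind == "plane") {
    n <- matrix(rep(c(0, 0, surface$nsign), each = nrow(p)), ncol = 3L)
  } else {
    dx <- p[, 1] - surface$center[1]
    dz <- p[, 3] - surface$center[2]
    r <- sqrt(dx^2 + dz^2)
    if (any(r < 1e-9)) {
      abort("normal undefined for a point on the cylinder axis",
            class = "memcurv_undefined_normal")
    }
    n <- cbind(surface$s * dx / r, 0, surface$s * dz / r)
  }
  if (leaflet == "inner") n <- -n
  unname(n)
}

#' Specify an analysis sector
#'
#' Analyses of bicelle systems are restricted to a sector around the symmetry
#' plane so that the semicircular caps (lipid reservoirs) never contaminate
#' the statistics. On a cylinder the sector is an arc of `+/- half_angle`
#' degrees around the anchor direction; on a plane it is a slab
#' `|x - x_anchor| <= half_width` nm.
#'
#' @param mode `"arc"` or `"slab"`.
#' @param half_angle Arc half-extent in degrees, in (0, 90].
#' @param half_width Slab half-extent in nm, > 0.
#' @return A `sector_spec` object.
#' @export
sector_spec <- function(mode = c("arc", "slab"), half_angle = 30, half_width = 3) {
  mode <- match.arg(mode)
  if (mode == "arc") {
    if (!is.numeric(half_angle) || half_angle <= 0 || half_angle > 90) {
      abort("arc half_angle must lie in (0, 90] degrees",
            class = "memcurv_invalid_parameter")
    }
  } else if (!is.numeric(half_width) || half_width <= 0) {
    abort("slab half_width must be > 0 nm", class = "memcurv_invalid_parameter")
  }
  structure(list(mode = mode, half_angle = half_angle, half_width = half_width),
            class = "sector_spec")
}

#' Mask points inside the analysis sector
#'
#' @param surface A `surface_model`.
#' @param points A 3-vector or n x 3 matrix (nm).
#' @param sector A [sector_spec()]; `NULL` selects everything.
#' @return Logical vector, `TRUE` for points inside the sector.
#' @export
sector_mask <- function(surface, points, sector) {
  stopifnot(inherits(surface, "surface_model"))
  p <- as_points(points)
  if (is.null(sector)) return(rep(TRUE, nrow(p)))
  stopifnot(inherits(sector, "sector_spec"))
  if (sector$mode == "arc") {
    if (surface$kind != "cylinder") {
      abort("arc sectors are only defined on a cylindrical surface",
            class = "memcurv_invalid_mode")
    }
    ref <- atan2(surface$anchor[1] - surface$center[1],
                 surface$anchor[3] - surface$center[2])
    ang <- atan2(p[, 1] - surface$center[1], p[, 3] - surface$center[2]) - ref
    ang <- atan2(sin(ang), cos(ang))  # wrap to (-pi, pi]
    abs(ang) <= deg2rad(sector$half_angle) + 1e-12
  } else {
    abs(p[, 1] - surface$anchor[1]) <= sector$half_width + 1e-12
  }
}

# Algebraic (Kasa) circle fit in the XZ projection: linear least squares on
# x^2 + z^2 + D x + E z + F = 0. Returns center and radius.
kasa_fit <- function(x, z) {
  A <- cbind(x, z, 1)
  b <- -(x^2 + z^2)
  qrA <- qr(A)
  if (qrA$rank < 3L) {
    abort("degenerate geometry: points are collinear in the XZ plane",
          class = "memcurv_fit_degenerate")
  }
  coef <- qr.coef(qrA, b)
  cx <- -coef[1] / 2
  cz <- -coef[2] / 2
  R2 <- cx^2 + cz^2 - coef[3]
  if (!is.finite(R2) || R2 <= 0) {
    abort("degenerate geometry: circle fit failed",
          class = "memcurv_fit_degenerate")
  }
  list(center = c(cx, cz), radius = sqrt(R2))
}

# Geometric least-squares refinement: minimize sum_i (r_i - R)^2 over the
# center, with R profiled out as mean(r_i). Gauss-Newton-free: BFGS on the
# profiled objective, tight tolerance.
geometric_circle_fit <- function(x, z, init) {
  obj <- function(ctr) {
    r <- sqrt((x - ctr[1])^2 + (z - ctr[2])^2)
    sum((r - mean(r))^2)
  }
  opt <- stats::optim(init$center, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  r <- sqrt((x - opt$par[1])^2 + (z - opt$par[2])^2)
  list(center = opt$par, radius = mean(r), rss = opt$value)
}

#' Fit a mid-surface model to a point cloud
#'
#' Fits either a plane (mean height) or a Y-axis cylinder (least-squares
#' circle in the XZ projection: algebraic Kasa fit refined by geometric least
#' squares) to a set of points, e.g. lipid head-group or wall-anchor
#' positions. The caller declares which side the outer leaflet faces; the
#' returned signed curvature then follows the convention that positive
#' curvature means the outer monolayer is convex.
#'
#' @param points An n x 3 matrix (nm); at least 3 points for a plane, at
#'   least 6 non-collinear points for a cylinder.
#' @param kind `"auto"`, `"plane"` or `"cylinder"`. `"auto"` picks the
#'   cylinder when the circle fit improves markedly on the plane fit and the
#'   fitted radius is physically meaningful (< 1000 nm).
#' @param outer For a cylinder, `"away"` (default) if the outer leaflet faces
#'   away from the cylinder axis (convex outer, positive curvature) or
#'   `"toward"` for the opposite; for a plane, `"+z"`/`"-z"` also accepted.
#' @return A `surface_model`.
#' @export
fit_surface <- function(points, kind = c("auto", "plane", "cylinder"),
                        outer = "away") {
  kind <- match.arg(kind)
  p <- as_points(points)
  nsign <- if (identical(outer, "-z") || identical(outer, "toward")) -1 else 1
  fit_plane <- function() {
    if (nrow(p) < 3L) abort("plane fit needs >= 3 points",
                            class = "memcurv_invalid_parameter")
    z0 <- mean(p[, 3])
    s <- make_surface(0, anchor = c(mean(p[, 1]), mean(p[, 2]), z0),
                      outer = if (nsign > 0) "+z" else "-z")
    attr(s, "rss") <- sum((p[, 3] - z0)^2)
    s
  }
  fit_cyl <- function() {
    if (nrow(p) < 6L) abort("cylinder fit needs >= 6 points",
                            class = "memcurv_invalid_parameter")
    init <- kasa_fit(p[, 1], p[, 3])
    g <- geometric_circle_fit(p[, 1], p[, 3], init)
    # anchor: surface point nearest to the centroid of the data
    cen <- c(mean(p[, 1]), mean(p[, 3]))
    u <- cen - g$center
    if (vnorm(u) < 1e-12) u <- c(0, 1)
    u <- u / vnorm(u)
    apt <- g$center + g$radius * u
    s <- structure(list(kind = "cylinder", center = g$center,
                        radius = g$radius, s = nsign, axis = c(0, 1, 0),
                        anchor = c(apt[1], mean(p[, 2]), apt[2])),
                   class = "surface_model")
    attr(s, "rss") <- g$rss
    s
  }
  if (kind == "plane") return(fit_plane())
  if (kind == "cylinder") return(fit_cyl())
  pl <- fit_plane()
  cy <- tryCatch(fit_cyl(), memcurv_error = function(e) NULL)
  if (is.null(cy) || cy$radius > 1000 ||
      attr(cy, "rss") > 0.5 * attr(pl, "rss")) pl else cy
}
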