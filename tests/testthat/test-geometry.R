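test_that("make_surface builds cylinders and planes with the sign convention", {
  s <- make_surface(0.2, anchor = c(0, 0, 0))
  expect_equal(s$kind, "cylinder")
  expect_equal(s$radius, 5.0)
  expect_equal(surface_curvature(s), 0.2, tolerance = 1e-12)

  p <- make_surface(0, anchor = c(1, 2, 3))
  expect_equal(p$kind, "plane")
  expect_equal(surface_curvature(p), 0)
  expect_equal(signed_depth(p, c(0, 0, 3)), 0)

  # opposite curvature sign puts the center on the opposite side
  sm <- make_surface(-0.2)
  expect_equal(sm$center[2], 5.0)
  expect_equal(s$center[2], -5.0)
  expect_equal(surface_curvature(sm), -0.2, tolerance = 1e-12)

  expect_error(make_surface(1.5), class = "memcurv_invalid_parameter")
})

test_that("signed depth and normals follow their definitions", {
  s <- make_surface(0.2)            # R = 5, center (0, -5), s = +1
  expect_equal(signed_depth(s, c(0, 3, 0)), 0)
  # radial distance 7.5 -> depth +2.5
  expect_equal(signed_depth(s, c(0, 0, 2.5)), 2.5)
  expect_equal(drop(outer_normal(s, c(5, 1, -5))), c(1, 0, 0))
  expect_equal(drop(outer_normal(s, c(5, 1, -5), leaflet = "inner")),
               c(-1, 0, 0))
  expect_error(outer_normal(s, c(0, 0, -5)), class = "memcurv_undefined_normal")

  p <- make_surface(0)
  expect_equal(signed_depth(p, c(4, 7, -1.3)), -1.3)
  expect_equal(drop(outer_normal(p, c(4, 7, -1.3))), c(0, 0, 1))
  pm <- make_surface(0, outer = "-z")
  expect_equal(signed_depth(pm, c(0, 0, -1.3)), 1.3)
})

test_that("circle fitting recovers curvature for clean and noisy samples", {
  pts <- circle_points(5, n = 100)
  f <- fit_surface(pts, kind = "cylinder")
  expect_lt(abs(abs(surface_curvature(f)) - 0.2), 1e-9)

  # exact plane
  plane_pts <- cbind(runif(20, -3, 3), runif(20, -3, 3), 2.0)
  fp <- fit_surface(plane_pts, kind = "plane")
  expect_equal(fp$z0, 2.0, tolerance = 1e-12)
  expect_equal(surface_curvature(fp), 0)

  # isotropic Gaussian noise sigma = 0.05 nm
  set.seed(42)
  noisy <- circle_points(5, n = 200) + matrix(rnorm(600, 0, 0.05), ncol = 3)
  fn <- fit_surface(noisy, kind = "cylinder")
  expect_lt(abs(abs(surface_curvature(fn)) - 0.2), 0.01)

  # collinear points cannot define a cylinder
  line <- cbind(seq(0, 5, length.out = 10), 0, seq(0, 5, length.out = 10))
  expect_error(fit_surface(line, kind = "cylinder"),
               class = "memcurv_fit_degenerate")
})

test_that("fit/generate round trip recovers the curvature for all signs", {
  for (c0 in c(-0.2, 0, 0.2)) {
    srf <- make_surface(c0)
    pts <- if (c0 == 0) {
      cbind(seq(-3, 3, length.out = 50), 0, 0)
    } else {
      circle_points(1 / abs(c0), center = srf$center, n = 50,
                    arc = c(-0.6, 0.6))
    }
    fitted <- fit_surface(pts, kind = if (c0 == 0) "plane" else "cylinder",
                          outer = if (c0 < 0) "toward" else "away")
    expect_lt(abs(surface_curvature(fitted) - c0), 1e-9)
  }
})

test_that("the plane is the exact flat limit of the cylinder depth", {
  tiny <- make_surface(1e-8)
  flat <- make_surface(0)
  set.seed(3)
  pts <- cbind(runif(50, -3, 3), runif(50, -3, 3), runif(50, -3, 3))
  expect_lt(max(abs(signed_depth(tiny, pts) - signed_depth(flat, pts))), 1e-6)
})

test_that("the outer normal is the gradient of the signed depth", {
  h <- 1e-6
  for (srf in list(make_surface(0.2), make_surface(-0.2), make_surface(0))) {
    set.seed(7)
    pts <- cbind(runif(10, -2, 2), runif(10, -2, 2), runif(10, 0.5, 2.5))
    n <- outer_normal(srf, pts)
    grad <- sapply(1:3, function(k) {
      dp <- pts; dm <- pts
      dp[, k] <- dp[, k] + h
      dm[, k] <- dm[, k] - h
      (signed_depth(srf, dp) - signed_depth(srf, dm)) / (2 * h)
    })
    expect_lt(max(abs(grad - n)), 1e-5)
    expect_equal(sqrt(rowSums(n^2)), rep(1, 10), tolerance = 1e-12)
  }
})

test_that("sector masks select arcs on cylinders and slabs on planes", {
  s <- make_surface(0.2)  # anchor (0,0,0), center (0,-5)
  arc30 <- sector_spec("arc", half_angle = 30)
  at_angle <- function(deg) {
    c(5 * sin(deg2rad_t <- deg * pi / 180), 0, -5 + 5 * cos(deg2rad_t))
  }
  expect_true(sector_mask(s, at_angle(0), arc30))
  expect_true(sector_mask(s, at_angle(29.9), arc30))
  expect_false(sector_mask(s, at_angle(40), arc30))

  p <- make_surface(0)
  slab <- sector_spec("slab", half_width = 3)
  expect_true(sector_mask(p, c(-2.9, 0, 1), slab))
  expect_false(sector_mask(p, c(3.5, 0, 1), slab))
  expect_error(sector_mask(p, c(0, 0, 0), arc30), class = "memcurv_invalid_mode")
  expect_error(sector_spec("arc", half_angle = 120),
               class = "memcurv_invalid_parameter")
})
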