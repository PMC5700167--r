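test_that("flat walls have exact grid spacing and separation", {
  g <- generate_walls(wall_spec())
  d <- as.matrix(dist(g$outer$anchors))
  diag(d) <- Inf
  expect_equal(min(d), 0.51, tolerance = 1e-12)
  expect_equal(unique(g$outer$anchors[, 3]), 2.5)
  expect_equal(unique(g$inner$anchors[, 3]), -2.5)
  expect_identical(g$outer$anchors, g$outer$shells)
})

test_that("curved walls sit at mid-radius +/- D/2 with arc spacing d", {
  g <- generate_walls(wall_spec(curvature = 0.2))
  fo <- fit_surface(g$outer$anchors, kind = "cylinder")
  fi <- fit_surface(g$inner$anchors, kind = "cylinder")
  expect_lt(abs(fo$radius - 7.5), 1e-9)
  expect_lt(abs(fi$radius - 2.5), 1e-9)
  # along-arc neighbor spacing equals the grid spacing on each wall
  for (w in list(list(a = g$outer$anchors, r = 7.5),
                 list(a = g$inner$anchors, r = 2.5))) {
    row <- w$a[w$a[, 2] == w$a[1, 2], , drop = FALSE]
    row <- row[order(atan2(row[, 1], row[, 3] + 5)), , drop = FALSE]
    chord <- sqrt(rowSums((row[-1, ] - row[-nrow(row), ])^2))
    arc <- 2 * w$r * asin(chord / (2 * w$r))
    expect_lt(max(abs(arc - 0.51)), 1e-6)
  }
  # negative curvature flips the outer wall to the smaller radius
  gm <- generate_walls(wall_spec(curvature = -0.2))
  expect_lt(abs(fit_surface(gm$outer$anchors, "cylinder")$radius - 2.5), 1e-9)
})

test_that("degenerate and invalid wall specs are rejected", {
  expect_error(generate_walls(wall_spec(extent = c(0.4, 0.4))),
               class = "memcurv_empty_wall")
  # 2^(1/6)*0.70 = 0.786 < 0.8: not purely repulsive within the cutoff
  expect_error(wall_spec(sigma = 0.70), class = "memcurv_validation_error")
  expect_error(wall_spec(separation = -1), class = "memcurv_invalid_parameter")
})

test_that("repulsivity bound matches the closed form and a derivative scan", {
  r_min <- check_repulsive(wall_spec())
  expect_equal(as.numeric(r_min), 2^(1 / 6) * 0.85, tolerance = 1e-12)
  expect_true(attr(r_min, "holds"))

  # independent oracle: sign scan of dV/dr on a 1e-4 nm grid
  r <- seq(0.05, as.numeric(r_min) - 1e-6, by = 1e-4)
  V <- lj_potential(r, 0.85, 1e-5)
  expect_true(all(diff(V) < 0))
  # and the slope turns positive just beyond r_min
  r2 <- seq(as.numeric(r_min) + 1e-6, 1.2, by = 1e-4)
  expect_true(all(diff(lj_potential(r2, 0.85, 1e-5)) > 0))

  # boundary case: sigma chosen so r_min equals the cutoff exactly
  b <- check_repulsive(wall_spec(sigma = 0.8 / 2^(1 / 6)))
  expect_equal(as.numeric(b), 0.8, tolerance = 1e-12)
  expect_true(attr(b, "holds"))
  expect_false(attr(check_repulsive(0.70), "holds") %in% TRUE)
})

test_that("bending plans conserve beads, spacing and wall separation", {
  spec <- wall_spec(extent = c(4.08, 1.53))
  flat <- generate_walls(spec)
  plan <- suppressWarnings(plan_bending(flat, 0.2, n_steps = 4))
  expect_length(plan$steps, 5L)
  expect_identical(plan$steps[[1]], flat)
  cs <- plan$curvatures
  expect_equal(cs, 0.2 * (0:4) / 4)
  for (k in seq_along(plan$steps)) {
    g <- plan$steps[[k]]
    expect_identical(nrow(g$outer$anchors), nrow(flat$outer$anchors))
    if (cs[k] == 0) next
    fo <- fit_surface(g$outer$anchors, "cylinder")
    fi <- fit_surface(g$inner$anchors, "cylinder")
    # wall separation conserved
    expect_lt(abs(abs(fo$radius - fi$radius) - spec$separation), 1e-6)
    # interpolated curvature recovered from the wall radii
    expect_lt(abs(2 / (fo$radius + fi$radius) - cs[k]), 1e-6)
    # along-arc spacing conserved at every step
    for (w in list(list(a = g$outer$anchors, f = fo),
                   list(a = g$inner$anchors, f = fi))) {
      row <- w$a[w$a[, 2] == w$a[1, 2], , drop = FALSE]
      chord <- sqrt(rowSums((row[-1, ] - row[-nrow(row), ])^2))
      arc <- 2 * w$f$radius * asin(pmin(1, chord / (2 * w$f$radius)))
      expect_lt(max(abs(arc - spec$spacing)), 1e-6)
    }
  }
})

test_that("trivial bending plans behave as identities", {
  flat <- generate_walls(wall_spec(extent = c(4.08, 1.53)))
  one <- suppressWarnings(plan_bending(flat, 0.2, n_steps = 1))
  expect_length(one$steps, 2L)
  idty <- plan_bending(flat, 0, n_steps = 3)
  for (g in idty$steps) {
    expect_equal(g$outer$anchors, flat$outer$anchors)
  }
  expect_error(plan_bending(flat, 0.2, n_steps = 0),
               class = "memcurv_invalid_parameter")
})

test_that("automatic step counts respect the displacement cap", {
  flat <- generate_walls(wall_spec(extent = c(4.08, 1.53)))
  plan <- plan_bending(flat, 0.2)
  expect_lte(plan$max_step_disp, 0.05 + 1e-12)
  expect_gt(plan$n_steps, 1L)
})
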