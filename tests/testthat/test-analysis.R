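test_that("density profiles are unit-normalized and flat for uniform slabs", {
  set.seed(31)
  n <- 20000
  atoms <- data.frame(name = "P", resname = "PC", resid = seq_len(n),
                      x = runif(n, -5, 5), y = runif(n, -5, 5),
                      z = runif(n, -2, 2), element = "P", leaflet = "outer")
  frame <- membrane_frame(atoms, c(10, 10, 4))
  prof <- density_profiles(frame, make_surface(0), bin_width = 0.2,
                           weighting = "number")
  bw <- attr(prof, "bin_width")
  expect_equal(sum(prof$density) * bw, 1, tolerance = 1e-6)
  # per-bin counts within 3 sigma of the Poisson expectation
  counts <- prof$density * bw * n
  expected <- n * bw / 4
  expect_true(all(abs(counts - expected) < 3.5 * sqrt(expected)))
})

test_that("a cylindrical shell shows a single peak at its depth", {
  set.seed(32)
  n <- 5000
  th <- runif(n, -0.5, 0.5)
  r <- 5 + 1.75
  atoms <- data.frame(name = "P", resname = "PC", resid = seq_len(n),
                      x = r * sin(th), y = runif(n, -3, 3),
                      z = -5 + r * cos(th), element = "P", leaflet = "outer")
  frame <- membrane_frame(atoms, c(20, 6, 20))
  prof <- density_profiles(frame, make_surface(0.2), bin_width = 0.05,
                           weighting = "number")
  expect_equal(prof$depth[which.max(prof$density)], 1.75, tolerance = 0.05)
  expect_equal(sum(prof$density) * 0.05, 1, tolerance = 1e-6)
})

test_that("empty group selections are an error", {
  frame <- heads_frame(cbind(0:5, 0, 0))
  expect_error(
    density_profiles(frame, make_surface(0),
                     groups = list(none = function(a) a$name == "ZZ")),
    class = "memcurv_empty_group")
})

test_that("order parameter limits: all-trans, isotropic, magic angle", {
  # template bilayer: C-H bonds exactly perpendicular to the +Z normal
  frame <- build_bicelle(composition(outer = c(PC = 4), inner = c(PC = 4)),
                         grid = c(2, 2), seed = 1)
  op <- order_parameters(frame, make_surface(0))
  expect_equal(op$scd, rep(-0.5, nrow(op)), tolerance = 1e-12)

  # isotropic C-H orientations average to zero
  set.seed(33)
  nv <- 1e5
  v <- matrix(rnorm(3 * nv), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  iso <- order_parameters(ch_pair_frame(v), make_surface(0))
  expect_lt(abs(iso$scd), 0.01)

  # magic angle: 3cos^2(theta) - 1 = 0
  th <- acos(1 / sqrt(3))
  dirs <- cbind(sin(th), 0, cos(th))[rep(1, 10), ]
  magic <- order_parameters(ch_pair_frame(dirs), make_surface(0))
  expect_lt(abs(magic$scd), 1e-9)
})

test_that("missing hydrogens and unknown species are rejected", {
  frame <- heads_frame(cbind(runif(6), runif(6), 0))
  expect_error(order_parameters(frame, make_surface(0)),
               class = "memcurv_explicit_h_required")
  full <- build_bicelle(composition(outer = c(PC = 4), inner = c(PC = 4)),
                        grid = c(2, 2), seed = 1)
  expect_error(order_parameters(full, make_surface(0), species = "XXX"),
               class = "memcurv_validation_error")
})

test_that("an imposed order-parameter profile is recovered", {
  spec <- fixture_spec(curvature = 0.2,
                       comp = composition(outer = c(PC = 36, SM = 12),
                                          inner = c(PC = 36, SM = 12)),
                       chol_minor_frac = 0, seed = 14)
  fx <- make_membrane_fixture(spec)
  op <- order_parameters(fx$frame, fx$surface)
  truth <- fx$truth$scd
  for (i in seq_len(nrow(op))) {
    expect_lt(abs(op$scd[i] - truth[as.character(op$carbon[i])]), 0.02)
  }
  # both species, both leaflets, all 17 carbons present
  expect_equal(nrow(op), 2 * 2 * 17)
})

test_that("cholesterol axis geometry maps to inclination and minor fraction", {
  mk_chol <- function(resid, o3, c17, box = c(20, 20, 20)) {
    data.frame(name = c("O3", "C17"), resname = "CHL", resid = resid,
               x = c(o3[1], c17[1]), y = c(o3[2], c17[2]),
               z = c(o3[3], c17[3]), element = c("O", "C"), leaflet = NA)
  }
  atoms <- rbind(
    mk_chol(1L, c(0, 0, 1.5), c(0, 0, 0.6)),     # axis || outer normal -> 0 deg
    mk_chol(2L, c(1, 0.45, 0), c(1, -0.45, 0)),  # horizontal at mid-surface
    mk_chol(3L, c(2, 0, -1.5), c(2, 0, -0.6)))   # inner leaflet, 0 deg
  frame <- membrane_frame(atoms, c(20, 20, 20))
  rep <- cholesterol_metrics(frame, make_surface(0),
                             head_surface_depth = c(outer = 2, inner = 2))
  r <- rep$records
  expect_equal(r$incl[r$leaflet == "outer"], 0, tolerance = 1e-9)
  expect_equal(r$incl[r$leaflet == "inner"], 0, tolerance = 1e-9)
  expect_equal(r$incl[r$leaflet == "central"], 90, tolerance = 1e-9)
  expect_equal(unname(rep$counts["central"]), 1)
  expect_equal(rep$minor_fraction, 100 / 3, tolerance = 1e-9)
  # depth measured from the declared head surface
  expect_equal(r$depth_surface[r$leaflet == "outer"], 0.5, tolerance = 1e-9)
})

test_that("constructed minor fractions are counted exactly", {
  comp <- composition(outer = c(PC = 60, CHL = 40), inner = c(PC = 60, CHL = 40))
  fx <- make_membrane_fixture(fixture_spec(curvature = 0, comp = comp,
                                           chol_minor_frac = 2.5, seed = 3))
  expect_equal(fx$truth$n_minor, 2L)
  rep <- cholesterol_metrics(fx$frame, fx$surface)
  expect_equal(rep$minor_fraction, 2.5, tolerance = 1e-9)
  expect_equal(unname(rep$counts["central"]), 2)
  # angle histogram masses sum to one; inclination peaks where constructed
  for (h in rep$angle_hist) expect_equal(sum(h$mass), 1, tolerance = 1e-9)
  expect_lt(rep$peaks$angle_peak[rep$peaks$leaflet == "outer"], 5)
})

test_that("analyses ignore everything outside the sector", {
  spec <- fixture_spec(curvature = 0.2,
                       comp = composition(outer = c(PC = 48), inner = c(PC = 48)),
                       chol_minor_frac = 0, seed = 8)
  fx <- make_membrane_fixture(spec)
  sector <- sector_spec("arc", half_angle = 20)
  # mangle atoms far outside the sector (margin leaves the atoms of
  # edge-of-sector molecules untouched); moving along Y keeps arc angles
  mangle <- function(frame) {
    xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
    out <- !sector_mask(fx$surface, xyz, sector_spec("arc", half_angle = 40))
    frame$atoms$y[out] <- frame$atoms$y[out] + 40
    frame
  }
  f2 <- mangle(fx$frame)
  d1 <- density_profiles(fx$frame, fx$surface, sector = sector)
  d2 <- density_profiles(f2, fx$surface, sector = sector)
  expect_equal(d1, d2)
  o1 <- order_parameters(fx$frame, fx$surface, sector = sector)
  o2 <- order_parameters(f2, fx$surface, sector = sector)
  expect_equal(o1, o2)
})
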