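test_that("the default asymmetric composition builds with the printed counts", {
  frame <- build_bicelle(composition(), grid = c(17, 6), seed = 11)
  res <- frame$atoms[!duplicated(frame$atoms$resid), ]
  counts <- table(res$resname, res$leaflet)
  # 102 phospholipids and 51 cholesterol per monolayer
  pl <- rownames(counts) != "CHL"
  expect_equal(sum(counts[pl, "outer"]), 102L)
  expect_equal(sum(counts[pl, "inner"]), 102L)
  expect_equal(unname(counts["CHL", c("outer", "inner")]), c(51L, 51L))
  # per-species asymmetry: PS only inside, SM enriched outside
  expect_equal(sum(res$resname == "PS" & res$leaflet == "outer"), 0L)
  expect_equal(sum(res$resname == "PS" & res$leaflet == "inner"), 30L)
  expect_equal(sum(res$resname == "SM" & res$leaflet == "outer"), 42L)
  expect_equal(sum(res$resname == "PE" & res$leaflet == "inner"), 46L)
})

test_that("count/grid mismatches and unknown species are rejected", {
  short <- composition(outer = c(PC = 60, SM = 40, CHL = 10),
                       inner = c(PC = 102, CHL = 10))
  expect_error(build_bicelle(short, grid = c(17, 6), seed = 1),
               class = "memcurv_composition_error")
  expect_error(composition(outer = c(XX = 10)),
               class = "memcurv_validation_error")
  expect_error(composition(outer = c(PC = -1)),
               class = "memcurv_validation_error")
})

test_that("building is deterministic per seed", {
  f1 <- build_bicelle(composition(), seed = 5)
  f2 <- build_bicelle(composition(), seed = 5)
  f3 <- build_bicelle(composition(), seed = 6)
  expect_identical(f1$atoms, f2$atoms)
  expect_false(identical(f1$atoms$resname, f3$atoms$resname))
  dir <- withr::local_tempdir()
  write_gro(f1, file.path(dir, "a.gro"))
  write_gro(f2, file.path(dir, "b.gro"))
  expect_identical(readLines(file.path(dir, "a.gro")),
                   readLines(file.path(dir, "b.gro")))
})

test_that("selective repulsion keeps proximal heavy atoms only", {
  frame <- build_bicelle(composition(), seed = 2)
  sel <- selective_repulsion_atoms(frame)
  a <- frame$atoms
  # pick one PC molecule and check its chain carbons
  pc <- a$resid[a$resname == "PC"][1]
  included <- c(sel$outer, sel$inner)
  in_pc <- intersect(included, which(a$resid == pc))
  names_in <- a$name[in_pc]
  expect_true(all(sprintf("C%dA", 2:9) %in% names_in))
  expect_false(any(sprintf("C%dA", 10:18) %in% names_in))
  expect_true("P" %in% names_in)
  # hydrogens and cholesterol never participate; sets are disjoint
  expect_false(any(a$element[included] == "H"))
  expect_false(any(a$resname[included] == "CHL"))
  expect_length(intersect(sel$outer, sel$inner), 0L)
  expect_equal(sel$override$sigma, 0.8)
  expect_equal(sel$override$epsilon, 1e-7)
})

test_that("untagged phospholipids trigger a tagging error", {
  frame <- build_bicelle(composition(), seed = 2)
  frame$atoms$leaflet <- NA_character_
  expect_error(selective_repulsion_atoms(frame),
               class = "memcurv_tagging_error")
})

test_that("leaflet assignment follows head-group depth and the central band", {
  atoms <- rbind(
    data.frame(name = "P", resname = "PC", resid = 1L,
               x = 0, y = 0, z = 1.9, element = "P", leaflet = NA),
    data.frame(name = "P", resname = "PE", resid = 2L,
               x = 0, y = 0, z = -1.9, element = "P", leaflet = NA),
    data.frame(name = c("O3", "C17"), resname = "CHL", resid = 3L,
               x = 0, y = c(0, 0.9), z = 0.1, element = c("O", "C"),
               leaflet = NA),
    data.frame(name = c("O3", "C17"), resname = "CHL", resid = 4L,
               x = 0, y = 0, z = c(-1.5, -0.6), element = c("O", "C"),
               leaflet = NA))
  frame <- membrane_frame(atoms, c(10, 10, 10))
  tagged <- assign_leaflets(frame, make_surface(0), chol_central_halfwidth = 0.5)
  tag <- tagged$atoms$leaflet[!duplicated(tagged$atoms$resid)]
  expect_equal(tag, c("outer", "inner", "central", "inner"))

  # a residue without its head reference atom is a naming error
  bad <- membrane_frame(
    data.frame(name = "C2A", resname = "PC", resid = 1L, x = 0, y = 0, z = 1,
               element = "C", leaflet = NA), c(5, 5, 5))
  expect_error(assign_leaflets(bad, make_surface(0)),
               class = "memcurv_naming_error")
})
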