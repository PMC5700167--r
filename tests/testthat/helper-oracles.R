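# Test helpers: independent oracles and small fixture constructors.

# Brute-force nearest-site pixel integration of the Voronoi cell of
# `sites[target, ]` (2D). Integrates over a box of half-width `halfw` around
# the target; valid for cells fully contained in that box.
pixel_voronoi_area <- function(sites, target, pixel = 1e-3, halfw = 1.5) {
  gx <- seq(sites[target, 1] - halfw, sites[target, 1] + halfw, by = pixel)
  gy <- seq(sites[target, 2] - halfw, sites[target, 2] + halfw, by = pixel)
  count <- 0
  for (yy in gy) {  # row-chunked to bound memory
    best <- rep(Inf, length(gx))
    owner <- integer(length(gx))
    for (s in seq_len(nrow(sites))) {
      d2 <- (gx - sites[s, 1])^2 + (yy - sites[s, 2])^2
      upd <- d2 < best
      best[upd] <- d2[upd]
      owner[upd] <- s
    }
    count <- count + sum(owner == target)
  }
  count * pixel^2
}

# Points sampled on a circle of radius R in the XZ plane (y spread given),
# as an n x 3 matrix.
circle_points <- function(R, center = c(0, -R), n = 100, y = 0,
                          arc = c(-pi, pi)) {
  th <- seq(arc[1], arc[2], length.out = n)
  cbind(center[1] + R * sin(th), y, center[2] + R * cos(th))
}

# A frame holding only head (P) atoms at the given positions.
heads_frame <- function(xyz, leaflet = "outer", resname = "PC",
                        box = c(50, 50, 50)) {
  xyz <- as.matrix(xyz)
  membrane_frame(data.frame(
    name = "P", resname = resname, resid = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = "P",
    leaflet = leaflet, stringsAsFactors = FALSE), box)
}

# A frame of single C-H pairs (one per residue) with the given unit C-H
# directions; carbons on a plane grid, species PC, chain carbon C2A.
ch_pair_frame <- function(dirs, leaflet = "outer") {
  n <- nrow(dirs)
  cx <- ((seq_len(n) - 1) %% 1000) * 0.5
  cy <- ((seq_len(n) - 1) %/% 1000) * 0.5
  atoms <- data.frame(
    name = rep(c("P", "C2A", "H2A1"), n),
    resname = "PC",
    resid = rep(seq_len(n), each = 3L),
    x = as.vector(rbind(cx, cx, cx + 0.109 * dirs[, 1])),
    y = as.vector(rbind(cy, cy, cy + 0.109 * dirs[, 2])),
    z = as.vector(rbind(2, 1, 1 + 0.109 * dirs[, 3])),
    element = rep(c("P", "C", "H"), n),
    leaflet = leaflet, stringsAsFactors = FALSE)
  membrane_frame(atoms, c(600, 600, 10))
}

# Hexagonal lattice (2D) with spacing a: nrow x ncol sites.
hex_lattice <- function(a, nrows = 7, ncols = 7) {
  pts <- list()
  for (j in seq_len(nrows)) {
    for (i in seq_len(ncols)) {
      pts[[length(pts) + 1L]] <- c((i - 1) * a + (j %% 2) * a / 2,
                                   (j - 1) * a * sqrt(3) / 2)
    }
  }
  m <- do.call(rbind, pts)
  sweep(m, 2, colMeans(m))
}

# Mean in-sector, non-edge area of one leaflet.
mean_leaflet_apl <- function(frame, surface, leaflet, ...) {
  ap <- areas_per_lipid(frame, surface, ...)
  ok <- !ap$edge & ap$in_sector & ap$leaflet == leaflet & !is.na(ap$area)
  mean(ap$area[ok])
}
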