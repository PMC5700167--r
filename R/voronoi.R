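# Tangent-plane Voronoi cells. The tessellation itself is delegated to
# deldir; this file handles the per-lipid tangent-plane projection and the
# bounded/edge-cell bookkeeping.

# Area of the Voronoi cell of the site at the origin, given neighbor sites in
# tangent-plane coordinates. The tessellation window is the [-bound, bound]^2
# square; a cell touching the window is not closed by data and is flagged.
voronoi_cell_area <- function(neighbors_xy, bound) {
  if (is.null(dim(neighbors_xy))) neighbors_xy <- matrix(neighbors_xy, ncol = 2)
  if (nrow(neighbors_xy) < 3L) {
    return(list(area = NA_real_, edge = TRUE))
  }
  pts <- rbind(c(0, 0), neighbors_xy)
  dd <- deldir::deldir(pts[, 1], pts[, 2],
                       rw = c(-bound, bound, -bound, bound),
                       suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  # locate the target's tile (deldir can drop duplicated points)
  pt <- vapply(tl, function(t) t$pt[1]^2 + t$pt[2]^2, numeric(1))
  k <- which.min(pt)
  if (pt[k] > 1e-16) return(list(area = NA_real_, edge = TRUE))
  tile <- tl[[k]]
  list(area = tile$area, edge = any(tile$bp))
}

#' Tangent-plane Voronoi areas per lipid
#'
#' For each lipid, the tangent plane of the fitted membrane surface is taken
#' at its head-group reference atom; the head positions of same-leaflet
#' neighbors within `cutoff` are projected onto that plane, and the area of
#' the Voronoi cell centred on the target lipid is returned. Cells that are
#' not closed by neighbor data (edge lipids, or fewer than three projected
#' neighbors) are flagged and must be excluded from leaflet means.
#'
#' @param frame A leaflet-tagged [membrane_frame()].
#' @param surface The fitted mid-surface.
#' @param cutoff Neighbor search radius (nm). Default 1.5.
#' @param sector Optional [sector_spec()]; lipids outside keep their area but
#'   are marked `in_sector = FALSE`.
#' @param leaflets Leaflets to process.
#' @return data.frame with `resid`, `species`, `leaflet`, `area` (nm^2),
#'   `edge`, `in_sector`.
#' @export
areas_per_lipid <- function(frame, surface, cutoff = 1.5, sector = NULL,
                            leaflets = c("outer", "inner")) {
  stopifnot(inherits(frame, "membrane_frame"))
  rt <- residue_table(frame)
  rt <- rt[!is.na(rt$head) & rt$leaflet %in% leaflets, , drop = FALSE]
  if (nrow(rt) < 4L) {
    abort("need at least 4 head-tagged lipids in the selected leaflets",
          class = "memcurv_invalid_parameter")
  }
  heads <- frame_xyz(frame)[rt$head, , drop = FALSE]
  insec <- sector_mask(surface, heads, sector)
  out <- data.frame(resid = rt$resid, species = rt$resname,
                    leaflet = rt$leaflet, area = NA_real_, edge = TRUE,
                    in_sector = insec, stringsAsFactors = FALSE)
  for (lf in unique(rt$leaflet)) {
    sel <- which(rt$leaflet == lf)
    hp <- heads[sel, , drop = FALSE]
    for (t in seq_along(sel)) {
      d2 <- rowSums(sweep(hp, 2, hp[t, ])^2)
      nb <- which(d2 > 1e-12 & d2 <= cutoff^2)
      if (length(nb) < 3L) next
      nvec <- drop(outer_normal(surface, hp[t, ], leaflet = "outer"))
      basis <- tangent_basis(nvec)
      rel <- sweep(hp[nb, , drop = FALSE], 2, hp[t, ])
      xy <- cbind(rel %*% basis$e1, rel %*% basis$e2)
      cell <- voronoi_cell_area(xy, bound = cutoff)
      out$area[sel[t]] <- cell$area
      out$edge[sel[t]] <- cell$edge
    }
  }
  out
}

#' Aggregate per-lipid areas into a species x leaflet report
#'
#' Pools per-frame [areas_per_lipid()] tables, drops flagged (edge,
#' undefined or out-of-sector) cells and reports the mean and standard
#' deviation over all molecule-frames.
#'
#' @param areas One area table or a list of them (one per frame).
#' @return data.frame with `species`, `leaflet`, `mean_area`, `sd_area`, `n`.
#' @export
aggregate_apl <- function(areas) {
  if (is.data.frame(areas)) areas <- list(areas)
  if (length(areas) < 1L) abort("at least one frame of areas is required",
                                class = "memcurv_invalid_parameter")
  all <- do.call(rbind, areas)
  keep <- !all$edge & all$in_sector & !is.na(all$area)
  all <- all[keep, , drop = FALSE]
  if (nrow(all) == 0L) abort("no bounded in-sector cells to aggregate",
                             class = "memcurv_invalid_parameter")
  agg <- do.call(rbind, lapply(
    split(all, list(all$species, all$leaflet), drop = TRUE),
    function(g) data.frame(species = g$species[1], leaflet = g$leaflet[1],
                           mean_area = mean(g$area),
                           sd_area = stats::sd(g$area), n = nrow(g),
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg[order(agg$species, agg$leaflet), , drop = FALSE]
}
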