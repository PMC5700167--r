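# Curvature-aware analyses: signed-depth density profiles, deuterium order
# parameters against the local membrane normal, and cholesterol
# inclination/depth/minor-fraction statistics. All operations accept a single
# frame or a list of frames (with one surface, or one surface per frame) and
# restrict themselves to the analysis sector.

as_frame_list <- function(frames) {
  if (inherits(frames, "membrane_frame")) list(frames) else frames
}

surface_for <- function(surface, k) {
  if (inherits(surface, "surface_model")) surface else surface[[k]]
}

#' Default atom-group selectors for density profiles
#'
#' `heads`: phosphorus atoms; `tails`: acyl-chain carbons and their
#' hydrogens; `chol`: all cholesterol atoms.
#'
#' @return Named list of predicate functions on the atom table.
#' @export
default_density_groups <- function() {
  list(
    heads = function(a) a$name == "P",
    tails = function(a) grepl("^[CH][0-9]+[AB][12]?$", a$name) &
      a$resname %in% PHOSPHOLIPID_SPECIES,
    chol = function(a) a$resname == CHOL_RESNAME
  )
}

#' Normalized density profiles along the signed depth coordinate
#'
#' Histograms the signed depth of the selected atom groups, weighting by
#' atomic mass (or unit weight), dividing by the per-bin volume — constant
#' for a planar membrane, proportional to the local radius `R + s*depth` for
#' a cylindrical one — and normalizing each group's profile to unit integral.
#'
#' @param frames A [membrane_frame()] or list of frames.
#' @param surface A surface model, or a list with one per frame.
#' @param groups Named list of predicate functions on the atom table;
#'   default [default_density_groups()].
#' @param bin_width Depth bin width (nm). Default 0.01.
#' @param sector Optional [sector_spec()].
#' @param weighting `"mass"` or `"number"`.
#' @param by_leaflet Split each group by the atoms' leaflet tag.
#' @return data.frame with `group`, `leaflet`, `depth` (bin centre, nm),
#'   `density` (nm^-1 along depth; each group integrates to 1).
#' @export
density_profiles <- function(frames, surface, groups = default_density_groups(),
                             bin_width = 0.01, sector = NULL,
                             weighting = c("mass", "number"),
                             by_leaflet = FALSE) {
  weighting <- match.arg(weighting)
  frames <- as_frame_list(frames)
  if (length(groups) == 0L) abort("at least one atom group is required",
                                  class = "memcurv_empty_group")
  samples <- list()
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    srf <- surface_for(surface, k)
    xyz <- frame_xyz(f)
    depth <- signed_depth(srf, xyz)
    insec <- sector_mask(srf, xyz, sector)
    geomw <- if (srf$kind == "cylinder") {
      r <- srf$radius + srf$s * depth
      1 / pmax(abs(r), 1e-9)
    } else rep(1, length(depth))
    w <- if (weighting == "mass") element_mass(f$atoms$element) else
      rep(1, length(depth))
    for (g in names(groups)) {
      sel <- groups[[g]](f$atoms) & insec
      if (!any(sel)) next
      lf <- if (by_leaflet) f$atoms$leaflet[sel] else "all"
      samples[[length(samples) + 1L]] <- data.frame(
        group = g, leaflet = ifelse(is.na(lf), "untagged", lf),
        depth = depth[sel], w = w[sel] * geomw[sel],
        stringsAsFactors = FALSE)
    }
  }
  if (length(samples) == 0L) {
    abort("no atoms matched any group selection", class = "memcurv_empty_group")
  }
  s <- do.call(rbind, samples)
  lo <- floor(min(s$depth) / bin_width) * bin_width
  hi <- ceiling(max(s$depth) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  out <- lapply(split(s, list(s$group, s$leaflet), drop = TRUE), function(g) {
    bin <- findInterval(g$depth, breaks, rightmost.closed = TRUE)
    dens <- vapply(seq_along(centers), function(b) sum(g$w[bin == b]),
                   numeric(1))
    dens <- dens / (sum(dens) * bin_width)
    data.frame(group = g$group[1], leaflet = g$leaflet[1], depth = centers,
               density = dens, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bin_width") <- bin_width
  class(res) <- c("density_profile", "data.frame")
  res
}

# Parse chain hydrogens "H<i><chain><1|2>" and pair them with their carbon.
chain_ch_pairs <- function(atoms) {
  hm <- regmatches(atoms$name, regexec("^H([0-9]+)([AB])([12])$", atoms$name))
  is_h <- lengths(hm) == 4L
  if (!any(is_h)) return(NULL)
  hi <- which(is_h)
  hinfo <- do.call(rbind, hm[is_h])
  cname <- paste0("C", hinfo[, 2], hinfo[, 3])
  ckey <- paste(atoms$resid[hi], cname)
  allkey <- paste(atoms$resid, atoms$name)
  ci <- match(ckey, allkey)
  ok <- !is.na(ci)
  data.frame(h = hi[ok], c = ci[ok], carbon = as.integer(hinfo[ok, 2]),
             resid = atoms$resid[hi[ok]])
}

#' Deuterium order parameters of the lipid tails
#'
#' For every tail carbon `i`, `S_CD(i) = <(3 cos^2 theta - 1)/2>` where
#' `theta` is the angle between each C-H bond and the local membrane normal
#' at the lipid's head-group position, averaged over hydrogens, molecules and
#' frames within the analysis sector. `S_CD = -0.5` for C-H perpendicular to
#' the normal (all-trans chain along the normal) and 0 for isotropic
#' orientations.
#'
#' @inheritParams density_profiles
#' @param species Phospholipid species to include (default: all present).
#' @param leaflets Leaflets to include.
#' @return data.frame with `species`, `leaflet`, `carbon`, `scd`, `sd`, `n`.
#' @export
order_parameters <- function(frames, surface, species = NULL,
                             leaflets = c("outer", "inner"), sector = NULL) {
  frames <- as_frame_list(frames)
  chunks <- list()
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    srf <- surface_for(surface, k)
    a <- f$atoms
    pairs <- chain_ch_pairs(a)
    if (is.null(pairs)) {
      abort("no chain C-H pairs found: explicit hydrogens are required",
            class = "memcurv_explicit_h_required")
    }
    rt <- residue_table(f)
    if (!is.null(species)) {
      unknown <- setdiff(species, c(PHOSPHOLIPID_SPECIES, CHOL_RESNAME))
      if (length(unknown)) {
        abort(paste0("unknown species: ", paste(unknown, collapse = ", ")),
              class = "memcurv_validation_error")
      }
    }
    keep <- rt$resname %in% (species %||% PHOSPHOLIPID_SPECIES) &
      rt$leaflet %in% leaflets & !is.na(rt$head)
    heads <- frame_xyz(f)[rt$head[keep], , drop = FALSE]
    if (!is.null(sector)) keep[keep] <- sector_mask(srf, heads, sector)
    rkeep <- rt$resid[keep]
    p <- pairs[pairs$resid %in% rkeep, , drop = FALSE]
    if (nrow(p) == 0L) next
    # normal at each molecule's head position (sign-symmetric in S_CD)
    ridx <- match(p$resid, rt$resid)
    nrm <- outer_normal(srf, frame_xyz(f)[rt$head[ridx], , drop = FALSE])
    ch <- frame_xyz(f)[p$h, , drop = FALSE] - frame_xyz(f)[p$c, , drop = FALSE]
    ch <- ch / sqrt(rowSums(ch^2))
    cosm <- rowSums(ch * nrm)
    chunks[[length(chunks) + 1L]] <- data.frame(
      species = rt$resname[ridx], leaflet = rt$leaflet[ridx],
      carbon = p$carbon, s = (3 * cosm^2 - 1) / 2, stringsAsFactors = FALSE)
  }
  if (length(chunks) == 0L) abort("no lipids selected",
                                  class = "memcurv_validation_error")
  s <- do.call(rbind, chunks)
  agg <- do.call(rbind, lapply(
    split(s, list(s$species, s$leaflet, s$carbon), drop = TRUE),
    function(g) data.frame(species = g$species[1], leaflet = g$leaflet[1],
                           carbon = g$carbon[1], scd = mean(g$s),
                           sd = stats::sd(g$s), n = nrow(g),
                           stringsAsFactors = FALSE)))
  agg <- agg[order(agg$species, agg$leaflet, agg$carbon), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("order_profile", "data.frame")
  agg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian-kernel smoothing of histogram counts (bandwidth in bins).
smooth_counts <- function(counts, bw) {
  n <- length(counts)
  if (n < 2L || bw <= 0) return(counts)
  idx <- seq_len(n)
  vapply(idx, function(i) {
    w <- stats::dnorm(idx - i, sd = bw)
    sum(w * counts) / sum(w)
  }, numeric(1))
}

normalized_hist <- function(x, breaks) {
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  bin <- bin[bin >= 1 & bin < length(breaks)]
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  mass <- if (sum(counts) > 0) counts / sum(counts) else counts
  data.frame(center = breaks[-length(breaks)] + diff(breaks) / 2,
             mass = mass, counts = counts)
}

hist_peak <- function(h, bw) {
  if (sum(h$counts) == 0L) return(NA_real_)
  h$center[which.max(smooth_counts(h$counts, bw))]
}

#' Cholesterol inclination, depth and minor-fraction statistics
#'
#' The cholesterol long axis is the vector from the tail-branching carbon to
#' the hydroxyl group; the inclination angle is measured against the local
#' outward normal of the molecule's leaflet. Depth is the distance of the
#' hydroxyl oxygen below that leaflet's head-group surface (the peak of the
#' head-group density, recomputed from the data unless supplied). Molecules
#' whose hydroxyl sits within `central_halfwidth` of the mid-surface form
#' the horizontally-lying interleaflet *minor* fraction, reported as a
#' percentage of all cholesterol.
#'
#' @inheritParams density_profiles
#' @param central_halfwidth Mid-surface band half-width (nm). Default 0.5.
#' @param branch_atom Name of the tail-branching carbon. Default `"C17"`.
#' @param head_surface_depth Optional `c(outer =, inner =)` override of the
#'   per-leaflet head-surface depth (nm); when `NULL` it is taken as the
#'   smoothed peak of the phosphorus depth distribution.
#' @param angle_bin,depth_bin Histogram bin widths (degrees, nm).
#' @param smooth_bw Gaussian smoothing bandwidth for peak finding, in bins.
#' @return A `chol_report` list: `angle_hist`, `depth_hist` (per leaflet),
#'   `peaks`, `minor_fraction` (percent), `counts`.
#' @export
cholesterol_metrics <- function(frames, surface, sector = NULL,
                                central_halfwidth = 0.5, branch_atom = "C17",
                                head_surface_depth = NULL, angle_bin = 2,
                                depth_bin = 0.025, smooth_bw = 2) {
  frames <- as_frame_list(frames)
  recs <- list()
  pdepth <- list()
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    srf <- surface_for(surface, k)
    a <- f$atoms
    xyz <- frame_xyz(f)
    chol <- which(a$resname == CHOL_RESNAME)
    if (length(chol) == 0L) next
    byres <- split(chol, a$resid[chol])
    o3 <- vapply(byres, function(i) i[a$name[i] == "O3"][1], integer(1))
    br <- vapply(byres, function(i) i[a$name[i] == branch_atom][1], integer(1))
    if (any(is.na(o3)) || any(is.na(br))) {
      abort(sprintf(
        "cholesterol residues lack O3 and/or %s atoms: check naming",
        branch_atom), class = "memcurv_naming_error")
    }
    opos <- xyz[o3, , drop = FALSE]
    insec <- sector_mask(srf, opos, sector)
    dep <- signed_depth(srf, opos)
    axis <- xyz[o3, , drop = FALSE] - xyz[br, , drop = FALSE]
    axis <- axis / sqrt(rowSums(axis^2))
    nout <- outer_normal(srf, opos)
    leaflet <- ifelse(abs(dep) <= central_halfwidth, "central",
                      ifelse(dep > 0, "outer", "inner"))
    nsign <- ifelse(leaflet == "inner", -1, 1)
    cosm <- pmin(1, pmax(-1, rowSums(axis * nout) * nsign))
    recs[[length(recs) + 1L]] <- data.frame(
      frame = k, leaflet = leaflet, depth_mid = dep,
      incl = rad2deg(acos(cosm)), in_sector = insec,
      stringsAsFactors = FALSE)
    # head-group surface from phosphorus depths
    pidx <- which(a$name == "P")
    if (length(pidx)) {
      pd <- signed_depth(srf, xyz[pidx, , drop = FALSE])
      psec <- sector_mask(srf, xyz[pidx, , drop = FALSE], sector)
      pdepth[[length(pdepth) + 1L]] <- pd[psec]
    }
  }
  if (length(recs) == 0L) abort("no cholesterol found",
                                class = "memcurv_naming_error")
  r <- do.call(rbind, recs)
  r <- r[r$in_sector, , drop = FALSE]
  # per-leaflet head-surface depth (positive magnitude)
  hs <- c(outer = NA_real_, inner = NA_real_)
  if (!is.null(head_surface_depth)) {
    hs[names(head_surface_depth)] <- head_surface_depth
  } else if (length(pdepth)) {
    pd <- unlist(pdepth)
    for (lf in c("outer", "inner")) {
      v <- if (lf == "outer") pd[pd > 0] else -pd[pd < 0]
      if (length(v) >= 3L) {
        h <- normalized_hist(v, seq(0, max(v) + depth_bin, by = depth_bin))
        hs[lf] <- hist_peak(h, smooth_bw)
      }
    }
  }
  r$depth_surface <- ifelse(r$leaflet %in% c("outer", "inner"),
                            hs[r$leaflet] - abs(r$depth_mid), NA_real_)
  abreaks <- seq(0, 180, by = angle_bin)
  angle_hist <- list()
  depth_hist <- list()
  peaks <- list()
  for (lf in c("outer", "inner", "central")) {
    g <- r[r$leaflet == lf, , drop = FALSE]
    if (nrow(g) == 0L) next
    ah <- normalized_hist(g$incl, abreaks)
    angle_hist[[lf]] <- ah
    pk_a <- hist_peak(ah, smooth_bw)
    pk_d <- NA_real_
    if (lf != "central" && any(is.finite(g$depth_surface))) {
      dv <- g$depth_surface[is.finite(g$depth_surface)]
      dbreaks <- seq(floor(min(dv) / depth_bin) * depth_bin,
                     max(dv) + depth_bin, by = depth_bin)
      dh <- normalized_hist(dv, dbreaks)
      depth_hist[[lf]] <- dh
      pk_d <- hist_peak(dh, smooth_bw)
    }
    peaks[[lf]] <- data.frame(leaflet = lf, angle_peak = pk_a,
                              depth_peak = pk_d, n = nrow(g),
                              stringsAsFactors = FALSE)
  }
  counts <- table(factor(r$leaflet, levels = c("outer", "inner", "central")))
  structure(list(
    angle_hist = angle_hist, depth_hist = depth_hist,
    peaks = do.call(rbind, peaks),
    minor_fraction = 100 * as.numeric(counts["central"]) / nrow(r),
    counts = counts, head_surface_depth = hs, records = r
  ), class = "chol_report")
}

#' @export
print.chol_report <- function(x, ...) {
  cat("cholesterol report\n")
  cat(sprintf("  molecules (frame-pooled): outer %d, inner %d, central %d\n",
              x$counts["outer"], x$counts["inner"], x$counts["central"]))
  cat(sprintf("  minor (interleaflet) fraction: %.2f%%\n", x$minor_fraction))
  if (!is.null(x$peaks)) {
    for (i in seq_len(nrow(x$peaks))) {
      cat(sprintf("  %s: inclination peak %.1f deg, depth peak %s nm\n",
                  x$peaks$leaflet[i], x$peaks$angle_peak[i],
                  ifelse(is.na(x$peaks$depth_peak[i]), "-",
                         sprintf("%.3f", x$peaks$depth_peak[i]))))
    }
  }
  invisible(x)
}
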