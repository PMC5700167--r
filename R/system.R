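#' Leaflet composition table
#'
#' Per-species molecule counts for the outer and inner monolayers. The
#' default reproduces the erythrocyte-like asymmetric plasma-membrane
#' composition used for the bicelle systems: sphingomyelin and PC enriched
#' outside, PE and PS inside, cholesterol split evenly.
#'
#' @param outer,inner Named integer vectors of per-species counts; names from
#'   `SM`, `PC`, `PE`, `PS`, `CHL`.
#' @return A `composition` data.frame with columns `species`, `outer`,
#'   `inner`.
#' @export
composition <- function(outer = c(SM = 42, PC = 46, PE = 14, PS = 0, CHL = 51),
                        inner = c(SM = 12, PC = 14, PE = 46, PS = 30, CHL = 51)) {
  species <- union(names(outer), names(inner))
  bad <- setdiff(species, c(PHOSPHOLIPID_SPECIES, CHOL_RESNAME))
  if (length(bad)) {
    abort(paste0("unknown species: ", paste(bad, collapse = ", ")),
          class = "memcurv_validation_error")
  }
  o <- ifelse(species %in% names(outer), outer[species], 0L)
  i <- ifelse(species %in% names(inner), inner[species], 0L)
  if (any(o < 0) || any(i < 0) || any(o != round(o)) || any(i != round(i))) {
    abort("composition counts must be non-negative integers",
          class = "memcurv_validation_error")
  }
  structure(data.frame(species = species, outer = as.integer(o),
                       inner = as.integer(i), stringsAsFactors = FALSE),
            class = c("composition", "data.frame"))
}

comp_counts <- function(comp, leaflet, what = c("phospholipid", "chol")) {
  what <- match.arg(what)
  keep <- if (what == "chol") comp$species == CHOL_RESNAME
          else comp$species != CHOL_RESNAME
  stats::setNames(comp[[leaflet]][keep], comp$species[keep])
}

#' Assemble an initial flat asymmetric bilayer from a composition table
#'
#' Phospholipids are arranged on an `nx x ny` grid in each monolayer, with
#' the species shuffled deterministically by the seed; cholesterol molecules
#' are intercalated at random positions between the grid sites. The result is
#' the planar starting structure that is subsequently caged by the walls and
#' bent (solvation, caps and equilibration belong to the simulation engine).
#'
#' @param comp A [composition()].
#' @param grid Grid dimensions `c(nx, ny)`; `nx * ny` must equal the
#'   phospholipid count of each leaflet. Default `c(17, 6)`.
#' @param spacing In-plane grid spacing (nm). Default 0.8.
#' @param head_depth Distance of the phosphorus plane from the bilayer
#'   mid-plane (nm). Default 2.0.
#' @param chol_head_depth Depth of the cholesterol hydroxyl oxygen (nm).
#' @param chol_mode Cholesterol placement; only `"intercalated_random"`.
#' @param seed Integer seed (mandatory: placement must be reproducible).
#' @return A [membrane_frame()] with leaflet tags assigned.
#' @export
build_bicelle <- function(comp, grid = c(17, 6), spacing = 0.8,
                          head_depth = 2.0, chol_head_depth = 1.4,
                          chol_mode = "intercalated_random", seed) {
  stopifnot(inherits(comp, "composition"))
  if (!identical(chol_mode, "intercalated_random")) {
    abort("unknown chol_mode", class = "memcurv_invalid_parameter")
  }
  if (missing(seed)) abort("a seed is required for reproducible placement",
                           class = "memcurv_invalid_parameter")
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  for (lf in c("outer", "inner")) {
    npl <- sum(comp_counts(comp, lf))
    if (npl != nx * ny) {
      abort(sprintf(
        "%s leaflet has %d phospholipids but the %d x %d grid holds %d sites",
        lf, npl, nx, ny, nx * ny), class = "memcurv_composition_error")
    }
  }
  with_seed(seed, {
    pieces <- list()
    resid <- 0L
    for (lf in c("outer", "inner")) {
      sgn <- if (lf == "outer") 1 else -1
      nvec <- c(0, 0, sgn)
      basis <- tangent_basis(nvec)
      counts <- comp_counts(comp, lf)
      species <- sample(rep(names(counts), counts))
      sites <- expand.grid(
        ix = seq_len(nx) - (nx + 1) / 2,
        iy = seq_len(ny) - (ny + 1) / 2, KEEP.OUT.ATTRS = FALSE)
      for (k in seq_along(species)) {
        tmpl <- lipid_template(species[k])
        origin <- c(sites$ix[k] * spacing, sites$iy[k] * spacing,
                    sgn * head_depth)
        resid <- resid + 1L
        pos <- place_template(tmpl, origin, nvec, basis$e1, basis$e2)
        pieces[[length(pieces) + 1L]] <- data.frame(
          name = tmpl$name, resname = species[k], resid = resid,
          x = pos[, 1], y = pos[, 2], z = pos[, 3],
          element = tmpl$element, leaflet = lf, stringsAsFactors = FALSE)
      }
      nchol <- sum(comp_counts(comp, lf, "chol"))
      if (nchol > 0) {
        tmpl <- lipid_template(CHOL_RESNAME)
        # intercalated: random offsets within the grid extent
        cx <- stats::runif(nchol, -nx / 2, nx / 2) * spacing
        cy <- stats::runif(nchol, -ny / 2, ny / 2) * spacing
        for (k in seq_len(nchol)) {
          origin <- c(cx[k], cy[k], sgn * chol_head_depth)
          resid <- resid + 1L
          pos <- place_template(tmpl, origin, nvec, basis$e1, basis$e2)
          pieces[[length(pieces) + 1L]] <- data.frame(
            name = tmpl$name, resname = CHOL_RESNAME, resid = resid,
            x = pos[, 1], y = pos[, 2], z = pos[, 3],
            element = tmpl$element, leaflet = lf, stringsAsFactors = FALSE)
        }
      }
    }
    atoms <- do.call(rbind, pieces)
    box <- c(nx * spacing + 4, ny * spacing, 2 * head_depth + 4)
    membrane_frame(atoms, box)
  })
}

#' Selective inter-monolayer repulsion parameters
#'
#' A weak artificial van der Waals repulsion acting only between lipids of
#' opposite leaflets. It penalizes lateral monolayer mixing in the bicelle
#' caps while leaving the bilayer region untouched: the distal tail carbons
#' (below the chain double bond) are excluded so tail ends from opposite
#' leaflets still interdigitate normally, and cholesterol is excluded
#' entirely so it can diffuse through the caps.
#'
#' @param sigma,epsilon LJ parameters; defaults 0.8 nm and 1e-7.
#' @param distal_min_index Chain carbons with index >= this are "distal" and
#'   excluded. Default 10 (the oleoyl 9-10 double bond boundary).
#' @return A `repulsion_spec` object.
#' @export
repulsion_spec <- function(sigma = 0.8, epsilon = 1e-7, distal_min_index = 10L) {
  if (sigma <= 0 || epsilon <= 0) abort("sigma and epsilon must be > 0",
                                        class = "memcurv_invalid_parameter")
  structure(list(sigma = sigma, epsilon = epsilon,
                 distal_min_index = as.integer(distal_min_index)),
            class = "repulsion_spec")
}

#' Atom sets carrying the selective inter-monolayer repulsion
#'
#' Selects, per leaflet, the heavy atoms of the phospholipids excluding the
#' distal tail carbons; hydrogens and cholesterol never participate. Returns
#' the two index sets plus a GROMACS-style energy-group description of the
#' inter-set-only nonbonded override.
#'
#' @param frame A leaflet-tagged [membrane_frame()].
#' @param spec A [repulsion_spec()].
#' @return List with `outer`, `inner` (integer atom indices), and `override`
#'   (sigma, epsilon, index-group and mdp fragment lines).
#' @export
selective_repulsion_atoms <- function(frame, spec = repulsion_spec()) {
  stopifnot(inherits(frame, "membrane_frame"), inherits(spec, "repulsion_spec"))
  a <- frame$atoms
  pl <- a$resname %in% PHOSPHOLIPID_SPECIES
  if (any(pl & is.na(a$leaflet))) {
    abort("phospholipid atoms without a leaflet tag; run assign_leaflets first",
          class = "memcurv_tagging_error")
  }
  ci <- tail_carbon_index(a$name)
  distal <- !is.na(ci) & ci >= spec$distal_min_index
  eligible <- pl & a$element != "H" & !distal
  outer <- which(eligible & a$leaflet == "outer")
  inner <- which(eligible & a$leaflet == "inner")
  ndx <- c("[ LIP_OUT ]",
           paste(strwrap(paste(outer, collapse = " "), width = 78),
                 collapse = "\n"),
           "[ LIP_IN ]",
           paste(strwrap(paste(inner, collapse = " "), width = 78),
                 collapse = "\n"))
  mdp <- c("; selective inter-monolayer repulsion (acts between groups only)",
           "energygrps        = LIP_OUT LIP_IN",
           sprintf("; pair override: sigma = %g nm, epsilon = %g", spec$sigma,
                   spec$epsilon),
           "; implement via energygrp-table or duplicated atom types with",
           "; [ nonbond_params ] entries between OUT_* and IN_* type copies")
  list(outer = outer, inner = inner,
       override = list(sigma = spec$sigma, epsilon = spec$epsilon,
                       ndx_lines = ndx, mdp_lines = mdp))
}

#' Assign leaflet tags from the fitted mid-surface
#'
#' Phospholipids are tagged by the sign of the signed depth of their
#' phosphorus atom; cholesterol by its hydroxyl oxygen, with molecules within
#' `chol_central_halfwidth` of the mid-surface tagged `"central"` (the
#' horizontally-lying interleaflet minor fraction).
#'
#' @param frame A [membrane_frame()].
#' @param surface A [make_surface()] / [fit_surface()] model.
#' @param chol_central_halfwidth Half-width of the central band (nm).
#' @return The frame with `leaflet` tags replaced.
#' @export
assign_leaflets <- function(frame, surface, chol_central_halfwidth = 0.5) {
  stopifnot(inherits(frame, "membrane_frame"))
  rt <- residue_table(frame)
  if (any(is.na(rt$head))) {
    bad <- rt$resname[is.na(rt$head)][1]
    abort(sprintf(
      "residue %s lacks its head reference atom (P / O3): check naming",
      bad), class = "memcurv_naming_error")
  }
  depth <- signed_depth(surface, frame_xyz(frame)[rt$head, , drop = FALSE])
  tag <- ifelse(depth >= 0, "outer", "inner")
  chol <- rt$resname == CHOL_RESNAME
  tag[chol & abs(depth) <= chol_central_halfwidth] <- "central"
  frame$atoms$leaflet <- tag[match(frame$atoms$resid, rt$resid)]
  frame
}
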