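# Minimal single-conformer pseudo-lipid templates. These carry exactly the
# atoms the builders and analyses touch: the phosphorus head reference, acyl
# chain carbons C2..C18 with explicit hydrogen pairs, and for cholesterol the
# hydroxyl oxygen and the tail-branching carbon defining its long axis.
# Local frame: head reference at the origin, +z toward the head-group side
# (mapped onto the local outer normal at placement time), chains along -z.

PHOSPHOLIPID_SPECIES <- c("SM", "PC", "PE", "PS")
CHOL_RESNAME <- "CHL"

#' Pseudo-lipid template coordinates
#'
#' @param species One of `"SM"`, `"PC"`, `"PE"`, `"PS"`, `"CHL"`.
#' @param n_carbons Number of chain carbons per acyl chain (C2..C(n+1)).
#' @return data.frame with `name`, `element` and local `dx`, `dy`, `dz` (nm).
#' @export
lipid_template <- function(species, n_carbons = 17) {
  if (species == CHOL_RESNAME) {
    return(data.frame(
      name = c("O3", "C17", "C20"),
      element = c("O", "C", "C"),
      dx = 0, dy = 0, dz = c(0, -0.90, -1.05),
      stringsAsFactors = FALSE
    ))
  }
  if (!species %in% PHOSPHOLIPID_SPECIES) {
    abort(sprintf("unknown lipid species: %s", species),
          class = "memcurv_validation_error")
  }
  rows <- list(data.frame(name = "P", element = "P", dx = 0, dy = 0, dz = 0,
                          stringsAsFactors = FALSE))
  for (ch in c("A", "B")) {
    xoff <- if (ch == "A") -0.15 else 0.15
    for (i in seq(2, n_carbons + 1)) {
      cz <- -(0.30 + 0.10 * (i - 2))
      rows[[length(rows) + 1L]] <- data.frame(
        name = c(sprintf("C%d%s", i, ch),
                 sprintf("H%d%s1", i, ch), sprintf("H%d%s2", i, ch)),
        element = c("C", "H", "H"),
        dx = c(xoff, xoff + 0.109, xoff - 0.109),
        dy = 0, dz = cz, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Place a template at `origin` with local +z along `nvec` and local x/y along
# the tangent basis (e1, e2).
place_template <- function(tmpl, origin, nvec, e1, e2) {
  pos <- outer(tmpl$dx, e1) + outer(tmpl$dy, e2) + outer(tmpl$dz, nvec)
  sweep(pos, 2, origin, `+`)
}

# Orthonormal tangent basis for a normal vector: e1 in the bending (XZ)
# plane, e2 along the cylinder axis where possible.
tangent_basis <- function(nvec) {
  yhat <- c(0, 1, 0)
  if (abs(sum(nvec * yhat)) > 0.99) {
    e1 <- c(1, 0, 0)
  } else {
    e1 <- normalize(cross3(yhat, nvec))
  }
  e2 <- cross3(nvec, e1)
  list(e1 = e1, e2 = e2)
}

# Tail-carbon index parsed from a chain-atom name ("C12A" -> 12), NA for
# non-chain atoms.
tail_carbon_index <- function(name) {
  m <- regmatches(name, regexec("^C([0-9]+)[AB]$", name))
  vapply(m, function(g) if (length(g) == 2L) as.integer(g[2]) else NA_integer_,
         integer(1))
}
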