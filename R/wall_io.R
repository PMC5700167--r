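# GROMACS-dialect writers for the wall geometry: a GRO coordinate file and an
# ITP topology fragment (atom types, nonbonded overrides, zero-length bonds,
# anchor restraints).

# Default atom types of the lipid acyl-tail carbons the shells repel.
# Configurable: force-field naming differs between lipid parameter sets.
DEFAULT_TAIL_ATOMTYPES <- c("CTL2", "CTL3", "CEL1")

wall_frame <- function(geom) {
  mk <- function(w, resid, resname) {
    n <- nrow(w$anchors)
    data.frame(
      name = c(rep("WA", n), rep("WS", n)),
      resname = resname,
      resid = resid,
      x = c(w$anchors[, 1], w$shells[, 1]),
      y = c(w$anchors[, 2], w$shells[, 2]),
      z = c(w$anchors[, 3], w$shells[, 3]),
      element = "X",
      stringsAsFactors = FALSE
    )
  }
  atoms <- rbind(mk(geom$outer, 1L, "WALO"), mk(geom$inner, 2L, "WALI"))
  span <- apply(atoms[, c("x", "y", "z")], 2, function(v) diff(range(v)))
  box <- pmax(span + 2, c(1, 1, 1))
  membrane_frame(atoms, box)
}

wall_itp_lines <- function(geom, spec, tail_atomtypes = DEFAULT_TAIL_ATOMTYPES) {
  n <- nrow(geom$outer$anchors)
  fmt_atom <- function(nr, type, name) {
    sprintf("%6d  %-6s  1  WAL  %-4s %6d  0.000  %s", nr, type, name, nr,
            if (type == "WANC") "0.000" else "1.000")
  }
  c(
    "; memcurv wall topology fragment (GROMACS dialect)",
    "; anchors (WANC): dummy particles fixed in absolute coordinates, no",
    ";   nonbonded interactions; shells (WSH): bonded to their anchor by a",
    ";   zero-length harmonic bond and repelling lipid tail carbons only.",
    "",
    "[ atomtypes ]",
    ";name  at.num     mass   charge  ptype   sigma  epsilon",
    "WANC        0    0.000    0.000      V   0.000    0.000",
    "WSH         0    1.000    0.000      A   0.000    0.000",
    "",
    "[ nonbond_params ]",
    "; shell-tail override: purely repulsive within the short-range cutoff",
    ";  i     j  func        sigma      epsilon",
    sprintf("WSH  %-5s    1  %11.6g  %11.6g", tail_atomtypes,
            spec$sigma, spec$epsilon),
    "",
    "[ moleculetype ]",
    "; one wall = one molecule: anchors 1..N, shells N+1..2N",
    "WALL    1",
    "",
    "[ atoms ]",
    fmt_atom(seq_len(n), "WANC", "WA"),
    fmt_atom(n + seq_len(n), "WSH", "WS"),
    "",
    "[ bonds ]",
    ";   i      j  func  length  k",
    sprintf("%6d %6d     1   0.000  %g", seq_len(n), n + seq_len(n),
            spec$k_bond),
    "",
    "; Anchor immobilization, two interchangeable options:",
    ";  (a) freeze group: add the WA atoms to freezegrps in the mdp, or",
    ";  (b) stiff position restraints, enabled with -DWALL_POSRES:",
    "#ifdef WALL_POSRES",
    "[ position_restraints ]",
    ";   i  func      kx      ky      kz",
    sprintf("%6d     1  100000  100000  100000", seq_len(n)),
    "#endif"
  )
}

#' Write wall coordinate and topology files
#'
#' Emits a GRO coordinate file (anchors first, then shells, per wall) and an
#' ITP topology fragment declaring the anchor and shell atom types, the
#' shell-tail nonbonded override at the spec's `(sigma, epsilon)`, the
#' zero-length anchor-shell bonds with the spec's force constant, and anchor
#' immobilization (freeze group or position restraints). Output is
#' deterministic for a fixed geometry.
#'
#' @param geom A [generate_walls()] geometry.
#' @param spec The matching [wall_spec()] (defaults to `geom$spec`).
#' @param prefix Output path prefix; writes `<prefix>_walls.gro` and
#'   `<prefix>_walls.itp`.
#' @param dialect Only `"gromacs"` is supported.
#' @param tail_atomtypes Atom type names of the tail carbons the shells
#'   interact with.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_wall_files <- function(geom, spec = geom$spec, prefix = "wall",
                             dialect = "gromacs",
                             tail_atomtypes = DEFAULT_TAIL_ATOMTYPES) {
  stopifnot(inherits(geom, "wall_geometry"))
  if (!identical(dialect, "gromacs")) {
    abort(sprintf("unknown topology dialect: %s", dialect),
          class = "memcurv_invalid_parameter")
  }
  if (nrow(geom$outer$anchors) == 0L) {
    abort("empty wall geometry", class = "memcurv_empty_wall")
  }
  gro <- paste0(prefix, "_walls.gro")
  itp <- paste0(prefix, "_walls.itp")
  write_gro(wall_frame(geom), gro, title = "memcurv restraining walls")
  writeLines(wall_itp_lines(geom, spec, tail_atomtypes), itp)
  invisible(c(gro = gro, itp = itp))
}
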