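#' Membrane configuration container
#'
#' A `membrane_frame` holds one configuration: an atom table with species and
#' leaflet annotations plus the box vectors. Positions are in nm throughout.
#'
#' @param atoms A data.frame with columns `name` (atom name), `resname`,
#'   `resid` (integer, unique per molecule), `x`, `y`, `z` (nm); optional
#'   `element` (inferred from the name when absent) and `leaflet`
#'   (`"outer"`, `"inner"`, `"central"` or `NA`).
#' @param box Box lengths `c(lx, ly, lz)` in nm (rectangular box).
#' @return A `membrane_frame` object.
#' @export
membrane_frame <- function(atoms, box) {
  req <- c("name", "resname", "resid", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z))) {
    abort("atom positions must be finite")
  }
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms$leaflet)) atoms$leaflet <- NA_character_
  atoms$leaflet <- as.character(atoms$leaflet)
  atoms$resid <- as.integer(atoms$resid)
  # every atom of a residue must share one leaflet tag
  spl <- split(atoms$leaflet, atoms$resid)
  bad <- vapply(spl, function(v) length(unique(v)) > 1L, logical(1))
  if (any(bad)) abort("residues with inconsistent leaflet tags found")
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    abort("box must be three positive lengths (nm)")
  }
  structure(list(atoms = atoms, box = as.numeric(box)),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  nres <- length(unique(x$atoms$resid))
  tab <- table(x$atoms$resname[!duplicated(x$atoms$resid)])
  cat(sprintf("membrane_frame: %d atoms, %d residues, box %.2f x %.2f x %.2f nm\n",
              nrow(x$atoms), nres, x$box[1], x$box[2], x$box[3]))
  cat("  residues:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

# positions as n x 3 matrix
frame_xyz <- function(frame) {
  as.matrix(frame$atoms[, c("x", "y", "z")])
}

# one row per residue: resname, leaflet, and the index of its head reference
# atom (P for phospholipids, hydroxyl O for cholesterol)
residue_table <- function(frame, head_atoms = c(CHL = "O3", default = "P")) {
  a <- frame$atoms
  idx <- split(seq_len(nrow(a)), a$resid)
  resid <- as.integer(names(idx))
  resname <- vapply(idx, function(i) a$resname[i[1L]], character(1))
  leaflet <- vapply(idx, function(i) a$leaflet[i[1L]], character(1))
  head_i <- vapply(seq_along(idx), function(k) {
    i <- idx[[k]]
    hn <- if (resname[k] %in% names(head_atoms)) head_atoms[[resname[k]]]
          else head_atoms[["default"]]
    j <- i[a$name[i] == hn]
    if (length(j) == 0L) NA_integer_ else j[1L]
  }, integer(1))
  data.frame(resid = resid, resname = resname, leaflet = leaflet,
             head = head_i, row.names = NULL, stringsAsFactors = FALSE)
}
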