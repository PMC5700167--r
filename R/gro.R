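# GROMACS GRO coordinate files (fixed-column, nm, 3 decimals). Multi-frame
# GRO files are valid GROMACS trajectories and are the package's text-based
# trajectory format.

format_gro_atoms <- function(atoms) {
  resid <- atoms$resid %% 100000L
  atnum <- (seq_len(nrow(atoms))) %% 100000L
  sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
          resid, substr(atoms$resname, 1, 5), substr(atoms$name, 1, 5),
          atnum, atoms$x, atoms$y, atoms$z)
}

#' Write a configuration (or trajectory) as a GRO file
#'
#' @param frame A [membrane_frame()] or a list of frames (written as a
#'   multi-frame GRO trajectory).
#' @param file Output path.
#' @param title Title line; frames in a trajectory get `t=` appended.
#' @return `file`, invisibly.
#' @export
write_gro <- function(frame, file, title = "memcurv configuration") {
  frames <- if (inherits(frame, "membrane_frame")) list(frame) else frame
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    stopifnot(inherits(f, "membrane_frame"))
    writeLines(sprintf("%s t= %.3f", title, k - 1), con)
    writeLines(sprintf("%5d", nrow(f$atoms)), con)
    writeLines(format_gro_atoms(f$atoms), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]), con)
  }
  invisible(file)
}

#' Read a GRO file
#'
#' Reads single- or multi-frame GRO files. Residue and atom names are
#' whitespace-trimmed; velocities, if present, are ignored.
#'
#' @param file Path to a GRO file.
#' @param multi If `TRUE`, always return a list of frames; otherwise a single
#'   frame is returned when the file holds exactly one.
#' @return A [membrane_frame()] or list thereof.
#' @export
read_gro <- function(file, multi = FALSE) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) abort(sprintf("malformed GRO atom count at line %d", i + 1L))
    body <- lines[(i + 2L):(i + 1L + natoms)]
    atoms <- data.frame(
      resid = as.integer(substr(body, 1, 5)),
      resname = trimws(substr(body, 6, 10)),
      name = trimws(substr(body, 11, 15)),
      x = as.numeric(substr(body, 21, 28)),
      y = as.numeric(substr(body, 29, 36)),
      z = as.numeric(substr(body, 37, 44)),
      stringsAsFactors = FALSE
    )
    boxline <- strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]]
    box <- as.numeric(boxline[1:3])
    frames[[length(frames) + 1L]] <- membrane_frame(atoms, box)
    i <- i + 3L + natoms
  }
  if (length(frames) == 1L && !multi) frames[[1L]] else frames
}

#' Write a configuration as a PDB file
#'
#' Thin wrapper over `bio3d::write.pdb` (coordinates converted nm to
#' Angstrom).
#'
#' @param frame A [membrane_frame()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdb_frame <- function(frame, file) {
  stopifnot(inherits(frame, "membrane_frame"))
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("the bio3d package is required for PDB output")
  }
  a <- frame$atoms
  xyz <- as.vector(t(frame_xyz(frame) * 10))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = a$resid %% 10000L, resid = substr(a$resname, 1, 4),
                   elety = substr(a$name, 1, 4), eleno = seq_len(nrow(a)),
                   chain = rep("A", nrow(a)))
  invisible(file)
}
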