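#' Default configuration
#'
#' All tunable defaults in one place: wall and selective-repulsion
#' parameters, analysis-sector extents, histogram bin widths and the
#' species atom-naming maps. Values the original membrane-bending protocol
#' states are reproduced exactly (wall sigma 0.85 nm, epsilon 1e-5, bond k
#' 10 kJ mol^-1 nm^-2, separation 5.0 nm, grid spacing 0.51 nm; repulsion
#' sigma 0.8 nm, epsilon 1e-7).
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    wall = list(sigma = 0.85, epsilon = 1e-5, k_bond = 10, separation = 5.0,
                spacing = 0.51, cutoff = 0.8, max_step_disp = 0.05,
                extent = c(10, 3.06)),
    repulsion = list(sigma = 0.8, epsilon = 1e-7, distal_min_index = 10),
    sector = list(mode = "arc", half_angle = 30, half_width_frac = 0.3),
    bins = list(angle = 2, depth = 0.025, density = 0.01),
    species = list(head_atoms = list(default = "P", CHL = "O3"),
                   chol_branch_atom = "C17",
                   tail_atomtypes = DEFAULT_TAIL_ATOMTYPES),
    chol_central_halfwidth = 0.5,
    seed = 1
  )
}

#' Write / read a configuration file (YAML)
#'
#' @param config A configuration list.
#' @param file Path.
#' @return `read_config`: the configuration list (defaults filled in for
#'   missing entries); `write_config`: `file`, invisibly.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_lists(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_lists(default_config(), cfg)
}

#' Read a leaflet composition table
#'
#' Plain whitespace- or tab-separated text with a header line
#' `species outer inner`.
#'
#' @param file Path.
#' @return A [composition()].
#' @export
read_composition <- function(file) {
  tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  need <- c("species", "outer", "inner")
  if (!all(need %in% names(tab))) {
    abort("composition file needs columns: species outer inner",
          class = "memcurv_validation_error")
  }
  composition(outer = stats::setNames(tab$outer, tab$species),
              inner = stats::setNames(tab$inner, tab$species))
}

#' Write a tidy TSV report
#'
#' @param df A data.frame.
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_tsv_report <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
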