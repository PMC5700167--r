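# Internal helpers shared across modules.

#' @keywords internal
abort <- function(msg, class = "memcurv_error", ...) {
  stop(structure(
    class = c(class, "memcurv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Coerce a point / set of points to an n x 3 numeric matrix.
as_points <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) abort("a 3D point must have exactly 3 coordinates")
    p <- matrix(as.numeric(p), nrow = 1L)
  }
  p <- as.matrix(p)
  if (ncol(p) != 3L) abort("points must be an n x 3 matrix")
  storage.mode(p) <- "double"
  if (any(!is.finite(p))) abort("point coordinates must be finite")
  p
}

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Run code with a private RNG state seeded from `seed`, restoring the caller's
# state afterwards so package functions never disturb the user's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("a single finite numeric seed is required")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Standard atomic masses (u) for the elements occurring in the pseudo-lipids.
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                 S = 32.06, X = 1.0)

element_mass <- function(element) {
  m <- ATOMIC_MASS[element]
  m[is.na(m)] <- 1.0
  unname(m)
}

# Infer the chemical element from an atom name (first alphabetic character).
guess_element <- function(name) {
  el <- toupper(substr(gsub("^[0-9]+", "", name), 1L, 1L))
  el[!el %in% names(ATOMIC_MASS)] <- "X"
  el
}
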