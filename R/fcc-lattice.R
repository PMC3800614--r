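# FCC lattice geometry: basis vectors, neighbourhood, and the relative
# (basis-vector string) encoding of chains. All arithmetic is exact integer
# arithmetic so self-avoidance checks are bit-exact.

#' The 12 FCC basis vectors
#'
#' Returns the 12 displacement vectors connecting an FCC lattice point to its
#' neighbours, in the frozen canonical order `v1..v12`. Every vector has two
#' `+-1` components and one zero component (squared length 2), and the set is
#' closed under negation. This order defines the scan order of every
#' "first successful move" search in the package.
#'
#' @return A 12 x 3 integer matrix with rownames `v1..v12` and colnames
#'   `x`, `y`, `z`.
#' @export
#' @examples
#' fcc_basis()
fcc_basis <- function() {
  b <- fcc_basis_cpp()
  dimnames(b) <- list(paste0("v", 1:12), c("x", "y", "z"))
  b
}

as_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (!is.matrix(coords) || ncol(coords) != 3)
    stop("coordinates must be an n x 3 matrix")
  storage.mode(coords) <- "integer"
  if (anyNA(coords)) stop("coordinates must be finite integers")
  coords
}

#' Neighbours of a lattice point
#'
#' @param p Integer vector of length 3.
#' @return A 12 x 3 integer matrix: `p + v` for each basis vector `v`, in the
#'   frozen order `v1..v12`.
#' @export
#' @examples
#' fcc_neighbors(c(0, 0, 0))
fcc_neighbors <- function(p) {
  p <- as.integer(p)
  if (length(p) != 3L || anyNA(p)) stop("p must be an integer 3-vector")
  b <- fcc_basis()
  b + matrix(p, nrow = 12L, ncol = 3L, byrow = TRUE)
}

#' Are two lattice points FCC neighbours?
#'
#' True iff `b - a` is one of the 12 basis vectors, i.e. iff the squared
#' Euclidean distance between the points is exactly 2.
#'
#' @param a,b Integer vectors of length 3.
#' @return Logical scalar.
#' @export
#' @examples
#' fcc_are_neighbors(c(0, 0, 0), c(1, 1, 0))  # TRUE
#' fcc_are_neighbors(c(0, 0, 0), c(2, 0, 0))  # FALSE
fcc_are_neighbors <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != 3L || length(b) != 3L) stop("points must be 3-vectors")
  sum((b - a)^2) == 2L
}

# step-difference -> basis index lookup (27 cells keyed by dx,dy,dz in -1..1),
# built lazily so no compiled code runs at source time
.lut_cache <- new.env(parent = emptyenv())
basis_lut <- function() {
  if (is.null(.lut_cache$lut)) {
    lut <- rep(NA_integer_, 27L)
    b <- fcc_basis_cpp()
    key <- (b[, 1] + 1L) + 3L * (b[, 2] + 1L) + 9L * (b[, 3] + 1L)
    lut[key + 1L] <- 1:12
    .lut_cache$lut <- lut
  }
  .lut_cache$lut
}

#' Encode a chain of lattice points as basis-vector indices
#'
#' The relative encoding of a chain of `n` points is the sequence of `n - 1`
#' basis-vector indices (1..12) of its steps. Encodings are
#' translation-invariant, and two conformations are considered duplicates iff
#' their encodings are identical (no quotienting by lattice symmetries).
#'
#' @param coords An n x 3 integer matrix of lattice points; consecutive rows
#'   must be lattice neighbours.
#' @return Integer vector of length `n - 1` with values in 1..12.
#' @export
#' @examples
#' fcc_encode(rbind(c(0, 0, 0), c(1, 1, 0)))  # 1 (= v1)
fcc_encode <- function(coords) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  if (n == 1L) return(integer(0))
  d <- diff(coords)
  if (any(d < -1L) || any(d > 1L))
    stop("consecutive points are not lattice neighbours")
  idx <- basis_lut()[(d[, 1] + 1L) + 3L * (d[, 2] + 1L) + 9L * (d[, 3] + 1L) + 1L]
  if (anyNA(idx)) stop("consecutive points are not lattice neighbours")
  idx
}

#' Decode a basis-vector index string into lattice coordinates
#'
#' The inverse of [fcc_encode()]: the first point is anchored at the origin
#' and each subsequent point adds the indexed basis vector. Self-avoidance is
#' deliberately NOT checked here (the caller validates), so revisiting walks
#' decode without error.
#'
#' @param enc Integer vector of basis-vector indices in 1..12 (may be empty).
#' @return An `(length(enc) + 1)` x 3 integer coordinate matrix.
#' @export
#' @examples
#' fcc_decode(c(1, 2))  # out and straight back: a revisit of the origin
fcc_decode <- function(enc) {
  enc <- as.integer(enc)
  if (anyNA(enc) || any(enc < 1L | enc > 12L))
    stop("basis-vector indices must be in 1..12")
  if (length(enc) == 0L)
    return(matrix(0L, nrow = 1L, ncol = 3L))
  b <- fcc_basis_cpp()
  steps <- b[enc, , drop = FALSE]
  out <- rbind(0L, apply(steps, 2L, cumsum))
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Serialise / parse a relative encoding as a comma-separated string
#'
#' @param enc Integer vector of basis indices.
#' @param s A string such as `"1,4,1"`.
#' @return `encoding_string()` a character scalar; `parse_encoding()` an
#'   integer vector.
#' @export
encoding_string <- function(enc) paste(as.integer(enc), collapse = ",")

#' @rdname encoding_string
#' @export
parse_encoding <- function(s) {
  if (!nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}
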