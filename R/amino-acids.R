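# Residue alphabet, hydrophobic/polar classification, and the two contact
# energy models (binary HP and the empirical Berrera 20x20 matrix, "BM").
# The residue order below is the row/column order of the published BM table
# and is frozen throughout the package.

AA_THREE <- c("Cys", "Met", "Phe", "Ile", "Leu", "Val", "Trp", "Tyr", "Ala",
              "Gly", "Thr", "Ser", "Gln", "Asn", "Glu", "Asp", "His", "Arg",
              "Lys", "Pro")
AA_ONE <- c("C", "M", "F", "I", "L", "V", "W", "Y", "A", "G",
            "T", "S", "Q", "N", "E", "D", "H", "R", "K", "P")

# hydrophobic class: Gly, Ala, Pro, Val, Leu, Ile, Met, Phe, Tyr, Trp
AA_HYDROPHOBIC <- c("G", "A", "P", "V", "L", "I", "M", "F", "Y", "W")

#' Hydrophobic/polar classification of the 20 amino acids
#'
#' The binary partition used by the HP model and by the hydrophobic-core
#' machinery: hydrophobic (H) residues are Gly, Ala, Pro, Val, Leu, Ile, Met,
#' Phe, Tyr and Trp; the remaining ten are polar (P). Note that under this
#' partition Cys is polar and both Gly and Pro are hydrophobic.
#'
#' @return A named character vector mapping each one-letter code to `"H"` or
#'   `"P"`.
#' @export
#' @examples
#' hp_classification()[c("F", "C")]
hp_classification <- function() {
  cls <- ifelse(AA_ONE %in% AA_HYDROPHOBIC, "H", "P")
  names(cls) <- AA_ONE
  cls
}

split_sequence <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) != 1L)
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1]]
  toupper(sequence)
}

#' Map residue letters to the frozen BM row/column indices
#'
#' @param sequence A single string of one-letter codes (or a character
#'   vector of single letters).
#' @return Integer vector of indices into the BM matrix order. Unknown
#'   letters are a hard error: the benchmark sequences contain only the 20
#'   standard residues, so no X/B tolerance is offered.
#' @export
aa_index <- function(sequence) {
  letters1 <- split_sequence(sequence)
  idx <- match(letters1, AA_ONE)
  if (anyNA(idx))
    stop("unknown residue letter(s): ",
         paste(unique(letters1[is.na(idx)]), collapse = ", "))
  idx
}

#' @rdname aa_index
#' @return `is_hydrophobic()`: logical vector, TRUE for H-class residues.
#' @export
is_hydrophobic <- function(sequence) {
  split_sequence(sequence) %in% AA_HYDROPHOBIC
}

# lower-triangle rows of the published 20x20 contact-potential table,
# in AA_THREE order (row i has i entries)
.bm_lower <- list(
  c(-3.477),
  c(-2.24, -1.901),
  c(-2.424, -2.304, -2.467),
  c(-2.41, -2.286, -2.53, -2.691),
  c(-2.343, -2.208, -2.491, -2.647, -2.501),
  c(-2.258, -2.079, -2.391, -2.568, -2.447, -2.385),
  c(-2.08, -2.09, -2.286, -2.303, -2.222, -2.097, -1.867),
  c(-1.892, -1.834, -1.963, -1.998, -1.919, -1.79, -1.834, -1.335),
  c(-1.7, -1.517, -1.75, -1.872, -1.728, -1.731, -1.565, -1.318, -1.119),
  c(-1.101, -0.897, -1.034, -0.885, -0.767, -0.756, -1.142, -0.818, -0.29,
    0.219),
  c(-1.243, -0.999, -1.237, -1.36, -1.202, -1.24, -1.077, -0.892, -0.717,
    -0.311, -0.617),
  c(-1.306, -0.893, -1.178, -1.037, -0.959, -0.933, -1.145, -0.859, -0.607,
    -0.261, -0.548, -0.519),
  c(-0.835, -0.72, -0.807, -0.778, -0.729, -0.642, -0.997, -0.687, -0.323,
    0.033, -0.342, -0.26, 0.054),
  c(-0.788, -0.658, -0.79, -0.669, -0.524, -0.673, -0.884, -0.67, -0.371,
    -0.23, -0.463, -0.423, -0.253, -0.367),
  c(-0.179, -0.209, -0.419, -0.439, -0.366, -0.335, -0.624, -0.453, -0.039,
    0.443, -0.192, -0.161, 0.179, 0.16, 0.933),
  c(-0.616, -0.409, -0.482, -0.402, -0.291, -0.298, -0.613, -0.631, -0.235,
    -0.097, -0.382, -0.521, 0.022, -0.344, 0.634, 0.179),
  c(-1.499, -1.252, -1.33, -1.234, -1.176, -1.118, -1.383, -1.222, -0.646,
    -0.325, -0.72, -0.639, -0.29, -0.455, -0.324, -0.664, -1.078),
  c(-0.771, -0.611, -0.805, -0.854, -0.758, -0.664, -0.912, -0.745, -0.327,
    -0.05, -0.247, -0.264, -0.042, -0.114, -0.374, -0.584, -0.307, 0.2),
  c(-0.112, -0.146, -0.27, -0.253, -0.222, -0.2, -0.391, -0.349, 0.196,
    0.589, 0.155, 0.223, 0.334, 0.271, -0.057, -0.176, 0.388, 0.815, 1.339),
  c(-1.196, -0.788, -1.076, -0.991, -0.771, -0.886, -1.278, -1.067, -0.374,
    -0.042, -0.222, -0.199, -0.035, -0.018, 0.257, 0.189, -0.346, -0.023,
    0.661, 0.129)
)

# transcription self-check, asserted when the matrix is first built
.BM_CHECKSUM <- -173.978

.model_cache <- new.env(parent = emptyenv())

#' The Berrera et al. 20x20 contact-potential matrix (BM model)
#'
#' Symmetric matrix of empirical residue-residue contact energies
#' (dimensionless energy units), embedded verbatim from the published table.
#' Rows and columns are ordered Cys, Met, Phe, Ile, Leu, Val, Trp, Tyr, Ala,
#' Gly, Thr, Ser, Gln, Asn, Glu, Asp, His, Arg, Lys, Pro and named by
#' one-letter code. A checksum over the 210 lower-triangle entries is
#' asserted at first use.
#'
#' @return A 20 x 20 symmetric numeric matrix.
#' @export
#' @examples
#' bm_matrix()["F", "F"]  # -2.467
bm_matrix <- function() {
  if (!is.null(.model_cache$bm)) return(.model_cache$bm)
  m <- matrix(0, 20L, 20L, dimnames = list(AA_ONE, AA_ONE))
  for (i in 1:20) m[i, 1:i] <- .bm_lower[[i]]
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  stopifnot(lengths(.bm_lower) == 1:20,
            isTRUE(all.equal(sum(m[lower.tri(m, diag = TRUE)]),
                             .BM_CHECKSUM, tolerance = 1e-9)))
  .model_cache$bm <- m
  m
}

#' The HP contact energy model as a 20x20 matrix
#'
#' Each non-consecutive contact between two hydrophobic residues contributes
#' -1; all other contacts contribute 0.
#'
#' @return A 20 x 20 numeric matrix in the same residue order as
#'   [bm_matrix()].
#' @export
hp_matrix <- function() {
  if (!is.null(.model_cache$hp)) return(.model_cache$hp)
  h <- AA_ONE %in% AA_HYDROPHOBIC
  m <- -outer(h, h) * 1.0
  dimnames(m) <- list(AA_ONE, AA_ONE)
  .model_cache$hp <- m
  m
}

#' Look up a contact energy model by name
#'
#' @param model `"bm"` for the 20x20 empirical matrix, `"hp"` for the binary
#'   hydrophobic-polar model, or a user-supplied symmetric 20x20 matrix in
#'   the frozen residue order.
#' @return A 20 x 20 numeric matrix.
#' @export
energy_matrix <- function(model = c("bm", "hp")) {
  if (is.matrix(model)) {
    if (!all(dim(model) == c(20L, 20L)) || !isSymmetric(unname(model)))
      stop("a custom energy model must be a symmetric 20 x 20 matrix")
    return(model)
  }
  switch(match.arg(model), bm = bm_matrix(), hp = hp_matrix())
}

#' Spell an H/P pattern as representative amino acids
#'
#' Convenience for toy hydrophobic-polar experiments: `"H"` becomes Leu (a
#' hydrophobic residue) and `"P"` becomes Lys (a polar one), so the pattern
#' can be fed through the standard 20-letter machinery.
#'
#' @param pattern A string over the letters H and P.
#' @return A string over the letters L and K.
#' @export
#' @examples
#' hp_sequence("HPHH")  # "LKLL"
hp_sequence <- function(pattern) {
  letters1 <- split_sequence(pattern)
  if (!all(letters1 %in% c("H", "P")))
    stop("pattern must use only the letters H and P")
  paste(ifelse(letters1 == "H", "L", "K"), collapse = "")
}
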