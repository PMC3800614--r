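# The conformation data model: an amino-acid sequence embedded as a
# self-avoiding walk on the FCC lattice, carrying both Cartesian coordinates
# and the relative (basis-vector) encoding.

new_conformation <- function(sequence, coords, encoding, aa, h) {
  structure(list(sequence = sequence, coords = coords, encoding = encoding,
                 aa = aa, h = h),
            class = "conformation")
}

#' Construct a lattice conformation
#'
#' A conformation couples a protein sequence with a chain of FCC lattice
#' points, one per residue. Exactly one of `coords` or `encoding` must be
#' given; the other representation is derived. Consecutive points must be
#' lattice neighbours (a gap is an error), but self-avoidance is not
#' enforced at construction time - use [validate_conformation()], which
#' returns `FALSE` for colliding chains rather than raising.
#'
#' @param sequence A string of one-letter amino-acid codes.
#' @param coords An n x 3 integer matrix of lattice points.
#' @param encoding An integer vector of n-1 basis-vector indices (1..12).
#' @return An object of class `"conformation"` with fields `sequence`,
#'   `coords`, `encoding`, `aa` (BM-order residue indices) and `h`
#'   (hydrophobic mask).
#' @export
#' @examples
#' conformation("FK", coords = rbind(c(0, 0, 0), c(1, 1, 0)))
conformation <- function(sequence, coords = NULL, encoding = NULL) {
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  sequence <- toupper(sequence)
  aa <- aa_index(sequence)
  n <- length(aa)
  if (n < 1L) stop("sequence must contain at least one residue")
  if (is.null(coords) == is.null(encoding))
    stop("give exactly one of 'coords' or 'encoding'")
  if (is.null(coords)) {
    encoding <- as.integer(encoding)
    coords <- fcc_decode(encoding)
  } else {
    coords <- as_coord_matrix(coords)
    encoding <- fcc_encode(coords)
  }
  if (nrow(coords) != n)
    stop("sequence length (", n, ") does not match chain length (",
         nrow(coords), ")")
  new_conformation(sequence, coords, encoding, aa, is_hydrophobic(sequence))
}

# internal fast path: replace the coordinates of a conformation whose
# sequence bookkeeping is already in place (used by move operators)
with_coords <- function(conf, coords) {
  storage.mode(coords) <- "integer"
  conf$coords <- coords
  conf$encoding <- fcc_encode(coords)
  conf
}

is_conformation <- function(x) inherits(x, "conformation")

#' Validate the self-avoiding-walk invariants of a conformation
#'
#' Checks that consecutive residues are lattice neighbours, that no lattice
#' point is visited twice, and that the stored encoding decodes to the
#' stored coordinates (up to the translation anchoring the first residue at
#' the origin). Returns `FALSE` on violation instead of raising.
#'
#' @param conf A [conformation()].
#' @return Logical scalar.
#' @export
validate_conformation <- function(conf) {
  if (!is_conformation(conf)) return(FALSE)
  n <- length(conf$aa)
  if (!is.matrix(conf$coords) || nrow(conf$coords) != n) return(FALSE)
  if (length(conf$encoding) != n - 1L) return(FALSE)
  if (!is_saw_cpp(conf$coords)) return(FALSE)
  anchored <- sweep(conf$coords, 2L, conf$coords[1L, ])
  identical(unname(fcc_decode(conf$encoding)), unname(anchored))
}

stop_if_invalid <- function(conf) {
  if (!validate_conformation(conf))
    stop("invalid conformation: not a self-avoiding walk on the FCC lattice")
  invisible(conf)
}

#' Non-consecutive lattice contacts of a conformation
#'
#' A contact is a residue pair (i, j) with j > i + 1 occupying neighbouring
#' lattice points. Enumeration probes the 12 neighbour points of every
#' residue through an occupancy index (equivalent to, and tested against,
#' the quadratic all-pairs scan).
#'
#' @param conf A valid [conformation()].
#' @return A data frame with integer columns `i`, `j` (1-based, i < j - 1)
#'   and a `class` column with values `"HH"`, `"HP"`, `"PP"`.
#' @export
contacts <- function(conf) {
  stop_if_invalid(conf)
  p <- contact_pairs_cpp(conf$coords)
  cls <- c("PP", "HP", "HH")[conf$h[p[, 1]] + conf$h[p[, 2]] + 1L]
  data.frame(i = p[, 1], j = p[, 2],
             class = if (nrow(p)) cls else character(0),
             stringsAsFactors = FALSE)
}

#' Contact energies of a conformation
#'
#' `energy_hp()` scores -1 per non-consecutive hydrophobic-hydrophobic
#' contact; `energy_bm()` sums the empirical 20x20 contact potentials over
#' all non-consecutive contacts; `conformation_energy()` dispatches on a
#' model name or custom matrix.
#'
#' @param conf A valid [conformation()].
#' @param model See [energy_matrix()].
#' @return Numeric scalar (dimensionless energy units).
#' @export
#' @examples
#' conf <- conformation("FSSF",
#'   coords = rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(1, -1, 0)))
#' energy_bm(conf)  # -2.467: a single Phe-Phe contact
#' energy_hp(conf)  # -1
conformation_energy <- function(conf, model = c("bm", "hp")) {
  stop_if_invalid(conf)
  contact_energy_cpp(conf$coords, conf$aa, energy_matrix(model))
}

#' @rdname conformation_energy
#' @export
energy_hp <- function(conf) conformation_energy(conf, "hp")

#' @rdname conformation_energy
#' @export
energy_bm <- function(conf) conformation_energy(conf, "bm")

#' Count contacts by hydrophobicity class
#'
#' @param conf A valid [conformation()].
#' @return Named integer vector `c(HH, HP, PP, total)`; the three classes
#'   partition the contact set.
#' @export
contact_class_counts <- function(conf) {
  cc <- contacts(conf)
  c(HH = sum(cc$class == "HH"), HP = sum(cc$class == "HP"),
    PP = sum(cc$class == "PP"), total = nrow(cc))
}

#' Hydrophobic core centre (HCC)
#'
#' The componentwise arithmetic mean of the coordinates of all hydrophobic
#' residues. This centroid is the attractor used by the macro-mutation
#' operator when squeezing hydrophobic residues together.
#'
#' @param conf A [conformation()] whose sequence contains at least one
#'   hydrophobic residue.
#' @return Numeric vector of length 3.
#' @export
hydrophobic_core_center <- function(conf) {
  if (!any(conf$h))
    stop("sequence has no hydrophobic residues: HCC is undefined")
  colMeans(conf$coords[conf$h, , drop = FALSE])
}

#' @export
print.conformation <- function(x, ...) {
  n <- length(x$aa)
  cat("FCC lattice conformation: ", n, " residues\n", sep = "")
  cat("  sequence: ", x$sequence, "\n", sep = "")
  cat("  encoding: ", encoding_string(x$encoding), "\n", sep = "")
  if (validate_conformation(x)) {
    cc <- contact_class_counts(x)
    cat(sprintf("  E_BM = %.2f, E_HP = %.0f, contacts HH/HP/PP = %d/%d/%d\n",
                energy_bm(x), energy_hp(x), cc["HH"], cc["HP"], cc["PP"]))
  } else {
    cat("  (not a valid self-avoiding walk)\n")
  }
  invisible(x)
}

#' Serialise a conformation to a one-record TSV or JSON file
#'
#' The record carries the sequence, the comma-separated relative encoding,
#' the coordinates, both energies and the contact-class counts.
#'
#' @param conf A valid [conformation()].
#' @param file Output path.
#' @param format `"tsv"` or `"json"` (JSON requires the jsonlite package).
#' @return `file`, invisibly.
#' @export
write_conformation <- function(conf, file, format = c("tsv", "json")) {
  stop_if_invalid(conf)
  format <- match.arg(format)
  cc <- contact_class_counts(conf)
  rec <- list(sequence = conf$sequence,
              encoding = encoding_string(conf$encoding),
              coords = paste(apply(conf$coords, 1L, paste, collapse = " "),
                             collapse = ";"),
              E_BM = energy_bm(conf), E_HP = energy_hp(conf),
              HH = unname(cc["HH"]), HP = unname(cc["HP"]),
              PP = unname(cc["PP"]), total = unname(cc["total"]))
  if (format == "tsv") {
    write.table(as.data.frame(rec), file = file, sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("JSON output requires the 'jsonlite' package")
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), file)
  }
  invisible(file)
}

#' Read the first record of a FASTA file as a plain sequence string
#'
#' @param file Path to a single-record amino-acid FASTA file.
#' @return Upper-case sequence string.
#' @export
read_fasta_sequence <- function(file) {
  recs <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE)
  if (length(recs) < 1L) stop("no sequence records in ", file)
  toupper(as.character(recs[[1]]))
}
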