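# Evaluation machinery: distance-matrix RMSD, lattice-to-Angstrom scaling,
# relative improvement percentages, rank-sum testing and progress-trace
# aggregation.

#' Pairwise C-alpha distance matrix of a lattice conformation, in Angstrom
#'
#' Euclidean distances between residue coordinates, scaled so that one
#' lattice bond maps to 3.8 A (the average C-alpha-C-alpha distance). A
#' lattice bond has Euclidean length sqrt(2) in lattice units - the squared
#' neighbour distance is 2 - so the scale factor is 3.8 / sqrt(2).
#'
#' @param conf A valid [conformation()].
#' @return A symmetric n x n numeric matrix with zero diagonal and
#'   `attr(, "source") = "predicted-lattice"`.
#' @export
lattice_distance_matrix <- function(conf) {
  stop_if_invalid(conf)
  m <- as.matrix(dist(conf$coords)) * (3.8 / sqrt(2))
  dimnames(m) <- NULL
  attr(m, "source") <- "predicted-lattice"
  m
}

#' Pairwise distance matrix of native C-alpha coordinates
#'
#' @param coords An n x 3 numeric matrix of coordinates already in Angstrom.
#' @return A symmetric distance matrix with `attr(, "source") = "native"`.
#' @export
native_distance_matrix <- function(coords) {
  m <- as.matrix(dist(coords))
  dimnames(m) <- NULL
  attr(m, "source") <- "native"
  m
}

#' Distance-matrix RMSD
#'
#' The root mean square deviation between two structures computed over all
#' residue pairs of their distance matrices:
#' `sqrt( sum_{i<j} (d_ij^p - d_ij^n)^2 / (n (n - 1) / 2) )`.
#' No superposition is involved, so the measure is invariant to rigid
#' motions of either structure.
#'
#' @param pred,native Same-sized square distance matrices (Angstrom).
#' @return RMSD in Angstrom.
#' @export
#' @examples
#' drmsd(matrix(c(0, 3.8, 3.8, 0), 2), matrix(c(0, 7.6, 7.6, 0), 2))  # 3.8
drmsd <- function(pred, native) {
  if (!is.matrix(pred) || !is.matrix(native) ||
      !all(dim(pred) == dim(native)) || nrow(pred) != ncol(pred))
    stop("pred and native must be square distance matrices of equal size")
  n <- nrow(pred)
  if (n < 2L) stop("need at least 2 residues")
  up <- upper.tri(pred)
  sqrt(sum((pred[up] - native[up])^2) / (n * (n - 1) / 2))
}

#' Relative improvement percentage
#'
#' `RI = (E_t - E_r) / E_r * 100`, the improvement of a target method over a
#' reference. For energies the signed formula is reported (improvements on
#' negative energies come out positive); for RMSD comparisons the published
#' convention is the absolute value, selected with `absolute = TRUE`.
#'
#' @param target,reference Numeric values (reference must be nonzero).
#' @param absolute Report `|RI|`.
#' @return Percentage.
#' @export
#' @examples
#' relative_improvement(-162.72, -156.32)  # 4.09
relative_improvement <- function(target, reference, absolute = FALSE) {
  if (any(reference == 0)) stop("reference value must be nonzero")
  ri <- (target - reference) / reference * 100
  if (absolute) abs(ri) else ri
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with normal approximation and tie
#' correction, as used to assess the significance of differences between
#' per-run energy (or RMSD) samples of two algorithms.
#'
#' @param a,b Numeric samples (nonempty).
#' @return List with `U` (number of pairs where `a` exceeds `b`, ties
#'   counted half) and the two-sided `p.value`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("samples must be nonempty")
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value)
}

#' Average best-so-far energy per time interval across runs
#'
#' Replicates the progress-curve bookkeeping: for each trace the best energy
#' reached by the end of each interval is read off, then averaged across
#' traces. Traces may be `ga_result` objects or their `trace` data frames
#' (columns `elapsed` and `best_energy`).
#'
#' @param traces A list of run traces.
#' @param interval Interval width in seconds.
#' @return A data frame with columns `time` and `mean_best`.
#' @export
progress_summary <- function(traces, interval) {
  if (length(traces) == 0L) stop("need at least one trace")
  stopifnot(interval > 0)
  dfs <- lapply(traces, function(tr) {
    if (inherits(tr, "ga_result")) tr <- tr$trace
    tr
  })
  t_max <- max(vapply(dfs, function(d) max(d$elapsed), numeric(1)))
  times <- seq(interval, by = interval,
               length.out = max(1L, ceiling(t_max / interval)))
  best_at <- function(d, t) {
    i <- which(d$elapsed <= t)
    # before the first recorded generation, the initial best stands
    if (length(i) == 0L) d$best_energy[1L] else d$best_energy[max(i)]
  }
  mean_best <- vapply(times, function(t)
    mean(vapply(dfs, best_at, numeric(1), t = t)), numeric(1))
  data.frame(time = times, mean_best = mean_best)
}

#' Extract the C-alpha trace of a PDB structure
#'
#' Reads ATOM records and returns the C-alpha coordinates of one chain, for
#' use as the native reference in [drmsd()] comparisons (residue
#' correspondence with a model is positional, 1:1 by index).
#'
#' @param file Path to a PDB file.
#' @param chain Optional chain identifier; default takes all chains.
#' @return An n x 3 numeric matrix of coordinates in Angstrom.
#' @export
read_native_ca <- function(file, chain = NULL) {
  pdb <- bio3d::read.pdb(file)
  sel <- if (is.null(chain)) bio3d::atom.select(pdb, "calpha")
         else bio3d::atom.select(pdb, "calpha", chain = chain)
  matrix(pdb$xyz[sel$xyz], ncol = 3L, byrow = TRUE)
}

#' Write a comparison table in the published column layout
#'
#' Formats per-protein comparison records (target and reference energies and
#' RMSDs with their relative improvements) as a TSV file.
#'
#' @param records A data frame with columns `id`, `E_t`, `E_r`, `rmsd_t`,
#'   `rmsd_r`.
#' @param file Output path.
#' @return The augmented data frame (with `ri_energy`, `ri_rmsd`),
#'   invisibly written to `file`.
#' @export
write_comparison_table <- function(records, file) {
  need <- c("id", "E_t", "E_r", "rmsd_t", "rmsd_r")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records$ri_energy <- relative_improvement(records$E_t, records$E_r)
  records$ri_rmsd <- relative_improvement(records$rmsd_t, records$rmsd_r,
                                          absolute = TRUE)
  write.table(records, file = file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(records)
}
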