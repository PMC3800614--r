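# Independent brute-force oracles and fuzzing helpers. These deliberately
# avoid the package's occupancy-index code paths: contacts come from a
# quadratic all-pairs scan and random walks from a stand-alone rejection
# grower, so agreement is a genuine cross-check.

# O(n^2) all-pairs contact scan
brute_contacts <- function(coords) {
  n <- nrow(coords)
  out <- matrix(integer(0), 0L, 2L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i + 1 && sum((coords[j, ] - coords[i, ])^2) == 2)
        out <- rbind(out, c(i, j))
    }
  }
  out
}

brute_energy <- function(coords, sequence, emat) {
  idx <- aa_index(sequence)
  p <- brute_contacts(coords)
  if (nrow(p) == 0L) return(0)
  sum(emat[cbind(idx[p[, 1]], idx[p[, 2]])])
}

brute_class_counts <- function(coords, sequence) {
  h <- is_hydrophobic(sequence)
  p <- brute_contacts(coords)
  if (nrow(p) == 0L) return(c(HH = 0L, HP = 0L, PP = 0L, total = 0L))
  k <- h[p[, 1]] + h[p[, 2]]
  c(HH = sum(k == 2L), HP = sum(k == 1L), PP = sum(k == 0L),
    total = nrow(p))
}

# random self-avoiding walk by rejection growth (restart on dead ends)
rand_saw <- function(n) {
  basis <- fcc_basis()
  repeat {
    coords <- matrix(0L, n, 3L)
    seen <- "0 0 0"
    ok <- TRUE
    for (k in seq_len(n - 1L)) {
      nb <- basis + matrix(coords[k, ], 12L, 3L, byrow = TRUE)
      keys <- paste(nb[, 1], nb[, 2], nb[, 3])
      free <- which(!(keys %in% seen))
      if (length(free) == 0L) { ok <- FALSE; break }
      pick <- free[sample.int(length(free), 1L)]
      coords[k + 1L, ] <- nb[pick, ]
      seen <- c(seen, keys[pick])
    }
    if (ok) return(coords)
  }
}

rand_conf <- function(n, mode = "aa") {
  conformation(random_sequence(n, mode), coords = rand_saw(n))
}

# a maximally extended zig-zag conformation (no non-consecutive contacts)
straight_conf <- function(sequence) {
  n <- nchar(sequence)
  conformation(sequence, encoding = rep(c(1L, 4L), length.out = n - 1L))
}

# the 4-residue ring used for single-contact constructions: residues 1 and 4
# are lattice neighbours, no other non-consecutive pair is
ring4_coords <- rbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(2L, 0L, 0L),
                      c(1L, -1L, 0L))
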