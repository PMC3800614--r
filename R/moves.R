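# Conformational move operators. Every operator either returns a new
# conformation that passes validate_conformation() or reports "infeasible"
# and leaves its input untouched; no operator ever alters the sequence.
# All "first successful" scans use the frozen basis order v1..v12 and
# traverse residues N-terminus to C-terminus.

move_result <- function(status, conformation = NULL, operator = NA_character_,
                        site = NA_integer_, detail = NULL) {
  structure(list(status = status, conformation = conformation,
                 operator = operator, site = site, detail = detail),
            class = "move_result")
}

#' Did a move succeed?
#'
#' @param x A move result as returned by the move operators.
#' @return Logical scalar.
#' @export
move_succeeded <- function(x) {
  inherits(x, "move_result") && identical(x$status, "success")
}

#' @export
print.move_result <- function(x, ...) {
  cat("move ", x$operator, " at site ", x$site, ": ", x$status, "\n", sep = "")
  invisible(x)
}

#' Candidate target points for a diagonal move
#'
#' The free lattice points adjacent to both chain neighbours of interior
#' residue `i`, in frozen basis order. On the FCC lattice two points one
#' bond apart share four neighbours, so a residue typically has up to four
#' diagonal destinations.
#'
#' @param conf A valid [conformation()].
#' @param i Interior residue index (2..n-1).
#' @return An m x 3 integer matrix (possibly zero rows).
#' @export
diagonal_candidates <- function(conf, i) {
  diagonal_candidates_cpp(conf$coords, as.integer(i))
}

#' Diagonal move
#'
#' Relocates interior residue `i` to a free lattice point adjacent to both
#' of its chain neighbours. Candidates are scanned in frozen basis order and
#' the first one accepted by `accept` is taken.
#'
#' @param conf A valid [conformation()].
#' @param i Interior residue index (2..n-1).
#' @param accept Optional predicate `function(point)` filtering candidate
#'   destinations; the default accepts any free candidate.
#' @return A move result: success with the new conformation, or infeasible.
#' @export
diagonal_move <- function(conf, i, accept = NULL) {
  stop_if_invalid(conf)
  i <- as.integer(i)
  cand <- diagonal_candidates(conf, i)
  for (r in seq_len(nrow(cand))) {
    p <- cand[r, ]
    if (!is.null(accept) && !isTRUE(accept(p))) next
    coords <- conf$coords
    coords[i, ] <- p
    return(move_result("success", with_coords(conf, coords),
                       "diagonal", i, detail = list(target = p)))
  }
  move_result("infeasible", operator = "diagonal", site = i)
}

#' Feasible pull-move targets for a residue
#'
#' Enumerates the free target points to which residue `i` can be pulled, in
#' frozen order, together with the drag direction: `dir = +1` keeps the bond
#' towards the successor and drags predecessors along vacated positions,
#' `dir = -1` is the mirror image. End residues additionally admit simple
#' relocations next to the penultimate residue.
#'
#' @param conf A valid [conformation()].
#' @param i Residue index (1..n).
#' @return An m x 4 integer matrix with columns `x`, `y`, `z`, `dir`.
#' @export
pull_targets <- function(conf, i) {
  m <- pull_targets_cpp(conf$coords, as.integer(i))
  colnames(m) <- c("x", "y", "z", "dir")
  m
}

#' Pull move
#'
#' Moves residue `i` to a free target point and drags the chain on one side
#' along the vacated positions until the walk is valid again. Pull moves are
#' local and reversible, and a feasible pull never produces an invalid
#' conformation: dragged residues reuse only positions just vacated by the
#' chain itself.
#'
#' @param conf A valid [conformation()].
#' @param i Residue index (1..n).
#' @param target Integer 3-vector, the destination of residue `i`.
#' @param direction `"auto"` (default; drag-predecessors preferred),
#'   `"nterm"` (drag residues on the N side) or `"cterm"`.
#' @return A move result; on success `detail` records the drag direction and
#'   the moved segment.
#' @export
#' @examples
#' conf <- conformation("LKL", encoding = c(1, 4))
#' tg <- pull_targets(conf, 3)
#' pull_move(conf, 3, tg[1, 1:3])
pull_move <- function(conf, i, target, direction = c("auto", "nterm", "cterm")) {
  stop_if_invalid(conf)
  dir <- switch(match.arg(direction), auto = 0L, nterm = 1L, cterm = -1L)
  res <- pull_move_cpp(conf$coords, as.integer(i), as.integer(target), dir)
  if (!isTRUE(res$feasible))
    return(move_result("infeasible", operator = "pull", site = as.integer(i)))
  out <- with_coords(conf, res$coords)
  stopifnot(validate_conformation(out))
  move_result("success", out, "pull", as.integer(i),
              detail = list(target = as.integer(target), dir = res$dir,
                            moved = c(res$from, res$to)))
}

#' The frozen rotation operation set
#'
#' The nine proper axis rotations (90, 180, 270 degrees about x, y and z).
#' Each is a signed permutation matrix mapping the FCC basis-vector set to
#' itself, so rotated chain segments stay on the lattice.
#'
#' @return A named list of nine integer 3x3 matrices.
#' @export
rotation_ops <- function() {
  r90 <- function(axis) {
    m <- switch(axis,
                x = rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0)),
                y = rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0)),
                z = rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)))
    storage.mode(m) <- "integer"
    m
  }
  out <- list()
  for (axis in c("x", "y", "z")) {
    m <- r90(axis)
    out[[paste0(axis, "90")]] <- m
    out[[paste0(axis, "180")]] <- m %*% m
    out[[paste0(axis, "270")]] <- m %*% m %*% m
  }
  out
}

# raw tail rotation; no validity check (hot path for exhaustive scans)
rotate_tail_coords <- function(coords, i, op) {
  n <- nrow(coords)
  pivot <- coords[i, ]
  tail_idx <- (i + 1L):n
  rel <- sweep(coords[tail_idx, , drop = FALSE], 2L, pivot)
  coords[tail_idx, ] <- sweep(rel %*% t(op), 2L, pivot, `+`)
  storage.mode(coords) <- "integer"
  coords
}

#' Rotation move
#'
#' Applies a lattice point-group rotation to the chain segment following the
#' pivot residue: residues `i+1..n` are mapped by `op` about the pivot's
#' coordinates. Succeeds iff the result is still a self-avoiding walk.
#'
#' @param conf A valid [conformation()].
#' @param i Interior pivot index (2..n-1).
#' @param op One of the matrices from [rotation_ops()], their name, or the
#'   identity matrix (which trivially succeeds).
#' @return A move result.
#' @export
rotation_move <- function(conf, i, op) {
  stop_if_invalid(conf)
  i <- as.integer(i)
  n <- nrow(conf$coords)
  if (i < 2L || i > n - 1L) stop("pivot must be an interior residue")
  if (is.character(op)) op <- rotation_ops()[[op]]
  if (is.null(op) || !is.matrix(op) || !all(dim(op) == c(3L, 3L)))
    stop("op must be a 3x3 rotation matrix or the name of one")
  storage.mode(op) <- "integer"
  coords <- rotate_tail_coords(conf$coords, i, op)
  if (!is_saw_cpp(coords))
    return(move_result("infeasible", operator = "rotation", site = i))
  move_result("success", with_coords(conf, coords), "rotation", i)
}

# maximal collinear run [a, b] containing the bond (i, i+1)
collinear_run <- function(coords, i) {
  n <- nrow(coords)
  d <- coords[i + 1L, ] - coords[i, ]
  a <- i
  while (a > 1L && all(coords[a, ] - coords[a - 1L, ] == d)) a <- a - 1L
  b <- i + 1L
  while (b < n && all(coords[b + 1L, ] - coords[b, ] == d)) b <- b + 1L
  list(a = a, b = b, d = d)
}

#' Tilt move
#'
#' Translates a maximal collinear run of residues to a parallel lattice line
#' one basis step away, then re-attaches both flanks by dragging residues
#' along the vacated positions (the same drag rule as pull moves). The run
#' is the maximal straight segment containing the bond `(i, i+1)`; offsets
#' are scanned in frozen basis order among the basis vectors orthogonal to
#' the run direction, and the first offset whose parallel line is entirely
#' free is taken.
#'
#' @param conf A valid [conformation()].
#' @param i Bond anchor index (1..n-1).
#' @return A move result; infeasible when every parallel line is blocked.
#' @name tilt_move
NULL

# raw tilt on a coordinate matrix; returns NULL when infeasible
tilt_coords <- function(coords, i) {
  n <- nrow(coords)
  run <- collinear_run(coords, i)
  a <- run$a; b <- run$b
  others <- setdiff(seq_len(n), a:b)
  occ <- paste(coords[others, 1L], coords[others, 2L], coords[others, 3L])
  basis <- fcc_basis_cpp()
  for (k in 1:12) {
    u <- basis[k, ]
    if (sum(u * run$d) != 0L) next
    shifted <- sweep(coords[a:b, , drop = FALSE], 2L, u, `+`)
    if (any(paste(shifted[, 1L], shifted[, 2L], shifted[, 3L]) %in% occ)) next
    new_coords <- coords
    new_coords[a:b, ] <- shifted
    # drag the N-side flank along vacated positions
    j <- a - 1L
    while (j >= 1L) {
      if (fcc_are_neighbors(coords[j, ], new_coords[j + 1L, ])) break
      new_coords[j, ] <- coords[j + 1L, ]
      j <- j - 1L
    }
    # drag the C-side flank
    j <- b + 1L
    while (j <= n) {
      if (fcc_are_neighbors(coords[j, ], new_coords[j - 1L, ])) break
      new_coords[j, ] <- coords[j - 1L, ]
      j <- j + 1L
    }
    if (!is_saw_cpp(new_coords)) next  # defensive; the drag rule preserves SAW
    storage.mode(new_coords) <- "integer"
    return(list(coords = new_coords, run = c(a, b), offset = u))
  }
  NULL
}

#' @rdname tilt_move
#' @export
tilt_move <- function(conf, i) {
  stop_if_invalid(conf)
  i <- as.integer(i)
  n <- nrow(conf$coords)
  if (i < 1L || i > n - 1L) stop("bond index must be in 1..n-1")
  res <- tilt_coords(conf$coords, i)
  if (is.null(res))
    return(move_result("infeasible", operator = "tilt", site = i))
  move_result("success", with_coords(conf, res$coords), "tilt", i,
              detail = list(run = res$run, offset = res$offset))
}

#' Single-point crossover of two conformations
#'
#' Both parents are split after residue `k`; each child takes the relative
#' encoding of one parent's head and the other parent's tail. Children are
#' decoded from the origin and validated independently - either may be
#' infeasible when the recombined walk self-intersects.
#'
#' @param a,b Valid [conformation()]s over the same sequence.
#' @param k Split index, 1..n-1 (`k = n-1` exchanges an empty tail and
#'   reproduces the parents).
#' @return A list of two move results, `child1` (head of `a`) and `child2`.
#' @export
crossover_single_point <- function(a, b, k) {
  stop_if_invalid(a); stop_if_invalid(b)
  if (!identical(a$sequence, b$sequence))
    stop("parents must share one sequence")
  n <- length(a$aa)
  k <- as.integer(k)
  if (k < 1L || k > n - 1L) stop("split index must be in 1..n-1")
  head_a <- a$encoding[seq_len(k)]
  head_b <- b$encoding[seq_len(k)]
  tail_a <- if (k < n - 1L) a$encoding[(k + 1L):(n - 1L)] else integer(0)
  tail_b <- if (k < n - 1L) b$encoding[(k + 1L):(n - 1L)] else integer(0)
  child_of <- function(enc) {
    coords <- fcc_decode(enc)
    if (!is_saw_cpp(coords))
      return(move_result("infeasible", operator = "crossover", site = k))
    move_result("success", conformation(a$sequence, encoding = enc),
                "crossover", k)
  }
  list(child1 = child_of(c(head_a, tail_b)),
       child2 = child_of(c(head_b, tail_a)))
}

# exact squared distance of lattice points to the hydrophobic core centre,
# scaled by nH^2 to stay in integer arithmetic: HCC = S / nH, so
# |p - HCC|^2 * nH^2 = |nH * p - S|^2
.hcc_sqdist <- function(p, S, nH) sum((nH * p - S)^2)

#' Hydrophobic-core-directed macro-mutation
#'
#' A composite operator applying a series of diagonal moves in one step. A
#' single Bernoulli draw per call selects the residue class to traverse:
#' with probability `p` the polar residues, otherwise the hydrophobic ones.
#' Residues of the chosen class are visited N- to C-terminus; a polar
#' residue takes its first feasible diagonal move, while a hydrophobic
#' residue takes the first feasible diagonal move that does not increase its
#' Cartesian distance from the hydrophobic core centre (HCC). The HCC is
#' recomputed after every accepted relocation, all accepted relocations are
#' applied as one composite move, and the whole traversal is repeated
#' `repeats` times. The result is always a valid conformation, possibly
#' identical to the input; repeated application squeezes the hydrophobic
#' residues into a core.
#'
#' In `mode = "bm"` the hydrophobicity knowledge is switched off: every
#' interior residue is visited and the first diagonal move that does not
#' increase the BM energy is taken (the ablation used to isolate the value
#' of the HP classification).
#'
#' @param conf A valid [conformation()].
#' @param p Probability of selecting the polar class for this call
#'   (default 0.2).
#' @param repeats Number of full traversal passes (default 3).
#' @param mode `"hp"` (hydrophobic-core directed) or `"bm"` (energy
#'   directed).
#' @param emat Energy matrix for `mode = "bm"`.
#' @return A move result, always a success; `detail$moves` counts accepted
#'   relocations.
#' @export
macro_mutation <- function(conf, p = 0.2, repeats = 3L,
                           mode = c("hp", "bm"), emat = bm_matrix()) {
  stop_if_invalid(conf)
  mode <- match.arg(mode)
  stopifnot(p >= 0, p <= 1, repeats >= 1L)
  n <- length(conf$aa)
  coords <- conf$coords
  moves <- 0L
  if (mode == "hp") {
    target_polar <- runif(1L) < p
    sites <- which(if (target_polar) !conf$h else conf$h)
    sites <- sites[sites > 1L & sites < n]
    nH <- sum(conf$h)
    S <- colSums(coords[conf$h, , drop = FALSE])
    for (pass in seq_len(repeats)) {
      for (i in sites) {
        cand <- diagonal_candidates_cpp(coords, i)
        if (nrow(cand) == 0L) next
        pick <- 0L
        if (target_polar) {
          pick <- 1L
        } else {
          d_old <- .hcc_sqdist(coords[i, ], S, nH)
          for (r in seq_len(nrow(cand))) {
            if (.hcc_sqdist(cand[r, ], S, nH) <= d_old) { pick <- r; break }
          }
        }
        if (pick > 0L) {
          if (conf$h[i]) S <- S - coords[i, ] + cand[pick, ]
          coords[i, ] <- cand[pick, ]
          moves <- moves + 1L
        }
      }
    }
  } else {
    sites <- seq_len(n)[-c(1L, n)]
    e_cur <- contact_energy_cpp(coords, conf$aa, emat)
    for (pass in seq_len(repeats)) {
      for (i in sites) {
        cand <- diagonal_candidates_cpp(coords, i)
        for (r in seq_len(nrow(cand))) {
          trial <- coords
          trial[i, ] <- cand[r, ]
          e_new <- contact_energy_cpp(trial, conf$aa, emat)
          if (e_new <= e_cur) {
            coords <- trial
            e_cur <- e_new
            moves <- moves + 1L
            break
          }
        }
      }
    }
  }
  out <- with_coords(conf, coords)
  stopifnot(validate_conformation(out))
  move_result("success", out, "macro", NA_integer_,
              detail = list(moves = moves, mode = mode))
}
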