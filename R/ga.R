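# The genetic-algorithm engine: duplicate-free populations, exhaustive
# operator application (a candidate replaces its parent only when strictly
# better, so the best energy never worsens), and pull-move random-walk
# stagnation recovery.

#' Search configuration for the genetic algorithm
#'
#' The four variants select how the two energy resolutions are mixed:
#' \describe{
#'   \item{BH}{BM energy for search and reporting; the macro-mutation is
#'     directed by the HP classification towards the hydrophobic core
#'     centre. This is the headline algorithm.}
#'   \item{BD}{BM energy everywhere; the macro-mutation applies repeated
#'     diagonal moves accepted by BM energy, with no hydrophobicity
#'     knowledge.}
#'   \item{BM}{BM energy, no macro-mutation operator at all (baseline).}
#'   \item{HP}{HP energy for search (macro-mutation still core-directed);
#'     results are reported in BM energy.}
#' }
#'
#' @param variant One of `"BH"`, `"BD"`, `"BM"`, `"HP"`.
#' @param pop_size Population size (default 100).
#' @param max_generations Generation budget.
#' @param time_limit Wall-clock budget in seconds (`Inf` to disable).
#' @param stagnation_window Generations without best-energy improvement
#'   before random-walk diversification (default 20).
#' @param energy_band Relative energy-change band accepted by the random
#'   walk, default `c(0.05, 0.10)`.
#' @param diversity_band Encoding-diversity band accepted by the random
#'   walk, default `c(0.10, 0.75)`.
#' @param p_polar Macro-mutation probability of traversing polar residues
#'   (default 0.2).
#' @param macro_repeats Macro-mutation traversal passes per call.
#' @param rw_pull_factor Random-walk pull budget as a multiple of chain
#'   length (default 50).
#' @param operators Operator roster; defaults to the uniform set
#'   crossover/rotation/diagonal/pull/tilt/macro (macro dropped for the BM
#'   variant).
#' @param init_max_tries Restart budget per member during initialisation.
#' @param seed RNG seed; identical (sequence, config, seed) triples give
#'   identical searches.
#' @return A list of class `"ga_config"`.
#' @export
ga_config <- function(variant = c("BH", "BD", "BM", "HP"),
                      pop_size = 100L,
                      max_generations = 100L,
                      time_limit = Inf,
                      stagnation_window = 20L,
                      energy_band = c(0.05, 0.10),
                      diversity_band = c(0.10, 0.75),
                      p_polar = 0.2,
                      macro_repeats = 3L,
                      rw_pull_factor = 50L,
                      operators = NULL,
                      init_max_tries = 1000L,
                      seed = 1L) {
  variant <- match.arg(variant)
  pop_size <- as.integer(pop_size)
  stopifnot(pop_size >= 2L,
            length(energy_band) == 2L, length(diversity_band) == 2L,
            energy_band[1] >= 0, energy_band[2] <= 1,
            energy_band[1] < energy_band[2],
            diversity_band[1] >= 0, diversity_band[2] <= 1,
            diversity_band[1] < diversity_band[2],
            p_polar >= 0, p_polar <= 1, macro_repeats >= 1L,
            stagnation_window >= 1L)
  if (is.null(operators)) {
    operators <- c("crossover", "rotation", "diagonal", "pull", "tilt",
                   "macro")
    if (variant == "BM") operators <- setdiff(operators, "macro")
  }
  structure(list(variant = variant, pop_size = pop_size,
                 max_generations = max_generations, time_limit = time_limit,
                 stagnation_window = as.integer(stagnation_window),
                 energy_band = energy_band, diversity_band = diversity_band,
                 p_polar = p_polar, macro_repeats = as.integer(macro_repeats),
                 rw_pull_factor = rw_pull_factor, operators = operators,
                 init_max_tries = as.integer(init_max_tries),
                 seed = as.integer(seed),
                 search_model = if (variant == "HP") "hp" else "bm",
                 macro_mode = if (variant == "BD") "bm" else "hp"),
            class = "ga_config")
}

pop_key <- function(conf) encoding_string(conf$encoding)

# deterministic fallback chain: an extended zig-zag with a kink after
# `kink` steps (kink 0 is the pure x-axis zig-zag); valid for every kink
fallback_walk <- function(n, kink = 0L) {
  steps <- integer(n - 1L)
  if (n > 1L) {
    kink <- max(0L, min(as.integer(kink), n - 1L))
    xzig <- rep(c(1L, 4L), length.out = n - 1L)         # v1, v4, v1, ...
    zzig <- rep(c(5L, 9L), length.out = n - 1L)         # v5, v9, v5, ...
    # kink 0 is the pure x-axis zig-zag; larger kinks bend an increasingly
    # long tail into the z-increasing zig-zag plane
    steps <- c(head_or_empty(xzig, n - 1L - kink),
               head_or_empty(zzig, kink))
  }
  steps
}

head_or_empty <- function(x, k) if (k > 0L) x[seq_len(k)] else integer(0)

# one attempt at growing a random SAW by uniform choice among free
# neighbour points; NULL on dead-end
grow_random_saw <- function(n, basis) {
  coords <- matrix(0L, n, 3L)
  occ <- new.env(hash = TRUE, parent = emptyenv())
  assign("0 0 0", TRUE, envir = occ)
  for (k in seq_len(n - 1L)) {
    nb <- basis + matrix(coords[k, ], 12L, 3L, byrow = TRUE)
    keys <- paste(nb[, 1L], nb[, 2L], nb[, 3L])
    free <- !vapply(keys, exists, logical(1L), envir = occ, USE.NAMES = FALSE)
    if (!any(free)) return(NULL)
    pick <- which(free)[sample.int(sum(free), 1L)]
    coords[k + 1L, ] <- nb[pick, ]
    assign(keys[pick], TRUE, envir = occ)
  }
  coords
}

#' Initialise a duplicate-free population of random conformations
#'
#' Members are grown as random self-avoiding walks: the first residue at the
#' origin, each successive residue at a uniformly chosen free neighbour
#' point, restarting on dead ends. If no valid (or non-duplicate) walk is
#' found within `max_tries` restarts, a deterministic extended zig-zag chain
#' is used instead; additional fallbacks get a kink at increasing positions
#' so the population stays duplicate-free.
#'
#' @param sequence Amino-acid sequence string.
#' @param size Number of members.
#' @param max_tries Restart budget per member.
#' @return A list of valid, pairwise distinct [conformation()]s.
#' @export
initialise_population <- function(sequence, size, max_tries = 1000L) {
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  n <- length(aa_index(sequence))
  basis <- fcc_basis_cpp()
  members <- list()
  keys <- character(0)
  fallback_next <- 0L
  for (m in seq_len(size)) {
    conf <- NULL
    tries <- 0L
    while (tries < max_tries) {
      tries <- tries + 1L
      coords <- grow_random_saw(n, basis)
      if (is.null(coords)) next
      cand <- conformation(sequence, coords = coords)
      if (pop_key(cand) %in% keys) next
      conf <- cand
      break
    }
    if (is.null(conf)) {
      # deterministic fallback, perturbed until distinct
      while (fallback_next <= n - 1L) {
        cand <- conformation(sequence,
                             encoding = fallback_walk(n, fallback_next))
        fallback_next <- fallback_next + 1L
        if (!(pop_key(cand) %in% keys)) { conf <- cand; break }
      }
    }
    if (is.null(conf)) break  # chain too short to host more distinct members
    members[[length(members) + 1L]] <- conf
    keys <- c(keys, pop_key(conf))
  }
  members
}

# energy of raw coordinates under a prepared matrix (hot path)
coord_energy <- function(coords, aa, emat) contact_energy_cpp(coords, aa, emat)

#' Exhaustive application of a mutation operator
#'
#' Scans the operator's application sites in frozen order (residues N to C,
#' candidate targets in basis order) and returns the first resulting
#' conformation with strictly lower search energy than the parent; if no
#' site improves, the parent survives unchanged. The returned energy is
#' therefore never above the parent's.
#'
#' @param conf A valid [conformation()].
#' @param operator `"diagonal"`, `"rotation"`, `"pull"`, `"tilt"` or
#'   `"macro"`.
#' @param config A [ga_config()] (supplies the energy model and
#'   macro-mutation parameters).
#' @return A conformation.
#' @export
exhaustive_mutation_step <- function(conf, operator, config = ga_config()) {
  emat <- energy_matrix(config$search_model)
  e0 <- coord_energy(conf$coords, conf$aa, emat)
  n <- length(conf$aa)
  better <- function(coords) coord_energy(coords, conf$aa, emat) < e0
  if (operator == "diagonal") {
    for (i in seq_len(n)[-c(1L, n)]) {
      cand <- diagonal_candidates_cpp(conf$coords, i)
      for (r in seq_len(nrow(cand))) {
        coords <- conf$coords
        coords[i, ] <- cand[r, ]
        if (better(coords)) return(with_coords(conf, coords))
      }
    }
  } else if (operator == "rotation") {
    ops <- rotation_ops()
    for (i in seq_len(n)[-c(1L, n)]) {
      for (op in ops) {
        coords <- rotate_tail_coords(conf$coords, i, op)
        if (is_saw_cpp(coords) && better(coords))
          return(with_coords(conf, coords))
      }
    }
  } else if (operator == "pull") {
    for (i in seq_len(n)) {
      tg <- pull_targets_cpp(conf$coords, i)
      for (r in seq_len(nrow(tg))) {
        res <- pull_move_cpp(conf$coords, i, tg[r, 1:3], tg[r, 4L])
        if (isTRUE(res$feasible) && better(res$coords))
          return(with_coords(conf, res$coords))
      }
    }
  } else if (operator == "tilt") {
    for (i in seq_len(n - 1L)) {
      res <- tilt_move(conf, i)
      if (move_succeeded(res) && better(res$conformation$coords))
        return(res$conformation)
    }
  } else if (operator == "macro") {
    res <- macro_mutation(conf, p = config$p_polar,
                          repeats = config$macro_repeats,
                          mode = config$macro_mode, emat = emat)
    if (better(res$conformation$coords)) return(res$conformation)
  } else {
    stop("unknown mutation operator: ", operator)
  }
  conf
}

#' Exhaustive single-point crossover of two parents
#'
#' Generates children at every split point, pools them with the parents and
#' returns the two lowest-energy pool members; ties are broken by order of
#' generation (parents first, then children by split point). The best
#' returned energy consequently never exceeds the better parent's.
#'
#' @param a,b Valid [conformation()]s over one sequence.
#' @param config A [ga_config()].
#' @return A list of two conformations.
#' @export
exhaustive_crossover_step <- function(a, b, config = ga_config()) {
  emat <- energy_matrix(config$search_model)
  n <- length(a$aa)
  pool <- list(a, b)
  for (k in seq_len(n - 1L)) {
    ch <- crossover_single_point(a, b, k)
    if (move_succeeded(ch$child1)) pool <- c(pool, list(ch$child1$conformation))
    if (move_succeeded(ch$child2)) pool <- c(pool, list(ch$child2$conformation))
  }
  e <- vapply(pool, function(cf) coord_energy(cf$coords, cf$aa, emat),
              numeric(1))
  pool[order(e)[1:2]]
}

add_member <- function(members, keys, conf) {
  k <- pop_key(conf)
  if (k %in% keys) return(list(members = members, keys = keys, added = FALSE))
  members[[length(members) + 1L]] <- conf
  list(members = members, keys = c(keys, k), added = TRUE)
}

#' Run one GA generation
#'
#' A single operator is drawn (uniformly from the roster) and used for the
#' whole generation. Mutation-type generations map every member through
#' [exhaustive_mutation_step()]; crossover generations repeatedly draw
#' random parent pairs and add both outputs of
#' [exhaustive_crossover_step()]. New members are added only if their
#' relative encoding is not already present (duplicate-free replacement);
#' when a mutated child collides with an existing member its parent is
#' re-added instead, and the incumbent best member always survives
#' crossover generations.
#'
#' @param pop A list of conformations (duplicate-free).
#' @param config A [ga_config()].
#' @return A list with the new `pop` and the `operator` used.
#' @export
ga_generation <- function(pop, config = ga_config()) {
  operator <- sample(config$operators, 1L)
  emat <- energy_matrix(config$search_model)
  members <- list()
  keys <- character(0)
  if (operator == "crossover") {
    energies <- vapply(pop, function(cf)
      coord_energy(cf$coords, cf$aa, emat), numeric(1))
    st <- add_member(members, keys, pop[[which.min(energies)]])
    members <- st$members; keys <- st$keys
    target <- length(pop)
    attempts <- 0L
    while (length(members) < target && attempts < 3L * target) {
      attempts <- attempts + 1L
      idx <- sample.int(length(pop), 2L, replace = TRUE)
      out <- exhaustive_crossover_step(pop[[idx[1]]], pop[[idx[2]]], config)
      for (cf in out) {
        st <- add_member(members, keys, cf)
        members <- st$members; keys <- st$keys
      }
    }
  } else {
    for (cf in pop) {
      child <- exhaustive_mutation_step(cf, operator, config)
      st <- add_member(members, keys, child)
      if (!st$added) st <- add_member(members, keys, cf)
      members <- st$members; keys <- st$keys
    }
  }
  list(pop = members, operator = operator)
}

#' Pull-move random walk for stagnation recovery
#'
#' Applies random feasible pull moves to break a premature hydrophobic core
#' while monitoring two quantities relative to the starting state: the
#' relative energy change `|dE / E0|` and the structural diversity `D`, the
#' fraction of differing relative-encoding positions. Among all visited
#' states whose energy change lies inside `energy_band` and whose diversity
#' lies inside `diversity_band`, the one with maximal diversity is returned
#' - a state close to the input in energy but as far from it as possible in
#' structure. The walk is bounded by `rw_pull_factor * n` pull moves; if no
#' visited state qualifies (in particular when the starting energy is 0, so
#' a relative band is undefined) the input is returned unchanged.
#'
#' @param conf A valid [conformation()].
#' @param config A [ga_config()].
#' @return A valid conformation.
#' @export
random_walk <- function(conf, config = ga_config()) {
  emat <- energy_matrix(config$search_model)
  e0 <- coord_energy(conf$coords, conf$aa, emat)
  if (e0 == 0) return(conf)
  n <- length(conf$aa)
  enc0 <- conf$encoding
  budget <- ceiling(config$rw_pull_factor * n)
  cur <- conf$coords
  best <- NULL
  best_d <- -1
  for (step in seq_len(budget)) {
    moved <- FALSE
    for (attempt in seq_len(n)) {
      i <- sample.int(n, 1L)
      tg <- pull_targets_cpp(cur, i)
      if (nrow(tg) == 0L) next
      r <- sample.int(nrow(tg), 1L)
      res <- pull_move_cpp(cur, i, tg[r, 1:3], tg[r, 4L])
      if (!isTRUE(res$feasible)) next
      cur <- res$coords
      moved <- TRUE
      break
    }
    if (!moved) break  # no feasible pull anywhere near the sampled sites
    e <- coord_energy(cur, conf$aa, emat)
    rel_e <- abs((e - e0) / e0)
    d <- mean(fcc_encode(cur) != enc0)
    if (rel_e >= config$energy_band[1] && rel_e <= config$energy_band[2] &&
        d >= config$diversity_band[1] && d <= config$diversity_band[2] &&
        d > best_d) {
      best <- cur
      best_d <- d
    }
  }
  if (is.null(best)) conf else with_coords(conf, best)
}

#' Run the genetic algorithm
#'
#' The main search loop: initialise a duplicate-free population, then apply
#' [ga_generation()] until the generation or wall-clock budget is exhausted.
#' When the best energy has not improved for `stagnation_window`
#' generations, every member is diversified by [random_walk()] (with
#' re-deduplication) before the search continues. The best conformation
#' found anywhere in the run is tracked separately and returned, so the
#' best-so-far energy series in the trace is non-increasing.
#'
#' @param sequence Amino-acid sequence string (or a FASTA file read through
#'   [read_fasta_sequence()]).
#' @param config A [ga_config()].
#' @return An object of class `"ga_result"`: list with `best` (conformation),
#'   `best_energy` (search-model energy), `energy_bm`, `energy_hp`,
#'   `contact_counts`, `trace` (one row per generation: generation, operator,
#'   best and mean energy, stagnation counter, random-walk flag, elapsed
#'   seconds), and `config`.
#' @export
#' @examples
#' cfg <- ga_config(variant = "BH", pop_size = 10, max_generations = 10,
#'                  seed = 42)
#' res <- ga_run(hp_sequence("HPHHPH"), cfg)
#' res$best_energy
ga_run <- function(sequence, config = ga_config()) {
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  set.seed(config$seed)
  t0 <- proc.time()[[3]]
  emat <- energy_matrix(config$search_model)
  pop <- initialise_population(sequence, config$pop_size,
                               config$init_max_tries)
  energies <- vapply(pop, function(cf)
    coord_energy(cf$coords, cf$aa, emat), numeric(1))
  best_i <- which.min(energies)
  best <- pop[[best_i]]
  best_e <- energies[best_i]
  stag <- 0L
  rows <- vector("list", 0L)
  gen <- 0L
  while (gen < config$max_generations &&
         (proc.time()[[3]] - t0) < config$time_limit) {
    gen <- gen + 1L
    step <- ga_generation(pop, config)
    pop <- step$pop
    energies <- vapply(pop, function(cf)
      coord_energy(cf$coords, cf$aa, emat), numeric(1))
    gen_best <- min(energies)
    if (gen_best < best_e) {
      best_e <- gen_best
      best <- pop[[which.min(energies)]]
      stag <- 0L
    } else {
      stag <- stag + 1L
    }
    rw <- FALSE
    if (stag >= config$stagnation_window) {
      walked <- lapply(pop, random_walk, config = config)
      members <- list(); keys <- character(0)
      for (cf in walked) {
        st <- add_member(members, keys, cf)
        members <- st$members; keys <- st$keys
      }
      pop <- members
      stag <- 0L
      rw <- TRUE
    }
    rows[[gen]] <- data.frame(
      generation = gen, operator = step$operator,
      best_energy = best_e, mean_energy = mean(energies),
      stagnation = stag, random_walk = rw,
      elapsed = proc.time()[[3]] - t0)
  }
  trace <- if (length(rows)) do.call(rbind, rows) else
    data.frame(generation = integer(0), operator = character(0),
               best_energy = numeric(0), mean_energy = numeric(0),
               stagnation = integer(0), random_walk = logical(0),
               elapsed = numeric(0))
  structure(list(best = best, best_energy = best_e,
                 energy_bm = energy_bm(best), energy_hp = energy_hp(best),
                 contact_counts = contact_class_counts(best),
                 trace = trace, config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA result (variant ", x$config$variant, ", ",
      nrow(x$trace), " generations)\n", sep = "")
  cat(sprintf("  best search energy: %.3f\n", x$best_energy))
  cat(sprintf("  E_BM = %.2f, E_HP = %.0f\n", x$energy_bm, x$energy_hp))
  cc <- x$contact_counts
  cat(sprintf("  contacts HH/HP/PP/total = %d/%d/%d/%d\n",
              cc["HH"], cc["HP"], cc["PP"], cc["total"]))
  invisible(x)
}
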