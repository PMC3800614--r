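test_that("initialisation yields valid, duplicate-free populations", {
  set.seed(181)
  pop <- initialise_population(random_sequence(20), size = 15)
  expect_length(pop, 15L)
  expect_true(all(vapply(pop, validate_conformation, logical(1))))
  keys <- vapply(pop, function(cf) encoding_string(cf$encoding), character(1))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("with no random tries the deterministic fallback family is used", {
  set.seed(191)
  pop <- initialise_population(random_sequence(12), size = 4, max_tries = 0)
  expect_true(all(vapply(pop, validate_conformation, logical(1))))
  # first fallback is the pure extended zig-zag, later ones get a kink
  expect_identical(pop[[1]]$encoding, rep(c(1L, 4L), length.out = 11L))
  keys <- vapply(pop, function(cf) encoding_string(cf$encoding), character(1))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("exhaustive mutation never worsens energy and matches a site-scan oracle", {
  cfg <- ga_config(variant = "BH", pop_size = 5, seed = 1)
  emat <- energy_matrix("bm")
  set.seed(201)
  for (trial in 1:10) {
    cf <- rand_conf(sample(6:18, 1))
    e0 <- energy_bm(cf)
    for (op in c("diagonal", "rotation", "pull", "tilt")) {
      out <- exhaustive_mutation_step(cf, op, cfg)
      expect_lte(energy_bm(out), e0)
      expect_true(validate_conformation(out))
    }
    # independent first-improvement oracle for the diagonal operator
    out <- exhaustive_mutation_step(cf, "diagonal", cfg)
    want <- cf
    found <- FALSE
    for (i in 2:(nrow(cf$coords) - 1L)) {
      if (found) break
      cand <- diagonal_candidates(cf, i)
      for (r in seq_len(nrow(cand))) {
        coords <- cf$coords
        coords[i, ] <- cand[r, ]
        trial_conf <- conformation(cf$sequence, coords = coords)
        if (energy_bm(trial_conf) < e0) {
          want <- trial_conf
          found <- TRUE
          break
        }
      }
    }
    expect_identical(out$encoding, want$encoding)
  }
})

test_that("a parent at a local optimum survives exhaustive mutation unchanged", {
  gm <- global_minimum(hp_sequence("HHHHHH"), "hp")
  cfg <- ga_config(variant = "HP", pop_size = 5, seed = 1)
  set.seed(211)
  for (op in c("diagonal", "rotation", "pull", "tilt", "macro")) {
    out <- exhaustive_mutation_step(gm$conformation, op, cfg)
    expect_identical(out$encoding, gm$conformation$encoding)
  }
})

test_that("exhaustive crossover returns the two best of parents plus children", {
  cfg <- ga_config(variant = "BH", pop_size = 5, seed = 1)
  set.seed(221)
  s <- random_sequence(9)
  a <- conformation(s, coords = rand_saw(9))
  out <- exhaustive_crossover_step(a, a, cfg)
  expect_identical(out[[1]]$encoding, a$encoding)
  expect_identical(out[[2]]$encoding, a$encoding)
  for (trial in 1:10) {
    a <- conformation(s, coords = rand_saw(9))
    b <- conformation(s, coords = rand_saw(9))
    out <- exhaustive_crossover_step(a, b, cfg)
    e_out <- vapply(out, energy_bm, numeric(1))
    expect_lte(min(e_out), min(energy_bm(a), energy_bm(b)))
    # brute-force pool check
    pool <- list(a, b)
    for (k in 1:8) {
      ch <- crossover_single_point(a, b, k)
      for (child in ch)
        if (move_succeeded(child)) pool <- c(pool, list(child$conformation))
    }
    e_pool <- sort(vapply(pool, energy_bm, numeric(1)))
    expect_equal(sort(e_out), e_pool[1:2])
  }
})

test_that("a single-member mutation generation reduces to the exhaustive step", {
  cfg <- ga_config(variant = "BH", pop_size = 2, seed = 3,
                   operators = "diagonal")
  set.seed(231)
  cf <- rand_conf(12)
  set.seed(7)
  gen <- ga_generation(list(cf), cfg)
  expect_identical(gen$operator, "diagonal")
  direct <- exhaustive_mutation_step(cf, "diagonal", cfg)
  expect_length(gen$pop, 1L)
  expect_identical(gen$pop[[1]]$encoding, direct$encoding)
})

test_that("generations keep populations duplicate-free and never lose the best", {
  cfg <- ga_config(variant = "BH", pop_size = 10, seed = 5)
  set.seed(241)
  pop <- initialise_population(random_sequence(14), 10)
  best <- min(vapply(pop, energy_bm, numeric(1)))
  set.seed(6)
  for (g in 1:12) {
    gen <- ga_generation(pop, cfg)
    pop <- gen$pop
    keys <- vapply(pop, function(cf) encoding_string(cf$encoding),
                   character(1))
    expect_identical(anyDuplicated(keys), 0L)
    expect_true(all(vapply(pop, validate_conformation, logical(1))))
    new_best <- min(vapply(pop, energy_bm, numeric(1)))
    expect_lte(new_best, best)
    best <- new_best
  }
})

test_that("the random walk returns the input or an in-band diversified state", {
  cfg <- ga_config(variant = "BH", pop_size = 5, seed = 1)
  # zero starting energy: the relative band is undefined, input returned
  set.seed(251)
  flat <- straight_conf("KAKA")
  expect_identical(random_walk(flat, cfg)$encoding, flat$encoding)
  for (trial in 1:8) {
    cf <- rand_conf(sample(12:20, 1))
    e0 <- energy_bm(cf)
    if (e0 == 0) next
    out <- random_walk(cf, cfg)
    expect_true(validate_conformation(out))
    if (!identical(out$encoding, cf$encoding)) {
      rel_e <- abs((energy_bm(out) - e0) / e0)
      d <- mean(out$encoding != cf$encoding)
      expect_gte(rel_e, cfg$energy_band[1])
      expect_lte(rel_e, cfg$energy_band[2])
      expect_gte(d, cfg$diversity_band[1])
      expect_lte(d, cfg$diversity_band[2])
    }
  }
})

test_that("the GA finds the toy HP optimum and records a monotone trace", {
  seqs <- hp_sequence("HPHH")
  oracle <- global_minimum(seqs, "hp")
  cfg <- ga_config(variant = "HP", pop_size = 8, max_generations = 15,
                   seed = 9)
  res <- ga_run(seqs, cfg)
  expect_equal(res$best_energy, oracle$min_energy)
  expect_true(all(diff(res$trace$best_energy) <= 0))
  expect_true(validate_conformation(res$best))
})

test_that("identical seed and config reproduce the search exactly", {
  cfg <- ga_config(variant = "BH", pop_size = 6, max_generations = 8,
                   seed = 123)
  s <- load_benchmarks()$sequence[1]
  r1 <- ga_run(s, cfg)
  r2 <- ga_run(s, cfg)
  drop_elapsed <- function(tr) tr[setdiff(names(tr), "elapsed")]
  expect_identical(drop_elapsed(r1$trace), drop_elapsed(r2$trace))
  expect_identical(r1$best$encoding, r2$best$encoding)
})
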