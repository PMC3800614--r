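test_that("diagonal candidates are the free common neighbours, in frozen order", {
  # A=(0,0,0), B=(1,1,0), C=(2,0,0): common neighbours of A and C are
  # (1,1,0), (1,-1,0), (1,0,1), (1,0,-1); B's own point is occupied
  conf <- conformation("KKK",
                       coords = rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)))
  cand <- diagonal_candidates(conf, 2)
  expect_identical(unname(cand),
                   rbind(c(1L, -1L, 0L), c(1L, 0L, 1L), c(1L, 0L, -1L)))
  res <- diagonal_move(conf, 2)
  expect_true(move_succeeded(res))
  expect_identical(res$conformation$coords[2, ], c(1L, -1L, 0L))
  # brute-force oracle: scan all lattice points near the chain
  set.seed(81)
  for (trial in 1:15) {
    cf <- rand_conf(sample(4:20, 1))
    i <- sample(2:(nrow(cf$coords) - 1L), 1)
    got <- diagonal_candidates(cf, i)
    occ <- apply(cf$coords, 1, paste, collapse = ",")
    want <- NULL
    for (r in 1:12) {
      p <- fcc_neighbors(cf$coords[i - 1L, ])[r, ]
      if (fcc_are_neighbors(p, cf$coords[i + 1L, ]) &&
          !(paste(p, collapse = ",") %in% occ))
        want <- rbind(want, p)
    }
    if (is.null(want)) want <- matrix(integer(0), 0, 3)
    expect_identical(unname(got), unname(want))
  }
})

test_that("diagonal moves keep the chain connected and self-avoiding", {
  set.seed(91)
  for (trial in 1:40) {
    cf <- rand_conf(sample(4:30, 1))
    n <- nrow(cf$coords)
    i <- sample(2:(n - 1L), 1)
    res <- diagonal_move(cf, i)
    if (move_succeeded(res)) {
      out <- res$conformation
      expect_true(validate_conformation(out))
      # structural connectivity, not just via validate()
      expect_true(fcc_are_neighbors(out$coords[i - 1L, ], out$coords[i, ]))
      expect_true(fcc_are_neighbors(out$coords[i, ], out$coords[i + 1L, ]))
      expect_identical(out$sequence, cf$sequence)
    } else {
      expect_identical(nrow(diagonal_candidates(cf, i)), 0L)
    }
  }
})

test_that("pulling a terminal residue to a neighbour of the penultimate one moves only it", {
  set.seed(101)
  for (trial in 1:10) {
    cf <- rand_conf(sample(4:15, 1))
    n <- nrow(cf$coords)
    tg <- pull_targets(cf, n)
    simple <- tg[tg[, "dir"] == -1L, , drop = FALSE]
    if (nrow(simple) == 0L) next
    res <- pull_move(cf, n, simple[1, 1:3], direction = "cterm")
    expect_true(move_succeeded(res))
    expect_identical(res$conformation$coords[-n, ], cf$coords[-n, ])
    expect_identical(res$conformation$coords[n, ],
                     unname(simple[1, 1:3]))
  }
})

test_that("every successful pull move has an inverse pull", {
  set.seed(111)
  for (trial in 1:10) {
    cf <- rand_conf(6)
    n <- 6L
    for (i in seq_len(n)) {
      tg <- pull_targets(cf, i)
      for (r in seq_len(nrow(tg))) {
        dirs <- if (tg[r, "dir"] == 1L) "nterm" else "cterm"
        res <- pull_move(cf, i, tg[r, 1:3], direction = dirs)
        if (!move_succeeded(res)) next
        expect_true(validate_conformation(res$conformation))
        # search the inverse move space for a pull restoring cf
        restored <- FALSE
        for (j in seq_len(n)) {
          tg2 <- pull_targets(res$conformation, j)
          for (r2 in seq_len(nrow(tg2))) {
            d2 <- if (tg2[r2, "dir"] == 1L) "nterm" else "cterm"
            back <- pull_move(res$conformation, j, tg2[r2, 1:3],
                              direction = d2)
            if (move_succeeded(back) &&
                identical(back$conformation$coords, cf$coords)) {
              restored <- TRUE
              break
            }
          }
          if (restored) break
        }
        expect_true(restored)
      }
    }
  }
})

test_that("tilt moves translate straight runs and re-attach the flanks", {
  # fully straight chain along repeated v1: tilting any interior bond kinks it
  straight <- conformation("KKKKKK", encoding = rep(1L, 5))
  res <- tilt_move(straight, 3)
  expect_true(move_succeeded(res))
  expect_true(validate_conformation(res$conformation))
  expect_false(identical(res$conformation$coords, straight$coords))
  set.seed(121)
  for (trial in 1:30) {
    cf <- rand_conf(sample(4:25, 1))
    i <- sample(nrow(cf$coords) - 1L, 1)
    res <- tilt_move(cf, i)
    if (move_succeeded(res)) {
      expect_true(validate_conformation(res$conformation))
      expect_identical(res$conformation$sequence, cf$sequence)
    }
  }
})

test_that("rotation moves succeed exactly when the rotated tail is clash-free", {
  ops <- rotation_ops()
  expect_length(ops, 9L)
  # every op maps the basis set onto itself
  b <- fcc_basis()
  keys <- apply(b, 1, paste, collapse = ",")
  for (op in ops) {
    mapped <- b %*% t(op)
    expect_true(all(apply(mapped, 1, paste, collapse = ",") %in% keys))
  }
  cf <- straight_conf("KKKKKK")
  ident <- diag(3L)
  res <- rotation_move(cf, 3, ident)
  expect_true(move_succeeded(res))
  expect_identical(res$conformation$coords, cf$coords)
  # a truly collinear chain folded back on itself by 180 degrees clashes
  collinear <- conformation("KKKKK", encoding = rep(1L, 4))
  res180 <- rotation_move(collinear, 3, "z180")
  expect_identical(res180$status, "infeasible")
  set.seed(131)
  for (trial in 1:30) {
    cf <- rand_conf(sample(4:25, 1))
    i <- sample(2:(nrow(cf$coords) - 1L), 1)
    op <- sample(names(ops), 1)
    res <- rotation_move(cf, i, op)
    if (move_succeeded(res))
      expect_true(validate_conformation(res$conformation))
  }
})

test_that("single-point crossover recombines encodings and validates children", {
  set.seed(141)
  s <- random_sequence(10)
  a <- conformation(s, coords = rand_saw(10))
  b <- conformation(s, coords = rand_saw(10))
  n <- 10L
  # k = n - 1 exchanges an empty tail: children equal the parents
  ch <- crossover_single_point(a, b, n - 1L)
  expect_identical(ch$child1$conformation$encoding, a$encoding)
  expect_identical(ch$child2$conformation$encoding, b$encoding)
  # identical parents reproduce the parent at every split point
  for (k in seq_len(n - 1L)) {
    ch <- crossover_single_point(a, a, k)
    expect_identical(ch$child1$conformation$encoding, a$encoding)
  }
  for (trial in 1:10) {
    a <- conformation(s, coords = rand_saw(10))
    b <- conformation(s, coords = rand_saw(10))
    for (k in seq_len(n - 1L)) {
      ch <- crossover_single_point(a, b, k)
      for (child in ch) {
        if (move_succeeded(child)) {
          expect_true(validate_conformation(child$conformation))
          expect_identical(child$conformation$sequence, s)
          expect_identical(child$conformation$encoding,
                           c(if (identical(child, ch$child1)) a$encoding[1:k]
                             else b$encoding[1:k],
                             if (k < n - 1L) {
                               if (identical(child, ch$child1))
                                 b$encoding[(k + 1):(n - 1)]
                               else a$encoding[(k + 1):(n - 1)]
                             } else integer(0)))
        }
      }
    }
  }
  expect_error(crossover_single_point(a, conformation("KK", encoding = 1L), 1),
               "sequence")
})

test_that("macro-mutation always yields a valid conformation of the same sequence", {
  # no interior residue of the chosen class: unchanged
  set.seed(151)
  allP <- straight_conf("KKKKK")
  res <- macro_mutation(allP, p = 0)  # forces the hydrophobic class
  expect_true(move_succeeded(res))
  expect_identical(res$conformation$encoding, allP$encoding)
  set.seed(161)
  for (trial in 1:30) {
    cf <- rand_conf(sample(6:30, 1))
    res <- macro_mutation(cf, p = 0.2, repeats = 2)
    expect_true(validate_conformation(res$conformation))
    expect_identical(res$conformation$sequence, cf$sequence)
    resb <- macro_mutation(cf, mode = "bm")
    expect_true(validate_conformation(resb$conformation))
  }
})

test_that("repeated core-directed macro-mutation squeezes the hydrophobic core", {
  set.seed(171)
  before <- numeric(0)
  after <- numeric(0)
  for (trial in 1:100) {
    cf <- rand_conf(16, mode = "hp")
    before <- c(before, energy_hp(cf))
    out <- cf
    for (k in 1:3) out <- macro_mutation(out, p = 0, repeats = 2)$conformation
    after <- c(after, energy_hp(out))
  }
  # in distribution, H-H contacts accumulate (energies drop)
  expect_true(all(after <= 0))
  expect_lt(mean(after), mean(before))
})
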