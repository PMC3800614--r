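test_that("validation accepts SAWs and rejects revisits, gaps and mismatches", {
  good <- straight_conf("MKKYTC")
  expect_true(validate_conformation(good))
  # immediate reversal revisits the origin
  bad <- conformation("MKK", encoding = c(1L, 2L))
  expect_false(validate_conformation(bad))
  expect_error(conformation("MK", coords = rbind(c(0, 0, 0), c(3, 0, 0))),
               "neighbours")
  expect_error(conformation("MKK", coords = rbind(c(0, 0, 0), c(1, 1, 0))),
               "does not match")
  expect_error(conformation("MZ", encoding = 1L), "unknown residue")
  # agreement with an independent all-pairs distinctness check
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(3:25, 1)
    enc <- sample(12L, n - 1L, replace = TRUE)
    coords <- fcc_decode(enc)
    conf <- conformation(random_sequence(n), encoding = enc)
    distinct <- nrow(unique(coords)) == n
    expect_identical(validate_conformation(conf), distinct)
  }
})

test_that("contact enumeration agrees with the quadratic oracle", {
  expect_identical(nrow(contacts(straight_conf("MKKYTCTV"))), 0L)
  # 4-residue U-shape: only residues 1 and 4 touch
  u <- conformation("KKKK", coords = ring4_coords)
  cc <- contacts(u)
  expect_identical(cc$i, 1L)
  expect_identical(cc$j, 4L)
  set.seed(41)
  for (trial in 1:20) {
    conf <- rand_conf(sample(5:40, 1))
    got <- as.matrix(contacts(conf)[, c("i", "j")])
    want <- brute_contacts(conf$coords)
    expect_identical(unname(got), unname(want))
  }
})

test_that("HP energy counts hydrophobic contacts and BM energy sums the matrix", {
  expect_identical(energy_hp(straight_conf("LLLLLL")), 0)
  f <- conformation("FSSF", coords = ring4_coords)
  expect_identical(energy_hp(f), -1)
  expect_equal(energy_bm(f), -2.467)
  expect_identical(unname(contact_class_counts(f)), c(1L, 0L, 0L, 1L))
  set.seed(51)
  for (trial in 1:20) {
    conf <- rand_conf(sample(5:40, 1))
    expect_equal(energy_bm(conf),
                 brute_energy(conf$coords, conf$sequence, bm_matrix()))
    expect_equal(energy_hp(conf),
                 brute_energy(conf$coords, conf$sequence, hp_matrix()))
    cc <- contact_class_counts(conf)
    expect_identical(cc, brute_class_counts(conf$coords, conf$sequence))
    expect_identical(sum(cc[1:3]), cc[["total"]])
    expect_equal(energy_hp(conf), -as.numeric(cc[["HH"]]))
  }
})

test_that("BM energy is translation invariant and orientation symmetric", {
  set.seed(61)
  for (trial in 1:10) {
    conf <- rand_conf(sample(6:20, 1))
    shifted <- conformation(conf$sequence,
                            coords = sweep(conf$coords, 2L, c(3L, -2L, 5L), `+`))
    expect_equal(energy_bm(conf), energy_bm(shifted))
    # reversing the chain reverses every contact pair (i, j) -> (j, i)
    rev_conf <- conformation(paste(rev(strsplit(conf$sequence, "")[[1]]),
                                   collapse = ""),
                             coords = conf$coords[nrow(conf$coords):1, ])
    expect_equal(energy_bm(conf), energy_bm(rev_conf))
  }
  m <- bm_matrix()
  expect_true(isSymmetric(unname(m)))
})

test_that("the hydrophobic core centre is the mean of H-residue coordinates", {
  # one H residue (Phe) at (2, 0, 2): HCC is that point
  conf1 <- conformation("SFS",
                        coords = rbind(c(1, 1, 2), c(2, 0, 2), c(3, 1, 2)))
  expect_equal(hydrophobic_core_center(conf1), c(2, 0, 2))
  # two H residues at (0,0,0) and (2,2,0)
  conf2 <- conformation("LKL",
                        coords = rbind(c(0, 0, 0), c(1, 1, 0), c(2, 2, 0)))
  expect_equal(hydrophobic_core_center(conf2), c(1, 1, 0))
  expect_error(hydrophobic_core_center(straight_conf("KKKK")),
               "no hydrophobic")
  set.seed(71)
  for (trial in 1:10) {
    conf <- rand_conf(sample(5:30, 1))
    if (!any(conf$h)) next
    manual <- apply(conf$coords[conf$h, , drop = FALSE], 2, mean)
    expect_equal(hydrophobic_core_center(conf), manual)
  }
})

test_that("conformations serialise to TSV and JSON records", {
  conf <- conformation("FSSF", coords = ring4_coords)
  tsv <- tempfile(fileext = ".tsv")
  write_conformation(conf, tsv)
  rec <- read.delim(tsv)
  expect_identical(rec$sequence, "FSSF")
  expect_identical(rec$encoding, "1,4,2")
  expect_equal(rec$E_BM, -2.467)
  expect_identical(rec$HH, 1L)
  skip_if_not_installed("jsonlite")
  js <- tempfile(fileext = ".json")
  write_conformation(conf, js, format = "json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$E_BM, -2.467)
  expect_identical(parse_encoding(parsed$encoding), conf$encoding)
})

test_that("FASTA input round-trips through the packaged writer", {
  f <- tempfile(fileext = ".fasta")
  write_benchmark_fasta(f)
  s <- read_fasta_sequence(f)
  expect_identical(s, load_benchmarks()$sequence[1])
})
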