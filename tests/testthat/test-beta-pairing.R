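test_that("score_pairing matches the position-loop oracle", {
  tab <- toy_pairing_table()
  for (seed in 1:10) {
    la <- sample(12:20, 1)
    sa <- random_peptide_seq(la, seed)
    sb <- random_peptide_seq(la + 3, seed + 100)
    L <- sample(2:8, 1)
    a0 <- sample(la - L + 1, 1)
    b0 <- sample(la + 3 - L + 1, 1)
    for (orient in c("parallel", "antiparallel")) {
      got <- score_pairing(sa, sb, c(a0, a0 + L - 1), c(b0, b0 + L - 1),
                           orient, tab)
      want <- oracle_score_pairing(
        strsplit(sa, "")[[1]][a0:(a0 + L - 1)],
        strsplit(sb, "")[[1]][b0:(b0 + L - 1)], orient, tab$par, tab$anti)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("score_pairing base cases and validation", {
  tab <- toy_pairing_table()
  # length-1 segment: single lookup
  expect_equal(score_pairing("LV", "GK", c(1, 1), c(2, 2), "parallel", tab),
               tab$par["L", "K"])
  # constant table: energy = -L
  m <- matrix(-1, 20, 20,
              dimnames = list(ionlock:::AA_ALPHABET, ionlock:::AA_ALPHABET))
  const <- pairing_energy_table(m, m, "const")
  expect_equal(score_pairing("LVLVLV", "GKGKGK", c(1, 6), c(1, 6),
                             "antiparallel", const), -6)
  expect_error(score_pairing("LVLV", "GK", c(1, 4), c(1, 2), "parallel",
                             tab), "equal length")
  expect_error(score_pairing("LVLV", "GK", c(1, 5), c(1, 2), "parallel",
                             tab), "out of bounds")
})

test_that("antiparallel scoring is invariant under segment swap", {
  tab <- toy_pairing_table()
  for (seed in 1:6) {
    sa <- random_peptide_seq(12, seed)
    sb <- random_peptide_seq(12, seed + 50)
    e1 <- score_pairing(sa, sb, c(2, 9), c(3, 10), "antiparallel", tab)
    e2 <- score_pairing(sb, sa, c(3, 10), c(2, 9), "antiparallel", tab)
    expect_equal(e1, e2, tolerance = 1e-12)
  }
})

test_that("enumerate_pairings is complete, sorted, and oracle-identical", {
  tab <- toy_pairing_table()
  cases <- list(c(8, 10), c(12, 15), c(15, 15))
  for (k in seq_along(cases)) {
    sa <- random_peptide_seq(cases[[k]][1], 7 * k)
    sb <- random_peptide_seq(cases[[k]][2], 7 * k + 1)
    got <- enumerate_pairings(sa, sb, min_len = 4, max_results = 1e6,
                              table = tab)
    want <- oracle_enumerate(sa, sb, 4, tab$par, tab$anti)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$energy, want$energy, tolerance = 1e-12)
    expect_equal(got$a_start, want$a_start)
    expect_equal(got$orientation, want$orientation)
    expect_false(is.unsorted(round(got$energy, 9)))
  }

  # self-pairing with a table favoring identical residues: the global best is
  # the parallel, in-register, full-length self-alignment (PIRA)
  sa <- random_peptide_seq(10, 11)
  best <- enumerate_pairings(sa, sa, min_len = 4, max_results = 1,
                             table = toy_pairing_table())
  expect_equal(nrow(best), 1L)
  expect_equal(best$orientation, "parallel")
  expect_equal(best$register, 0L)
  expect_equal(c(best$a_start, best$a_end), c(1L, 10L))

  # short inputs below min_len: empty result
  empty <- enumerate_pairings("LVL", "GKG", min_len = 4)
  expect_equal(nrow(empty), 0L)
})

test_that("classify_amyloid uses a strict threshold", {
  expect_true(classify_amyloid(-29.2))
  expect_false(classify_amyloid(-22.2))
  expect_false(classify_amyloid(-29.0))  # boundary: strict inequality
  expect_true(classify_amyloid(-5, threshold = -4))
})

test_that("aggregation_profile matches exhaustive recomputation", {
  tab <- toy_pairing_table()
  seq <- random_peptide_seq(12, 21)
  top <- 50
  res <- enumerate_pairings(seq, seq, min_len = 4, max_results = top,
                            table = tab)
  want <- numeric(12)
  for (i in seq_len(nrow(res))) {
    for (pos in res$a_start[i]:res$a_end[i]) {
      if (want[pos] == 0 || res$energy[i] < want[pos]) {
        want[pos] <- res$energy[i]
      }
    }
  }
  expect_equal(aggregation_profile(seq, tab, 4, top), want)

  # homopolymer with a uniform table: flat interior profile
  m <- matrix(-0.5, 20, 20,
              dimnames = list(ionlock:::AA_ALPHABET, ionlock:::AA_ALPHABET))
  flat_tab <- pairing_energy_table(m, m)
  prof <- aggregation_profile(strrep("V", 10), flat_tab, min_len = 4,
                              max_results = 1e6)
  expect_equal(length(unique(prof)), 1L)

  # too short for any pairing: all zeros
  expect_equal(aggregation_profile("LVL", tab, min_len = 4), c(0, 0, 0))
})

test_that("pairing table TSV round-trips", {
  tab <- toy_pairing_table()
  long <- expand.grid(residue_a = ionlock:::AA_ALPHABET,
                      residue_b = ionlock:::AA_ALPHABET,
                      stringsAsFactors = FALSE)
  long <- rbind(cbind(long, orientation = "parallel",
                      energy = as.vector(tab$par)),
                cbind(long, orientation = "antiparallel",
                      energy = as.vector(tab$anti)))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  back <- read_pairing_table(path)
  expect_equal(back$par, tab$par)
  expect_equal(back$anti, tab$anti)
  # asymmetric antiparallel table is rejected
  bad <- tab$anti; bad["A", "C"] <- bad["A", "C"] + 1
  expect_error(pairing_energy_table(tab$par, bad), "symmetric")
})
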