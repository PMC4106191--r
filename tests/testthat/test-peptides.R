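test_that("fixtures load with the documented lengths and lock residues", {
  peps <- load_fixtures()
  expected_len <- c("SP-C human" = 35, "SP-C dog" = 35, "SP-C pig" = 35,
                    "rSP-C" = 34, "SP-Css" = 34, "SP-Cff" = 34,
                    "SP-Css ion-lock 1" = 34, "SP-Cff ion-lock 1" = 34,
                    "SP-C33 UCLA" = 33, "SP-C33 ion-lock 1" = 33,
                    "SP-C33 ion-lock 2" = 33)
  expect_setequal(names(peps), names(expected_len))
  for (nm in names(expected_len)) {
    expect_equal(length(peps[[nm]]), unname(expected_len[nm]), info = nm)
  }

  # legend residue anchors
  il1 <- residues(peps[["SP-Css ion-lock 1"]])
  expect_equal(il1[20], "E")
  expect_equal(il1[24], "K")
  il2 <- residues(peps[["SP-C33 ion-lock 2"]])
  expect_equal(il2[c(15, 19, 20, 24)], c("K", "E", "E", "K"))
  r <- residues(peps[["rSP-C"]])
  expect_equal(r[c(4, 5, 32)], c("F", "F", "I"))  # C4F, C5F, M32I

  expect_error(get_fixture("no-such-peptide"), "unknown peptide id")
  expect_error(load_fixtures(tempfile()), "configuration error")
})

test_that("peptide construction validates alphabet and length", {
  expect_equal(peptide("p", "gipssPVHLKR")$sequence, "GIPSSPVHLKR")
  expect_error(peptide("p", "GIPXSPVHLKR"), "non-standard residue")
  expect_error(peptide("p", "GIP"), "length")
  expect_error(peptide("p", strrep("A", 61)), "length")
})

test_that("ion-lock specs enforce i+4 spacing and non-overlap", {
  expect_silent(ion_lock_spec(list(c(20, 24))))
  expect_silent(ion_lock_spec(list(c(19, 15))))  # cation first is fine
  expect_error(ion_lock_spec(list(c(20, 23))), "i, i\\+4")
  expect_error(ion_lock_spec(list(c(20, 24), c(24, 28))), "overlap")
})

test_that("apply_ion_lock reproduces the fixture ion-lock peptides", {
  peps <- load_fixtures()
  cases <- list(
    list(parent = "SP-Css", lock = list(c(20, 24)),
         fixture = "SP-Css ion-lock 1"),
    list(parent = "SP-Cff", lock = list(c(20, 24)),
         fixture = "SP-Cff ion-lock 1"),
    list(parent = "SP-C33 UCLA", lock = list(c(20, 24)),
         fixture = "SP-C33 ion-lock 1"),
    list(parent = "SP-C33 UCLA", lock = list(c(19, 15), c(20, 24)),
         fixture = "SP-C33 ion-lock 2"))
  for (cs in cases) {
    got <- apply_ion_lock(peps[[cs$parent]], ion_lock_spec(cs$lock))
    expect_equal(got$sequence, peps[[cs$fixture]]$sequence,
                 info = cs$fixture)
    # exactly 2 substitutions per pair, length preserved
    expect_equal(length(got), length(peps[[cs$parent]]))
    diffs <- sum(residues(got) != residues(peps[[cs$parent]]))
    expect_lte(diffs, 2L * length(cs$lock))
  }

  # idempotent on a peptide already carrying the lock
  il <- peps[["SP-Css ion-lock 1"]]
  again <- apply_ion_lock(il, ion_lock_spec(list(c(20, 24))))
  expect_equal(again$sequence, il$sequence)

  expect_error(apply_ion_lock(peps[["SP-C33 UCLA"]],
                              ion_lock_spec(list(c(31, 35)))),
               "out of bounds")
})

test_that("FASTA round-trips exactly and rejects bad records", {
  peps <- load_fixtures()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(peps, path)
  back <- read_fasta(path)
  expect_equal(names(back), names(peps))
  for (nm in names(peps)) {
    expect_equal(back[[nm]]$sequence, peps[[nm]]$sequence)
  }

  lc <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">low", "gipsspvhlkrll"), lc)
  expect_equal(read_fasta(lc)[[1]]$sequence, "GIPSSPVHLKRLL")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "GIPXXPVHLKRLL"), bad)
  expect_error(read_fasta(bad), "non-standard residue")
  expect_error(read_fasta(tempfile()), "no such FASTA")
})
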