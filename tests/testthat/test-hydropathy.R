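test_that("poly-glycine window total equals the direct table sum", {
  scale <- ww_octanol_scale()
  p <- peptide("polyG", strrep("G", 19))
  prof <- window_hydropathy(p, scale, 19)
  expect_equal(nrow(prof$windows), 1L)
  expect_equal(prof$windows$total, -19 * scale$dg[["G"]], tolerance = 1e-12)
  # single-window peptide: best segment is that window
  expect_equal(best_transmembrane_segment(prof)$start, 1L)
})

test_that("window totals match a brute-force per-residue oracle", {
  scale <- ww_octanol_scale()
  for (seed in 1:8) {
    n <- 20 + seed
    seq <- random_peptide_seq(n, seed)
    p <- peptide("rand", seq)
    w <- sample(c(5, 9, 19), 1)
    prof <- window_hydropathy(p, scale, w)
    expect_equal(prof$windows$total,
                 oracle_window_hydropathy(seq, scale$dg, w),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("engaged lock windows match the oracle and dominate disengaged", {
  scale <- ww_octanol_scale()
  p <- get_fixture("SP-Css ion-lock 1")
  on_ <- ion_lock_spec(list(c(20, 24)), engaged = TRUE)
  off <- ion_lock_spec(list(c(20, 24)), engaged = FALSE)
  prof_on <- window_hydropathy(p, scale, 19, on_)
  prof_off <- window_hydropathy(p, scale, 19, off)
  expect_equal(prof_on$windows$total,
               oracle_window_hydropathy(p$sequence, scale$dg, 19,
                                        list(pairs = list(c(20, 24)),
                                             engaged = TRUE),
                                        scale$salt_bridge_pair_dg),
               tolerance = 1e-12)
  # engagement never lowers any window
  expect_true(all(prof_on$windows$total >= prof_off$windows$total - 1e-12))
  # pair straddling a window boundary scores as disengaged: windows ending
  # before residue 24 agree between the two profiles
  pre <- prof_on$windows$end < 24
  expect_equal(prof_on$windows$total[pre], prof_off$windows$total[pre])
})

test_that("monotonicity: a more favorable residue never lowers a window", {
  scale <- ww_octanol_scale()
  seq <- random_peptide_seq(30, 99)
  p1 <- peptide("a", seq)
  res <- strsplit(seq, "")[[1]]
  pos <- 15
  res[pos] <- "L"  # most favorable side chain in the scale's core set
  p2 <- peptide("b", paste(res, collapse = ""))
  w1 <- window_hydropathy(p1, scale, 9)$windows
  w2 <- window_hydropathy(p2, scale, 9)$windows
  touches <- w1$start <= pos & w1$end >= pos
  expect_true(all(w2$total[touches] >= w1$total[touches] - 1e-12))
  expect_equal(w2$total[!touches], w1$total[!touches])
})

test_that("best segment ties break to the smallest start", {
  p <- peptide("uniform", strrep("V", 25))
  prof <- window_hydropathy(p, window = 19)
  expect_equal(prof$best_segment$start, 1L)
  # rSP-C has a genuine two-way tie (windows 12 and 13); smallest start wins
  expect_equal(window_hydropathy(get_fixture("rSP-C"))$best_segment$start,
               12L)
})

test_that("engagement_delta is nonnegative and additive for joint pairs", {
  p <- get_fixture("SP-Css ion-lock 1")
  d <- engagement_delta(p, locks = ion_lock_spec(list(c(20, 24))))
  expect_gte(d, 0)
  expect_equal(d, 6.33, tolerance = 0.02)  # 10.3 - 4.0 regime

  # two engaged pairs inside one window: delta equals the sum of per-pair
  # deltas computed on the shared maximizing window (direct summation)
  p2 <- get_fixture("SP-C33 ion-lock 2")
  locks2 <- ion_lock_spec(list(c(19, 15), c(20, 24)))
  scale <- ww_octanol_scale()
  d2 <- engagement_delta(p2, locks = locks2)
  per_pair <- (scale$dg[["E"]] + scale$dg[["K"]] -
                 scale$salt_bridge_pair_dg)
  expect_equal(d2, 2 * per_pair, tolerance = 1e-9)

  # a lock pair that no window can contain jointly with the maximum: a
  # peptide whose best window excludes the pair gives delta 0
  seqs <- paste0(strrep("L", 21), "AEAAAKAAA")  # lock at 23/27, max in 1-19
  p3 <- peptide("tail-lock", seqs)
  d3 <- engagement_delta(p3, window = 19,
                         locks = ion_lock_spec(list(c(23, 27))))
  expect_equal(d3, 0)
})

test_that("validation: bad windows and locks error", {
  p <- get_fixture("SP-Css")
  expect_error(window_hydropathy(p, window = 40), "exceeds peptide length")
  expect_error(window_hydropathy(p, locks = ion_lock_spec(list(c(20, 24)))),
               "does not reference E/K")
  expect_error(hydropathy_scale(c(A = 1)), "cover all 20")
  expect_error(ww_octanol_scale(salt_bridge_pair_dg = 10),
               "never be penalizing")
})

test_that("scale YAML override round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("G: -2.5", "salt_bridge_pair_dg: 0.2"), path)
  sc <- read_scale_yaml(path)
  expect_equal(sc$dg[["G"]], -2.5)
  expect_equal(sc$salt_bridge_pair_dg, 0.2)
  expect_equal(sc$dg[["L"]], ww_octanol_scale()$dg[["L"]])
})
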