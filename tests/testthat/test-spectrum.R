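test_that("spectrum construction validates and normalizes orientation", {
  s <- ir_spectrum(seq(1700, 1600, by = -2), rep(0.1, 51))
  expect_equal(s$wavenumbers[1], 1600)  # stored ascending
  expect_error(ir_spectrum(c(1600, 1600, 1604), c(1, 1, 1)),
               "strictly monotone")
  expect_error(ir_spectrum(c(1600, 1602), c(1, NA)), "finite")
  expect_error(ir_spectrum(c(1600, 1602), c(1, 2, 3)), "length")
})

test_that("subtract_reference is pointwise and grid-strict", {
  g <- gen_amide_spectrum(amide_preset("helix_rich"), noise_sd = 0)
  s <- g$spectrum
  expect_equal(subtract_reference(s, s)$absorbance,
               rep(0, length(s$wavenumbers)))
  expect_equal(subtract_reference(s, s, scale = 0)$absorbance, s$absorbance)
  other <- ir_spectrum(s$wavenumbers + 1, s$absorbance)
  expect_error(subtract_reference(s, other), "grids differ")

  # synthetic peptide + lipid background minus background recovers peptide
  lipid <- ir_spectrum(s$wavenumbers, 0.2 + 0.001 * (s$wavenumbers - 1600))
  mix <- ir_spectrum(s$wavenumbers, s$absorbance + lipid$absorbance)
  rec <- subtract_reference(mix, lipid)
  expect_equal(rec$absorbance, s$absorbance, tolerance = 1e-12)
})

test_that("two-column spectrum files round-trip (csv and tsv)", {
  g <- gen_amide_spectrum(amide_preset("mixed_sheet_helix"), noise_sd = 0.01,
                          seed = 5)
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_spectrum(g$spectrum, path)
    back <- read_spectrum(path)
    expect_equal(back$wavenumbers, g$spectrum$wavenumbers)
    expect_equal(back$absorbance, g$spectrum$absorbance, tolerance = 1e-12)
  }
  expect_error(read_spectrum(tempfile()), "no such spectrum")
})

test_that("minimal JCAMP-DX forms parse", {
  g <- gen_amide_spectrum(amide_preset("helix_rich"), noise_sd = 0)
  s <- g$spectrum
  # XYPOINTS form
  p1 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=xypoints demo", "##DATA TYPE=INFRARED SPECTRUM",
               "##XYPOINTS=(XY..XY)",
               paste(s$wavenumbers, s$absorbance, sep = ","),
               "##END="), p1)
  b1 <- read_jcamp(p1)
  expect_equal(b1$wavenumbers, s$wavenumbers)
  expect_equal(b1$absorbance, s$absorbance, tolerance = 1e-9)
  expect_equal(b1$id, "xypoints demo")

  # XYDATA (X++(Y..Y)) form with YFACTOR
  p2 <- withr::local_tempfile(fileext = ".jdx")
  yf <- 1e-6
  yint <- round(s$absorbance / yf)
  rows <- split(seq_along(s$wavenumbers),
                ceiling(seq_along(s$wavenumbers) / 6))
  body <- vapply(rows, function(ii) {
    paste(c(s$wavenumbers[ii[1]], yint[ii]), collapse = " ")
  }, character(1))
  writeLines(c("##TITLE=xydata demo", "##XFACTOR=1",
               sprintf("##YFACTOR=%g", yf),
               sprintf("##FIRSTX=%g", s$wavenumbers[1]),
               sprintf("##LASTX=%g", s$wavenumbers[length(s$wavenumbers)]),
               sprintf("##NPOINTS=%d", length(s$wavenumbers)),
               "##XYDATA=(X++(Y..Y))", body, "##END="), p2)
  b2 <- read_jcamp(p2)
  expect_equal(b2$wavenumbers, s$wavenumbers, tolerance = 1e-9)
  expect_equal(b2$absorbance, s$absorbance, tolerance = 2 * yf)

  p3 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=empty", "##END="), p3)
  expect_error(read_jcamp(p3), "no XYDATA")
})

test_that("band_area integrates by trapezoid", {
  x <- seq(1600, 1700, by = 2)
  s <- ir_spectrum(x, rep(2, length(x)))
  expect_equal(band_area(s, c(1620, 1640)), 40)  # 2 * width
  expect_error(band_area(s, c(1900, 1910)), "fewer than 2 points")
})
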