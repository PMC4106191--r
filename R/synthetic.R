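# Deterministic synthetic-data generators. Every generator returns both the
# simulated measurement and a machine-readable truth record, so recovery
# tests compare pipeline output against truth rather than against
# hard-coded numbers. All randomness flows through a caller-supplied seed
# (R's default Mersenne-Twister stream), restored on exit.

#' Default wavenumber grid for synthetic amide-I spectra
#'
#' 1590-1720 cm^-1 at 2 cm^-1 steps, matching a spectrometer resolution of
#' 2 cm^-1.
#' @return Numeric vector of wavenumbers.
#' @export
default_grid <- function() seq(1590, 1720, by = 2)

#' Band presets emulating the experimentally observed spectral regimes
#'
#' * `helix_rich`: dominant ~1655 cm^-1 helix band (the SP-C33 / ion-lock
#'   regime), true helix fraction >= 0.6.
#' * `parallel_fibril`: major ~1630 cm^-1 sheet band with a companion at
#'   ~1691 cm^-1 of < 5% amplitude (amyloid fibril signature).
#' * `antiparallel_oligomer`: ~1630 cm^-1 major plus a ~1695 cm^-1 band at
#'   20% of the major amplitude.
#' * `mixed_sheet_helix`: comparable sheet and helix bands.
#'
#' Preset numbers are generator conventions inside the conventional class
#' windows, not measured values.
#'
#' @param name Preset name.
#' @return A band data.frame (see [bands()]).
#' @export
amide_preset <- function(name = c("helix_rich", "parallel_fibril",
                                  "antiparallel_oligomer",
                                  "mixed_sheet_helix")) {
  name <- match.arg(name)
  switch(name,
    helix_rich = bands(center = c(1630, 1655, 1672, 1641),
                       width = c(16, 22, 16, 14),
                       amplitude = c(0.08, 1.00, 0.16, 0.12)),
    parallel_fibril = bands(center = c(1630, 1657, 1672, 1691),
                            width = c(18, 18, 14, 12),
                            amplitude = c(1.00, 0.25, 0.10, 0.04)),
    antiparallel_oligomer = bands(center = c(1630, 1657, 1695),
                                  width = c(18, 18, 14),
                                  amplitude = c(1.00, 0.25, 0.20)),
    mixed_sheet_helix = bands(center = c(1630, 1655, 1670, 1643),
                              width = c(18, 20, 14, 14),
                              amplitude = c(0.60, 0.60, 0.20, 0.20)))
}

# True class fractions of a band set under the assignment windows.
.truth_fractions <- function(b, windows = assignment_windows()) {
  assign_fractions(b, windows)
}

#' Generate a synthetic amide-I spectrum
#'
#' Sum of Gaussian-Lorentzian bands plus an optional linear baseline plus
#' additive Gaussian noise on absorbance. The truth record carries the exact
#' bands and their class fractions.
#'
#' @param band_set A band data.frame (e.g. [amide_preset()]).
#' @param noise_sd Additive absorbance noise sd (default 0.01; 0 gives the
#'   exact analytic band sum).
#' @param grid Wavenumber grid (default [default_grid()]).
#' @param baseline `c(intercept, slope)` of a linear baseline (default flat
#'   zero).
#' @param seed Integer seed (required when `noise_sd > 0` for
#'   reproducibility).
#' @param id Sample id.
#' @return List with `spectrum` (an `"ir_spectrum"`) and `truth`
#'   (`bands`, `fractions`, `noise_sd`, `baseline`).
#' @export
gen_amide_spectrum <- function(band_set = amide_preset("helix_rich"),
                               noise_sd = 0.01, grid = default_grid(),
                               baseline = c(0, 0), seed = NULL,
                               id = "synthetic") {
  stopifnot(is.data.frame(band_set), noise_sd >= 0)
  if (any(band_set$center < min(grid)) || any(band_set$center > max(grid))) {
    stop("band centers must lie within the grid", call. = FALSE)
  }
  y <- eval_bands(grid, band_set, baseline)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  }
  list(spectrum = ir_spectrum(grid, y, id = id),
       truth = list(bands = band_set,
                    fractions = .truth_fractions(band_set),
                    noise_sd = noise_sd, baseline = baseline))
}

#' Generate a random multi-band amide-I spectrum
#'
#' Draws 3-5 component bands, at most one per conformational class, with
#' centers inside slightly shrunk class windows, widths 12-22 cm^-1 and
#' amplitudes 0.3-1.0; classes at 2 cm^-1 instrument resolution are kept
#' resolvable by requiring >= 12 cm^-1 center separation. Used by the
#' deconvolution recovery tests.
#'
#' @param seed Integer seed (drives band draw and noise).
#' @param n_bands 3, 4 or 5; default drawn uniformly.
#' @param noise_sd Additive noise sd (default 0.01, i.e. SNR >= 30 for the
#'   weakest allowed band).
#' @return As [gen_amide_spectrum()].
#' @export
gen_random_amide_spectrum <- function(seed, n_bands = NULL, noise_sd = 0.01) {
  pools <- list(sheet_low = c(1618, 1634), disordered = c(1638, 1644),
                helix = c(1648, 1660), turn = c(1666, 1679),
                sheet_high = c(1686, 1702))
  band_set <- with_seed(seed, {
    nb <- if (is.null(n_bands)) sample(3:5, 1) else as.integer(n_bands)
    stopifnot(nb >= 3L, nb <= 5L)
    classes <- sample(names(pools), nb)
    for (try in 1:100) {
      centers <- vapply(classes, function(cl) {
        stats::runif(1, pools[[cl]][1], pools[[cl]][2])
      }, numeric(1))
      if (min(dist(centers)) >= 12) break
    }
    bands(center = centers,
          width = stats::runif(nb, 12, 22),
          amplitude = stats::runif(nb, 0.3, 1.0),
          shape = stats::runif(nb, 0.3, 0.7))
  })
  gen_amide_spectrum(band_set, noise_sd = noise_sd,
                     seed = if (is.null(seed)) NULL else seed + 1L,
                     id = sprintf("random-%s", seed))
}

#' Generate a synthetic polarized spectrum pair
#'
#' Forward thick-film dichroism model: the parallel and perpendicular
#' amide-I areas of a helix band are proportional to
#' `Ex^2 (1-K_z)/2 + Ez^2 K_z` and `Ey^2 (1-K_z)/2`, where `K_z` follows
#' from the tilt angle. Multiplicative Gaussian noise (default 2%) is
#' applied to each area.
#'
#' @param tilt_deg True helix tilt from the membrane normal, degrees.
#' @param fields A [field_params()].
#' @param area_noise_sd Multiplicative area noise sd (default 0.02).
#' @param base_area Isotropic-equivalent band area scale (default 10).
#' @param seed Integer seed.
#' @param spectra If `TRUE`, also emit full `"ir_spectrum"` objects (a
#'   1656 cm^-1 helix band scaled to the noisy areas).
#' @return List with `a_parallel`, `a_perpendicular`, optionally
#'   `spec_parallel`/`spec_perpendicular`, and `truth` (`tilt_deg`,
#'   `R_exact`).
#' @export
gen_polarized_pair <- function(tilt_deg, fields = field_params(),
                               area_noise_sd = 0.02, base_area = 10,
                               seed = NULL, spectra = FALSE) {
  stopifnot(tilt_deg >= 0, tilt_deg <= 90, area_noise_sd >= 0)
  s_helix <- (3 * cos(tilt_deg * pi / 180)^2 - 1) / 2
  k_z <- (2 * s_helix * fields$s_alpha + 1) / 3
  p_par <- fields$e_x^2 * (1 - k_z) / 2 + fields$e_z^2 * k_z
  p_perp <- fields$e_y^2 * (1 - k_z) / 2
  noise <- if (area_noise_sd > 0) {
    with_seed(seed, stats::rnorm(2, 0, area_noise_sd))
  } else c(0, 0)
  a_par <- base_area * p_par * (1 + noise[1])
  a_perp <- base_area * p_perp * (1 + noise[2])
  out <- list(a_parallel = a_par, a_perpendicular = a_perp,
              truth = list(tilt_deg = tilt_deg, R_exact = p_par / p_perp))
  if (spectra) {
    grid <- default_grid()
    b <- bands(center = 1656, width = 18, amplitude = 1)
    shape <- eval_bands(grid, b) / b$area   # unit-area band profile
    out$spec_parallel <- ir_spectrum(grid, shape * a_par, id = "parallel",
                                     polarization = 0)
    out$spec_perpendicular <- ir_spectrum(grid, shape * a_perp,
                                          id = "perpendicular",
                                          polarization = 90)
  }
  out
}

#' Generate a synthetic H/D exchange series
#'
#' Two (by default) first-order exchange compartments plus a non-exchanging
#' plateau drive the amide II / amide I area ratio; multiplicative Gaussian
#' noise (default 2%) is applied to the amide II areas.
#'
#' @param amplitudes Compartment amplitudes, % (default `c(25, 24)`).
#' @param half_lives Compartment half-lives, minutes (default `c(10, 120)`,
#'   the fast/intermediate regime).
#' @param plateau Non-exchanging plateau, % (default 51);
#'   `sum(amplitudes) + plateau` must be 100.
#' @param times Sampling times, minutes (default 14 points over 0-360).
#' @param noise_sd Multiplicative noise sd on amide II areas (default 0.02).
#' @param amide_I_area Constant amide I area (default 10).
#' @param ratio0 True amide II / amide I ratio at t = 0 (default 0.5).
#' @param seed Integer seed.
#' @return List with `series` (an [hdx_series()]) and `truth`
#'   (`amplitudes`, `half_lives`, `plateau`, `curve` function of t).
#' @export
gen_hdx_series <- function(amplitudes = c(25, 24), half_lives = c(10, 120),
                           plateau = 51,
                           times = c(0, 5, 10, 15, 20, 30, 45, 60, 90,
                                     120, 180, 240, 300, 360),
                           noise_sd = 0.02, amide_I_area = 10, ratio0 = 0.5,
                           seed = NULL) {
  stopifnot(length(amplitudes) == length(half_lives), all(half_lives > 0),
            all(amplitudes >= 0), plateau >= 0)
  if (abs(sum(amplitudes) + plateau - 100) > 1e-6) {
    stop("amplitudes + plateau must sum to 100", call. = FALSE)
  }
  pct <- .hdx_model(times, amplitudes, half_lives)
  ratio <- ratio0 * pct / 100
  mult <- if (noise_sd > 0) {
    with_seed(seed, 1 + stats::rnorm(length(times), 0, noise_sd))
  } else rep(1, length(times))
  series <- hdx_series(times,
                       amide_II_area = pmax(ratio * amide_I_area * mult,
                                            1e-9),
                       amide_I_area = rep(amide_I_area, length(times)))
  list(series = series,
       truth = list(amplitudes = amplitudes, half_lives = half_lives,
                    plateau = plateau,
                    curve = function(t) .hdx_model(t, amplitudes,
                                                   half_lives)))
}
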