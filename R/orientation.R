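# Polarized-ATR orientation analysis: dichroic ratio of the amide-I helix
# band -> order parameters -> maximum helix tilt angle, plus the closed-form
# forward model (thick-film approximation) used by the synthetic generator.

#' Evanescent-field parameters for the thick-film ATR model
#'
#' @param e_x,e_y,e_z Electric-field amplitudes of the evanescent wave at the
#'   germanium interface (dimensionless; defaults 1.398, 1.516, 1.625).
#' @param alpha Angle between the amide-I transition dipole and the helix
#'   axis, degrees (default 39).
#' @return A list of class `"field_params"`.
#' @export
field_params <- function(e_x = 1.398, e_y = 1.516, e_z = 1.625, alpha = 39) {
  stopifnot(e_x > 0, e_y > 0, e_z > 0, alpha >= 0, alpha < 90)
  s_alpha <- (3 * cos(alpha * pi / 180)^2 - 1) / 2
  if (abs(s_alpha) < 1e-9) {
    stop("alpha at the magic angle: dipole order parameter cannot be mapped ",
         "to a helix order parameter", call. = FALSE)
  }
  structure(list(e_x = e_x, e_y = e_y, e_z = e_z, alpha = alpha,
                 s_alpha = s_alpha),
            class = "field_params")
}

#' Dichroic ratio of a polarized spectrum pair
#'
#' `R = A_parallel / A_perpendicular`, the ratio of integrated amide-I band
#' areas at 0 and 90 degree polarization. Inputs are either two areas or two
#' full spectra, integrated by the trapezoid rule over `band_window`.
#'
#' @param parallel,perpendicular Either positive numeric areas, or
#'   `"ir_spectrum"` objects.
#' @param band_window Integration window, cm^-1 (default the helix amide-I
#'   band `c(1645, 1662)`); ignored for numeric areas.
#' @return The dichroic ratio (dimensionless).
#' @export
dichroic_ratio <- function(parallel, perpendicular,
                           band_window = c(1645, 1662)) {
  area <- function(v) {
    if (inherits(v, "ir_spectrum")) band_area(v, band_window) else as.numeric(v)
  }
  a_par <- area(parallel)
  a_perp <- area(perpendicular)
  if (!is.finite(a_par) || !is.finite(a_perp) || a_par <= 0 || a_perp <= 0) {
    stop("band areas must be positive", call. = FALSE)
  }
  a_par / a_perp
}

#' Order parameters from a dichroic ratio
#'
#' Thick-film inversion: the transition-dipole order parameter is
#' `S_dipole = (Ex^2 - R*Ey^2 + Ez^2) / (Ex^2 - R*Ey^2 - 2*Ez^2)` and the
#' helix-axis order parameter follows by dividing out the dipole geometry,
#' `S_helix = S_dipole / [(3 cos^2 alpha - 1)/2]`. With the default fields
#' the physically attainable range of R is about `[1.418, 4.357]`
#' (`S_helix` in `[-0.5, 1]`).
#'
#' @param R Dichroic ratio.
#' @param fields A [field_params()].
#' @param clamp If `TRUE`, out-of-range R is clamped to the nearest
#'   attainable value with a warning instead of erroring (disorder in the
#'   multilayer biases R; clamping maps R > R_max to theta = 0 and
#'   R < R_min to theta = 90).
#' @return List with `s_dipole` and `s_helix`.
#' @export
order_parameter <- function(R, fields = field_params(), clamp = FALSE) {
  stopifnot(inherits(fields, "field_params"), is.numeric(R), length(R) == 1L,
            is.finite(R))
  rng <- dichroic_range(fields)
  if (R < rng[1] || R > rng[2]) {
    if (!clamp) {
      stop(sprintf(paste0("R = %.4g outside the attainable range ",
                          "[%.4g, %.4g] for these fields; use clamp = TRUE ",
                          "to map onto the nearest limiting tilt"),
                   R, rng[1], rng[2]), call. = FALSE)
    }
    warning(sprintf("R = %.4g clamped into [%.4g, %.4g]", R, rng[1], rng[2]),
            call. = FALSE)
    R <- min(max(R, rng[1]), rng[2])
  }
  ex2 <- fields$e_x^2; ey2 <- fields$e_y^2; ez2 <- fields$e_z^2
  s_dipole <- (ex2 - R * ey2 + ez2) / (ex2 - R * ey2 - 2 * ez2)
  list(s_dipole = s_dipole, s_helix = s_dipole / fields$s_alpha)
}

#' Attainable dichroic-ratio range for a field geometry
#' @param fields A [field_params()].
#' @return `c(R_min, R_max)` corresponding to tilt 90 and 0 degrees.
#' @export
dichroic_range <- function(fields = field_params()) {
  c(forward_dichroic_ratio(90, fields), forward_dichroic_ratio(0, fields))
}

#' Maximum tilt angle from a helix order parameter
#'
#' Inverts `S = (3 cos^2 Theta - 1)/2`. Because multilayer disorder biases R
#' downwards, the result is a maximum tilt: the true tilt from the membrane
#' normal is at most this large.
#'
#' @param s_helix Helix-axis order parameter in `[-0.5, 1]`.
#' @return Tilt angle Theta in degrees, in `[0, 90]`.
#' @examples
#' tilt_angle(1)    # 0
#' tilt_angle(0)    # 54.7 (magic angle)
#' tilt_angle(-0.5) # 90
#' @export
tilt_angle <- function(s_helix) {
  stopifnot(is.numeric(s_helix), length(s_helix) == 1L)
  if (!is.finite(s_helix) || s_helix < -0.5 - 1e-12 || s_helix > 1 + 1e-12) {
    stop("helix order parameter must lie in [-0.5, 1]", call. = FALSE)
  }
  s_helix <- min(max(s_helix, -0.5), 1)
  acos(sqrt((2 * s_helix + 1) / 3)) * 180 / pi
}

#' Forward model: dichroic ratio from a tilt angle
#'
#' The generator/oracle inverse of [order_parameter()] + [tilt_angle()]:
#' with `S_dipole = S_helix(theta) * S_alpha` and
#' `K_z = (2 S_dipole + 1)/3`,
#' `R = [Ex^2 (1 - K_z)/2 + Ez^2 K_z] / [Ey^2 (1 - K_z)/2]`.
#'
#' @param theta_deg Tilt angle from the membrane normal, degrees, in
#'   `[0, 90]`.
#' @param fields A [field_params()].
#' @return The dichroic ratio.
#' @examples
#' forward_dichroic_ratio(0)      # ~4.36
#' forward_dichroic_ratio(54.74)  # ~2.00 (isotropic limit)
#' @export
forward_dichroic_ratio <- function(theta_deg, fields = field_params()) {
  stopifnot(is.numeric(theta_deg), all(theta_deg >= 0), all(theta_deg <= 90))
  s_helix <- (3 * cos(theta_deg * pi / 180)^2 - 1) / 2
  s_dipole <- s_helix * fields$s_alpha
  k_z <- (2 * s_dipole + 1) / 3
  (fields$e_x^2 * (1 - k_z) / 2 + fields$e_z^2 * k_z) /
    (fields$e_y^2 * (1 - k_z) / 2)
}

#' Full orientation analysis of a polarized pair
#'
#' @inheritParams dichroic_ratio
#' @inheritParams order_parameter
#' @return A list of class `"orientation_result"`: `R`, `s_dipole`,
#'   `s_helix`, `theta_max` (degrees).
#' @export
orientation_analysis <- function(parallel, perpendicular,
                                 band_window = c(1645, 1662),
                                 fields = field_params(), clamp = FALSE) {
  R <- dichroic_ratio(parallel, perpendicular, band_window)
  s <- order_parameter(R, fields, clamp = clamp)
  structure(list(R = R, s_dipole = s$s_dipole, s_helix = s$s_helix,
                 theta_max = tilt_angle(s$s_helix)),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf(
    "<orientation_result> R = %.3f, S_dipole = %.3f, S_helix = %.3f, max tilt %.1f deg\n",
    x$R, x$s_dipole, x$s_helix, x$theta_max))
  invisible(x)
}
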