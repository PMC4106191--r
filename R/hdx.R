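# Hydrogen/deuterium exchange kinetics: amide II / amide I normalization,
# multi-exponential compartment fitting, unexchanged-helix arithmetic.
#
# Amide protons H-bonded inside a lipid-buried transmembrane helix resist
# exchange: the decay of the amide II band area (N-H bend) relative to the
# amide I area, followed over 0-6 h, decomposes into fast and intermediate
# first-order compartments plus a non-exchanging plateau.

#' Construct an H/D exchange series
#'
#' @param times Minutes, ascending, first value 0.
#' @param amide_II_area Amide II band areas (1525-1565 cm^-1), > 0.
#' @param amide_I_area Amide I band areas (1600-1700 cm^-1), > 0.
#' @return A data.frame of class `"hdx_series"`.
#' @export
hdx_series <- function(times, amide_II_area, amide_I_area) {
  times <- as.numeric(times)
  stopifnot(length(times) == length(amide_II_area),
            length(times) == length(amide_I_area))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly ascending", call. = FALSE)
  }
  if (any(amide_I_area <= 0) || any(amide_II_area <= 0)) {
    stop("band areas must be positive", call. = FALSE)
  }
  structure(data.frame(time_min = times,
                       amide_II_area = as.numeric(amide_II_area),
                       amide_I_area = as.numeric(amide_I_area)),
            class = c("hdx_series", "data.frame"))
}

#' Read an H/D series from TSV
#' @param path TSV with columns `time_min`, `amide_II_area`, `amide_I_area`.
#' @return An `"hdx_series"`.
#' @export
read_hdx_series <- function(path) {
  tab <- utils::read.delim(path)
  needed <- c("time_min", "amide_II_area", "amide_I_area")
  if (!all(needed %in% names(tab))) {
    stop("H/D series TSV needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  hdx_series(tab$time_min, tab$amide_II_area, tab$amide_I_area)
}

#' Percent unexchanged amide protons vs time
#'
#' The amide II / amide I area ratio is proportional to the remaining amide
#' protons; normalizing by the t = 0 ratio gives
#' `curve(t) = 100 * [AII(t)/AI(t)] / [AII(0)/AI(0)]`.
#'
#' @param series An [hdx_series()]; must contain a t = 0 point.
#' @return A data.frame with `time_min` and `percent_unexchanged`
#'   (100 at t = 0 by construction).
#' @export
percent_unexchanged <- function(series) {
  stopifnot(inherits(series, "hdx_series"))
  if (series$time_min[1] != 0) {
    stop("series must start at t = 0 for normalization", call. = FALSE)
  }
  ratio <- series$amide_II_area / series$amide_I_area
  data.frame(time_min = series$time_min,
             percent_unexchanged = 100 * ratio / ratio[1])
}

# y(t) for amplitudes a (per compartment), half-lives th, plateau = 100-sum(a)
.hdx_model <- function(t, a, th) {
  y <- rep(100 - sum(a), length(t))
  for (i in seq_along(a)) y <- y + a[i] * exp(-log(2) * t / th[i])
  y
}

#' Fit exchange compartments to a percent-unexchanged curve
#'
#' Least-squares fit of
#' `y(t) = plateau + sum_i a_i * exp(-ln2 * t / t_half_i)` with `a_i >= 0`,
#' `plateau >= 0` and the sum-to-100 constraint enforced exactly through the
#' parameterization `plateau = 100 - sum(a_i)`. Initialization is a
#' deterministic multi-start over log-spaced half-life combinations
#' (3, 10, 30, 120, 480 min), so fits are reproducible without a seed; the
#' best start wins.
#'
#' @param curve A data.frame with `time_min` and `percent_unexchanged`
#'   (e.g. from [percent_unexchanged()]).
#' @param n_components Number of exponential compartments (1-3, default 2:
#'   fast + intermediate).
#' @param half_life_max Upper bound on compartment half-lives, minutes.
#'   The compartment model describes fast and intermediate exchange with
#'   half-lives between 10 and 120 min; the default bound of 150 min (that
#'   regime plus 25% margin) assigns anything slower to the non-exchanging
#'   plateau. Without the bound a slow exponential is confounded with the
#'   plateau on a 0-6 h window and plateau estimates degrade severely.
#' @return A list of class `"exchange_fit"`: `amplitudes` (%, one per
#'   compartment, ordered by ascending half-life), `half_lives` (min,
#'   ascending), `plateau` (%), `rss`, `fitted` (function of t).
#' @export
fit_exchange <- function(curve, n_components = 2L, half_life_max = 150) {
  stopifnot(is.data.frame(curve),
            all(c("time_min", "percent_unexchanged") %in% names(curve)))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > 3L) {
    stop("n_components must be 1, 2 or 3", call. = FALSE)
  }
  t <- curve$time_min
  y <- curve$percent_unexchanged
  if (length(t) < 2L * n_components + 2L) {
    stop("need at least ", 2L * n_components + 2L, " time points",
         call. = FALSE)
  }

  # For fixed half-lives the model is linear in the amplitudes:
  # y - 100 = sum_i a_i (E_i - 1) with E_i = exp(-ln2 t / th_i). Solving the
  # small constrained least-squares (a >= 0, sum(a) <= 100) exactly by
  # active-set enumeration profiles the amplitudes out, so the outer search
  # runs over half-lives only and cannot be derailed by amplitude plateaus.
  # Band areas carry multiplicative error, so the fit is weighted least
  # squares with weights 1/y^2 (constant relative error), the maximum-
  # likelihood weighting for the stated noise model.
  wts <- 1 / pmax(y, 1)^2
  amp_solve <- function(th) {
    E <- vapply(th, function(h) exp(-log(2) * t / h), numeric(length(t)))
    sw <- sqrt(wts)
    A <- (E - 1) * sw
    b <- (y - 100) * sw
    n <- length(th)
    best <- list(a = rep(0, n), sse = sum(b^2))
    subsets <- unlist(lapply(seq_len(n), function(k) {
      utils::combn(n, k, simplify = FALSE)
    }), recursive = FALSE)
    for (S in subsets) {
      As <- A[, S, drop = FALSE]
      AtA <- crossprod(As)
      Atb <- crossprod(As, b)
      sols <- list()
      free <- tryCatch(solve(AtA, Atb), error = function(e) NULL)
      if (!is.null(free)) sols <- c(sols, list(drop(free)))
      # boundary: amplitudes exhaust 100% (plateau = 0)
      k <- length(S)
      kkt <- tryCatch({
        M <- rbind(cbind(AtA, rep(1, k)), c(rep(1, k), 0))
        drop(solve(M, c(Atb, 100)))[seq_len(k)]
      }, error = function(e) NULL)
      if (!is.null(kkt)) sols <- c(sols, list(kkt))
      for (a_s in sols) {
        if (any(a_s < -1e-9) || sum(a_s) > 100 + 1e-9) next
        a <- rep(0, n)
        a[S] <- pmax(a_s, 0)
        sse <- sum((A %*% a - b)^2)
        if (sse < best$sse) best <- list(a = a, sse = sse)
      }
    }
    best
  }

  obj <- function(lpar) amp_solve(exp(lpar))$sse

  grid <- unique(pmin(c(3, 10, 30, 120, 480), half_life_max))
  starts <- if (n_components == 1L) {
    lapply(grid, function(g) g)
  } else if (n_components == 2L) {
    out <- list()
    for (i in seq_along(grid)) for (j in seq_along(grid)) {
      if (j > i) out[[length(out) + 1L]] <- c(grid[i], grid[j])
    }
    out
  } else {
    out <- list()
    for (i in seq_along(grid)) for (j in seq_along(grid)) for (k in seq_along(grid)) {
      if (j > i && k > j) out[[length(out) + 1L]] <- c(grid[i], grid[j], grid[k])
    }
    out
  }

  lower <- rep(log(0.1), n_components)
  upper <- rep(log(half_life_max), n_components)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(log(st), obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("exchange fit failed to converge from every start", call. = FALSE)
  }
  th <- exp(best$par)
  a <- amp_solve(th)$a
  ord <- order(th)
  a <- a[ord]; th <- th[ord]
  plateau <- 100 - sum(a)
  structure(list(amplitudes = a, half_lives = th, plateau = plateau,
                 rss = sum((y - .hdx_model(t, a, th))^2),
                 n = length(t),
                 fitted = function(tt) .hdx_model(tt, a, th)),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("<exchange_fit>\n")
  for (i in seq_along(x$amplitudes)) {
    cat(sprintf("  compartment %d: %.1f%%, t1/2 = %.1f min\n", i,
                x$amplitudes[i], x$half_lives[i]))
  }
  cat(sprintf("  plateau (non-exchanging): %.1f%%\n", x$plateau))
  invisible(x)
}

#' Unexchanged helical residues from a plateau and helix content
#'
#' `(plateau/100) * helix_residue_count(helix_fraction, n_residues)`:
#' the number of helical residues whose amide protons never exchange,
#' i.e. the bilayer-buried core of the transmembrane helix. Values below 10
#' are reported to one decimal, larger ones to the nearest integer.
#'
#' @param plateau_pct Non-exchanging plateau, %.
#' @param helix_fraction Alpha-helix fraction in `[0, 1]`.
#' @param n_residues Peptide length.
#' @return Residue count (one decimal below 10, integer otherwise).
#' @examples
#' unexchanged_helix_residues(51, 0.631, 34)    # ~11
#' unexchanged_helix_residues(23.2, 0.446, 34)  # ~3.5
#' @export
unexchanged_helix_residues <- function(plateau_pct, helix_fraction,
                                       n_residues) {
  stopifnot(plateau_pct >= 0, plateau_pct <= 100)
  v <- (plateau_pct / 100) * helix_residue_count(helix_fraction, n_residues)
  if (v < 10) round(v, 1) else round(v)
}
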