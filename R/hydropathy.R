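# Sliding-window whole-residue octanol hydropathy with an engaged/disengaged
# salt-bridge option, in the style of the MPEx transmembrane-helix predictor.

#' The Wimley-White whole-residue octanol hydropathy scale
#'
#' Per-residue water -> n-octanol transfer free energies (kcal/mol) including
#' the peptide-backbone contribution, with charged-state values for Asp, Glu,
#' Lys and Arg and neutral His (pH 7 context). Positive values oppose
#' membrane partitioning. The engaged Glu(-)-Lys(+) salt-bridge pair is
#' assigned a single small joint transfer energy (`salt_bridge_pair_dg`,
#' default +0.1 kcal/mol): formation of the electrostatically neutral ion
#' pair removes almost all of the large individual charge penalties, leaving
#' only a modest net cost.
#'
#' @param salt_bridge_pair_dg Total transfer free energy (kcal/mol) assigned
#'   to one engaged Glu-Lys pair, replacing the two individual charged-residue
#'   terms. Must be less than dG(E) + dG(K) so engagement is never penalizing.
#' @return A list of class `"hydropathy_scale"` with elements `dg` (named
#'   numeric vector over the 20 residues) and `salt_bridge_pair_dg`.
#' @export
ww_octanol_scale <- function(salt_bridge_pair_dg = 0.1) {
  dg <- c(A =  0.50, R =  1.81, N =  0.85, D =  3.64, C = -0.02,
          Q =  0.77, E =  3.63, G =  1.15, H =  0.11, I = -1.12,
          L = -1.25, K =  2.80, M = -0.67, F = -1.71, P =  0.14,
          S =  0.46, T =  0.25, W = -2.09, Y = -0.71, V = -0.46)
  hydropathy_scale(dg, salt_bridge_pair_dg)
}

#' Construct a hydropathy scale
#'
#' @param dg Named numeric vector of per-residue water->octanol transfer free
#'   energies (kcal/mol), one entry for each of the 20 standard residues.
#' @param salt_bridge_pair_dg Joint transfer energy for an engaged Glu-Lys
#'   pair (kcal/mol).
#' @return An object of class `"hydropathy_scale"`.
#' @export
hydropathy_scale <- function(dg, salt_bridge_pair_dg = 0.1) {
  stopifnot(is.numeric(dg), is.numeric(salt_bridge_pair_dg),
            length(salt_bridge_pair_dg) == 1L)
  if (!all(AA_ALPHABET %in% names(dg))) {
    stop("hydropathy scale must cover all 20 standard residues",
         call. = FALSE)
  }
  if (!all(is.finite(dg)) || !is.finite(salt_bridge_pair_dg)) {
    stop("hydropathy scale values must be finite", call. = FALSE)
  }
  if (salt_bridge_pair_dg >= dg[["E"]] + dg[["K"]]) {
    stop("salt_bridge_pair_dg must be < dG(E) + dG(K): ",
         "engagement can never be penalizing", call. = FALSE)
  }
  structure(list(dg = dg[AA_ALPHABET],
                 salt_bridge_pair_dg = salt_bridge_pair_dg),
            class = "hydropathy_scale")
}

#' Read a hydropathy scale override from YAML
#'
#' The file maps 1-letter codes to kcal/mol values and may carry a
#' `salt_bridge_pair_dg` entry; unspecified residues fall back to
#' [ww_octanol_scale()].
#' @param path YAML file.
#' @return A `"hydropathy_scale"`.
#' @export
read_scale_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- ww_octanol_scale()
  sb <- cfg$salt_bridge_pair_dg %||% base$salt_bridge_pair_dg
  cfg$salt_bridge_pair_dg <- NULL
  dg <- base$dg
  for (nm in names(cfg)) {
    if (!nm %in% AA_ALPHABET) stop("unknown residue '", nm, "' in ", path,
                                   call. = FALSE)
    dg[[nm]] <- as.numeric(cfg[[nm]])
  }
  hydropathy_scale(dg, sb)
}

# Engaged pairs fully inside [start, end]; a pair straddling the window
# boundary is treated as disengaged for that window (a bridge cannot be
# half-counted).
.pairs_in_window <- function(locks, start, end) {
  if (is.null(locks) || !locks$engaged) return(list())
  Filter(function(pr) all(pr >= start & pr <= end), locks$pairs)
}

# Window total in kcal/mol: hydropathy = -sum(dG), so favorable octanol
# partitioning is positive.
.window_total <- function(res_dg, res, start, end, locks, scale) {
  total_dg <- sum(res_dg[start:end])
  for (pr in .pairs_in_window(locks, start, end)) {
    total_dg <- total_dg - res_dg[pr[1]] - res_dg[pr[2]] +
      scale$salt_bridge_pair_dg
  }
  -total_dg
}

#' Sliding-window hydropathy profile of a peptide
#'
#' Each window total is minus the sum of per-residue water->octanol transfer
#' free energies over the window, so that higher positive values mean
#' stronger predicted lipid-bilayer partitioning. If `locks` is given and
#' engaged, any Glu-Lys pair falling entirely inside a window has its two
#' individual charged-residue terms replaced by the scale's joint
#' salt-bridge energy; a disengaged spec scores the Glu and Lys as free
#' charges.
#'
#' @param p A [peptide()].
#' @param scale A [hydropathy_scale()]; default the Wimley-White octanol
#'   scale.
#' @param window Window length in residues (default 19, roughly a
#'   bilayer-spanning helix).
#' @param locks Optional [ion_lock_spec()]; positions must hold E (anion) and
#'   K (cation) in `p`.
#' @return An object of class `"hydropathy_profile"`: a list with `peptide`,
#'   `window`, a data.frame `windows` (columns `start`, `end`, `total`), and
#'   `best_segment` (`start`, `end`, `value`).
#' @examples
#' prof <- window_hydropathy(get_fixture("rSP-C"))
#' prof$best_segment  # residues 12-30, ~11.3 kcal/mol
#' @export
window_hydropathy <- function(p, scale = ww_octanol_scale(), window = 19L,
                              locks = NULL) {
  stopifnot(inherits(p, "peptide"), inherits(scale, "hydropathy_scale"))
  window <- as.integer(window)
  n <- length(p)
  if (window < 1L || window > n) {
    stop("window length ", window, " exceeds peptide length ", n,
         call. = FALSE)
  }
  res <- residues(p)
  if (!is.null(locks)) {
    stopifnot(inherits(locks, "ion_lock_spec"))
    for (pr in locks$pairs) {
      if (any(pr > n)) stop("lock position out of bounds", call. = FALSE)
      if (res[pr[1]] != "E" || res[pr[2]] != "K") {
        stop("lock (", pr[1], ",", pr[2], ") does not reference E/K residues",
             " in '", p$id, "'", call. = FALSE)
      }
    }
  }
  res_dg <- unname(scale$dg[res])
  starts <- seq_len(n - window + 1L)
  totals <- vapply(starts, function(s) {
    .window_total(res_dg, res, s, s + window - 1L, locks, scale)
  }, numeric(1))
  windows <- data.frame(start = starts, end = starts + window - 1L,
                        total = totals)
  best <- which.max(totals)  # which.max takes the first maximum: ties break
  structure(list(peptide = p$id, window = window, windows = windows,
                 best_segment = list(start = windows$start[best],
                                     end = windows$end[best],
                                     value = windows$total[best])),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("<hydropathy_profile> %s, window %d (%d windows)\n",
              x$peptide, x$window, nrow(x$windows)))
  cat(sprintf("  best segment %d-%d: %.2f kcal/mol\n",
              x$best_segment$start, x$best_segment$end, x$best_segment$value))
  invisible(x)
}

#' Best transmembrane segment of a hydropathy profile
#'
#' @param profile A `"hydropathy_profile"` from [window_hydropathy()].
#' @return List with `start`, `end`, `value` of the window with maximal
#'   total; ties go to the smallest start.
#' @export
best_transmembrane_segment <- function(profile) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  if (nrow(profile$windows) == 0L) stop("empty profile", call. = FALSE)
  profile$best_segment
}

#' Hydropathy gain from engaging the salt bridge(s)
#'
#' Best-segment hydropathy with the locks engaged minus the best-segment
#' hydropathy with the same locks disengaged. Because engagement never
#' lowers a window total, the delta is always >= 0; it is 0 when no lock
#' pair lies inside the maximizing windows.
#'
#' @inheritParams window_hydropathy
#' @param locks An [ion_lock_spec()] (its `engaged` flag is ignored; both
#'   states are evaluated).
#' @return Numeric, kcal/mol.
#' @examples
#' engagement_delta(get_fixture("SP-Css ion-lock 1"),
#'                  locks = ion_lock_spec(list(c(20, 24))))  # ~6.3
#' @export
engagement_delta <- function(p, scale = ww_octanol_scale(), window = 19L,
                             locks) {
  stopifnot(inherits(locks, "ion_lock_spec"), length(locks$pairs) >= 1L)
  on_ <- ion_lock_spec(locks$pairs, engaged = TRUE)
  off <- ion_lock_spec(locks$pairs, engaged = FALSE)
  e <- window_hydropathy(p, scale, window, on_)$best_segment$value
  d <- window_hydropathy(p, scale, window, off)$best_segment$value
  e - d
}
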