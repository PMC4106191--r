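# Infrared spectrum container and I/O (two-column CSV/TSV, minimal JCAMP-DX).

#' Construct an infrared spectrum
#'
#' @param wavenumbers Strictly monotone grid, cm^-1.
#' @param absorbance Absorbance values (arbitrary units), same length, finite.
#' @param id Sample id.
#' @param polarization Optional polarizer angle in degrees (0 = parallel,
#'   90 = perpendicular) for polarized-ATR spectra.
#' @return An object of class `"ir_spectrum"`.
#' @export
ir_spectrum <- function(wavenumbers, absorbance, id = "",
                        polarization = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    stop("wavenumber and absorbance vectors differ in length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) stop("spectrum needs >= 2 points",
                                     call. = FALSE)
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0))) {
    stop("wavenumber grid must be strictly monotone", call. = FALSE)
  }
  if (!all(is.finite(absorbance)) || !all(is.finite(wavenumbers))) {
    stop("spectrum values must be finite", call. = FALSE)
  }
  if (d[1] < 0) {  # store ascending
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 id = id, polarization = polarization),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %s: %d points, %.1f-%.1f cm^-1%s\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              if (!is.null(x$polarization))
                sprintf(", polarization %g deg", x$polarization) else ""))
  invisible(x)
}

#' Read a spectrum from a two-column CSV/TSV file
#'
#' Column 1 = wavenumber (cm^-1), column 2 = absorbance; the delimiter is
#' inferred from the extension (`.csv` -> comma, otherwise tab/whitespace).
#' Lines starting with `#` are skipped.
#'
#' @param path File path.
#' @param id Sample id; defaults to the file name.
#' @return An `"ir_spectrum"`.
#' @export
read_spectrum <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop("no such spectrum file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           comment.char = "#",
                           col.names = c("wavenumber", "absorbance"),
                           colClasses = "numeric")
  ir_spectrum(tab$wavenumber, tab$absorbance, id = id)
}

#' Write a spectrum to a two-column file
#'
#' @param s An `"ir_spectrum"`.
#' @param path Output path (`.csv` -> comma-separated, else tab).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "ir_spectrum"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(data.frame(s$wavenumbers, s$absorbance), path,
                     sep = sep, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a JCAMP-DX infrared spectrum (minimal reader)
#'
#' Supports the two common tabular forms: `##XYDATA=(X++(Y..Y))` with
#' XFACTOR/YFACTOR/FIRSTX/LASTX/NPOINTS, and `##XYPOINTS=(XY..XY)` /
#' `##PEAK TABLE=(XY..XY)` pairs. Compressed (SQZ/DIF/DUP) encodings are not
#' supported.
#'
#' @param path JCAMP-DX file.
#' @param id Sample id; defaults to the file's `##TITLE` if present.
#' @return An `"ir_spectrum"`.
#' @export
read_jcamp <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such JCAMP file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE,
                value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^##", key, "=\\s*"), "", hit[1], ignore.case = TRUE)
  }
  id <- id %||% get_field("TITLE") %||% basename(path)
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)

  xy_start <- grep("^##(XYPOINTS|PEAK ?TABLE)=", lines, ignore.case = TRUE)
  xydata_start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  block_lines <- function(start) {
    rest <- lines[(start + 1L):length(lines)]
    stop_at <- grep("^##", rest)
    if (length(stop_at) > 0L) rest <- rest[seq_len(stop_at[1] - 1L)]
    rest[nzchar(trimws(rest))]
  }

  if (length(xy_start) > 0L) {
    body <- block_lines(xy_start[1])
    toks <- as.numeric(unlist(strsplit(paste(body, collapse = " "),
                                       "[,;[:space:]]+")))
    toks <- toks[!is.na(toks)]
    if (length(toks) < 4L || length(toks) %% 2L != 0L) {
      stop("malformed JCAMP XY table in ", path, call. = FALSE)
    }
    x <- toks[seq(1, length(toks), by = 2)]
    y <- toks[seq(2, length(toks), by = 2)]
    return(ir_spectrum(x, y, id = id))
  }
  if (length(xydata_start) > 0L) {
    xf <- num(get_field("XFACTOR"), 1)
    yf <- num(get_field("YFACTOR"), 1)
    body <- block_lines(xydata_start[1])
    ys <- list(); xs <- numeric(0)
    for (ln in body) {
      toks <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
      if (anyNA(toks)) stop("unsupported JCAMP encoding in ", path,
                            call. = FALSE)
      xs <- c(xs, toks[1])
      ys[[length(ys) + 1L]] <- toks[-1]
    }
    npts <- vapply(ys, length, integer(1))
    firstx <- num(get_field("FIRSTX"), xs[1] * xf)
    lastx <- num(get_field("LASTX"), NA_real_)
    n <- sum(npts)
    if (is.na(lastx)) stop("JCAMP XYDATA without LASTX in ", path,
                           call. = FALSE)
    x <- seq(firstx, lastx, length.out = n)
    y <- unlist(ys) * yf
    return(ir_spectrum(x, y, id = id))
  }
  stop("no XYDATA/XYPOINTS block found in JCAMP file ", path, call. = FALSE)
}

#' Subtract a scaled reference spectrum
#'
#' Pointwise `sample - scale * reference`, as used to remove the solvent or
#' hydrated-lipid background from a peptide spectrum. Grids must be
#' identical: no silent resampling.
#'
#' @param sample,reference `"ir_spectrum"` objects on the same grid.
#' @param scale Reference scale factor (default 1).
#' @return An `"ir_spectrum"`.
#' @export
subtract_reference <- function(sample, reference, scale = 1) {
  stopifnot(inherits(sample, "ir_spectrum"), inherits(reference, "ir_spectrum"))
  if (length(sample$wavenumbers) != length(reference$wavenumbers) ||
      max(abs(sample$wavenumbers - reference$wavenumbers)) > 1e-9) {
    stop("sample and reference grids differ; resample explicitly first",
         call. = FALSE)
  }
  ir_spectrum(sample$wavenumbers, sample$absorbance - scale * reference$absorbance,
              id = sample$id, polarization = sample$polarization)
}

#' Integrate a spectrum over a wavenumber window (trapezoid rule)
#'
#' @param s An `"ir_spectrum"`.
#' @param window Length-2 numeric `c(lo, hi)` in cm^-1.
#' @return The integrated area (a.u. x cm^-1).
#' @export
band_area <- function(s, window) {
  stopifnot(inherits(s, "ir_spectrum"), length(window) == 2L)
  window <- sort(as.numeric(window))
  keep <- s$wavenumbers >= window[1] & s$wavenumbers <= window[2]
  if (sum(keep) < 2L) stop("fewer than 2 points in integration window",
                           call. = FALSE)
  x <- s$wavenumbers[keep]; y <- s$absorbance[keep]
  sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
}
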