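# Sequence data model, bundled SP-C peptide fixtures, ion-lock construction.

#' Construct a peptide
#'
#' A peptide is a short (10-60 residue) amino-acid sequence in 1-letter code
#' with 1-based residue numbering, as used throughout the SP-C mimic toolkit.
#'
#' @param id Short name, e.g. `"SP-Css ion-lock 1"`.
#' @param sequence Character scalar of 1-letter codes. Lowercase is
#'   normalized to uppercase.
#' @param description Optional free text.
#' @return An object of class `"peptide"` with fields `id`, `sequence`,
#'   `description`.
#' @examples
#' peptide("toy", "GIPSSPVHLKRLLIVVVVVV")
#' @export
peptide <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("peptide '", id, "': non-standard residue code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nchar(sequence)
  if (n < 10L || n > 60L) {
    stop("peptide '", id, "': length ", n,
         " outside the 10-60 residue scope of this toolkit", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, description = description),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s (%d aa)\n  %s\n", x$id, nchar(x$sequence),
              x$sequence))
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  invisible(x)
}

#' @export
length.peptide <- function(x) nchar(x$sequence)

#' Residues of a peptide as a character vector
#' @param p A [peptide()].
#' @return Character vector of 1-letter codes, index = residue position.
#' @export
residues <- function(p) {
  stopifnot(inherits(p, "peptide"))
  strsplit(p$sequence, "")[[1]]
}

#' Specify ion-lock (salt-bridge) pairs
#'
#' An ion-lock is a Glu(-)...Lys(+) pair spaced at i, i+4 along the helix
#' (one helical turn), so the side chains can meet. Each pair records the
#' anion (Glu) and cation (Lys) positions; `engaged` states whether the
#' bridge is treated as close-range (formed) downstream.
#'
#' @param pairs A list of length-2 integer vectors `c(anion, cation)`, or a
#'   two-column matrix with columns anion, cation.
#' @param engaged Logical: treat bridges as engaged (close-range, default)
#'   or disengaged (long-range free charges).
#' @return An object of class `"ion_lock_spec"`.
#' @examples
#' ion_lock_spec(list(c(20, 24)))
#' ion_lock_spec(list(c(19, 15), c(20, 24)))  # K15/E19 has the cation first
#' @export
ion_lock_spec <- function(pairs, engaged = TRUE) {
  if (is.matrix(pairs)) pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  stopifnot(is.list(pairs), length(pairs) >= 1L, is.logical(engaged))
  pairs <- lapply(pairs, function(pr) {
    pr <- as.integer(pr)
    if (length(pr) != 2L || anyNA(pr) || any(pr < 1L)) {
      stop("each ion-lock pair must be two positive positions c(anion, cation)",
           call. = FALSE)
    }
    if (abs(pr[2] - pr[1]) != 4L) {
      stop("ion-lock spacing must be i, i+4: got positions ", pr[1], " and ",
           pr[2], call. = FALSE)
    }
    pr
  })
  pos <- unlist(pairs)
  if (anyDuplicated(pos)) {
    stop("ion-lock pairs overlap: position(s) ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "),
         " used more than once", call. = FALSE)
  }
  structure(list(pairs = pairs, engaged = isTRUE(engaged)),
            class = "ion_lock_spec")
}

#' @export
print.ion_lock_spec <- function(x, ...) {
  cat("<ion_lock_spec>", if (x$engaged) "engaged" else "disengaged", "\n")
  for (pr in x$pairs) cat(sprintf("  E%d / K%d\n", pr[1], pr[2]))
  invisible(x)
}

#' Load the bundled SP-C peptide fixtures
#'
#' Returns the suite of native SP-C proteins and SP-C mimic peptides bundled
#' with the package: human/dog/pig SP-C (35 aa), rSP-C (34 aa), SP-Css,
#' SP-Cff and their ion-lock 1 variants (34 aa), and SP-C33 UCLA with its
#' ion-lock 1 and ion-lock 2 variants (33 aa).
#'
#' @param path Optional override of the fixture TSV (columns `id`,
#'   `sequence`, `description`); defaults to the copy shipped in
#'   `inst/extdata`.
#' @return A named list of [peptide()] objects, named by id.
#' @examples
#' peps <- load_fixtures()
#' peps[["SP-Css ion-lock 1"]]
#' @export
load_fixtures <- function(path = NULL) {
  path <- path %||% system.file("extdata", "spc_peptides.tsv",
                                package = "ionlock", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    stop("fixture table not found: configuration error", call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("id", "sequence", "description")
  if (!all(needed %in% names(tab)) || nrow(tab) == 0L) {
    stop("fixture table '", path,
         "' is garbled: expected columns id, sequence, description",
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    peptide(tab$id[i], tab$sequence[i], tab$description[i])
  })
  stats::setNames(out, tab$id)
}

#' Look up one fixture peptide by id
#'
#' @param id Fixture name, e.g. `"rSP-C"`.
#' @param fixtures Optionally a pre-loaded fixture list.
#' @return A [peptide()].
#' @export
get_fixture <- function(id, fixtures = load_fixtures()) {
  if (!id %in% names(fixtures)) {
    stop("unknown peptide id '", id, "'; available: ",
         paste(names(fixtures), collapse = ", "), call. = FALSE)
  }
  fixtures[[id]]
}

#' Apply an ion-lock substitution to a peptide
#'
#' Substitutes Glu (E) at each anion position and Lys (K) at each cation
#' position of `spec`, returning a new peptide whose id carries the lock
#' annotation. Applying a spec whose positions already hold E/K is a no-op on
#' the sequence.
#'
#' @param p A [peptide()].
#' @param spec An [ion_lock_spec()]; positions must lie within `p`.
#' @return A new [peptide()].
#' @examples
#' spcss <- get_fixture("SP-Css")
#' apply_ion_lock(spcss, ion_lock_spec(list(c(20, 24))))
#' @export
apply_ion_lock <- function(p, spec) {
  stopifnot(inherits(p, "peptide"), inherits(spec, "ion_lock_spec"))
  res <- residues(p)
  n <- length(res)
  for (pr in spec$pairs) {
    if (any(pr > n)) {
      stop("ion-lock position ", max(pr), " out of bounds for '", p$id,
           "' (", n, " aa)", call. = FALSE)
    }
    res[pr[1]] <- "E"
    res[pr[2]] <- "K"
  }
  ann <- paste(vapply(spec$pairs, function(pr) {
    sprintf("E%d/K%d", pr[1], pr[2])
  }, character(1)), collapse = "; ")
  peptide(paste0(p$id, "(", ann, ")"), paste(res, collapse = ""),
          p$description)
}

#' Read peptides from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` with the package's
#' validation rules: lowercase is normalized to uppercase and any character
#' outside the 20 standard codes (including `X`) is rejected.
#'
#' @param path FASTA file path.
#' @return Named list of [peptide()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop("malformed FASTA '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) stop("FASTA '", path, "' contains no records",
                              call. = FALSE)
  # the whole header line is the id: fixture names contain spaces and the
  # round-trip contract preserves ids exactly
  ids <- names(set)
  out <- lapply(seq_along(set), function(i) {
    peptide(ids[i], as.character(set[[i]]))
  })
  stats::setNames(out, ids)
}

#' Write peptides to a FASTA file
#'
#' @param peptides A list of [peptide()] objects (or a single peptide).
#' @param path Output path.
#' @return `path`, invisibly. Round-trips exactly with [read_fasta()].
#' @export
write_fasta <- function(peptides, path) {
  if (inherits(peptides, "peptide")) peptides <- list(peptides)
  stopifnot(all(vapply(peptides, inherits, logical(1), "peptide")))
  seqs <- Biostrings::AAStringSet(vapply(peptides, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- vapply(peptides, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
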