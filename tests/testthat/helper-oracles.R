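# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with plain loops and never call the implementation path
# they check.

# Window hydropathy by direct per-residue summation.
oracle_window_hydropathy <- function(sequence, dg, window, locks = NULL,
                                     pair_dg = 0.1) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  totals <- numeric(n - window + 1)
  for (s in seq_along(totals)) {
    e <- s + window - 1
    tot <- 0
    for (i in s:e) tot <- tot + dg[[res[i]]]
    if (!is.null(locks) && isTRUE(locks$engaged)) {
      for (pr in locks$pairs) {
        if (all(pr >= s & pr <= e)) {
          tot <- tot - dg[[res[pr[1]]]] - dg[[res[pr[2]]]] + pair_dg
        }
      }
    }
    totals[s] <- -tot
  }
  totals
}

# Pairing energy by explicit position loop.
oracle_score_pairing <- function(a_chars, b_chars, orientation, par_m,
                                 anti_m) {
  L <- length(a_chars)
  total <- 0
  for (i in seq_len(L)) {
    j <- if (orientation == "parallel") i else L + 1 - i
    m <- if (orientation == "parallel") par_m else anti_m
    total <- total + m[a_chars[i], b_chars[j]]
  }
  total
}

# Exhaustive enumeration of all equal-length segment pairings.
oracle_enumerate <- function(seq_a, seq_b, min_len, par_m, anti_m) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  rows <- list()
  for (L in seq.int(min_len, min(length(a), length(b)))) {
    for (as_ in seq_len(length(a) - L + 1)) {
      for (bs in seq_len(length(b) - L + 1)) {
        ra <- a[as_:(as_ + L - 1)]
        rb <- b[bs:(bs + L - 1)]
        for (orient in c("parallel", "antiparallel")) {
          rows[[length(rows) + 1]] <- data.frame(
            a_start = as_, a_end = as_ + L - 1, b_start = bs,
            b_end = bs + L - 1, orientation = orient,
            energy = oracle_score_pairing(ra, rb, orient, par_m, anti_m))
        }
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out[order(round(out$energy, 9), out$a_start,
            match(out$orientation, c("parallel", "antiparallel")),
            out$b_start), ]
}

random_peptide_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(ionlock:::AA_ALPHABET, n,
                                      replace = TRUE), collapse = ""))
}
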