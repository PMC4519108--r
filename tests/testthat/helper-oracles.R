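# Independent brute-force oracles for property tests. These deliberately
# use a different decomposition from the package internals: the repeat
# oracle compares motif-sized blocks with vectorized substring equality
# and per-candidate while-loops; the package scanner uses lagged raw-byte
# comparison with run-length encoding.

oracle_ssrs <- function(seq, min_p = 2L, max_p = 7L, min_len = 20L,
                        forbid_N = TRUE) {
  n <- nchar(seq)
  out <- list()
  for (p in min_p:max_p) {
    if (n < 2L * p) next
    starts <- 1:(n - 2L * p + 1L)
    b1 <- substring(seq, starts, starts + p - 1L)
    b2 <- substring(seq, starts + p, starts + 2L * p - 1L)
    cand <- starts[b1 == b2]
    for (i in cand) {
      # region-start: cannot shift one base left
      if (i > 1L && substr(seq, i - 1L, i - 1L) ==
            substr(seq, i + p - 1L, i + p - 1L)) next
      motif <- substr(seq, i, i + p - 1L)
      # primitive motif only (otherwise reported at the true period)
      primitive <- TRUE
      for (d in 1:(p - 1L)) {
        if (p %% d == 0L && strrep(substr(motif, 1L, d), p / d) == motif) {
          primitive <- FALSE
          break
        }
      }
      if (!primitive) next
      copies <- 2L
      j <- i + 2L * p
      while (j + p - 1L <= n && substr(seq, j, j + p - 1L) == motif) {
        copies <- copies + 1L
        j <- j + p
      }
      trailing <- 0L
      while (j + trailing <= n &&
             substr(seq, j + trailing, j + trailing) ==
               substr(motif, trailing + 1L, trailing + 1L)) {
        trailing <- trailing + 1L
      }
      tract_len <- copies * p
      if (tract_len < min_len) next
      if (forbid_N &&
          grepl("N", substr(seq, i, i + tract_len + trailing - 1L),
                fixed = TRUE)) next
      out[[length(out) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + tract_len, period = p,
        motif = motif, copies = copies, tract_len = tract_len,
        trailing_bp = trailing, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      period = integer(), motif = character(),
                      copies = integer(), tract_len = integer(),
                      trailing_bp = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$period), , drop = FALSE]
}

# smallest length L in the multiset whose >=L cumulative sum reaches half
# the total, by trying every distinct length
oracle_n50 <- function(lens) {
  half <- sum(lens) / 2
  cands <- sort(unique(lens))
  ok <- vapply(cands, function(L) sum(lens[lens >= L]) >= half, TRUE)
  max(cands[ok])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_dna_seeded <- function(n, seed) {
  withr::with_seed(seed, random_dna(n))
}
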