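#' Primer design constraints
#'
#' Conventional constraint set for SSR genotyping primers. All values are
#' configurable; panel contracts never depend on specific primer sequences.
#'
#' @param len_range Primer length bounds in bp.
#' @param tm_range Melting-temperature bounds in degrees Celsius
#'   (nearest-neighbor model, see [tm_nn()]).
#' @param gc_range GC-fraction bounds.
#' @param max_homopolymer Longest allowed single-base run inside a primer.
#' @param product_range Amplicon length bounds in bp.
#' @param flank_window How far from the tract (bp) primers may be sought;
#'   bounds the candidate search.
#' @return A list of class `primer_config`.
#' @export
primer_config <- function(len_range = c(18L, 24L),
                          tm_range = c(55, 62),
                          gc_range = c(0.40, 0.60),
                          max_homopolymer = 4L,
                          product_range = c(100L, 400L),
                          flank_window = 200L) {
  stopifnot(length(len_range) == 2L, len_range[1] <= len_range[2],
            length(tm_range) == 2L, tm_range[1] <= tm_range[2],
            length(gc_range) == 2L, gc_range[1] <= gc_range[2],
            length(product_range) == 2L, product_range[1] <= product_range[2],
            max_homopolymer >= 1L, flank_window >= len_range[2])
  structure(
    list(len_range = as.integer(len_range), tm_range = as.numeric(tm_range),
         gc_range = as.numeric(gc_range),
         max_homopolymer = as.integer(max_homopolymer),
         product_range = as.integer(product_range),
         flank_window = as.integer(flank_window)),
    class = "primer_config"
  )
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K), 5'->3' stacks.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature under the unified nearest-neighbor
#' thermodynamic model with initiation terms, a monovalent-salt
#' correction of `16.6 log10[Na+]`, and primer concentration `conc_nM`
#' (Tm = dH / (dS + R ln(C/4)) in Kelvin).
#'
#' @param seq Primer sequence(s), `{A,C,G,T}`.
#' @param na_mM Monovalent cation concentration, mM.
#' @param conc_nM Primer concentration, nM.
#' @return Melting temperature(s) in degrees Celsius.
#' @export
tm_nn <- function(seq, na_mM = 50, conc_nM = 250) {
  vapply(toupper(seq), function(s) {
    n <- nchar(s)
    stopifnot(n >= 2L, !grepl("[^ACGT]", s))
    stacks <- substring(s, seq_len(n - 1L), 2:n)
    dh <- sum(NN_DH[stacks])
    ds <- sum(NN_DS[stacks])
    # initiation: terminal G/C 0.1/-2.8, terminal A/T 2.3/4.1
    for (term in c(substr(s, 1L, 1L), substr(s, n, n))) {
      if (term %in% c("G", "C")) {
        dh <- dh + 0.1; ds <- ds - 2.8
      } else {
        dh <- dh + 2.3; ds <- ds + 4.1
      }
    }
    tm_k <- dh * 1000 / (ds + 1.987 * log(conc_nM * 1e-9 / 4))
    tm_k - 273.15 + 16.6 * log10(na_mM / 1000)
  }, 0, USE.NAMES = FALSE)
}

#' Wallace (2+4) rule melting temperature
#'
#' `Tm = 2 (A+T) + 4 (G+C)`; the classical back-of-envelope estimate,
#' kept as an independent cross-check of [tm_nn()].
#'
#' @inheritParams tm_nn
#' @return Temperature(s) in degrees Celsius.
#' @export
tm_wallace <- function(seq) {
  s <- toupper(seq)
  gc <- stringr::str_count(s, "[GC]")
  at <- stringr::str_count(s, "[AT]")
  2 * at + 4 * gc
}

max_homopolymer_run <- function(seq) {
  vapply(seq, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, 0L, USE.NAMES = FALSE)
}

gc_fraction <- function(seq) {
  stringr::str_count(seq, "[GC]") / nchar(seq)
}

# All constraint-passing primer candidates on the plus strand of `seq`
# whose 5' start lies in [from, to] (1-based). Returns start/len/seq/tm.
candidate_primers <- function(seq, from, to, config) {
  lens <- config$len_range[1]:config$len_range[2]
  grid <- expand.grid(start = from:to, len = lens)
  grid <- grid[grid$start + grid$len - 1L <= nchar(seq), , drop = FALSE]
  if (nrow(grid) == 0L) return(NULL)
  grid$seq <- substring(seq, grid$start, grid$start + grid$len - 1L)
  grid <- grid[!grepl("N", grid$seq, fixed = TRUE), , drop = FALSE]
  if (nrow(grid) == 0L) return(NULL)
  gc <- gc_fraction(grid$seq)
  keep <- gc >= config$gc_range[1] & gc <= config$gc_range[2] &
    max_homopolymer_run(grid$seq) <= config$max_homopolymer
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L) return(NULL)
  grid$tm <- tm_nn(grid$seq)
  grid <- grid[grid$tm >= config$tm_range[1] & grid$tm <= config$tm_range[2], ,
               drop = FALSE]
  if (nrow(grid) == 0L) return(NULL)
  grid
}

#' Design a primer pair flanking one SSR locus
#'
#' Searches both flanks of the tract for primers satisfying the
#' configuration (length, Tm, GC, homopolymer, product size) whose
#' amplicon contains the full tract, and returns the best-scoring pair:
#' minimal forward/reverse Tm difference, then minimal product length,
#' with positional tie-breaks so the result is deterministic. Failure to
#' design (insufficient or unsuitable flank) returns `NULL`, an expected
#' outcome for a substantial fraction of loci.
#'
#' @param record One row of a sequence tibble (or a list with `id`, `seq`).
#' @param locus One row of a locus tibble from [find_ssrs()].
#' @param config A [primer_config()].
#' @return A one-row tibble (`fwd_seq`, `rev_seq`, `fwd_start`,
#'   `rev_start`, `tm_fwd`, `tm_rev`, `product_len`) or `NULL`. Positions
#'   are 0-based positions of each primer's 5' base on the plus strand
#'   (for the reverse primer, the 5' base is the rightmost template base).
#' @export
design_primers <- function(record, locus, config = primer_config()) {
  seq <- record$seq[1]
  if (record$id[1] != locus$seq_id[1]) {
    stop("locus ", locus$seq_id[1], " does not lie on record ",
         record$id[1], call. = FALSE)
  }
  n <- nchar(seq)
  tract_start1 <- locus$start[1] + 1L   # 1-based first tract base
  tract_end1 <- locus$end[1]            # 1-based last tract base
  if (tract_end1 > n) stop("locus extends beyond record", call. = FALSE)
  min_len <- config$len_range[1]
  if (tract_start1 - 1L < min_len || n - tract_end1 < min_len) return(NULL)

  fwd_from <- max(1L, tract_start1 - config$flank_window)
  fwd <- candidate_primers(seq, fwd_from, tract_start1 - min_len, config)
  if (is.null(fwd)) return(NULL)
  fwd <- fwd[fwd$start + fwd$len - 1L < tract_start1, , drop = FALSE]
  if (nrow(fwd) == 0L) return(NULL)

  rev_to <- min(n, tract_end1 + config$flank_window)
  rev <- candidate_primers(seq, tract_end1 + 1L, rev_to, config)
  if (is.null(rev)) return(NULL)

  # amplicon runs from the forward primer's 5' base to the reverse
  # primer's 5' base (rightmost template base)
  best <- NULL
  for (i in seq_len(nrow(fwd))) {
    f <- fwd[i, ]
    r_end <- rev$start + rev$len - 1L          # rev primer 5' base (plus strand)
    prod <- r_end - f$start + 1L
    ok <- prod >= config$product_range[1] & prod <= config$product_range[2]
    if (!any(ok)) next
    cand <- rev[ok, , drop = FALSE]
    cand_prod <- prod[ok]
    dt <- abs(cand$tm - f$tm)
    ord <- order(dt, cand_prod, cand$start, cand$len)
    j <- ord[1L]
    score <- c(dt[j], cand_prod[j], f$start, f$len, cand$start[j], cand$len[j])
    if (is.null(best) || score_less(score, best$score)) {
      best <- list(score = score, f = f, r = cand[j, ], prod = cand_prod[j])
    }
  }
  if (is.null(best)) return(NULL)
  f <- best$f; r <- best$r
  rev_5prime <- r$start + r$len - 1L
  tibble::tibble(
    fwd_seq = f$seq,
    rev_seq = revcomp(r$seq),
    fwd_start = f$start - 1L,
    rev_start = rev_5prime - 1L,
    tm_fwd = f$tm,
    tm_rev = r$tm,
    product_len = best$prod
  )
}

score_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Design primers for every locus in a panel
#'
#' Maps [design_primers()] over a locus table, producing marker candidates.
#' Loci for which no constraint-satisfying pair exists are retained with
#' `primer_ok = FALSE` so design-failure counts can be reported.
#'
#' @param seqs Sequence tibble containing every `seq_id` in `loci`.
#' @param loci Locus tibble from [find_ssrs()].
#' @param config A [primer_config()].
#' @return `loci` with primer columns appended and a `primer_ok` flag.
#' @export
design_panel <- function(seqs, loci, config = primer_config()) {
  check_seq_tbl(seqs)
  seq_map <- stats::setNames(seqs$seq, seqs$id)
  missing <- setdiff(unique(loci$seq_id), names(seq_map))
  if (length(missing) > 0L) {
    stop("loci reference unknown sequence id(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  primer_rows <- purrr::map(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    rec <- list(id = locus$seq_id, seq = seq_map[[locus$seq_id]])
    pp <- design_primers(rec, locus, config)
    if (is.null(pp)) {
      tibble::tibble(fwd_seq = NA_character_, rev_seq = NA_character_,
                     fwd_start = NA_integer_, rev_start = NA_integer_,
                     tm_fwd = NA_real_, tm_rev = NA_real_,
                     product_len = NA_integer_, primer_ok = FALSE)
    } else {
      dplyr::mutate(pp, primer_ok = TRUE)
    }
  })
  dplyr::bind_cols(loci, dplyr::bind_rows(primer_rows))
}

count_occurrences <- function(pattern, subjects) {
  sum(vapply(subjects, function(s) {
    hits <- gregexpr(pattern, s, fixed = TRUE)[[1]]
    sum(hits > 0L)
  }, 0L, USE.NAMES = FALSE))
}

#' Screen marker candidates for primer uniqueness
#'
#' A candidate is unique iff neither primer occurs (as an exact substring,
#' on either strand) more than once across the background contig set. A
#' primer necessarily occurs once at its own locus; any further occurrence
#' disqualifies the pair, since PCR could then amplify off-target.
#'
#' @param candidates Marker-candidate tibble from [design_panel()] (rows
#'   with `primer_ok = FALSE` are dropped).
#' @param background Sequence tibble to count occurrences in (typically the
#'   full enriched contig set).
#' @return The candidates with a `unique` flag, filtered to `unique = TRUE`.
#'   The full flagged table is available as attribute `"screened"`.
#' @export
uniqueness_screen <- function(candidates, background) {
  check_seq_tbl(background, "background")
  if (nrow(background) == 0L) stop("background must be non-empty", call. = FALSE)
  cand <- dplyr::filter(candidates, .data$primer_ok)
  if (nrow(cand) == 0L) {
    out <- dplyr::mutate(cand, unique = logical(0))
    attr(out, "screened") <- out
    return(out)
  }
  subjects <- background$seq
  occ <- function(p) {
    rc <- revcomp(p)
    n <- count_occurrences(p, subjects)
    if (rc != p) n <- n + count_occurrences(rc, subjects)
    n
  }
  n_fwd <- vapply(cand$fwd_seq, occ, 0L, USE.NAMES = FALSE)
  n_rev <- vapply(cand$rev_seq, occ, 0L, USE.NAMES = FALSE)
  flagged <- dplyr::mutate(cand, unique = n_fwd <= 1L & n_rev <= 1L)
  out <- dplyr::filter(flagged, .data$unique)
  attr(out, "screened") <- flagged
  out
}
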