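#' Configuration for cross-genotype contig matching
#'
#' @param max_evalue Maximum expectation value for retained alignment rows
#'   (default 1e-9, the conventional cutoff for cross-assembly nucleotide
#'   homology searches).
#' @param min_identity Minimum percent identity for the internal matcher.
#' @param min_aln_len Minimum alignment length (bp) for the internal
#'   matcher.
#' @param flank_tol Tolerance (bp) when mapping a tract midpoint through an
#'   alignment to its counterpart; absorbs small indels in the flanks.
#' @param seed_k Exact-seed length (bp) for the internal matcher.
#' @return A list of class `compare_config`.
#' @export
compare_config <- function(max_evalue = 1e-9, min_identity = 90,
                           min_aln_len = 100L, flank_tol = 10L,
                           seed_k = 21L) {
  stopifnot(max_evalue > 0, min_identity > 0, min_aln_len > 0,
            flank_tol > 0, seed_k > 0)
  structure(
    list(max_evalue = max_evalue, min_identity = min_identity,
         min_aln_len = as.integer(min_aln_len),
         flank_tol = as.integer(flank_tol), seed_k = as.integer(seed_k)),
    class = "compare_config"
  )
}

MATCH_COLS <- c("query_id", "subject_id", "pct_identity", "aln_len",
                "mismatches", "gap_opens", "q_start", "q_end",
                "s_start", "s_end", "evalue", "bitscore")

empty_match_tbl <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(),
    pct_identity = numeric(), aln_len = integer(),
    mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bitscore = numeric()
  )
}

#' Load a 12-column tabular pairwise-alignment file
#'
#' Reads the standard 12-column tab-separated alignment dialect
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, E-value, bit score; subject
#' start greater than subject end marks a minus-strand hit). Rows whose
#' E-value exceeds `config$max_evalue` are discarded.
#'
#' @param path Path to the tabular alignment file (no header).
#' @param config A [compare_config()].
#' @return A tibble of match rows: `query_id`, `subject_id`,
#'   `pct_identity`, `aln_len`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.
#' @export
load_match_table <- function(path, config = compare_config()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(empty_match_tbl())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("malformed alignment row at line ", bad, ": expected 12 fields, got ",
         nf[bad], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2L, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1L)
  bad_num <- which(rowSums(is.na(num)) > 0L)
  if (length(bad_num) > 0L) {
    stop("malformed alignment row at line ", bad_num[1L],
         ": non-numeric field", call. = FALSE)
  }
  out <- tibble::tibble(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = num[, 1L], aln_len = as.integer(num[, 2L]),
    mismatches = as.integer(num[, 3L]), gap_opens = as.integer(num[, 4L]),
    q_start = as.integer(num[, 5L]), q_end = as.integer(num[, 6L]),
    s_start = as.integer(num[, 7L]), s_end = as.integer(num[, 8L]),
    evalue = num[, 9L], bitscore = num[, 10L]
  )
  dplyr::filter(out, .data$evalue <= config$max_evalue)
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

# low-complexity seed mask: TRUE for k-mers that are periodic with period
# <= max_p (k-mers inside a repeat tract), which would seed spurious
# matches between unrelated contigs sharing a motif
is_periodic_kmer <- function(kmers, max_p = 7L) {
  vapply(kmers, function(km) {
    ch <- charToRaw(km)
    n <- length(ch)
    for (p in seq_len(min(max_p, n - 1L))) {
      if (all(ch[seq_len(n - p)] == ch[(p + 1L):n])) return(TRUE)
    }
    FALSE
  }, TRUE, USE.NAMES = FALSE)
}

# per-start mask of repeat-dominated or N-containing k-mer windows.
# A seed must be anchored by at least MIN_SEED_ANCHOR bases lying outside
# any short-period repeat region, otherwise two unrelated contigs sharing
# a motif would seed a tract-only "alignment" (a repeat tract plus a
# coincidentally equal boundary base can reach min_aln_len on its own).
MIN_SEED_ANCHOR <- 6L

masked_kmer_starts <- function(seq, k, max_p = 7L, min_region = 12L) {
  n <- nchar(seq)
  n_starts <- n - k + 1L
  if (n_starts < 1L) return(logical(0))
  ch <- charToRaw(seq)
  covered <- rep(FALSE, n)          # base lies inside a repeat region
  for (p in seq_len(max_p)) {
    if (n <= p) break
    m <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths + p >= min_region)
    for (j in hit) {
      covered[starts[j]:(ends[j] + p)] <- TRUE
    }
  }
  covered <- covered | ch == charToRaw("N")
  cs <- c(0L, cumsum(as.integer(covered)))
  win_cov <- cs[(k + 1L):(n + 1L)] - cs[seq_len(n_starts)]
  win_cov > k - MIN_SEED_ANCHOR
}

# tibble of unmasked k-mers for a set of sequences
kmer_table <- function(ids, seqs, k) {
  purrr::map2(ids, seqs, function(id, s) {
    km <- seq_kmers(s, k)
    if (length(km) == 0L) return(NULL)
    keep <- !masked_kmer_starts(s, k)
    if (!any(keep)) return(NULL)
    tibble::tibble(id = id, pos = which(keep), kmer = km[keep])
  }) |> dplyr::bind_rows()
}

# count matching bases between q[q_from..q_to] and s[q_from+off..q_to+off]
segment_matches <- function(q, s, q_from, q_to, off) {
  qi <- charToRaw(substr(q, q_from, q_to))
  si <- charToRaw(substr(s, q_from + off, q_to + off))
  sum(qi == si)
}

#' Match contig sets with an internal seed-and-extend aligner
#'
#' Self-contained substitute for an external nucleotide homology search so
#' that the pipeline runs with no external tool. Exact `seed_k`-mer seeds
#' index the subject set on both strands; low-complexity (periodic) seeds
#' are masked so that unrelated contigs sharing a repeat motif do not
#' match through their tracts. For each query/subject pair the
#' seed-supported diagonals are turned into ungapped segments and merged
#' into one alignment row whose endpoints span all segments — the
#' equivalent of a gapped alignment whose single gap sits between
#' diagonals, which is exactly what a repeat-length difference between
#' two otherwise homologous contigs produces. Pairs reaching
#' `min_identity` (matches over summed segment length) and `min_aln_len`
#' are emitted; `evalue` is 0 as a sentinel for internally generated
#' matches. Deterministic.
#'
#' @param p1,p2 Sequence tibbles (query and subject sets).
#' @param config A [compare_config()].
#' @return A match tibble in the same shape as [load_match_table()]'s
#'   output; minus-strand hits have `s_start > s_end`.
#' @export
internal_match <- function(p1, p2, config = compare_config()) {
  check_seq_tbl(p1, "p1"); check_seq_tbl(p2, "p2")
  if (nrow(p1) == 0L || nrow(p2) == 0L) {
    stop("both contig sets must be non-empty", call. = FALSE)
  }
  k <- config$seed_k
  # subject index over both strands, low-complexity seeds masked
  rc_seq <- stats::setNames(revcomp(p2$seq), p2$id)
  idx <- dplyr::bind_rows(
    dplyr::mutate(kmer_table(p2$id, p2$seq, k), strand = "+"),
    dplyr::mutate(kmer_table(p2$id, unname(rc_seq), k), strand = "-")
  )
  names(idx)[names(idx) == "id"] <- "subject"
  names(idx)[names(idx) == "pos"] <- "s_pos"
  s_len <- stats::setNames(nchar(p2$seq), p2$id)
  s_seq <- stats::setNames(p2$seq, p2$id)
  q_seq <- stats::setNames(p1$seq, p1$id)

  qt <- kmer_table(p1$id, p1$seq, k)
  if (nrow(qt) == 0L || nrow(idx) == 0L) return(empty_match_tbl())
  names(qt) <- c("query", "qpos", "kmer")
  qt <- qt[!duplicated(qt[c("query", "kmer")]), , drop = FALSE]
  hits <- dplyr::inner_join(idx, qt, by = "kmer",
                            relationship = "many-to-many")
  if (nrow(hits) == 0L) return(empty_match_tbl())
  hits$offset <- hits$s_pos - hits$qpos
  # one ungapped segment per seed-supported diagonal of each
  # query/subject/strand combination
  all_segs <- dplyr::summarise(
    dplyr::group_by(hits, .data$query, .data$subject, .data$strand,
                    .data$offset),
    q_from = min(.data$qpos), q_to = max(.data$qpos) + k - 1L,
    support = dplyr::n(), .groups = "drop"
  )
  groups <- split(all_segs,
                  paste(all_segs$query, all_segs$subject, all_segs$strand,
                        sep = "\r"))

  rows <- list()
  for (segs in groups) {
    qid <- segs$query[1L]
    sid <- segs$subject[1L]
    minus <- segs$strand[1L] == "-"
    qseq <- q_seq[[qid]]; nq <- nchar(qseq)
    ns <- s_len[[sid]]
    stmpl <- if (minus) rc_seq[[sid]] else s_seq[[sid]]
    {
      # stray repeated seeds make singleton diagonals; drop them unless
      # the pair has nothing better
      if (any(segs$support >= 2L)) {
        segs <- segs[segs$support >= 2L, , drop = FALSE]
      }
      segs <- dplyr::arrange(segs, .data$q_from, .data$offset)
      # truncate overlapping segments so q intervals are disjoint
      aln_len <- 0L; matches <- 0L
      q_start <- NA_integer_; q_end <- NA_integer_
      s_start <- NA_integer_; s_end <- NA_integer_
      prev_end <- 0L
      for (j in seq_len(nrow(segs))) {
        q_from <- max(segs$q_from[j], prev_end + 1L, 1L - segs$offset[j])
        q_to <- min(segs$q_to[j], nq, ns - segs$offset[j])
        if (q_to < q_from) next
        seg_m <- segment_matches(qseq, stmpl, q_from, q_to, segs$offset[j])
        seg_len <- q_to - q_from + 1L
        # a diagonal whose own segment falls below the identity floor is
        # a seed artifact, not homology
        if (100 * seg_m / seg_len < config$min_identity) next
        matches <- matches + seg_m
        aln_len <- aln_len + seg_len
        if (is.na(q_start)) {
          q_start <- q_from
          s_start <- q_from + segs$offset[j]
        }
        q_end <- q_to
        s_end <- q_to + segs$offset[j]
        prev_end <- q_to
      }
      if (aln_len == 0L) next
      pid <- 100 * matches / aln_len
      if (pid < config$min_identity || aln_len < config$min_aln_len) next
      if (minus) {
        s_start <- ns - s_start + 1L
        s_end <- ns - s_end + 1L
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        query_id = qid, subject_id = sid, pct_identity = pid,
        aln_len = aln_len,
        mismatches = aln_len - matches,
        gap_opens = max(0L, nrow(segs) - 1L),
        q_start = q_start, q_end = q_end,
        s_start = s_start, s_end = s_end,
        evalue = 0, bitscore = 2 * matches
      )
    }
  }
  if (length(rows) == 0L) {
    return(empty_match_tbl())
  }
  dplyr::bind_rows(rows)
}

# Map a 1-based query coordinate through an alignment row to subject
# coordinates by linear interpolation (exact for ungapped alignments).
map_through_alignment <- function(q_pos, row) {
  span_q <- row$q_end - row$q_start
  span_s <- row$s_end - row$s_start
  frac <- if (span_q == 0) 0 else (q_pos - row$q_start) / span_q
  row$s_start + frac * span_s
}

#' Pair shared SSRs across genotypes and call polymorphism
#'
#' For each genotype-1 SSR, finds its counterpart in genotype 2 through
#' the contig match table: the counterpart must share the canonical motif
#' (reverse-complement canonicalized for minus-strand hits) and its tract
#' midpoint, mapped through the alignment, must lie within `flank_tol` bp
#' of the genotype-2 tract midpoint. Match rows for a contig are tried in
#' order (smallest E-value, then highest identity, then lexicographic
#' subject id); the first row yielding a correspondence determines the
#' call. Verdicts follow the repeat-length rule: a tract-length difference
#' of at least one motif period is `polymorphic`, a smaller difference is
#' `monomorphic`, and an SSR with no qualifying counterpart is `no_match`.
#'
#' @param matches Match tibble ([load_match_table()] / [internal_match()]).
#' @param ssrs_p1,ssrs_p2 Locus tibbles from [find_ssrs()] for the two
#'   genotypes.
#' @param config A [compare_config()].
#' @param known_ids Optional character vector of valid contig ids (both
#'   genotypes); match rows referencing ids outside it raise an error.
#' @return A tibble of calls: `p1_seq_id`, `p2_seq_id`, `motif`,
#'   `p1_tract_len`, `p2_tract_len`, `period`, `verdict`, plus the p1 locus
#'   coordinates (`p1_start`, `p1_end`). One row per genotype-1 SSR.
#' @export
pair_ssrs <- function(matches, ssrs_p1, ssrs_p2, config = compare_config(),
                      known_ids = NULL) {
  if (!is.null(known_ids)) {
    unknown <- setdiff(unique(c(matches$query_id, matches$subject_id)),
                       known_ids)
    if (length(unknown) > 0L) {
      stop("match table references unknown sequence id(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(ssrs_p1) == 0L) {
    return(tibble::tibble(
      p1_seq_id = character(), p2_seq_id = character(), motif = character(),
      p1_tract_len = integer(), p2_tract_len = integer(), period = integer(),
      verdict = character(), p1_start = integer(), p1_end = integer()
    ))
  }
  p2_by_id <- split(ssrs_p2, ssrs_p2$seq_id)
  calls <- purrr::map(seq_len(nrow(ssrs_p1)), function(i) {
    locus <- ssrs_p1[i, ]
    no_match <- tibble::tibble(
      p1_seq_id = locus$seq_id, p2_seq_id = NA_character_,
      motif = canonical_motif(locus$motif),
      p1_tract_len = locus$tract_len, p2_tract_len = NA_integer_,
      period = locus$period, verdict = "no_match",
      p1_start = locus$start, p1_end = locus$end
    )
    rows <- matches[matches$query_id == locus$seq_id, , drop = FALSE]
    if (nrow(rows) == 0L) return(no_match)
    rows <- rows[order(rows$evalue, -rows$pct_identity, rows$subject_id), ,
                 drop = FALSE]
    mid_q <- (locus$start + locus$end) / 2 + 0.5  # 1-based midpoint
    motif1 <- canonical_motif(locus$motif)
    for (j in seq_len(nrow(rows))) {
      row <- rows[j, ]
      minus <- row$s_start > row$s_end
      cand <- p2_by_id[[row$subject_id]]
      if (is.null(cand) || nrow(cand) == 0L) next
      motif2 <- canonical_motif(cand$motif,
                                if (minus) "minus" else "plus")
      mid_s <- map_through_alignment(mid_q, row)
      mid2 <- (cand$start + cand$end) / 2 + 0.5
      ok <- motif2 == motif1 & abs(mid2 - mid_s) <= config$flank_tol
      if (!any(ok)) next
      hit <- cand[which(ok)[which.min(abs(mid2[ok] - mid_s))], ]
      delta <- abs(locus$tract_len - hit$tract_len)
      return(tibble::tibble(
        p1_seq_id = locus$seq_id, p2_seq_id = row$subject_id,
        motif = motif1,
        p1_tract_len = locus$tract_len, p2_tract_len = hit$tract_len,
        period = locus$period,
        verdict = if (delta >= locus$period) "polymorphic" else "monomorphic",
        p1_start = locus$start, p1_end = locus$end
      ))
    }
    no_match
  })
  dplyr::bind_rows(calls)
}

#' Strand-insensitive canonical motif class
#'
#' The lexicographically smaller of a motif's plus- and minus-strand
#' canonical forms, so that homologous tracts compare equal regardless of
#' which strand either assembly stored them on.
#'
#' @param motif Motif string(s).
#' @return Canonical class representative(s).
#' @export
motif_strand_class <- function(motif) {
  pmin(canonical_motif(motif, "plus"), canonical_motif(motif, "minus"))
}

#' Reconcile reciprocal comparison directions
#'
#' The final marker panel keeps only SSR pairs called polymorphic in both
#' search directions (genotype 1 vs 2 and 2 vs 1); asymmetric best-hit
#' artifacts are thereby removed. Per-direction verdict counts are
#' retained for reporting.
#'
#' @param calls_1v2 Calls from [pair_ssrs()] with genotype 1 as query.
#' @param calls_2v1 Calls with genotype 2 as query (its `p1_*` columns
#'   refer to genotype 2; they are re-oriented internally).
#' @return An object of class `ssr_comparison`: the reconciled polymorphic
#'   call tibble, with per-direction count tables retained for [glance()].
#' @export
bidirectional_reconcile <- function(calls_1v2, calls_2v1) {
  key <- function(a, b, motif) paste(a, b, motif, sep = "\r")
  poly1 <- dplyr::filter(calls_1v2, .data$verdict == "polymorphic")
  poly2 <- dplyr::filter(calls_2v1, .data$verdict == "polymorphic")
  k1 <- key(poly1$p1_seq_id, poly1$p2_seq_id,
            if (nrow(poly1)) motif_strand_class(poly1$motif) else character(0))
  k2 <- key(poly2$p2_seq_id, poly2$p1_seq_id,
            if (nrow(poly2)) motif_strand_class(poly2$motif) else character(0))
  final <- poly1[k1 %in% k2, , drop = FALSE]
  direction_counts <- dplyr::bind_rows(
    dplyr::count(calls_1v2, .data$verdict) |>
      dplyr::mutate(direction = "1v2"),
    dplyr::count(calls_2v1, .data$verdict) |>
      dplyr::mutate(direction = "2v1")
  ) |>
    tidyr::pivot_wider(names_from = "verdict", values_from = "n",
                       values_fill = 0L)
  structure(
    list(panel = final, calls_1v2 = calls_1v2, calls_2v1 = calls_2v1,
         direction_counts = direction_counts),
    class = "ssr_comparison"
  )
}

#' @export
print.ssr_comparison <- function(x, ...) {
  cat("Cross-genotype SSR comparison\n")
  cat("  reconciled polymorphic panel:", nrow(x$panel), "loci\n")
  cat("  per-direction verdict counts:\n")
  print(as.data.frame(x$direction_counts), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-genotype comparison
#'
#' @param x An `ssr_comparison` from [bidirectional_reconcile()].
#' @param direction Which call set to return: the reconciled polymorphic
#'   `"panel"` (default) or the per-direction calls.
#' @param ... Unused.
#' @return A tibble of calls.
#' @export
tidy.ssr_comparison <- function(x, direction = c("panel", "1v2", "2v1"),
                                ...) {
  direction <- match.arg(direction)
  tibble::as_tibble(switch(direction,
    panel = x$panel, "1v2" = x$calls_1v2, "2v1" = x$calls_2v1))
}

#' One-row summary of a cross-genotype comparison
#'
#' @param x An `ssr_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with per-direction verdict counts and the
#'   reconciled panel size.
#' @export
glance.ssr_comparison <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    tidyr::pivot_longer(x$direction_counts, -"direction",
                        names_to = "verdict", values_to = "n"),
    names_from = c("direction", "verdict"), values_from = "n",
    names_sep = "_"
  )
  dplyr::mutate(wide, n_reconciled_polymorphic = nrow(x$panel))
}
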