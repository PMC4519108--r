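#' Configuration for perfect tandem-repeat scanning
#'
#' @param min_period,max_period Motif-length bounds in bp. Mononucleotide
#'   runs are never reported, so `min_period` must exceed 1.
#' @param min_tract_len Minimum tract length in bp counting whole motif
#'   copies only; the default (20 bp) is the conventional minimum for
#'   genotypable microsatellites.
#' @param forbid_N Reject tracts containing `N` (default `TRUE`).
#' @return A list of class `ssr_config`.
#' @export
ssr_config <- function(min_period = 2L, max_period = 7L,
                       min_tract_len = 20L, forbid_N = TRUE) {
  min_period <- as.integer(min_period)
  max_period <- as.integer(max_period)
  min_tract_len <- as.integer(min_tract_len)
  if (min_period <= 1L || min_period > max_period) {
    stop("need 1 < min_period <= max_period", call. = FALSE)
  }
  if (min_tract_len < 2L * min_period) {
    stop("min_tract_len must be at least two motif copies", call. = FALSE)
  }
  structure(
    list(min_period = min_period, max_period = max_period,
         min_tract_len = min_tract_len, forbid_N = isTRUE(forbid_N)),
    class = "ssr_config"
  )
}

# TRUE iff motif is not a whole-number repetition of a shorter unit
# (e.g. "ATAT" = 2 x "AT" is not primitive; "AA" is a period-1 run).
is_primitive_motif <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L &&
        strrep(substr(motif, 1L, d), p %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Scan sequences for perfect tandem repeats (SSRs)
#'
#' Finds every maximal perfect tandem tract whose motif period lies in
#' `[min_period, max_period]` and whose tract length (whole copies only)
#' meets `min_tract_len`. A tract is reported once, at its true (smallest)
#' period: motifs that are themselves repetitions of a shorter unit are
#' suppressed. Tracts are anchored at the leftmost base of the maximal
#' repeat region; a trailing partial motif copy is not counted in `copies`
#' but its length is reported as `trailing_bp`.
#'
#' @param seqs Sequence tibble (columns `id`, `seq`), e.g. from
#'   [read_fasta()].
#' @param config An [ssr_config()].
#' @return A tibble of loci sorted by (`seq_id`, `start`, `period`):
#'   `seq_id`, `start`, `end` (0-based half-open), `period`, `motif`,
#'   `copies`, `tract_len`, `trailing_bp`.
#' @examples
#' find_ssrs(tibble::tibble(id = "x", seq = strrep("AT", 10)))
#' @export
find_ssrs <- function(seqs, config = ssr_config()) {
  check_seq_tbl(seqs)
  stopifnot(inherits(config, "ssr_config"))
  out <- purrr::map2(seqs$id, seqs$seq, scan_one_sequence, config = config)
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(
      seq_id = character(), start = integer(), end = integer(),
      period = integer(), motif = character(), copies = integer(),
      tract_len = integer(), trailing_bp = integer()
    ))
  }
  dplyr::arrange(res, .data$seq_id, .data$start, .data$period)
}

# Per-period lagged self-comparison: s[i] == s[i + p] run-length encoded.
# A maximal run of TRUE of length L starting at i is a repeat region of
# L + p bases with period p, anchored at i.
scan_one_sequence <- function(id, seq, config) {
  n <- nchar(seq)
  if (n < config$min_tract_len) return(NULL)
  ch <- charToRaw(seq)
  n_raw <- charToRaw("N")
  acc <- list()
  for (p in config$min_period:config$max_period) {
    if (n <= p) next
    m <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    if (config$forbid_N) {
      m <- m & ch[seq_len(n - p)] != n_raw & ch[(p + 1L):n] != n_raw
    }
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths + p >= config$min_tract_len)
    for (k in hit) {
      region_start <- starts[k]           # 1-based
      region_len <- r$lengths[k] + p
      copies <- region_len %/% p
      tract_len <- copies * p
      if (tract_len < config$min_tract_len) next
      motif <- substr(seq, region_start, region_start + p - 1L)
      if (!is_primitive_motif(motif)) next
      acc[[length(acc) + 1L]] <- list(
        seq_id = id,
        start = region_start - 1L,        # 0-based half-open
        end = region_start - 1L + tract_len,
        period = p,
        motif = motif,
        copies = copies,
        tract_len = tract_len,
        trailing_bp = region_len - tract_len
      )
    }
  }
  if (length(acc) == 0L) return(NULL)
  dplyr::bind_rows(acc)
}

REVCOMP_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a nucleotide string
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}`.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(ch), names(REVCOMP_MAP))
    if (length(bad) > 0L) {
      stop("invalid nucleotide(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    paste(rev(REVCOMP_MAP[ch]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Canonical form of a repeat motif
#'
#' Rotation-normalized (and, on the minus strand, reverse-complemented)
#' representative of a motif, so that motifs of homologous tracts compare
#' equal regardless of where the scanner anchored them or which strand an
#' alignment hit. The canonical form is the lexicographically smallest
#' rotation; for `orientation = "minus"` the motif is reverse-complemented
#' first. Idempotent for plus orientation.
#'
#' @param motif Motif string(s), characters in `{A,C,G,T}`, length 2-7.
#' @param orientation `"plus"` or `"minus"`.
#' @return Canonical motif string(s).
#' @examples
#' canonical_motif("TA")            # "AT"
#' canonical_motif("GAA", "minus")  # "CTT"
#' @export
canonical_motif <- function(motif, orientation = c("plus", "minus")) {
  orientation <- match.arg(orientation)
  vapply(motif, function(m) {
    if (nchar(m) < 2L || nchar(m) > 7L || grepl("[^ACGT]", m)) {
      stop("motif must be 2-7 bases over {A,C,G,T}: got ", m, call. = FALSE)
    }
    if (orientation == "minus") m <- revcomp(m)
    p <- nchar(m)
    rot <- vapply(seq_len(p), function(i) {
      paste0(substr(m, i, p), substr(m, 1L, i - 1L))
    }, "")
    min(rot)
  }, "", USE.NAMES = FALSE)
}

#' Write an SSR locus table as TSV
#'
#' Coordinates are converted to 1-based inclusive for the human-readable
#' report (internal coordinates are 0-based half-open).
#'
#' @param loci Locus tibble from [find_ssrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_table <- function(loci, path) {
  out <- dplyr::mutate(loci, start = .data$start + 1L)
  readr::write_tsv(out, path)
  invisible(path)
}
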