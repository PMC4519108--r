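#' Read a FASTA file into a sequence tibble
#'
#' Sequences are stored uppercase. Only `A`, `C`, `G`, `T` and the assembly
#' gap/ambiguity character `N` are accepted; any other IUPAC ambiguity code
#' is rejected so that downstream repeat arithmetic stays exact.
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @return A tibble with columns `id` (character, the header token up to the
#'   first whitespace) and `seq` (uppercase nucleotide string), one row per
#'   record in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt", ">b", "GGGG"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    warning("FASTA file is empty: ", path, call. = FALSE)
    return(tibble::tibble(id = character(), seq = character()))
  }
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  bad <- ids[grepl("[^ACGTN]", seqs)]
  if (length(bad) > 0L) {
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = ids, seq = unname(seqs))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id` and `seq` as returned by
#'   [read_fasta()].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  check_seq_tbl(seqs)
  ss <- Biostrings::BStringSet(seqs$seq)
  names(ss) <- seqs$id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

check_seq_tbl <- function(seqs, arg = "seqs") {
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    stop("`", arg, "` must be a data frame with columns `id` and `seq`",
         call. = FALSE)
  }
  invisible(seqs)
}

#' Assembly summary statistics
#'
#' Computes contig count, total length, N50, length range and base
#' composition for a contig set. The N50 is the contig length L such that
#' contigs of length >= L together contain at least half of the assembly's
#' bases (descending-sorted lengths, cumulative sum). `N` bases count toward
#' lengths but are excluded from the composition denominator, so
#' `at_fraction + gc_fraction == 1` whenever any non-N base exists.
#'
#' @param seqs Sequence tibble (columns `id`, `seq`).
#' @return A one-row tibble: `n_contigs`, `total_bp`, `n50`, `min_len`,
#'   `max_len`, `mean_len`, `at_fraction`, `gc_fraction`.
#' @examples
#' seqs <- tibble::tibble(
#'   id = paste0("c", 1:5),
#'   seq = strrep("A", c(10, 9, 8, 7, 6))
#' )
#' assembly_stats(seqs)$n50  # 8
#' @export
assembly_stats <- function(seqs) {
  check_seq_tbl(seqs)
  if (nrow(seqs) == 0L) {
    stop("cannot compute assembly statistics for an empty contig set",
         call. = FALSE)
  }
  lens <- nchar(seqs$seq)
  base_counts <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs$seq), baseOnly = TRUE
  )
  acgt <- colSums(base_counts[, c("A", "C", "G", "T"), drop = FALSE])
  non_n <- sum(acgt)
  tibble::tibble(
    n_contigs = length(lens),
    total_bp = sum(lens),
    n50 = n50_value(lens),
    min_len = min(lens),
    max_len = max(lens),
    mean_len = mean(lens),
    at_fraction = if (non_n > 0) (acgt[["A"]] + acgt[["T"]]) / non_n else NA_real_,
    gc_fraction = if (non_n > 0) (acgt[["G"]] + acgt[["C"]]) / non_n else NA_real_
  )
}

n50_value <- function(lens) {
  stopifnot(length(lens) > 0L)
  lens <- sort(lens, decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1L]]
}

#' Enrich a contig set by the N50-length rule
#'
#' Data-reduction step used ahead of repeat scanning on draft assemblies:
#' only contigs longer than the set's own N50 are retained. With
#' `strict = FALSE` the comparison becomes `>=`.
#'
#' @param seqs Sequence tibble (columns `id`, `seq`).
#' @param strict Keep contigs strictly longer than the N50 (default), or at
#'   least as long when `FALSE`.
#' @return The retained rows of `seqs`, input order preserved.
#' @export
n50_filter <- function(seqs, strict = TRUE) {
  check_seq_tbl(seqs)
  n50 <- assembly_stats(seqs)$n50
  lens <- nchar(seqs$seq)
  keep <- if (strict) lens > n50 else lens >= n50
  seqs[keep, , drop = FALSE]
}
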