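#' Default homology-keyword blacklists
#'
#' Descriptor keywords marking organellar or repetitive sequences to be
#' excluded from nuclear marker panels. The EST list is applied at a
#' protein-homology E-value cutoff of 0.001, the genomic list at 1e-9.
#'
#' @format Character vectors.
#' @name blacklists
NULL

#' @rdname blacklists
#' @export
est_blacklist <- function() {
  c("ribosomal", "retro-element", "gag protein", "chloroplast",
    "mitochondria")
}

#' @rdname blacklists
#' @export
genomic_blacklist <- function() {
  c("chloroplast", "mitochondria", "retroelement", "gag protein")
}

# lowercase and strip every non-alphanumeric character, so that
# "Retro-Element" == "retroelement" == "retro element"
normalize_descriptor <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

#' Exclude sequences by homology-descriptor keywords
#'
#' A sequence is excluded iff any of its annotation hits at or below
#' `max_evalue` has a descriptor containing any blacklist keyword.
#' Matching is case-insensitive normalized-substring: hyphens, spaces and
#' other punctuation are stripped from both sides before the substring
#' test, so inconsistent spellings ("retro-element" vs "retroelement")
#' behave identically.
#'
#' @param hits Annotation tibble with columns `seq_id`, `descriptor`,
#'   `evalue` (coordinates optional).
#' @param blacklist Character vector of keywords; see [est_blacklist()]
#'   and [genomic_blacklist()].
#' @param max_evalue Hits above this E-value are ignored.
#' @return Character vector of `seq_id`s to exclude (unique, sorted).
#' @export
keyword_filter <- function(hits, blacklist = genomic_blacklist(),
                           max_evalue = 1e-9) {
  stopifnot(length(blacklist) > 0L)
  if (nrow(hits) == 0L) return(character(0))
  use <- dplyr::filter(hits, .data$evalue <= max_evalue)
  if (nrow(use) == 0L) return(character(0))
  desc <- normalize_descriptor(use$descriptor)
  keys <- normalize_descriptor(blacklist)
  flagged <- Reduce(`|`, lapply(keys, function(k) {
    stringr::str_detect(desc, stringr::fixed(k))
  }))
  sort(unique(use$seq_id[flagged]))
}

#' Position of an SSR relative to a homology region
#'
#' Labels a repeat tract by where it sits relative to its sequence's
#' protein-homology region: entirely left of the region is `before`,
#' entirely right is `after`, any overlap is `within`; a sequence with no
#' hit is `no_homology`.
#'
#' @param locus One row of a locus tibble (0-based half-open `start`,
#'   `end`).
#' @param best_hit One row of an annotation tibble (`seq_id`, `q_start`,
#'   `q_end`, 1-based inclusive), or `NULL`.
#' @return One of `"before"`, `"after"`, `"within"`, `"no_homology"`.
#' @export
position_category <- function(locus, best_hit = NULL) {
  if (is.null(best_hit) || nrow(best_hit) == 0L) return("no_homology")
  if (best_hit$seq_id[1] != locus$seq_id[1]) {
    stop("locus and hit are on different sequences: ", locus$seq_id[1],
         " vs ", best_hit$seq_id[1], call. = FALSE)
  }
  region_lo <- min(best_hit$q_start[1], best_hit$q_end[1])
  region_hi <- max(best_hit$q_start[1], best_hit$q_end[1])
  tract_lo <- locus$start[1] + 1L   # 1-based inclusive
  tract_hi <- locus$end[1]
  if (tract_hi < region_lo) "before"
  else if (tract_lo > region_hi) "after"
  else "within"
}

#' Categorize a marker panel against homology regions
#'
#' Selects one best hit per sequence (smallest E-value; ties broken by
#' lexicographic descriptor), labels every candidate by
#' [position_category()], and tabulates the panel as `outside_homology`
#' (before or after the homology region), `no_homology`, and
#' `within_homology`. The three counts partition the panel.
#'
#' @param candidates Marker-candidate tibble (must carry `seq_id`,
#'   `start`, `end`).
#' @param hits Annotation tibble (`seq_id`, `descriptor`, `q_start`,
#'   `q_end`, `evalue`).
#' @return A list with `categories` (per-candidate tibble with a
#'   `category` column) and `counts` (one-row tibble of the three counts).
#' @export
categorize_panel <- function(candidates, hits) {
  best <- hits |>
    dplyr::arrange(.data$evalue, .data$descriptor) |>
    dplyr::distinct(.data$seq_id, .keep_all = TRUE)
  cat_of <- vapply(seq_len(nrow(candidates)), function(i) {
    locus <- candidates[i, ]
    hit <- best[best$seq_id == locus$seq_id, , drop = FALSE]
    position_category(locus, if (nrow(hit) == 0L) NULL else hit)
  }, "")
  categories <- dplyr::mutate(candidates, category = cat_of)
  counts <- tibble::tibble(
    outside_homology = sum(cat_of %in% c("before", "after")),
    no_homology = sum(cat_of == "no_homology"),
    within_homology = sum(cat_of == "within")
  )
  list(categories = categories, counts = counts)
}
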