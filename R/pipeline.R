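#' End-to-end cross-genotype SSR marker pipeline
#'
#' Chains the discovery stages on two assemblies: N50 enrichment of each
#' contig set, repeat scanning, primer design and uniqueness screening,
#' reciprocal contig matching with polymorphism calling, bidirectional
#' reconciliation, homology-keyword exclusion, and (by default, matching
#' how validation panels are typically picked) restriction of the final
#' panel to di- and tri-nucleotide motifs. Every stage's input/output
#' counts are logged to stderr.
#'
#' @param p1,p2 Sequence tibbles for the two genotypes (from
#'   [read_fasta()] or [generate_pair()]).
#' @param matches_1v2,matches_2v1 Optional externally computed match
#'   tables ([load_match_table()]); when `NULL` the internal
#'   seed-and-extend matcher is used.
#' @param annotations Optional annotation tibble for the keyword filter;
#'   `NULL` skips the filter.
#' @param scan_cfg,primer_cfg,cmp_cfg Stage configurations.
#' @param blacklist Keyword blacklist for [keyword_filter()].
#' @param keyword_max_evalue E-value cutoff for the keyword filter.
#' @param ditri_only Restrict the final panel to di-/tri-nucleotide
#'   motifs.
#' @param primer_screen Require a designable, unique primer pair before a
#'   genotype-1 SSR enters the comparison (the standard flow). Disable to
#'   call a verdict for every detected locus.
#' @param enrich Apply the N50 contig-length enrichment first.
#' @param quiet Suppress stage logging.
#' @return A list of class `ssr_pipeline`: final `panel`, the
#'   `comparison` (`ssr_comparison` object), per-stage intermediate
#'   tables, and a `stage_counts` tibble.
#' @export
run_pipeline <- function(p1, p2,
                         matches_1v2 = NULL, matches_2v1 = NULL,
                         annotations = NULL,
                         scan_cfg = ssr_config(),
                         primer_cfg = primer_config(),
                         cmp_cfg = compare_config(),
                         blacklist = genomic_blacklist(),
                         keyword_max_evalue = 1e-9,
                         ditri_only = TRUE,
                         enrich = FALSE,
                         primer_screen = TRUE,
                         quiet = FALSE) {
  log_stage <- function(...) if (!quiet) message("[ssrforge] ", ...)
  counts <- list()
  note <- function(stage, n_in, n_out) {
    counts[[length(counts) + 1L]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out)
    log_stage(stage, ": ", n_in, " -> ", n_out)
  }
  check_seq_tbl(p1, "p1"); check_seq_tbl(p2, "p2")
  if (nrow(p1) == 0L) stop("stage enrich: genotype-1 contig set is empty",
                           call. = FALSE)
  if (nrow(p2) == 0L) stop("stage enrich: genotype-2 contig set is empty",
                           call. = FALSE)

  if (enrich) {
    e1 <- n50_filter(p1); e2 <- n50_filter(p2)
    note("enrich_p1", nrow(p1), nrow(e1))
    note("enrich_p2", nrow(p2), nrow(e2))
    p1 <- e1; p2 <- e2
    if (nrow(p1) == 0L || nrow(p2) == 0L) {
      stop("stage enrich: no contigs above the N50 length", call. = FALSE)
    }
  }

  ssrs_p1 <- find_ssrs(p1, scan_cfg)
  ssrs_p2 <- find_ssrs(p2, scan_cfg)
  note("scan_p1", nrow(p1), nrow(ssrs_p1))
  note("scan_p2", nrow(p2), nrow(ssrs_p2))

  if (primer_screen) {
    panel_p1 <- design_panel(p1, ssrs_p1, primer_cfg)
    primed_p1 <- dplyr::filter(panel_p1, .data$primer_ok)
    note("primers_p1", nrow(panel_p1), nrow(primed_p1))
    screened_p1 <- uniqueness_screen(primed_p1, p1)
    note("uniqueness_p1", nrow(primed_p1), nrow(screened_p1))
    compare_p1 <- dplyr::semi_join(ssrs_p1, screened_p1,
                                   by = c("seq_id", "start"))
  } else {
    screened_p1 <- NULL
    compare_p1 <- ssrs_p1
  }

  if (is.null(matches_1v2)) {
    if (nrow(ssrs_p1) == 0L || nrow(ssrs_p2) == 0L) {
      stop("stage compare: no SSR loci to compare", call. = FALSE)
    }
    matches_1v2 <- internal_match(p1, p2, cmp_cfg)
    matches_2v1 <- internal_match(p2, p1, cmp_cfg)
  }
  known <- c(p1$id, p2$id)
  calls_1v2 <- pair_ssrs(matches_1v2, compare_p1, ssrs_p2, cmp_cfg,
                         known_ids = known)
  calls_2v1 <- pair_ssrs(matches_2v1, ssrs_p2, ssrs_p1, cmp_cfg,
                         known_ids = known)
  note("compare_1v2", nrow(ssrs_p1), nrow(calls_1v2))
  note("compare_2v1", nrow(ssrs_p2), nrow(calls_2v1))

  comparison <- bidirectional_reconcile(calls_1v2, calls_2v1)
  panel <- comparison$panel
  note("reconcile", nrow(dplyr::filter(calls_1v2,
                                       .data$verdict == "polymorphic")),
       nrow(panel))

  if (!is.null(annotations)) {
    excluded <- keyword_filter(annotations, blacklist, keyword_max_evalue)
    before <- nrow(panel)
    panel <- dplyr::filter(panel, !.data$p1_seq_id %in% excluded,
                           !.data$p2_seq_id %in% excluded)
    note("keyword_filter", before, nrow(panel))
  }

  if (ditri_only) {
    before <- nrow(panel)
    panel <- dplyr::filter(panel, .data$period %in% c(2L, 3L))
    note("ditri_restrict", before, nrow(panel))
  }

  structure(
    list(panel = panel, comparison = comparison,
         ssrs_p1 = ssrs_p1, ssrs_p2 = ssrs_p2,
         marker_panel_p1 = screened_p1,
         matches_1v2 = matches_1v2, matches_2v1 = matches_2v1,
         stage_counts = dplyr::bind_rows(counts)),
    class = "ssr_pipeline"
  )
}

#' @export
print.ssr_pipeline <- function(x, ...) {
  cat("ssrforge pipeline result\n")
  cat("  final marker panel:", nrow(x$panel), "loci\n\n")
  print(as.data.frame(x$stage_counts), row.names = FALSE)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `ssr_pipeline`.
#' @param ... Unused.
#' @export
tidy.ssr_pipeline <- function(x, ...) {
  tibble::as_tibble(x$panel)
}

#' @rdname run_pipeline
#' @export
glance.ssr_pipeline <- function(x, ...) {
  dplyr::mutate(glance(x$comparison), n_final_panel = nrow(x$panel))
}
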