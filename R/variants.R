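#' Read site records from a VCF
#'
#' Parses a VCF 4.x file (plain or gzipped) into a site-level tibble with
#' the INFO-field total depth (`DP`) and RMS mapping quality (`MQ`), the
#' convention written by the samtools/bcftools calling stack. Records
#' missing either annotation get `NA`, which [hard_filter()] drops with a
#' counted warning.
#'
#' @param path Path to a VCF file.
#' @return A tibble: `chrom`, `pos`, `ref`, `alt` (comma-separated when
#'   multiallelic), `depth`, `map_q`.
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    depth = dp,
    map_q = mq
  )
}

#' Hard-filter variant sites by depth and mapping quality
#'
#' Retains sites supported by at least `min_depth` reads and a mapping
#' quality of at least `min_mq` (both bounds inclusive). Sites missing
#' either annotation are dropped and counted in a single warning.
#'
#' @param records Variant tibble from [read_vcf_records()].
#' @param min_depth Minimum total read depth (default 10).
#' @param min_mq Minimum mapping quality (default 30).
#' @return The retained rows, input order preserved.
#' @export
hard_filter <- function(records, min_depth = 10, min_mq = 30) {
  stopifnot(min_depth > 0, min_mq > 0)
  missing <- is.na(records$depth) | is.na(records$map_q)
  if (any(missing)) {
    warning(sum(missing), " record(s) missing DP or MQ dropped",
            call. = FALSE)
  }
  keep <- !missing & records$depth >= min_depth & records$map_q >= min_mq
  records[keep, , drop = FALSE]
}

BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- {
  g <- expand.grid(to = BASES, from = BASES, stringsAsFactors = FALSE)
  paste0(g$from, ">", g$to)[g$from != g$to]
}
TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Classify variants and count the substitution spectrum
#'
#' Splits filtered sites into biallelic SNPs, indels, and multiallelic
#' sites, and tallies the 12 directed nucleotide substitutions (A>C ...
#' T>G) over the biallelic SNPs only. Strands are not collapsed: G>A and
#' C>T are separate cells, matching how variant callers report the
#' reference-relative spectrum. Multiallelic sites are counted once and
#' excluded from the 12-cell spectrum.
#'
#' @param records Variant tibble (typically after [hard_filter()]).
#' @return An object of class `variant_spectrum`: list with `spectrum`
#'   (12-row tibble: `substitution`, `n`, `transition`), `n_snp`,
#'   `n_indel`, `n_multiallelic`, `ti_tv`.
#' @export
classify_and_count <- function(records) {
  multi <- grepl(",", records$alt, fixed = TRUE)
  snp <- !multi & nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    records$ref %in% BASES & records$alt %in% BASES
  indel <- !multi & !snp
  sub <- paste0(records$ref[snp], ">", records$alt[snp])
  counts <- vapply(SUBSTITUTIONS, function(s) sum(sub == s), 0L)
  ti <- sum(counts[TRANSITIONS])
  tv <- sum(counts) - ti
  structure(
    list(
      spectrum = tibble::tibble(
        substitution = SUBSTITUTIONS,
        n = unname(counts),
        transition = SUBSTITUTIONS %in% TRANSITIONS
      ),
      n_snp = sum(snp),
      n_indel = sum(indel),
      n_multiallelic = sum(multi),
      ti_tv = if (tv > 0) ti / tv else NA_real_
    ),
    class = "variant_spectrum"
  )
}

#' @export
print.variant_spectrum <- function(x, ...) {
  cat("Variant substitution spectrum\n")
  cat("  SNPs:", x$n_snp, " indels:", x$n_indel,
      " multiallelic:", x$n_multiallelic, "\n")
  cat("  Ti/Tv:", format(x$ti_tv, digits = 4), "\n")
  print(as.data.frame(x$spectrum), row.names = FALSE)
  invisible(x)
}

#' @rdname classify_and_count
#' @param x A `variant_spectrum`.
#' @param ... Unused.
#' @export
tidy.variant_spectrum <- function(x, ...) {
  dplyr::mutate(x$spectrum,
                fraction = if (x$n_snp > 0) .data$n / x$n_snp else NA_real_)
}

#' @rdname classify_and_count
#' @export
glance.variant_spectrum <- function(x, ...) {
  tibble::tibble(n_snp = x$n_snp, n_indel = x$n_indel,
                 n_multiallelic = x$n_multiallelic, ti_tv = x$ti_tv)
}

#' Plot a substitution spectrum
#'
#' Bar chart of the 12 directed substitution counts, transitions
#' highlighted.
#'
#' @param object A `variant_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.variant_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$substitution, y = .data$n,
                               fill = .data$transition)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "substitution (ref > alt)", y = "count",
                  fill = "transition") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
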