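PERIOD_CLASSES <- c("di", "tri", "tetra", "penta", "hexa", "hepta")
MARKER_STATUSES <- c("polymorphic", "monomorphic", "failed")

#' Motif-class label for a motif period
#'
#' @param period Integer motif length(s) in 2..7.
#' @return Factor over `di` ... `hepta`.
#' @export
period_class <- function(period) {
  stopifnot(all(period %in% 2:7))
  factor(PERIOD_CLASSES[period - 1L], levels = PERIOD_CLASSES)
}

#' Cross-tabulate markers by motif class and status
#'
#' Builds the standard marker-summary table: counts of polymorphic,
#' monomorphic and failed (no-amplification) markers per motif class
#' (di- through hepta-nucleotide), class totals, and each class's percent
#' share of the grand total (2 decimals).
#'
#' @param markers Tibble with columns `period_class` (values `di` ...
#'   `hepta`) and `status` (`polymorphic`, `monomorphic`, `failed`).
#' @return An object of class `marker_summary`: list with `counts` (wide
#'   tibble, one row per status plus a total row), `percent` (named
#'   per-class percentages), `grand_total`.
#' @export
motif_distribution <- function(markers) {
  stopifnot(all(markers$period_class %in% PERIOD_CLASSES),
            all(markers$status %in% MARKER_STATUSES))
  pc <- factor(markers$period_class, levels = PERIOD_CLASSES)
  st <- factor(markers$status, levels = MARKER_STATUSES)
  tab <- table(status = st, class = pc)
  counts <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "status")
  class_totals <- colSums(tab)
  grand <- sum(tab)
  totals_row <- tibble::tibble(
    status = "total",
    !!!as.list(stats::setNames(as.integer(class_totals), PERIOD_CLASSES))
  )
  percent <- round(100 * class_totals / grand, 2)
  structure(
    list(
      counts = dplyr::bind_rows(
        dplyr::mutate(counts,
                      dplyr::across(-"status", as.integer)),
        totals_row
      ),
      percent = percent,
      grand_total = grand
    ),
    class = "marker_summary"
  )
}

#' @export
print.marker_summary <- function(x, ...) {
  cat("Marker motif-class distribution (n =", x$grand_total, ")\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat("percent:",
      paste0(names(x$percent), " ", sprintf("%.2f", x$percent), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' @rdname motif_distribution
#' @param x A `marker_summary`.
#' @param ... Unused.
#' @return `tidy()`: long tibble of status x class counts with class
#'   percentages; `glance()`: one-row totals.
#' @export
tidy.marker_summary <- function(x, ...) {
  long <- tidyr::pivot_longer(x$counts, -"status", names_to = "period_class",
                              values_to = "n")
  pct <- tibble::tibble(period_class = names(x$percent),
                        pct_of_total = unname(x$percent))
  dplyr::left_join(long, pct, by = "period_class")
}

#' @rdname motif_distribution
#' @export
glance.marker_summary <- function(x, ...) {
  tibble::tibble(grand_total = x$grand_total,
                 !!!stats::setNames(as.list(unname(x$percent)),
                                    paste0("pct_", names(x$percent))))
}

#' Plot a marker motif-class distribution
#'
#' @param object A `marker_summary`.
#' @param ... Unused.
#' @return A ggplot object (stacked bars, one per motif class).
#' @export
autoplot.marker_summary <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::filter(d, .data$status != "total")
  d$period_class <- factor(d$period_class, levels = PERIOD_CLASSES)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$period_class, y = .data$n,
                                  fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "motif class", y = "markers", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Polymorphism and failure rates of a marker panel
#'
#' Two deliberately different denominators: the polymorphic rate is taken
#' over markers that amplified (`n_poly + n_mono`), while the failure rate
#' is taken over all tested markers (`n_poly + n_mono + n_failed`). This
#' is the convention under which a panel of 314 polymorphic, 62
#' monomorphic and 8 failed markers has a polymorphic rate of 83.51% and
#' a failure rate of ~2%.
#'
#' @param n_poly,n_mono,n_failed Marker counts.
#' @return One-row tibble: counts, `pct_polymorphic`, `pct_failure`
#'   (2 decimals), and integer display versions `pct_polymorphic_display`,
#'   `pct_failure_display`.
#' @export
panel_rates <- function(n_poly, n_mono, n_failed) {
  stopifnot(n_poly >= 0, n_mono >= 0, n_failed >= 0)
  amplified <- n_poly + n_mono
  tested <- amplified + n_failed
  pct_poly <- if (amplified > 0) round(100 * n_poly / amplified, 2) else NA_real_
  pct_fail <- if (tested > 0) round(100 * n_failed / tested, 2) else NA_real_
  tibble::tibble(
    n_poly = n_poly, n_mono = n_mono, n_failed = n_failed,
    pct_polymorphic = pct_poly,
    pct_failure = pct_fail,
    pct_polymorphic_display = round(pct_poly),
    pct_failure_display = round(pct_fail)
  )
}

#' Read-alignment outcome shares
#'
#' Percentages of items (reads or collapsed tags) aligning zero times,
#' exactly once, and more than once against a reference, each as a share
#' of the total (2 decimals).
#'
#' @param n_zero,n_once,n_multi Counts per outcome.
#' @return One-row tibble with counts and `pct_zero`, `pct_once`,
#'   `pct_multi`.
#' @export
alignment_outcome_summary <- function(n_zero, n_once, n_multi) {
  stopifnot(n_zero >= 0, n_once >= 0, n_multi >= 0)
  total <- n_zero + n_once + n_multi
  if (total == 0) stop("total count must be positive", call. = FALSE)
  tibble::tibble(
    n_zero = n_zero, n_once = n_once, n_multi = n_multi,
    pct_zero = round(100 * n_zero / total, 2),
    pct_once = round(100 * n_once / total, 2),
    pct_multi = round(100 * n_multi / total, 2)
  )
}
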