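#' Configuration for the two-genotype synthetic assembly generator
#'
#' Defines a pair of related draft assemblies with planted microsatellite
#' truth: every planted tract is perfect and maximal, per-locus
#' copy-number differences between the genotypes follow `p_polymorphic`
#' and `delta_range`, a `p_no_match` fraction of partner contigs is
#' deleted from genotype 2, flanks may carry substitution noise, and
#' organellar decoy contigs carry blacklist descriptors.
#'
#' @param n_contigs Contigs per genotype (before decoys/deletions).
#' @param contig_len_range Contig length bounds, bp.
#' @param n_planted_ssrs How many contigs carry one planted SSR each
#'   (must be <= `n_contigs`).
#' @param motif_alphabet Primitive motifs (period 2-7) to draw from.
#' @param copies_range Copy-number bounds for genotype 1.
#' @param p_polymorphic Probability a matched locus differs in copy
#'   number between the genotypes.
#' @param delta_range Copy-number difference bounds for polymorphic loci.
#' @param p_no_match Probability a locus's partner contig is deleted from
#'   genotype 2.
#' @param p_revcomp Probability a genotype-2 partner contig is stored
#'   reverse-complemented (exercises minus-strand matching).
#' @param flank_snp_rate Per-base substitution probability in genotype-2
#'   flanks.
#' @param n_decoys Organellar decoy contigs (each carries a polymorphic
#'   SSR and a blacklist descriptor).
#' @param seed Random seed; generation is deterministic given the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_contigs = 200L,
                       contig_len_range = c(600L, 1200L),
                       n_planted_ssrs = n_contigs,
                       motif_alphabet = c("AT", "AC", "AG", "CT",
                                          "AAT", "AAG", "ATC",
                                          "AAAT", "AAAC",
                                          "AAAAT", "AACGT",
                                          "AACGAT", "AACGAAT"),
                       copies_range = c(10L, 15L),
                       p_polymorphic = 0.4,
                       delta_range = c(1L, 3L),
                       p_no_match = 0.1,
                       p_revcomp = 0.25,
                       flank_snp_rate = 0,
                       n_decoys = 5L,
                       seed = 1L) {
  stopifnot(n_planted_ssrs <= n_contigs,
            p_polymorphic >= 0, p_polymorphic <= 1,
            p_no_match >= 0, p_no_match <= 1,
            p_revcomp >= 0, p_revcomp <= 1,
            flank_snp_rate >= 0, flank_snp_rate < 1,
            copies_range[1] >= 2L, delta_range[1] >= 1L)
  periods <- nchar(motif_alphabet)
  if (any(periods < 2L | periods > 7L) ||
      !all(vapply(motif_alphabet, is_primitive_motif, TRUE))) {
    stop("motif_alphabet must contain primitive motifs of period 2-7",
         call. = FALSE)
  }
  if (copies_range[1] * min(periods) < 20L) {
    stop("copies_range[1] x shortest period must be >= 20 bp so planted ",
         "tracts are detectable", call. = FALSE)
  }
  max_tract <- (copies_range[2] + delta_range[2]) * max(periods)
  if (max_tract + 2L * 60L > contig_len_range[1]) {
    stop("contigs too short for the largest plantable tract plus flanks",
         call. = FALSE)
  }
  structure(
    list(n_contigs = as.integer(n_contigs),
         contig_len_range = as.integer(contig_len_range),
         n_planted_ssrs = as.integer(n_planted_ssrs),
         motif_alphabet = motif_alphabet,
         copies_range = as.integer(copies_range),
         p_polymorphic = p_polymorphic,
         delta_range = as.integer(delta_range),
         p_no_match = p_no_match,
         p_revcomp = p_revcomp,
         flank_snp_rate = flank_snp_rate,
         n_decoys = as.integer(n_decoys),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# random flank whose boundary base cannot extend the adjacent tract
random_flank <- function(n, forbid_last = NULL, forbid_first = NULL) {
  ch <- sample(BASES, n, replace = TRUE)
  if (!is.null(forbid_last) && n > 0L) {
    ch[n] <- sample(setdiff(BASES, forbid_last), 1L)
  }
  if (!is.null(forbid_first) && n > 0L) {
    ch[1L] <- sample(setdiff(BASES, forbid_first), 1L)
  }
  paste(ch, collapse = "")
}

# contig = left flank + motif^copies + right flank, rejection-sampled so
# the repeat scanner finds exactly the planted tract
build_planted_contig <- function(len, motif, copies, scan_cfg,
                                 max_tries = 50L) {
  p <- nchar(motif)
  tract <- strrep(motif, copies)
  tract_len <- nchar(tract)
  flank_min <- 120L
  for (try in seq_len(max_tries)) {
    left_len <- sample(flank_min:(len - tract_len - flank_min), 1L)
    right_len <- len - tract_len - left_len
    left <- random_flank(left_len,
                         forbid_last = substr(motif, p, p))
    right <- random_flank(right_len,
                          forbid_first = substr(motif, 1L, 1L))
    seq <- paste0(left, tract, right)
    loci <- find_ssrs(tibble::tibble(id = "x", seq = seq), scan_cfg)
    if (nrow(loci) == 1L && loci$start == left_len &&
        loci$tract_len == tract_len && loci$motif == motif) {
      return(list(seq = seq, start = left_len))
    }
  }
  stop("failed to build a clean planted contig in ", max_tries, " tries",
       call. = FALSE)
}

# SSR-free random contig (rejection-sampled)
build_plain_contig <- function(len, scan_cfg, max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    seq <- random_seq(len)
    if (nrow(find_ssrs(tibble::tibble(id = "x", seq = seq), scan_cfg)) == 0L) {
      return(seq)
    }
  }
  stop("failed to build an SSR-free contig", call. = FALSE)
}

mutate_flanks <- function(seq, tract_start0, tract_len, rate, scan_cfg,
                          motif, max_tries = 20L) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  flank_pos <- setdiff(seq_len(n), (tract_start0 + 1L):(tract_start0 + tract_len))
  for (try in seq_len(max_tries)) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- flank_pos[stats::runif(length(flank_pos)) < rate]
    for (i in hit) {
      ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
    }
    out <- paste(ch, collapse = "")
    loci <- find_ssrs(tibble::tibble(id = "x", seq = out), scan_cfg)
    if (nrow(loci) == 1L && loci$start == tract_start0 &&
        loci$tract_len == tract_len && loci$motif == motif) {
      return(out)
    }
  }
  stop("flank mutation kept breaking the planted tract", call. = FALSE)
}

DECOY_DESCRIPTORS <- c(
  "chloroplast ribulose-1,5-bisphosphate carboxylase large subunit",
  "mitochondria NADH dehydrogenase subunit 4",
  "Retro-element pol polyprotein",
  "GAG protein, Ty3-gypsy family",
  "chloroplast photosystem II protein D1"
)

NEUTRAL_DESCRIPTORS <- c(
  "putative serine/threonine protein kinase",
  "ABC transporter family protein",
  "zinc finger CCCH domain protein",
  "heat shock protein 70",
  "cytochrome P450 monooxygenase"
)

#' Generate a paired two-genotype assembly fixture with planted SSR truth
#'
#' Emulates two related draft assemblies: homologous contig pairs carry
#' one perfect, maximal microsatellite each, with copy-number differences
#' (polymorphic), identical tracts (monomorphic), or a deleted genotype-2
#' partner (no match), per the configured probabilities. Genotype-2
#' partners may be reverse-complemented and their flanks carry optional
#' substitution noise. Decoy contigs emulate organellar contamination and
#' receive blacklist descriptors in the annotation table; a subset of
#' ordinary contigs receives neutral protein-homology annotations placed
#' before, after or across the tract.
#'
#' @param config A [sim_config()].
#' @param scan_cfg The [ssr_config()] under which planted tracts must be
#'   the only detectable loci.
#' @return A list of class `sim_pair`: `p1`, `p2` (sequence tibbles),
#'   `truth` (tibble: `p1_id`, `p2_id`, `motif` (canonical), `period`,
#'   `copies_p1`, `copies_p2`, `expected_verdict`, `decoy`),
#'   `annotations` (tibble: `seq_id`, `descriptor`, `q_start`, `q_end`,
#'   `evalue`), and the `config`.
#' @export
generate_pair <- function(config = sim_config(), scan_cfg = ssr_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(config$seed)

  n_plant <- config$n_planted_ssrs
  n_plain <- config$n_contigs - n_plant
  p1 <- list(); p2 <- list(); truth <- list(); ann <- list()

  plant_one <- function(id1, id2, decoy = FALSE) {
    len <- sample(config$contig_len_range[1]:config$contig_len_range[2], 1L)
    motif <- sample(config$motif_alphabet, 1L)
    p <- nchar(motif)
    copies1 <- sample(config$copies_range[1]:config$copies_range[2], 1L)
    built <- build_planted_contig(len, motif, copies1, scan_cfg)

    deleted <- !decoy && stats::runif(1) < config$p_no_match
    poly <- stats::runif(1) < config$p_polymorphic || decoy
    copies2 <- copies1
    if (!deleted && poly) {
      delta <- sample(config$delta_range[1]:config$delta_range[2], 1L)
      sgn <- if ((copies1 - delta) * p >= scan_cfg$min_tract_len &&
                 stats::runif(1) < 0.5) -1L else 1L
      copies2 <- copies1 + sgn * delta
    }
    seq2 <- NA_character_
    if (!deleted) {
      # same flanks, adjusted tract, optional flank noise and revcomp
      left <- substr(built$seq, 1L, built$start)
      right <- substr(built$seq, built$start + copies1 * p + 1L, nchar(built$seq))
      seq2 <- paste0(left, strrep(motif, copies2), right)
      seq2 <- mutate_flanks(seq2, built$start, copies2 * p,
                            config$flank_snp_rate, scan_cfg, motif)
      if (stats::runif(1) < config$p_revcomp) seq2 <- revcomp(seq2)
    }
    verdict <- if (deleted) "no_match"
      else if (copies2 != copies1) "polymorphic" else "monomorphic"
    list(
      p1 = tibble::tibble(id = id1, seq = built$seq),
      p2 = if (deleted) NULL else tibble::tibble(id = id2, seq = seq2),
      truth = tibble::tibble(
        p1_id = id1, p2_id = if (deleted) NA_character_ else id2,
        motif = canonical_motif(motif), period = p,
        copies_p1 = copies1, copies_p2 = if (deleted) NA_integer_ else copies2,
        expected_verdict = verdict, decoy = decoy
      ),
      tract_start = built$start,
      tract_len = copies1 * p
    )
  }

  for (i in seq_len(n_plant)) {
    id1 <- sprintf("P1_c%04d", i); id2 <- sprintf("P2_c%04d", i)
    res <- plant_one(id1, id2)
    p1[[length(p1) + 1L]] <- res$p1
    if (!is.null(res$p2)) p2[[length(p2) + 1L]] <- res$p2
    truth[[length(truth) + 1L]] <- res$truth
    # ~half of the ordinary contigs get a neutral homology annotation
    if (stats::runif(1) < 0.5) {
      n1 <- nchar(res$p1$seq)
      placement <- sample(c("before", "after", "within"), 1L)
      region <- switch(placement,
        before = c(1L, max(2L, res$tract_start - 10L)),
        after = c(min(n1 - 1L, res$tract_start + res$tract_len + 10L), n1),
        within = c(max(1L, res$tract_start - 20L),
                   min(n1, res$tract_start + res$tract_len + 20L))
      )
      ann[[length(ann) + 1L]] <- tibble::tibble(
        seq_id = id1, descriptor = sample(NEUTRAL_DESCRIPTORS, 1L),
        q_start = region[1], q_end = region[2],
        evalue = 10^stats::runif(1, -60, -15)
      )
    }
  }
  for (i in seq_len(n_plain)) {
    len <- sample(config$contig_len_range[1]:config$contig_len_range[2], 1L)
    seq <- build_plain_contig(len, scan_cfg)
    id1 <- sprintf("P1_plain%04d", i); id2 <- sprintf("P2_plain%04d", i)
    p1[[length(p1) + 1L]] <- tibble::tibble(id = id1, seq = seq)
    p2[[length(p2) + 1L]] <- tibble::tibble(id = id2, seq = seq)
  }
  for (i in seq_len(config$n_decoys)) {
    id1 <- sprintf("P1_decoy%02d", i); id2 <- sprintf("P2_decoy%02d", i)
    res <- plant_one(id1, id2, decoy = TRUE)
    p1[[length(p1) + 1L]] <- res$p1
    if (!is.null(res$p2)) p2[[length(p2) + 1L]] <- res$p2
    truth[[length(truth) + 1L]] <- res$truth
    n1 <- nchar(res$p1$seq)
    ann[[length(ann) + 1L]] <- tibble::tibble(
      seq_id = id1,
      descriptor = DECOY_DESCRIPTORS[(i - 1L) %% length(DECOY_DESCRIPTORS) + 1L],
      q_start = 1L, q_end = n1, evalue = 10^stats::runif(1, -80, -30)
    )
  }

  structure(
    list(p1 = dplyr::bind_rows(p1), p2 = dplyr::bind_rows(p2),
         truth = dplyr::bind_rows(truth),
         annotations = if (length(ann) > 0L) dplyr::bind_rows(ann) else
           tibble::tibble(seq_id = character(), descriptor = character(),
                          q_start = integer(), q_end = integer(),
                          evalue = numeric()),
         config = config),
    class = "sim_pair"
  )
}

#' @export
print.sim_pair <- function(x, ...) {
  cat("Synthetic two-genotype assembly pair (seed ", x$config$seed, ")\n",
      sep = "")
  cat("  genotype 1:", nrow(x$p1), "contigs; genotype 2:", nrow(x$p2),
      "contigs\n")
  cat("  planted loci:", nrow(x$truth), "(",
      sum(x$truth$decoy), "decoy )\n")
  print(table(x$truth$expected_verdict))
  invisible(x)
}

#' Simulate a site-level variant table and write it as VCF
#'
#' Draws `n` variant sites with a specified directed-substitution
#' distribution, indel and multiallelic fractions, and integer depth and
#' mapping-quality annotations, for exercising the hard filter and
#' spectrum counter.
#'
#' @param n Number of records.
#' @param sub_probs Named probability vector over the 12 directed
#'   substitutions (default uniform).
#' @param p_indel,p_multi Fractions of indel and multiallelic records.
#' @param depth_range,mq_range Bounds for the uniform integer DP and MQ
#'   draws.
#' @param seed Random seed.
#' @return A variant tibble shaped like [read_vcf_records()]'s output.
#' @export
simulate_variant_table <- function(n, sub_probs = NULL, p_indel = 0.1,
                                   p_multi = 0.05,
                                   depth_range = c(1L, 60L),
                                   mq_range = c(10L, 60L),
                                   seed = 1L) {
  if (is.null(sub_probs)) {
    sub_probs <- stats::setNames(rep(1 / 12, 12L), SUBSTITUTIONS)
  }
  stopifnot(setequal(names(sub_probs), SUBSTITUTIONS))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(seed)
  kind <- sample(c("snp", "indel", "multi"), n, replace = TRUE,
                 prob = c(1 - p_indel - p_multi, p_indel, p_multi))
  sub <- sample(SUBSTITUTIONS, n, replace = TRUE,
                prob = sub_probs[SUBSTITUTIONS])
  ref <- substr(sub, 1L, 1L)
  alt <- substr(sub, 3L, 3L)
  alt[kind == "indel"] <- paste0(ref[kind == "indel"],
                                 strrep("A", sample(1:3, sum(kind == "indel"),
                                                    replace = TRUE)))
  alt[kind == "multi"] <- vapply(which(kind == "multi"), function(i) {
    paste(sample(setdiff(BASES, ref[i]), 2L), collapse = ",")
  }, "")
  tibble::tibble(
    chrom = "chr1",
    pos = sort(sample.int(10L * n, n)),
    ref = ref, alt = alt,
    depth = sample(depth_range[1]:depth_range[2], n, replace = TRUE),
    map_q = sample(mq_range[1]:mq_range[2], n, replace = TRUE)
  )
}

#' Write a variant tibble as a minimal VCF 4.2 file
#'
#' @param records Variant tibble (`chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `map_q`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"RMS mapping quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- ifelse(
    is.na(records$depth) | is.na(records$map_q),
    ifelse(is.na(records$depth) & is.na(records$map_q), ".",
           ifelse(is.na(records$depth),
                  paste0("MQ=", records$map_q),
                  paste0("DP=", records$depth))),
    paste0("DP=", records$depth, ";MQ=", records$map_q)
  )
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", "PASS", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
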