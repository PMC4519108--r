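one_seq <- function(s) tibble::tibble(id = "x", seq = s)

test_that("the 20 bp tract-length threshold is an inclusive boundary", {
  at20 <- find_ssrs(one_seq(strrep("AT", 10)))
  expect_equal(nrow(at20), 1L)
  expect_equal(at20$period, 2L)
  expect_equal(at20$motif, "AT")
  expect_equal(at20$copies, 10L)
  expect_equal(at20$tract_len, 20L)
  expect_equal(c(at20$start, at20$end), c(0L, 20L))

  expect_equal(nrow(find_ssrs(one_seq(strrep("AT", 9)))), 0L)  # 18 bp
})

test_that("planted tracts are recovered with exact boundaries", {
  withr::local_seed(17)
  plants <- list(
    list(motif = "AG", copies = 12L),
    list(motif = "AAT", copies = 8L),
    list(motif = "ACGT", copies = 6L),
    list(motif = "AACGT", copies = 5L),
    list(motif = "AACGTAG", copies = 4L)
  )
  # space tracts far apart in a 10 kb sequence of non-repetitive filler
  filler <- function(n) {
    repeat {
      s <- random_dna(n)
      if (nrow(find_ssrs(one_seq(s))) == 0L) return(s)
    }
  }
  parts <- character(0)
  truth <- list()
  pos <- 0L
  for (p in plants) {
    gap <- filler(1500L)
    tract <- strrep(p$motif, p$copies)
    # guard the junctions so the tract stays maximal
    left_ch <- setdiff(c("A", "C", "G", "T"),
                       substr(p$motif, nchar(p$motif), nchar(p$motif)))[1]
    right_ch <- setdiff(c("A", "C", "G", "T"), substr(p$motif, 1, 1))[1]
    parts <- c(parts, gap, left_ch, tract, right_ch)
    start <- pos + 1500L + 1L
    truth[[length(truth) + 1L]] <- c(start = start,
                                     len = nchar(tract))
    pos <- start + nchar(tract) + 1L
  }
  seq <- paste(parts, collapse = "")
  found <- find_ssrs(one_seq(seq))
  expect_equal(nrow(found), length(plants))
  expect_equal(found$start, vapply(truth, `[[`, 0L, "start"))
  expect_equal(found$tract_len, vapply(truth, `[[`, 0L, "len"))
  expect_equal(found$motif,
               vapply(plants, `[[`, "", "motif"))
})

test_that("detector agrees with the brute-force oracle on random sequences", {
  withr::local_seed(19)
  for (rep in 1:60) {
    # AT-rich alphabet raises the accidental-repeat rate
    s <- paste(sample(c("A", "T", "A", "T", "C", "G"), 800, replace = TRUE),
               collapse = "")
    got <- find_ssrs(one_seq(s))
    want <- oracle_ssrs(s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0L) {
      expect_equal(got$start, want$start)
      expect_equal(got$period, want$period)
      expect_equal(got$motif, want$motif)
      expect_equal(got$copies, want$copies)
      expect_equal(got$trailing_bp, want$trailing_bp)
    }
  }
})

test_that("a tract is reported only at its true period", {
  # (AT)x12 must never surface as an ATAT period-4 locus
  found <- find_ssrs(one_seq(strrep("AT", 12)))
  expect_equal(found$period, 2L)
  # homopolymer disguised as a di: "AA" is period 1, rejected
  expect_equal(nrow(find_ssrs(one_seq(strrep("A", 40)))), 0L)
  # no reported locus contained in another with smaller period
  withr::local_seed(23)
  for (rep in 1:20) {
    s <- paste0(random_dna(200), strrep("CAG", 9), random_dna(200),
                strrep("TA", 14), random_dna(200))
    loci <- find_ssrs(one_seq(s))
    if (nrow(loci) < 2L) next
    for (i in seq_len(nrow(loci))) {
      inside <- loci$start >= loci$start[i] & loci$end <= loci$end[i] &
        loci$period < loci$period[i]
      inside[i] <- FALSE
      expect_false(any(inside))
    }
  }
})

test_that("partial trailing copies are noted but not counted", {
  # (GAA)x7 + "GA" = 23 bp region, 21 bp tract, 2 bp trailing
  found <- find_ssrs(one_seq(paste0("C", strrep("GAA", 7), "GAC")))
  expect_equal(found$copies, 7L)
  expect_equal(found$tract_len, 21L)
  expect_equal(found$trailing_bp, 2L)
})

test_that("tracts containing N are suppressed when forbid_N is set", {
  s <- paste0(strrep("AT", 6), "N", strrep("TA", 6))
  expect_equal(nrow(find_ssrs(one_seq(s))), 0L)
  cfg <- ssr_config(min_tract_len = 12L, forbid_N = FALSE)
  expect_gt(nrow(find_ssrs(one_seq(s), cfg)), 0L)
})

test_that("canonical_motif normalizes rotation and strand", {
  expect_equal(canonical_motif("TA"), "AT")
  expect_equal(canonical_motif("GAA", "minus"), "CTT")
  expect_equal(canonical_motif("AT", "minus"), "AT")
  expect_error(canonical_motif("AXT"), "A,C,G,T")
})

test_that("canonical_motif is idempotent under plus orientation", {
  withr::local_seed(29)
  for (rep in 1:100) {
    p <- sample(2:7, 1L)
    m <- random_dna(p)
    for (o in c("plus", "minus")) {
      cm <- canonical_motif(m, o)
      expect_equal(canonical_motif(cm, "plus"), cm)
    }
  }
})
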