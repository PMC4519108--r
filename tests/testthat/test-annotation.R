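hit_tbl <- function(seq_id, descriptor, evalue = 1e-20,
                    q_start = 150L, q_end = 300L) {
  tibble::tibble(seq_id = seq_id, descriptor = descriptor,
                 q_start = q_start, q_end = q_end, evalue = evalue)
}

test_that("blacklisted descriptors exclude their sequences", {
  hits <- dplyr::bind_rows(
    hit_tbl("s1", "chloroplast ribulose bisphosphate carboxylase"),
    hit_tbl("s2", "putative kinase"),
    hit_tbl("s3", "Retro-Element pol polyprotein"),
    hit_tbl("s4", "60S ribosomal protein L7"),
    hit_tbl("s5", "mitochondria ATP synthase", evalue = 1e-2)
  )
  # genomic list, E <= 1e-9: s5's weak hit is ignored
  expect_equal(keyword_filter(hits, genomic_blacklist(), 1e-9),
               c("s1", "s3"))
  # EST list at 0.001 adds ribosomal; s5 still above threshold
  expect_equal(keyword_filter(hits, est_blacklist(), 0.001),
               c("s1", "s3", "s4"))
})

test_that("keyword matching survives case and punctuation variation", {
  variants <- c("RetroElement", "retro element", "RETRO-ELEMENT",
                "a retro-element-like protein")
  hits <- hit_tbl(paste0("s", seq_along(variants)), variants)
  # oracle: strip non-alphanumerics, lowercase, substring test
  oracle <- hits$seq_id[grepl("retroelement",
                              gsub("[^a-z0-9]", "", tolower(hits$descriptor)),
                              fixed = TRUE)]
  expect_equal(keyword_filter(hits, c("retroelement"), 1), sort(oracle))
  expect_equal(keyword_filter(hits, c("retro-element"), 1), sort(oracle))
})

test_that("growing the blacklist never shrinks the excluded set", {
  withr::local_seed(51)
  words <- c("kinase", "chloroplast", "ribosomal", "transporter",
             "mitochondria", "gag protein", "helicase")
  hits <- hit_tbl(paste0("s", 1:40),
                  replicate(40, paste(sample(words, 2), collapse = " ")))
  keys <- c("chloroplast", "mitochondria", "ribosomal", "gag protein")
  prev <- character(0)
  for (k in seq_along(keys)) {
    cur <- keyword_filter(hits, keys[1:k], 1)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("position categories follow the overlap rule", {
  locus <- function(start, end) {
    tibble::tibble(seq_id = "s1", start = start, end = end)
  }
  region <- hit_tbl("s1", "x", q_start = 150L, q_end = 300L)
  expect_equal(position_category(locus(100L, 120L), region), "before")
  expect_equal(position_category(locus(350L, 380L), region), "after")
  expect_equal(position_category(locus(290L, 310L), region), "within")
  expect_equal(position_category(locus(100L, 120L), NULL), "no_homology")
  # 1-bp overlap at the boundary counts as within
  expect_equal(position_category(locus(149L, 160L), region), "within")
  # swapped hit coordinates are normalized
  rev_region <- hit_tbl("s1", "x", q_start = 300L, q_end = 150L)
  expect_equal(position_category(locus(100L, 120L), rev_region), "before")
  expect_error(position_category(
    tibble::tibble(seq_id = "other", start = 1L, end = 30L), region),
    "different sequences")
})

test_that("categorize_panel partitions the panel and keeps totals", {
  cand <- tibble::tibble(
    seq_id = paste0("s", 1:6),
    start = c(100L, 100L, 350L, 50L, 40L, 200L),
    end = c(120L, 120L, 380L, 80L, 70L, 240L)
  )
  hits <- dplyr::bind_rows(
    hit_tbl("s1", "a"),                       # before -> outside
    hit_tbl("s2", "b"),                       # before -> outside
    hit_tbl("s3", "c"),                       # after  -> outside
    hit_tbl("s6", "d", q_start = 180L, q_end = 260L)  # within
  )                                            # s4, s5: no hit
  res <- categorize_panel(cand, hits)
  expect_equal(res$counts$outside_homology, 3L)
  expect_equal(res$counts$no_homology, 2L)
  expect_equal(res$counts$within_homology, 1L)
  expect_equal(sum(unlist(res$counts)), nrow(cand))

  allmiss <- categorize_panel(cand, hits[0, ])
  expect_equal(unlist(allmiss$counts),
               c(outside_homology = 0L, no_homology = 6L,
                 within_homology = 0L))
})

test_that("category counts always partition random panels", {
  withr::local_seed(53)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    cand <- tibble::tibble(
      seq_id = paste0("s", 1:n),
      start = sample(1:500, n, replace = TRUE)
    )
    cand$end <- cand$start + sample(20:60, n, replace = TRUE)
    with_hit <- sample(n, sample(0:n, 1))
    hits <- if (length(with_hit) > 0) {
      hit_tbl(paste0("s", with_hit), "desc",
              q_start = sample(1:400, length(with_hit), replace = TRUE),
              q_end = sample(100:600, length(with_hit), replace = TRUE))
    } else hit_tbl(character(0), character(0))[0, ]
    res <- categorize_panel(cand, hits)
    expect_equal(sum(unlist(res$counts)), n)
    expect_true(all(res$categories$category %in%
                      c("before", "after", "within", "no_homology")))
  }
})

test_that("multiple hits per sequence resolve to the smallest E-value", {
  cand <- tibble::tibble(seq_id = "s1", start = 100L, end = 120L)
  hits <- dplyr::bind_rows(
    hit_tbl("s1", "weak", evalue = 1e-5, q_start = 10L, q_end = 90L),
    hit_tbl("s1", "strong", evalue = 1e-40, q_start = 200L, q_end = 400L)
  )
  res <- categorize_panel(cand, hits)
  expect_equal(res$categories$category, "before")  # judged vs the strong hit
})
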