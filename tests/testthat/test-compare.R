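match_row <- function(query, subject, evalue = 1e-20, identity = 99,
                      q_start = 1L, q_end = 500L, s_start = 1L,
                      s_end = 500L, aln_len = 500L) {
  paste(query, subject, identity, aln_len, 2, 0, q_start, q_end,
        s_start, s_end, format(evalue), 900, sep = "\t")
}

test_that("load_match_table applies the E-value cutoff", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(match_row("q1", "s1", evalue = 1e-12),
               match_row("q2", "s2", evalue = 1e-6)), path)
  tab <- load_match_table(path)
  expect_equal(tab$query_id, "q1")    # 1e-6 exceeds the e-9 maximum
  expect_equal(tab$evalue, 1e-12)
})

test_that("load_match_table reports the malformed line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(match_row("q1", "s1"),
               "q2\ts2\tbroken",
               match_row("q3", "s3")), path)
  expect_error(load_match_table(path), "line 2")
})

test_that("internal_match finds identical contigs at full identity", {
  withr::local_seed(31)
  shared <- random_dna(500)
  p1 <- tibble::tibble(id = "a1", seq = shared)
  p2 <- tibble::tibble(id = "b1", seq = shared)
  m <- internal_match(p1, p2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pct_identity, 100)
  expect_equal(m$aln_len, 500L)
  expect_equal(m$evalue, 0)
})

test_that("contigs sharing no seed k-mer do not match", {
  p1 <- tibble::tibble(id = "a1", seq = random_dna_seeded(400, 32))
  p2 <- tibble::tibble(id = "b1", seq = random_dna_seeded(400, 33))
  expect_equal(nrow(internal_match(p1, p2)), 0L)
})

test_that("planted substitutions depress identity proportionally", {
  withr::local_seed(34)
  base <- random_dna(1000)
  ch <- strsplit(base, "")[[1]]
  flip <- sample(1000L, 20L)                 # 2% divergence
  for (i in flip) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  p1 <- tibble::tibble(id = "a1", seq = base)
  p2 <- tibble::tibble(id = "b1", seq = paste(ch, collapse = ""))
  m <- internal_match(p1, p2)
  expect_equal(nrow(m), 1L)
  expect_gt(m$pct_identity, 96)
  expect_lt(m$pct_identity, 100)
})

test_that("minus-strand partners are matched with flipped coordinates", {
  withr::local_seed(35)
  shared <- random_dna(600)
  p1 <- tibble::tibble(id = "a1", seq = shared)
  p2 <- tibble::tibble(id = "b1", seq = revcomp(shared))
  m <- internal_match(p1, p2)
  expect_equal(nrow(m), 1L)
  expect_gt(m$s_start, m$s_end)
})

# --- pair_ssrs -------------------------------------------------------

two_genotype_fixture <- function(copies1, copies2, motif = "AT",
                                 seed = 41) {
  withr::with_seed(seed, {
    p <- nchar(motif)
    repeat {
      left <- random_dna(300); right <- random_dna(300)
      if (substr(left, 300, 300) != substr(motif, p, p) &&
          substr(right, 1, 1) != substr(motif, 1, 1)) break
    }
    p1 <- tibble::tibble(id = "P1_x", seq = paste0(left, strrep(motif, copies1), right))
    p2 <- tibble::tibble(id = "P2_x", seq = paste0(left, strrep(motif, copies2), right))
    list(p1 = p1, p2 = p2)
  })
}

test_that("the tract-length rule separates polymorphic from monomorphic", {
  fx <- two_genotype_fixture(12L, 10L)      # delta 4 >= period 2
  calls <- pair_ssrs(internal_match(fx$p1, fx$p2),
                     find_ssrs(fx$p1), find_ssrs(fx$p2))
  expect_equal(calls$verdict, "polymorphic")
  expect_equal(calls$p1_tract_len, 24L)
  expect_equal(calls$p2_tract_len, 20L)

  fx2 <- two_genotype_fixture(8L, 8L, motif = "GAA", seed = 42)
  calls2 <- pair_ssrs(internal_match(fx2$p1, fx2$p2),
                      find_ssrs(fx2$p1), find_ssrs(fx2$p2))
  expect_equal(calls2$verdict, "monomorphic")
})

test_that("an SSR with no matched partner contig is a no_match", {
  fx <- two_genotype_fixture(12L, 12L)
  other <- tibble::tibble(id = "P2_y", seq = random_dna_seeded(600, 43))
  calls <- pair_ssrs(internal_match(fx$p1, other),
                     find_ssrs(fx$p1), find_ssrs(other))
  expect_equal(calls$verdict, "no_match")
  expect_true(is.na(calls$p2_seq_id))
})

test_that("pair_ssrs rejects match rows with unknown sequence ids", {
  fx <- two_genotype_fixture(12L, 10L)
  m <- internal_match(fx$p1, fx$p2)
  expect_error(
    pair_ssrs(m, find_ssrs(fx$p1), find_ssrs(fx$p2),
              known_ids = "something_else"),
    "unknown sequence id"
  )
})

test_that("every genotype-1 SSR receives exactly one verdict", {
  sim <- generate_pair(sim_config(n_contigs = 30L, n_decoys = 0L,
                                  seed = 44))
  ssrs1 <- find_ssrs(sim$p1); ssrs2 <- find_ssrs(sim$p2)
  calls <- pair_ssrs(internal_match(sim$p1, sim$p2), ssrs1, ssrs2)
  expect_equal(nrow(calls), nrow(ssrs1))
  expect_true(all(calls$verdict %in%
                    c("polymorphic", "monomorphic", "no_match")))
  counts <- table(calls$verdict)
  expect_equal(sum(counts), nrow(ssrs1))
})

test_that("reconciliation keeps only bidirectionally polymorphic pairs", {
  call_tbl <- function(p1, p2, motif, v) {
    tibble::tibble(p1_seq_id = p1, p2_seq_id = p2, motif = motif,
                   p1_tract_len = 24L, p2_tract_len = 20L, period = 2L,
                   verdict = v, p1_start = 10L, p1_end = 34L)
  }
  c12 <- dplyr::bind_rows(
    call_tbl("a1", "b1", "AT", "polymorphic"),
    call_tbl("a2", "b2", "AC", "polymorphic"),   # asymmetric: mono in 2v1
    call_tbl("a3", "b3", "AG", "monomorphic")
  )
  c21 <- dplyr::bind_rows(
    call_tbl("b1", "a1", "AT", "polymorphic"),
    call_tbl("b2", "a2", "AC", "monomorphic"),
    call_tbl("b3", "a3", "AG", "monomorphic")
  )
  rec <- bidirectional_reconcile(c12, c21)
  expect_equal(rec$panel$p1_seq_id, "a1")
  g <- glance(rec)
  expect_equal(g$`1v2_polymorphic`, 2L)
  expect_equal(g$`2v1_polymorphic`, 1L)
  expect_equal(g$n_reconciled_polymorphic, 1L)
})

test_that("swapping genotypes leaves the reconciled panel invariant", {
  sim <- generate_pair(sim_config(n_contigs = 25L, n_decoys = 0L,
                                  p_no_match = 0, seed = 45))
  cfg <- compare_config()
  s1 <- find_ssrs(sim$p1); s2 <- find_ssrs(sim$p2)
  m12 <- internal_match(sim$p1, sim$p2, cfg)
  m21 <- internal_match(sim$p2, sim$p1, cfg)
  fwd <- bidirectional_reconcile(pair_ssrs(m12, s1, s2, cfg),
                                 pair_ssrs(m21, s2, s1, cfg))
  swp <- bidirectional_reconcile(pair_ssrs(m21, s2, s1, cfg),
                                 pair_ssrs(m12, s1, s2, cfg))
  key_fwd <- sort(paste(fwd$panel$p1_seq_id, fwd$panel$p2_seq_id,
                        fwd$panel$motif))
  key_swp <- sort(paste(swp$panel$p2_seq_id, swp$panel$p1_seq_id,
                        swp$panel$motif))
  expect_equal(key_fwd, key_swp)
})
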