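# ssrforge

Cross-genotype microsatellite (SSR) marker discovery from draft
assemblies, in R.

## The problem

Breeding programs for crops without reference-grade genomes still lean
heavily on simple sequence repeat (SSR) markers: short tandem repeats
whose copy number differs between genotypes, genotyped cheaply by PCR
product length. Given two *de novo* draft assemblies of related
genotypes, which repeats are worth ordering primers for? Most detected
SSRs fail in the lab — the tract may be identical in both parents
(monomorphic), the flanks may not support primers, or the "marker" may
sit in organellar or retroelement sequence.

`ssrforge` implements the full in-silico triage as a tested,
tibble-first R library plus a thin CLI:

1. **Enrichment** — compute assembly statistics and keep only contigs
   longer than the assembly's N50 (`assembly_stats()`, `n50_filter()`).
2. **Repeat scanning** — find every maximal perfect tandem repeat with
   motif period 2–7 and tract length ≥ 20 bp (`find_ssrs()`), with
   rotation/strand motif canonicalization (`canonical_motif()`).
3. **Primer design** — pick a flanking primer pair under conventional
   length/Tm/GC/product constraints (nearest-neighbor melting
   temperatures), and drop pairs whose primers occur more than once in
   the assembly (`design_panel()`, `uniqueness_screen()`).
4. **Cross-genotype comparison** — match SSR-bearing contigs between
   the genotypes in both directions (external 12-column tabular
   alignment files via `load_match_table()`, or the built-in
   seed-and-extend matcher `internal_match()`), pair shared SSRs, and
   call each pair **polymorphic** (tract lengths differ by at least one
   motif period), **monomorphic**, or **no match** (`pair_ssrs()`).
   The final panel keeps only pairs polymorphic in both directions
   (`bidirectional_reconcile()`).
5. **Annotation filtering** — exclude sequences whose protein-homology
   descriptors contain organellar/repetitive keywords
   (`keyword_filter()`), and classify each repeat as before / after /
   within its sequence's homology region (`categorize_panel()`).
6. **Variant spectra** — hard-filter a VCF at DP ≥ 10 and MQ ≥ 30 and
   tally the 12 directed nucleotide substitutions and Ti/Tv
   (`hard_filter()`, `classify_and_count()`).
7. **Reporting** — motif-class × status tables with class percentages,
   panel polymorphism/failure rates, and alignment-outcome shares
   (`motif_distribution()`, `panel_rates()`,
   `alignment_outcome_summary()`).

A seeded synthetic-data generator (`generate_pair()`) builds paired
two-genotype assemblies with planted repeat truth — copy-number
deltas, deleted partner contigs, flank SNPs, reverse-complemented
partners, organellar decoys — so the whole pipeline is testable
offline.

## Worked example

```r
library(ssrforge)

sim <- generate_pair(sim_config(n_contigs = 40, n_decoys = 3, seed = 7))
res <- run_pipeline(sim$p1, sim$p2, annotations = sim$annotations,
                    ditri_only = FALSE, quiet = TRUE)
res
#> ssrforge pipeline result
#>   final marker panel: 13 loci
#>
#>           stage n_in n_out
#>         scan_p1   43    43
#>         scan_p2   39    39
#>      primers_p1   43    43
#>   uniqueness_p1   43    43
#>     compare_1v2   43    43
#>     compare_2v1   39    39
#>       reconcile   16    16
#>  keyword_filter   16    13
```

43 contigs (40 ordinary + 3 organellar decoys) each carry one planted
SSR; 39 survive in genotype 2 (4 partners deleted). All 43 loci get
primers that pass uniqueness, and each direction calls one verdict per
locus. 16 genotype-1 calls are polymorphic and all 16 are confirmed in
the reciprocal direction; the keyword filter then removes the 3 decoy
markers (their descriptors contain "chloroplast", "mitochondria",
"retro-element"), leaving the 13 genuinely nuclear polymorphic loci.
Per-locus calls and summaries are tibbles:

```r
tidy(res)                  # final panel: ids, motif, tract lengths, verdict
glance(res)                # per-direction verdict counts, panel size
tidy(res$comparison, "1v2")

panel_rates(314, 62, 8)
#> # A tibble: 1 x 7
#>   n_poly n_mono n_failed pct_polymorphic pct_failure pct_polymorphic_display
#>    <dbl>  <dbl>    <dbl>           <dbl>       <dbl>                   <dbl>
#> 1    314     62        8            83.5        2.08                      84
```

A panel of 314 polymorphic, 62 monomorphic and 8 failed markers is
83.51% polymorphic among markers that amplified, with a 2% failure
rate over all markers tested — note the two deliberately different
denominators.

`autoplot()` methods draw the motif-class distribution
(`marker_summary`) and the substitution spectrum (`variant_spectrum`).
A command-line front end for every stage lives at
`inst/cli/ssrforge.R` (`stats`, `enrich`, `scan`, `primers`, `compare`,
`annotate-filter`, `vcf-spectrum`, `simulate`, `pipeline`).

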