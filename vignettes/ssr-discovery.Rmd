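---
title: "Cross-genotype SSR marker discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-genotype SSR marker discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrforge)
```

`ssrforge` predicts which microsatellites (SSRs) will behave as
polymorphic PCR markers between two related genotypes, given only their
draft assemblies. This vignette explains the underlying models, the
parameters that matter, the numerical choices, and what the synthetic
fixtures do and do not establish about real data.

## The repeat model

An SSR locus is a *perfect* tandem repetition of a motif of period 2–7
bp. The scanner (`find_ssrs()`) reports every maximal tract whose
whole-copy length reaches `min_tract_len` (default 20 bp, the usual
floor for a fragment-length-genotypable repeat). Three conventions
remove ambiguity:

* **True period only.** A motif that is itself a repetition of a
  shorter unit (e.g. `ATAT`, or the period-1 run `AA`) is never
  reported; `(AT)x10` surfaces once, as a period-2 locus.
  Mononucleotide runs are excluded altogether — they are poor markers
  and standard motif classes start at dinucleotides.
* **Left anchoring, integral copies.** A maximal repeat region may end
  in a partial motif copy. The tract is anchored at the region's
  leftmost base, `copies` counts whole copies, and the partial remnant
  is reported as `trailing_bp`. Tract length is therefore always
  `copies * period`, which keeps allele-length arithmetic exact.
* **Compound tracts** (adjacent tracts of different motifs) are
  separate loci; imperfect repeats are out of scope by design — a
  single mismatch terminates a tract.

Internally coordinates are 0-based half-open; every table writer emits
1-based inclusive coordinates and says so.

Motif identity across assemblies is decided on canonical forms:
`canonical_motif()` takes the lexicographically smallest rotation
(reverse-complementing first for minus-strand hits), and
`motif_strand_class()` additionally collapses the two strands — the
form used when reconciling the two search directions, since either
assembler may have stored either strand.

## From repeat to marker candidate

`design_primers()` searches up to `flank_window` (200 bp) on each side
of a tract for primers of 18–24 bp, melting temperature 55–62 °C,
GC fraction 0.40–0.60, homopolymer runs ≤ 4, and an amplicon of
100–400 bp containing the whole tract. Melting temperatures use the
unified nearest-neighbor thermodynamic parameters (SantaLucia 1998)
with a 16.6·log10[Na+] salt correction at 50 mM Na+ and 250 nM primer;
the Wallace 2+4 rule is included (`tm_wallace()`) as an independent
cross-check. Among feasible pairs the winner minimizes the
forward/reverse Tm difference, then product length, with positional
tie-breaks, so design is deterministic. Design failure is an expected,
counted outcome, not an error: real flanks frequently cannot host a
compliant pair. These constraint values are conventional for SSR
genotyping panels and fully configurable; no downstream contract
depends on a specific primer sequence.

`uniqueness_screen()` then removes any candidate whose forward or
reverse primer occurs more than once — as an exact substring on either
strand — across the background contig set, since such a primer could
prime off-target. Exact matching was chosen over k-mismatch
uniqueness, which is under-specified and an order of magnitude more
expensive.

## Cross-genotype comparison

Contig matching accepts external 12-column tabular alignment tables
(rows above the `max_evalue` cutoff of 1e-9 are discarded) or uses the
built-in matcher. `internal_match()` is a seed-and-extend aligner:
exact 21-mer seeds, indexed on both subject strands, define diagonals;
each seed-supported diagonal becomes an ungapped segment and the
segments of one contig pair merge into a single alignment row. A
repeat-length difference between otherwise homologous contigs shifts
the downstream flank by a fixed offset, so such a pair yields exactly
two diagonals — the merged row is the equivalent of a gapped alignment
with one gap, at a fraction of the cost. Two guards keep seeds honest:

* a seed must contain at least 6 bases outside any short-period repeat
  region, otherwise two unrelated contigs sharing a motif would "match"
  through their tracts alone;
* singleton diagonals are dropped when better-supported ones exist,
  and any segment whose own identity falls below `min_identity` is
  discarded as a seed artifact.

Pairs must reach 90% identity over 100 aligned bases. The `evalue`
field of internally generated rows is 0, a sentinel meaning
"internally matched, no E-value statistics" — reproducing BLAST
statistics is a non-goal.

`pair_ssrs()` gives every genotype-1 SSR exactly one verdict. Its
contig's match rows are ranked by E-value, then percent identity, then
subject id; rows are tried in order and the first yielding a
*correspondence* decides. A genotype-2 SSR corresponds when (a) the
canonical motifs agree after orientation adjustment and (b) the
genotype-1 tract midpoint, mapped through the alignment, lands within
`flank_tol` (10 bp) of the genotype-2 tract midpoint. Midpoint
tolerance was chosen over exact coordinate mapping to absorb
indel-containing flanks and the approximation of interpolating through
gapped external alignments. Mapping is linear interpolation between
the alignment's endpoints — exact for ungapped rows, and accurate at
tract midpoints for single-indel rows because the interpolation error
is proportional to the tract's relative position in the contig.

The verdict rule: with both tracts present, a tract-length difference
of at least one motif period is **polymorphic**, anything smaller is
**monomorphic**; otherwise **no match**. Since perfect tracts can only
differ by whole periods, one period is the smallest observable allele
difference — the natural reading of "polymorphic by repeat length",
and configurable.

Because best-hit choices need not be symmetric, both directions are
computed and `bidirectional_reconcile()` keeps only pairs polymorphic
in both, retaining the per-direction count tables (the two directions
routinely disagree by a handful of calls). The end-to-end
`run_pipeline()` applies, in order: optional N50 enrichment → scan →
primer design and uniqueness → reciprocal comparison → reconciliation
→ keyword exclusion → optional di-/tri-nucleotide restriction. The
di/tri restriction mirrors how validation panels are usually picked
(longer motifs amplify and score less reliably); it is on in the
pipeline and off in library use.

## Enrichment, annotation and variant conventions

* **N50 enrichment.** `n50_filter()` keeps contigs *strictly* longer
  than the set's N50 — the literal reading of "greater than the N50" —
  with `strict = FALSE` for the inclusive variant. Note the corner
  case: in a set whose N50 equals its maximum length (e.g. lengths
  {100, 1}, or all lengths equal), the strict rule keeps nothing.
  `N` bases count toward contig length (scaffold gaps are part of the
  assembly) but are excluded from AT/GC composition denominators.
  Ambiguity codes other than `N` are rejected outright: repeat
  arithmetic on a fuzzy alphabet would be meaningless.
* **Keyword exclusion.** Descriptor matching is normalized substring —
  lowercase, all punctuation stripped — so "Retro-Element",
  "retroelement" and "retro element" behave identically; growing the
  blacklist can only grow the excluded set. Defaults: the EST-style
  list {ribosomal, retro-element, gag protein, chloroplast,
  mitochondria} at E ≤ 0.001, the genomic list {chloroplast,
  mitochondria, retroelement, gag protein} at E ≤ 1e-9.
* **Homology position.** One best hit per sequence (smallest E-value,
  ties by descriptor) positions each repeat before / after / within
  the homology region; *any* overlap counts as within, since partial
  overlap is otherwise undefined.
* **Variants.** DP and MQ are read from the site-level INFO fields
  (the samtools/bcftools convention); the hard filter keeps
  DP ≥ 10 ∧ MQ ≥ 30, both bounds inclusive, and records missing either
  annotation are dropped with a counted warning. Multiallelic sites are
  tallied once and excluded from the 12-cell substitution spectrum;
  strands are not collapsed (G→A and C→T stay separate cells), so the
  spectrum remains reference-directed.
* **Rates.** `panel_rates()` deliberately uses two denominators:
  % polymorphic over markers that amplified, % failure over all
  markers tested — the only reading under which a 314/62/8 panel is
  simultaneously ~84% polymorphic and ~2% failed. Machine output is
  2-decimal; display columns round to integers.

## The synthetic genotype pairs

`generate_pair()` emulates exactly the study conditions the pipeline
targets: two related draft assemblies, by default 200 contigs of
600–1200 bp each carrying one planted SSR (primitive motifs of period
2–7, 10–15 copies, so every tract is detectable at the 20 bp floor).
For each locus the genotype-2 partner is deleted with probability 0.1
(the "no match" class), otherwise differs by 1–3 copies with
probability 0.4, is reverse-complemented with probability 0.25, and
its flanks carry substitutions at a configurable per-base rate (0 by
default; 0.5% in the noisy test condition). Five decoy contigs carry
organellar/retroelement descriptors. Flanks are rejection-sampled so
that planted tracts are perfect, maximal and the *only* loci present,
and boundary bases are constrained so no tract extends into its flank.
Generation is deterministic given `seed` and restores the caller's RNG
state.

What passing on these fixtures shows: exact boundary recovery,
correct verdict logic under strand flips, indels-by-repeat-length,
flank SNPs, deletions, and correct exclusion of annotated decoys. What
it does not show: behavior on imperfect or compound repeats, on
assemblies with collapsed repeats or chimeric contigs, on gapped-flank
homology beyond single tract indels, or calibration of any E-value —
real BLAST tables should be preferred over the internal matcher when
an aligner is available.

Problem sizes in the shipped checks were chosen to exercise the
asymptotics while staying comfortable on a laptop: detector-vs-oracle
on 1,000 random 2-kb sequences, verdict recovery on 200-locus pairs,
N50 against brute force on 1,000 length multisets, a 1,000-record VCF
against a hand filter.

## Known limitations

* Perfect repeats only; a single interruption splits a tract.
* The internal matcher is ungapped-by-segments: flank indels *between*
  seeds are tolerated, but heavily gapped homology will under-align
  and should come from a real aligner via `load_match_table()`.
* Primer scoring ignores secondary structure, dimers and multiplex
  compatibility; tailed-genotyping chemistry is representable only as
  literal tail columns, with no thermodynamic treatment.
* Equal-length biallelic substitutions of more than one base (MNPs)
  are binned with indels by the variant classifier.
* E-values are never computed internally; external tables are filtered
  on the E-values they bring.

```{r example}
sim <- generate_pair(sim_config(n_contigs = 30, n_decoys = 2, seed = 1))
res <- run_pipeline(sim$p1, sim$p2, annotations = sim$annotations,
                    ditri_only = FALSE, quiet = TRUE)
res$stage_counts
glance(res)
```
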