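---
title: "Mapping drug-resistance landscapes from pooled-colony sequencing: methods and design"
author: "poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping drug-resistance landscapes from pooled-colony sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The problem and the procedure

Resistance screens against topoisomerase II poisons (ciprofloxacin, vosaroxin,
etoposide) can yield hundreds of surviving colonies, each carrying a plasmid
with a chemically mutagenized copy of the topoisomerase ORF. Sequencing
colonies one by one does not scale; instead, all colonies surviving a drug
selection are scraped together, the ORF is PCR-amplified from the pooled
plasmid DNA, fragmented, and deep-sequenced. The resistance "landscape" is
then read out computationally:

1. **Align** every read to the ORF amplicon, admitting only *unique*
   placements with *at most one mismatch* per read.
2. **Extract** mismatch-bearing reads and discard mismatches whose base
   quality falls below Q38 (99.98% base-calling confidence,
   `quality_confidence(38)`), so that calls reflect real plasmid variants
   rather than sequencing error.
3. **Convert** each surviving nucleotide mismatch to its amino-acid
   substitution via the codon containing it, counting *supporting reads* per
   substitution.
4. **Rank** substitutions by supporting reads and truncate to the **top N**
   (default 100): because the pool is a PCR product, read counts do not
   estimate colony counts, but highly supported mutations are unlikely to be
   artifacts.
5. **Map** the ranked landscape onto protein domains, compare it across
   phenotype classes (e.g. Cip^R^Vos^S^ vs Cip^R^Vos^R^ screens), audit its
   mutational spectrum, and check concordance with per-mutant validation
   phenotypes.

The package implements all five stages plus a synthetic-data generator that
reproduces the statistical structure this analysis assumes, so the whole
pipeline is testable end to end without any external data.

## The synthetic pool: what it emulates

`mutagenize()` models hydroxylamine mutagenesis of plasmid DNA. Hydroxylamine
is strongly biased toward GC->AT transitions, but the exact proportion varies
between preparations and is rarely measured, so the generator exposes it as
`gc_to_at_fraction` with **default 0.9**: a strong bias that still allows the
transversion-class hits (e.g. Pro->His changes) that real screens recover.
With probability `gc_to_at_fraction` an induced change is C->T or G->A at a
uniformly chosen C/G site; otherwise it is a uniformly chosen *other*
substitution, so the realized spectrum fraction is exactly Bernoulli in the
configured value and calibration tests can use exact binomial bands.

Mutations per plasmid are **Poisson(1.5)** by default. Selected, functional
alleles are dominated by one or two changes (a heavily mutated ORF rarely
complements); the mean is exposed for sensitivity analyses. Colony abundances
in the scraped pool are **log-normal (sdlog = 1)** by default, emulating the
uneven colony sizes of a plate scraped after three days of growth; a uniform
model is available for tests. PCR amplification bias is deliberately *not*
modeled: pooled-PCR read counts are known not to track colony numbers, and a
single abundance skew already produces that decoupling.

`simulate_reads()` produces single-end 100-nt reads (read length and pairing
of the original run are not critical to the method; single-end keeps the
aligner contract simple) from fragments uniform on **200-500 nt**, the
enzymatic fragmentation window of the library prep. Per-base Phred scores are
drawn from a configurable `quality_model` (the default is a discrete
Illumina-like mixture concentrated at Q40 with a low-quality tail), and when
`error_coupling` is on each base flips to a uniformly chosen other base with
probability `10^(-Q/10)`. What the generator does **not** emulate: adapter
read-through and quality trimming (inputs are assumed pre-trimmed), indels,
chimeric PCR artifacts, paired-end structure, and the compound ~30-35%
colony-count drop after mutagenesis (selection survival is purely
phenotype-driven via `apply_selection()`). Passing tests therefore demonstrate
correctness of the computational pipeline under its stated assumptions, not
robustness to every artifact of real libraries.

## The aligner and its contract

The reference is a single short amplicon, so the package uses an exact
k-mer seed index (`build_index()`, default **k = 31**) with non-overlapping
seed placement and full ungapped verification of every seed hit, rather than a
general-purpose genome aligner. With at most one mismatch allowed and reads at
least 2k long, at least one seed of any admissible placement is exact, so the
seed stage loses no sensitivity; this is verified against a brute-force
all-offset oracle in the test suite.

Statuses follow best-stratum semantics, stated declaratively so an oracle can
reproduce them:

* `unique` — exactly one placement attains the minimal mismatch count, and
  that count is <= 1. A read with one exact placement plus secondary
  1-mismatch placements is unique at the exact locus.
* `ambiguous` — two or more placements tie at the minimal count (<= 1);
  such reads are excluded from calling.
* `too_many_mismatches` — the read anchors to the reference (some seed
  matches exactly at an in-bounds placement) but every anchored placement
  carries >= 2 mismatches.
* `unmapped` — no seed anchors anywhere (including reads shorter than k).

`N` bases count as mismatches but are never emitted as observations (an `N`
cannot support a substitution call). Mismatches falling in the amplicon
flanks outside the ORF are counted in summaries but produce no ORF
observation. Quality strings are strictly Phred+33; scores outside [0, 62]
fail fast, which rejects Phred+64 data at parse time. All coordinates on
user-facing surfaces are 1-based (ORF nucleotide positions and residue
numbers from the initiator methionine), matching how mutations are named in
the field (e.g. E571K, W653STOP).

## Calling, ranking and numerical choices

`call_and_rank()` groups quality-filtered observations by `(orf_pos,
alt_base)` and counts supporting reads as *distinct read identifiers* (with
<= 1 mismatch per read these coincide with observation counts, but the
contract is stated for safety). A read whose single mismatch falls below the
quality threshold contributes nothing — it is not recounted as wild type.
Synonymous changes are always computed and flagged, and excluded from the
ranking by default (`include_synonymous = FALSE`); stop gains are kept by
default, since nonsense alleles can be genuine hits. An observation whose
recorded reference base disagrees with the reference sequence aborts the run
with the position named (corruption guard).

Ordering is fully deterministic: supporting reads descending, then residue
ascending, then alternate amino acid, then ORF position and base. The table
is truncated to `top_n` (default 100) and the supporting count at the last
reported rank is recorded as `threshold_reads` — the analogue of a screen's
read cutoff. Entries beyond rank N that tie with the rank-N count are never
dropped silently: they are reported in the `boundary_ties` attribute while
the default report stays exactly N rows. Whether a published top-100 was
computed over nucleotide mismatches or amino-acid-collapsed substitutions is
generally ambiguous; the package keeps nucleotide-level rows as the primary
view (two degenerate routes to one amino acid stay separate) and provides
`collapse_to_aa()` for the residue-level view.

Two invariants are enforced by property tests: raising `min_quality` never
increases any supporting count and never introduces new calls; and total
supporting reads never exceed the number of mismatch-bearing unique
alignments, with equality when nothing is filtered and synonymous calls are
included.

## Landscape analyses

`domain_tally()` assigns each call to the most deeply nested annotated domain
containing its residue ("deepest containment"); since published figures are
sometimes ambiguous about whether embedded-domain hits are counted in their
parent, both the deepest view and a `rollup = TRUE` parent view are provided.
`compare_screens()` partitions the union of two landscapes into
`A_only`/`B_only`/`shared` by `(residue, alt_aa)` identity — the residue-level
convention of structural overlap figures — with a nucleotide-level option.
`spectrum_audit()` reports the GC->AT fraction of a call set with
transversions listed for inspection. `selection_summary()` is the plating
bookkeeping (confirmed/plated, two decimals). `classify_resistance()` labels
validated mutants resistant when their log10 viable-count fold-change reaches
**2** (the 100-fold class; the strong class at >= 4 log10 corresponds to
10 000-fold), and scores concordance against the screen's expectation. The
threshold is exposed because published work describes the two strata rather
than a formal cutoff.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale chosen
so the statistics are decisive: a packaged synthetic 300-codon ORF with 60-nt
flanks; 10^4 randomized reads (0-3 injected substitutions, both strands, a
reference with an exact internal duplication) for oracle-equivalence; a
spike-in benchmark of 1 000 alleles carrying 30 known substitutions at >= 50x
realized site coverage from 50 000 reads with quality-coupled errors; a
20 000-read null run at constant Q38 for calibration against the analytic
expectation; and 10^4 induced changes per spectrum calibration point. Every
stochastic step takes an explicit seed, and identical configuration plus seed
yields byte-identical FASTQ, truth tables and call tables; the pipeline log
records seeds and input checksums so any stage can be re-run in isolation.

## Known limitations

The aligner is intentionally specialized to short amplicon references; it is
ungapped, so indel-bearing reads surface as `too_many_mismatches` or
`unmapped` rather than being recovered. Statistical enrichment against an
unselected input library is out of scope (such a control is typically not
sequenced in this design), as are UMI-based deduplication, consensus error
correction, and structural or conservation-based annotation of hits. Where a
published landscape depends on the full raw sequencing data (specific top-100
lists and their read cutoffs), the package reproduces the *procedure* and
validates it on synthetic ground truth rather than asserting those exact
values.
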