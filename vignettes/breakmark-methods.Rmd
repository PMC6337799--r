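---
title: "Mapping dsODN-marked double-strand breaks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dsODN-marked double-strand breaks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Cells transfected with a double-stranded oligodeoxynucleotide (dsODN) capture
the oligo into DNA double-strand breaks during repair, covalently marking
every break — nuclease-induced or spontaneous. Ligation-mediated nested PCR
from the integrated ODN out to a sonication-adapter then converts each marked
break into a sequencing amplicon whose structure is

```
primer2 | reporter | genomic flank (junction ... sonication break) -> adapter
```

The ODN–genome junction coordinate identifies the break; the sonication
breakpoint varies molecule by molecule and identifies independent source
fragments.

The central artifact in this assay is *mispriming*: PCR can initiate at
genomic loci that merely resemble the ODN primer, producing amplicons that
look exactly like break junctions. The fix implemented here uses a dsODN
long enough that the nested primer sits upstream of a *reporter* segment:
only molecules genuinely primed on the ODN carry the reporter in the read.
`detect_reporter()` performs an ungapped Hamming comparison of the reporter
against the read prefix; reads missing it (within
`reporter_max_mismatch`, default 1) are artifact candidates. A mode switch
(`mode = "guideseq"`) disables the filter so the unfiltered legacy analysis
can be run over identical reads and compared.

## From reads to sites

1. **Demultiplexing** by an exact barcode prefix on the adapter-side read
   (Hamming tolerance configurable, default 0).
2. **Trimming** removes `primer2` (+ reporter when present) so that
   position 0 of the genomic sequence *is* the junction base, removes
   barcode + adapter from the mate, and cuts 3' read-through into the
   reverse complement of the opposite element.
3. **Alignment**: a seeded (k = 15), ungapped aligner with a 5%-of-length
   mismatch budget places each fragment; the mate refines the sonication
   breakpoint. Real data can instead enter as SAM
   (`import_sam()`, MAPQ floor 30 — a convention, not a calibrated value).
   Ties in best score are never broken arbitrarily: tied fragments are
   flagged non-unique and excluded from site calling (but counted).
4. **Site calling**: unique junctions are chained single-linkage with
   `cluster_gap` (default 25 bp — wider than Cas9 resection spread, narrow
   enough to keep nearby loci apart; the value is recorded in run
   metadata). The site position is the abundance-weighted modal junction
   with ties broken toward the smaller coordinate — junctions are discrete
   and the mode matches the pile-up reading, robust to resection tails.

## Abundance: inferred cells

PCR duplicates carry no information about how many cells contributed a
break. Sonication shear points do: each independently isolated fragment has
its own breakpoint. `quantify_abundance()` counts distinct
`(strand, junction, break)` signatures per site. Both endpoints and the
strand enter the signature so equal fragment *lengths* arising from
different junctions or orientations never collapse.

## On/off-target annotation

`scan_guide()` finds every genomic window (both strands) matching at least
`match_min` of the 20 protospacer bases — positional identities only, no
gaps or bulges — with a perfect IUPAC match to the PAM (default `NGG`).
Defaults are `match_min = 14/20` and an assignment window of
`match_window = 100` bp between a site and a match's cut position; the cut
sits `cut_offset = -3` bp from the PAM (standard blunt SpCas9 geometry,
configurable). An ambiguous genome base `N` matches nothing except the `N`
PAM symbol. The distance anchor is the match's *cut position* — the
biologically meaningful point — though the anchor choice is reported with
the output.

Specificity is reported under both accounting rules:

* **filtered** — on-target abundance over the abundance of guide-matched
  sites only;
* **unfiltered** — the same numerator over *all* site abundance, so
  spontaneous breaks count against the nuclease.

The filtered estimate can never fall below the unfiltered one (its
denominator is a subset), which the test suite asserts on every simulation.

## The mispriming diagnostic

If residual misprimed molecules are present, their inferred junctions abut
genomic sequence resembling the primer. `score_flank()` extracts the
`|primer|` bases ending at each junction on the priming strand (3'-anchored:
extension requires a matched 3' terminus) and counts identities to the
primer. A null distribution is built from uniformly sampled positions of
the *same* assembly (controlling base composition), and
`mispriming_test()` applies a one-sided two-sample rank test with the
tie-corrected normal approximation — scores are small integers with heavy
ties, which favours a rank test over a Kolmogorov–Smirnov statistic. Events
are deduplicated to distinct loci before scoring so PCR depth does not
pseudo-replicate the sample. The fraction of loci above the null's 99th
percentile is reported alongside.

## Annotation enrichment

For each annotation track and window size, local densities are computed at
site positions and at seeded uniform random positions (3 per site, non-N),
and summarised as the rank-based ROC area
\(P(\text{site} > \text{control}) + \tfrac12 P(\text{tie})\): 0.5 means no
association, above 0.5 enrichment (red in heatmaps), below depletion
(blue). Significance is by label permutation (default 10,000 shuffles,
seeded; a tie-corrected normal approximation is available), with stars at
the conventional raw-p thresholds (\*\*\* < 0.001 ≤ \*\* < 0.01 ≤ \* <
0.05); a Benjamini–Hochberg column is additionally emitted because the
heatmap tests many cells. Window sizes default to 1 kb–1 Mb including the
canonical 10 kb. Interval tracks yield the covered fraction of the window;
numeric tracks (e.g. the built-in per-tile AT fraction, `at_track()`) yield
the length-weighted mean. Windows are clipped at contig edges and the
denominator is the clipped width — a fixed denominator would deplete edge
windows artificially and break the exact-0.5 identity for a
whole-genome track. A percent-enrichment summary,
`100 * (mean site density - mean control density) / mean control density`,
is emitted with each cell and documented in the output metadata.

## What the simulator emulates — and what it does not

`simulate_genome()` draws i.i.d. sequence at a chosen GC content and lays
down a gene track; `plant_guide_sites()` writes protospacer variants with
*exactly* the requested substitution counts plus a concrete PAM;
`plant_spontaneous_sites()` adds guide-free breaks, optionally biased into
genes; `plant_misprime_loci()` writes the primer immediately 5' of a
junction while forcing the downstream read prefix to stay dissimilar from
the reporter. `simulate_reads()` then emits the full amplicon grammar:
per-fragment strand (ODN enters breaks in both orientations), resection
offsets of ±2 bp around the cut, sonication lengths uniform on
`[read_len, 3*read_len]` (any spread exercising the deduplication logic
suffices; the value is not observable in the outputs), duplicate reads that
re-emit existing fragments with probability `dup_rate`, and misprimed reads
lacking the reporter. Sequencing error is off by default so recovery
assertions can be exact; a uniform substitution rate is available for
robustness experiments.

Deliberately not emulated: PCR chimeras (a distinct artifact class with no
published algorithmic definition to target), quality-score structure
(qualities are carried but unused — the method defines no quality filter),
indels, and the repeat/composition structure of real genomes. Passing tests
therefore demonstrate algorithmic correctness on a clean substrate, not
performance on human data: real genomes add multi-mapping (handled by
exclusion, at a sensitivity cost) and context-dependent mispriming the
uniform null only approximates.

Mispriming loci counts in simulations are chosen so that the fraction of
*distinct loci* affected matches the read-level mispriming fraction (e.g.
60 loci per 200 kb at 30% misprimed reads): mispriming arises wherever
primer-like sequence occurs, so its locus-level footprint mirrors its read
share rather than concentrating in a handful of positions. Planted-site
read weights default to 50 (on-target) : 5 (off-target) : 1 (spontaneous),
giving the dominant on-target pile-up and long spontaneous tail seen in
this assay class.

## Numerical and design choices

* All internal coordinates are 0-based half-open; BED output is 0-based,
  human-readable TSVs carry an explicit `position_1based` column.
* All randomness flows from explicit seeds; seeded helpers save and
  restore the caller's RNG state, so identical runs are byte-identical
  (hash-compared in tests).
* `roc_area` on two identical constant vectors is exactly 0.5; permutation
  p-values use the add-one estimator `(1 + #{perm >= obs}) / (B + 1)` and
  a small epsilon guards ties in the observed deviation.
* A completely tied rank test reports p = 0.5 with no direction.
* Degenerate inputs: empty event sets produce empty (not failing) site
  tables; a 1-vs-1 density comparison reports p = 1; a zero-abundance
  specificity denominator reports NA with an explicit reason string.
* Problem sizes in the shipped test suite: oracle equivalence on twenty
  100 kb genomes; end-to-end recovery on 50,000 read pairs over a 1 Mb
  genome; calibration suites at 200 replicates (rank test: n = 60 vs 400;
  permutation test: n = m = 30 at 2,000 shuffles). These sizes give the
  binomial margins quoted in the tests while keeping the suite quick on a
  single CPU.

## Known limitations

The aligner is ungapped by design (junction recovery, not variant calling);
indel-containing fragments near the junction will mis-place or drop.
Multi-mapping fragments are excluded from site calling, so breaks inside
repeats are under-counted. The reporter check is ungapped at a fixed
offset; an indel inside the reporter defeats it. The enrichment engine
treats tracks as given — it does not model track uncertainty. No
multiple-testing correction is applied to the starred raw p-values (the
adjusted column is provided separately).
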