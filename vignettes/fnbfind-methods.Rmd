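---
title: "Finding causative FNB deletions: models, parameters and design choices"
author: "fnbfind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding causative FNB deletions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnbfind)
```

## The genetic model

Fast-neutron bombardment deletes chromosomal segments more or less at
random; a phenotype-causing deletion in a mutant line is expected to be
homozygous in that line (FNB lines are propagated to homozygosity before
phenotyping). `fnbfind` exploits joint multi-sample genotyping: when the
mutant pool, a wild-type-like pool from the same segregating population, a
wild-type accession control and optionally several unrelated FNB lines are
genotyped *against the same reference in one call set*, the causal site is
the one whose genotype vector matches the design's expectation and nothing
else's.

Three designs are supported (`study_design()`):

* **`RECESSIVE_BSA`** — F2 bulked segregant analysis. Mutant-phenotype F2
  plants are pooled (expected `1/1` at the causal site); wild-type-like
  F2 plants are a ~1:2 mixture of `+/+` and `+/m` genotypes, so their
  pooled genotype call is expected heterozygous (`0/1`); the wild-type
  accession is `0/0`. Appropriate when F2 mutant:wild-type-like counts fit
  1:3 (`chisq_segregation()`).
* **`NONRECESSIVE_F3`** — when segregation departs from 1:3, pools are
  built from F3 families that no longer segregate; the wild-type-like pool
  is then fixed `0/0`.
* **`INDIVIDUAL`** — no segregating population; the mutant line is
  compared directly with the wild type. This trades linkage evidence for
  speed: every line-private homozygous coding deletion remains a
  candidate.

Irrelevant-mutant cohort lines are expected `0/0` at the causal site in
every design; a variant homozygous in any of them is shared mutagenesis or
accession background and is subtracted (stage `COHORT`).

The package deliberately computes no allele-frequency sliding windows or
QTL-seq statistics: in this setting the genotype pattern itself *is* the
linkage evidence.

## Filtering cascade and its provenance

`filter_candidates()` runs fixed, ordered stages so that counts are
reproducible and every exclusion is attributable:

1. `QUALITY` — site `QUAL` ≥ 30, per-role-sample `GQ` ≥ 20 and `DP` ≥ 5 by
   default (`quality_thresholds()`). No published threshold exists for
   this step, so the defaults are package choices pitched at ~30×
   sequencing depth, and everything is overridable. Missing `QUAL`, `GQ`
   or `DP` values *fail* the corresponding check whenever its threshold is
   positive: the pattern logic presupposes confidently called genotypes,
   and treating absent evidence as passing would manufacture candidates at
   no-call sites.
2. `CLASS` — deletion selection. Only DELETION-class records (ALT a
   prefix of REF after normalization, length difference ≥ 1) are eligible;
   SNVs and insertions are retained in the decision log but never become
   candidates, since FNB causal lesions are deletions.
3. `PATTERN` — the design genotype expectation at mutant pool,
   wild-type-like pool and control. A `MISSING` genotype never matches any
   expectation (strict mode).
4. `COHORT` — homozygous-reference in every irrelevant mutant, with the
   failing sample named. `lenient_missing = TRUE` tolerates missing calls
   here only — cohort samples are often sequenced shallower, and a no-call
   in a mutual control is weaker evidence of sharing than a called `1/1`.

Stage counts always sum to the number of decomposed input records.

## Variant normalization and coordinates

Multiallelic records are decomposed into one variant per ALT; a sample's
genotype for decomposed allele *a* is `1/1` iff both alleles equal *a*,
`0/1` iff exactly one does, `0/0` iff neither does and none is missing
(other ALT alleles count as reference for that decomposed variant). The
pattern logic is defined for biallelic genotypes only, so decomposition
happens at the reader, once.

Alleles are normalized by shared suffix-then-prefix trimming (position
advanced on prefix trims, one base always retained) before
classification. The deleted interval of an anchored deletion at `pos`
with length `L` is `[pos + 1, pos + L]` — the anchor base is not deleted —
and this convention is asserted in the tests. Internally the annotation
arithmetic uses the native 1-based inclusive GFF3/VCF coordinates via
`GenomicRanges`; BED-like depth files use half-open 0-based intervals, as
BED does.

## Consequence calling

`classify_deletions()` intersects each deleted interval with the
annotation index (`load_annotation()`):

* For multi-mRNA genes the *representative transcript* — longest total
  CDS — is used, so each gene reports one consequence.
* `cds_bases_deleted` is the total overlap with that transcript's CDS;
  the effect is `FRAMESHIFT` iff it is positive and not a multiple of 3,
  `IN_FRAME_DELETION` if a positive multiple of 3, and
  `WHOLE_OR_PARTIAL_GENE_LOSS` when the deletion contains the gene's
  entire CDS span (the mod-3 question is moot for a gene that is gone).
* Region classes follow the precedence CDS > UTR > intron > intergenic;
  a deletion touching more than one class is `MIXED` and keeps the most
  severe effect. Where a GFF3 dialect omits UTR features, UTRs are derived
  as exonic-minus-CDS; introns are derived as within-gene gaps between
  exons. Classification ignores strand throughout (a deleted base is
  deleted on both strands), which the tests assert as strand-flip
  invariance.
* A deletion overlapping several genes reports all gene IDs and the most
  severe per-gene effect.

`prioritize()` ranks gene loss and frameshifts first (they are not
ordered against each other — both are null alleles), then in-frame
deletions, then UTR, intronic and intergenic hits, ties in genomic order.

## Presence–absence detection

Deletions of tens of kilobases and larger do not survive as indel records;
they appear as coverage dropouts. `detect_pav()` works entirely on
windowed depth tracks:

| parameter | default | meaning |
|---|---|---|
| `window_size` | 500 bp | depth binning; calls are resolved to ±1 window |
| `max_mutant_ratio` | 0.1 | max mutant/control normalized depth inside a deletion; nonzero to tolerate mismapped reads inside true deletions |
| `min_control_norm_depth` | 0.5 | control must be adequately covered — a region depleted in *both* samples (a deletion shared with the control) is never called |
| `min_windows` | 2 | minimum flagged windows per call; one window (≤ 500 bp) is indel territory and too noise-prone |
| `merge_gap_windows` | 1 | bridge isolated noisy windows inside a long deletion |

Both tracks are normalized by their genome-wide median window depth, so
calls are invariant to overall depth differences between samples
(asserted exactly in the tests), and tightening `max_mutant_ratio` can
only shrink the flagged set (likewise asserted). The flagging rule is
evaluated as `mutant_norm ≤ ratio × control_norm`, which avoids division
by zero in empty control windows. Call means are computed over flagged
windows only, so the reported ratio always obeys the threshold. At 30×
and 500-bp windows a homozygous dropout window has expected count 0
against ~15,000 in the control, so the per-window test is essentially
noise-free; the operating characteristics are measured in the acceptance
suite (recovery of a 5-kb homozygous deletion to ±1 window, and
no-call-on-null, each in ≥ 95% of 100 seeded replicates).

Tracks come either from 4-column BED-like files (`read_depth_track()`) or
from a sorted, indexed BAM via pileup (`depth_track_from_alignment()`).
The window grid must be identical across samples; resampling mismatched
grids is out of scope, and mismatches are an explicit error.

## Segregation test

`chisq_segregation()` is the uncorrected χ² goodness-of-fit statistic with
expected counts scaled to the observed total and one degree of freedom.
No Yates correction by default — the uncorrected statistic is the standard
for two-class segregation ratios — but `correct = TRUE` is available. A
warning is issued when any expected count is below 5. The test suite
checks the p-value against the independent normal-square identity
`P(χ²₁ > x) = 2Φ(−√x)` rather than re-calling the same CDF.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates: a uniform-composition random genome;
non-overlapping gene models (2–3 CDS exons of 300–900 bp in multiples of
3, 200–400 bp introns, 100–250 bp UTRs, ~1 gene per ≥ 5 kb); causal
deletions placed inside a requested feature class and emitted as
left-aligned anchored VCF records with the design's genotype pattern;
background classes that each violate exactly one filter condition (shared
homozygous deletions, heterozygous-in-mutant deletions, SNVs and
insertions with an otherwise causal pattern, cohort-private homozygous
deletions, low-QUAL records); and window-level Poisson depth tracks
(counts ~ Poisson(depth × window), mutant rate scaled by 0 or 0.5 over
implanted large deletions). Defaults — 30× depth, 500-kb genome, 20
genes, a 7-bp causal CDS deletion, ~50 background records — mirror a
typical FNB mapping experiment, where FNB lines carry few background
mutations relative to chemical mutagenesis.

Deliberately *not* modelled: read-level errors, mapping ambiguity from
genome duplications, GC-coverage bias, pooled allele-frequency noise
(pool genotypes are emitted as clean diploid calls), and upstream caller
artefacts. Passing tests therefore demonstrate the correctness of the
filtering, annotation arithmetic and detection logic — not robustness to
caller miscalls; on real data the quality thresholds and the visual
review of candidates carry that weight. Problem sizes in the test and
acceptance suites (80–500 kb genomes, ≤ 60 variants per fixture, 1 Mb /
2,000-window depth replicates) were chosen so the full loop runs in
seconds while every code path is exercised.

Seed determinism is a contract: one `set.seed()` at entry, sequential
draws, no timestamps or compression in any output, so identical
configurations are byte-identical — asserted file-by-file in the tests.

## Numerical and degenerate-input choices

* Genotype classes are pure string functions; anything diploid over
  alleles {0, 1} maps to the four classes, everything else to `OTHER`
  (never matching any expectation), partial-missing genotypes to
  `MISSING`.
* An empty variant stream, an all-reference VCF, or a zero-event
  simulation are empty results, not errors; zero depth normalizers,
  mismatched window grids, unindexed BAMs, infeasible simulator
  placements and invalid role configurations are explicit errors.
* Ranking ties are broken by genomic order, making reports stable and
  reproducible byte-for-byte.

## Known limitations

* Pool genotypes are taken at face value from the caller; extreme pool
  imbalance (e.g. a small wild-type-like pool missing the heterozygous
  call) will drop the causal site at the `PATTERN` stage. The decision
  log (`decisions.tsv`) exists precisely to audit near-miss sites.
* PAV detection reports window-resolution intervals, not breakpoints;
  split-read refinement is intentionally out of scope.
* Consequence calling uses one representative transcript per gene;
  isoform-specific effects are not reported.
* The `INDIVIDUAL` design cannot distinguish causal from linked or
  coincidental private deletions — it narrows candidates, the cohort
  subtraction narrows them further, and validation remains experimental.
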