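---
title: "Gene-centric profiling of iron-related pathways with anchored per-cell normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric profiling of iron-related pathways with anchored per-cell normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(0)
```

```{r setup, message = FALSE}
library(ferro)
library(dplyr)
```

## The problem

In high-nutrient low-chlorophyll (HNLC) ocean regions, iron limits both
phytoplankton and heterotrophic prokaryotes. Which iron-acquisition and
iron-sparing strategies different prokaryotic groups deploy — siderophore
uptake through TonB-dependent transporters, direct Fe2+/Fe3+ transport,
replacing the iron–sulfur electron carrier ferredoxin with iron-free
flavodoxin, bacterioferritin storage, or rerouting the TCA cycle through
the glyoxylate shunt — can be read from metatranscriptomes, but raw read
counts only give *relative* contributions. Comparing a taxon's activity
between an iron-limited and an iron-replete station requires absolute,
per-cell transcript numbers, which sequencing alone cannot provide.

`ferro` implements a gene-centric workflow that combines four data types
to get there:

1. metatranscriptome reads recruited to curated, pathway-tagged protein
   databases (best translated-alignment hit per read);
2. 16S amplicon relative abundances, corrected for per-taxon 16S rRNA
   gene copy numbers;
3. CARD-FISH total prokaryotic cell counts, which scale corrected
   amplicon proportions to cells per litre; and
4. a qPCR anchor: the transcript:gene-copy ratio of a single-copy gene
   in one abundant taxon (SAR11 isocitrate lyase), measured per station.

## The normalization model

Let `qT/qC` be the qPCR transcript:gene-copy ratio of the anchor gene,
and `nC` the anchor taxon's cells per litre from the census. The anchor
identity

```
qT/qC = mT_iso / nC
```

is solved for `mT_iso`, the absolute anchor transcripts per litre. For a
single-copy gene, gene copies per litre equal cells per litre; a
`gene_copies_per_cell` parameter (default 1) generalizes this. Relating
`mT_iso` to the number of metatranscriptome reads recruited to the
anchor (taxon, gene) in the same sample gives a sample-specific factor

```
f = mT_iso / anchor_reads        [transcripts per read]
```

which converts every other (taxon, pathway) read count to transcripts
per litre, `mT = f * count`. Dividing by the taxon's cells per litre
yields per-cell expression, reported as transcripts per 1e5 cells.
Between-station contrasts are `log10` ratios of per-cell expression,
computed per replicate pair and summarized by mean and min–max; pairs
with a zero member are skipped and reported rather than imputed with a
pseudo-count, which would silently bias log-ratios.

Because `f` is rebuilt from the anchor reads of each sample, the result
is invariant to sequencing depth: multiplying all counts of a sample by
any constant cancels exactly. Stations without a qPCR anchor are
excluded from absolute normalization and keep only relative profiles.

**Verification channel.** Ribosomal-protein transcripts (`RIB`) serve
as an internal control: their per-cell expression should be nearly
station-invariant compared with the iron pathways, so a between-station
RIB log10 ratio far from zero (threshold 1.0 by default, flagged not
failed) indicates a normalization problem.

## Reference databases and recruitment

Reference records carry their pathway code (`SU`, `F2`, `F3`, `FL`,
`ST`, `ACN`, `ICL`, `RIB`), a five-rank lineage
(phylum–class–order–family–genus, padded with `"unassigned"`), and a
KEGG id, all machine-readable in the FASTA header:

```
>ACC1|pathway=SU|tax=Proteobacteria;Gammaproteobacteria;Alteromonadales;Alteromonadaceae;Alteromonas|kegg=K02014
```

The header dialect is this package's own convention; only `RIB` records
may lack a KEGG id, as ribosomal references are typically annotated
only taxonomically. Candidate curation keeps sequences with an e-value
*strictly* below `1e-5` (ties excluded), and the siderophore database
is additionally restricted to an allowed KEGG id set.

Recruitment consumes standard 12-column tabular output from a
production translated aligner and applies the best-hit rule as a
post-hoc argmax — highest bitscore, ties broken by lowest e-value then
smallest accession, hits above `e = 10` discarded — so parsed and
built-in search paths behave identically. Tie-breaking order is a
deterministic choice of this package; the e-value ceiling matches the
`-k 1 -e 10` search convention. The built-in
`naive_translated_search()` exists so desk-scale synthetic runs need no
external aligner: six-frame translation under the standard genetic code
(fuzzy codons to `X`, windows split at stops), exact amino-acid k-mer
seeds (k = 6), ungapped extension to the maximum-scoring diagonal
segment under BLOSUM62, bit scores via the ungapped Karlin–Altschul
parameters (lambda = 0.318, K = 0.134) and a pseudo e-value
`m n 2^(-bits)`. It makes no claim to gapped alignment, frameshift
handling or aligner-grade sensitivity.

## Profiling

Counts aggregate at any of the five ranks; `"unassigned"` is countable.
Three relative products are provided: taxon composition per pathway,
proportions relative to total prokaryotic reads, and percent pathway
shares with per-station mean and min–max across replicates. A
within-class view renormalizes family-level composition inside one
class, or inside the FCB (Fibrobacteres–Chlorobi–Bacteroidetes)
superphylum grouping, configurable as a phylum set. Counts are *not*
length-normalized: cross-pathway comparisons lean on the similar gene
lengths of the focal pathways, and reference lengths are retained in
the database so users can apply RPK-style scaling themselves if their
databases violate that assumption.

## The synthetic community generator

`simulate_community()` draws a ground truth that the rest of the
package is validated against; its defaults are the study conditions,
not tuning knobs:

* **Design**: 2 stations (iron-limited analog `R-2` listed first,
  replete analog `F-L`) × 2 replicate samples, depth 1e6 reads per
  sample.
* **Community**: 8 taxa at order rank spanning the focal marine groups
  (a SAR11/Pelagibacterales analog that carries the anchor gene, plus
  Rhodobacterales, Alteromonadales, Oceanospirillales, Pseudomonadales,
  Flavobacteriales, Actinomycetales, Synechococcales analogs). Cell
  densities are log-uniform over 1e7–5e8 cells/L — the focal orders are
  by construction the abundant ones — and 16S copy numbers are uniform
  integers 1–15.
* **Expression**: per-cell transcript rates at the replete station are
  log-uniform over 1e-3–1e-2 transcripts/cell for the protein-coding
  focal pathways (genes selected for study are detectable ones; typical
  marine cells carry far less than one mRNA per gene) and 10^-1.5–10^-0.5
  for ribosomal proteins. The limited station multiplies each rate by a
  fold-change drawn log-uniformly from 10–1000, except ribosomal
  proteins at a fixed 1.5. The SAR11 analog has structural zeros for
  siderophore, Fe2+, flavodoxin and storage transcripts while keeping a
  positive isocitrate-lyase rate, so the anchor is always defined.
* **Sampling**: one multinomial per sample over (taxon, pathway) bins
  plus a background bin holding 90% of reads (non-target mRNA), so
  pathway transcripts are a small minority of the pool and
  `total_prokaryotic_reads` exceeds the pathway sum, as in real data.
* **Observations**: amplicon fractions proportional to
  `cells x copies` with multinomial resampling at depth 1e5; CARD-FISH
  totals and qPCR ratios with mean-one lognormal noise (CV 0.1 each).

What the generator does *not* emulate: sequencing error profiles and
chimeras, rRNA contamination, primer bias in the qPCR assay itself,
taxa with inverted station patterns, and compositional coupling between
stations. Passing recovery tests therefore demonstrates that the
arithmetic chain is correct and robust to sampling and observation
noise of the stated magnitude — not that field data meet the model's
assumptions.

## A worked run

```{r pipeline}
cfg <- sim_config(seed = 7)
truth <- simulate_community(cfg)
counts <- simulate_counts(truth)
obs <- simulate_observations(truth)
expr <- ferro_pipeline(counts$counts, counts$meta, obs)
rec <- recovery_report(expr, truth, high_fold = 10)
c(median_rel_error = rec$median_rel_error,
  ordering_high_fold = rec$ordering_agreement_high_fold)
```

```{r rib}
rr <- station_log_ratio(
  expr[expr$station == "R-2", ], expr[expr$station == "F-L", ],
  tibble::tibble(sample_a = c("R-2-1", "R-2-2"),
                 sample_b = c("F-L-1", "F-L-2"))
)
verification_channel(rr)$overall_log10
```

## Numerical choices

* **Exact depth invariance.** `per_cell_from_counts()` computes
  `1e5 * mT_iso * (count / anchor_reads) / n(t)`, dividing the two
  integer-valued read counts first: scaling both by a common factor is
  then the same rational number, so the IEEE result is bit-identical.
  Computing `f = mT_iso / anchor_reads` first and multiplying later
  (the modular route via `anchor_scaling_factor()` and
  `absolute_transcripts()`) is algebraically identical but only
  invariant to rounding error.
* **Noiseless mode.** `simulate_counts(mode = "expected")` replaces the
  multinomial by its expectation (real-valued counts) and
  `simulate_observations(noiseless = TRUE)` disables all noise; the
  pipeline then inverts the generative model exactly, which pins down
  the arithmetic to float precision (~1e-16 relative).
* **Degenerate inputs.** Zero-total pathways yield empty compositions
  with a warning, never NaN; taxa with zero census cells are omitted
  from per-cell expression with a warning; an absent or zero anchor
  count is a hard calibration error for that sample; all-zero amplicon
  profiles are rejected.
* **Missing copy numbers** fall back to a configurable default (2.0)
  with a warning, since a bundled copy-number reference is out of
  scope.
* **Census rank** defaults to order, the rank at which the expression
  figures are reported; copy-number correction and grouping happen at
  the same rank. Whether anchor reads are counted at family or order
  level is a user choice via the anchor's `anchor_taxon`; order is the
  default in the simulator.
* **Seeds.** Each `simulate_*` step derives its stream from the single
  config seed plus a fixed small offset, so individual stages are
  reproducible in isolation and jointly.

## Validation suite and problem sizes

The test suite validates each stage against independent oracles
(hand-computed arithmetic, brute-force re-aggregation, an exhaustive
argmax re-implementation of best-hit selection on 1000 random hit
tables with deliberate ties) and the whole chain by parameter recovery:
noiseless invertibility to 1e-9 relative error, and at default noise a
median relative error of per-cell expression within 25%, perfect
recovery of the between-station ordering for entries with a true
fold-change of at least 10, and a ribosomal-protein log10 ratio within
0.2 of its generative value. Recruitment is validated by planting
back-translated reads (90 nt, five per reference) and requiring at
least 99% recovery of the true source record. These sizes — 8 taxa,
depth 1e6, hundreds of planted reads — were chosen as the smallest
community at which all noise regimes of the model are exercised.

## Known limitations

* The qPCR anchor propagates its own biases (primer mismatches,
  assumed single-copy gene) into every absolute number; only the
  *ratio* structure reduces them.
* Per-cell expression is only defined for taxa present in the census;
  amplicon taxa absent from the metatranscriptome taxonomy scale the
  census normalization but produce no expression output.
* The naive search is a correctness oracle, not a performance tool; use
  a production aligner's tabular output for real datasets.
* Replicates are kept separate end-to-end and summarized only at
  reporting; with two replicates the min–max bars are ranges, not
  confidence intervals.
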