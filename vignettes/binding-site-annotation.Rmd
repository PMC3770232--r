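---
title: "Annotating transcription-factor binding sites and integrating regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating transcription-factor binding sites and integrating regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakreg)
```

## The analysis

A genome-wide binding study of a transcription factor typically produces a
set of bound intervals (peaks) from a tiling-array or ChIP experiment,
together with expression contrasts after perturbing the factor —
shRNA-mediated knockdown (KD) and overexpression (OE).  The questions
`peakreg` answers about such data are:

* **Where does the factor bind relative to genes?**  Each peak is assigned
  to the gene whose transcription start site (TSS) is nearest, and the
  signed distances are binned into a histogram (an overlap class, 4 kb
  bins out to 40 kb on each side, and open tails).  Seeded random site
  sets placed uniformly over the covered space provide the null profile.
* **Is binding enriched in particular genomic classes?**  Peaks are
  classified against transcribed regions (midpoint rule) and compared
  with the platform's base composition via an odds ratio and an exact
  binomial test; distal peaks (nearest TSS beyond 4 kb) are compared with
  random sets for proximity (gap at most 1 kb) to regulatory-element
  tracks — DNase-hypersensitive sites, predicted enhancers, insulators —
  using a ratio of proportions and Fisher's exact test.
* **Does the factor's consensus motif explain binding?**  A degenerate
  IUPAC consensus (the default is the 6-mer `ATCRAT`) is scanned over
  both strands of the bound regions and of width-paired random regions
  sampled from the covered space, whose GC content is reported so the
  composition control is explicit; occupancy — the fraction of all
  consensus occurrences on the platform that fall inside bound regions —
  is the converse quantity.
* **Which targets does the factor actually regulate?**  A gene counts as
  regulated in a contrast when its linear fold change passes a symmetric
  threshold (1.5-fold or 1.25-fold: `2^log2fc >= thr` or `<= 1/thr`) with
  `p < 0.05`.  Direction is mapped to factor effect: down upon knockdown
  or up upon overexpression means activated by the factor.  Regulated
  fractions are reported overall, per distance bin, per per-gene site
  count (1 vs 2+), and per gene-position type.

### Gene-position types

For one binding site, three genes are distinguished: type 1, the
nearest-TSS gene; type 2, the nearest gene whose TSS lies on the opposite
side of the site midpoint; and type 3, the second-nearest gene on type
1's side, so that type 1 lies between the site and type 3.  Comparing
regulated fractions across the three types asks whether the factor only
regulates its nearest gene or also acts across an intervening gene.

## Coordinate and statistical conventions

All coordinates are 0-based half-open (BED native; GFF3 converted on
read).  The TSS is the first covered base for `+` genes and the last
(`end - 1`) for `-` genes.  Distance from a site to a TSS is zero when
the site contains the TSS, and otherwise the point-to-edge distance, with
the sign negative on the gene's upstream (5') side.  Nearest-TSS ties
prefer an overlapping gene, then the lexicographically smallest id, so
assignment is deterministic.  Distance bins are half-open and
far-inclusive: a distance of exactly 4000 falls in the first bin.
Cross-chromosome distances are an explicit `Inf`/`NA` sentinel, never a
large number.

Significance tests follow the simplest exact choices: a two-sided exact
binomial test against a fixed background fraction, Fisher's exact test
between two site sets, and no multiple-testing correction anywhere
(gene-level p-values are used raw).  Enrichment against a background
fraction is reported both as an odds ratio (the headline statistic, since
it reproduces published two-decimal values from printed percentages) and
as a plain ratio of proportions.

The chi-square homogeneity statistic across distance bins is computed
over the bins that satisfy Cochran's rule (expected counts of at least 5
under the pooled rate).  The far bins often hold very few genes; with
them included the statistic runs above its nominal type-I level, so they
are excluded from the statistic but kept in the reported table with their
denominators.

Consensus patterns are per-position allowed-base sets.  Any nonempty
subset of ACGT maps to one IUPAC letter, so matching is delegated to
`Biostrings`; the reverse-complement pattern is derived positionally
(complement each set, reverse).  The standard IUPAC table is the default
(`R = A/G`), with a documented override mechanism (e.g. `R = A/C`) for
reports that use a non-standard letter binding.  A position matching on
both strands (a palindromic instance) is counted once, on `+`; `N` in a
subject sequence matches nothing.

## The synthetic-data generator

Because the original arrays cannot be regenerated, every stage is
validated against a fully seeded generator whose defaults encode the
emulated study conditions:

| parameter | default | what it emulates |
|---|---|---|
| site width | lognormal, mean 503 bp (sd log 0.35) | mean called-peak width 503 bp, range ~150–1100 bp |
| genome GC | 0.47 | the ~47% GC of bound and unbound regions |
| TSS-proximal fraction | 0.46, bell SD 650 bp | ~47% of sites within 4 kb of a TSS, ~14% overlapping one |
| motif plant fraction | 0.472 | consensus present at 47.2% of bound sites |
| element folds | 1.49 / 1.45 / 1.01 | DHS / enhancer / insulator proximity folds |
| regulated fraction | 0.084 above 1.5-fold | 8.4% of targets regulated |
| activated share | 0.52 | 52% activated vs 48% repressed |

Where the study conditions do not pin a value, realistic choices were
fixed once: 4 chromosomes of 7.5 Mb, 400 genes with lognormal lengths
(median 14 kb), 1500 peaks, null `log2fc ~ N(0, 0.25)` with uniform null
p-values (planted p-values uniform on (0, 0.05)).  The bell SD and
proximal fraction were solved analytically so that the overlap /
within-4 kb / beyond-40 kb shares land near the emulated profile given
this gene density.  One RNG stream per generator stage is derived from
the master seed, so adding a stage never perturbs earlier outputs, and
every artifact is byte-identical across runs with the same seed.

Design choices inside the generator worth knowing about:

* **Peaks are mutually disjoint** by default (overlapping placements are
  resampled, with a retry cap), as called peak sets are; this also keeps
  planted-motif recovery unbiased, since a planted instance can never sit
  inside a second peak.  `allow_overlap = TRUE` lifts the constraint.
* **Element enrichment is planted by attachment**: for a target fold
  `f`, `k = round(b(f-1) n_distal / (1-b))` elements are placed within
  1 kb of distinct random distal peaks (`b` is the analytic baseline
  proximity probability of the uniform background), making the expected
  measured fold equal `f`.  Folds below 1 are rejected as infeasible —
  the uniform background cannot be depleted.
* **Expression is emitted as (log2 fold change, p) pairs** per gene and
  contrast; array normalisation is upstream of everything modelled here.
  Planting is independent of site-TSS distance by default (the flat
  profile); an optional distance-decay mode (`exp(-d/10 kb)` weighting)
  exists for power studies.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: probe-level array noise and peak-calling
artifacts; sequence composition beyond i.i.d. bases at a fixed GC (no
CpG islands, repeats or codon structure); clustered or divergent gene
architecture; correlated expression noise between contrasts; and any
dependence of binding on sequence beyond the planted consensus.

## Numerical and degenerate-input behaviour

Empty site lists, empty tracks, empty bins and zero-hit scans are flagged
(`NA` with a warning or a zero denominator in the table) rather than
silently dropped.  A genome whose genes cannot fit, or an element fold
infeasible for the track density, is a configuration error with an
explanation.  Width-paired random regions are resampled rather than
allowed to straddle covered-region boundaries, keeping widths honest.
GC matching of random regions (accept/reject to within 1 GC point) is
available but off by default; GC is always reported instead, which is the
control actually needed.

Two geometric facts discovered while validating the distance machinery
are worth recording.  First, with realistic gene bodies the
upstream/downstream flank totals of uniformly placed sites are *not*
symmetric: every site inside a gene body is downstream of its own TSS.
Second, even with point-like genes, one realised genome's up/down split
fluctuates with its intergenic gap layout by far more than binomial site
sampling suggests.  The symmetry property of the histogram therefore
holds — and is tested — in expectation across seeded genomes with
point-like genes.

## Problem sizes

The shipped validation suite runs the generator at the default scale
(1500 sites, 400 genes, 30 Mb with sequences) for motif recovery, and at
study scale (4000 genes, 2000 sites, 100 Mb, annotation only) across 20
seeds for regulated-fraction recovery and the flat distance profile;
element-fold recovery averages 20 seeds at the default scale.  A full
synthetic end-to-end pipeline run, including sequence simulation and
genome-wide scanning, completes in about two minutes on one CPU.

## Limitations

The package consumes called peaks and processed expression contrasts; it
does not call peaks, normalise arrays, lift coordinates between
assemblies, or discover motifs de novo.  Significance is per-quantity
and uncorrected, mirroring the analysis it re-implements; users comparing
many tracks or thresholds should correct externally.  The promoter-array
capture model is a pure window-overlap calculation and ignores
probe-level tiling of commercial designs.
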