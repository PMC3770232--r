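# peakreg

Downstream analysis of transcription-factor binding-site sets from
tiling-array or ChIP experiments, for researchers asking where a factor
binds relative to genes and which of its putative targets it actually
regulates.  The package covers the standard post-peak-calling questions
in one tested pipeline:

* **Distance to TSS** — assign every bound interval to its nearest
  transcription start site (signed, edge-based, deterministic
  tie-breaking), bin the distances (overlap, 4 kb bins to ±40 kb, open
  tails), and compare with seeded random site sets.
* **Genomic-class enrichment** — classify sites against transcribed
  regions (midpoint rule) and test against the platform composition:
  for observed non-transcribed fraction *p₁* and background *p₀*, the
  enrichment is the odds ratio
  (*p₁*/(1−*p₁*)) / (*p₀*/(1−*p₀*)) with a two-sided exact binomial
  p-value; distal sites (nearest TSS > 4 kb) are tested for proximity
  (gap ≤ 1 kb) to DHS / enhancer / insulator tracks against random sets
  by a ratio of proportions and Fisher's exact test.
* **Consensus-motif occupancy** — scan a degenerate IUPAC consensus
  (default `ATCRAT`) over both strands of bound regions and of
  width-paired random regions (GC reported for the composition
  control), plus the converse occupancy: the fraction of all consensus
  occurrences in covered space that are bound.
* **Promoter-array capture** — predict which sites and target genes
  fall inside platform windows around TSSs (Nimblegen −3.5 kb/+0.75 kb,
  Agilent −5.5 kb/+2.5 kb, Affymetrix −7.5 kb/+2.45 kb), and overlap
  target-gene lists between platforms.
* **Regulation integration** — call genes up/down per knockdown (KD)
  and overexpression (OE) contrast at symmetric linear fold thresholds
  (1.5 / 1.25, *p* < 0.05), map direction to factor effect (down in KD
  or up in OE ⇒ activated by the factor), and report regulated
  fractions overall, by distance bin (with a chi-square homogeneity
  test), by per-gene site count, and by gene-position type (nearest
  gene; nearest opposite-side gene; next gene beyond the nearest).
* **Synthetic data** — a fully seeded generator (genome, sequences,
  peaks, element tracks, expression contrasts) with a ground-truth
  manifest, so the whole pipeline is testable without any downloads.

All coordinates are 0-based half-open (BED convention); see the
methods vignette (`vignettes/binding-site-annotation.Rmd`) for every
convention and design choice.

## Worked example

```r
library(peakreg)

cfg <- simulation_config(seed = 42)
ds  <- simulate_dataset(cfg)          # annotation, FASTA, peaks, tracks, contrasts
ds
#> Synthetic dataset (seed 42)
#> Genome annotation
#>   chromosomes: 4 (30.0 Mb total)
#>   genes:       400
#>   transcribed: 22.8% of genome
#>   sites:       1500
#>   elements:    dhs, enhancers, insulators
#>   expression:  800 rows

asn <- nearest_tss(ds$sites, ds$annotation)
h   <- distance_histogram(asn)
# 13.5% of sites overlap a TSS, 53.2% lie within 4 kb, 14.2% beyond 40 kb

cls <- classify_transcribed(ds$sites, ds$annotation)
odds_enrichment(cls$count_out, cls$count_in,
                1 - whole_genome_design(ds$annotation)$transcribed_fraction)
#> Enrichment (exact binomial vs background fraction): n=1500  observed=64.1%  background=77.2%
#>   fold=0.83  odds ratio=0.53  p=2.084e-30

cmp <- matched_random_fraction(ds$sites, whole_genome_design(ds$annotation),
                               ds$sequences, compile_pattern("ATCRAT"), seed = 1)
cmp$bound
#> Motif scan: 983/1500 regions with a match (65.5%), 1385 occurrences, GC 46.9%
cmp$random
#> Motif scan: 513/1500 regions with a match (34.2%), 645 occurrences, GC 47.0%

calls <- call_regulation(ds$expression, regulation_thresholds(1.5))
regulated_fraction(calls, unique(asn$gene_id[!is.na(asn$gene_id)]))
#>   contrast   n regulated activated repressed regulated_fraction
#> 1    union 398        33        19        14         0.08291457
#> 2       KD 398        33        19        14         0.08291457
#> 3       OE 398        33        19        14         0.08291457
```

Reading the numbers: the generator planted the consensus in 47.2% of
peaks — the scan finds matches in 65.5% of bound regions against a 34.2%
size-matched background, and (0.655 − 0.342)/(1 − 0.342) ≈ 0.476
recovers the planted fraction.  TSS-proximal placement puts half the
sites within 4 kb of a TSS, which also makes them *depleted* in
non-transcribed space (odds ratio 0.53) on this sparse genome.  The
regulated fraction among the 398 target genes with profiling data,
8.3%, recovers the planted 8.4%.

The same analyses run end to end over files on disk:

```r
run_pipeline("all", list(out_dir = "out", seed = 42))   # TSV report bundle
```

or from a shell via the thin wrapper
`Rscript inst/scripts/peakreg-cli.R all --out out --seed 42`
(subcommands: `simulate`, `map-tss`, `enrich`, `motif`, `coverage`,
`regulate`, `all`; a YAML config can override any default, and reruns
with the same config and seed are byte-identical).

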