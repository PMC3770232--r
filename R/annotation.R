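#' Genome annotation: chromosomes, genes and transcribed regions
#'
#' Bundles chromosome lengths, a gene table and the merged union of gene
#' bodies (the transcribed-region set) used to classify binding sites.
#' The TSS of each gene follows the strand rule: the first covered base
#' (`start`) for `+` genes, the last covered base (`end - 1`) for `-`
#' genes.
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (`+`/`-`), `id` (unique); 0-based half-open coordinates.
#' @param chrom_lengths named numeric vector, chromosome name -> length bp.
#' @param transcribed optional externally supplied region set
#'   (chrom/start/end data.frame); defaults to the merged gene bodies.
#' @return object of class `genome_annotation` with elements `genes`
#'   (with a derived `tss` column), `chrom_lengths` and `transcribed`.
#' @export
genome_annotation <- function(genes, chrom_lengths, transcribed = NULL) {
  genes <- intervals(genes$chrom, genes$start, genes$end,
                     strand = genes$strand, id = genes$id)
  if (any(genes$strand == "*"))
    stop("gene strand must be '+' or '-'")
  chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  unknown <- setdiff(unique(genes$chrom), names(chrom_lengths))
  if (length(unknown))
    stop("genes on chromosomes without a length: ",
         paste(unknown, collapse = ", "))
  if (any(genes$end > chrom_lengths[genes$chrom]))
    stop("gene interval extends beyond its chromosome")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  if (is.null(transcribed)) transcribed <- merge_intervals(genes)
  else transcribed <- merge_intervals(
    intervals(transcribed$chrom, transcribed$start, transcribed$end))
  structure(list(genes = genes, chrom_lengths = chrom_lengths,
                 transcribed = transcribed),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("Genome annotation\n")
  cat("  chromosomes:", length(x$chrom_lengths),
      sprintf("(%.1f Mb total)", sum(x$chrom_lengths) / 1e6), "\n")
  cat("  genes:      ", nrow(x$genes), "\n")
  cat(sprintf("  transcribed: %.1f%% of genome\n",
              100 * total_width(x$transcribed) / sum(x$chrom_lengths)))
  invisible(x)
}

#' Array design: probe-covered genomic space
#'
#' The covered regions of a tiling platform, with the fraction of covered
#' bases that fall inside transcribed regions (the background used for
#' transcribed/non-transcribed enrichment).
#'
#' @param covered_regions chrom/start/end data.frame of covered space
#'   (merged on construction).
#' @param annotation optional [genome_annotation()] used to compute
#'   `transcribed_fraction`; when omitted the fraction is `NA`.
#' @return object of class `array_design` with `covered_regions` and
#'   `transcribed_fraction`.
#' @export
array_design <- function(covered_regions, annotation = NULL) {
  covered <- merge_intervals(covered_regions)
  tf <- NA_real_
  if (!is.null(annotation)) {
    cov_gr <- as_granges(covered)
    tr_gr <- as_granges(annotation$transcribed)
    inter <- GenomicRanges::intersect(cov_gr, tr_gr, ignore.strand = TRUE)
    tf <- sum(GenomicRanges::width(inter)) / total_width(covered)
  }
  structure(list(covered_regions = covered, transcribed_fraction = tf),
            class = "array_design")
}

#' Whole-genome array design from an annotation
#'
#' Convenience wrapper: covered space equal to the full chromosomes.
#'
#' @param annotation a [genome_annotation()].
#' @return an [array_design()].
#' @export
whole_genome_design <- function(annotation) {
  array_design(
    data.frame(chrom = names(annotation$chrom_lengths), start = 0,
               end = as.numeric(annotation$chrom_lengths),
               stringsAsFactors = FALSE),
    annotation
  )
}
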