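## Promoter-array capture prediction: which binding sites (and which
## target genes) fall inside platform-specific windows around TSSs.

#' Promoter-array window
#'
#' A strand-oriented window `[TSS - upstream, TSS + downstream]` (both
#' bounds inclusive after orientation) describing the genomic space a
#' promoter-array platform tiles around each TSS.
#'
#' @param platform platform name.
#' @param upstream,downstream extents in bp (`>= 0`, not both 0).
#' @return object of class `promoter_window`.
#' @export
promoter_window <- function(platform, upstream, downstream) {
  if (upstream < 0 || downstream < 0 || upstream + downstream <= 0)
    stop("window extents must be >= 0 and not both 0")
  structure(list(platform = platform, upstream = upstream,
                 downstream = downstream), class = "promoter_window")
}

#' Default promoter-array platform windows
#'
#' The shipped window set: Nimblegen -3.5 kb/+0.75 kb, Agilent
#' -5.5 kb/+2.5 kb, Affymetrix -7.5 kb/+2.45 kb; user-overridable.
#'
#' @return named list of [promoter_window()] objects.
#' @export
default_promoter_windows <- function() {
  list(
    Nimblegen = promoter_window("Nimblegen", 3500, 750),
    Agilent = promoter_window("Agilent", 5500, 2500),
    Affymetrix = promoter_window("Affymetrix", 7500, 2450)
  )
}

## genomic windows (0-based closed [wstart, wend]) for all genes
gene_windows <- function(annotation, window) {
  g <- annotation$genes
  ws <- ifelse(g$strand == "+", g$tss - window$upstream,
               g$tss - window$downstream)
  we <- ifelse(g$strand == "+", g$tss + window$downstream,
               g$tss + window$upstream)
  data.frame(chrom = g$chrom, wstart = pmax(0, ws), wend = we, id = g$id,
             stringsAsFactors = FALSE)
}

#' Would sites be captured by a promoter array?
#'
#' A site is captured iff it overlaps the strand-oriented window of at
#' least one gene's TSS (any gene, not only the site's assigned one: a
#' probe at another gene's promoter still detects the fragment).
#'
#' @param sites interval data.frame of binding sites.
#' @param annotation a [genome_annotation()].
#' @param window a [promoter_window()].
#' @return logical vector, one element per site.
#' @export
site_captured <- function(sites, annotation, window) {
  if (nrow(sites) == 0) return(logical())
  w <- gene_windows(annotation, window)
  wgr <- GenomicRanges::GRanges(w$chrom,
                                IRanges::IRanges(w$wstart + 1, w$wend + 1))
  GenomicRanges::countOverlaps(as_granges(sites), wgr) > 0
}

#' Site and target-gene capture fractions for a platform window
#'
#' `site_fraction` is the fraction of sites captured; `gene_fraction` the
#' fraction of nearest-TSS target genes with at least one captured
#' assigned site (a gene with one distal and one proximal site counts as
#' captured even though not all its sites are).
#'
#' @param sites interval data.frame of binding sites (non-empty).
#' @param annotation a [genome_annotation()].
#' @param window a [promoter_window()].
#' @param assignment optional precomputed [nearest_tss()] table.
#' @return list with `site_fraction`, `gene_fraction`, `n_sites`,
#'   `n_genes` (genes with >= 1 assigned site).
#' @export
capture_fractions <- function(sites, annotation, window,
                              assignment = NULL) {
  if (nrow(sites) == 0) {
    warning("no sites: capture fractions undefined")
    return(list(site_fraction = NA_real_, gene_fraction = NA_real_,
                n_sites = 0L, n_genes = 0L))
  }
  captured <- site_captured(sites, annotation, window)
  if (is.null(assignment)) assignment <- nearest_tss(sites, annotation)
  ok <- !is.na(assignment$gene_id)
  gene_cap <- tapply(captured[ok], assignment$gene_id[ok], any)
  list(site_fraction = mean(captured),
       gene_fraction = if (length(gene_cap)) mean(gene_cap) else NA_real_,
       n_sites = nrow(sites), n_genes = length(gene_cap))
}

#' Overlap of one target-gene list with another
#'
#' @param list_a,list_b character vectors of unique gene ids.
#' @return list with `n_a`, `n_intersect` and `fraction`
#'   (`|A n B| / |A|`; `NA` with a warning when A is empty).
#' @export
target_overlap <- function(list_a, list_b) {
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  if (length(list_a) == 0) {
    warning("empty target list A: overlap undefined")
    return(list(n_a = 0L, n_intersect = 0L, fraction = NA_real_))
  }
  n_int <- length(intersect(list_a, list_b))
  list(n_a = length(list_a), n_intersect = n_int,
       fraction = n_int / length(list_a))
}
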