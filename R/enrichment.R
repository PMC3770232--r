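## Classification of sites against transcribed regions and element tracks,
## with exact enrichment statistics (binomial test against a fixed
## background fraction; Fisher's exact test between two site sets).

enrichment_result <- function(n_sites, observed_fraction,
                              background_fraction, p_value, test_name) {
  odds <- function(p) p / (1 - p)
  structure(list(
    n_sites = n_sites,
    observed_fraction = observed_fraction,
    background_fraction = background_fraction,
    fold = if (background_fraction > 0)
      observed_fraction / background_fraction else NA_real_,
    odds_ratio = odds(observed_fraction) / odds(background_fraction),
    p_value = p_value,
    test_name = test_name
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment (%s): n=%d  observed=%.1f%%  background=%.1f%%\n  fold=%.2f  odds ratio=%.2f  p=%.4g\n",
    x$test_name, x$n_sites, 100 * x$observed_fraction,
    100 * x$background_fraction, x$fold, x$odds_ratio, x$p_value))
  invisible(x)
}

#' Classify binding sites as transcribed or non-transcribed
#'
#' A site counts as transcribed iff its midpoint `floor((start+end)/2)`
#' lies inside a transcribed region, so every site is assigned to exactly
#' one class.
#'
#' @param sites interval data.frame of binding sites.
#' @param annotation a [genome_annotation()] (its `transcribed` set is
#'   used).
#' @return list with `count_in`, `count_out` and the per-site logical
#'   `transcribed`.
#' @export
classify_transcribed <- function(sites, annotation) {
  if (nrow(sites) == 0)
    return(list(count_in = 0L, count_out = 0L, transcribed = logical()))
  tr <- annotation$transcribed
  if (nrow(tr) == 0) {
    inside <- rep(FALSE, nrow(sites))
  } else {
    mid <- interval_midpoint(sites)
    pts <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(mid + 1, mid + 1))
    inside <- GenomicRanges::countOverlaps(pts, as_granges(tr)) > 0
  }
  list(count_in = sum(inside), count_out = sum(!inside), transcribed = inside)
}

#' Enrichment of sites in non-transcribed regions
#'
#' Compares the observed non-transcribed fraction of a site set with a
#' fixed platform background fraction; reports both the odds ratio
#' (the headline enrichment statistic) and the simple ratio of
#' proportions, with a two-sided exact binomial p-value.
#'
#' @param count_non,count_tr numbers of sites in non-transcribed and
#'   transcribed regions (`count_non + count_tr >= 1`).
#' @param bg_non_fraction background non-transcribed fraction of the
#'   platform's covered space, strictly between 0 and 1.
#' @return an `enrichment_result`.
#' @export
odds_enrichment <- function(count_non, count_tr, bg_non_fraction) {
  n <- count_non + count_tr
  if (n < 1) stop("need at least one site")
  if (bg_non_fraction <= 0 || bg_non_fraction >= 1)
    stop("bg_non_fraction must be strictly between 0 and 1")
  p <- binom.test(count_non, n, bg_non_fraction)$p.value
  enrichment_result(n, count_non / n, bg_non_fraction, p,
                    "exact binomial vs background fraction")
}

#' Enrichment result from printed fractions
#'
#' Odds ratio and proportion ratio computed directly from an observed and
#' a background fraction (e.g. percentages printed in a summary table),
#' with the exact binomial p-value evaluated at the implied count.
#'
#' @param observed_fraction,background_fraction proportions in (0,1).
#' @param n number of sites behind `observed_fraction`.
#' @return an `enrichment_result`.
#' @export
fraction_enrichment <- function(observed_fraction, background_fraction, n) {
  p <- binom.test(round(observed_fraction * n), n,
                  background_fraction)$p.value
  enrichment_result(n, observed_fraction, background_fraction, p,
                    "exact binomial vs background fraction")
}

#' Fraction of sites within a gap of an element track
#'
#' A site is "near" when the gap (bases strictly between; 0 when
#' overlapping or abutting) to the nearest element is at most `max_gap`
#' (inclusive).  Sites on chromosomes without elements are never near.
#'
#' @param sites interval data.frame (non-empty).
#' @param elements interval data.frame of the element track.
#' @param max_gap maximum gap in bp (default 1000).
#' @return the near fraction (scalar); 0 when the track is empty.
#' @export
element_proximity_fraction <- function(sites, elements, max_gap = 1000) {
  if (nrow(sites) == 0) {
    warning("empty site list: proximity fraction undefined")
    return(NA_real_)
  }
  if (nrow(elements) == 0) return(0)
  hits <- GenomicRanges::distanceToNearest(as_granges(sites),
                                           as_granges(elements))
  near <- S4Vectors::mcols(hits)$distance <= max_gap
  sum(near) / nrow(sites)
}

#' Proximity enrichment of observed vs random sites
#'
#' Fold difference of near-element fractions between an observed and a
#' random site set (ratio of proportions), with a two-sided Fisher exact
#' p-value on the near/far by observed/random 2x2 table.
#'
#' @param sites observed sites (typically pre-filtered to the distal set,
#'   nearest-TSS distance > 4 kb).
#' @param random_sites a matched random set (see [random_site_set()]).
#' @param elements element track intervals.
#' @param max_gap maximum gap in bp (default 1000, inclusive).
#' @return an `enrichment_result` (`fold` is the ratio of proportions;
#'   `NA` with a warning when the random fraction is 0).
#' @export
proximity_fold <- function(sites, random_sites, elements, max_gap = 1000) {
  if (nrow(sites) == 0 || nrow(random_sites) == 0)
    stop("both site sets must be non-empty")
  f_obs <- element_proximity_fraction(sites, elements, max_gap)
  f_rand <- element_proximity_fraction(random_sites, elements, max_gap)
  n1 <- nrow(sites); n0 <- nrow(random_sites)
  tab <- matrix(c(round(f_obs * n1), n1 - round(f_obs * n1),
                  round(f_rand * n0), n0 - round(f_rand * n0)), nrow = 2)
  p <- fisher.test(tab)$p.value
  if (f_rand == 0)
    warning("random near fraction is 0: fold undefined")
  res <- enrichment_result(n1, f_obs, f_rand, p, "Fisher exact vs random set")
  if (f_rand == 0) res$fold <- NA_real_
  res
}
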