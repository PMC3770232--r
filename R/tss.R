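## Distance-to-TSS mapping: signed distances, nearest-TSS assignment with
## deterministic tie-breaking, the binned distance histogram and seeded
## random null site sets.

#' Signed distance from binding sites to gene TSSs
#'
#' Pairwise signed distance: 0 when the site interval contains the TSS;
#' otherwise the point-to-interval distance from the TSS to the nearest
#' site edge, negative when the site lies on the gene's upstream (5')
#' side given its strand, positive downstream.  Site/gene pairs on
#' different chromosomes give `NA` (callers must filter).
#'
#' @param sites interval data.frame of binding sites.
#' @param genes gene data.frame with `chrom`, `strand`, `tss` columns
#'   (as in `genome_annotation()$genes`); recycled against `sites`.
#' @return numeric vector of signed base-pair distances.
#' @export
signed_tss_distance <- function(sites, genes) {
  n <- max(nrow(sites), nrow(genes))
  si <- rep_len(seq_len(nrow(sites)), n)
  gi <- rep_len(seq_len(nrow(genes)), n)
  s <- sites$start[si]; e <- sites$end[si]
  tss <- genes$tss[gi]; strand <- genes$strand[gi]
  mag <- pmax(0, s - tss, tss - e)
  site_left <- tss - e > 0   # site entirely 5' (genomically left) of TSS
  site_right <- s - tss > 0
  upstream <- (strand == "+" & site_left) | (strand == "-" & site_right)
  d <- ifelse(upstream, -mag, mag)
  d[sites$chrom[si] != genes$chrom[gi]] <- NA_real_
  d
}

#' Assign each binding site to its nearest TSS
#'
#' The assigned gene minimises the absolute signed distance; ties are
#' broken by preferring a TSS-overlapping gene, then the lexicographically
#' smallest gene id.  Sites on chromosomes without genes get an `NA`
#' assignment.
#'
#' @param sites interval data.frame of binding sites (column `id`).
#' @param annotation a [genome_annotation()].
#' @return data.frame with columns `site_id`, `gene_id`, `distance`
#'   (signed bp, `NA` when unassigned), one row per site in input order.
#' @export
nearest_tss <- function(sites, annotation) {
  genes <- annotation$genes
  out <- data.frame(
    site_id = if (!is.null(sites$id)) sites$id
      else paste0("site_", seq_len(nrow(sites))),
    gene_id = NA_character_, distance = NA_real_,
    stringsAsFactors = FALSE)
  if (nrow(sites) == 0) return(out)
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(nrow(sites))) {
    gidx <- by_chrom[[sites$chrom[i]]]
    if (is.null(gidx)) next
    g <- genes[gidx, , drop = FALSE]
    d <- signed_tss_distance(sites[i, , drop = FALSE], g)
    mag <- abs(d)
    best <- which(mag == min(mag))
    if (length(best) > 1) {
      # prefer genes whose TSS the site actually overlaps, then id order
      ov <- sites$start[i] <= g$tss[best] & g$tss[best] < sites$end[i]
      if (any(ov)) best <- best[ov]
      best <- best[order(g$id[best])][1]
    }
    out$gene_id[i] <- g$id[best]
    out$distance[i] <- d[best]
  }
  out
}

## bin labels for the signed-distance histogram
histogram_bin_labels <- function(bin_width, max_distance) {
  nb <- max_distance / bin_width
  if (nb != round(nb)) stop("max_distance must be a multiple of bin_width")
  kb <- function(x) ifelse(x %% 1000 == 0, paste0(x / 1000, "kb"), paste0(x, "bp"))
  edges <- seq(0, max_distance, by = bin_width)
  lab <- paste0(kb(edges[-length(edges)]), "-", kb(edges[-1]))
  c("overlap",
    paste0("up_", lab), paste0("up_gt_", kb(max_distance)),
    paste0("down_", lab), paste0("down_gt_", kb(max_distance)))
}

#' Signed distance-to-TSS histogram
#'
#' Bins nearest-TSS distances into an overlap bin plus half-open
#' `(0, w], (w, 2w], ...` bins on each side of the TSS (far-inclusive: a
#' distance of exactly `-bin_width` falls in the first upstream bin) and
#' an open `> max_distance` bin per side.
#'
#' @param distances signed distances as returned by [nearest_tss()]
#'   (a data.frame with a `distance` column, or a numeric vector);
#'   `NA` (unassigned) entries are dropped and counted separately.
#' @param bin_width bin width in bp (default 4000).
#' @param max_distance last finite bin edge in bp (default 40000).
#' @return object of class `distance_histogram`: `counts` (named integer
#'   vector over bin labels), `percent` (counts / n_total * 100, `NA` when
#'   no site was assigned), `n_total`, `n_unassigned`, `bin_width`,
#'   `max_distance`.
#' @export
distance_histogram <- function(distances, bin_width = 4000,
                               max_distance = 40000) {
  if (is.data.frame(distances)) distances <- distances$distance
  n_unassigned <- sum(is.na(distances))
  d <- distances[!is.na(distances)]
  labels <- histogram_bin_labels(bin_width, max_distance)
  counts <- setNames(integer(length(labels)), labels)
  nb <- max_distance / bin_width
  if (length(d)) {
    mag <- abs(d)
    bin <- ceiling(mag / bin_width)        # 0 for overlap, 1..nb finite, >nb far
    side <- ifelse(d < 0, "up", "down")
    idx <- ifelse(mag == 0, 1,
                  ifelse(side == "up", 1, nb + 2) + pmin(bin, nb + 1))
    tab <- table(factor(idx, levels = seq_along(labels)))
    counts[] <- as.integer(tab)
  }
  n_total <- length(d)
  pct <- if (n_total > 0) 100 * counts / n_total
    else setNames(rep(NA_real_, length(labels)), labels)
  structure(list(counts = counts, percent = pct, n_total = n_total,
                 n_unassigned = n_unassigned, bin_width = bin_width,
                 max_distance = max_distance),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat("Distance-to-TSS histogram (", x$n_total, " sites",
      if (x$n_unassigned) paste0(", ", x$n_unassigned, " unassigned"),
      ")\n", sep = "")
  print(data.frame(bin = names(x$counts), count = as.integer(x$counts),
                   percent = round(x$percent, 1), row.names = NULL))
  invisible(x)
}

#' Export a distance histogram as a data.frame (TSV-ready)
#' @param x a `distance_histogram`.
#' @return data.frame with columns `bin`, `count`, `percent`.
#' @export
as.data.frame.distance_histogram <- function(x, ...) {
  data.frame(bin = names(x$counts), count = as.integer(x$counts),
             percent = x$percent, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Random null binding-site set
#'
#' Places `n` sites uniformly over covered genomic space (an
#' [array_design()]'s covered regions, or whole chromosomes when given a
#' [genome_annotation()]); widths are drawn by `width_sampler`.  Sites
#' never straddle a covered-region boundary (placement is uniform over
#' eligible start positions).  Deterministic for a given seed.
#'
#' @param space an [array_design()] or [genome_annotation()].
#' @param n number of sites (`n <= 0` gives an empty set).
#' @param widths observed widths to resample with replacement (the
#'   default width model), or a function `function(n)` returning widths.
#' @param seed integer RNG seed.
#' @param prefix id prefix (default `"rand"`).
#' @return interval data.frame of `n` sites.
#' @export
random_site_set <- function(space, n, widths, seed, prefix = "rand") {
  if (inherits(space, "genome_annotation")) space <- whole_genome_design(space)
  regions <- space$covered_regions
  empty <- intervals(character(), numeric(), numeric(), id = character())
  if (n <= 0) return(empty)
  set.seed(as.integer(seed))
  w <- if (is.function(widths)) widths(n)
    else sample(widths, n, replace = TRUE)
  w <- pmax(1, round(w))
  rlen <- regions$end - regions$start
  if (max(w) > max(rlen))
    stop("covered space too small for the sampled widths")
  chrom <- character(n); start <- numeric(n)
  for (i in seq_len(n)) {
    elig <- rlen - w[i] + 1          # eligible start positions per region
    elig[elig < 0] <- 0
    r <- sample.int(nrow(regions), 1, prob = elig)
    chrom[i] <- regions$chrom[r]
    start[i] <- regions$start[r] + sample.int(elig[r], 1) - 1
  }
  intervals(chrom, start, start + w, id = paste0(prefix, "_", seq_len(n)))
}
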