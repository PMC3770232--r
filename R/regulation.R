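## Regulation calls from knockdown (KD) and overexpression (OE)
## expression contrasts, and the regulated-fraction analyses: overall,
## by distance bin, by site count and by gene position relative to the
## binding site.

#' Regulation thresholds
#'
#' A linear fold-change cut-off (symmetric: up means fold >= threshold,
#' down means fold <= 1/threshold) combined with a strict p-value rule
#' (`p < p_threshold`).
#'
#' @param fold_threshold linear fold > 1 (typically 1.5 or 1.25).
#' @param p_threshold p-value cut-off in (0,1), default 0.05.
#' @return object of class `regulation_thresholds`.
#' @export
regulation_thresholds <- function(fold_threshold = 1.5, p_threshold = 0.05) {
  if (fold_threshold <= 1) stop("fold_threshold must be > 1")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must be in (0,1)")
  structure(list(fold_threshold = fold_threshold, p_threshold = p_threshold),
            class = "regulation_thresholds")
}

#' Per-contrast up/down/unchanged call
#'
#' `up` when `2^log2fc >= fold_threshold` and `p < p_threshold`; `down`
#' when `2^log2fc <= 1/fold_threshold` and `p < p_threshold`; otherwise
#' `unchanged`.  Rows with missing fold change or p-value are `excluded`.
#'
#' @param log2fc,p numeric vectors (signed log2 fold change; p-value).
#' @param thresholds a [regulation_thresholds()].
#' @return character vector over `up`, `down`, `unchanged`, `excluded`.
#' @export
call_contrast <- function(log2fc, p, thresholds) {
  lt <- log2(thresholds$fold_threshold)
  status <- rep("unchanged", length(log2fc))
  status[which(log2fc >= lt & p < thresholds$p_threshold)] <- "up"
  status[which(log2fc <= -lt & p < thresholds$p_threshold)] <- "down"
  status[is.na(log2fc) | is.na(p)] <- "excluded"
  status
}

#' Combine KD and OE calls into a factor-effect direction
#'
#' Down upon knockdown or up upon overexpression is evidence the factor
#' activates the gene; up upon knockdown or down upon overexpression,
#' that it represses.  Consistent evidence gives `activated_by_factor` /
#' `repressed_by_factor`; contradictory passing contrasts give
#' `conflicting`; no passing contrast gives `unchanged`.
#'
#' @param kd_status,oe_status character vectors from [call_contrast()]
#'   (`excluded` is treated as no evidence).
#' @return character vector of overall directions.
#' @export
combine_calls <- function(kd_status, oe_status) {
  act <- (kd_status == "down") | (oe_status == "up")
  rep_ <- (kd_status == "up") | (oe_status == "down")
  out <- rep("unchanged", length(kd_status))
  out[act & !rep_] <- "activated_by_factor"
  out[rep_ & !act] <- "repressed_by_factor"
  out[act & rep_] <- "conflicting"
  out
}

#' Call regulation for every gene in an expression table
#'
#' Reshapes a long (gene, log2fc, p, contrast) table into one row per
#' gene with the per-contrast statuses and the combined factor-effect
#' direction.  A gene absent from a contrast is `excluded` for that
#' contrast.
#'
#' @param expression data.frame as returned by [read_expression()].
#' @param thresholds a [regulation_thresholds()].
#' @return data.frame with columns `gene`, `kd`, `oe`, `overall`,
#'   `regulated` (logical: overall is not `unchanged`).
#' @export
call_regulation <- function(expression, thresholds) {
  genes <- unique(expression$gene)
  one <- function(lbl) {
    sub <- expression[expression$contrast == lbl, , drop = FALSE]
    st <- setNames(rep("excluded", length(genes)), genes)
    if (nrow(sub))
      st[sub$gene] <- call_contrast(sub$log2fc, sub$p, thresholds)
    unname(st)
  }
  kd <- one("KD"); oe <- one("OE")
  overall <- combine_calls(kd, oe)
  overall[kd == "excluded" & oe == "excluded"] <- "excluded"
  data.frame(gene = genes, kd = kd, oe = oe, overall = overall,
             regulated = !(overall %in% c("unchanged", "excluded")),
             stringsAsFactors = FALSE)
}

#' Regulated fractions for a target-gene list
#'
#' Fractions of regulated (any direction, conflicting included),
#' activated and repressed genes among targets with profiling data, for
#' the KD contrast, the OE contrast and their union.
#'
#' @param calls output of [call_regulation()].
#' @param targets optional character vector restricting the denominator
#'   to a target-gene list (default: all genes with data).
#' @return data.frame with one row per contrast (`union`, `KD`, `OE`)
#'   and columns `n`, `regulated`, `activated`, `repressed` plus their
#'   `_fraction` counterparts.
#' @export
regulated_fraction <- function(calls, targets = NULL) {
  if (!is.null(targets)) calls <- calls[calls$gene %in% targets, ,
                                        drop = FALSE]
  calls <- calls[calls$overall != "excluded", , drop = FALSE]
  n <- nrow(calls)
  if (n == 0) warning("empty denominator: no targets with profiling data")
  row_for <- function(lbl, reg, act, repr) {
    data.frame(contrast = lbl, n = n, regulated = sum(reg),
               activated = sum(act), repressed = sum(repr),
               regulated_fraction = if (n) sum(reg) / n else NA_real_,
               activated_fraction = if (n) sum(act) / n else NA_real_,
               repressed_fraction = if (n) sum(repr) / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(
    row_for("union", calls$regulated,
            calls$overall == "activated_by_factor",
            calls$overall == "repressed_by_factor"),
    row_for("KD", calls$kd %in% c("up", "down"),
            calls$kd == "down", calls$kd == "up"),
    row_for("OE", calls$oe %in% c("up", "down"),
            calls$oe == "up", calls$oe == "down")
  )
}

#' Per-gene distance to the nearest assigned binding site
#'
#' Inverts a [nearest_tss()] assignment: each target gene's distance is
#' the signed distance of minimum magnitude over its assigned sites.
#'
#' @param assignment a [nearest_tss()] table.
#' @return data.frame with columns `gene`, `distance`, `n_sites`.
#' @export
gene_site_distances <- function(assignment) {
  ok <- !is.na(assignment$gene_id)
  a <- assignment[ok, , drop = FALSE]
  sp <- split(a$distance, a$gene_id)
  data.frame(gene = names(sp),
             distance = vapply(sp, function(d) d[which.min(abs(d))], 0),
             n_sites = lengths(sp), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Regulated fraction by distance bin
#'
#' Bins target genes by their signed site distance (same binning as
#' [distance_histogram()]) and reports per-bin denominators, regulated
#' counts and fractions, plus a chi-square homogeneity test across the
#' non-empty bins.
#'
#' @param gene_distances output of [gene_site_distances()].
#' @param calls output of [call_regulation()].
#' @param bin_width,max_distance binning parameters (defaults 4000 and
#'   40000 bp).
#' @return list with `table` (bin, n, regulated, fraction) and the
#'   chi-square `statistic`, `df` and `p_value` over non-empty bins.
#' @export
regulated_by_distance_bin <- function(gene_distances, calls,
                                      bin_width = 4000,
                                      max_distance = 40000) {
  reg <- setNames(calls$regulated, calls$gene)
  has_data <- setNames(calls$overall != "excluded", calls$gene)
  gd <- gene_distances[gene_distances$gene %in% calls$gene, , drop = FALSE]
  gd <- gd[has_data[gd$gene], , drop = FALSE]
  labels <- histogram_bin_labels(bin_width, max_distance)
  nb <- max_distance / bin_width
  mag <- abs(gd$distance)
  bin <- ceiling(mag / bin_width)
  idx <- ifelse(mag == 0, 1,
                ifelse(gd$distance < 0, 1, nb + 2) + pmin(bin, nb + 1))
  f <- factor(idx, levels = seq_along(labels))
  n <- as.integer(table(f))
  nreg <- as.integer(tapply(reg[gd$gene], f, sum, default = 0))
  tab <- data.frame(bin = labels, n = n, regulated = nreg,
                    fraction = ifelse(n > 0, nreg / n, NA_real_),
                    stringsAsFactors = FALSE)
  # Cochran's rule: the chi-square approximation needs expected counts
  # of at least 5, so bins too sparse for it are excluded from the
  # homogeneity statistic (they stay in the table with their
  # denominators; the far bins are often very small)
  pooled <- sum(tab$regulated) / max(1, sum(tab$n))
  keep <- tab$n > 0 & tab$n * pooled >= 5 & tab$n * (1 - pooled) >= 5
  if (sum(keep) >= 2 && sum(tab$regulated[keep]) > 0 &&
      sum(tab$regulated[keep]) < sum(tab$n[keep])) {
    ct <- suppressWarnings(chisq.test(
      rbind(tab$regulated[keep], tab$n[keep] - tab$regulated[keep])))
    stat <- unname(ct$statistic); df <- unname(ct$parameter)
    p <- ct$p.value
  } else {
    stat <- NA_real_; df <- NA_real_; p <- NA_real_
  }
  list(table = tab, statistic = stat, df = df, p_value = p)
}

#' Regulated fraction by per-gene site count
#'
#' Rows for genes with any number of sites, exactly one site, and two or
#' more sites; an empty `2+` class is reported with a zero denominator
#' and `NA` fraction.
#'
#' @param gene_distances output of [gene_site_distances()] (its
#'   `n_sites` column is used).
#' @param calls output of [call_regulation()].
#' @return data.frame with columns `class`, `n`, `regulated`, `fraction`.
#' @export
regulated_by_site_count <- function(gene_distances, calls) {
  reg <- setNames(calls$regulated, calls$gene)
  has_data <- setNames(calls$overall != "excluded", calls$gene)
  gd <- gene_distances[gene_distances$gene %in% calls$gene, , drop = FALSE]
  gd <- gd[has_data[gd$gene], , drop = FALSE]
  one_row <- function(lbl, sel) {
    n <- sum(sel); r <- sum(reg[gd$gene[sel]])
    data.frame(class = lbl, n = n, regulated = r,
               fraction = if (n > 0) r / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(one_row("any", rep(TRUE, nrow(gd))),
        one_row("1", gd$n_sites == 1),
        one_row("2+", gd$n_sites >= 2))
}

#' Classify genes by position relative to each binding site
#'
#' For each site: type 1 is the nearest-TSS gene; type 2 the nearest
#' gene whose TSS lies on the opposite side of the site midpoint from
#' type 1's; type 3 the second-nearest gene on type 1's side (so type
#' 1 lies between the site and type 3).  Slots may be empty near
#' chromosome ends; ties are broken by gene id.  When a TSS coincides
#' with the site midpoint its side is taken as downstream (+1).
#'
#' @param sites interval data.frame of binding sites.
#' @param annotation a [genome_annotation()].
#' @return data.frame with columns `site_id`, `type1`, `type2`, `type3`
#'   (gene ids or `NA`).
#' @export
classify_gene_position <- function(sites, annotation) {
  genes <- annotation$genes
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  out <- data.frame(
    site_id = if (!is.null(sites$id)) sites$id
      else paste0("site_", seq_len(nrow(sites))),
    type1 = NA_character_, type2 = NA_character_, type3 = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sites))) {
    gidx <- by_chrom[[sites$chrom[i]]]
    if (is.null(gidx)) next
    g <- genes[gidx, , drop = FALSE]
    d <- signed_tss_distance(sites[i, , drop = FALSE], g)
    mag <- abs(d)
    ord <- order(mag, g$id)
    mid <- interval_midpoint(sites[i, , drop = FALSE])
    side <- sign(g$tss - mid)
    side[side == 0] <- 1
    t1 <- ord[1]
    out$type1[i] <- g$id[t1]
    opp <- ord[ord != t1 & side[ord] == -side[t1]]
    if (length(opp)) out$type2[i] <- g$id[opp[1]]
    same <- ord[ord != t1 & side[ord] == side[t1]]
    if (length(same)) out$type3[i] <- g$id[same[1]]
  }
  out
}

#' Regulated fraction by gene-position type
#'
#' For each position type (1, 2, 3) collects the genes occupying that
#' slot across all sites (deduplicated; a gene occupying several types
#' for different sites counts in each) and reports the regulated
#' fraction at each supplied threshold.
#'
#' @param position output of [classify_gene_position()].
#' @param calls_list named list of [call_regulation()] outputs, one per
#'   threshold (e.g. `list("1.5" = ..., "1.25" = ...)`).
#' @return data.frame with columns `type`, `n_genes` and one
#'   `fraction_<name>` column per threshold (`NA` and zero denominator
#'   when a type is empty).
#' @export
regulated_by_position_type <- function(position, calls_list) {
  res <- lapply(c(type1 = "type1", type2 = "type2", type3 = "type3"),
                function(col) unique(position[[col]][!is.na(position[[col]])]))
  out <- data.frame(type = c(1, 2, 3),
                    n_genes = vapply(res, length, 0L),
                    stringsAsFactors = FALSE)
  for (nm in names(calls_list)) {
    calls <- calls_list[[nm]]
    reg <- setNames(calls$regulated, calls$gene)
    has <- setNames(calls$overall != "excluded", calls$gene)
    out[[paste0("fraction_", nm)]] <- vapply(res, function(gs) {
      gs <- gs[gs %in% calls$gene]
      gs <- gs[has[gs]]
      if (!length(gs)) NA_real_ else mean(reg[gs])
    }, 0)
  }
  out
}
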