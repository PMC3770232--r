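## Synthetic-data generator: a seeded genome (annotation + sequence),
## binding-site set, regulatory-element tracks and KD/OE expression
## contrasts with a ground-truth manifest, emulating the statistical
## structure of a tiling-array binding study so every downstream stage is
## testable without external data.

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: ~503 bp mean site width
#' (lognormal, range roughly 150-1100 bp), 47% GC sequence, a TSS-centred
#' bell (SD 2 kb) placing 45% of sites so that ~47% land within 4 kb of a
#' TSS once the uniform background is added, a degenerate 6-mer consensus
#' planted in 47.2% of sites, element tracks with proximity folds
#' 1.49 / 1.45 / 1.01, and two expression contrasts with 8.4% of genes
#' regulated above 1.5-fold (52% activated).
#'
#' @param seed master integer seed (mandatory); one RNG stream per
#'   generator stage is derived from it, so adding a stage does not
#'   perturb earlier outputs.
#' @param n_chroms,chrom_length number and length (bp) of chromosomes.
#' @param n_genes number of genes (placed without overlap).
#' @param gene_length_meanlog,gene_length_sdlog lognormal gene-length
#'   parameters.
#' @param n_sites number of binding sites.
#' @param site_width_meanlog,site_width_sdlog lognormal site-width
#'   parameters (defaults give mean 503 bp).
#' @param tss_proximal_fraction fraction of sites placed by the
#'   TSS-centred bell; the rest are uniform.
#' @param tss_sd SD (bp) of the bell around the chosen TSS.
#' @param allow_overlap permit peaks to overlap each other (default
#'   `FALSE`: overlapping placements are resampled, as called peak sets
#'   are disjoint).
#' @param gc_content genome GC fraction.
#' @param motif_consensus IUPAC consensus planted into sites.
#' @param motif_plant_fraction fraction of sites receiving one planted
#'   instance.
#' @param elements named list of tracks, each
#'   `list(n =, width =, fold =)`; `fold` is the target proximity fold
#'   of distal sites vs a random set.
#' @param proximity_gap,distal_cutoff proximity window and distal
#'   definition (bp).
#' @param regulated_fraction fraction of genes planted as regulated
#'   above `fold_target`.
#' @param activated_share share of planted genes activated by the factor
#'   (down in KD, up in OE).
#' @param fold_target linear fold the planted effects exceed.
#' @param effect_rate rate of the exponential excess of planted
#'   `|log2fc|` above `log2(fold_target)`.
#' @param sigma_null SD of null log2 fold changes (null p-values are
#'   uniform on (0,1); planted ones uniform on (0, 0.05)).
#' @param kd_response_prob,oe_response_prob probability a planted gene
#'   responds in each contrast (1 = responds in both).
#' @param distance_decay logical; when `TRUE` planting probability
#'   decays with site-TSS distance (`exp(-d/decay_scale)`), otherwise
#'   planting is independent of distance.
#' @param decay_scale decay length in bp.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed,
                              n_chroms = 4, chrom_length = 7.5e6,
                              n_genes = 400,
                              gene_length_meanlog = log(14000),
                              gene_length_sdlog = 0.6,
                              n_sites = 1500,
                              site_width_meanlog = log(503) - 0.35^2 / 2,
                              site_width_sdlog = 0.35,
                              tss_proximal_fraction = 0.46,
                              tss_sd = 650,
                              allow_overlap = FALSE,
                              gc_content = 0.47,
                              motif_consensus = "ATCRAT",
                              motif_plant_fraction = 0.472,
                              elements = list(
                                dhs = list(n = 3000, width = 300, fold = 1.49),
                                enhancers = list(n = 3000, width = 600, fold = 1.45),
                                insulators = list(n = 1500, width = 400, fold = 1.01)),
                              proximity_gap = 1000, distal_cutoff = 4000,
                              regulated_fraction = 0.084,
                              activated_share = 0.52,
                              fold_target = 1.5, effect_rate = 3,
                              sigma_null = 0.25,
                              kd_response_prob = 1, oe_response_prob = 1,
                              distance_decay = FALSE, decay_scale = 10000) {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  fracs <- c(cfg$tss_proximal_fraction, cfg$gc_content,
             cfg$motif_plant_fraction, cfg$regulated_fraction,
             cfg$activated_share, cfg$kd_response_prob,
             cfg$oe_response_prob)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0,1]")
  if (cfg$n_chroms < 1 || cfg$chrom_length <= 0)
    stop("need at least one chromosome of positive length")
  structure(cfg, class = "simulation_config")
}

## one RNG stream per stage, derived from the master seed
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 10007 + stage) %% 2147483629)
}

#' Simulate a genome: annotation and sequence
#'
#' Genes are placed without overlap (lognormal lengths, exponential
#' stick-breaking gaps), strands are Bernoulli(0.5), and each chromosome
#' sequence is i.i.d. with `P(G) + P(C) = gc_content`.  Byte-identical
#' across runs with the same seed.
#'
#' @param config a [simulation_config()].
#' @param sequences generate chromosome sequences (set `FALSE` for
#'   annotation-only studies; much faster).
#' @return list with `annotation` (a [genome_annotation()]) and
#'   `sequences` (named character vector of chromosome sequences, or
#'   `NULL`).
#' @export
simulate_genome <- function(config, sequences = TRUE) {
  set.seed(stage_seed(config$seed, 1))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  lens <- setNames(rep(config$chrom_length, config$n_chroms), chroms)
  n <- config$n_genes
  per <- diff(floor(seq(0, n, length.out = config$n_chroms + 1)))
  genes <- NULL
  if (n > 0) {
    glen <- pmax(200, round(rlnorm(n, config$gene_length_meanlog,
                                   config$gene_length_sdlog)))
    idx <- rep(seq_len(config$n_chroms), per)
    parts <- lapply(seq_len(config$n_chroms), function(ci) {
      li <- glen[idx == ci]
      k <- length(li)
      if (k == 0) return(NULL)
      L <- lens[ci]
      if (sum(li) > 0.95 * L)
        stop("genes cannot fit in chromosome ", chroms[ci])
      gaps <- rexp(k + 1)
      gaps <- gaps / sum(gaps) * (L - sum(li))
      start <- floor(cumsum(gaps[seq_len(k)]) + cumsum(c(0, li[-k])))
      data.frame(chrom = chroms[ci], start = start, end = start + li,
                 stringsAsFactors = FALSE)
    })
    genes <- do.call(rbind, parts)
    genes$strand <- ifelse(rbinom(n, 1, 0.5) == 1, "+", "-")
    genes$id <- sprintf("gene_%04d", seq_len(n))
  } else {
    genes <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        id = character(), stringsAsFactors = FALSE)
  }
  ann <- genome_annotation(genes, lens)
  seqs <- NULL
  if (sequences) {
    bases <- charToRaw("ACGT")
    p <- c((1 - config$gc_content) / 2, config$gc_content / 2,
           config$gc_content / 2, (1 - config$gc_content) / 2)
    seqs <- vapply(chroms, function(ch)
      rawToChar(sample(bases, lens[ch], replace = TRUE, prob = p)), "")
  }
  list(annotation = ann, sequences = seqs)
}

## sample one concrete instance of a degenerate pattern (forward strand)
sample_instance <- function(pattern) {
  paste(vapply(pattern$sets, function(s)
    if (length(s) == 1) s else sample(s, 1), ""), collapse = "")
}

revcomp_chr <- function(x) {
  paste(rev(complement_set(strsplit(x, "")[[1]])), collapse = "")
}

#' Simulate binding sites (peaks) and plant motif instances
#'
#' A `tss_proximal_fraction` of peaks is centred at normal draws around
#' randomly chosen TSSs (SD `tss_sd`), the remainder uniformly over the
#' chromosomes; widths are lognormal.  Out-of-bounds placements are
#' resampled (capped at 100 retries).  When sequences are supplied, a
#' `motif_plant_fraction` of peaks receives one concrete consensus
#' instance written at a uniform position within the peak, on a random
#' strand.
#'
#' @param annotation a [genome_annotation()] from [simulate_genome()].
#' @param config a [simulation_config()].
#' @param sequences named character vector of chromosome sequences (or
#'   `NULL` to skip planting).
#' @return list with `sites` (interval data.frame), `manifest`
#'   (per-peak: id, placement mode, planted flag) and `sequences`
#'   (modified copy).
#' @export
simulate_peaks <- function(annotation, config, sequences = NULL) {
  set.seed(stage_seed(config$seed, 2))
  n <- config$n_sites
  lens <- annotation$chrom_lengths
  chroms <- names(lens)
  empty <- intervals(character(), numeric(), numeric(), id = character())
  if (n <= 0)
    return(list(sites = empty,
                manifest = data.frame(id = character(),
                                      placement = character(),
                                      planted_motif = logical()),
                sequences = sequences))
  w <- pmax(10, round(rlnorm(n, config$site_width_meanlog,
                             config$site_width_sdlog)))
  n_tss <- nrow(annotation$genes)
  proximal <- rbinom(n, 1, config$tss_proximal_fraction) == 1 & n_tss > 0
  chrom <- character(n); start <- numeric(n)
  placed_by_chrom <- setNames(
    rep(list(data.frame(start = numeric(), end = numeric())), length(chroms)),
    chroms)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(1000)) {
      if (proximal[i]) {
        gi <- sample.int(n_tss, 1)
        ch <- annotation$genes$chrom[gi]
        center <- round(rnorm(1, annotation$genes$tss[gi], config$tss_sd))
        st <- center - floor(w[i] / 2)
      } else {
        ch <- sample(chroms, 1, prob = lens)
        st <- floor(runif(1, 0, lens[ch] - w[i]))
      }
      if (st < 0 || st + w[i] > lens[ch]) next
      if (!config$allow_overlap) {
        prev <- placed_by_chrom[[ch]]
        if (any(st < prev$end & st + w[i] > prev$start)) next
      }
      chrom[i] <- ch; start[i] <- st; placed <- TRUE
      placed_by_chrom[[ch]] <-
        rbind(placed_by_chrom[[ch]],
              data.frame(start = st, end = st + w[i]))
      break
    }
    if (!placed) stop("could not place peak ", i, " after 1000 retries")
  }
  sites <- intervals(chrom, start, start + w,
                     id = sprintf("peak_%04d", seq_len(n)))
  planted <- rbinom(n, 1, config$motif_plant_fraction) == 1
  if (is.null(sequences)) {
    planted[] <- FALSE
  } else {
    pattern <- compile_pattern(config$motif_consensus)
    for (i in which(planted)) {
      if (w[i] < pattern$length) { planted[i] <- FALSE; next }
      pos <- start[i] + sample.int(w[i] - pattern$length + 1, 1) - 1
      inst <- sample_instance(pattern)
      if (runif(1) < 0.5) inst <- revcomp_chr(inst)
      substr(sequences[[chrom[i]]], pos + 1,
             pos + pattern$length) <- inst
    }
  }
  manifest <- data.frame(id = sites$id,
                         placement = ifelse(proximal, "tss_proximal",
                                            "uniform"),
                         planted_motif = planted,
                         stringsAsFactors = FALSE)
  list(sites = sites, manifest = manifest, sequences = sequences)
}

#' Simulate regulatory-element tracks with planted proximity enrichment
#'
#' For each track, `k` elements are placed within `proximity_gap` of
#' distinct randomly chosen distal peaks (gap uniform in `[0, gap]`) and
#' the rest uniformly, with `k` solved from the configured fold so that
#' the expected measured proximity fold (distal sites vs a random set)
#' equals it: `k = round(b (fold - 1) n_distal / (1 - b))` where `b` is
#' the analytic baseline proximity probability under uniform placement.
#'
#' @param annotation a [genome_annotation()].
#' @param sites simulated peaks.
#' @param config a [simulation_config()].
#' @return list with `tracks` (named list of element interval
#'   data.frames) and `manifest` (per-track: n, attached count, target
#'   fold).
#' @export
simulate_elements <- function(annotation, sites, config) {
  lens <- annotation$chrom_lengths
  G <- sum(lens)
  asn <- nearest_tss(sites, annotation)
  distal <- which(!is.na(asn$distance) &
                    abs(asn$distance) > config$distal_cutoff)
  mean_w <- if (nrow(sites)) mean(interval_width(sites)) else 0
  tracks <- list()
  man <- NULL
  ti <- 0
  for (nm in names(config$elements)) {
    ti <- ti + 1
    set.seed(stage_seed(config$seed, 10 + ti))
    el <- config$elements[[nm]]
    n_e <- el$n; w_e <- el$width; fold <- el$fold
    if (n_e == 0) {
      tracks[[nm]] <- intervals(character(), numeric(), numeric(),
                                id = character())
      man <- rbind(man, data.frame(track = nm, n = 0L, attached = 0L,
                                   target_fold = fold))
      next
    }
    if (fold < 1)
      stop("track '", nm, "': folds below 1 cannot be planted ",
           "(background cannot be depleted)")
    footprint <- mean_w + w_e + 2 * config$proximity_gap
    b <- 1 - (1 - footprint / G)^n_e
    k <- round(b * (fold - 1) * length(distal) / (1 - b))
    if (k > min(n_e, length(distal)))
      stop("track '", nm, "': requested fold ", fold,
           " infeasible for track density (needs ", k,
           " attached elements, have ", n_e, " elements and ",
           length(distal), " distal peaks)")
    chrom <- character(n_e); start <- numeric(n_e)
    if (k > 0) {
      anchors <- distal[sample.int(length(distal), k)]
      for (j in seq_len(k)) {
        s <- sites[anchors[j], ]
        g <- sample.int(config$proximity_gap + 1, 1) - 1
        right <- runif(1) < 0.5
        st <- if (right) s$end + g else s$start - g - w_e
        if (st < 0) st <- s$end + g
        if (st + w_e > lens[s$chrom]) st <- max(0, s$start - g - w_e)
        chrom[j] <- s$chrom; start[j] <- st
      }
    }
    if (n_e > k) {
      for (j in seq(k + 1, n_e)) {
        ch <- sample(names(lens), 1, prob = lens)
        chrom[j] <- ch
        start[j] <- floor(runif(1, 0, lens[ch] - w_e))
      }
    }
    tracks[[nm]] <- intervals(chrom, start, start + w_e,
                              id = sprintf("%s_%04d", nm, seq_len(n_e)))
    man <- rbind(man, data.frame(track = nm, n = n_e, attached = k,
                                 target_fold = fold))
  }
  list(tracks = tracks, manifest = man)
}

#' Simulate KD and OE expression contrasts with planted regulation
#'
#' Unregulated genes draw `log2fc ~ N(0, sigma_null)` and `p ~ U(0,1)`;
#' planted regulated genes draw `|log2fc| = log2(fold_target) +
#' Exp(effect_rate)` and `p ~ U(0, 0.05)`, with signs consistent with
#' the activated/repressed assignment (activated: down in KD, up in OE).
#' By default planting is independent of site-TSS distance; the
#' distance-decay mode weights planting by `exp(-d / decay_scale)`.
#'
#' @param annotation a [genome_annotation()].
#' @param sites simulated peaks (needed only for distance-decay mode;
#'   may be `NULL`).
#' @param config a [simulation_config()].
#' @return list with `expression` (gene, log2fc, p, contrast rows for
#'   both contrasts) and `manifest` (per-gene: planted flag, direction,
#'   per-contrast response flags).
#' @export
simulate_expression <- function(annotation, sites, config) {
  set.seed(stage_seed(config$seed, 4))
  genes <- annotation$genes$id
  n <- length(genes)
  n_planted <- round(config$regulated_fraction * n)
  if (config$regulated_fraction > 0 && n_planted < 1) {
    warning("regulated_fraction x n_genes < 1: planting zero genes")
    n_planted <- 0
  }
  weights <- rep(1, n)
  if (config$distance_decay && !is.null(sites) && nrow(sites) > 0) {
    gd <- gene_site_distances(nearest_tss(sites, annotation))
    d <- setNames(abs(gd$distance), gd$gene)[genes]
    w <- exp(-d / config$decay_scale)
    w[is.na(w)] <- exp(-10)      # genes without sites: far-distance floor
    weights <- w
  }
  planted_idx <- if (n_planted > 0)
    sample.int(n, n_planted, prob = weights) else integer()
  planted <- seq_len(n) %in% planted_idx
  activated <- planted & rbinom(n, 1, config$activated_share) == 1
  kd_resp <- planted & rbinom(n, 1, config$kd_response_prob) == 1
  oe_resp <- planted & rbinom(n, 1, config$oe_response_prob) == 1
  draw_contrast <- function(responds, up_sign) {
    lfc <- rnorm(n, 0, config$sigma_null)
    p <- runif(n)
    k <- sum(responds)
    if (k > 0) {
      mag <- log2(config$fold_target) + rexp(k, config$effect_rate)
      lfc[responds] <- up_sign[responds] * mag
      p[responds] <- runif(k, 0, 0.05)
    }
    list(lfc = lfc, p = p)
  }
  # activated by factor: down in KD, up in OE
  kd_sign <- ifelse(activated, -1, 1)
  oe_sign <- ifelse(activated, 1, -1)
  kd <- draw_contrast(kd_resp, kd_sign)
  oe <- draw_contrast(oe_resp, oe_sign)
  expression <- rbind(
    data.frame(gene = genes, log2fc = kd$lfc, p = kd$p, contrast = "KD",
               stringsAsFactors = FALSE),
    data.frame(gene = genes, log2fc = oe$lfc, p = oe$p, contrast = "OE",
               stringsAsFactors = FALSE))
  manifest <- data.frame(
    gene = genes, planted_regulated = planted,
    direction = ifelse(planted, ifelse(activated, "activated",
                                       "repressed"), NA_character_),
    kd_responds = kd_resp, oe_responds = oe_resp,
    stringsAsFactors = FALSE)
  list(expression = expression, manifest = manifest)
}

#' Simulate a complete dataset (and optionally write it to disk)
#'
#' Chains [simulate_genome()], [simulate_peaks()],
#' [simulate_elements()] and [simulate_expression()]; the optional
#' on-disk bundle comprises `genes.tsv`, `chroms.tsv`, `genome.fa`,
#' `peaks.bed`, one BED per element track, `expression.tsv` and a
#' `ground_truth.json` manifest, every file parseable by the package's
#' readers and byte-identical across runs with the same seed.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory (created if needed).
#' @param sequences generate and write genome sequence (default `TRUE`).
#' @return object of class `synthetic_dataset`: `annotation`,
#'   `sequences`, `sites`, `elements`, `expression`, `manifest`
#'   (`$peaks`, `$genes`, `$elements`), `config`.
#' @export
simulate_dataset <- function(config, dir = NULL, sequences = TRUE) {
  gen <- simulate_genome(config, sequences = sequences)
  pk <- simulate_peaks(gen$annotation, config, gen$sequences)
  el <- simulate_elements(gen$annotation, pk$sites, config)
  ex <- simulate_expression(gen$annotation, pk$sites, config)
  ds <- structure(list(
    annotation = gen$annotation, sequences = pk$sequences,
    sites = pk$sites, elements = el$tracks, expression = ex$expression,
    manifest = list(peaks = pk$manifest, genes = ex$manifest,
                    elements = el$manifest),
    config = config), class = "synthetic_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset (seed ", x$config$seed, ")\n", sep = "")
  print(x$annotation)
  cat("  sites:      ", nrow(x$sites), "\n")
  cat("  elements:   ", paste(names(x$elements), collapse = ", "), "\n")
  cat("  expression: ", nrow(x$expression), "rows\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#' @param ds a `synthetic_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- ds$annotation$genes
  write_tsv(g[c("chrom", "start", "end", "strand", "id")],
            file.path(dir, "genes.tsv"))
  write_tsv(data.frame(chrom = names(ds$annotation$chrom_lengths),
                       length = as.numeric(ds$annotation$chrom_lengths)),
            file.path(dir, "chroms.tsv"))
  if (!is.null(ds$sequences)) {
    seqs <- Biostrings::DNAStringSet(ds$sequences)
    Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fa"))
  }
  write_bed(ds$sites, file.path(dir, "peaks.bed"))
  for (nm in names(ds$elements))
    write_bed(ds$elements[[nm]], file.path(dir, paste0(nm, ".bed")))
  write_tsv(ds$expression, file.path(dir, "expression.tsv"))
  jsonlite::write_json(ds$manifest, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)
  invisible(dir)
}
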