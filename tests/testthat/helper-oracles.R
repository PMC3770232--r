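# Independent brute-force oracles and small fixture builders used across
# the suite.  The oracles enumerate; they never call the code paths they
# check.

# naive degenerate-consensus scanner: check every offset against the
# expanded per-position base sets, both strands, palindromes kept on '+'
naive_scan <- function(seq_chr, pattern) {
  bases <- strsplit(toupper(seq_chr), "")[[1]]
  L <- length(bases)
  k <- pattern$length
  hits <- data.frame(pos = integer(), strand = character())
  if (L < k) return(hits)
  for (off in 0:(L - k)) {
    window <- bases[(off + 1):(off + k)]
    fw <- all(vapply(seq_len(k), function(j)
      window[j] %in% pattern$sets[[j]], TRUE))
    rv <- all(vapply(seq_len(k), function(j)
      window[j] %in% pattern$revcomp_sets[[j]], TRUE))
    if (fw) hits <- rbind(hits, data.frame(pos = off, strand = "+"))
    else if (rv) hits <- rbind(hits, data.frame(pos = off, strand = "-"))
  }
  hits
}

# exhaustive nearest-TSS scan with the same tie rules, via direct
# per-gene arithmetic (not signed_tss_distance)
brute_nearest <- function(site, genes) {
  genes <- genes[genes$chrom == site$chrom, , drop = FALSE]
  if (nrow(genes) == 0) return(list(gene = NA_character_, d = NA_real_))
  mag <- pmax(0, site$start - genes$tss, genes$tss - site$end)
  ov <- site$start <= genes$tss & genes$tss < site$end
  best <- which(mag == min(mag))
  if (length(best) > 1) {
    if (any(ov[best])) best <- best[ov[best]]
    best <- best[order(genes$id[best])]
  }
  b <- best[1]
  upstream <- if (genes$strand[b] == "+") genes$tss[b] - site$end > 0
    else site$start - genes$tss[b] > 0
  list(gene = genes$id[b], d = if (upstream) -mag[b] else mag[b])
}

# two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins
hyper_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small hand-built annotation: two chromosomes, mixed strands
toy_annotation <- function() {
  genes <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000, 8000, 20000, 5000),
    end = c(5000, 12000, 30000, 9000),
    strand = c("+", "-", "+", "-"),
    id = c("gA", "gB", "gC", "gD"),
    stringsAsFactors = FALSE)
  genome_annotation(genes, c(chr1 = 100000, chr2 = 50000))
}

# random small annotation for property tests
random_annotation <- function(n_genes, chrom_len = 2e5, seed) {
  set.seed(seed)
  start <- sort(sample.int(chrom_len - 3000, n_genes))
  len <- sample(200:2000, n_genes, replace = TRUE)
  genes <- data.frame(
    chrom = "chr1", start = start,
    end = pmin(start + len, chrom_len),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    id = sprintf("g%03d", seq_len(n_genes)),
    stringsAsFactors = FALSE)
  genome_annotation(genes, c(chr1 = chrom_len))
}

random_dna <- function(n, p_gc = 0.5, p_n = 0) {
  probs <- c((1 - p_gc) * (1 - p_n) / 2, p_gc * (1 - p_n) / 2,
             p_gc * (1 - p_n) / 2, (1 - p_gc) * (1 - p_n) / 2, p_n)
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE, prob = probs),
        collapse = "")
}
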