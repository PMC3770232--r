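# Regulation calls from KD/OE contrasts and the regulated-fraction
# analyses.

test_that("per-contrast calls follow the fold and p rules", {
  thr15 <- regulation_thresholds(1.5)
  thr125 <- regulation_thresholds(1.25)
  expect_equal(call_contrast(log2(0.60), 0.01, thr15), "down")
  expect_equal(call_contrast(log2(1.30), 0.01, thr15), "unchanged")
  expect_equal(call_contrast(log2(1.30), 0.01, thr125), "up")
  expect_equal(call_contrast(log2(2.0), 0.20, thr15), "unchanged")
  # boundaries: fold exactly at threshold passes, p exactly 0.05 fails
  expect_equal(call_contrast(log2(1.5), 0.049, thr15), "up")
  expect_equal(call_contrast(log2(1.5), 0.05, thr15), "unchanged")
  expect_equal(call_contrast(NA, 0.01, thr15), "excluded")
  expect_equal(call_contrast(0.9, NA, thr15), "excluded")
  expect_error(regulation_thresholds(0.9), "> 1")
})

test_that("KD/OE combination maps to factor effect with conflicts", {
  expect_equal(combine_calls("down", "unchanged"), "activated_by_factor")
  expect_equal(combine_calls("unchanged", "down"), "repressed_by_factor")
  expect_equal(combine_calls("up", "up"), "conflicting")
  expect_equal(combine_calls("down", "up"), "activated_by_factor")
  expect_equal(combine_calls("up", "down"), "repressed_by_factor")
  expect_equal(combine_calls("unchanged", "unchanged"), "unchanged")
  expect_equal(combine_calls("excluded", "up"), "activated_by_factor")
})

test_that("statuses partition the expression table", {
  set.seed(8)
  thr <- regulation_thresholds(1.5)
  for (rep in 1:10) {
    n <- 300
    expr <- data.frame(
      gene = rep(sprintf("g%03d", 1:n), 2),
      log2fc = rnorm(2 * n, 0, 0.6),
      p = runif(2 * n),
      contrast = rep(c("KD", "OE"), each = n),
      stringsAsFactors = FALSE)
    expr$log2fc[sample.int(2 * n, 10)] <- NA
    calls <- call_regulation(expr, thr)
    expect_equal(nrow(calls), n)
    for (col in c("kd", "oe"))
      expect_equal(sum(calls[[col]] %in%
                         c("up", "down", "unchanged", "excluded")), n)
    # overall is unchanged iff no contrast passed
    passed <- calls$kd %in% c("up", "down") | calls$oe %in% c("up", "down")
    expect_equal(calls$overall == "unchanged" |
                   calls$overall == "excluded", !passed)
  }
})

test_that("the 1.5-fold regulated set is nested in the 1.25-fold set", {
  cfg <- simulation_config(seed = 23, n_genes = 800, n_sites = 0,
                           chrom_length = 2e7)
  gen <- simulate_genome(cfg, sequences = FALSE)
  ex <- simulate_expression(gen$annotation, NULL, cfg)
  c15 <- call_regulation(ex$expression, regulation_thresholds(1.5))
  c125 <- call_regulation(ex$expression, regulation_thresholds(1.25))
  expect_true(all(c15$gene[c15$regulated] %in% c125$gene[c125$regulated]))
  expect_gte(sum(c125$regulated), sum(c15$regulated))
})

test_that("planted direction is always recovered when both contrasts pass", {
  cfg <- simulation_config(seed = 29, n_genes = 1000, n_sites = 0,
                           chrom_length = 2e7, regulated_fraction = 0.2)
  gen <- simulate_genome(cfg, sequences = FALSE)
  ex <- simulate_expression(gen$annotation, NULL, cfg)
  calls <- call_regulation(ex$expression, regulation_thresholds(1.5))
  man <- ex$manifest
  merged <- merge(calls, man, by = "gene")
  both_pass <- merged$kd %in% c("up", "down") &
    merged$oe %in% c("up", "down") & merged$planted_regulated
  expect_gt(sum(both_pass), 50)
  expect_true(all(
    merged$overall[both_pass & merged$direction == "activated"] ==
      "activated_by_factor"))
  expect_true(all(
    merged$overall[both_pass & merged$direction == "repressed"] ==
      "repressed_by_factor"))
})

test_that("KD-only responders make union counts exceed OE counts", {
  cfg <- simulation_config(seed = 31, n_genes = 1500, n_sites = 0,
                           chrom_length = 3e7, regulated_fraction = 0.15,
                           oe_response_prob = 0.3)
  gen <- simulate_genome(cfg, sequences = FALSE)
  ex <- simulate_expression(gen$annotation, NULL, cfg)
  calls <- call_regulation(ex$expression, regulation_thresholds(1.5))
  s <- regulated_fraction(calls)
  expect_gt(s$regulated[s$contrast == "union"],
            s$regulated[s$contrast == "OE"])
  expect_gt(s$regulated[s$contrast == "KD"],
            s$regulated[s$contrast == "OE"])
})

test_that("regulated fractions reproduce printed summary arithmetic", {
  # 347 regulated of 4140 targets with data -> 8.4%
  n <- 4140
  expr <- data.frame(
    gene = rep(sprintf("g%04d", 1:n), 2),
    log2fc = rep(c(rep(1.2, 347), rep(0, n - 347)), 2),
    p = rep(c(rep(0.001, 347), rep(0.9, n - 347)), 2),
    contrast = rep(c("KD", "OE"), each = n), stringsAsFactors = FALSE)
  calls <- call_regulation(expr, regulation_thresholds(1.5))
  s <- regulated_fraction(calls)
  expect_equal(s$regulated[s$contrast == "union"], 347)
  expect_equal(round(100 * s$regulated_fraction[s$contrast == "union"], 1),
               8.4)
})

test_that("regulated fraction by site count mirrors printed table rows", {
  # 255 regulated of 613 genes with 2+ sites -> 41.6%
  n1 <- 3527; n2 <- 613
  genes <- c(sprintf("a%04d", 1:n1), sprintf("b%04d", 1:n2))
  gd <- data.frame(gene = genes, distance = 0,
                   n_sites = c(rep(1, n1), rep(2, n2)),
                   stringsAsFactors = FALSE)
  reg <- c(rep(TRUE, 278), rep(FALSE, n1 - 278),
           rep(TRUE, 255), rep(FALSE, n2 - 255))
  calls <- data.frame(gene = genes, kd = "unchanged", oe = "unchanged",
                      overall = ifelse(reg, "activated_by_factor",
                                       "unchanged"),
                      regulated = reg, stringsAsFactors = FALSE)
  tab <- regulated_by_site_count(gd, calls)
  expect_equal(tab$regulated[tab$class == "2+"], 255)
  expect_equal(round(100 * tab$fraction[tab$class == "2+"], 1), 41.6)
  expect_equal(round(100 * tab$fraction[tab$class == "1"], 1), 7.9)
  # all genes one site: 2+ row flagged with zero denominator
  tab2 <- regulated_by_site_count(gd[gd$n_sites == 1, ], calls)
  expect_equal(tab2$n[tab2$class == "2+"], 0)
  expect_true(is.na(tab2$fraction[tab2$class == "2+"]))
})

test_that("distance-bin table: all-regulated toy set and denominators", {
  gd <- data.frame(gene = c("g1", "g2", "g3"),
                   distance = c(0, -2000, 41000), n_sites = 1)
  calls <- data.frame(gene = c("g1", "g2", "g3"), kd = "down",
                      oe = "unchanged", overall = "activated_by_factor",
                      regulated = TRUE, stringsAsFactors = FALSE)
  r <- regulated_by_distance_bin(gd, calls)
  tab <- r$table
  nonempty <- tab[tab$n > 0, ]
  expect_equal(nonempty$fraction, rep(1, 3))
  expect_equal(sum(tab$n), 3)
  expect_true(all(is.na(tab$fraction[tab$n == 0])))
})

test_that("gene position types follow the side-and-order rules", {
  genes <- data.frame(
    chrom = "chr1",
    start = c(40000, 62000, 90000),
    end = c(50000, 70000, 100000),
    strand = c("-", "+", "+"),
    id = c("left10k", "right2k", "right30k"),
    stringsAsFactors = FALSE)
  # site midpoint at 60000: TSSs at 49999 (left), 62000, 90000 (right)
  ann <- genome_annotation(genes, c(chr1 = 2e5))
  pos <- classify_gene_position(intervals("chr1", 59750, 60250, id = "s"),
                                ann)
  expect_equal(pos$type1, "right2k")
  expect_equal(pos$type2, "left10k")
  expect_equal(pos$type3, "right30k")
  # single-gene chromosome: only type 1
  ann1 <- genome_annotation(genes[1, ], c(chr1 = 2e5))
  pos1 <- classify_gene_position(intervals("chr1", 59750, 60250), ann1)
  expect_equal(pos1$type1, "left10k")
  expect_true(is.na(pos1$type2) && is.na(pos1$type3))
  # equidistant opposite-side genes: id tie-break, loser becomes type 2
  genes_tie <- data.frame(
    chrom = "chr1", start = c(8000, 11000), end = c(9001, 12000),
    strand = c("-", "+"), id = c("gA", "gB"), stringsAsFactors = FALSE)
  ann_tie <- genome_annotation(genes_tie, c(chr1 = 1e5))
  pos_tie <- classify_gene_position(intervals("chr1", 9500, 10500), ann_tie)
  expect_equal(pos_tie$type1, "gA")
  expect_equal(pos_tie$type2, "gB")
})

test_that("regulation by position type handles empty slots and zeros", {
  genes <- data.frame(chrom = "chr1", start = c(1000, 20000),
                      end = c(2000, 21000), strand = c("+", "+"),
                      id = c("g1", "g2"), stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, c(chr1 = 1e5))
  pos <- classify_gene_position(intervals("chr1", 5000, 5500), ann)
  calls <- data.frame(gene = c("g1", "g2"), kd = "unchanged",
                      oe = "unchanged", overall = "unchanged",
                      regulated = FALSE, stringsAsFactors = FALSE)
  tab <- regulated_by_position_type(pos, list("1.5" = calls))
  expect_equal(tab$fraction_1.5[tab$type %in% c(1, 2)], c(0, 0))
  expect_equal(tab$n_genes[tab$type == 3], 0)
  expect_true(is.na(tab$fraction_1.5[tab$type == 3]))
})
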