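# The seeded generator: determinism, composition, placement and the
# ground-truth manifest.

small_cfg <- function(seed, ...) {
  simulation_config(seed = seed, n_chroms = 2, chrom_length = 1e6,
                    n_genes = 60, n_sites = 120,
                    elements = list(dhs = list(n = 200, width = 300,
                                               fold = 1.5)),
                    ...)
}

test_that("the same seed reproduces every artifact byte-identically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(small_cfg(101), dir = d1)
  simulate_dataset(small_cfg(101), dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 6)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  d3 <- withr::local_tempdir()
  simulate_dataset(small_cfg(102), dir = d3)
  expect_false(identical(readLines(file.path(d1, "peaks.bed")),
                         readLines(file.path(d3, "peaks.bed"))))
})

test_that("written artifacts are parseable by the package readers", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg(7), dir = d)
  ann <- read_gene_table(file.path(d, "genes.tsv"),
                         file.path(d, "chroms.tsv"))
  expect_equal(ann$genes$tss, ds$annotation$genes$tss)
  sites <- read_bed(file.path(d, "peaks.bed"))
  expect_equal(sites$start, ds$sites$start)
  expr <- read_expression(file.path(d, "expression.tsv"))
  expect_equal(nrow(expr), nrow(ds$expression))
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_setequal(names(gt), c("peaks", "genes", "elements"))
  # manifest covers every peak and gene exactly once
  expect_setequal(gt$peaks$id, ds$sites$id)
  expect_setequal(gt$genes$gene, ds$annotation$genes$id)
})

test_that("sequence composition hits the configured GC content", {
  cfg <- simulation_config(seed = 11, n_chroms = 1, chrom_length = 1e6,
                           n_genes = 10, gc_content = 0.5)
  gen <- simulate_genome(cfg)
  gc <- sum(strsplit(gen$sequences[[1]], "")[[1]] %in% c("G", "C"))
  n <- nchar(gen$sequences[[1]])
  expect_lt(abs(gc / n - 0.5), 3 * sqrt(0.25 / n))
  # and at the default 0.47 the pooled region GC reports accordingly
  cfg2 <- simulation_config(seed = 12, n_chroms = 1, chrom_length = 5e5,
                            n_genes = 10, n_sites = 50)
  gen2 <- simulate_genome(cfg2)
  pk <- simulate_peaks(gen2$annotation, cfg2, gen2$sequences)
  res <- region_consensus_fraction(pk$sites, pk$sequences,
                                   compile_pattern("ATCRAT"))
  expect_lt(abs(res$gc_content_of_regions - 0.47), 0.02)
})

test_that("a gene-free genome yields only non-transcribed sites", {
  cfg <- simulation_config(seed = 13, n_chroms = 1, chrom_length = 5e5,
                           n_genes = 0, n_sites = 40)
  gen <- simulate_genome(cfg, sequences = FALSE)
  expect_equal(nrow(gen$annotation$transcribed), 0)
  pk <- simulate_peaks(gen$annotation, cfg)
  cls <- classify_transcribed(pk$sites, gen$annotation)
  expect_equal(cls$count_in, 0)
  expect_equal(cls$count_out, nrow(pk$sites))
})

test_that("a pure TSS-bell places nearly all sites within 4 kb", {
  cfg <- simulation_config(seed = 15, tss_proximal_fraction = 1,
                           tss_sd = 1000, n_sites = 1000)
  gen <- simulate_genome(cfg, sequences = FALSE)
  pk <- simulate_peaks(gen$annotation, cfg)
  d <- nearest_tss(pk$sites, gen$annotation)$distance
  expect_gte(mean(abs(d) <= 4000), 0.95)
})

test_that("degenerate generator inputs behave as contracted", {
  cfg0 <- simulation_config(seed = 17, n_chroms = 1, chrom_length = 2e5,
                            n_genes = 10, n_sites = 0)
  gen <- simulate_genome(cfg0, sequences = FALSE)
  pk <- simulate_peaks(gen$annotation, cfg0)
  expect_equal(nrow(pk$sites), 0)
  expect_equal(nrow(pk$manifest), 0)
  # genes that cannot fit are a config error
  cfg_big <- simulation_config(seed = 18, n_chroms = 1, chrom_length = 1e4,
                               n_genes = 50)
  expect_error(simulate_genome(cfg_big, sequences = FALSE), "cannot fit")
  # sub-unit planting count warns and plants nothing
  cfg_f <- simulation_config(seed = 19, n_chroms = 1, chrom_length = 2e5,
                             n_genes = 10, n_sites = 5,
                             regulated_fraction = 0.01)
  gen_f <- simulate_genome(cfg_f, sequences = FALSE)
  expect_warning(ex <- simulate_expression(gen_f$annotation, NULL, cfg_f),
                 "zero genes")
  expect_equal(sum(ex$manifest$planted_regulated), 0)
  expect_error(simulation_config(seed = 1, gc_content = 1.2), "fractions")
  expect_error(simulation_config(), "seed")
})

test_that("activated_share = 1 makes every planted gene down-KD / up-OE", {
  cfg <- simulation_config(seed = 21, n_chroms = 1, chrom_length = 1e7,
                           n_genes = 300, n_sites = 0,
                           regulated_fraction = 0.2, activated_share = 1)
  gen <- simulate_genome(cfg, sequences = FALSE)
  ex <- simulate_expression(gen$annotation, NULL, cfg)
  planted <- ex$manifest$gene[ex$manifest$planted_regulated]
  kd <- ex$expression[ex$expression$contrast == "KD", ]
  oe <- ex$expression[ex$expression$contrast == "OE", ]
  expect_true(all(kd$log2fc[kd$gene %in% planted] < 0))
  expect_true(all(oe$log2fc[oe$gene %in% planted] > 0))
})

test_that("with no planting the regulated estimate stays near the null
           crossing rate", {
  cfg <- simulation_config(seed = 25, n_chroms = 2, chrom_length = 2e7,
                           n_genes = 2000, n_sites = 0,
                           regulated_fraction = 0)
  gen <- simulate_genome(cfg, sequences = FALSE)
  ex <- simulate_expression(gen$annotation, NULL, cfg)
  calls <- call_regulation(ex$expression, regulation_thresholds(1.5))
  # per-contrast null crossing probability, closed form
  null_rate <- 0.05 * 2 * pnorm(-log2(1.5) / cfg$sigma_null)
  union_bound <- 2 * null_rate
  est <- mean(calls$regulated)
  expect_lte(est, union_bound + 3 * sqrt(union_bound / 2000) + 1e-9)
})

test_that("element tracks: no-enrichment and zero-element cases", {
  cfg <- simulation_config(seed = 27,
                           elements = list(
                             flat = list(n = 1500, width = 300, fold = 1.0),
                             none = list(n = 0, width = 300, fold = 1.5)))
  gen <- simulate_genome(cfg, sequences = FALSE)
  pk <- simulate_peaks(gen$annotation, cfg)
  el <- simulate_elements(gen$annotation, pk$sites, cfg)
  expect_equal(el$manifest$attached[el$manifest$track == "flat"], 0)
  expect_equal(nrow(el$tracks$none), 0)
  asn <- nearest_tss(pk$sites, gen$annotation)
  distal <- pk$sites[!is.na(asn$distance) & abs(asn$distance) > 4000, ]
  rs <- random_site_set(gen$annotation, nrow(distal),
                        widths = interval_width(distal), seed = 99)
  pf <- proximity_fold(distal, rs, el$tracks$flat)
  # fold = 1 planted: observed within binomial error of the random set
  se <- sqrt(2 * pf$background_fraction *
               (1 - pf$background_fraction) / nrow(distal))
  expect_lt(abs(pf$observed_fraction - pf$background_fraction), 3 * se)
  expect_equal(element_proximity_fraction(distal, el$tracks$none), 0)
  # an infeasible fold is a config error with an explanation
  cfg_bad <- simulation_config(seed = 28,
                               elements = list(tiny = list(n = 1, width = 100,
                                                           fold = 500)))
  gen_b <- simulate_genome(cfg_bad, sequences = FALSE)
  pk_b <- simulate_peaks(gen_b$annotation, cfg_bad)
  expect_error(simulate_elements(gen_b$annotation, pk_b$sites, cfg_bad),
               "infeasible")
})
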