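## End-to-end pipeline: configuration, stage chaining, TSV report bundle
## and run log.  Every percentage in every report is written next to its
## denominator.

#' Default pipeline configuration
#'
#' A single flat, documented key-value structure; values supplied in
#' `config` (a list or a YAML file) override these defaults.
#'
#' @return nested list of defaults: `out_dir`, `seed`, `inputs` (paths:
#'   `genes`, `chrom_lengths`, `peaks`, `genome_fasta`, `expression`,
#'   and `elements`, a named list of BED paths), `thresholds` (`folds`,
#'   `p`, `bin_width`, `max_distance`, `proximity_gap`,
#'   `distal_cutoff`), `motif` (`consensus`, `code_overrides`),
#'   `n_random_sets`, and `simulate` (overrides passed to
#'   [simulation_config()]).
#' @export
pipeline_defaults <- function() {
  list(
    out_dir = "peakreg_output",
    seed = 1,
    inputs = list(genes = NULL, chrom_lengths = NULL, peaks = NULL,
                  genome_fasta = NULL, expression = NULL,
                  elements = list()),
    thresholds = list(folds = c(1.5, 1.25), p = 0.05, bin_width = 4000,
                      max_distance = 40000, proximity_gap = 1000,
                      distal_cutoff = 4000),
    motif = list(consensus = "ATCRAT", code_overrides = NULL),
    n_random_sets = 3,
    simulate = list()
  )
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file (YAML)
#' @param path path to a YAML config file.
#' @return configuration list merged over [pipeline_defaults()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  deep_merge(pipeline_defaults(), yaml::read_yaml(path))
}

require_input <- function(cfg, key) {
  val <- cfg$inputs[[key]]
  if (is.null(val)) stop("missing input: inputs$", key)
  if (is.character(val) && !file.exists(val))
    stop("missing input file for inputs$", key, ": ", val)
  val
}

## assemble in-memory state from config paths or a simulated dataset
pipeline_state <- function(cfg, simulated = NULL) {
  if (!is.null(simulated)) {
    return(list(annotation = simulated$annotation,
                sites = simulated$sites,
                genome = simulated$sequences,
                elements = simulated$elements,
                expression = simulated$expression))
  }
  ann <- read_gene_table(require_input(cfg, "genes"),
                         require_input(cfg, "chrom_lengths"))
  sites <- read_bed(require_input(cfg, "peaks"))
  genome <- cfg$inputs$genome_fasta
  elements <- lapply(cfg$inputs$elements, read_bed)
  expr <- if (!is.null(cfg$inputs$expression))
    read_expression(cfg$inputs$expression) else NULL
  list(annotation = ann, sites = sites, genome = genome,
       elements = elements, expression = expr)
}

#' Run the analysis pipeline
#'
#' Chains the package's stages over one configuration and writes a
#' TSV report bundle plus a run log (configuration, seeds, package
#' version) into `out_dir`.  Reruns with the same config and seed
#' produce identical bytes.
#'
#' @param subcommand one of `"simulate"`, `"map-tss"`, `"enrich"`,
#'   `"motif"`, `"coverage"`, `"regulate"`, `"all"`.
#' @param config a configuration list (merged over
#'   [pipeline_defaults()]) or the path to a YAML config file.
#' @return invisibly, the list of report paths written.
#' @export
run_pipeline <- function(subcommand = "all", config = list()) {
  subcommand <- match.arg(subcommand,
                          c("all", "simulate", "map-tss", "enrich",
                            "motif", "coverage", "regulate"))
  cfg <- if (is.character(config)) read_pipeline_config(config)
    else deep_merge(pipeline_defaults(), config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  reports <- character()
  emit <- function(df, name) {
    path <- file.path(out, name)
    write_tsv(df, path)
    reports <<- c(reports, path)
    path
  }

  simulated <- NULL
  if (subcommand %in% c("simulate", "all")) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim_cfg <- do.call(simulation_config, sim_args)
    simulated <- simulate_dataset(sim_cfg, dir = file.path(out, "data"))
    reports <- c(reports, file.path(out, "data"))
    if (subcommand == "simulate") {
      write_run_log(cfg, reports, out)
      return(invisible(reports))
    }
  }
  st <- pipeline_state(cfg, simulated)
  thr <- cfg$thresholds
  asn <- NULL
  if (subcommand %in% c("all", "map-tss", "enrich", "coverage", "regulate"))
    asn <- nearest_tss(st$sites, st$annotation)

  if (subcommand %in% c("all", "map-tss")) {
    emit(asn, "map_tss_assignment.tsv")
    h <- distance_histogram(asn, thr$bin_width, thr$max_distance)
    emit(as.data.frame(h), "distance_histogram.tsv")
    for (i in seq_len(cfg$n_random_sets)) {
      rs <- random_site_set(st$annotation, nrow(st$sites),
                            widths = interval_width(st$sites),
                            seed = stage_seed(cfg$seed, 100 + i))
      hr <- distance_histogram(nearest_tss(rs, st$annotation),
                               thr$bin_width, thr$max_distance)
      emit(as.data.frame(hr), sprintf("random_histogram_%d.tsv", i))
    }
  }

  if (subcommand %in% c("all", "enrich")) {
    design <- whole_genome_design(st$annotation)
    cls <- classify_transcribed(st$sites, st$annotation)
    bg_non <- 1 - design$transcribed_fraction
    en <- odds_enrichment(cls$count_out, cls$count_in, bg_non)
    emit(data.frame(n_sites = en$n_sites,
                    non_transcribed = cls$count_out,
                    transcribed = cls$count_in,
                    observed_non_fraction = en$observed_fraction,
                    background_non_fraction = en$background_fraction,
                    fold = en$fold, odds_ratio = en$odds_ratio,
                    p_value = en$p_value),
         "transcribed_enrichment.tsv")
    distal <- st$sites[!is.na(asn$distance) &
                         abs(asn$distance) > thr$distal_cutoff, ,
                       drop = FALSE]
    if (nrow(distal) > 0 && length(st$elements)) {
      rs <- random_site_set(st$annotation, nrow(distal),
                            widths = interval_width(distal),
                            seed = stage_seed(cfg$seed, 200))
      rows <- lapply(names(st$elements), function(nm) {
        pf <- proximity_fold(distal, rs, st$elements[[nm]],
                             thr$proximity_gap)
        data.frame(track = nm, n_distal = pf$n_sites,
                   n_random = nrow(rs),
                   observed_fraction = pf$observed_fraction,
                   random_fraction = pf$background_fraction,
                   fold = pf$fold, p_value = pf$p_value,
                   stringsAsFactors = FALSE)
      })
      emit(do.call(rbind, rows), "element_proximity.tsv")
    }
  }

  if (subcommand %in% c("all", "motif")) {
    if (is.null(st$genome)) stop("missing input: inputs$genome_fasta")
    pattern <- compile_pattern(cfg$motif$consensus,
                               cfg$motif$code_overrides)
    design <- whole_genome_design(st$annotation)
    cmp <- matched_random_fraction(st$sites, design, st$genome, pattern,
                                   seed = stage_seed(cfg$seed, 300))
    occ <- motif_occupancy(design, st$sites, st$genome, pattern)
    emit(data.frame(
      set = c("bound", "random"),
      n_regions = c(cmp$bound$n_regions, cmp$random$n_regions),
      with_consensus = c(cmp$bound$n_with_match, cmp$random$n_with_match),
      fraction = c(cmp$bound$fraction_with_match,
                   cmp$random$fraction_with_match),
      gc_content = c(cmp$bound$gc_content_of_regions,
                     cmp$random$gc_content_of_regions),
      fisher_p = cmp$p_value,
      occupancy_hits = occ$n_hits, occupancy_bound = occ$n_bound,
      occupancy_fraction = occ$fraction,
      stringsAsFactors = FALSE), "motif_summary.tsv")
  }

  calls_list <- NULL
  if (subcommand %in% c("all", "coverage", "regulate") &&
      !is.null(st$expression)) {
    calls_list <- lapply(thr$folds, function(f)
      call_regulation(st$expression, regulation_thresholds(f, thr$p)))
    names(calls_list) <- as.character(thr$folds)
  }

  if (subcommand %in% c("all", "coverage")) {
    rows <- lapply(default_promoter_windows(), function(w) {
      cf <- capture_fractions(st$sites, st$annotation, w, assignment = asn)
      data.frame(platform = w$platform, upstream = w$upstream,
                 downstream = w$downstream, n_sites = cf$n_sites,
                 site_fraction = cf$site_fraction, n_genes = cf$n_genes,
                 gene_fraction = cf$gene_fraction,
                 stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, rows), "array_capture.tsv")
    if (!is.null(calls_list)) {
      w1 <- default_promoter_windows()[[1]]
      captured <- site_captured(st$sites, st$annotation, w1)
      cap_genes <- unique(asn$gene_id[captured & !is.na(asn$gene_id)])
      rows <- lapply(names(calls_list), function(nm) {
        calls <- calls_list[[nm]]
        reg_genes <- calls$gene[calls$regulated &
                                  calls$gene %in% asn$gene_id]
        ov <- target_overlap(reg_genes, cap_genes)
        data.frame(threshold = nm, n_regulated_targets = ov$n_a,
                   captured = ov$n_intersect, fraction = ov$fraction,
                   stringsAsFactors = FALSE)
      })
      emit(do.call(rbind, rows), "target_overlap.tsv")
    }
  }

  if (subcommand %in% c("all", "regulate")) {
    if (is.null(calls_list)) stop("missing input: inputs$expression")
    targets <- unique(asn$gene_id[!is.na(asn$gene_id)])
    gd <- gene_site_distances(asn)
    summaries <- lapply(names(calls_list), function(nm) {
      s <- regulated_fraction(calls_list[[nm]], targets)
      cbind(threshold = nm, s)
    })
    emit(do.call(rbind, summaries), "regulation_summary.tsv")
    bydist <- lapply(names(calls_list), function(nm) {
      r <- regulated_by_distance_bin(gd, calls_list[[nm]],
                                     thr$bin_width, thr$max_distance)
      cbind(threshold = nm, r$table,
            chisq_stat = r$statistic, chisq_p = r$p_value)
    })
    emit(do.call(rbind, bydist), "regulation_by_distance.tsv")
    bycount <- lapply(names(calls_list), function(nm)
      cbind(threshold = nm,
            regulated_by_site_count(gd, calls_list[[nm]])))
    emit(do.call(rbind, bycount), "regulation_by_site_count.tsv")
    pos <- classify_gene_position(st$sites, st$annotation)
    emit(regulated_by_position_type(pos, calls_list),
         "regulation_by_position.tsv")
  }

  write_run_log(cfg, reports, out)
  invisible(reports)
}

## flatten a config to sorted key=value lines (stable across runs)
flatten_config <- function(x, prefix = "") {
  out <- character()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v)) out <- c(out, flatten_config(v, key))
    else if (!is.null(v))
      out <- c(out, paste0(key, " = ", paste(format(v), collapse = ", ")))
  }
  out
}

write_run_log <- function(cfg, reports, out) {
  lines <- c("peakreg run log",
             paste0("package_version = ", as.character(packageVersion("peakreg"))),
             paste0("seed = ", cfg$seed),
             "",
             "configuration:",
             paste0("  ", sort(flatten_config(cfg))),
             "",
             "reports:",
             paste0("  ", reports))
  writeLines(lines, file.path(out, "run_log.txt"))
}
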