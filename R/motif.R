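## Degenerate-consensus motif scanning.  Patterns are per-position allowed
## base sets (any nonempty subset of ACGT maps to one IUPAC letter, so
## Biostrings does the matching); hits on both strands are deduplicated at
## palindromic positions; 'N' in a subject sequence matches nothing.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

set_to_iupac <- function(set) {
  key <- paste(sort(set), collapse = "")
  keys <- vapply(IUPAC_CODES, function(s) paste(sort(s), collapse = ""), "")
  names(IUPAC_CODES)[match(key, keys)]
}

complement_set <- function(set) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[set])
}

#' Compile a degenerate consensus pattern
#'
#' Expands an IUPAC consensus into an explicit per-position allowed-base
#' table and derives the reverse-complement pattern positionally
#' (complement each allowed set, then reverse).  `code_overrides` lets a
#' letter be rebound to a non-standard base set (e.g. `list(R = c("A",
#' "C"))` for reports that use R for A/C); the default table is standard
#' IUPAC.
#'
#' @param consensus non-empty string over IUPAC letters.
#' @param code_overrides optional named list, letter -> character vector
#'   of allowed bases.
#' @return object of class `motif_pattern` with elements `consensus`,
#'   `sets`, `revcomp_sets`, `iupac`, `revcomp_iupac`, `length`.
#' @export
compile_pattern <- function(consensus, code_overrides = NULL) {
  consensus <- toupper(consensus)
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  table <- IUPAC_CODES
  if (!is.null(code_overrides)) {
    for (nm in names(code_overrides)) {
      set <- toupper(code_overrides[[nm]])
      if (!length(set) || !all(set %in% c("A", "C", "G", "T")))
        stop("override for '", nm, "' must be a nonempty subset of ACGT")
      table[[toupper(nm)]] <- set
    }
  }
  letters <- strsplit(consensus, "")[[1]]
  unknown <- setdiff(letters, names(table))
  if (length(unknown))
    stop("unknown consensus letter(s): ", paste(unknown, collapse = ", "))
  sets <- table[letters]
  rc_sets <- rev(lapply(sets, complement_set))
  structure(list(
    consensus = consensus,
    sets = sets,
    revcomp_sets = rc_sets,
    iupac = paste(vapply(sets, set_to_iupac, ""), collapse = ""),
    revcomp_iupac = paste(vapply(rc_sets, set_to_iupac, ""), collapse = ""),
    length = length(sets)
  ), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("Motif pattern:", x$consensus, "->", x$iupac,
      "(revcomp", paste0(x$revcomp_iupac, ")"), "\n")
  invisible(x)
}

## strand-specific raw matcher; drops hits spanning non-ACGT letters
match_one_strand <- function(subject, iupac, len) {
  m <- Biostrings::matchPattern(iupac, subject, fixed = "subject")
  st <- Biostrings::start(m)
  if (length(st)) {
    ok <- vapply(st, function(s) {
      sub <- as.character(Biostrings::subseq(subject, s, s + len - 1))
      !grepl("[^ACGT]", sub)
    }, TRUE)
    st <- st[ok]
  }
  st
}

#' Scan one sequence for a degenerate consensus
#'
#' Reports all 0-based start positions where every base falls in the
#' pattern's allowed set: the forward pattern gives `+` hits, the
#' reverse-complement pattern `-` hits.  A position where both match
#' (palindromic instance) is reported once, on `+`.  `N` (or any
#' non-ACGT letter) in the sequence matches nothing.
#'
#' @param seq character string or `Biostrings::DNAString` over ACGTN.
#' @param pattern a [compile_pattern()] object.
#' @param both_strands scan the reverse-complement pattern too (default
#'   `TRUE`).
#' @return data.frame with columns `pos` (0-based) and `strand`, sorted
#'   by position.
#' @export
scan_sequence <- function(seq, pattern, both_strands = TRUE) {
  subject <- if (methods::is(seq, "DNAString")) seq
    else Biostrings::DNAString(toupper(as.character(seq)))
  fw <- match_one_strand(subject, pattern$iupac, pattern$length)
  rv <- if (both_strands)
    match_one_strand(subject, pattern$revcomp_iupac, pattern$length)
    else integer()
  rv <- setdiff(rv, fw)                      # palindromic dedup: keep '+'
  out <- data.frame(pos = as.integer(c(fw, rv)) - 1L,
                    strand = rep(c("+", "-"), c(length(fw), length(rv))),
                    stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

## read a FASTA path, or pass through a DNAStringSet / named character
## vector of chromosome sequences
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome))) {
    if (!file.exists(genome)) stop("file not found: ", genome)
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(genome))
  stop("genome must be a DNAStringSet, named sequences, or a FASTA path")
}

## extract region sequences (0-based half-open) from a genome
region_sequences <- function(regions, genome) {
  genome <- load_genome(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing))
    stop("regions on sequences absent from FASTA: ",
         paste(missing, collapse = ", "))
  lens <- setNames(Biostrings::width(genome), names(genome))
  over <- which(regions$end > lens[regions$chrom])
  if (length(over))
    stop("region beyond sequence end: ", regions$chrom[over[1]], ":",
         regions$start[over[1]], "-", regions$end[over[1]])
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    regions$start[i] + 1, regions$end[i]))
  }, ""))
  names(seqs) <- if (!is.null(regions$id)) regions$id
    else paste0("region_", seq_len(nrow(regions)))
  seqs
}

## GC fraction over a DNAStringSet (pooled across sequences)
pooled_gc <- function(seqs) {
  if (length(seqs) == 0 || sum(Biostrings::width(seqs)) == 0)
    return(NA_real_)
  gc <- sum(Biostrings::letterFrequency(seqs, "GC"))
  acgt <- sum(Biostrings::letterFrequency(seqs, "ACGT"))
  if (acgt == 0) NA_real_ else gc / acgt
}

motif_scan_result <- function(n_regions, n_with_match, total_occurrences,
                              gc_content) {
  structure(list(
    n_regions = n_regions, n_with_match = n_with_match,
    fraction_with_match = if (n_regions > 0) n_with_match / n_regions
      else NA_real_,
    total_occurrences = total_occurrences,
    gc_content_of_regions = gc_content
  ), class = "motif_scan_result")
}

#' @export
print.motif_scan_result <- function(x, ...) {
  cat(sprintf(
    "Motif scan: %d/%d regions with a match (%.1f%%), %d occurrences, GC %.1f%%\n",
    x$n_with_match, x$n_regions, 100 * x$fraction_with_match,
    x$total_occurrences, 100 * x$gc_content_of_regions))
  invisible(x)
}

#' Fraction of regions containing a consensus match
#'
#' Scans every region on both strands and reports how many contain at
#' least one match, the total (palindrome-deduplicated) occurrence count
#' and the pooled GC content of the region sequences.
#'
#' @param regions interval data.frame of regions.
#' @param genome named `DNAStringSet` or FASTA path covering the regions.
#' @param pattern a [compile_pattern()] object.
#' @return a `motif_scan_result`.
#' @export
region_consensus_fraction <- function(regions, genome, pattern) {
  seqs <- region_sequences(regions, genome)
  hits <- lapply(seq_along(seqs), function(i)
    scan_sequence(seqs[[i]], pattern))
  nh <- vapply(hits, nrow, 0L)
  motif_scan_result(length(seqs), sum(nh > 0), sum(nh), pooled_gc(seqs))
}

#' Consensus occurrence in width-paired random regions
#'
#' Samples one random region per input region (same width, uniform over
#' the design's covered space, seeded) and scans them, so the bound-region
#' match fraction can be compared with a size-matched background whose GC
#' content is reported alongside.  Optionally each random region is
#' accept/reject resampled until its GC content is within `gc_tol` of its
#' paired bound region.
#'
#' @param regions bound regions (widths are reused, paired).
#' @param design an [array_design()] whose covered space is sampled.
#' @param genome named `DNAStringSet` or FASTA path.
#' @param pattern a [compile_pattern()] object.
#' @param seed integer RNG seed.
#' @param gc_match logical; GC-match each random region to its pair.
#' @param gc_tol GC tolerance for matching (default 0.01 = 1 point).
#' @return list with `bound` and `random` (`motif_scan_result`s),
#'   `random_regions`, and the two-sided Fisher `p_value` for the
#'   difference in match fractions.
#' @export
matched_random_fraction <- function(regions, design, genome, pattern, seed,
                                    gc_match = FALSE, gc_tol = 0.01) {
  genome <- load_genome(genome)
  widths <- interval_width(regions)
  if (total_width(design$covered_regions) < sum(widths))
    stop("covered space smaller than the total region width")
  rand <- random_site_set(design, nrow(regions), widths = function(n) widths,
                          seed = seed, prefix = "bg")
  if (gc_match) {
    target_gc <- vapply(seq_len(nrow(regions)), function(i)
      pooled_gc(region_sequences(regions[i, , drop = FALSE], genome)), 0)
    for (i in seq_len(nrow(rand))) {
      tries <- 0
      repeat {
        gc_i <- pooled_gc(region_sequences(rand[i, , drop = FALSE], genome))
        if (is.na(target_gc[i]) || abs(gc_i - target_gc[i]) <= gc_tol) break
        tries <- tries + 1
        if (tries > 1000) {
          warning("GC matching failed for region ", i, " after 1000 tries")
          break
        }
        repl <- random_site_set(design, 1, widths = function(n) widths[i],
                                seed = seed + 7919 * i + tries)
        rand[i, c("chrom", "start", "end")] <-
          repl[1, c("chrom", "start", "end")]
      }
    }
  }
  bound_res <- region_consensus_fraction(regions, genome, pattern)
  rand_res <- region_consensus_fraction(rand, genome, pattern)
  tab <- matrix(c(bound_res$n_with_match,
                  bound_res$n_regions - bound_res$n_with_match,
                  rand_res$n_with_match,
                  rand_res$n_regions - rand_res$n_with_match), nrow = 2)
  list(bound = bound_res, random = rand_res, random_regions = rand,
       p_value = fisher.test(tab)$p.value)
}

#' Bound fraction of all consensus occurrences on an array
#'
#' Enumerates every (deduplicated, both-strand) consensus hit in the
#' design's covered space and reports the fraction whose 0-based start
#' position lies inside any bound region.
#'
#' @param design an [array_design()].
#' @param regions bound regions (subset of the covered space).
#' @param genome named `DNAStringSet` or FASTA path.
#' @param pattern a [compile_pattern()] object.
#' @return list with `n_hits`, `n_bound` and `fraction` (`NA` with a
#'   warning when there are no hits).
#' @export
motif_occupancy <- function(design, regions, genome, pattern) {
  covered <- design$covered_regions
  seqs <- region_sequences(covered, genome)
  hit_list <- lapply(seq_along(seqs), function(i) {
    h <- scan_sequence(seqs[[i]], pattern)
    if (nrow(h) == 0) return(NULL)
    data.frame(chrom = covered$chrom[i], pos = covered$start[i] + h$pos,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hit_list)
  if (is.null(hits) || nrow(hits) == 0) {
    warning("no consensus hits in covered space: occupancy undefined")
    return(list(n_hits = 0L, n_bound = 0L, fraction = NA_real_))
  }
  if (nrow(regions) > 0) {
    pts <- GenomicRanges::GRanges(hits$chrom,
                                  IRanges::IRanges(hits$pos + 1, hits$pos + 1))
    inside <- GenomicRanges::countOverlaps(pts, as_granges(regions)) > 0
  } else inside <- rep(FALSE, nrow(hits))
  list(n_hits = nrow(hits), n_bound = sum(inside),
       fraction = sum(inside) / nrow(hits))
}
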