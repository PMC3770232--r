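## Core interval machinery.  Intervals are plain data.frames with columns
## chrom, start, end in 0-based half-open coordinates (BED convention); the
## helpers below convert to 1-based closed IRanges/GRanges for overlap and
## distance queries so that a single coordinate convention rules the package.

#' Construct a set of genomic intervals
#'
#' Validates and normalises a chrom/start/end(/strand) table into the plain
#' 0-based half-open representation used throughout the package.
#'
#' @param chrom character vector of chromosome names (non-empty).
#' @param start,end numeric vectors; `0 <= start < end`, end exclusive.
#' @param strand optional vector over `"+"`, `"-"`, `"*"` (unstranded).
#' @param id optional character vector of unique identifiers.
#' @param score optional numeric score.
#' @return data.frame with columns `chrom`, `start`, `end` and any of
#'   `strand`, `id`, `score` that were supplied.
#' @export
intervals <- function(chrom, start, end, strand = NULL, id = NULL,
                      score = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (!is.null(strand) && length(strand) == 1) strand <- rep(strand, n)
  if (length(start) != n || length(end) != n || length(chrom) != n)
    stop("chrom, start and end must have equal length")
  if (any(is.na(chrom) | !nzchar(chrom)))
    stop("chrom names must be non-empty")
  if (any(is.na(start) | is.na(end)))
    stop("start/end must not contain NA")
  if (any(start < 0))
    stop("start must be >= 0")
  if (any(start >= end))
    stop("start must be < end (0-based half-open)")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", "*")))
      stop("strand must be one of '+', '-', '*'")
    df$strand <- strand
  }
  if (!is.null(id)) {
    id <- as.character(id)
    if (anyDuplicated(id))
      stop("interval ids must be unique")
    df$id <- id
  }
  if (!is.null(score)) df$score <- as.numeric(score)
  df
}

## 0-based half-open data.frame -> GRanges (1-based closed)
as_granges <- function(df, strand = NULL) {
  str <- if (!is.null(strand)) strand
    else if (!is.null(df$strand)) df$strand
    else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = str
  )
}

interval_width <- function(df) df$end - df$start

interval_midpoint <- function(df) floor((df$start + df$end) / 2)

#' Gap between two intervals
#'
#' Number of bases strictly between two intervals; 0 when they overlap or
#' abut.  Intervals on different chromosomes are infinitely far apart
#' (`Inf` sentinel, never a large finite number).
#'
#' @param a,b interval data.frames (recycled to common length).
#' @return numeric vector of base-pair gaps (`>= 0`, possibly `Inf`).
#' @export
interval_gap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  g <- pmax(0, pmax(a$start[ai], b$start[bi]) - pmin(a$end[ai], b$end[bi]))
  g[a$chrom[ai] != b$chrom[bi]] <- Inf
  g
}

#' Merge overlapping or abutting intervals
#'
#' @param df interval data.frame.
#' @return data.frame of disjoint merged intervals, sorted by chrom/start.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::reduce(as_granges(df, strand = "*"))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

total_width <- function(df) sum(df$end - df$start)
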