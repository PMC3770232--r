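## Readers and writers for the plain-text formats every stage consumes:
## BED (3-6 columns, native 0-based half-open), a documented gene TSV (or
## GFF3 as an alternate dialect), chromosome-length sidecars and per-gene
## expression contrasts.  All writers emit tab-separated UTF-8.

#' Read binding sites or element intervals from a BED file
#'
#' Coordinates are interpreted as BED 0-based half-open; file order is
#' preserved.  The optional 4th column becomes the id (otherwise ids
#' `site_1`, `site_2`, ... are assigned), the optional 5th the score and
#' the optional 6th the strand.
#'
#' @param path path to a BED file (>= 3 tab-separated columns per line).
#' @return interval data.frame with columns chrom/start/end/id (and
#'   score/strand when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0)
    return(intervals(character(), numeric(), numeric(), id = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED parse error at line ", which(nf < 3)[1],
         ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": non-integer coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": start >= end")
  id <- if (all(nf >= 4)) vapply(fields, `[`, "", 4)
    else paste0("site_", seq_along(lines))
  score <- if (all(nf >= 5))
    suppressWarnings(as.numeric(vapply(fields, `[`, "", 5))) else NULL
  strand <- if (all(nf >= 6)) vapply(fields, `[`, "", 6) else NULL
  if (!is.null(strand) && !all(strand %in% c("+", "-", "."))) strand <- NULL
  if (!is.null(strand)) strand[strand == "."] <- "*"
  intervals(chrom, start, end, strand = strand, id = id, score = score)
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: coordinates round-trip bit-exactly.
#'
#' @param df interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  id <- if (!is.null(df$id)) df$id else paste0("site_", seq_len(nrow(df)))
  cols <- list(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE), id)
  if (!is.null(df$score)) {
    cols <- c(cols, list(df$score))
    if (!is.null(df$strand)) {
      st <- df$strand
      st[st == "*"] <- "."
      cols <- c(cols, list(st))
    }
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Accepts either the documented TSV dialect (header columns `chrom`,
#' `start`, `end`, `strand`, `id`; 0-based half-open) or GFF3
#' (`.gff`/`.gff3`; 1-based inclusive, converted on read, gene id taken
#' from the `ID=` attribute).  The TSS is derived from the strand rule:
#' `start` for `+` genes, `end - 1` for `-` genes.
#'
#' @param path path to the gene table.
#' @param chrom_lengths named numeric vector of chromosome lengths, or the
#'   path to a two-column (chrom, length) TSV sidecar.
#' @return a [genome_annotation()] object.
#' @export
read_gene_table <- function(path, chrom_lengths) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(chrom_lengths) && length(chrom_lengths) == 1 &&
      file.exists(chrom_lengths))
    chrom_lengths <- read_chrom_lengths(chrom_lengths)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gf <- read.table(path, sep = "\t", comment.char = "#", quote = "",
                     stringsAsFactors = FALSE)
    gf <- gf[gf[[3]] == "gene", , drop = FALSE]
    id <- sub(".*ID=([^;]+).*", "\\1", gf[[9]])
    genes <- data.frame(chrom = gf[[1]], start = gf[[4]] - 1, end = gf[[5]],
                        strand = gf[[7]], id = id, stringsAsFactors = FALSE)
  } else {
    genes <- read.table(path, sep = "\t", header = TRUE, quote = "",
                        stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand", "id")
    if (!all(need %in% names(genes)))
      stop("gene table must have columns: ", paste(need, collapse = ", "))
    genes <- genes[need]
  }
  genome_annotation(genes, chrom_lengths)
}

#' Read a chromosome-length sidecar (chrom, length TSV with header)
#' @param path path to the TSV.
#' @return named numeric vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  tb <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(as.numeric(tb[[2]]), tb[[1]])
}

#' Read per-gene expression contrasts
#'
#' TSV with header columns `gene`, `log2fc`, `p`, `contrast`
#' (contrast in `KD`, `OE`).
#'
#' @param path path to the expression TSV.
#' @return data.frame with those four columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "p", "contrast")
  if (!all(need %in% names(tb)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  if (!all(tb$contrast %in% c("KD", "OE")))
    stop("contrast must be 'KD' or 'OE'")
  tb[need]
}

## tab-separated writer with header, fixed formatting for byte-stable reruns
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
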