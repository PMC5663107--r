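# Genome build representation, fixed-width window partition, and
# variant -> window coordinate arithmetic.
#
# Conventions: all coordinates are 1-based and inclusive at both ends.
# BED-format inputs (0-based half-open) are converted on read by
# rtracklayer, so everything downstream of the readers is 1-based.

#' Create a genome build
#'
#' A genome build is an ordered set of chromosomes with lengths. It is the
#' substrate for the fixed-width window partition on which all annotation
#' and scoring operates.
#'
#' @param name build name (e.g. `"toy"`).
#' @param chromosomes named integer vector of chromosome lengths in bp;
#'   names are chromosome names, order is preserved.
#' @return an object of class `genome_build`.
#' @examples
#' genome_build("toy", c(chr1 = 1e6, chr2 = 1e6))
#' @export
genome_build <- function(name, chromosomes) {
  if (length(chromosomes) == 0) stop("no chromosomes")
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("chromosomes must be a named vector")
  if (anyDuplicated(names(chromosomes)))
    stop("chromosome names must be unique")
  lens <- as.numeric(chromosomes)
  if (any(!is.finite(lens)) || any(lens < 1))
    stop("chromosome lengths must be >= 1")
  structure(
    list(name = name, chrom = names(chromosomes), length = floor(lens)),
    class = "genome_build"
  )
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("genome build '%s': %d chromosome(s), %s bp total\n",
              x$name, length(x$chrom),
              format(sum(x$length), big.mark = ",")))
  invisible(x)
}

#' Read a genome build from a chrom-sizes file
#'
#' @param path two-column tab-delimited file: chromosome name, length in bp.
#' @param name build name to attach; defaults to the file name.
#' @return a `genome_build`.
#' @export
read_chrom_sizes <- function(path, name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) == 0) stop("no chromosomes")
  genome_build(name, stats::setNames(df$length, df$chrom))
}

chrom_length <- function(build, chrom) {
  i <- match(chrom, build$chrom)
  if (anyNA(i)) stop(sprintf("unknown chromosome '%s' in build '%s'",
                             chrom[which(is.na(i))[1]], build$name))
  build$length[i]
}

build_seqinfo <- function(build) {
  GenomeInfoDb::Seqinfo(seqnames = build$chrom,
                        seqlengths = build$length,
                        genome = build$name)
}

#' Partition a genome into consecutive fixed-width windows
#'
#' Each chromosome is tiled by consecutive non-overlapping windows of
#' `window_size` bp; the final window of a chromosome is truncated at the
#' chromosome end (never dropped), so every base belongs to exactly one
#' window. Window indices are 0-based within each chromosome; window `i`
#' starts at base `i * window_size + 1`.
#'
#' @param build a [genome_build()].
#' @param window_size window width in bp (default 200).
#' @return an object of class `window_partition` with elements
#'   `build`, `window_size`, `windows` (data.frame chrom/index/start/end),
#'   `gr` (the windows as a `GRanges`), `n_windows` (per chromosome) and
#'   `offsets` (0-based global row offset of each chromosome's first window).
#' @export
partition_genome <- function(build, window_size = 200) {
  stopifnot(inherits(build, "genome_build"))
  if (length(build$chrom) == 0) stop("no chromosomes")
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1) stop("window_size must be >= 1")

  si <- build_seqinfo(build)
  gr <- GenomicRanges::tileGenome(si, tilewidth = window_size,
                                  cut.last.tile.in.chrom = TRUE)
  # tileGenome emits tiles chromosome by chromosome in seqinfo order
  nwin <- ceiling(build$length / window_size)
  names(nwin) <- build$chrom
  idx <- unlist(lapply(nwin, function(n) seq_len(n) - 1L), use.names = FALSE)
  windows <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    index = idx,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  offsets <- c(0, cumsum(nwin))[seq_along(nwin)]
  names(offsets) <- build$chrom
  structure(
    list(build = build, window_size = window_size, windows = windows,
         gr = gr, n_windows = nwin, offsets = offsets),
    class = "window_partition"
  )
}

total_windows <- function(partition) sum(partition$n_windows)

#' @export
print.window_partition <- function(x, ...) {
  cat(sprintf("window partition of '%s': %d windows of %d bp over %d chromosome(s)\n",
              x$build$name, total_windows(x), x$window_size,
              length(x$build$chrom)))
  invisible(x)
}

#' Map a genomic position to its window index
#'
#' @param pos 1-based position(s) in bp.
#' @param window_size window width in bp.
#' @param chrom_len optional chromosome length; when given, positions
#'   outside `[1, chrom_len]` raise an error.
#' @return 0-based window index (integer vector).
#' @examples
#' variant_to_window(c(1, 200, 201), 200)  # 0 0 1
#' @export
variant_to_window <- function(pos, window_size, chrom_len = NULL) {
  pos <- as.numeric(pos)
  if (any(pos < 1)) stop("out of bounds")
  if (!is.null(chrom_len) && any(pos > chrom_len)) stop("out of bounds")
  as.integer((pos - 1) %/% window_size)
}

# Global (1-based) row index of the window hosting each (chrom, pos), in the
# row order of the partition's annotation matrix. NA for out-of-bounds input.
global_window_row <- function(partition, chrom, pos) {
  i <- match(chrom, partition$build$chrom)
  len <- partition$build$length[i]
  ok <- !is.na(i) & pos >= 1 & pos <= len
  out <- rep(NA_integer_, length(pos))
  out[ok] <- as.integer(partition$offsets[chrom[ok]] +
                          (pos[ok] - 1) %/% partition$window_size + 1)
  out
}

#' Read genomic intervals from BED / bedGraph / wiggle
#'
#' Thin wrapper around [rtracklayer::import()]; 0-based half-open BED
#' coordinates are converted to the package's 1-based inclusive convention.
#'
#' @param path file path; format inferred from the extension.
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present in the input, `score` and `strand`.
#' @export
read_intervals <- function(path) {
  gr <- rtracklayer::import(path)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$score)) df$score <- as.numeric(gr$score)
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands != "*")) df$strand <- strands
  df
}

# Intervals -> GRanges on the build's seqinfo; rows on unknown chromosomes
# are dropped and counted, ranges are clipped to chromosome ends.
intervals_to_gr <- function(df, build) {
  known <- df$chrom %in% build$chrom
  n_skipped <- sum(!known)
  df <- df[known, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = build$chrom),
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    seqinfo = build_seqinfo(build)
  )
  if (!is.null(df$score)) gr$score <- df$score
  out_of_range <- GenomicRanges::start(gr) > chrom_length(build, as.character(GenomicRanges::seqnames(gr))) |
    GenomicRanges::end(gr) < 1
  n_skipped <- n_skipped + sum(out_of_range)
  gr <- suppressWarnings(GenomicRanges::trim(gr[!out_of_range]))
  attr(gr, "n_skipped") <- n_skipped
  gr
}
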