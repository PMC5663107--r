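# Genome-wide annotation matrix: fixed-width windows as rows, epigenomic
# and genomic features as columns. Variants are annotated through the
# window that contains them.
#
# Feature kinds:
#   count  — reads per window from a sequencing assay (DNase-seq,
#            FAIRE-seq, ChIP-seq ...), optionally adjusted for a matched
#            control track
#   binary — presence/absence of an element class (repeats, conserved
#            elements) overlapping the window
#   score  — per-window mean of a per-base score in [0,1] (e.g. phastCons)

#' Create a feature track
#'
#' A per-window numeric vector aligned to a window partition, tagged with
#' the feature's kind. Count tracks may carry a matched control vector;
#' library sizes default to the vector sums.
#'
#' @param feature_id unique feature name.
#' @param kind `"count"`, `"binary"` or `"score"`.
#' @param values per-window numeric vector (length = total window count of
#'   the partition it belongs to).
#' @param control_values optional per-window control counts (count kind).
#' @param library_size,control_library_size optional library sizes; default
#'   to `sum(values)` / `sum(control_values)`.
#' @return object of class `feature_track`.
#' @export
feature_track <- function(feature_id, kind = c("count", "binary", "score"),
                          values, control_values = NULL,
                          library_size = NULL,
                          control_library_size = NULL) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind == "binary" && !all(values %in% c(0, 1)))
    stop("binary track values must be 0/1")
  if (kind == "count" && any(values < 0))
    stop("count track values must be >= 0")
  if (!is.null(control_values)) {
    if (kind != "count") stop("control tracks only apply to count features")
    control_values <- as.numeric(control_values)
    if (length(control_values) != length(values))
      stop("control vector length mismatch")
  }
  structure(
    list(feature_id = feature_id, kind = kind, values = values,
         control_values = control_values,
         library_size = library_size %||%
           (if (kind == "count") sum(values) else NULL),
         control_library_size = control_library_size %||%
           (if (!is.null(control_values)) sum(control_values) else NULL)),
    class = "feature_track"
  )
}

#' Count reads per window
#'
#' Each read/fragment interval is assigned to the single window containing
#' its midpoint, so no read is counted twice and window counts sum to the
#' number of in-bounds reads. Reads on unknown chromosomes or with
#' midpoints off the chromosome are skipped and their count logged.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [read_intervals()].
#' @param partition a [partition_genome()] result.
#' @return integer vector of per-window counts (global window order).
#' @export
count_reads_per_window <- function(intervals, partition) {
  build <- partition$build
  mid <- (intervals$start + intervals$end) %/% 2
  known <- intervals$chrom %in% build$chrom
  len <- rep(NA_real_, nrow(intervals))
  len[known] <- chrom_length(build, intervals$chrom[known])
  ok <- known & mid >= 1 & mid <= len
  if (any(!ok))
    ds_log("count_reads_per_window: skipped %d read(s) outside the build",
           sum(!ok))
  row <- global_window_row(partition, intervals$chrom[ok], mid[ok])
  tabulate(row, nbins = total_windows(partition))
}

#' Adjust counts for a control track
#'
#' Library-size-scaled subtraction floored at zero:
#' `max(0, values - (library_size / control_library_size) * control)`.
#'
#' @param track a count [feature_track()] with `control_values`.
#' @return numeric vector of adjusted per-window values.
#' @export
adjust_for_control <- function(track) {
  stopifnot(inherits(track, "feature_track"))
  if (track$kind != "count") stop("control adjustment applies to count tracks")
  if (is.null(track$control_values)) stop("track has no control_values")
  if (length(track$control_values) != length(track$values))
    stop("control vector length mismatch")
  scale <- track$library_size / track$control_library_size
  pmax(0, track$values - scale * track$control_values)
}

#' Binarize element presence per window
#'
#' @param elements data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive); any overlap of at least 1 bp marks the window.
#' @param partition a [partition_genome()] result.
#' @return 0/1 integer vector per window.
#' @export
binarize_elements <- function(elements, partition) {
  if (is.null(elements) || nrow(elements) == 0)
    return(integer(total_windows(partition)))
  gr <- suppressWarnings(intervals_to_gr(elements, partition$build))
  as.integer(IRanges::overlapsAny(partition$gr, gr))
}

#' Per-window mean of a per-base score
#'
#' Mean over all bases of the window; bases not covered by any score
#' interval contribute 0. A track covering a window entirely at constant
#' `c` therefore yields exactly `c`.
#'
#' @param scores data.frame with `chrom`, `start`, `end`, `score`
#'   (bedGraph-style, 1-based inclusive after [read_intervals()]).
#' @param partition a [partition_genome()] result.
#' @return numeric vector of per-window means.
#' @export
window_conservation <- function(scores, partition) {
  nw <- total_windows(partition)
  out <- numeric(nw)
  if (is.null(scores) || nrow(scores) == 0) return(out)
  gr <- suppressWarnings(intervals_to_gr(scores, partition$build))
  ov <- GenomicRanges::findOverlaps(partition$gr, gr)
  if (length(ov) > 0) {
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(partition$gr)[q], GenomicRanges::ranges(gr)[s]))
    contrib <- w * gr$score[s]
    sums <- rowsum(contrib, q)
    out[as.integer(rownames(sums))] <- sums[, 1]
  }
  out / GenomicRanges::width(partition$gr)
}

#' Assemble the annotation matrix
#'
#' Binds feature tracks into the windows-by-features matrix. Count tracks
#' with a control are control-adjusted; column order follows the input
#' track order and is persisted with the matrix.
#'
#' @param tracks list of [feature_track()] objects aligned to `partition`.
#' @param partition a [partition_genome()] result.
#' @return object of class `annotation_matrix`: `partition`, `features`
#'   (data.frame feature_id/kind) and `matrix`.
#' @export
assemble_matrix <- function(tracks, partition) {
  ids <- vapply(tracks, function(t) t$feature_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate feature_id '%s'", ids[duplicated(ids)][1]))
  nw <- total_windows(partition)
  cols <- lapply(tracks, function(t) {
    if (length(t$values) != nw)
      stop(sprintf("track '%s' not aligned to the partition (%d values, %d windows)",
                   t$feature_id, length(t$values), nw))
    if (t$kind == "count" && !is.null(t$control_values))
      adjust_for_control(t) else t$values
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- ids
  structure(
    list(partition = partition,
         features = data.frame(feature_id = ids,
                               kind = vapply(tracks, function(t) t$kind,
                                             character(1)),
                               stringsAsFactors = FALSE),
         matrix = mat),
    class = "annotation_matrix"
  )
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("annotation matrix: %d windows x %d features (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%d %s", table(x$features$kind),
                            names(table(x$features$kind))),
                    collapse = ", ")))
  invisible(x)
}

#' Annotate variants with their window's feature vector
#'
#' Every variant inherits the full feature row of the window it falls
#' into; variants outside the build are skipped and logged.
#'
#' @param variants `variant_catalog` (or data.frame with `id`, `chrom`,
#'   `pos`).
#' @param am an [assemble_matrix()] result.
#' @return numeric matrix, one row per in-bounds variant (rownames = ids),
#'   with attribute `skipped` holding ids of out-of-bounds variants.
#' @export
annotate_variants <- function(variants, am) {
  stopifnot(inherits(am, "annotation_matrix"))
  row <- global_window_row(am$partition, variants$chrom, variants$pos)
  ok <- !is.na(row)
  if (any(!ok))
    ds_log("annotate_variants: skipped %d out-of-bounds variant(s)", sum(!ok))
  out <- am$matrix[row[ok], , drop = FALSE]
  rownames(out) <- variants$id[ok]
  attr(out, "skipped") <- variants$id[!ok]
  out
}

#' Persist / load an annotation matrix
#'
#' Gzipped tab-delimited matrix with a feature-id header row, plus a
#' sidecar `<path>.partition` descriptor (build name, chromosome sizes,
#' window size, feature kinds).
#'
#' @param am an `annotation_matrix`.
#' @param path output path (a `.tsv.gz` is written).
#' @return `path`, invisibly.
#' @export
write_annotation_matrix <- function(am, path) {
  con <- gzfile(path, "w")
  utils::write.table(am$matrix, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  close(con)
  side <- paste0(path, ".partition")
  writeLines(c(
    sprintf("build\t%s", am$partition$build$name),
    sprintf("window_size\t%d", am$partition$window_size),
    sprintf("chrom\t%s\t%d", am$partition$build$chrom,
            am$partition$build$length),
    sprintf("feature\t%s\t%s", am$features$feature_id, am$features$kind)
  ), side)
  invisible(path)
}

#' @rdname write_annotation_matrix
#' @export
read_annotation_matrix <- function(path) {
  side <- readLines(paste0(path, ".partition"))
  fields <- strsplit(side, "\t", fixed = TRUE)
  tag <- vapply(fields, `[`, character(1), 1)
  build <- genome_build(
    fields[[which(tag == "build")]][2],
    stats::setNames(
      as.numeric(vapply(fields[tag == "chrom"], `[`, character(1), 3)),
      vapply(fields[tag == "chrom"], `[`, character(1), 2))
  )
  wsize <- as.integer(fields[[which(tag == "window_size")]][2])
  partition <- partition_genome(build, wsize)
  mat <- as.matrix(utils::read.table(gzfile(path), sep = "\t", header = TRUE,
                                     check.names = FALSE))
  kinds <- vapply(fields[tag == "feature"], `[`, character(1), 3)
  ids <- vapply(fields[tag == "feature"], `[`, character(1), 2)
  structure(
    list(partition = partition,
         features = data.frame(feature_id = ids, kind = kinds,
                               stringsAsFactors = FALSE),
         matrix = mat),
    class = "annotation_matrix"
  )
}
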