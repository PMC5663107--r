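# Genome-wide D-score track: one value per window, every base inheriting
# its window's score; empirical score distribution for genome-wide
# percentiles; and the three query modes (by identifier, by region, and
# region averages), each with its fixed tab-delimited output layout.

#' Create a score track
#'
#' @param build a [genome_build()].
#' @param window_size window width in bp.
#' @param disease trait label of the model that produced the scores.
#' @param scores named list (one element per chromosome, in build order)
#'   of per-window score vectors in `[0, 1]`; values are quantized to 4
#'   decimals.
#' @return object of class `score_track`.
#' @export
score_track <- function(build, window_size, disease, scores) {
  stopifnot(inherits(build, "genome_build"))
  nwin <- ceiling(build$length / window_size)
  if (!identical(names(scores), build$chrom))
    stop("scores must be named by the build's chromosomes, in order")
  for (i in seq_along(scores)) {
    if (length(scores[[i]]) != nwin[i])
      stop(sprintf("chromosome '%s': %d scores for %d windows",
                   build$chrom[i], length(scores[[i]]), nwin[i]))
    if (any(scores[[i]] < 0 | scores[[i]] > 1))
      stop("scores must lie in [0, 1]")
  }
  structure(
    list(build = build, window_size = as.integer(window_size),
         disease = disease, scores = lapply(scores, quantize_score)),
    class = "score_track"
  )
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("score track '%s' on build '%s': %d windows of %d bp\n",
              x$disease, x$build$name,
              sum(lengths(x$scores)), x$window_size))
  invisible(x)
}

track_magic <- "#dscoretrack"
track_version <- 1L

#' Write / read a score track archive
#'
#' Gzipped text container: magic + version header, build name, window
#' size, disease label, then one block of 4-decimal scores per chromosome
#' and a terminating `#end` marker. Quantized values round-trip
#' bit-exactly; a missing terminator or a bad magic raises an error and no
#' partial track is returned.
#'
#' @param track a `score_track`.
#' @param path archive path (gzip-compressed text).
#' @return `path` (write) / the `score_track` (read).
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "score_track"))
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste(track_magic, track_version, sep = "\t"),
    paste("#build", track$build$name, sep = "\t"),
    paste("#window_size", track$window_size, sep = "\t"),
    paste("#disease", track$disease, sep = "\t")
  ), con)
  for (ch in track$build$chrom) {
    writeLines(sprintf("#chrom\t%s\t%d\t%d", ch,
                       chrom_length(track$build, ch),
                       length(track$scores[[ch]])), con)
    writeLines(sprintf("%.4f", track$scores[[ch]]), con)
  }
  writeLines("#end", con)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  lines <- readLines(gzfile(path))
  if (length(lines) == 0 || !startsWith(lines[1], paste0(track_magic, "\t")))
    stop("incompatible track file")
  ver <- as.integer(strsplit(lines[1], "\t")[[1]][2])
  if (is.na(ver) || ver != track_version) stop("incompatible track file")
  if (lines[length(lines)] != "#end")
    stop("truncated track file")
  get_tag <- function(tag) {
    l <- lines[startsWith(lines, paste0("#", tag, "\t"))]
    strsplit(l, "\t", fixed = TRUE)
  }
  wsize <- as.integer(get_tag("window_size")[[1]][2])
  disease <- get_tag("disease")[[1]][2]
  bname <- get_tag("build")[[1]][2]
  chrom_lines <- which(startsWith(lines, "#chrom\t"))
  if (length(chrom_lines) == 0) stop("incompatible track file")
  chroms <- character(0); lens <- numeric(0); scores <- list()
  bounds <- c(chrom_lines, length(lines))  # '#end' line
  for (i in seq_along(chrom_lines)) {
    hdr <- strsplit(lines[chrom_lines[i]], "\t", fixed = TRUE)[[1]]
    ch <- hdr[2]; len <- as.numeric(hdr[3]); nw <- as.integer(hdr[4])
    block <- lines[(chrom_lines[i] + 1):(bounds[i + 1] - 1)]
    if (length(block) != nw) stop("truncated track file")
    chroms <- c(chroms, ch); lens <- c(lens, len)
    scores[[ch]] <- as.numeric(block)
  }
  build <- genome_build(bname, stats::setNames(lens, chroms))
  score_track(build, wsize, disease, scores)
}

#' Export a track as bedGraph
#'
#' One line per window (0-based half-open, as bedGraph requires) for
#' genome-browser use; re-importing with [import_track_bedgraph()]
#' reproduces the track exactly.
#'
#' @param track a `score_track`.
#' @param path output `.bedGraph` path.
#' @export
export_track_bedgraph <- function(track, path) {
  part <- partition_genome(track$build, track$window_size)
  gr <- part$gr
  gr$score <- unlist(track$scores[track$build$chrom], use.names = FALSE)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname export_track_bedgraph
#' @param build,window_size,disease track metadata (bedGraph carries none).
#' @export
import_track_bedgraph <- function(path, build, window_size,
                                  disease = "trait") {
  df <- read_intervals(path)
  part <- partition_genome(build, window_size)
  vals <- numeric(total_windows(part))
  row <- global_window_row(part, df$chrom, df$start)
  vals[row] <- df$score
  per_chrom <- split(vals, rep(build$chrom, part$n_windows))
  score_track(build, window_size, disease, per_chrom[build$chrom])
}

#' D-score of a single base
#'
#' @param track a `score_track`.
#' @param chrom,pos 1-based genomic position.
#' @return the host window's score.
#' @export
base_score <- function(track, chrom, pos) {
  len <- chrom_length(track$build, chrom)
  if (any(pos < 1 | pos > len)) stop("out of bounds")
  track$scores[[chrom]][(pos - 1) %/% track$window_size + 1]
}

#' Empirical genome-wide score distribution
#'
#' Histogram of base-level scores with fixed bin width 1e-4 on `[0, 1]`;
#' each window contributes its width in bases to the bin of its (already
#' 4-decimal-quantized) score, so counts sum exactly to the genome length.
#'
#' @param track a `score_track`.
#' @return object of class `score_distribution` with `counts` (length
#'   10001, bin k = score k/10000) and `total`.
#' @export
build_distribution <- function(track) {
  stopifnot(inherits(track, "score_track"))
  counts <- numeric(10001)
  for (ch in track$build$chrom) {
    s <- track$scores[[ch]]
    len <- chrom_length(track$build, ch)
    w <- rep(track$window_size, length(s))
    w[length(w)] <- len - (length(s) - 1) * track$window_size
    k <- as.integer(round(s * 1e4)) + 1L
    agg <- rowsum(w, k)
    counts[as.integer(rownames(agg))] <- counts[as.integer(rownames(agg))] +
      agg[, 1]
  }
  structure(list(counts = counts, total = sum(track$build$length)),
            class = "score_distribution")
}

#' Genome-wide percentile of a score
#'
#' `100 * (number of bases with score <= s) / genome length`, under the
#' track's empirical distribution; non-decreasing in `s`, and 100 at the
#' track maximum.
#'
#' @param dist a [build_distribution()] result.
#' @param s score(s) in `[0, 1]`.
#' @return percentile(s) in `[0, 100]`.
#' @export
percentile <- function(dist, s) {
  stopifnot(inherits(dist, "score_distribution"))
  cum <- cumsum(dist$counts)
  k <- pmin(pmax(floor(s * 1e4 + 1e-9), -1), 10000)
  out <- numeric(length(s))
  pos <- k >= 0
  out[pos] <- 100 * cum[k[pos] + 1] / dist$total
  out
}

read_id_file <- function(path) {
  ids <- readLines(path)
  trimws(ids[nzchar(trimws(ids))])
}

read_region_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 3
  parsed <- lapply(fields[ok], function(f) {
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 1 || e < s) NULL
    else data.frame(chrom = f[1], start = s, end = e,
                    stringsAsFactors = FALSE)
  })
  bad <- sum(!ok) + sum(vapply(parsed, is.null, logical(1)))
  if (bad > 0)
    ds_warn("read_region_file: skipped %d malformed region line(s)", bad)
  out <- do.call(rbind, parsed[!vapply(parsed, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(chrom = character(0),
                                      start = numeric(0), end = numeric(0))
  out
}

#' Query D-scores by variant identifier
#'
#' One output row per matched identifier, in input order: variant
#' identifier, D-score, chromosome, position, genome-wide D-score
#' percentile. Unmatched identifiers are logged and omitted.
#'
#' @param ids character vector of identifiers (or use [read_id_file()]).
#' @param track a `score_track`.
#' @param dist the track's [build_distribution()].
#' @param catalog identifier -> position `variant_catalog`.
#' @return data.frame with columns `id`, `dscore`, `chrom`, `pos`,
#'   `percentile`.
#' @export
query_by_id <- function(ids, track, dist, catalog) {
  lk <- lookup_ids(ids, catalog)
  if (length(lk$unmatched) > 0)
    ds_warn("query_by_id: %d unmatched identifier(s): %s",
            length(lk$unmatched),
            paste(utils::head(lk$unmatched, 5), collapse = ", "))
  m <- lk$matched
  in_bounds <- m$chrom %in% track$build$chrom &
    m$pos >= 1 & m$pos <= chrom_length_safe(track$build, m$chrom)
  if (any(!in_bounds))
    ds_warn("query_by_id: %d variant(s) outside the scored build",
            sum(!in_bounds))
  m <- m[in_bounds, , drop = FALSE]
  sc <- vapply(seq_len(nrow(m)), function(i)
    base_score(track, m$chrom[i], m$pos[i]), numeric(1))
  data.frame(id = m$id, dscore = sc, chrom = m$chrom, pos = m$pos,
             percentile = round(percentile(dist, sc), 2),
             stringsAsFactors = FALSE)
}

chrom_length_safe <- function(build, chrom) {
  i <- match(chrom, build$chrom)
  ifelse(is.na(i), -1, build$length[i])
}

#' Query known variants inside genomic regions
#'
#' For each region (in input order), reports every catalog variant with
#' `start <= pos <= end`, ascending by position: chromosome, region start,
#' region end, variant identifier, variant position, D-score, percentile.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive; or use [read_region_file()]).
#' @inheritParams query_by_id
#' @return data.frame with columns `chrom`, `start`, `end`, `id`, `pos`,
#'   `dscore`, `percentile`.
#' @export
query_by_region <- function(regions, track, dist, catalog) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    hit <- catalog$chrom == r$chrom & catalog$pos >= r$start &
      catalog$pos <= r$end &
      catalog$pos <= chrom_length_safe(track$build, catalog$chrom)
    v <- catalog[hit, , drop = FALSE]
    if (nrow(v) == 0) return(NULL)
    v <- v[order(v$pos), , drop = FALSE]
    sc <- base_score(track, r$chrom, v$pos)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               id = v$id, pos = v$pos, dscore = sc,
               percentile = round(percentile(dist, sc), 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), id = character(0),
                      pos = numeric(0), dscore = numeric(0),
                      percentile = numeric(0))
  rownames(out) <- NULL
  out
}

#' Average D-score of genomic regions
#'
#' Mean and standard deviation of the per-base D-scores of each region
#' (window scores weighted by their overlap width; population SD, the
#' region being the whole population of interest), plus the genome-wide
#' percentile of the mean. Regions off the build are skipped and logged.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param track a `score_track`.
#' @param dist the track's [build_distribution()].
#' @return data.frame with columns `chrom`, `start`, `end`, `mean_dscore`,
#'   `mean_percentile`, `sd_dscore`.
#' @export
region_average <- function(regions, track, dist) {
  w <- track$window_size
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    len <- chrom_length_safe(track$build, r$chrom)
    if (len < 0 || r$start > len) {
      ds_warn("region_average: skipped region %s:%s-%s (off chromosome)",
              r$chrom, format(r$start, scientific = FALSE),
              format(r$end, scientific = FALSE))
      return(NULL)
    }
    end <- min(r$end, len)
    i1 <- (r$start - 1) %/% w; i2 <- (end - 1) %/% w
    idx <- i1:i2
    ov_start <- pmax(idx * w + 1, r$start)
    ov_end <- pmin((idx + 1) * w, end)
    wts <- ov_end - ov_start + 1
    s <- track$scores[[r$chrom]][idx + 1]
    n <- sum(wts)
    mu <- sum(wts * s) / n
    sdv <- sqrt(max(0, sum(wts * s^2) / n - mu^2))
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               mean_dscore = mu,
               mean_percentile = round(percentile(dist, mu), 2),
               sd_dscore = sdv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_dscore = numeric(0),
                      mean_percentile = numeric(0), sd_dscore = numeric(0))
  rownames(out) <- NULL
  out
}

#' Write a query result table
#'
#' Tab-delimited, in the query's fixed column order; no header unless
#' `header = TRUE`. D-scores are printed with 4 decimals, percentiles
#' with 2.
#'
#' @param rows a result of [query_by_id()], [query_by_region()] or
#'   [region_average()].
#' @param path output path.
#' @param header write a header line (default `FALSE`).
#' @export
write_query_result <- function(rows, path, header = FALSE) {
  fmt <- rows
  for (col in intersect(c("dscore", "mean_dscore", "sd_dscore"),
                        names(fmt)))
    fmt[[col]] <- sprintf("%.4f", fmt[[col]])
  for (col in intersect(c("percentile", "mean_percentile"), names(fmt)))
    fmt[[col]] <- sprintf("%.2f", fmt[[col]])
  for (col in intersect(c("start", "end", "pos"), names(fmt)))
    fmt[[col]] <- format(fmt[[col]], scientific = FALSE, trim = TRUE)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}
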