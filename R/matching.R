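# Negative (benign) training-set construction matched to the positive
# (risk) set, at a configurable ratio (default 10 negatives per positive).
#
# Two alternative matching strategies:
#   tss_matched    — negatives drawn so their distance-to-TSS distribution
#                    matches the positives', bin by bin
#   region_matched — negatives restricted to lie within max_dist (default
#                    10 kb) of at least one positive

#' TSS annotation
#'
#' @param chrom,pos parallel vectors giving transcription start sites
#'   (1-based bp).
#' @return object of class `tss_annotation`.
#' @export
tss_annotation <- function(chrom, pos) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty TSS annotation")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(sites = df), class = "tss_annotation")
}

#' Read a TSS annotation
#'
#' Accepts BED (for 6-column BED the site is the first transcribed base:
#' interval start on `+`, interval end on `-`) or a two-column
#' chrom<TAB>position table.
#'
#' @param path file path; `*.bed` is parsed as BED, anything else as the
#'   two-column table.
#' @return a `tss_annotation`.
#' @export
read_tss <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path)) {
    df <- read_intervals(path)
    site <- if (!is.null(df$strand)) {
      ifelse(df$strand == "-", df$end, df$start)
    } else df$start
    tss_annotation(df$chrom, site)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "pos"),
                            colClasses = c("character", "numeric"))
    tss_annotation(df$chrom, df$pos)
  }
}

#' Distance to the nearest transcription start site
#'
#' Unsigned distance in bp from each variant to the nearest TSS on the same
#' chromosome.
#'
#' @param variants a `variant_catalog` (or data.frame with `chrom`, `pos`).
#' @param tss a [tss_annotation()].
#' @return non-negative integer vector, one distance per variant.
#' @export
tss_distance <- function(variants, tss) {
  stopifnot(inherits(tss, "tss_annotation"))
  out <- rep(NA_real_, nrow(variants))
  for (ch in unique(variants$chrom)) {
    sites <- tss$sites$pos[tss$sites$chrom == ch]
    vi <- which(variants$chrom == ch)
    if (length(sites) == 0)
      stop(sprintf("no TSS on chromosome '%s'", ch))
    p <- variants$pos[vi]
    # nearest of the flanking sites in the sorted list
    j <- findInterval(p, sites)
    d_left <- ifelse(j >= 1, p - sites[pmax(j, 1)], Inf)
    d_right <- ifelse(j < length(sites), sites[pmin(j + 1, length(sites))] - p, Inf)
    out[vi] <- pmin(abs(d_left), abs(d_right))
  }
  as.integer(out)
}

#' Default distance-bin edges for TSS matching
#'
#' Log10-spaced edges on `1 + distance`, reflecting the heavy right tail of
#' TSS distances: `{0, 10^2, 10^2.5, ..., 10^6, Inf}`.
#'
#' @return numeric vector of bin edges.
#' @export
default_tss_bins <- function() {
  c(0, 10^seq(2, 6, by = 0.5), Inf)
}

new_matched_sets <- function(positives, negatives, strategy, ratio, seed,
                             report) {
  structure(
    list(positives = positives, negatives = negatives,
         strategy = strategy, ratio = ratio, seed = seed,
         report = report),
    class = "matched_sets"
  )
}

#' @export
print.matched_sets <- function(x, ...) {
  cat(sprintf("matched sets [%s]: %d positives, %d negatives (ratio %d, seed %d)\n",
              x$strategy, nrow(x$positives), nrow(x$negatives),
              x$ratio, x$seed))
  invisible(x)
}

#' TSS-distance-matched negative set
#'
#' Samples benign candidates so that, within each TSS-distance bin, the
#' number of negatives is `ratio` times the number of positives in that
#' bin (uniform sampling without replacement within the bin). When a bin
#' holds too few candidates the shortfall is borrowed from the nearest
#' non-exhausted bin, and every borrow is recorded in the bin report, so
#' the total is always exactly `ratio * n_positives` whenever the candidate
#' pool suffices.
#'
#' @param positives risk variants (`variant_catalog`).
#' @param candidates benign candidates (`variant_catalog`), disjoint from
#'   `positives`.
#' @param tss a [tss_annotation()].
#' @param ratio negatives per positive (default 10).
#' @param bins distance-bin edges applied to `1 + distance`
#'   (default [default_tss_bins()]).
#' @param seed RNG seed for the sampler (default 17).
#' @return a `matched_sets` object; `$report` is the per-bin table
#'   (positives, required, available, sampled, borrowed).
#' @export
match_negatives_tss <- function(positives, candidates, tss, ratio = 10,
                                bins = default_tss_bins(), seed = 17) {
  if (ratio < 1) stop("ratio must be >= 1")
  overlap <- intersect(positives$id, candidates$id)
  if (length(overlap) > 0)
    stop(sprintf("candidates must be disjoint from positives ('%s' in both)",
                 overlap[1]))
  need_total <- ratio * nrow(positives)
  if (nrow(candidates) < need_total)
    stop(sprintf("insufficient candidates: need %d, have %d (deficit %d)",
                 need_total, nrow(candidates),
                 need_total - nrow(candidates)))

  d_pos <- tss_distance(positives, tss)
  d_cand <- tss_distance(candidates, tss)
  nb <- length(bins) - 1
  bin_pos <- cut(1 + d_pos, breaks = bins, labels = FALSE,
                 include.lowest = TRUE)
  bin_cand <- cut(1 + d_cand, breaks = bins, labels = FALSE,
                  include.lowest = TRUE)

  n_pos_bin <- tabulate(bin_pos, nbins = nb)
  required <- ratio * n_pos_bin
  avail_idx <- split(seq_len(nrow(candidates)), factor(bin_cand, levels = 1:nb))

  # canonical candidate order so selection depends on seed, not input order
  ord <- order(candidates$chrom, candidates$pos, candidates$id)
  rank_of <- integer(nrow(candidates))
  rank_of[ord] <- seq_along(ord)

  selected <- integer(0)
  sampled <- integer(nb)
  borrowed <- integer(nb)
  withr::with_seed(seed, {
    remaining <- lapply(avail_idx, function(ix) ix[order(rank_of[ix])])
    take <- function(b, k) {
      pool <- remaining[[b]]
      k <- min(k, length(pool))
      if (k == 0) return(integer(0))
      pick <- if (length(pool) == 1 && k == 1) pool else sample(pool, k)
      remaining[[b]] <<- setdiff(pool, pick)
      pick
    }
    deficit <- integer(nb)
    for (b in seq_len(nb)) {
      got <- take(b, required[b])
      sampled[b] <- length(got)
      deficit[b] <- required[b] - length(got)
      selected <- c(selected, got)
    }
    for (b in which(deficit > 0)) {
      others <- order(abs(seq_len(nb) - b), seq_len(nb))
      for (o in setdiff(others, b)) {
        if (deficit[b] == 0) break
        got <- take(o, deficit[b])
        if (length(got) > 0) {
          ds_log("match_negatives_tss: bin %d short by %d; borrowed %d from bin %d",
                 b, deficit[b], length(got), o)
          borrowed[o] <- borrowed[o] + length(got)
          deficit[b] <- deficit[b] - length(got)
          selected <- c(selected, got)
        }
      }
    }
  })
  if (length(selected) < need_total)
    stop(sprintf("insufficient candidates: need %d, could place %d (deficit %d)",
                 need_total, length(selected), need_total - length(selected)))

  negatives <- candidates[sort(selected), , drop = FALSE]
  rownames(negatives) <- NULL
  report <- data.frame(
    bin = seq_len(nb),
    lower = bins[-length(bins)], upper = bins[-1],
    n_positives = n_pos_bin, required = required,
    available = lengths(avail_idx), sampled_in_bin = sampled,
    lent_to_other_bins = borrowed
  )
  new_matched_sets(positives, negatives, "tss_matched", ratio, seed, report)
}

#' Region-matched negative set
#'
#' Samples negatives uniformly without replacement from the candidates that
#' lie within `max_dist` bp of at least one positive on the same
#' chromosome. Delivers `ratio * n_positives` negatives, or the whole
#' eligible pool (with a warning) when it is smaller.
#'
#' @inheritParams match_negatives_tss
#' @param max_dist maximum distance to the nearest positive, bp
#'   (default 10000).
#' @return a `matched_sets` object; `$report` records pool size and any
#'   shortfall.
#' @export
match_negatives_region <- function(positives, candidates, max_dist = 10000,
                                   ratio = 10, seed = 17) {
  if (ratio < 1) stop("ratio must be >= 1")
  overlap <- intersect(positives$id, candidates$id)
  if (length(overlap) > 0)
    stop(sprintf("candidates must be disjoint from positives ('%s' in both)",
                 overlap[1]))
  dmin <- nearest_positive_distance(candidates, positives)
  eligible <- which(!is.na(dmin) & dmin <= max_dist)
  if (length(eligible) == 0)
    stop(sprintf("no candidate lies within %d bp of a positive", max_dist))

  need <- ratio * nrow(positives)
  n_take <- min(need, length(eligible))
  if (n_take < need)
    ds_warn("match_negatives_region: eligible pool (%d) smaller than required (%d); delivering %d",
            length(eligible), need, n_take)

  ord <- order(candidates$chrom[eligible], candidates$pos[eligible],
               candidates$id[eligible])
  eligible <- eligible[ord]
  pick <- withr::with_seed(seed, {
    if (length(eligible) == 1) eligible else sample(eligible, n_take)
  })
  negatives <- candidates[sort(pick), , drop = FALSE]
  rownames(negatives) <- NULL
  report <- data.frame(max_dist = max_dist, eligible = length(eligible),
                       required = need, delivered = n_take)
  new_matched_sets(positives, negatives, "region_matched", ratio, seed,
                   report)
}

# min distance from each query variant to the nearest positive on the same
# chromosome; NA when the chromosome has no positive
nearest_positive_distance <- function(queries, positives) {
  out <- rep(NA_real_, nrow(queries))
  for (ch in unique(queries$chrom)) {
    p <- sort(positives$pos[positives$chrom == ch])
    if (length(p) == 0) next
    qi <- which(queries$chrom == ch)
    q <- queries$pos[qi]
    j <- findInterval(q, p)
    d_left <- ifelse(j >= 1, q - p[pmax(j, 1)], Inf)
    d_right <- ifelse(j < length(p), p[pmin(j + 1, length(p))] - q, Inf)
    out[qi] <- pmin(abs(d_left), abs(d_right))
  }
  out
}

#' Serialize matched sets
#'
#' Writes `<prefix>.positives.tsv` and `<prefix>.negatives.tsv` in the
#' catalog format, each preceded by a provenance header (strategy, ratio,
#' seed, bin report).
#'
#' @param ms a `matched_sets` object.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_matched_sets <- function(ms, prefix) {
  stopifnot(inherits(ms, "matched_sets"))
  header <- c(
    sprintf("# strategy=%s ratio=%d seed=%d", ms$strategy, ms$ratio, ms$seed),
    paste0("# ", utils::capture.output(print(ms$report)))
  )
  paths <- paste0(prefix, c(".positives.tsv", ".negatives.tsv"))
  for (k in 1:2) {
    writeLines(header, paths[k])
    f <- file(paths[k], open = "a")
    cat_df <- as.data.frame(if (k == 1) ms$positives else ms$negatives)
    cat_df$maf <- ifelse(is.na(cat_df$maf), "", as.character(cat_df$maf))
    utils::write.table(cat_df[, c("id", "chrom", "pos", "maf", "traits")],
                       f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(f)
  }
  invisible(paths)
}
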