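# Feature-selection ensemble learner.
#
# Per-feature nonparametric two-sample tests (rank-sum for count/score
# features, Fisher's exact for binary features) measure how well each
# feature separates risk from benign variants; cross-validation selects
# the p-value threshold below which a feature is deemed informative. The
# classifier is an ensemble of balanced base learners: the 10x negatives
# are partitioned into disjoint folds the size of the positive set, one
# base classifier per fold, and the D-score of a variant is the average of
# the classifiers' probability votes — interpretable as the probability
# that the variant is disease/trait-associated.

#' Two-sample test for one feature
#'
#' Continuous kinds (`count`, `score`) use the two-sided Wilcoxon rank-sum
#' test; `binary` uses Fisher's exact test on the 2x2 presence table.
#' Identical degenerate groups return `p = 1` (no signal) rather than an
#' error.
#'
#' @param pos_values,neg_values feature values in the positive / negative
#'   group (non-empty numeric vectors).
#' @param kind `"count"`, `"score"` or `"binary"`.
#' @return list with `statistic`, `p_value`, `test_name`.
#' @export
test_feature <- function(pos_values, neg_values,
                         kind = c("count", "score", "binary")) {
  kind <- match.arg(kind)
  if (length(pos_values) == 0 || length(neg_values) == 0)
    stop("both groups must be non-empty")
  all_vals <- c(pos_values, neg_values)
  if (length(unique(all_vals)) == 1)
    return(list(statistic = NA_real_, p_value = 1,
                test_name = if (kind == "binary") "fisher" else "ranksum"))
  if (kind == "binary") {
    tab <- matrix(c(sum(pos_values == 1), sum(pos_values == 0),
                    sum(neg_values == 1), sum(neg_values == 0)),
                  nrow = 2)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    list(statistic = unname(ft$estimate), p_value = min(ft$p.value, 1),
         test_name = "fisher")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(pos_values, neg_values, alternative = "two.sided"))
    list(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
         test_name = "ranksum")
  }
}

# Per-feature tests over matched positive/negative annotation matrices.
feature_tests <- function(pos_mat, neg_mat, kinds) {
  stopifnot(ncol(pos_mat) == ncol(neg_mat), ncol(pos_mat) == length(kinds))
  res <- lapply(seq_len(ncol(pos_mat)), function(j)
    test_feature(pos_mat[, j], neg_mat[, j],
                 kind = if (kinds[j] == "binary") "binary" else "count"))
  data.frame(
    feature_id = colnames(pos_mat),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    test_name = vapply(res, `[[`, character(1), "test_name"),
    stringsAsFactors = FALSE
  )
}

# Rank-based AUC of scores for positives vs negatives (Mann-Whitney).
auc_rank <- function(score_pos, score_neg) {
  np <- length(score_pos); nn <- length(score_neg)
  r <- rank(c(score_pos, score_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Default p-value threshold grid
#'
#' `{1e-8, 1e-7, ..., 1e-2, 0.05, 0.1}`; candidate cutoffs for the
#' cross-validated feature-selection threshold.
#'
#' @return numeric vector, ascending.
#' @export
default_threshold_grid <- function() {
  c(10^seq(-8, -2), 0.05, 0.1)
}

#' Cross-validated selection of the feature p-value threshold
#'
#' For each candidate threshold, feature tests are computed within each
#' training fold only (no selection leakage); features with `p <=`
#' threshold feed a balanced ensemble whose held-out AUC is recorded. The
#' threshold maximizing mean held-out AUC wins, ties broken toward the
#' more stringent (smaller) threshold; a fold in which a threshold selects
#' zero features scores AUC 0.5 for that fold. Selected features are then
#' recomputed on the full training set at the winning threshold.
#'
#' @param pos_mat,neg_mat annotation-matrix rows of the positive /
#'   negative variants (columns = features, named).
#' @param kinds feature kinds aligned to the columns.
#' @param thresholds candidate p-value cutoffs
#'   (default [default_threshold_grid()]).
#' @param k number of folds (default 5).
#' @param seed RNG seed; folds and ensemble subsampling derive from it, so
#'   the result is independent of input row order.
#' @param learner base-learner name (see [get_learner()]).
#' @return list with `threshold`, `selected_features`, `cv_auc`
#'   (threshold x mean/per-fold AUC table), `feature_tests` (full-data
#'   test table) and `mean_auc` (mean held-out AUC at the chosen
#'   threshold).
#' @export
select_threshold_cv <- function(pos_mat, neg_mat, kinds,
                                thresholds = default_threshold_grid(),
                                k = 5, seed = 17, learner = "xgboost") {
  if (k < 2) stop("k must be >= 2")
  if (length(thresholds) == 0) stop("empty threshold grid")
  if (nrow(pos_mat) < k || nrow(neg_mat) < k)
    stop("need at least k positives and k negatives")
  thresholds <- sort(thresholds)
  lrn <- get_learner(learner)

  pos_mat <- pos_mat[canonical_row_order(pos_mat), , drop = FALSE]
  neg_mat <- neg_mat[canonical_row_order(neg_mat), , drop = FALSE]

  auc_tab <- matrix(NA_real_, nrow = length(thresholds), ncol = k)
  withr::with_seed(seed, {
    fold_pos <- sample(rep(seq_len(k), length.out = nrow(pos_mat)))
    fold_neg <- sample(rep(seq_len(k), length.out = nrow(neg_mat)))
    for (f in seq_len(k)) {
      tr_pos <- pos_mat[fold_pos != f, , drop = FALSE]
      tr_neg <- neg_mat[fold_neg != f, , drop = FALSE]
      te_pos <- pos_mat[fold_pos == f, , drop = FALSE]
      te_neg <- neg_mat[fold_neg == f, , drop = FALSE]
      tests <- feature_tests(tr_pos, tr_neg, kinds)
      for (ti in seq_along(thresholds)) {
        sel <- tests$feature_id[tests$p_value <= thresholds[ti]]
        if (length(sel) == 0) {
          ds_log("select_threshold_cv: threshold %g selected no features in fold %d; AUC set to 0.5",
                 thresholds[ti], f)
          auc_tab[ti, f] <- 0.5
          next
        }
        em <- train_ensemble(tr_pos, tr_neg, sel, seed = NULL,
                             learner = learner)
        auc_tab[ti, f] <- auc_rank(predict_dscore(em, te_pos),
                                   predict_dscore(em, te_neg))
      }
    }
  })

  mean_auc <- rowMeans(auc_tab)
  best <- which(mean_auc == max(mean_auc))[1]  # ascending grid: tie -> smaller
  tests_full <- feature_tests(pos_mat, neg_mat, kinds)
  sel_full <- tests_full$feature_id[tests_full$p_value <= thresholds[best]]
  list(
    threshold = thresholds[best],
    selected_features = sel_full,
    cv_auc = data.frame(threshold = thresholds, mean_auc = mean_auc,
                        auc_tab),
    feature_tests = tests_full,
    mean_auc = mean_auc[best]
  )
}

#' Train the balanced classifier ensemble
#'
#' Negatives are partitioned (after seeded shuffling of a canonical row
#' order) into `floor(n_neg / n_pos)` disjoint folds of size `n_pos`;
#' leftover negatives are discarded and logged. Base classifier `i` is
#' trained on all positives plus negative fold `i`, restricted to the
#' selected features — so each classifier sees an equal number of risk and
#' benign variants, and with the default 10:1 matched sets the ensemble
#' has 10 members.
#'
#' @param pos_mat,neg_mat annotation-matrix rows (columns named by
#'   feature).
#' @param selected_features feature ids to train on.
#' @param seed RNG seed; `NULL` uses the current RNG state (for callers
#'   that already seeded).
#' @param learner base-learner name (see [get_learner()]).
#' @param threshold optional p-value threshold to record as provenance.
#' @param provenance optional list recorded verbatim in the model.
#' @return object of class `ensemble_model`.
#' @export
train_ensemble <- function(pos_mat, neg_mat, selected_features, seed = 17,
                           learner = "xgboost", threshold = NA_real_,
                           provenance = list()) {
  if (nrow(pos_mat) < 2) stop("need at least 2 positives")
  if (nrow(neg_mat) < nrow(pos_mat))
    stop("cannot balance: fewer negatives than positives")
  missing_feat <- setdiff(selected_features, colnames(pos_mat))
  if (length(missing_feat) > 0)
    stop(sprintf("selected feature '%s' absent from the matrix",
                 missing_feat[1]))
  if (length(selected_features) == 0) stop("no selected features")

  pos <- pos_mat[canonical_row_order(pos_mat), selected_features,
                 drop = FALSE]
  neg_full <- neg_mat[canonical_row_order(neg_mat), selected_features,
                      drop = FALSE]
  np <- nrow(pos); nn <- nrow(neg_full)
  n_cls <- nn %/% np
  discarded <- nn - n_cls * np
  if (discarded > 0)
    ds_log("train_ensemble: discarding %d leftover negative(s) after partitioning into %d fold(s) of %d",
           discarded, n_cls, np)

  lrn <- get_learner(learner)
  do_fit <- function() {
    perm <- sample(nn)
    y <- c(rep(1, np), rep(0, np))
    lapply(seq_len(n_cls), function(i) {
      fold <- perm[((i - 1) * np + 1):(i * np)]
      X <- rbind(pos, neg_full[fold, , drop = FALSE])
      lrn$fit(X, y)
    })
  }
  classifiers <- if (is.null(seed)) do_fit() else withr::with_seed(seed, do_fit())

  structure(
    list(selected_features = selected_features,
         threshold = threshold,
         classifiers = classifiers,
         n_classifiers = n_cls,
         learner = learner,
         seed = seed,
         provenance = provenance),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble model: %d %s classifier(s), %d selected feature(s)%s\n",
              x$n_classifiers, x$learner, length(x$selected_features),
              if (is.na(x$threshold)) ""
              else sprintf(", threshold %g", x$threshold)))
  invisible(x)
}

#' Predict D-scores
#'
#' The D-score of a feature vector is the arithmetic mean of the
#' probability votes of all base classifiers; it lies in `[0, 1]` and can
#' be read as the probability that the variant/base is
#' disease/trait-associated.
#'
#' @param model an [train_ensemble()] result.
#' @param x named numeric vector, or matrix with feature-named columns
#'   covering `model$selected_features`.
#' @return numeric vector of D-scores (length = rows of `x`).
#' @export
predict_dscore <- function(model, x) {
  stopifnot(inherits(model, "ensemble_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  missing_feat <- setdiff(model$selected_features, colnames(x))
  if (length(missing_feat) > 0)
    stop(sprintf("feature vector is missing feature '%s'", missing_feat[1]))
  X <- x[, model$selected_features, drop = FALSE]
  lrn <- get_learner(model$learner)
  votes <- vapply(model$classifiers, function(cl) lrn$vote(cl, X),
                  numeric(nrow(X)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(X))
  clamp(rowMeans(votes), 0, 1)
}

#' Score every window of the genome
#'
#' Applies the model row-wise to the annotation matrix; each base of a
#' window inherits the window's D-score. Scores are quantized to 4
#' decimals in the resulting track.
#'
#' @param model an `ensemble_model`.
#' @param am an [assemble_matrix()] result whose features cover the
#'   model's selected features.
#' @param disease trait label stored in the track.
#' @return a `score_track` (see [score_track()]).
#' @export
score_genome <- function(model, am, disease = "trait") {
  stopifnot(inherits(am, "annotation_matrix"))
  s <- predict_dscore(model, am$matrix)
  part <- am$partition
  per_chrom <- split(quantize_score(s),
                     rep(part$build$chrom, part$n_windows))
  score_track(part$build, part$window_size, disease,
              per_chrom[part$build$chrom])
}

#' Model serialization
#'
#' Single-archive dump of the selected features, threshold, seed,
#' provenance and base classifiers, version-stamped so incompatible
#' archives are rejected on read.
#'
#' @param model an `ensemble_model`.
#' @param path archive path.
#' @return `path` (write) / the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ensemble_model"))
  saveRDS(list(magic = "dscoreR-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("incompatible model file"))
  if (!identical(obj$magic, "dscoreR-model") || !identical(obj$version, 1L))
    stop("incompatible model file")
  obj$model
}

#' Write a plain-text training report
#'
#' Per-feature test table, CV AUC per threshold and ensemble fold sizes;
#' numbers are printed with fixed precision so identical runs produce
#' byte-identical reports.
#'
#' @param cv a [select_threshold_cv()] result.
#' @param model the trained `ensemble_model`.
#' @param path output path.
#' @param n_pos,n_neg training-set sizes to record.
#' @export
write_training_report <- function(cv, model, path, n_pos, n_neg) {
  lines <- c(
    "# training report",
    sprintf("positives\t%d", n_pos),
    sprintf("negatives\t%d", n_neg),
    sprintf("n_classifiers\t%d", model$n_classifiers),
    sprintf("fold_size\t%d", n_pos),
    sprintf("learner\t%s", model$learner),
    sprintf("threshold\t%.10g", cv$threshold),
    sprintf("mean_cv_auc\t%.6f", cv$mean_auc),
    sprintf("selected_features\t%s",
            paste(cv$selected_features, collapse = ",")),
    "",
    "# cv_auc\tthreshold\tmean_auc",
    sprintf("cv\t%.10g\t%.6f", cv$cv_auc$threshold, cv$cv_auc$mean_auc),
    "",
    "# tests\tfeature_id\tstatistic\tp_value\ttest_name",
    sprintf("test\t%s\t%.6g\t%.6g\t%s",
            cv$feature_tests$feature_id, cv$feature_tests$statistic,
            cv$feature_tests$p_value, cv$feature_tests$test_name)
  )
  writeLines(lines, path)
  invisible(path)
}
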