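# Frozen expected values:
#   Complete separation at n = 5 + 5 gives two-sided p = 2/252 for both the
#   rank-sum test (2 extreme orderings out of C(10,5) equally likely rank
#   assignments) and Fisher's exact test (2 tables at least as extreme out
#   of C(10,5) under the hypergeometric null).
P_SEP <- 2 / choose(10, 5)

test_that("rank-sum and Fisher tests match exact enumeration at n = 5 + 5", {
  rs <- test_feature(c(6, 7, 8, 9, 10), c(1, 2, 3, 4, 5), kind = "count")
  expect_equal(rs$p_value, P_SEP, tolerance = 1e-12)
  expect_equal(rs$test_name, "ranksum")

  fi <- test_feature(rep(1, 5), rep(0, 5), kind = "binary")
  expect_equal(fi$p_value, P_SEP, tolerance = 1e-12)
  expect_equal(fi$test_name, "fisher")

  # identical degenerate groups carry no signal
  expect_equal(test_feature(rep(2, 4), rep(2, 6), "count")$p_value, 1)
  expect_equal(test_feature(rep(1, 4), rep(1, 6), "binary")$p_value, 1)
  expect_error(test_feature(numeric(0), 1:3, "count"), "non-empty")
})

test_that("the rank AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(9, {
    for (i in 1:5) {
      sp <- rnorm(40, mean = 0.5); sn <- rnorm(60)
      ours <- dscoreR:::auc_rank(sp, sn)
      ref <- as.numeric(pROC::auc(
        response = c(rep(1, 40), rep(0, 60)), predictor = c(sp, sn),
        direction = "<", quiet = TRUE))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("ensemble partitions negatives into balanced disjoint folds", {
  withr::with_seed(4, {
    pos <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, c("a", "b", "c")))
    neg <- matrix(rnorm(500 * 3), 500, dimnames = list(NULL, c("a", "b", "c")))
  })
  m <- train_ensemble(pos, neg, c("a", "b"), seed = 1)
  expect_equal(m$n_classifiers, 10)
  expect_equal(m$selected_features, c("a", "b"))

  withr::with_seed(4, {
    pos2 <- matrix(rnorm(10 * 2), 10, dimnames = list(NULL, c("a", "b")))
    neg2 <- matrix(rnorm(105 * 2), 105, dimnames = list(NULL, c("a", "b")))
  })
  expect_message(m2 <- train_ensemble(pos2, neg2, c("a", "b"), seed = 1),
                 "discarding 5 leftover")
  expect_equal(m2$n_classifiers, 10)
  expect_error(train_ensemble(neg2, pos2, c("a", "b"), seed = 1),
               "cannot balance")
})

test_that("D-scores are the mean of per-classifier votes (independent vote loop)", {
  fit <- small_fit()
  m <- fit$model
  withr::with_seed(12, {
    X <- matrix(rpois(100 * length(m$selected_features), 10), nrow = 100,
                dimnames = list(NULL, m$selected_features))
  })
  d <- predict_dscore(m, X)
  lrn <- get_learner(m$learner)
  manual <- rowMeans(vapply(m$classifiers, function(cl) lrn$vote(cl, X),
                            numeric(100)))
  expect_equal(d, manual, tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  expect_error(predict_dscore(m, X[, -1, drop = FALSE]),
               "missing feature")
})

test_that("retraining with the same seed reproduces the model; row order is irrelevant", {
  withr::with_seed(4, {
    pos <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, c("a", "b", "c")))
    neg <- matrix(rnorm(100 * 3), 100, dimnames = list(NULL, c("a", "b", "c")))
    X <- matrix(rnorm(30 * 3), 30, dimnames = list(NULL, c("a", "b", "c")))
  })
  m1 <- train_ensemble(pos, neg, c("a", "c"), seed = 8)
  m2 <- train_ensemble(pos, neg, c("a", "c"), seed = 8)
  expect_identical(predict_dscore(m1, X), predict_dscore(m2, X))
  # permuted training rows: same folds after canonical reordering
  m3 <- train_ensemble(pos[sample(20), ], neg[sample(100), ],
                       c("a", "c"), seed = 8)
  expect_identical(predict_dscore(m1, X), predict_dscore(m3, X))
})

test_that("CV threshold selection recovers planted features and their signal", {
  for (s in c(301, 302)) {
    w <- simulate_world(sim_config(n_risk = 100, n_benign_pool = 5000,
                                   n_features = 60, n_informative = 5,
                                   effect_size = 2, seed = s))
    am <- assemble_matrix(w$tracks, w$partition)
    pos <- risk_set(w$risk_catalog, "traitA")
    cand <- benign_candidates(w$benign_catalog, 0.05, w$risk_catalog)
    ms <- match_negatives_tss(pos, cand, w$tss, ratio = 10, seed = s)
    pm <- annotate_variants(ms$positives, am)
    nm <- annotate_variants(ms$negatives, am)
    cv <- select_threshold_cv(pm, nm, am$features$kind, k = 5, seed = s)
    expect_true(all(w$ground_truth$traitA %in% cv$selected_features))
    expect_gt(cv$mean_auc, 0.9)
  }
})

test_that("a single-threshold grid returns that threshold", {
  fit <- small_fit()
  pm <- annotate_variants(fit$ms$positives, fit$am)
  nm <- annotate_variants(fit$ms$negatives, fit$am)
  cv <- select_threshold_cv(pm, nm, fit$am$features$kind,
                            thresholds = 0.01, k = 3, seed = 2)
  expect_equal(cv$threshold, 0.01)
  expect_error(select_threshold_cv(pm, nm, fit$am$features$kind,
                                   thresholds = numeric(0), k = 3, seed = 2),
               "empty threshold grid")
})

test_that("window scores equal row-wise prediction and propagate to bases", {
  fit <- small_fit()
  s <- predict_dscore(fit$model, fit$am$matrix)
  expect_equal(unlist(fit$track$scores, use.names = FALSE),
               quantize_score(s))
  # two variants in one window share a D-score
  expect_equal(base_score(fit$track, "chr1", 10),
               base_score(fit$track, "chr1", 150))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("adding a classifier moves the D-score toward its vote", {
  fit <- small_fit()
  m <- fit$model
  X <- fit$am$matrix[1:20, ]
  d <- predict_dscore(m, X)
  lrn <- get_learner(m$learner)
  v_new <- lrn$vote(m$classifiers[[1]], X[, m$selected_features, drop = FALSE])
  m_plus <- m
  m_plus$classifiers <- c(m$classifiers, m$classifiers[1])
  m_plus$n_classifiers <- m$n_classifiers + 1
  d_plus <- predict_dscore(m_plus, X)
  towards <- sign(d_plus - d) == sign(v_new - d) | abs(d_plus - d) < 1e-12
  expect_true(all(towards))
})

test_that("the glmnet learner trains and votes probabilities, with 1-feature fallback", {
  withr::with_seed(6, {
    pos <- matrix(rnorm(30 * 2, mean = 1), 30,
                  dimnames = list(NULL, c("a", "b")))
    neg <- matrix(rnorm(60 * 2), 60, dimnames = list(NULL, c("a", "b")))
  })
  m <- train_ensemble(pos, neg, c("a", "b"), seed = 2, learner = "glmnet")
  d <- predict_dscore(m, rbind(pos, neg))
  expect_true(all(d >= 0 & d <= 1))
  expect_gt(dscoreR:::auc_rank(d[1:30], d[31:90]), 0.7)
  m1 <- train_ensemble(pos, neg, "a", seed = 2, learner = "glmnet")
  expect_true(all(predict_dscore(m1, pos) >= 0))
})

test_that("models round-trip through their archive and reject foreign files", {
  fit <- small_fit()
  path <- tempfile(fileext = ".rds")
  write_model(fit$model, path)
  back <- read_model(path)
  X <- fit$am$matrix[1:10, ]
  expect_identical(predict_dscore(back, X), predict_dscore(fit$model, X))
  bad <- tempfile()
  saveRDS(list(x = 1), bad)
  expect_error(read_model(bad), "incompatible model file")
})
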