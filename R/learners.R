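# Pluggable base learners behind a fit/vote contract. A learner is a list
# with elements `name`, `fit(X, y, ...)` and `vote(fit, X)`; votes are
# probability estimates in [0, 1], never hard labels, so their average
# (the D-score) is graded.

#' Base-learner registry
#'
#' `"xgboost"` (default): depth-limited gradient-boosted trees
#' (`max_depth = 3`, `nrounds = 30`, `eta = 0.3`, logistic objective,
#' single thread for determinism). `"glmnet"`: ridge-regularized logistic
#' regression (`alpha = 0`, fixed small lambda); with a single selected
#' feature it falls back to an unpenalized logistic fit, since glmnet
#' requires two or more predictors.
#'
#' @param name learner name.
#' @return learner definition (list with `name`, `fit`, `vote`).
#' @export
get_learner <- function(name = c("xgboost", "glmnet")) {
  name <- match.arg(name)
  switch(name,
    xgboost = list(
      name = "xgboost",
      fit = function(X, y) {
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 3,
                        eta = 0.3, nthread = 1),
          data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
          nrounds = 30, verbose = 0
        )
      },
      vote = function(fit, X) {
        clamp(stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)),
              0, 1)
      }
    ),
    glmnet = list(
      name = "glmnet",
      fit = function(X, y) {
        if (ncol(X) >= 2) {
          fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                                lambda = 0.01, standardize = TRUE)
          list(kind = "glmnet", fit = fit)
        } else {
          df <- data.frame(y = y, x = X[, 1])
          fit <- suppressWarnings(
            stats::glm(y ~ x, data = df, family = stats::binomial()))
          list(kind = "glm", fit = fit)
        }
      },
      vote = function(fit, X) {
        p <- if (fit$kind == "glmnet") {
          as.numeric(stats::predict(fit$fit, X, type = "response"))
        } else {
          as.numeric(stats::predict(fit$fit, data.frame(x = X[, 1]),
                                    type = "response"))
        }
        clamp(p, 0, 1)
      }
    )
  )
}
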