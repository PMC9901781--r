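#' Gradient-boosted-tree imputation
#'
#' One boosted-tree regressor per feature, trained to predict that feature's
#' true (pre-amputation) value from the other, possibly-missing features of
#' the sparse training rows. Missing inputs are handled by the trees' native
#' default-branch routing, so no input encoding is needed. Missing query
#' entries are filled by the corresponding per-feature model and clipped to
#' \[0, 120\] dB.
#'
#' @param train Sparse training `audiogram_matrix` (the amputated inputs).
#' @param truth Dense `audiogram_matrix` holding the true values of `train`
#'   (same shape; supplies the regression targets).
#' @param query `audiogram_matrix` to complete.
#' @param n_estimators Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage per round (eta).
#' @param subsample Row subsample proportion per round.
#' @param seed Integer seed for the subsampling RNG.
#' @return Completed `audiogram_matrix`.
#' @export
impute_gbt <- function(train, truth, query, n_estimators = 100L,
                       max_depth = 3L, learning_rate = 0.1,
                       subsample = 1.0, seed = NULL) {
  fit <- fit_imputer(imputer_spec("XGB", list(
    n_estimators = as.integer(n_estimators), max_depth = as.integer(max_depth),
    learning_rate = learning_rate, subsample = subsample)),
    train, truth = truth, seed = seed)
  impute(fit, query)
}

fit_gbt_state <- function(train, truth, hp, seed) {
  if (is.null(truth)) {
    stop("XGB imputation is supervised: `truth` (the dense matrix whose ",
         "amputation produced `train`) is required", call. = FALSE)
  }
  tr <- unclass(train)
  tv <- unclass(truth)
  stopifnot(all(dim(tr) == dim(tv)))
  p <- ncol(tr)
  if (is.null(seed)) seed <- 0L
  models <- vector("list", p)
  for (j in seq_len(p)) {
    dtrain <- xgboost::xgb.DMatrix(tr[, -j, drop = FALSE],
                                   label = tv[, j], missing = NA)
    models[[j]] <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = hp$max_depth, eta = hp$learning_rate,
                    subsample = hp$subsample, nthread = 1,
                    seed = as.integer(seed) + j),
      data = dtrain, nrounds = hp$n_estimators, verbose = 0)
  }
  list(models = models)
}

#' @export
impute.fitted_XGB <- function(object, query, ...) {
  q <- unclass(query)
  filled <- q
  for (j in seq_len(ncol(q))) {
    rows <- which(is.na(q[, j]))
    if (length(rows) == 0) next
    dq <- xgboost::xgb.DMatrix(q[rows, -j, drop = FALSE], missing = NA)
    filled[rows, j] <- stats::predict(object$state$models[[j]], dq)
  }
  finish_imputation(filled, query)
}
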