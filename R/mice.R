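#' Impute a matrix by chained penalized regressions
#'
#' Iterative imputation in the MICE style, used here as a point-imputation
#' engine. All missing entries (in the training matrix and the query) are
#' first filled by a univariate statistic of the observed training columns.
#' Then for `m` rounds the features are visited round-robin in ascending
#' frequency order; at each visit the feature is regressed on all other
#' features with a penalized linear model fitted on the training rows where
#' that feature was originally observed, and every originally-missing entry
#' of the feature (train and query alike) is re-predicted. The estimator is
#' lasso (`"l1"`) or ridge (`"l2"`) regression at a fixed penalty strength
#' `lambda`, both suited to the strong multicollinearity of audiometric
#' thresholds.
#'
#' The reported completion is either the final round (presumed most
#' accurate) or, in the SICE variant, the per-entry mean of all `m` rounds.
#' With `m = 0` the initialization itself is returned. Outputs are clipped
#' to \[0, 120\] dB. The procedure is deterministic given the data and
#' hyperparameters.
#'
#' @param train Training `audiogram_matrix` (sparse allowed).
#' @param query `audiogram_matrix` to complete.
#' @param estimator `"l1"` (lasso) or `"l2"` (ridge).
#' @param lambda Positive penalty strength.
#' @param m Number of chained-imputation rounds.
#' @param init Initial fill statistic: `"mean"` or `"median"`.
#' @param output `"last_round"` or `"sice_mean"`.
#' @param strict When `TRUE`, a training feature with no observed values is
#'   an initialization error; when `FALSE` it is initialized from the grand
#'   mean of all observed training entries (the assessment engine's
#'   behavior under extreme amputation).
#' @return Completed `audiogram_matrix`.
#' @export
impute_mice <- function(train, query, estimator = c("l2", "l1"),
                        lambda = 0.1, m = 10L,
                        init = c("mean", "median"),
                        output = c("last_round", "sice_mean"),
                        strict = TRUE) {
  estimator <- match.arg(estimator)
  init <- match.arg(init)
  output <- match.arg(output)
  stopifnot(lambda > 0, m >= 0)
  tr <- unclass(train)
  q <- unclass(query)
  p <- ncol(tr)
  if (ncol(q) != p) stop("train and query feature grids differ", call. = FALSE)

  init_stat <- switch(init,
    mean   = colMeans(tr, na.rm = TRUE),
    median = apply(tr, 2, stats::median, na.rm = TRUE))
  if (any(!is.finite(init_stat))) {
    if (strict) {
      stop("cannot initialize: a training column has no observed values",
           call. = FALSE)
    }
    init_stat[!is.finite(init_stat)] <- mean(tr, na.rm = TRUE)
  }
  miss_tr <- is.na(tr)
  miss_q <- is.na(q)
  tr_f <- tr; q_f <- q
  for (j in seq_len(p)) {
    tr_f[miss_tr[, j], j] <- init_stat[j]
    q_f[miss_q[, j], j] <- init_stat[j]
  }
  alpha <- if (estimator == "l1") 1 else 0
  acc <- matrix(0, nrow(q), p)

  for (round in seq_len(m)) {
    for (j in seq_len(p)) {
      rows <- which(!miss_tr[, j])
      if (length(rows) < 2) next       # nothing to regress on; keep fill
      x <- tr_f[rows, -j, drop = FALSE]
      y <- tr_f[rows, j]
      n_tr <- sum(miss_tr[, j]); n_q <- sum(miss_q[, j])
      if (n_tr == 0 && n_q == 0) next
      if (stats::sd(y) == 0) {
        if (n_tr > 0) tr_f[miss_tr[, j], j] <- y[1]
        if (n_q > 0) q_f[miss_q[, j], j] <- y[1]
      } else {
        fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = lambda,
                              standardize = TRUE)
        if (n_tr > 0) {
          tr_f[miss_tr[, j], j] <- as.numeric(stats::predict(
            fit, newx = tr_f[miss_tr[, j], -j, drop = FALSE]))
        }
        if (n_q > 0) {
          q_f[miss_q[, j], j] <- as.numeric(stats::predict(
            fit, newx = q_f[miss_q[, j], -j, drop = FALSE]))
        }
      }
    }
    acc <- acc + q_f
  }
  filled <- if (output == "sice_mean" && m > 0) acc / m else q_f
  finish_imputation(filled, query)
}

#' @export
impute.fitted_MICE <- function(object, query, ...) {
  hp <- object$hyperparameters
  train <- audiogram_matrix(object$state$train,
                            frequencies = object$frequencies)
  impute_mice(train, query, estimator = hp$estimator, lambda = hp$lambda,
              m = hp$m, init = hp$init, output = hp$output,
              strict = isTRUE(object$state$strict))
}
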