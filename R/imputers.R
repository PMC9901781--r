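#' Specify an imputation model family and hyperparameters
#'
#' All six model families share one fit/transform contract: a spec is fitted
#' on a training audiogram matrix (supervised families additionally need the
#' dense ground truth paired with the sparse training inputs) and the fitted
#' model fills missing entries of a query matrix. Observed entries are never
#' modified and every imputed value is clipped to \[0, 120\] dB.
#'
#' Families:
#' \describe{
#'   \item{UI}{univariate imputation — per-feature mean / median / mode.}
#'   \item{INT}{within-audiogram interpolation — linear, monotone piecewise
#'     cubic (pchip), or cubic spline along the frequency axis.}
#'   \item{KNN}{k-nearest-neighbor imputation with partial (shared-feature)
#'     Euclidean distances and uniform or inverse-distance weights.}
#'   \item{MICE}{chained-equation imputation: round-robin penalized linear
#'     regressions (l1 or l2), output from the last round or the mean of all
#'     rounds (SICE).}
#'   \item{XGB}{gradient boosted trees, one regressor per feature, missing
#'     inputs routed natively.}
#'   \item{NN}{feed-forward multilayer perceptron (ReLU, Adam), missing
#'     inputs encoded as -1.}
#' }
#'
#' @param family One of `"UI"`, `"INT"`, `"KNN"`, `"MICE"`, `"XGB"`, `"NN"`.
#' @param hyperparameters Named list overriding family defaults.
#' @param grid Named list of candidate values for tuning; defaults to
#'   [default_grid()] for the family.
#' @return An `imputer_spec`.
#' @export
imputer_spec <- function(family = c("UI", "INT", "KNN", "MICE", "XGB", "NN"),
                         hyperparameters = list(), grid = NULL) {
  family <- match.arg(family)
  defaults <- default_hyperparameters(family)
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hp <- utils::modifyList(defaults, hyperparameters)
  if (is.null(grid)) grid <- default_grid(family)
  unknown <- setdiff(names(grid), names(defaults))
  if (length(unknown) > 0) {
    stop("grid names not legal for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(family = family, hyperparameters = hp, grid = grid),
            class = "imputer_spec")
}

default_hyperparameters <- function(family) {
  switch(family,
    UI   = list(strategy = "mean"),
    INT  = list(method = "pchip", x_axis = "log2"),
    KNN  = list(k = 5L, weighting = "distance"),
    MICE = list(estimator = "l2", lambda = 0.1, m = 10L,
                init = "mean", output = "last_round"),
    XGB  = list(n_estimators = 100L, max_depth = 3L,
                learning_rate = 0.1, subsample = 1.0),
    NN   = list(hidden_layers = 1L, nodes_per_layer = 64L,
                learning_rate = 1e-3, epochs = 200L, batch_size = 32L))
}

#' Default hyperparameter search grid per model family
#'
#' Candidate values searched during inner-loop tuning. Any subset can be
#' overridden through [imputer_spec()]'s `grid` argument.
#'
#' @param family Model family name.
#' @return Named list of candidate vectors.
#' @export
default_grid <- function(family = c("UI", "INT", "KNN", "MICE", "XGB", "NN")) {
  family <- match.arg(family)
  switch(family,
    UI   = list(strategy = c("mean", "median", "mode")),
    INT  = list(method = c("linear", "pchip", "cubic_spline")),
    KNN  = list(k = c(3L, 5L, 10L, 20L, 40L),
                weighting = c("uniform", "distance")),
    MICE = list(estimator = c("l1", "l2"), lambda = c(0.01, 0.1, 1.0),
                m = c(5L, 10L, 20L), init = c("mean", "median"),
                output = c("last_round", "sice_mean")),
    XGB  = list(n_estimators = c(100L, 300L), max_depth = c(3L, 6L),
                learning_rate = c(0.05, 0.1), subsample = c(0.8, 1.0)),
    NN   = list(hidden_layers = c(1L, 2L), nodes_per_layer = c(32L, 64L, 128L),
                learning_rate = c(1e-3, 1e-2)))
}

#' Fit an imputation model
#'
#' @param spec An [imputer_spec()].
#' @param train Training `audiogram_matrix` (sparse allowed; for INT the
#'   training matrix is unused beyond recording the frequency grid).
#' @param truth For the supervised families (XGB, NN): the dense
#'   `audiogram_matrix` whose amputation produced `train` — inputs are the
#'   sparse rows, targets the corresponding true values. Ignored otherwise.
#' @param seed Integer seed for the stochastic trainers (XGB subsampling,
#'   NN initialization and minibatching). Fits are reproducible given
#'   (seed, hyperparameters, data).
#' @param strict When `TRUE` (the default), a training feature with no
#'   observed values is a fit error. When `FALSE`, such features fall back
#'   to the grand mean of all observed training entries — the behavior the
#'   assessment engine relies on, since extreme amputation (e.g. 9 of 11
#'   features removed under heavily skewed weights) can empty a column of a
#'   modest dense subset.
#' @return A `fitted_imputer` whose subclass carries the family.
#' @export
fit_imputer <- function(spec, train, truth = NULL, seed = NULL, strict = TRUE) {
  stopifnot(inherits(spec, "imputer_spec"), inherits(train, "audiogram_matrix"))
  hp <- spec$hyperparameters
  state <- switch(spec$family,
    UI   = fit_univariate_state(train, hp$strategy, strict = strict),
    INT  = list(),
    KNN  = list(train = unclass(train),
                col_means = fallback_col_means(unclass(train))),
    MICE = list(train = unclass(train), strict = strict),
    XGB  = fit_gbt_state(train, truth, hp, seed),
    NN   = fit_mlp_state(train, truth, hp, seed))
  structure(list(family = spec$family, hyperparameters = hp, state = state,
                 frequencies = attr(train, "frequencies"), seed = seed),
            class = c(paste0("fitted_", spec$family), "fitted_imputer"))
}

#' Fill the missing entries of a query matrix
#'
#' @param object A `fitted_imputer` from [fit_imputer()].
#' @param query `audiogram_matrix` to complete.
#' @param ... Unused.
#' @return Completed `audiogram_matrix`: observed entries untouched, missing
#'   entries filled and clipped to \[0, 120\].
#' @export
impute <- function(object, query, ...) UseMethod("impute")

# shared tail: restore observed entries, clip imputed ones
finish_imputation <- function(filled, query) {
  q <- unclass(query)
  miss <- is.na(q)
  out <- q
  out[miss] <- pmin(pmax(filled[miss], 0), 120)
  audiogram_matrix(out, frequencies = attr(query, "frequencies"))
}

## ---------------------------------------------------------------- UI ----

fit_univariate_state <- function(train, strategy, strict = TRUE) {
  values <- unclass(train)
  empty <- colSums(!is.na(values)) == 0
  if (any(empty) && strict) {
    stop("cannot fit univariate imputer: no observed values at ",
         paste(colnames(values)[empty], collapse = ", "), " Hz",
         call. = FALSE)
  }
  if (all(is.na(values))) {
    stop("cannot fit univariate imputer: no observed values at all",
         call. = FALSE)
  }
  stat <- switch(strategy,
    mean   = colMeans(values, na.rm = TRUE),
    median = apply(values, 2, stats::median, na.rm = TRUE),
    mode   = apply(values, 2, column_mode),
    stop("unknown univariate strategy: ", strategy, call. = FALSE))
  stat[empty] <- mean(values, na.rm = TRUE)
  list(stat = stat)
}

# per-feature means with the grand mean substituted for empty features
fallback_col_means <- function(values) {
  cm <- colMeans(values, na.rm = TRUE)
  cm[!is.finite(cm)] <- mean(values, na.rm = TRUE)
  cm
}

# most frequent observed value; ties broken toward the smallest value
column_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Fit a univariate imputer
#'
#' Convenience wrapper: one statistic (mean, median or mode) per feature,
#' estimated from the observed values of each training column; transform
#' fills every missing entry with its column statistic.
#'
#' @param train Training `audiogram_matrix` (each column needs at least one
#'   observed value).
#' @param strategy `"mean"`, `"median"` or `"mode"`.
#' @return A `fitted_imputer`.
#' @export
fit_univariate <- function(train, strategy = c("mean", "median", "mode")) {
  strategy <- match.arg(strategy)
  fit_imputer(imputer_spec("UI", list(strategy = strategy)), train)
}

#' @export
impute.fitted_UI <- function(object, query, ...) {
  q <- unclass(query)
  filled <- matrix(object$state$stat, nrow = nrow(q), ncol = ncol(q),
                   byrow = TRUE)
  finish_imputation(filled, query)
}

## --------------------------------------------------------------- INT ----

#' Interpolate one sparse threshold vector
#'
#' Workhorse for the interpolation imputer. Interior missing points come
#' from the interpolant through the neighboring observed points; exterior
#' missing points from extending the nearest interpolant. Output is clipped
#' to \[0, 120\] dB.
#'
#' Methods: `"linear"` (two-point straight line between bracketing observed
#' points), `"pchip"` (monotone piecewise cubic Hermite — no overshoot,
#' preserves monotone runs) and `"cubic_spline"` (natural cubic spline,
#' continuous second derivative; falls back to linear with fewer than 3
#' observed points). With a single observed point every method degenerates
#' to constant extension; with none, interpolation is impossible and an
#' error is raised.
#'
#' @param y Numeric threshold vector with `NA` for missing.
#' @param x Abscissa for each entry. The audiological convention is octave
#'   spacing, i.e. `log2(frequency)`.
#' @param method Interpolation method.
#' @return Completed numeric vector.
#' @export
interpolate_instance <- function(y, x, method = c("linear", "pchip", "cubic_spline")) {
  method <- match.arg(method)
  obs <- which(!is.na(y))
  if (length(obs) == 0) {
    stop("cannot interpolate an instance with no observed thresholds",
         call. = FALSE)
  }
  if (length(obs) == length(y)) return(y)
  xo <- x[obs]; yo <- y[obs]
  out <- y
  fill <- which(is.na(y))
  if (length(obs) == 1) {
    out[fill] <- yo            # nearest interpolant degenerates to a constant
  } else if (method == "linear" || (method == "cubic_spline" && length(obs) < 3)) {
    out[fill] <- vapply(x[fill], linear_segment, numeric(1), xo = xo, yo = yo)
  } else {
    sf_method <- if (method == "pchip") "monoH.FC" else "natural"
    f <- stats::splinefun(xo, yo, method = sf_method)
    out[fill] <- f(x[fill])
  }
  pmin(pmax(out, 0), 120)
}

# straight line through the bracketing (or nearest terminal) observed pair
linear_segment <- function(xq, xo, yo) {
  j <- findInterval(xq, xo, rightmost.closed = FALSE)
  j <- min(max(j, 1L), length(xo) - 1L)   # exterior -> nearest segment
  yo[j] + (yo[j + 1] - yo[j]) / (xo[j + 1] - xo[j]) * (xq - xo[j])
}

#' @export
impute.fitted_INT <- function(object, query, ...) {
  impute_interpolation(query, method = object$hyperparameters$method,
                       x_axis = object$hyperparameters$x_axis)
}

#' Impute a matrix by within-audiogram interpolation
#'
#' Each audiogram is completed independently from its own observed
#' thresholds; no training data is used. See [interpolate_instance()].
#'
#' @param query `audiogram_matrix` to complete.
#' @param method `"linear"`, `"pchip"` or `"cubic_spline"`.
#' @param x_axis `"log2"` (octave spacing, the default audiological
#'   convention) or `"index"` (equispaced feature positions).
#' @return Completed `audiogram_matrix`.
#' @export
impute_interpolation <- function(query, method = c("linear", "pchip", "cubic_spline"),
                                 x_axis = c("log2", "index")) {
  method <- match.arg(method)
  x_axis <- match.arg(x_axis)
  freqs <- attr(query, "frequencies")
  x <- if (x_axis == "log2") log2(freqs) else seq_along(freqs)
  q <- unclass(query)
  filled <- t(apply(q, 1, interpolate_instance, x = x, method = method))
  finish_imputation(filled, query)
}

## --------------------------------------------------------------- KNN ----

#' @export
impute.fitted_KNN <- function(object, query, ...) {
  knn_fill(object$state$train, unclass(query),
           k = object$hyperparameters$k,
           weighting = object$hyperparameters$weighting,
           col_means = object$state$col_means, query = query)
}

#' Impute a matrix by k-nearest-neighbor donation
#'
#' For a sparse instance, distance to each donor is the root mean squared
#' difference over the features both have observed (a partial Euclidean
#' distance). Each missing entry is filled from the k nearest donors that
#' have that feature observed, combined with uniform weights (1/k each) or
#' weights proportional to inverse distance, normalized to sum to 1. When
#' no donor shares a feature with the instance (or none has the target
#' feature), the training column mean is used and the fallback is counted
#' in the result's `n_fallback` attribute.
#'
#' @param train Donor pool `audiogram_matrix`.
#' @param query `audiogram_matrix` to complete.
#' @param k Number of neighbors.
#' @param weighting `"uniform"` or `"distance"`.
#' @return Completed `audiogram_matrix`.
#' @export
impute_knn <- function(train, query, k = 5L,
                       weighting = c("uniform", "distance")) {
  weighting <- match.arg(weighting)
  tr <- unclass(train)
  knn_fill(tr, unclass(query), k = k, weighting = weighting,
           col_means = colMeans(tr, na.rm = TRUE), query = query)
}

knn_fill <- function(tr, q, k, weighting, col_means, query) {
  filled <- q
  tr_obs <- !is.na(tr)
  n_fallback <- 0L
  for (s in seq_len(nrow(q))) {
    miss <- which(is.na(q[s, ]))
    if (length(miss) == 0) next
    obs_s <- !is.na(q[s, ])
    # partial distances: mean squared difference over shared observed features
    diff2 <- sweep(tr[, obs_s, drop = FALSE], 2, q[s, obs_s])^2
    shared <- tr_obs[, obs_s, drop = FALSE]
    n_shared <- rowSums(shared)
    d <- sqrt(rowSums(diff2 * shared, na.rm = TRUE) /
                pmax(n_shared, 1))
    d[n_shared == 0] <- Inf
    for (j in miss) {
      eligible <- which(tr_obs[, j] & is.finite(d))
      if (length(eligible) == 0) {
        filled[s, j] <- col_means[j]
        n_fallback <- n_fallback + 1L
        next
      }
      nb <- eligible[order(d[eligible])][seq_len(min(k, length(eligible)))]
      dv <- d[nb]
      if (weighting == "uniform") {
        filled[s, j] <- mean(tr[nb, j])
      } else if (any(dv == 0)) {
        filled[s, j] <- mean(tr[nb[dv == 0], j])   # exact matches dominate
      } else {
        w <- (1 / dv) / sum(1 / dv)
        filled[s, j] <- sum(w * tr[nb, j])
      }
    }
  }
  out <- finish_imputation(filled, query)
  attr(out, "n_fallback") <- n_fallback
  out
}
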