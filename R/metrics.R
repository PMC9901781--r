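#' Error metrics over masked entries
#'
#' Imputation quality is scored only on the deliberately deleted
#' (ground-truth-known) entries. `mae()` is the mean absolute residual,
#' `rmse()` the root mean squared residual, and `r2()` the coefficient of
#' determination `1 - SS_res / SS_tot`, where the reference mean is the
#' mean of the true masked values in the scored sample — so a constant
#' imputer lands near 0 and can go negative.
#'
#' @param y Numeric vector of true (deleted) values.
#' @param f Numeric vector of imputed values, same length.
#' @return A single number (dB for `mae`/`rmse`, dimensionless for `r2`).
#' @export
mae <- function(y, f) {
  check_scores(y, f)
  mean(abs(y - f))
}

#' @rdname mae
#' @export
rmse <- function(y, f) {
  check_scores(y, f)
  sqrt(mean((y - f)^2))
}

#' @rdname mae
#' @export
r2 <- function(y, f) {
  check_scores(y, f)
  if (length(y) < 2) stop("r2 needs at least 2 scored entries", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("r2 undefined: true masked values are all identical", call. = FALSE)
  }
  1 - sum((y - f)^2) / ss_tot
}

check_scores <- function(y, f) {
  if (length(y) == 0) stop("no scored entries", call. = FALSE)
  if (length(y) != length(f)) {
    stop("true and imputed vectors differ in length", call. = FALSE)
  }
  invisible(NULL)
}

# score a completed matrix against the truth records from apply_mask()
score_against_truth <- function(completed, truth) {
  freqs <- attr(completed, "frequencies")
  col <- match(truth$frequency, freqs)
  f <- unclass(completed)[cbind(truth$row, col)]
  data.frame(y = truth$value, f = f)
}

#' Aggregate a metric across repeated simulations
#'
#' Mean and two-sided Student-t confidence interval
#' `mean +/- t(level, n-1) * sd / sqrt(n)` of per-simulation metric values.
#'
#' @param values Numeric vector of per-simulation metrics (length >= 2).
#' @param level Confidence level (0.95 for tables, 0.99 for sweep bands).
#' @return List with `mean`, `lo`, `hi`, `level`, `n`.
#' @export
aggregate_simulations <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need >= 2 simulation values for a confidence interval",
                  call. = FALSE)
  m <- mean(values)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  list(mean = m, lo = m - half, hi = m + half, level = level, n = n)
}

#' Compare two models' repeated-simulation error samples
#'
#' Two-sided Wilcoxon rank-sum test on the per-simulation error values of
#' two models. The verdict is `"a_better"` when model a has the lower mean
#' error and the difference is significant at `alpha` (symmetrically
#' `"b_better"`), otherwise `"indistinguishable"`.
#'
#' @param samples_a,samples_b Numeric vectors of per-simulation error values
#'   (length >= 2 each; lower is better).
#' @param alpha Significance level.
#' @return List with `p_value`, `verdict`, `mean_a`, `mean_b`.
#' @export
compare_models <- function(samples_a, samples_b, alpha = 0.01) {
  stopifnot(length(samples_a) >= 2, length(samples_b) >= 2)
  if (length(unique(c(samples_a, samples_b))) == 1) {
    return(list(p_value = 1, verdict = "indistinguishable",
                mean_a = mean(samples_a), mean_b = mean(samples_b)))
  }
  p <- suppressWarnings(
    stats::wilcox.test(samples_a, samples_b, alternative = "two.sided")$p.value)
  verdict <- if (p >= alpha) {
    "indistinguishable"
  } else if (mean(samples_a) < mean(samples_b)) "a_better" else "b_better"
  list(p_value = p, verdict = verdict,
       mean_a = mean(samples_a), mean_b = mean(samples_b))
}
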