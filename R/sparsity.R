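#' Profile the missingness structure of an audiogram matrix
#'
#' Computes the two axes along which audiometric sparsity is characterized:
#' the per-frequency missing rate (which features tend to be absent) and the
#' per-instance missing-count histogram (how many features are absent per
#' audiogram).
#'
#' @param m A cleaned `audiogram_matrix` (may be sparse).
#' @return A `sparsity_profile`: list with `feature_missing_rate` (named by
#'   frequency), `count_histogram` (probabilities over 0..n_features missing,
#'   summing to 1) and `n_source`.
#' @export
profile_sparsity <- function(m) {
  stopifnot(inherits(m, "audiogram_matrix"))
  if (nrow(m) == 0) stop("empty input: cannot profile 0 audiograms", call. = FALSE)
  values <- unclass(m)
  p <- ncol(values)
  rate <- colMeans(is.na(values))
  names(rate) <- as.character(attr(m, "frequencies"))
  counts <- rowSums(is.na(values))
  hist <- tabulate(counts + 1L, nbins = p + 1L) / nrow(values)
  names(hist) <- 0:p
  structure(list(feature_missing_rate = rate,
                 count_histogram = hist,
                 n_source = nrow(values)),
            class = "sparsity_profile")
}

#' @export
print.sparsity_profile <- function(x, ...) {
  cat(sprintf("<sparsity_profile> from %d audiograms\n", x$n_source))
  cat("  feature missing rate:\n")
  print(round(x$feature_missing_rate, 3))
  invisible(x)
}

# frequencies carrying 3-fold removal weight under the two synthetic
# structured distributions
TERMINAL_FREQS <- c(125, 250, 500, 4000, 6000, 8000)
CENTRAL_FREQS  <- c(750, 1000, 1500, 2000, 3000)

#' Per-feature removal weights for a sparsity distribution
#'
#' Four removal-weight schemes are supported:
#' \describe{
#'   \item{real_world}{weights proportional to the observed per-frequency
#'     missing rates of a profiled dataset (zero rates floored so sampling
#'     stays well-defined).}
#'   \item{random}{uniform over features.}
#'   \item{terminal}{3-fold weight on the terminal frequencies
#'     (125, 250, 500, 4000, 6000, 8000 Hz), 1 elsewhere.}
#'   \item{central}{3-fold weight on the central frequencies
#'     (750, 1000, 1500, 2000, 3000 Hz), 1 elsewhere.}
#' }
#' Weights are normalized to sum to 1.
#'
#' @param distribution One of `"real_world"`, `"random"`, `"terminal"`,
#'   `"central"`.
#' @param profile A `sparsity_profile` (required for `real_world`).
#' @param frequencies Frequencies (Hz) of the target matrix.
#' @param floor Minimum pre-normalization weight substituted for zero
#'   real-world rates.
#' @return Numeric weight vector, named by frequency, positive, summing to 1.
#' @export
make_weights <- function(distribution = c("real_world", "random", "terminal", "central"),
                         profile = NULL,
                         frequencies = audiogram_frequencies(),
                         floor = 1e-6) {
  distribution <- match.arg(distribution)
  p <- length(frequencies)
  w <- switch(distribution,
    random = rep(1, p),
    terminal = ifelse(frequencies %in% TERMINAL_FREQS, 3, 1),
    central = ifelse(frequencies %in% CENTRAL_FREQS, 3, 1),
    real_world = {
      if (is.null(profile)) {
        stop("real_world weights require a sparsity profile", call. = FALSE)
      }
      r <- profile$feature_missing_rate
      if (length(r) != p) {
        stop("profile covers ", length(r), " features, need ", p, call. = FALSE)
      }
      pmax(as.numeric(r), floor)
    })
  w <- w / sum(w)
  names(w) <- as.character(frequencies)
  w
}

#' Specify an amputation policy
#'
#' A mask policy fixes the two independently controlled axes of simulated
#' sparsity: the removal \emph{distribution} (per-feature weights) and the
#' removal \emph{quantity} (how many entries to delete per instance). The
#' quantity is either `fixed` (exactly `k` per instance) or `mirrored`
#' (per-instance counts drawn from a source count histogram truncated at
#' `cap` and renormalized, including count 0 with its source probability).
#'
#' @param distribution Distribution name, see [make_weights()].
#' @param quantity `"fixed"` or `"mirrored"`.
#' @param k Number of entries removed per instance (fixed policy).
#' @param cap Maximum removals per instance (mirrored policy).
#' @param profile A `sparsity_profile`; required for `real_world` weights
#'   and for the mirrored count histogram.
#' @param frequencies Frequencies of the target matrix.
#' @return A `mask_policy` object.
#' @export
mask_policy <- function(distribution = c("real_world", "random", "terminal", "central"),
                        quantity = c("fixed", "mirrored"),
                        k = NULL, cap = NULL,
                        profile = NULL,
                        frequencies = audiogram_frequencies()) {
  distribution <- match.arg(distribution)
  quantity <- match.arg(quantity)
  p <- length(frequencies)
  weights <- make_weights(distribution, profile = profile,
                          frequencies = frequencies)
  if (quantity == "fixed") {
    k <- as.integer(k)
    if (is.na(k) || k < 1 || k > p - 1) {
      stop("fixed `k` must be in [1, ", p - 1, "]", call. = FALSE)
    }
    count_dist <- NULL
  } else {
    cap <- as.integer(cap)
    if (is.na(cap) || cap < 1 || cap > p - 1) {
      stop("mirrored `cap` must be in [1, ", p - 1, "]", call. = FALSE)
    }
    if (is.null(profile)) {
      stop("mirrored quantity requires a sparsity profile", call. = FALSE)
    }
    h <- profile$count_histogram[seq_len(cap + 1L)]  # counts 0..cap
    if (sum(h) <= 0) stop("source histogram has no mass at counts <= cap",
                          call. = FALSE)
    count_dist <- h / sum(h)
  }
  structure(list(distribution = distribution, quantity = quantity,
                 k = k, cap = cap, weights = weights,
                 count_dist = count_dist, frequencies = frequencies),
            class = "mask_policy")
}

#' Sample an amputation mask
#'
#' For each instance independently: draw the number of entries to remove
#' (fixed `k`, or from the policy's truncated count distribution), then pick
#' that many distinct features by successive weighted draws without
#' replacement, with probabilities proportional to the remaining weights.
#'
#' @param n Number of instances in the target (dense) matrix.
#' @param policy A [mask_policy()].
#' @return A logical matrix `n x p` of class `amputation_mask`; `TRUE` marks
#'   entries to delete.
#' @export
sample_mask <- function(n, policy) {
  stopifnot(inherits(policy, "mask_policy"))
  p <- length(policy$weights)
  if (policy$quantity == "fixed") {
    ks <- rep.int(policy$k, n)
  } else {
    ks <- sample.int(length(policy$count_dist), n, replace = TRUE,
                     prob = policy$count_dist) - 1L
  }
  removed <- matrix(FALSE, nrow = n, ncol = p,
                    dimnames = list(NULL, names(policy$weights)))
  for (i in seq_len(n)) {
    if (ks[i] > 0) {
      removed[i, sample.int(p, ks[i], prob = policy$weights)] <- TRUE
    }
  }
  structure(removed, class = c("amputation_mask", "matrix", "array"))
}

#' Apply an amputation mask to a dense matrix
#'
#' Deletes the masked entries from `m`, recording the deleted ground-truth
#' values for later scoring. The masked entries must be observed in `m`
#' (amputation of an already-missing entry is a contract violation).
#'
#' @param m A dense-where-masked `audiogram_matrix`.
#' @param mask A logical mask from [sample_mask()], same shape as `m`.
#' @return List with `sparse` (the amputated `audiogram_matrix`) and `truth`
#'   (data frame `row`, `frequency`, `value` of the deleted entries).
#' @export
apply_mask <- function(m, mask) {
  stopifnot(inherits(m, "audiogram_matrix"))
  values <- unclass(m)
  mask <- unclass(mask)
  if (!all(dim(mask) == dim(values))) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match matrix ", paste(dim(values), collapse = "x"),
         call. = FALSE)
  }
  if (any(mask & is.na(values))) {
    stop("mask removes an already-missing entry", call. = FALSE)
  }
  idx <- which(mask, arr.ind = TRUE)
  truth <- data.frame(row = as.integer(idx[, 1]),
                      frequency = attr(m, "frequencies")[idx[, 2]],
                      value = values[idx])
  values[mask] <- NA_real_
  list(sparse = audiogram_matrix(values, frequencies = attr(m, "frequencies")),
       truth = truth[order(truth$row, truth$frequency), , drop = FALSE])
}
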