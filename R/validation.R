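#' Configuration for repeated nested cross-validation
#'
#' @param n_simulations Number of repeated simulations (instances are
#'   reshuffled before each, so fold partitions vary run to run).
#' @param outer_folds Outer folds for performance estimation.
#' @param inner_folds Inner folds for hyperparameter grid search.
#' @param ci_level Confidence level for across-simulation intervals.
#' @param seed Root RNG seed; every simulation and fold derives its own
#'   seed from it, so any cell is independently re-runnable.
#' @param safe_rmse_threshold Clinical safety bound in dB: pooled RMSE must
#'   stay below it for imputation to be considered safe.
#' @param cap Default cap on per-instance missing count for mirrored
#'   amputation.
#' @param max_grid Deterministic truncation of the hyperparameter grid (a
#'   runtime guard; the first `max_grid` rows of the expanded grid are
#'   searched).
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_simulations = 10L, outer_folds = 10L,
                      inner_folds = 10L, ci_level = 0.95, seed = 1L,
                      safe_rmse_threshold = 10, cap = 6L,
                      max_grid = Inf) {
  stopifnot(n_simulations >= 1, outer_folds >= 2, inner_folds >= 2)
  structure(list(n_simulations = as.integer(n_simulations),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 ci_level = ci_level, seed = as.integer(seed),
                 safe_rmse_threshold = safe_rmse_threshold,
                 cap = as.integer(cap), max_grid = max_grid),
            class = "cv_config")
}

# deterministic child seeds, kept well under 2^31
derive_seed <- function(root, sim, fold = 0L) {
  (as.integer(root) * 1009L + sim * 10007L + fold * 101L) %% 1000000007L
}

# split 1..n into k folds from a shuffled order; test subsets are disjoint
# and cover the data exactly once
fold_assignments <- function(n, k) {
  ord <- sample.int(n)
  split(ord, rep_len(seq_len(k), n))
}

expand_grid_list <- function(grid, max_grid = Inf) {
  if (length(grid) == 0) return(list(list()))
  df <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nrow(df) > max_grid) df <- df[seq_len(max_grid), , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# fit a candidate on amputated training data and score it on the masked
# entries of an amputated evaluation set
fit_score <- function(family, hp, sparse_fit, dense_fit, sparse_eval,
                      truth_eval, seed) {
  tryCatch({
    fit <- fit_imputer(imputer_spec(family, hp, grid = list()),
                       sparse_fit, truth = dense_fit, seed = seed,
                       strict = FALSE)
    completed <- impute(fit, sparse_eval)
    s <- score_against_truth(completed, truth_eval)
    rmse(s$y, s$f)
  }, error = function(e) NA_real_)   # degenerate inner split: drop candidate
}

# one outer fold: profile, densify, amputate, tune, refit, score
run_fold <- function(train, test, spec, distribution, quantity, k, cap, cfg,
                     fold_seed) {
  set.seed(fold_seed)
  prof_tr <- profile_sparsity(train)
  prof_te <- profile_sparsity(test)
  dense_tr <- complete_cases(train)
  dense_te <- complete_cases(test)
  if (nrow(dense_te) == 0 || nrow(dense_tr) < cfg$inner_folds) {
    stop("dense fold too small (", nrow(dense_tr), " train / ",
         nrow(dense_te), " test complete cases); reduce the number of ",
         "folds or supply more data", call. = FALSE)
  }
  pol_tr <- mask_policy(distribution, quantity, k = k, cap = cap,
                        profile = prof_tr,
                        frequencies = attr(train, "frequencies"))
  pol_te <- mask_policy(distribution, quantity, k = k, cap = cap,
                        profile = prof_te,
                        frequencies = attr(test, "frequencies"))

  candidates <- expand_grid_list(spec$grid, cfg$max_grid)
  chosen <- spec$hyperparameters
  if (length(candidates) > 1) {
    inner <- fold_assignments(nrow(dense_tr), cfg$inner_folds)
    scores <- matrix(NA_real_, length(inner), length(candidates))
    for (g in seq_along(inner)) {
      val_dense <- dense_tr[inner[[g]], ]
      fit_dense <- dense_tr[-inner[[g]], ]
      amp_fit <- apply_mask(fit_dense, sample_mask(nrow(fit_dense), pol_tr))
      amp_val <- apply_mask(val_dense, sample_mask(nrow(val_dense), pol_tr))
      if (nrow(amp_val$truth) == 0) next
      for (c in seq_along(candidates)) {
        hp <- utils::modifyList(spec$hyperparameters, candidates[[c]])
        scores[g, c] <- fit_score(spec$family, hp, amp_fit$sparse, fit_dense,
                                  amp_val$sparse, amp_val$truth,
                                  seed = fold_seed)
      }
    }
    mean_rmse <- colMeans(scores, na.rm = TRUE)
    if (any(is.finite(mean_rmse))) {
      chosen <- utils::modifyList(spec$hyperparameters,
                                  candidates[[which.min(mean_rmse)]])
    }
  }

  amp_tr <- apply_mask(dense_tr, sample_mask(nrow(dense_tr), pol_tr))
  amp_te <- apply_mask(dense_te, sample_mask(nrow(dense_te), pol_te))
  fit <- fit_imputer(imputer_spec(spec$family, chosen, grid = list()),
                     amp_tr$sparse, truth = dense_tr, seed = fold_seed,
                     strict = FALSE)
  completed <- impute(fit, amp_te$sparse)
  list(scores = score_against_truth(completed, amp_te$truth),
       chosen = chosen)
}

run_one_simulation <- function(parent, spec, distribution, quantity, k, cap,
                               cfg, sim) {
  set.seed(derive_seed(cfg$seed, sim))
  folds <- fold_assignments(nrow(parent), cfg$outer_folds)
  pooled <- vector("list", length(folds))
  chosen <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- parent[folds[[f]], ]
    train <- parent[-folds[[f]], ]
    res <- run_fold(train, test, spec, distribution, quantity, k, cap, cfg,
                    fold_seed = derive_seed(cfg$seed, sim, f))
    pooled[[f]] <- res$scores
    chosen[[f]] <- res$chosen
  }
  scores <- do.call(rbind, pooled)
  list(mae = mae(scores$y, scores$f),
       rmse = rmse(scores$y, scores$f),
       r2 = r2(scores$y, scores$f),
       n_scored = nrow(scores), chosen = chosen)
}

#' Assess one imputation model with repeated nested cross-validation
#'
#' The assessment engine. Per simulation: instances are shuffled and split
#' into disjoint outer folds. Per fold, the sparsity of the train and test
#' subsets is profiled independently (after the split, so no information
#' leaks between them), incomplete instances are dropped to form dense
#' subsets, and each dense subset is amputated under the requested policy
#' (real-world removal weights come from each subset's own profile).
#' Hyperparameters are tuned by inner k-fold grid search on freshly
#' amputated splits of the dense training subset (objective: RMSE on masked
#' entries); the winner is refitted on the amputated training subset and
#' used to impute the amputated test subset. Scored entries are pooled
#' across all outer folds into per-simulation MAE / RMSE / R-squared, and
#' simulations are aggregated into means with t confidence intervals.
#'
#' @param parent Cleaned (possibly sparse) `audiogram_matrix`.
#' @param spec An [imputer_spec()] (its `grid` defines the search space).
#' @param distribution Sparsity distribution for amputation, see
#'   [make_weights()].
#' @param quantity `"fixed"` or `"mirrored"`, see [mask_policy()].
#' @param k Removals per instance for the fixed policy.
#' @param cap Cap for the mirrored policy (defaults to `cfg$cap`).
#' @param cfg A [cv_config()].
#' @return A `metric_report`: per-simulation metric table plus aggregated
#'   `mae`, `rmse`, `r2` (each mean + CI) and per-fold chosen
#'   hyperparameters.
#' @export
run_nested_cv <- function(parent, spec,
                          distribution = "real_world",
                          quantity = c("mirrored", "fixed"),
                          k = NULL, cap = NULL, cfg = cv_config()) {
  quantity <- match.arg(quantity)
  if (is.null(cap)) cap <- cfg$cap
  sims <- lapply(seq_len(cfg$n_simulations), function(s) {
    run_one_simulation(parent, spec, distribution, quantity, k, cap, cfg, s)
  })
  per_sim <- data.frame(sim = seq_along(sims),
                        mae = vapply(sims, `[[`, numeric(1), "mae"),
                        rmse = vapply(sims, `[[`, numeric(1), "rmse"),
                        r2 = vapply(sims, `[[`, numeric(1), "r2"),
                        n_scored = vapply(sims, `[[`, numeric(1), "n_scored"))
  if (any(per_sim$mae < 4)) {
    warning("pooled MAE below the ~5 dB audiometric test-retest noise ",
            "floor; on real data this suggests overfitting or data leakage",
            call. = FALSE)
  }
  agg <- if (nrow(per_sim) >= 2) {
    list(mae = aggregate_simulations(per_sim$mae, cfg$ci_level),
         rmse = aggregate_simulations(per_sim$rmse, cfg$ci_level),
         r2 = aggregate_simulations(per_sim$r2, cfg$ci_level))
  } else {
    list(mae = list(mean = per_sim$mae, lo = NA, hi = NA,
                    level = cfg$ci_level, n = 1),
         rmse = list(mean = per_sim$rmse, lo = NA, hi = NA,
                     level = cfg$ci_level, n = 1),
         r2 = list(mean = per_sim$r2, lo = NA, hi = NA,
                   level = cfg$ci_level, n = 1))
  }
  structure(list(model = spec$family, distribution = distribution,
                 quantity = quantity, k = k, cap = cap,
                 per_sim = per_sim, mae = agg$mae, rmse = agg$rmse,
                 r2 = agg$r2, seed = cfg$seed,
                 chosen = lapply(sims, `[[`, "chosen")),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s | %s/%s | %d sims\n", x$model,
              x$distribution, x$quantity, nrow(x$per_sim)))
  cat(sprintf("  MAE  %.2f (%.2f-%.2f)\n", x$mae$mean, x$mae$lo, x$mae$hi))
  cat(sprintf("  RMSE %.2f (%.2f-%.2f)\n", x$rmse$mean, x$rmse$lo, x$rmse$hi))
  cat(sprintf("  R2   %.3f (%.3f-%.3f)\n", x$r2$mean, x$r2$lo, x$r2$hi))
  invisible(x)
}

report_row <- function(rep, extra = list()) {
  base <- data.frame(model = rep$model, distribution = rep$distribution,
                     quantity = rep$quantity,
                     k = if (is.null(rep$k)) NA_integer_ else rep$k,
                     cap = if (is.null(rep$cap)) NA_integer_ else rep$cap,
                     mae = rep$mae$mean, mae_lo = rep$mae$lo, mae_hi = rep$mae$hi,
                     rmse = rep$rmse$mean, rmse_lo = rep$rmse$lo,
                     rmse_hi = rep$rmse$hi,
                     r2 = rep$r2$mean, r2_lo = rep$r2$lo, r2_hi = rep$r2$hi)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

#' Sweep amputation quantity and distribution
#'
#' Full factorial grid of [run_nested_cv()] over fixed per-instance removal
#' counts `k_range` and the requested sparsity distributions.
#'
#' @param parent Cleaned sparse `audiogram_matrix`.
#' @param specs List of [imputer_spec()]s.
#' @param k_range Integer vector of fixed removal counts.
#' @param distributions Character vector of distribution names.
#' @param cfg A [cv_config()] (sweep bands conventionally use
#'   `ci_level = 0.99`).
#' @return An `experiment_result` with a tidy `table` and the underlying
#'   `reports`.
#' @export
sweep_quantity_distribution <- function(parent, specs, k_range = 1:10,
                                        distributions = c("real_world", "random",
                                                          "terminal", "central"),
                                        cfg = cv_config(ci_level = 0.99)) {
  reports <- list(); rows <- list(); i <- 0
  for (spec in specs) for (d in distributions) for (k in k_range) {
    rep <- run_nested_cv(parent, spec, distribution = d,
                         quantity = "fixed", k = k, cfg = cfg)
    i <- i + 1
    reports[[i]] <- rep
    rows[[i]] <- report_row(rep)
  }
  structure(list(table = do.call(rbind, rows), reports = reports,
                 seed = cfg$seed),
            class = "experiment_result")
}

#' Model selection under mirrored real-world sparsity
#'
#' Runs every model under every distribution with the mirrored-count policy
#' (per-instance missing counts drawn from each subset's own histogram,
#' truncated at `cfg$cap`) and reports a model-selection table plus
#' pairwise Wilcoxon rank-sum comparisons of the per-simulation RMSE
#' samples at `alpha`.
#'
#' @param parent Cleaned sparse `audiogram_matrix`.
#' @param specs List of [imputer_spec()]s.
#' @param distributions Distributions to evaluate.
#' @param cfg A [cv_config()].
#' @param alpha Significance level for pairwise comparisons.
#' @return An `experiment_result` with `table`, `reports` and `comparisons`.
#' @export
select_model <- function(parent, specs,
                         distributions = c("real_world", "random",
                                           "terminal", "central"),
                         cfg = cv_config(), alpha = 0.01) {
  reports <- list(); rows <- list(); i <- 0
  for (d in distributions) for (spec in specs) {
    rep <- run_nested_cv(parent, spec, distribution = d,
                         quantity = "mirrored", cap = cfg$cap, cfg = cfg)
    i <- i + 1
    reports[[i]] <- rep
    rows[[i]] <- report_row(rep)
  }
  table <- do.call(rbind, rows)
  comparisons <- list(); ci <- 0
  for (d in distributions) {
    in_d <- reports[vapply(reports, function(r) r$distribution == d, logical(1))]
    if (length(in_d) < 2 || nrow(in_d[[1]]$per_sim) < 2) next
    for (a in seq_along(in_d)) for (b in seq_along(in_d)) {
      if (a >= b) next
      cmp <- compare_models(in_d[[a]]$per_sim$rmse, in_d[[b]]$per_sim$rmse,
                            alpha = alpha)
      ci <- ci + 1
      comparisons[[ci]] <- data.frame(
        distribution = d, model_a = in_d[[a]]$model, model_b = in_d[[b]]$model,
        p_value = cmp$p_value, verdict = cmp$verdict,
        rmse_a = cmp$mean_a, rmse_b = cmp$mean_b)
    }
  }
  structure(list(table = table, reports = reports,
                 comparisons = if (length(comparisons)) do.call(rbind, comparisons) else NULL,
                 seed = cfg$seed),
            class = "experiment_result")
}

#' Sweep dataset size
#'
#' Per simulation and size, the sparse parent is subsampled without
#' replacement \emph{before} profiling and the nested-CV machinery, so
#' small datasets also carry noisier sparsity profiles, as they would in
#' reality.
#'
#' @param parent Cleaned sparse `audiogram_matrix`.
#' @param specs List of [imputer_spec()]s.
#' @param sizes Integer vector of dataset sizes.
#' @param cfg A [cv_config()].
#' @return An `experiment_result` keyed by (model, size).
#' @export
sweep_dataset_size <- function(parent, specs,
                               sizes = c(20, 40, 80, 160, 320, 640, 1280),
                               cfg = cv_config(ci_level = 0.99)) {
  if (any(sizes > nrow(parent))) {
    stop("requested size exceeds available instances (", nrow(parent), ")",
         call. = FALSE)
  }
  reports <- list(); rows <- list(); i <- 0
  for (spec in specs) for (size in sizes) {
    sims <- lapply(seq_len(cfg$n_simulations), function(s) {
      set.seed(derive_seed(cfg$seed, s, 999L) + size)
      sub <- parent[sample.int(nrow(parent), size), ]
      run_one_simulation(sub, spec, "real_world", "mirrored",
                         k = NULL, cap = cfg$cap, cfg, s)
    })
    per_sim <- data.frame(sim = seq_along(sims),
                          mae = vapply(sims, `[[`, numeric(1), "mae"),
                          rmse = vapply(sims, `[[`, numeric(1), "rmse"),
                          r2 = vapply(sims, `[[`, numeric(1), "r2"))
    rep <- list(model = spec$family, distribution = "real_world",
                quantity = "mirrored", k = NULL, cap = cfg$cap,
                per_sim = per_sim,
                mae = aggregate_simulations(per_sim$mae, cfg$ci_level),
                rmse = aggregate_simulations(per_sim$rmse, cfg$ci_level),
                r2 = aggregate_simulations(per_sim$r2, cfg$ci_level),
                seed = cfg$seed)
    class(rep) <- "metric_report"
    i <- i + 1
    reports[[i]] <- rep
    rows[[i]] <- report_row(rep, extra = list(size = size))
  }
  structure(list(table = do.call(rbind, rows), reports = reports,
                 seed = cfg$seed),
            class = "experiment_result")
}

#' Largest safely imputable missing count
#'
#' Scans a quantity sweep upward from k = 1 and returns, per model and
#' distribution, the largest k whose mean RMSE stays below the clinical
#' threshold before the first crossing; 0 when even k = 1 is unsafe.
#'
#' @param sweep An `experiment_result` from [sweep_quantity_distribution()]
#'   covering contiguous k from 1.
#' @param threshold Safety bound in dB RMSE (default 10).
#' @return Data frame with `model`, `distribution`, `safe_cap`.
#' @export
find_safe_cap <- function(sweep, threshold = 10) {
  tab <- sweep$table
  out <- list(); i <- 0
  for (mod in unique(tab$model)) for (d in unique(tab$distribution)) {
    cell <- tab[tab$model == mod & tab$distribution == d, ]
    if (nrow(cell) == 0) next
    cell <- cell[order(cell$k), ]
    ks <- cell$k
    if (ks[1] != 1 || any(diff(ks) != 1)) {
      stop("safe-cap scan needs contiguous k starting at 1; got k = ",
           paste(ks, collapse = ","), call. = FALSE)
    }
    safe <- 0L
    for (r in seq_len(nrow(cell))) {
      if (cell$rmse[r] < threshold) safe <- ks[r] else break
    }
    i <- i + 1
    out[[i]] <- data.frame(model = mod, distribution = d, safe_cap = safe)
  }
  do.call(rbind, out)
}
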