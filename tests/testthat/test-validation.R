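# machinery tests run on small synthetic sets with mild uniform missingness
# so that every fold has plenty of complete cases and cheap models suffice
mild_parent <- function(n = 240, seed = 157) {
  generate_sparse(generator_params(n = n, missing_rates = rep(0.15, 11),
                                   seed = seed))
}

test_that("outer test folds are disjoint and cover the data exactly once", {
  set.seed(163)
  folds <- audimpute:::fold_assignments(103, 10)
  all_idx <- sort(unname(unlist(folds)))
  expect_equal(all_idx, 1:103)
  expect_equal(length(folds), 10)
})

test_that("nested cross-validation is reproducible and well-formed", {
  parent <- mild_parent()
  cfg <- cv_config(n_simulations = 2, outer_folds = 3, inner_folds = 2,
                   seed = 11)
  rep1 <- run_nested_cv(parent, imputer_spec("UI"), "real_world", "mirrored",
                        cfg = cfg)
  rep2 <- run_nested_cv(parent, imputer_spec("UI"), "real_world", "mirrored",
                        cfg = cfg)
  expect_identical(rep1$per_sim, rep2$per_sim)
  expect_equal(nrow(rep1$per_sim), 2)
  expect_true(all(rep1$per_sim$rmse >= rep1$per_sim$mae))
  expect_true(rep1$rmse$lo <= rep1$rmse$mean && rep1$rmse$mean <= rep1$rmse$hi)
  # the inner search picked one of the legal strategies per fold
  strategies <- unlist(lapply(rep1$chosen, function(sim)
    vapply(sim, `[[`, character(1), "strategy")))
  expect_true(all(strategies %in% c("mean", "median", "mode")))
})

test_that("interpolation beats univariate imputation in the full pipeline", {
  parent <- mild_parent(300, seed = 167)
  cfg <- cv_config(n_simulations = 2, outer_folds = 3, inner_folds = 2,
                   seed = 13)
  ui <- run_nested_cv(parent, imputer_spec("UI"), "random", "fixed", k = 3,
                      cfg = cfg)
  int <- run_nested_cv(parent, imputer_spec("INT"), "random", "fixed", k = 3,
                       cfg = cfg)
  expect_lt(int$rmse$mean, ui$rmse$mean)
})

test_that("fold-size guards trigger on infeasible configurations", {
  parent <- mild_parent(30, seed = 173)
  cfg <- cv_config(n_simulations = 1, outer_folds = 10, inner_folds = 10,
                   seed = 17)
  expect_error(run_nested_cv(parent, imputer_spec("UI"), "random", "fixed",
                             k = 2, cfg = cfg), "fold")
  expect_error(sweep_dataset_size(parent, list(imputer_spec("UI")),
                                  sizes = 5000), "exceeds")
})

test_that("quantity sweep table is tidy and the safe-cap scan is correct", {
  parent <- mild_parent(300, seed = 179)
  cfg <- cv_config(n_simulations = 2, outer_folds = 3, inner_folds = 2,
                   seed = 19, ci_level = 0.99)
  sweep <- suppressWarnings(
    sweep_quantity_distribution(parent, list(imputer_spec("INT")),
                                k_range = 1:3,
                                distributions = "random", cfg = cfg))
  expect_equal(nrow(sweep$table), 3)
  expect_equal(sweep$table$k, 1:3)
  caps <- find_safe_cap(sweep, threshold = 10)
  # scan semantics against the computed table itself
  below <- sweep$table$rmse < 10
  expected <- if (!below[1]) 0L else max(which(cumprod(below) == 1))
  expect_equal(caps$safe_cap, expected)
  # a threshold of 0 dB is never safe
  expect_equal(find_safe_cap(sweep, threshold = 0)$safe_cap, 0L)
  # non-contiguous grids are rejected
  sweep$table <- sweep$table[c(1, 3), ]
  expect_error(find_safe_cap(sweep), "contiguous")
})

test_that("model selection reports tables and pairwise comparisons", {
  parent <- mild_parent(300, seed = 181)
  cfg <- cv_config(n_simulations = 2, outer_folds = 3, inner_folds = 2,
                   seed = 23, cap = 4L)
  sel <- suppressWarnings(
    select_model(parent, list(imputer_spec("UI"), imputer_spec("INT")),
                 distributions = "random", cfg = cfg))
  expect_equal(nrow(sel$table), 2)
  expect_equal(nrow(sel$comparisons), 1)
  expect_true(sel$comparisons$verdict %in%
                c("a_better", "b_better", "indistinguishable"))
})

test_that("dataset-size sweep keeps per-size reports separate", {
  parent <- mild_parent(400, seed = 191)
  cfg <- cv_config(n_simulations = 2, outer_folds = 3, inner_folds = 2,
                   seed = 29, cap = 4L)
  sw <- sweep_dataset_size(parent, list(imputer_spec("UI")),
                           sizes = c(120, 240), cfg = cfg)
  expect_equal(sw$table$size, c(120, 240))
  expect_true(all(is.finite(sw$table$rmse)))
})
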