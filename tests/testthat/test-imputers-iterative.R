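test_that("chained-equation imputation honors its output contracts", {
  tr <- gen_dense(80, seed = 61)
  q <- gen_dense(10, seed = 67)
  # a fully observed query comes back unchanged
  out <- impute_mice(tr, q, "l2", m = 3)
  expect_equal(unclass(out), unclass(q))
  # m = 0 returns the univariate initialization
  pol <- mask_policy("random", "fixed", k = 2)
  set.seed(71)
  amp <- apply_mask(q, sample_mask(10, pol))
  init_out <- impute_mice(tr, amp$sparse, "l2", m = 0, init = "mean")
  ui_out <- impute(fit_univariate(tr, "mean"), amp$sparse)
  expect_equal(unclass(init_out), unclass(ui_out))
  # sice output is the mean across rounds, not the last round
  last <- impute_mice(tr, amp$sparse, "l2", m = 5, output = "last_round")
  sice <- impute_mice(tr, amp$sparse, "l2", m = 5, output = "sice_mean")
  expect_false(identical(unclass(last), unclass(sice)))
  # deterministic given data and hyperparameters
  again <- impute_mice(tr, amp$sparse, "l2", m = 5, output = "last_round")
  expect_identical(unclass(last), unclass(again))
})

test_that("chained equations recover an exactly collinear masked column", {
  set.seed(73)
  n <- 120
  a <- runif(n, 20, 100)
  v <- cbind(a, a, runif(n, 20, 100), runif(n, 20, 100))
  freqs <- c(125, 250, 500, 1000)
  tr <- audiogram_matrix(v, frequencies = freqs)
  qv <- cbind(a[1:20], a[1:20], v[1:20, 3], v[1:20, 4])
  qv[1:10, 2] <- NA                      # mask half of the duplicate column
  q <- audiogram_matrix(qv, frequencies = freqs)
  out <- unclass(impute_mice(tr, q, "l2", lambda = 0.01, m = 5))
  expect_true(all(abs(out[1:10, 2] - a[1:10]) <= 0.5))
})

test_that("boosted-tree imputation is supervised, sane and reproducible", {
  dense <- gen_dense(400, seed = 79)
  pol <- mask_policy("random", "fixed", k = 3)
  set.seed(83)
  amp <- apply_mask(dense, sample_mask(400, pol))
  q <- apply_mask(gen_dense(60, seed = 89), sample_mask(60, pol))
  # truth is required
  expect_error(fit_imputer(imputer_spec("XGB"), amp$sparse), "truth")
  # constant training target predicts that constant
  cv <- unclass(dense); cv[, 1] <- 60
  cdense <- audiogram_matrix(cv, frequencies = freq11)
  cam <- apply_mask(cdense, sample_mask(400, pol))
  cq_v <- unclass(q$sparse); cq_v[, 1] <- NA
  cq <- audiogram_matrix(cq_v, frequencies = freq11)
  out <- impute_gbt(cam$sparse, cdense, cq, n_estimators = 50, seed = 1)
  expect_true(all(abs(unclass(out)[, 1] - 60) < 1e-3))
  # beats univariate imputation on correlated data
  gbt <- impute_gbt(amp$sparse, dense, q$sparse, n_estimators = 100, seed = 1)
  ui <- impute(fit_univariate(amp$sparse), q$sparse)
  s_gbt <- scores_for(gbt, q$truth)
  s_ui <- scores_for(ui, q$truth)
  expect_lt(rmse(s_gbt$y, s_gbt$f), rmse(s_ui$y, s_ui$f))
  # reproducible under seed even with subsampling
  a <- impute_gbt(amp$sparse, dense, q$sparse, n_estimators = 50,
                  subsample = 0.8, seed = 7)
  b <- impute_gbt(amp$sparse, dense, q$sparse, n_estimators = 50,
                  subsample = 0.8, seed = 7)
  expect_identical(unclass(a), unclass(b))
})

test_that("perceptron imputation learns correlated structure and is seeded", {
  dense <- gen_dense(600, seed = 97)
  pol <- mask_policy("random", "fixed", k = 3)
  set.seed(101)
  amp <- apply_mask(dense, sample_mask(600, pol))
  q <- apply_mask(gen_dense(80, seed = 103), sample_mask(80, pol))
  nn <- impute_mlp(amp$sparse, dense, q$sparse, hidden_layers = 1,
                   nodes_per_layer = 32, learning_rate = 3e-3,
                   epochs = 150, seed = 5)
  ui <- impute(fit_univariate(amp$sparse), q$sparse)
  s_nn <- scores_for(nn, q$truth)
  s_ui <- scores_for(ui, q$truth)
  expect_lt(rmse(s_nn$y, s_nn$f), rmse(s_ui$y, s_ui$f))
  # zero hidden layers: the linear-regression limit still trains and fills
  lin <- impute_mlp(amp$sparse, dense, q$sparse, hidden_layers = 0,
                    learning_rate = 3e-3, epochs = 100, seed = 5)
  expect_false(any(is.na(unclass(lin))))
  s_lin <- scores_for(lin, q$truth)
  expect_lt(rmse(s_lin$y, s_lin$f), rmse(s_ui$y, s_ui$f))
  # reproducible under seed
  a <- impute_mlp(amp$sparse, dense, q$sparse, epochs = 50, seed = 9)
  b <- impute_mlp(amp$sparse, dense, q$sparse, epochs = 50, seed = 9)
  expect_identical(unclass(a), unclass(b))
})

test_that("all imputers clip to the audiometer range and keep observed cells", {
  dense <- gen_dense(150, seed = 107)
  pol <- mask_policy("random", "fixed", k = 4)
  set.seed(109)
  amp_tr <- apply_mask(dense, sample_mask(150, pol))
  q <- apply_mask(gen_dense(30, seed = 113), sample_mask(30, pol))
  obs <- !is.na(unclass(q$sparse))
  fits <- list(
    impute(fit_univariate(dense), q$sparse),
    impute_interpolation(q$sparse, "cubic_spline"),
    impute_knn(dense, q$sparse, k = 3),
    impute_mice(amp_tr$sparse, q$sparse, "l1", m = 3),
    impute_gbt(amp_tr$sparse, dense, q$sparse, n_estimators = 30, seed = 1),
    impute_mlp(amp_tr$sparse, dense, q$sparse, epochs = 30, seed = 1))
  for (out in fits) {
    v <- unclass(out)
    expect_false(any(is.na(v)))
    expect_true(all(v >= 0 & v <= 120))
    expect_equal(v[obs], unclass(q$sparse)[obs])
  }
})

test_that("imputer specs validate hyperparameter names", {
  expect_error(imputer_spec("KNN", list(bogus = 1)), "bogus")
  expect_error(imputer_spec("MICE", grid = list(bogus = 1)), "bogus")
  spec <- imputer_spec("KNN", list(k = 7L))
  expect_equal(spec$hyperparameters$k, 7L)
  expect_equal(spec$hyperparameters$weighting, "distance")
})
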