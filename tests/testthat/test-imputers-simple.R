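# independent closed form for two-point linear interpolation:
# y1 = (y2 - y0)/(x2 - x0) * (x1 - x0) + y0
linear_oracle <- function(xq, x0, y0, x2, y2) {
  (y2 - y0) / (x2 - x0) * (xq - x0) + y0
}

test_that("univariate imputation fills column statistics", {
  v <- rbind(c(10, 0, 5, 7), c(20, 0, NA, 9), c(30, 120, NA, 11))
  m <- audiogram_matrix(v, frequencies = c(125, 250, 500, 1000))
  q <- audiogram_matrix(rbind(c(NA, NA, 50, NA)), frequencies = c(125, 250, 500, 1000))
  out <- vals(impute(fit_univariate(m, "mean"), q))
  expect_equal(out[1, 1], 20)
  expect_equal(out[1, 3], 50)                # observed passes through
  out_mode <- vals(impute(fit_univariate(m, "mode"), q))
  expect_equal(out_mode[1, 2], 0)
  out_med <- vals(impute(fit_univariate(m, "median"), q))
  expect_equal(out_med[1, 1], 20)
  # a column with no observed values cannot be fitted
  v[, 3] <- NA
  expect_error(fit_univariate(audiogram_matrix(v, frequencies = c(125, 250, 500, 1000))),
               "500")
})

test_that("linear interpolation matches the two-point closed form", {
  set.seed(31)
  x <- log2(freq11)
  for (rep in 1:25) {
    y_full <- runif(11, 20, 100)
    miss <- sample(11, sample(1:8, 1))
    y <- y_full; y[miss] <- NA
    obs <- which(!is.na(y))
    if (length(obs) < 2) next
    out <- interpolate_instance(y, x, "linear")
    for (j in miss) {
      xo <- x[obs]; yo <- y[obs]
      seg <- findInterval(x[j], xo)
      seg <- min(max(seg, 1), length(obs) - 1)
      expected <- linear_oracle(x[j], xo[seg], yo[seg], xo[seg + 1], yo[seg + 1])
      expect_equal(out[j], min(max(expected, 0), 120), tolerance = 1e-9)
    }
    expect_equal(out[obs], y_full[obs])      # observed untouched
  }
})

test_that("interpolation midpoint, monotonicity, extrapolation and clipping", {
  # equispaced axis: observed 20 and 40 around one gap -> midpoint 30
  y <- c(20, NA, 40)
  expect_equal(interpolate_instance(y, 1:3, "linear")[2], 30)
  # pchip preserves monotone runs between neighbors
  ym <- c(10, NA, 30, NA, 60, NA, 80, NA, 100, NA, 110)
  out <- interpolate_instance(ym, log2(freq11), "pchip")
  expect_true(all(diff(out) >= -1e-9))
  # linear extrapolation above the audiometer ceiling is clipped to 120
  ye <- c(100, 119, rep(NA, 9))
  oute <- interpolate_instance(ye, seq_len(11), "linear")
  expect_equal(oute[3:11], rep(120, 9))
  # single observed point: constant extension for every method
  y1 <- c(NA, 55, rep(NA, 9))
  for (meth in c("linear", "pchip", "cubic_spline")) {
    expect_equal(interpolate_instance(y1, log2(freq11), meth),
                 rep(55, 11))
  }
  # no observed points at all cannot be interpolated
  expect_error(interpolate_instance(rep(NA_real_, 11), log2(freq11), "linear"),
               "no observed")
  # cubic spline with two points falls back to the linear interpolant
  y2 <- c(20, NA, 40, rep(NA, 8))
  expect_equal(interpolate_instance(y2, 1:11, "cubic_spline"),
               interpolate_instance(y2, 1:11, "linear"))
})

test_that("interpolation imputes whole matrices row-independently", {
  m <- gen_dense(20, seed = 37)
  pol <- mask_policy("random", "fixed", k = 3)
  set.seed(41)
  amp <- apply_mask(m, sample_mask(20, pol))
  for (meth in c("linear", "pchip", "cubic_spline")) {
    out <- impute_interpolation(amp$sparse, meth)
    v <- unclass(out)
    expect_false(any(is.na(v)))
    expect_true(all(v >= 0 & v <= 120))
    obs <- !is.na(unclass(amp$sparse))
    expect_equal(v[obs], unclass(amp$sparse)[obs])
  }
})

test_that("knn reproduces the worked distance-weighting example", {
  # query shares one feature (value 0) with three donors at distances 1, 1, 2;
  # donor values for the missing feature are 10, 20, 60
  tr <- audiogram_matrix(rbind(c(1, 10), c(-1, 20), c(2, 60)),
                         frequencies = c(125, 250))
  q <- audiogram_matrix(rbind(c(0, NA)), frequencies = c(125, 250))
  uni <- vals(impute_knn(tr, q, k = 3, weighting = "uniform"))
  expect_equal(uni[1, 2], 30)
  dis <- vals(impute_knn(tr, q, k = 3, weighting = "distance"))
  expect_equal(dis[1, 2], (10 / 1 + 20 / 1 + 60 / 2) / (1 + 1 + 1 / 2))  # = 24
})

test_that("knn copies an identical donor and matches a brute-force oracle", {
  tr <- tiny_dense(10, freqs = freq11[1:5], seed = 43)
  q_vals <- unclass(tr)[3, , drop = FALSE]
  q_vals[1, 4] <- NA
  q <- audiogram_matrix(q_vals, frequencies = freq11[1:5])
  out <- vals(impute_knn(tr, q, k = 1))
  expect_equal(out[1, 4], vals(tr)[3, 4])

  # independent oracle: plain loops, no shared code with the implementation
  knn_oracle <- function(tr, q, k, weighting) {
    trv <- unclass(tr); qv <- unclass(q); out <- qv
    for (s in seq_len(nrow(qv))) {
      for (j in which(is.na(qv[s, ]))) {
        d <- rep(NA_real_, nrow(trv))
        for (i in seq_len(nrow(trv))) {
          shared <- which(!is.na(qv[s, ]) & !is.na(trv[i, ]))
          if (length(shared) > 0) {
            d[i] <- sqrt(mean((qv[s, shared] - trv[i, shared])^2))
          }
        }
        elig <- which(!is.na(trv[, j]) & !is.na(d))
        elig <- elig[order(d[elig])]
        nb <- elig[seq_len(min(k, length(elig)))]
        if (weighting == "uniform") {
          out[s, j] <- mean(trv[nb, j])
        } else if (any(d[nb] == 0)) {
          out[s, j] <- mean(trv[nb[d[nb] == 0], j])
        } else {
          w <- (1 / d[nb]); w <- w / sum(w)
          out[s, j] <- sum(w * trv[nb, j])
        }
      }
    }
    pmin(pmax(out, 0), 120)
  }

  set.seed(47)
  train <- gen_dense(50, seed = 47)
  pol <- mask_policy("random", "fixed", k = 3)
  qm <- apply_mask(gen_dense(20, seed = 53), sample_mask(20, pol))$sparse
  for (wgt in c("uniform", "distance")) {
    got <- unclass(impute_knn(train, qm, k = 5, weighting = wgt))
    want <- knn_oracle(train, qm, 5, wgt)
    tol <- if (wgt == "uniform") 0 else 1e-9
    expect_equal(got, want, tolerance = tol, ignore_attr = TRUE)
  }
})

test_that("knn falls back to the column mean when no donor is usable", {
  # donors observe the target feature but share nothing with the query
  tr <- audiogram_matrix(rbind(c(NA, 10), c(NA, 30)), frequencies = c(125, 250))
  q <- audiogram_matrix(rbind(c(50, NA)), frequencies = c(125, 250))
  out <- impute_knn(tr, q, k = 2)
  expect_equal(vals(out)[1, 2], 20)     # training column mean
  expect_equal(attr(out, "n_fallback"), 1L)
})
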