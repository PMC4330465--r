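printed_pic50 <- c(4.89, 3.35, 2.00, 4.16, 4.00, 4.89, 2.37, 4.92, 4.17,
                   3.49, 2.61, 4.11, 4.60, 5.18, 4.65, 3.96, 2.38, 3.87)

test_that("constant models predict the training mean or median", {
  expect_equal(ref_constant(c(1, 2, 3), "mean")$value, 2)
  # the packaged 18-compound training set
  act <- read_activity_csv(ache_training_path(), role = "train")
  expect_equal(act$pic50, printed_pic50)
  expect_equal(round(ref_constant(act$pic50, "mean")$value, 3), 3.867)
  # even-sized set: midpoint of the two central sorted values
  expect_equal(ref_constant(act$pic50, "median")$value, 4.055)
  preds <- predict_reference(ref_constant(act$pic50, "mean"),
                             data.frame(id = c("t1", "t2")))
  expect_equal(unname(preds), rep(mean(printed_pic50), 2))
})

test_that("univariate regression reference reports the straight line and R2", {
  x <- c(1, 2, 3, 4, 5)
  m <- ref_univariate(x, 2 * x + 1, name = "logP")
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 1)
  expect_equal(m$r2, 1)

  # orthogonal construction: R2 exactly 0
  x0 <- c(-1, 1, -1, 1)
  m0 <- ref_univariate(x0, c(1, 1, -1, -1), name = "TPSA")
  expect_equal(m0$r2, 0)

  # R2 is the squared Pearson correlation
  set.seed(6)
  xr <- rnorm(15); yr <- 0.4 * xr + rnorm(15)
  expect_equal(ref_univariate(xr, yr)$r2, cor(xr, yr)^2, tolerance = 1e-12)
  expect_error(ref_univariate(rep(1, 5), rnorm(5)), "constant")

  d <- matrix(c(6, 7), 2, 1, dimnames = list(c("t1", "t2"), "logP"))
  expect_equal(unname(predict_reference(m, data.frame(id = c("t1", "t2")), d)),
               c(13, 15))
})

test_that("nearest-neighbour models follow the map or the computed proxy", {
  act <- read_activity_csv(ache_training_path(), role = "train")
  map <- data.frame(test_id = "t1", train_id = "14")
  nn <- ref_nearest_neighbor(act, map = map)
  expect_equal(unname(predict_reference(nn, data.frame(id = "t1"))), 5.18)
  # uncovered test compound: per-compound failure, not an error
  p <- predict_reference(nn, data.frame(id = c("t1", "t9")))
  expect_true(is.na(p["t9"]))
  expect_identical(attr(p, "failures"), "t9")
  expect_error(ref_nearest_neighbor(act, map = data.frame(test_id = "t", train_id = "99")),
               "unknown training id")

  # computed policy equals brute-force scaled Euclidean argmin
  set.seed(14)
  tr_d <- matrix(rnorm(8 * 3), 8, 3,
                 dimnames = list(paste0("tr", 1:8), c("a", "b", "c")))
  te_d <- matrix(rnorm(4 * 3), 4, 3,
                 dimnames = list(paste0("te", 1:4), c("a", "b", "c")))
  train <- data.frame(id = rownames(tr_d), pic50 = rnorm(8))
  nn2 <- ref_nearest_neighbor(train, train_descriptors = tr_d)
  got <- predict_reference(nn2, data.frame(id = rownames(te_d)), te_d)
  sc <- autoscale(tr_d)
  tes <- apply_scaling(sc$params, te_d)
  want <- apply(tes, 1, function(r) {
    train$pic50[which.min(colSums((t(sc$scaled) - r)^2))]
  })
  expect_equal(unname(got), unname(want))

  # self-map on the training set gives perfect predictions
  self <- ref_nearest_neighbor(act, map = data.frame(test_id = act$id, train_id = act$id))
  expect_equal(rmsep(act$pic50, predict_reference(self, act)), 0)
})

test_that("the small PLS reference reuses the engine with the component rule", {
  set.seed(22)
  x <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("logP", "TPSA", "vdw_area")))
  y <- x[, 1] + rnorm(20, 0, 0.2)
  m <- ref_small_pls(x, y)
  expect_s3_class(m$model, "pls_model")
  te <- matrix(rnorm(6), 2, 3, dimnames = list(c("t1", "t2"), colnames(x)))
  p <- predict_reference(m, data.frame(id = c("t1", "t2")), te)
  expect_equal(unname(p), predict(m$model, te)$estimate)
})

test_that("reference evaluation table pools sets by the RMSEP union identity", {
  meas <- list(s1 = c(1, 2, 3), s2 = c(4, 5))
  perfect <- list(s1 = c(1, 2, 3), s2 = c(4, 5))
  offset <- lapply(meas, function(v) v + 0.7)
  tab <- evaluate_references(list(perfect = perfect, offset = offset), meas)
  expect_equal(unname(unlist(tab["perfect", ])), c(0, 0, 0))
  expect_equal(unname(unlist(tab["offset", ])), rep(0.7, 3), tolerance = 1e-12)
  # union column obeys the pooled identity
  ns <- vapply(meas, length, numeric(1))
  expect_equal(tab["offset", "combined"]^2,
               sum(ns * unlist(tab["offset", c("s1", "s2")])^2) / sum(ns),
               tolerance = 1e-12)
})

test_that("the training mean minimises RMSEP among constant predictors", {
  y <- printed_pic50
  base <- rmsep(y, rep(mean(y), length(y)))
  for (d in c(-0.5, -0.1, 0.1, 0.5)) {
    expect_gt(rmsep(y, rep(mean(y) + d, length(y))), base)
  }
})

test_that("constant-model RMSEP matches the closed form sqrt(var + bias^2)", {
  set.seed(33)
  mu_train <- 4; mu_test <- 4.8; sd_test <- 0.6; n <- 4000
  test_y <- rnorm(n, mu_test, sd_test)
  got <- rmsep(test_y, rep(mu_train, n))
  want <- sqrt(sd_test^2 + (mu_test - mu_train)^2)
  expect_equal(got, want, tolerance = 0.03) # Monte-Carlo slack
})
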