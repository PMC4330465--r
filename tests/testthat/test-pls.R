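test_that("one-component PLS on a single descriptor is the scaled OLS slope", {
  set.seed(1)
  x <- matrix(rnorm(20), dimnames = list(NULL, "d1"))
  y <- 2 * x[, 1] + rnorm(20, 0, 0.3)
  m <- pls_fit(x, y, 1)
  # in autoscaled space the univariate OLS slope is the Pearson correlation
  expect_equal(unname(m$coefficients), cor(x[, 1], y), tolerance = 1e-10)
  expect_equal(m$fitted, unname(fitted(lm(y ~ x[, 1]))), tolerance = 1e-10)
})

test_that("full-rank PLS reproduces the least-squares fit", {
  set.seed(2)
  for (i in 1:5) {
    n <- sample(10:20, 1); k <- sample(3:6, 1)
    x <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("d", 1:k)))
    y <- rnorm(n)
    m <- pls_fit(x, y, k)
    expect_equal(m$fitted, unname(fitted(lm(y ~ x))), tolerance = 1e-8)
    expect_equal(m$r2y, summary(lm(y ~ x))$r.squared, tolerance = 1e-8)
  }
})

test_that("NIPALS agrees with the Krylov-subspace closed form", {
  for (seed in 1:15) {
    prob <- random_problem(seed, n = sample(10:25, 1), k = sample(3:10, 1))
    for (a in 1:3) {
      m <- pls_fit(prob$x, prob$y, a)
      oracle <- helland_pls_fitted(prob$x, prob$y, a)
      expect_equal(m$fitted, oracle$fitted, tolerance = 1e-8)
      expect_equal(unname(m$coefficients), oracle$coefficients, tolerance = 1e-6)
    }
  }
})

test_that("score vectors are mutually orthogonal and R2Y well defined", {
  prob <- random_problem(31, n = 18, k = 8)
  m <- pls_fit(prob$x, prob$y, 3)
  g <- crossprod(m$scores)
  off <- g[upper.tri(g)]
  expect_true(all(abs(off) < 1e-8 * max(diag(g))))
  expect_gte(m$r2y, 0)
  expect_lte(m$r2y, 1)
  expect_lte(m$adj_r2y, m$r2y)
})

test_that("column permutations permute coefficients identically", {
  prob <- random_problem(8, n = 16, k = 5)
  m <- pls_fit(prob$x, prob$y, 2)
  perm <- c(3, 5, 1, 2, 4)
  m2 <- pls_fit(prob$x[, perm], prob$y, 2)
  expect_equal(unname(m2$coefficients), unname(m$coefficients[perm]),
               tolerance = 1e-10)
})

test_that("RMSEE uses the N-1-A denominator and is non-increasing in A", {
  # hand case: residuals (1,-1,1,-1) with A = 1 -> sqrt(4 / (4 - 1 - 1))
  y <- c(1, 2, 3, 4); fitted <- y - c(1, -1, 1, -1)
  fake <- structure(list(rmsee = sqrt(sum((y - fitted)^2) / (4 - 1 - 1))),
                    class = "pls_model")
  expect_equal(rmsee(fake), sqrt(2))

  # the residual sum of squares can only shrink with extra components;
  # RMSEE itself need not, because its denominator N-1-A shrinks too
  prob <- random_problem(5, n = 20, k = 6)
  sse <- vapply(1:4, function(a) {
    m <- pls_fit(prob$x, prob$y, a)
    m$rmsee^2 * (m$n - 1 - a)
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-10))

  exact <- pls_fit(prob$x, drop(prob$x %*% rep(1, 6)), 6)
  expect_lt(exact$rmsee, 1e-8)
})

test_that("RMSEP is the plain root mean square with divisor N", {
  expect_equal(rmsep(c(1, 2), c(1, 2)), 0)
  expect_equal(rmsep(c(1, 1), c(0.5, 1.5)), 0.5)
  expect_error(rmsep(1:3, 1:2), "mismatch")
  expect_error(rmsep(numeric(0), numeric(0)), "empty")
  # pooled-set identity: RMSEP(union)^2 = sum n_s RMSEP_s^2 / sum n_s
  set.seed(12)
  sets <- lapply(c(5, 7, 20), function(n) list(m = rnorm(n), p = rnorm(n)))
  per <- vapply(sets, function(s) rmsep(s$m, s$p), numeric(1))
  ns <- vapply(sets, function(s) length(s$m), numeric(1))
  pooled <- rmsep(unlist(lapply(sets, `[[`, "m")), unlist(lapply(sets, `[[`, "p")))
  expect_equal(pooled^2, sum(ns * per^2) / sum(ns), tolerance = 1e-12)
})

test_that("leave-one-out Q2 is exact in structure and sane at the extremes", {
  x <- matrix(seq(0, 10, length.out = 12), dimnames = list(NULL, "d"))
  y <- 1.5 * x[, 1] - 2
  cv <- loo_cv(x, y, 1)
  expect_equal(cv$q2, 1, tolerance = 1e-9)

  prob <- random_problem(77, n = 14, k = 4)
  cv <- loo_cv(prob$x, prob$y, 2)
  expect_equal(cv$q2, 1 - cv$press / cv$ss)
  # independent PRESS recomputation, fold by fold
  press2 <- 0
  for (i in seq_along(prob$y)) {
    m <- pls_fit(prob$x[-i, ], prob$y[-i], 2)
    xi <- apply_scaling(m$x_scaling, prob$x[i, , drop = FALSE])
    pred <- drop(unscale(m$y_scaling, matrix(drop(xi %*% m$coefficients), ncol = 1)))
    press2 <- press2 + (prob$y[i] - pred)^2
  }
  expect_equal(cv$press, press2, tolerance = 1e-12)
  expect_equal(cv$ss, sum((prob$y - mean(prob$y))^2))
})

test_that("component selection finds one factor for linear data, two when needed", {
  set.seed(41)
  # single latent factor seen through several descriptors
  t1 <- rnorm(30)
  x1 <- outer(t1, c(1, 0.8, -0.5)) + matrix(rnorm(90, 0, 0.01), 30)
  colnames(x1) <- paste0("d", 1:3)
  expect_equal(select_components(x1, t1 + rnorm(30, 0, 0.01))$ncomp, 1L)

  # two orthogonal latent factors, both driving y, seen through disjoint blocks
  t2 <- rnorm(30)
  x2 <- cbind(outer(t1, c(1, 1)), outer(t2, c(1, -1))) +
    matrix(rnorm(120, 0, 0.02), 30)
  # ensure y needs both: unequal loadings so one component cannot capture both
  y2 <- 2 * t1 + 0.9 * t2 + rnorm(30, 0, 0.05)
  colnames(x2) <- paste0("d", 1:4)
  expect_equal(select_components(x2, y2)$ncomp, 2L)
})

test_that("jack-knife intervals collapse for identical submodels and track truth", {
  fake_cv <- structure(list(
    coef_matrix = matrix(0.4, 3, 10, dimnames = list(c("a", "b", "c"), NULL)),
    model = list(coefficients = c(a = 0.4, b = 0.4, c = 0.4)),
    ncomp = 1), class = "pls_cv")
  ci <- jackknife_ci(fake_cv)
  expect_equal(ci$half_width, rep(0, 3))
  expect_true(all(ci$significant))

  # level consistency on synthetic data with known sparse beta
  n <- 100
  sig_hits <- zero_hits <- 0
  for (seed in 1:15) {
    set.seed(seed + 500)
    x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("d", 1:6)))
    beta <- c(1, -1, 0.8, 0, 0, 0)
    y <- drop(x %*% beta) + rnorm(n, 0, 0.5)
    ci <- jackknife_ci(loo_cv(x, y, 3), level = 0.90)
    sig_hits <- sig_hits + sum(ci$significant[1:3])
    zero_hits <- zero_hits + sum(ci$significant[4:6])
  }
  expect_equal(sig_hits, 45) # every true effect detected, all seeds
  expect_lte(zero_hits / 45, 0.2) # false-positive rate near the nominal level
})

test_that("predictions reproduce the training fit and DModX normalisation holds", {
  prob <- random_problem(61, n = 20, k = 7)
  m <- pls_fit(prob$x, prob$y, 2)
  pred <- predict(m, prob$x)
  expect_equal(pred$estimate, m$fitted, tolerance = 1e-10)
  # mean squared training DModX (with correction) is exactly 1
  expect_equal(mean(dmodx(m)^2), 1, tolerance = 1e-10)
  # DModXPS on the training rows differs from DModX only by the factor v
  v <- sqrt(m$n / (m$n - m$ncomp - 1))
  expect_equal(dmodx(m), pred$dmodx * v, tolerance = 1e-10)
  expect_gt(dmodx_crit(m), 0)

  # a grossly alien row is flagged outside the applicability domain
  far <- matrix(10, 1, 7, dimnames = list("alien", colnames(prob$x)))
  expect_true(predict(m, far)$outside_ad)

  bad <- prob$x[, 1:5]
  expect_error(predict(m, bad), "lacks column")
})

test_that("response permutation validates signal and rejects noise", {
  expect_error(permutation_test(matrix(rnorm(20), 10), rep(1, 10), 1),
               "constant response")

  prob <- random_problem(3, n = 15, k = 5, sigma = 0.2)
  rep_sig <- permutation_test(prob$x, prob$y, 2, n_perm = 30, seed = 7)
  expect_true(rep_sig$verdict)
  expect_gt(rep_sig$original$q2, max(rep_sig$perms$q2))
  # determinism
  rep_sig2 <- permutation_test(prob$x, prob$y, 2, n_perm = 30, seed = 7)
  expect_identical(rep_sig$perms, rep_sig2$perms)

  set.seed(91)
  x <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- rnorm(12)
  rep_noise <- permutation_test(x, y, 2, n_perm = 30, seed = 8)
  expect_false(rep_noise$verdict)
})

test_that("model JSON serialisation carries the prediction machinery", {
  prob <- random_problem(19, n = 12, k = 4)
  m <- pls_fit(prob$x, prob$y, 2)
  p <- withr::local_tempfile(fileext = ".json")
  write_pls_model(m, p)
  obj <- jsonlite::fromJSON(p)
  expect_equal(obj$ncomp, 2)
  expect_equal(obj$coefficients, unname(m$coefficients), tolerance = 1e-12)
  # reconstruct predictions from the serialised pieces alone
  xs <- sweep(sweep(prob$x, 2, obj$x_scaling$means), 2, obj$x_scaling$scales, "/")
  est <- drop(xs %*% obj$coefficients) * obj$y_scaling$scale + obj$y_scaling$mean
  expect_equal(est, m$fitted, tolerance = 1e-10)
})
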