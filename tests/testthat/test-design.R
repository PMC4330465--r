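make_lib <- function(sizes) {
  bb_library(stats::setNames(
    lapply(sizes, function(s) paste0("f", seq_len(s))),
    paste0("p", seq_along(sizes))))
}

test_that("candidate enumeration is the full deterministic Cartesian product", {
  cs <- enumerate_candidates(make_lib(c(3, 2, 2)))
  expect_equal(cs$n, 12)
  # lexicographic: first position varies slowest, last fastest
  expect_equal(cs$assignments$p1[1:5], c("f1", "f1", "f1", "f1", "f2"))
  expect_equal(cs$assignments$p3[1:4], c("f1", "f2", "f1", "f2"))
  expect_identical(enumerate_candidates(make_lib(c(3, 2, 2)))$assignments,
                   cs$assignments)

  one <- enumerate_candidates(make_lib(1))
  expect_equal(one$n, 1)
  expect_equal(unname(unclass(indicator_matrix(one, "full"))),
               matrix(1, 1, 1), ignore_attr = TRUE)

  expect_error(bb_library(list(p1 = character(0))), "at least one")
  expect_error(bb_library(list(p1 = c("a", "a"))), "unique")
})

test_that("a four-position library with 6x2x2x6 fragments yields 144 candidates", {
  cs <- enumerate_candidates(make_lib(c(6, 2, 2, 6)))
  expect_equal(cs$n, 144)
  X <- indicator_matrix(cs, "full")
  expect_equal(ncol(X), 16)
  # each position block's row sums are exactly 1 under full encoding
  for (pos in paste0("p", 1:4)) {
    block <- X[, startsWith(colnames(X), paste0(pos, ".")), drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, 144))
  }
  expect_equal(ncol(indicator_matrix(cs, "reduced")), 12)
})

test_that("library YAML round-trips", {
  lib <- make_lib(c(3, 2))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_library(lib, p)
  expect_identical(read_library(p)$positions, lib$positions)
})

test_that("Fedorov exchange attains the exhaustive D-optimum on small sets", {
  # trivial case: selecting everything
  cs <- enumerate_candidates(make_lib(c(2, 2)))
  sel <- d_optimal_select(cs, cs$n)
  expect_identical(sel$selected, seq_len(cs$n))

  # 8 candidates choose 4: C(8,4) = 70 subsets, brute-force oracle
  set.seed(11)
  X <- matrix(rbinom(8 * 3, 1, 0.5), 8, 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  X[, 1] <- c(1, 0, 1, 0, 1, 0, 1, 0) # ensure no constant column
  Xs <- autoscale(X, drop_constant = TRUE)$scaled
  oracle <- exhaustive_logdet_max(Xs, 4)
  sel <- d_optimal_select(X, 4, n_starts = 20, seed = 5)
  expect_equal(sel$log_det, oracle, tolerance = 1e-9)

  # determinism under a fixed seed
  sel2 <- d_optimal_select(X, 4, n_starts = 20, seed = 5)
  expect_identical(sel$selected, sel2$selected)
})

test_that("condition number is definitional, permutation- and sign-invariant", {
  q <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  expect_equal(condition_number(q, rescale = FALSE), 1, tolerance = 1e-10)
  expect_identical(condition_number(cbind(a = c(1, 2, 1, 3), b = c(1, 2, 1, 3)),
                                    rescale = FALSE), Inf)
  expect_error(condition_number(matrix(numeric(0), 0, 0)), "empty")

  set.seed(3)
  m <- matrix(rnorm(40), 10, 4)
  cn <- condition_number(m)
  expect_equal(condition_number(m[, c(3, 1, 4, 2)]), cn)
  flip <- m %*% diag(c(1, -1, 1, -1))
  expect_equal(condition_number(flip), cn)
})

test_that("orthogonal column blocks never decrease the full-set log determinant", {
  set.seed(7)
  for (i in 1:10) {
    X <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3))) * sqrt(12) # unit pop variance-ish
    X <- autoscale(X)$scaled
    base <- determinant(crossprod(X))$modulus
    # an extra block orthogonal to the existing columns
    Z <- matrix(rnorm(12 * 2), 12, 2)
    Z <- Z - X %*% solve(crossprod(X), crossprod(X, Z))
    aug <- determinant(crossprod(cbind(X, Z)))$modulus
    expect_gte(as.numeric(aug), as.numeric(base) - 1e-8)
  }
})

test_that("D-optimal selections beat the median random selection on conditioning", {
  cs <- enumerate_candidates(make_lib(c(4, 3, 2)))
  sel <- d_optimal_select(cs, 12, n_starts = 20, seed = 2)
  set.seed(99)
  rand_cn <- replicate(100, {
    idx <- sample(cs$n, 12)
    # random picks can drop a fragment entirely -> singular design
    tryCatch(condition_number(indicator_matrix(cs, "reduced")[idx, ]),
             error = function(e) Inf)
  })
  expect_lte(sel$condition_number, median(rand_cn))
})

test_that("balance reporting counts fragments and flags under-represented ones", {
  cs <- enumerate_candidates(make_lib(c(2, 2)))
  full <- balance_report(seq_len(4), cs)
  expect_true(attr(full, "verdict"))
  expect_equal(unique(full$count), 2) # n_select / 2 by symmetry

  # a selection that never uses p1.f2
  sub <- balance_report(c(1, 2), cs)
  expect_false(attr(sub, "verdict"))
  expect_true("p1.f2" %in% attr(sub, "failing"))
  expect_error(balance_report(integer(0), cs), "empty")
})
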