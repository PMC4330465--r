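# Independent oracles used to cross-check the implementation.  Each takes a
# computational route disjoint from the package's own.

# population autoscaling, kept separate from the package implementation
scale_pop_oracle <- function(x) {
  x <- sweep(as.matrix(x), 2, colMeans(x))
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

# Closed-form PLS1 via the Krylov-subspace characterisation (Helland 1988):
# the A-component PLS fit is the least-squares fit restricted to
# span{s, Ms, ..., M^(A-1) s} with s = X'y, M = X'X (scaled space).
helland_pls_fitted <- function(x, y, ncomp) {
  Xs <- scale_pop_oracle(x)
  ys <- drop(scale(y, center = TRUE, scale = FALSE))
  ys <- ys / sqrt(mean(ys^2))
  M <- crossprod(Xs)
  s <- crossprod(Xs, ys)
  K <- matrix(0, ncol(Xs), ncomp)
  v <- s
  for (a in seq_len(ncomp)) {
    K[, a] <- v
    v <- M %*% v
  }
  Q <- qr.Q(qr(K)) # orthonormalise for stability; same span
  b <- Q %*% solve(crossprod(Q, M %*% Q), crossprod(Q, s))
  fitted_scaled <- drop(Xs %*% b)
  list(coefficients = drop(b),
       fitted = mean(y) + fitted_scaled * sqrt(mean((y - mean(y))^2)))
}

# brute-force D-optimal subset: best log det(Xsel'Xsel) over all subsets
exhaustive_logdet_max <- function(Xs, n_select) {
  combos <- utils::combn(nrow(Xs), n_select)
  best <- -Inf
  for (j in seq_len(ncol(combos))) {
    d <- determinant(crossprod(Xs[combos[, j], , drop = FALSE]))
    v <- if (d$sign <= 0) -Inf else as.numeric(d$modulus)
    if (v > best) best <- v
  }
  best
}

# two-sample KS statistic as the sup-difference of empirical CDFs
ks_stat_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of the U
# distribution under the null (all assignments of ranks equally likely)
mw_exact_p_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  r <- rank(pooled)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  # two-sided: as extreme or more, measured as distance from the mean
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small random regression problem with planted signal
random_problem <- function(seed, n = 15, k = 6, sigma = 0.5) {
  set.seed(seed)
  x <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("d", seq_len(k))))
  beta <- rnorm(k)
  y <- drop(x %*% beta) + rnorm(n, 0, sigma)
  list(x = x, y = y, beta = beta)
}
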