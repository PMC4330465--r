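## NIPALS core on pre-scaled data.  Returns weights/loadings/scores and the
## regression vector b in scaled space; shared by fitting, cross-validation
## and permutation refits.
.pls_core <- function(Xs, ys, ncomp, tol = 1e-10, max_iter = 500L) {
  N <- nrow(Xs); K <- ncol(Xs)
  W <- P <- matrix(0, K, ncomp)
  Tm <- matrix(0, N, ncomp)
  q <- numeric(ncomp)
  X <- Xs; y <- ys
  for (a in seq_len(ncomp)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop(sprintf("PLS component %d: no remaining X-y covariance", a),
           call. = FALSE)
    }
    w <- w / nw
    iter <- 0L
    repeat {
      # with a single response the weight vector is stationary after one
      # pass; the loop is kept for the general NIPALS contract
      t_scr <- X %*% w
      tt <- sum(t_scr^2)
      if (tt < 1e-12) {
        stop(sprintf("PLS component %d: degenerate score vector", a),
             call. = FALSE)
      }
      qa <- sum(y * t_scr) / tt
      u <- y * qa
      w_new <- crossprod(X, u)
      w_new <- w_new / sqrt(sum(w_new^2))
      iter <- iter + 1L
      if (sum((w_new - w)^2) < tol^2 || iter >= max_iter) {
        if (iter >= max_iter && sum((w_new - w)^2) >= tol^2) {
          stop(sprintf("NIPALS did not converge for component %d", a),
               call. = FALSE)
        }
        w <- w_new
        break
      }
      w <- w_new
    }
    t_scr <- X %*% w
    tt <- sum(t_scr^2)
    p <- crossprod(X, t_scr) / tt
    qa <- sum(y * t_scr) / tt
    X <- X - tcrossprod(t_scr, p)
    y <- y - qa * t_scr
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t_scr; q[a] <- qa
  }
  b <- W %*% solve(crossprod(P, W), q)
  list(weights = W, x_loadings = P, scores = Tm, y_loadings = q,
       coefficients = drop(b), x_residuals = X)
}

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares with a single response.  Descriptors and the
#' response are centered and scaled to unit variance before model building;
#' coefficients are reported in that scaled space (the scale on which their
#' relative importance is interpreted) and fitted values are back-transformed
#' to response units.
#'
#' @param x Numeric descriptor matrix (N x K), no constant columns.
#' @param y Numeric response vector (here: pIC50), length N.
#' @param ncomp Number of PLS components A (N >= A + 2).
#' @param tol,max_iter NIPALS convergence control (change in the weight
#'   vector; default 1e-10, at most 500 iterations per component).
#' @return Object of class `pls_model` with components `ncomp`, `weights`,
#'   `x_loadings`, `y_loadings`, `scores`, `coefficients` (scaled space,
#'   named), `x_scaling`/`y_scaling` ([autoscale()] params), `fitted`,
#'   `residuals`, `y`, `r2y`, `adj_r2y`, `rmsee`, `r2x` (per-component
#'   fraction of X-variance), and the X-residual machinery used for DModX.
#' @seealso [predict.pls_model()], [loo_cv()], [permutation_test()]
#' @export
pls_fit <- function(x, y, ncomp, tol = 1e-10, max_iter = 500L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  N <- nrow(x); K <- ncol(x)
  if (length(y) != N) stop("length(y) must match nrow(x)", call. = FALSE)
  if (ncomp < 1 || ncomp != round(ncomp)) stop("'ncomp' must be a positive integer", call. = FALSE)
  if (N < ncomp + 2) stop("need N >= ncomp + 2 observations", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(K))

  xs <- autoscale(x)
  ys <- autoscale(matrix(y, ncol = 1, dimnames = list(NULL, "y")))
  core <- .pls_core(xs$scaled, drop(ys$scaled), ncomp, tol, max_iter)

  fitted_scaled <- drop(xs$scaled %*% core$coefficients)
  fitted <- drop(unscale(ys$params, matrix(fitted_scaled, ncol = 1)))
  ssy <- sum((y - mean(y))^2)
  r2y <- 1 - sum((y - fitted)^2) / ssy
  adj_r2y <- 1 - (1 - r2y) * (N - 1) / (N - 1 - ncomp)
  ssx <- sum(xs$scaled^2)
  r2x <- colSums(core$scores^2) * colSums(core$x_loadings^2) / ssx

  rownames(core$weights) <- rownames(core$x_loadings) <- colnames(xs$scaled)
  coefs <- stats::setNames(core$coefficients, colnames(xs$scaled))

  structure(list(
    ncomp = ncomp,
    weights = core$weights,
    x_loadings = core$x_loadings,
    y_loadings = core$y_loadings,
    scores = core$scores,
    coefficients = coefs,
    x_scaling = xs$params,
    y_scaling = ys$params,
    fitted = fitted,
    residuals = y - fitted,
    y = y,
    r2y = r2y,
    adj_r2y = adj_r2y,
    rmsee = sqrt(sum((y - fitted)^2) / (N - 1 - ncomp)),
    r2x = r2x,
    x_residuals = core$x_residuals,
    n = N, k = K
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: A = %d, N = %d, K = %d\n", x$ncomp, x$n, x$k))
  cat(sprintf("R2Y = %.3f, adj R2Y = %.3f, RMSEE = %.3f\n",
              x$r2y, x$adj_r2y, x$rmsee))
  cat(sprintf("R2X per component: %s\n",
              paste(sprintf("%.2f", x$r2x), collapse = ", ")))
  invisible(x)
}

#' Root-mean-square error of estimation
#'
#' Training-set error with the degrees-of-freedom corrected denominator
#' `N - 1 - A`: `RMSEE = sqrt(sum((y - y_fitted)^2) / (N - 1 - A))`.
#'
#' @param model A [pls_fit()] model.
#' @return RMSEE in response units.
#' @export
rmsee <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  model$rmsee
}

#' Root-mean-square error of prediction
#'
#' External test-set error: `RMSEP = sqrt(sum((y - y_pred)^2) / N)`, divisor
#' exactly N (no degrees-of-freedom correction — the test compounds were
#' never part of the fit).
#'
#' @param measured,predicted Equal-length numeric vectors.
#' @return RMSEP in response units.
#' @export
rmsep <- function(measured, predicted) {
  if (length(measured) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (length(measured) == 0) stop("empty input", call. = FALSE)
  sqrt(mean((measured - predicted)^2))
}

## ---------------------------------------------------------------------------
## Distance to model in X

# s0: pooled residual standard deviation of the training X-residuals
.dmodx_s0 <- function(model) {
  with(model, sqrt(sum(x_residuals^2) / ((n - 1 - ncomp) * (k - ncomp))))
}

#' Distance to model in X (DModX) of the training observations
#'
#' For observation i with X-residuals `e_ik` after A components,
#' `s_i = sqrt(sum_k e_ik^2 / (K - A))` is normalised by the pooled residual
#' standard deviation `s0 = sqrt(sum_ik e_ik^2 / ((N - 1 - A)(K - A)))`.
#' Training rows are additionally multiplied by the correction factor
#' `v = sqrt(N / (N - A - 1))` (slightly above 1), compensating for the fact
#' that an observation that is part of the model sits closer to it; with
#' this convention the mean squared DModX of the training set is exactly 1.
#' New observations use DModXPS, the same quantity without `v` (see
#' [predict.pls_model()]).
#'
#' @param model A [pls_fit()] model.
#' @return Numeric vector of normalised DModX values (>= 0).
#' @export
dmodx <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  s_i <- sqrt(rowSums(model$x_residuals^2) / (model$k - model$ncomp))
  v <- sqrt(model$n / (model$n - model$ncomp - 1))
  v * s_i / .dmodx_s0(model)
}

#' Critical DModX value at a given significance level
#'
#' Squared normalised DModX behaves approximately as an F ratio of residual
#' variances; the 1 - alpha quantile of F with `(K - A, (N - A - 1)(K - A))`
#' degrees of freedom gives the applicability-domain boundary
#' `DCrit = sqrt(qf(1 - alpha, K - A, (N - A - 1)(K - A)))`.
#'
#' @param model A [pls_fit()] model.
#' @param alpha Significance level (default 0.05, i.e. the 95% boundary).
#' @return Positive scalar.
#' @export
dmodx_crit <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "pls_model"))
  df1 <- model$k - model$ncomp
  df2 <- (model$n - model$ncomp - 1) * (model$k - model$ncomp)
  sqrt(stats::qf(1 - alpha, df1, df2))
}

#' Predict new observations and assess the applicability domain
#'
#' Applies the training scaling (never refit) to the new descriptor rows,
#' projects them through the model, and back-transforms to response units.
#' Each new row's distance to the model in X is reported as DModXPS
#' (normalised, without the training correction factor); rows beyond
#' [dmodx_crit()] are flagged as outside the applicability domain, i.e.
#' significantly dissimilar in physicochemical space from the molecules the
#' model was trained on.
#'
#' @param object A [pls_fit()] model.
#' @param newdata Matrix with the model's descriptor columns.
#' @param alpha Significance level for the applicability-domain boundary.
#' @param ... Unused.
#' @return Object of class `pls_prediction`: data.frame with `id`,
#'   `estimate`, `dmodx` (DModXPS), `outside_ad`; attribute `dcrit`.
#' @export
predict.pls_model <- function(object, newdata, alpha = 0.05, ...) {
  newdata <- as.matrix(newdata)
  Xs <- apply_scaling(object$x_scaling, newdata)
  # sequential deflation so the residual matrix drops out alongside scores
  E <- Xs
  scores <- matrix(0, nrow(Xs), object$ncomp)
  for (a in seq_len(object$ncomp)) {
    t_new <- drop(E %*% object$weights[, a])
    E <- E - tcrossprod(t_new, object$x_loadings[, a])
    scores[, a] <- t_new
  }
  est_scaled <- drop(scores %*% object$y_loadings)
  estimate <- drop(unscale(object$y_scaling, matrix(est_scaled, ncol = 1)))
  s_i <- sqrt(rowSums(E^2) / (object$k - object$ncomp))
  dmx <- s_i / .dmodx_s0(object)
  dcrit <- dmodx_crit(object, alpha)
  out <- data.frame(
    id = if (!is.null(rownames(newdata))) rownames(newdata) else as.character(seq_len(nrow(newdata))),
    estimate = estimate,
    dmodx = dmx,
    outside_ad = dmx > dcrit,
    stringsAsFactors = FALSE
  )
  structure(out, dcrit = dcrit, alpha = alpha,
            class = c("pls_prediction", "data.frame"))
}

## ---------------------------------------------------------------------------
## Cross-validation and derived validation machinery

#' Leave-one-out cross-validation of a PLS model
#'
#' Each observation is left out once; the model (including the scaling
#' parameters, which are re-estimated inside every fold) is refit on the
#' remaining N - 1 rows and the held-out response predicted.  The
#' cross-validated correlation is `Q2 = 1 - PRESS/SS` where
#' `PRESS = sum_i (y_i - yhat_(-i))^2` and `SS = sum_i (y_i - ybar)^2`
#' (ybar over all rows).  Q2 can be negative; a value close to R2Y
#' indicates a robust model.  The N leave-one-out submodels are retained
#' for jack-knife coefficient intervals.
#'
#' @inheritParams pls_fit
#' @return Object of class `pls_cv`: `q2`, `press`, `ss`,
#'   `loo_predictions`, `coef_matrix` (K x N scaled-space coefficients of
#'   the submodels), `model` (the full-data fit), `ncomp`.
#' @export
loo_cv <- function(x, y, ncomp) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  N <- nrow(x)
  if (N < ncomp + 3) stop("need N >= ncomp + 3 for leave-one-out", call. = FALSE)
  full <- pls_fit(x, y, ncomp)
  preds <- numeric(N)
  coefs <- matrix(NA_real_, ncol(x), N,
                  dimnames = list(colnames(x) %||% paste0("X", seq_len(ncol(x))), NULL))
  for (i in seq_len(N)) {
    fold <- pls_fit(x[-i, , drop = FALSE], y[-i], ncomp)
    xi <- apply_scaling(fold$x_scaling, x[i, , drop = FALSE])
    pred_scaled <- drop(xi %*% fold$coefficients)
    preds[i] <- drop(unscale(fold$y_scaling, matrix(pred_scaled, ncol = 1)))
    coefs[, i] <- fold$coefficients
  }
  press <- sum((y - preds)^2)
  ss <- sum((y - mean(y))^2)
  structure(list(q2 = 1 - press / ss, press = press, ss = ss,
                 loo_predictions = preds, coef_matrix = coefs,
                 model = full, ncomp = ncomp),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out CV: A = %d, Q2 = %.3f (PRESS = %.3f, SS = %.3f)\n",
              x$ncomp, x$q2, x$press, x$ss))
  invisible(x)
}

#' Choose the number of PLS components from cross-validation
#'
#' A single-response PLS model should rarely need more than one component;
#' weak non-linearity may justify one or two more.  Component a + 1 is
#' accepted only when it improves Q2 by more than `limit` (default 0.05),
#' up to a hard cap of `a_max` (default 3).
#'
#' @inheritParams pls_fit
#' @param a_max Maximum components to probe.
#' @param limit Minimum incremental Q2 gain to accept a further component.
#' @return Object of class `component_selection`: `ncomp` (the choice) and
#'   `q2` (the Q2 path over 1..a_max, as far as probed).
#' @export
select_components <- function(x, y, a_max = 3, limit = 0.05) {
  if (a_max < 1) stop("'a_max' must be >= 1", call. = FALSE)
  q2s <- numeric(0)
  ncomp <- 1L
  for (a in seq_len(a_max)) {
    q2s[a] <- loo_cv(x, y, a)$q2
    if (a > 1 && q2s[a] - q2s[a - 1] > limit) ncomp <- a
    if (a > 1 && q2s[a] - q2s[a - 1] <= limit) break
  }
  structure(list(ncomp = ncomp, q2 = q2s, limit = limit),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("Selected A = %d (Q2 path: %s; entry limit %.2f)\n", x$ncomp,
              paste(sprintf("%.3f", x$q2), collapse = " -> "), x$limit))
  invisible(x)
}

#' Jack-knife confidence intervals for PLS coefficients
#'
#' Uses the spread of the N leave-one-out coefficient estimates around
#' their mean: `SE_k = sqrt(((N-1)/N) * sum_i (b_k^(-i) - bbar_k)^2)`, with
#' the interval `b_k +/- t_{1-(1-level)/2, N-1} * SE_k` centred on the
#' full-model coefficient.  A coefficient is deemed significant when its
#' interval excludes zero — the criterion used to read the coefficient
#' plots of a designed SAR/QSAR study.
#'
#' @param cv A [loo_cv()] result (which retains the submodels).
#' @param level Two-sided confidence level, default 0.90.
#' @return Object of class `coefficient_ci`: data.frame with `name`, `b`
#'   (scaled space), `half_width`, `lower`, `upper`, `significant`.
#' @export
jackknife_ci <- function(cv, level = 0.90) {
  stopifnot(inherits(cv, "pls_cv"))
  if (!(level > 0 && level < 1)) stop("'level' must be in (0,1)", call. = FALSE)
  B <- cv$coef_matrix
  N <- ncol(B)
  bbar <- rowMeans(B)
  se <- sqrt((N - 1) / N * rowSums((B - bbar)^2))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = N - 1)
  b <- cv$model$coefficients
  out <- data.frame(name = names(b), b = unname(b),
                    half_width = tcrit * se,
                    stringsAsFactors = FALSE)
  out$lower <- out$b - out$half_width
  out$upper <- out$b + out$half_width
  out$significant <- out$lower > 0 | out$upper < 0
  rownames(out) <- NULL
  structure(out, level = level, class = c("coefficient_ci", "data.frame"))
}

# lightweight Q2 without submodel retention, for permutation refits
.loo_q2 <- function(x, y, ncomp) {
  N <- nrow(x)
  preds <- numeric(N)
  for (i in seq_len(N)) {
    xs <- autoscale(x[-i, , drop = FALSE])
    ysc <- autoscale(matrix(y[-i], ncol = 1))
    core <- .pls_core(xs$scaled, drop(ysc$scaled), ncomp)
    xi <- apply_scaling(xs$params, x[i, , drop = FALSE])
    preds[i] <- drop(unscale(ysc$params, matrix(drop(xi %*% core$coefficients), ncol = 1)))
  }
  1 - sum((y - preds)^2) / sum((y - mean(y))^2)
}

#' Response-permutation (y-scrambling) validation
#'
#' The response vector is scrambled `n_perm` times (default 200) and a
#' model of the same dimensionality refit to each scrambled response.  A
#' model that reflects a real structure-activity relationship must
#' outperform every scrambled refit.  For each permutation the report
#' records the absolute correlation between scrambled and original
#' response, R2Y and the leave-one-out Q2.  The verdict is `pass` when the
#' intercepts of the regression lines of R2Y and Q2 versus |correlation|
#' (the value extrapolated to a fully scrambled response) lie below the
#' original model's values and no permuted Q2 reaches the original Q2.
#'
#' @inheritParams pls_fit
#' @param n_perm Number of permutations (>= 10).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `permutation_report`: `perms` (data.frame
#'   `cor_abs`, `r2y`, `q2`), `original` (list `r2y`, `q2`),
#'   `intercepts`, `verdict`, `n_perm`, `seed`.
#' @export
permutation_test <- function(x, y, ncomp, n_perm = 200, seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (n_perm < 10) stop("'n_perm' must be >= 10", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response (SS = 0)", call. = FALSE)
  orig <- list(r2y = pls_fit(x, y, ncomp)$r2y, q2 = .loo_q2(x, y, ncomp))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  res <- matrix(NA_real_, n_perm, 3,
                dimnames = list(NULL, c("cor_abs", "r2y", "q2")))
  for (p in seq_len(n_perm)) {
    yp <- sample(y)
    res[p, "cor_abs"] <- abs(stats::cor(yp, y))
    res[p, "r2y"] <- pls_fit(x, yp, ncomp)$r2y
    res[p, "q2"] <- .loo_q2(x, yp, ncomp)
  }
  perms <- as.data.frame(res)
  int_r2 <- unname(stats::coef(stats::lm(r2y ~ cor_abs, data = perms))[1])
  int_q2 <- unname(stats::coef(stats::lm(q2 ~ cor_abs, data = perms))[1])
  verdict <- int_r2 < orig$r2y && int_q2 < orig$q2 && max(perms$q2) < orig$q2
  structure(list(perms = perms, original = orig,
                 intercepts = c(r2y = int_r2, q2 = int_q2),
                 verdict = verdict, n_perm = n_perm, seed = seed),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("Permutation test (%d scrambles): %s\n", x$n_perm,
              if (x$verdict) "PASS" else "FAIL"))
  cat(sprintf("  original R2Y = %.3f, Q2 = %.3f\n", x$original$r2y, x$original$q2))
  cat(sprintf("  intercepts at |cor| = 0: R2Y %.3f, Q2 %.3f; max permuted Q2 %.3f\n",
              x$intercepts["r2y"], x$intercepts["q2"], max(x$perms$q2)))
  invisible(x)
}

#' Serialise a PLS model to JSON
#'
#' Plain-text serialisation (scaling, weights, loadings, coefficients,
#' component count) sufficient to reconstruct predictions; no binary
#' formats.
#'
#' @param model A [pls_fit()] model.
#' @param path Output path.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(
    ncomp = model$ncomp,
    descriptors = names(model$coefficients),
    coefficients = unname(model$coefficients),
    weights = unclass(model$weights),
    x_loadings = unclass(model$x_loadings),
    y_loadings = model$y_loadings,
    x_scaling = list(means = unname(model$x_scaling$column_means),
                     scales = unname(model$x_scaling$column_scales)),
    y_scaling = list(mean = unname(model$y_scaling$column_means),
                     scale = unname(model$y_scaling$column_scales)),
    stats = list(r2y = model$r2y, adj_r2y = model$adj_r2y,
                 rmsee = model$rmsee, n = model$n, k = model$k)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
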