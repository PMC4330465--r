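#' Define a combinatorial building-block library
#'
#' A library is an ordered set of substitution positions (for the designed
#' inhibitor series: `pIa`, `pIb`, `pII`, `pIII`), each with an ordered list
#' of candidate fragments.  Every full molecule picks exactly one fragment
#' per position, so the candidate space is the Cartesian product.
#'
#' @param positions Named list: position label -> character vector of
#'   fragment labels (unique within a position, at least one each).
#' @return Object of class `bb_library`.
#' @examples
#' lib <- bb_library(list(pI = c("a", "b", "c"), pII = c("short", "long")))
#' @export
bb_library <- function(positions) {
  if (!is.list(positions) || length(positions) == 0 || is.null(names(positions)) ||
      any(!nzchar(names(positions)))) {
    stop("'positions' must be a non-empty named list", call. = FALSE)
  }
  positions <- lapply(positions, as.character)
  if (any(vapply(positions, length, 1L) == 0)) {
    stop("every position needs at least one fragment", call. = FALSE)
  }
  if (any(vapply(positions, anyDuplicated, 1L) > 0)) {
    stop("fragment labels must be unique within a position", call. = FALSE)
  }
  structure(list(positions = positions), class = "bb_library")
}

#' Read a building-block library from YAML or JSON
#'
#' File layout: `positions: {pIa: [...], pIb: [...], ...}` (a top-level
#' `positions` key is optional; a bare map of positions is also accepted).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [bb_library()].
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(obj$positions)) obj <- obj$positions
  bb_library(obj)
}

#' Write a building-block library to YAML
#' @param lib A [bb_library()].
#' @param path Output path.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "bb_library"))
  yaml::write_yaml(list(positions = lib$positions), path)
  invisible(path)
}

#' Enumerate all candidate molecules of a library
#'
#' Produces the full Cartesian product of fragments in deterministic
#' lexicographic order (first position varying slowest) together with the
#' binary fragment-indicator ("conditional descriptor") matrix.
#'
#' @param lib A [bb_library()].
#' @return Object of class `candidate_set`: list with `assignments` (a
#'   data.frame, one column per position), `library`, and `n` candidates.
#'   Use [indicator_matrix()] for the 0/1 encoding.
#' @export
enumerate_candidates <- function(lib) {
  stopifnot(inherits(lib, "bb_library"))
  grid <- rev(expand.grid(rev(lib$positions), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  names(grid) <- names(lib$positions)
  rownames(grid) <- sprintf("cand%03d", seq_len(nrow(grid)))
  structure(list(assignments = grid, library = lib, n = nrow(grid)),
            class = "candidate_set")
}

#' Binary indicator encoding of a candidate set
#'
#' Under the `full` encoding every fragment gets one presence/absence
#' column, so each position's block has row sums of exactly 1 and becomes
#' collinear after centering.  The `reduced` encoding drops the last
#' fragment of each position as the reference level, which keeps the
#' information matrix nonsingular without changing the ranking of D-optimal
#' subsets.
#'
#' @param cs A `candidate_set` (or any data.frame of fragment assignments
#'   with a matching `bb_library` passed as `lib`).
#' @param encoding `"full"` or `"reduced"`.
#' @param lib Library override when `cs` is a bare data.frame.
#' @return A [descriptor_matrix()] of kind `conditional` (columns named
#'   `<position>.<fragment>`).
#' @export
indicator_matrix <- function(cs, encoding = c("full", "reduced"), lib = NULL) {
  encoding <- match.arg(encoding)
  if (inherits(cs, "candidate_set")) {
    assign <- cs$assignments
    lib <- cs$library
  } else {
    assign <- as.data.frame(cs)
    if (is.null(lib)) stop("need a bb_library when passing bare assignments", call. = FALSE)
  }
  blocks <- lapply(names(lib$positions), function(pos) {
    frags <- lib$positions[[pos]]
    keep <- if (encoding == "reduced" && length(frags) > 1) frags[-length(frags)] else frags
    m <- vapply(keep, function(f) as.numeric(assign[[pos]] == f),
                numeric(nrow(assign)))
    m <- matrix(m, nrow = nrow(assign),
                dimnames = list(rownames(assign), paste0(pos, ".", keep)))
    m
  })
  descriptor_matrix(do.call(cbind, blocks), kind = "conditional")
}

#' Condition number of a design matrix
#'
#' Ratio of the largest to the smallest singular value of the (optionally
#' autoscaled) matrix; 1 for a completely orthogonal design, `Inf` when the
#' matrix is singular.  With `pseudo = TRUE` only singular values above
#' `tol * max(sv)` enter the ratio, which is the convention needed for the
#' full indicator encoding whose centered position blocks are exactly
#' collinear.
#'
#' @param x Numeric matrix (e.g. a selected design).
#' @param rescale Autoscale (center, unit variance, population divisor) the
#'   matrix before the SVD.  Default `TRUE`, matching the practice of
#'   scaling conditional descriptors prior to design diagnostics.
#' @param pseudo Drop numerically-zero singular values instead of returning
#'   `Inf`.
#' @param tol Relative tolerance deciding which singular values are zero.
#' @return Positive scalar (possibly `Inf`).
#' @export
condition_number <- function(x, rescale = TRUE, pseudo = FALSE, tol = 1e-8) {
  x <- as.matrix(x)
  if (length(x) == 0) stop("empty matrix", call. = FALSE)
  if (rescale) x <- autoscale(x)$scaled
  sv <- svd(x, nu = 0, nv = 0)$d
  zero <- sv <= tol * max(sv)
  if (any(zero) && !pseudo) return(Inf)
  sv <- sv[!zero]
  max(sv) / min(sv)
}

## Fedorov exchange machinery ------------------------------------------------

# delta of det(M) for swapping selected row xi against candidate row xj:
# det(M_new)/det(M) = 1 + d_j - d_i - (d_i d_j - d_ij^2), d_* = x' M^-1 x
.exchange_deltas <- function(Minv, Xsel, Xout) {
  A <- Xsel %*% Minv
  d_i <- rowSums(A * Xsel)
  d_j <- rowSums((Xout %*% Minv) * Xout)
  C <- A %*% t(Xout)
  outer(-d_i, d_j, "+") + 1 - (outer(d_i, d_j) - C^2)
}

.logdet_xtx <- function(X) {
  d <- determinant(crossprod(X), logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}

#' D-optimal subset selection by Fedorov exchange
#'
#' Selects `n_select` candidates maximising `det(Xsel' Xsel)` of the
#' centered-and-scaled indicator matrix, so that the chosen molecules
#' reflect the diversity of the whole candidate set.  Classical Fedorov
#' single-swap steepest ascent is restarted from `n_starts` random subsets;
#' the search ranks subsets on a ridge-stabilised information matrix
#' (jitter 1e-8) but the reported `log_det` is computed without ridge.
#' Results are deterministic given `seed`; ties between equally good optima
#' break to the lexicographically smallest index set.
#'
#' @param x A `candidate_set`, or a numeric/indicator matrix of candidates.
#'   For a candidate set the reduced encoding is used for the optimisation
#'   (see [indicator_matrix()]) while balance reporting uses full fragment
#'   names.
#' @param n_select Number of candidates to select.
#' @param n_starts Random restarts (default 50).
#' @param seed Integer seed governing all restarts.
#' @return Object of class `d_selection`: `selected` (sorted candidate
#'   indices), `log_det`, `condition_number` (of the selected rows,
#'   autoscaled on the selection), `balance` (fragment occurrence counts
#'   when a library is available), `n_starts`, `seed`.
#' @export
d_optimal_select <- function(x, n_select, n_starts = 50, seed = 1) {
  cs <- NULL
  if (inherits(x, "candidate_set")) {
    cs <- x
    X <- indicator_matrix(cs, encoding = "reduced")
  } else {
    X <- as.matrix(x)
  }
  N <- nrow(X)
  if (n_select > N) stop("n_select exceeds the number of candidates", call. = FALSE)
  Xs <- autoscale(X, drop_constant = TRUE)$scaled
  p <- ncol(Xs)
  if (n_select < p) {
    warning("n_select < number of design columns: information matrix is singular",
            call. = FALSE)
  }
  if (n_select == N) {
    sel <- seq_len(N)
  } else {
    ridge <- diag(1e-8, p)
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
    best <- NULL
    best_ld <- -Inf
    for (s in seq_len(n_starts)) {
      idx <- sort(sample.int(N, n_select))
      repeat {
        M <- crossprod(Xs[idx, , drop = FALSE]) + ridge
        Minv <- tryCatch(solve(M), error = function(e) NULL)
        if (is.null(Minv)) break
        deltas <- .exchange_deltas(Minv, Xs[idx, , drop = FALSE],
                                   Xs[-idx, , drop = FALSE])
        if (max(deltas) <= 1 + 1e-9) break
        w <- which(deltas == max(deltas), arr.ind = TRUE)[1, ]
        idx[w[1]] <- setdiff(seq_len(N), idx)[w[2]]
        idx <- sort(idx)
      }
      ld <- .logdet_xtx(Xs[idx, , drop = FALSE])
      # keep the larger log-det; lexicographically smallest index set on ties
      if (is.null(best) || ld > best_ld + 1e-9) {
        best <- idx; best_ld <- ld
      } else if (is.finite(ld) && abs(ld - best_ld) <= 1e-9) {
        diff1 <- which(idx != best)[1]
        if (!is.na(diff1) && idx[diff1] < best[diff1]) best <- idx
      }
    }
    sel <- best
  }
  Xsel <- X[sel, , drop = FALSE]
  cond <- tryCatch(condition_number(Xsel, rescale = TRUE),
                   error = function(e) Inf)
  balance <- NULL
  if (!is.null(cs)) {
    balance <- unlist(lapply(names(cs$library$positions), function(pos) {
      counts <- table(factor(cs$assignments[[pos]][sel],
                             levels = cs$library$positions[[pos]]))
      stats::setNames(as.integer(counts), paste0(pos, ".", names(counts)))
    }))
  }
  structure(list(selected = sel,
                 log_det = .logdet_xtx(autoscale(X, drop_constant = TRUE)$scaled[sel, , drop = FALSE]),
                 condition_number = cond,
                 balance = balance,
                 n_select = n_select, n_starts = n_starts, seed = seed),
            class = "d_selection")
}

#' @export
print.d_selection <- function(x, ...) {
  cat(sprintf("D-optimal selection: %d candidates, log det(Xsel'Xsel) = %.4f, condition number = %.3f\n",
              x$n_select, x$log_det, x$condition_number))
  cat("Selected:", paste(x$selected, collapse = " "), "\n")
  invisible(x)
}

#' Fragment balance of a selection
#'
#' Counts how often each fragment occurs among the selected candidates and
#' checks the design rule that every building block should recur at least
#' `threshold` times (default 2) so its effect is estimable.
#'
#' @param sel A `d_selection` (or integer vector of candidate indices).
#' @param cs The `candidate_set` the selection refers to.
#' @param threshold Minimum required occurrence per fragment.
#' @return Object of class `balance_report`: data.frame with `position`,
#'   `fragment`, `count`, plus attributes `verdict` (`TRUE` iff all counts
#'   >= threshold) and `failing` (fragment names below threshold).
#' @export
balance_report <- function(sel, cs, threshold = 2) {
  idx <- if (inherits(sel, "d_selection")) sel$selected else as.integer(sel)
  if (length(idx) == 0) stop("empty selection", call. = FALSE)
  stopifnot(inherits(cs, "candidate_set"))
  rows <- do.call(rbind, lapply(names(cs$library$positions), function(pos) {
    counts <- table(factor(cs$assignments[[pos]][idx],
                           levels = cs$library$positions[[pos]]))
    data.frame(position = pos, fragment = names(counts),
               count = as.integer(counts), stringsAsFactors = FALSE)
  }))
  failing <- paste0(rows$position, ".", rows$fragment)[rows$count < threshold]
  structure(rows, verdict = length(failing) == 0, failing = failing,
            threshold = threshold, class = c("balance_report", "data.frame"))
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("Fragment balance (threshold %d): %s\n", attr(x, "threshold"),
              if (attr(x, "verdict")) "PASS" else
                paste("FAIL -", paste(attr(x, "failing"), collapse = ", "))))
  print.data.frame(x)
  invisible(x)
}
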