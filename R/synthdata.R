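# deterministic child seeds so each stage draws from its own stream;
# offsets stay well below 2^31
.child_seed <- function(master, stage) {
  (as.integer(master) %% 1000003L) * 1009L + stage * 7919L
}

#' Generate a synthetic designed-study dataset
#'
#' Emulates the statistical structure of a designed inhibitor series: a
#' combinatorial building-block library, an optional D-optimal subset, and
#' an additive latent fragment-effect response
#' `y = intercept + sum_position beta[fragment] + eps`, `eps ~ N(0, sigma^2)`
#' i.i.d.  The true effects are stored so recovery can be tested.  The
#' default shape mirrors a four-position library with 144 combinations from
#' which 18 molecules are selected, and the default noise of 0.45 pIC50
#' units corresponds to the half-log-unit estimation error typical of such
#' assays.
#'
#' @param library_shape Named integer vector of fragments per position
#'   (default `c(pIa = 6, pIb = 2, pII = 2, pIII = 6)`).
#' @param beta Named numeric vector of true additive effects, one entry per
#'   fragment label (`<position>.f<j>`); default draws each effect from
#'   N(0, 0.75^2) using a child seed.
#' @param sigma Noise standard deviation in response units (>= 0).
#' @param n_select Number of molecules to select D-optimally; `NULL` keeps
#'   the full candidate set.
#' @param intercept Baseline response (default 4, a typical mid-micromolar
#'   pIC50).
#' @param seed Master seed; all child streams derive from it
#'   deterministically, so regeneration is bit-identical.
#' @return Object of class `synthetic_study`: list with `library`,
#'   `candidates`, `selection` (or NULL), `x` (conditional indicator matrix
#'   of the realised set, full encoding), `x_reduced`, `activity`
#'   (an `activity_table`), `beta`, `sigma`, `intercept`, `seed`.
#' @export
generate_study <- function(library_shape = c(pIa = 6, pIb = 2, pII = 2, pIII = 6),
                           beta = NULL, sigma = 0.45, n_select = 18,
                           intercept = 4, seed = 1) {
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (is.null(names(library_shape))) {
    names(library_shape) <- paste0("p", seq_along(library_shape))
  }
  lib <- bb_library(lapply(stats::setNames(nm = names(library_shape)), function(pos) {
    paste0("f", seq_len(library_shape[[pos]]))
  }))
  cs <- enumerate_candidates(lib)
  frag_labels <- colnames(indicator_matrix(cs, encoding = "full"))
  if (is.null(beta)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(.child_seed(seed, 1L))
    beta <- stats::setNames(stats::rnorm(length(frag_labels), 0, 0.75), frag_labels)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  } else {
    missing <- setdiff(frag_labels, names(beta))
    if (length(missing)) {
      beta[missing] <- 0
    }
    beta <- beta[frag_labels]
  }

  selection <- NULL
  idx <- seq_len(cs$n)
  if (!is.null(n_select)) {
    if (n_select > cs$n) stop("infeasible n_select", call. = FALSE)
    selection <- d_optimal_select(cs, n_select, n_starts = 20,
                                  seed = .child_seed(seed, 2L))
    idx <- selection$selected
  }
  x_full <- indicator_matrix(cs, encoding = "full")[idx, , drop = FALSE]
  x_red <- indicator_matrix(cs, encoding = "reduced")[idx, , drop = FALSE]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(.child_seed(seed, 3L))
  eps <- stats::rnorm(length(idx), 0, sigma)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  y <- intercept + drop(x_full %*% beta) + eps

  activity <- data.frame(
    id = rownames(x_full),
    name = rownames(x_full),
    smiles = NA_character_,
    ic50_uM = pic50_to_ic50(y),
    ic50_lo_uM = NA_real_, ic50_hi_uM = NA_real_,
    pic50 = y,
    protonation = NA_character_,
    censored = FALSE,
    stringsAsFactors = FALSE
  )
  activity <- structure(activity, role = "train", set_label = "synthetic",
                        warnings = character(0),
                        class = c("activity_table", "data.frame"))

  structure(list(library = lib, candidates = cs, selection = selection,
                 x = descriptor_matrix(x_full, "conditional"),
                 x_reduced = descriptor_matrix(x_red, "conditional"),
                 activity = activity, beta = beta, sigma = sigma,
                 intercept = intercept, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d candidates, %d realised molecules, sigma = %.2f, seed = %d\n",
              x$candidates$n, nrow(x$x), x$sigma, x$seed))
  invisible(x)
}

#' Generate correlated quantitative descriptor blocks
#'
#' Samples Gaussian descriptors whose target correlation matrix is built
#' from independent blocks: descriptors within a block share a common
#' target correlation, cross-block correlations default to zero.  This
#' emulates the confounding patterns of real physicochemical descriptor
#' tables — e.g. a two-descriptor block at target 0.94 mimics a pair of
#' frontier-orbital energies that cannot be resolved from one another.
#' The implied correlation matrix is checked for positive
#' semi-definiteness before sampling.
#'
#' @param n_rows Number of compounds.
#' @param block_sizes Integer vector of block sizes.
#' @param within Target correlation inside each block (recycled).
#' @param between Target correlation across blocks (default 0).
#' @param seed Integer seed.
#' @return A [descriptor_matrix()] of kind `quantitative`, columns
#'   `blk<i>_d<j>`, with the target matrix in attribute `target_cor`.
#' @export
generate_descriptors <- function(n_rows, block_sizes, within = 0.9,
                                 between = 0, seed = 1) {
  k <- sum(block_sizes)
  within <- rep_len(within, length(block_sizes))
  target <- matrix(between, k, k)
  at <- 0L
  cn <- character(k)
  for (b in seq_along(block_sizes)) {
    idx <- at + seq_len(block_sizes[b])
    target[idx, idx] <- within[b]
    cn[idx] <- paste0("blk", b, "_d", seq_len(block_sizes[b]))
    at <- at + block_sizes[b]
  }
  diag(target) <- 1
  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("requested correlation structure is not positive semi-definite", call. = FALSE)
  # PSD square root tolerating a semi-definite target
  es <- eigen(target, symmetric = TRUE)
  root <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), k) %*% t(es$vectors)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  z <- matrix(stats::rnorm(n_rows * k), n_rows, k)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  m <- z %*% root
  dimnames(m) <- list(sprintf("cpd%04d", seq_len(n_rows)), cn)
  out <- descriptor_matrix(m, "quantitative")
  attr(out, "target_cor") <- target
  out
}

#' Write a synthetic study to plain-text files
#'
#' Writes the library YAML, the activity CSV, the conditional indicator
#' CSV, and a truth JSON (beta, sigma, intercept, seed) into a directory.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    library = file.path(dir, "library.yaml"),
    activity = file.path(dir, "activity.csv"),
    indicators = file.path(dir, "indicators.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_library(study$library, paths["library"])
  utils::write.csv(as.data.frame(study$activity), paths["activity"],
                   row.names = FALSE, quote = FALSE, na = "")
  write_matrix_csv(study$x, paths["indicators"])
  jsonlite::write_json(
    list(beta = as.list(study$beta), sigma = study$sigma,
         intercept = study$intercept, seed = study$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
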