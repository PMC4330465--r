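#' Absolute pairwise correlation matrix of descriptors
#'
#' Columns are centered and scaled to unit variance with the population
#' divisor, after which the correlation of descriptors 1 and 2 is
#' `rho = sum_i x_i1 * x_i2 / N` — exactly the Pearson coefficient.
#' Coefficients are reported as absolute values, so entries lie in
#' \[0, 1\] with a unit diagonal.
#'
#' @param m Numeric matrix (rows = compounds, columns = named descriptors);
#'   at least 3 rows, no constant columns.
#' @return A K x K matrix of class `correlation_matrix` with attribute
#'   `n_obs`.
#' @export
correlation_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need at least 3 observations", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  scaled <- autoscale(m, divisor = "population")$scaled
  rho <- abs(crossprod(scaled) / nrow(m))
  # guard against floating drift off the definitional bounds
  rho[rho > 1] <- 1
  diag(rho) <- 1
  structure(rho, n_obs = nrow(m),
            class = c("correlation_matrix", class(rho)))
}

#' Screen a correlation matrix for redundant descriptor pairs
#'
#' Lists every off-diagonal pair whose absolute correlation exceeds
#' `threshold` (default 0.7, the conventional redundancy cutoff).  When
#' anchor descriptors are named — e.g. surface area and the number of
#' rotatable bonds — the report also counts, per anchor set, how many other
#' descriptors exceed the threshold against at least one anchor.
#'
#' @param cm A [correlation_matrix()].
#' @param threshold Cutoff in (0, 1).
#' @param anchors Optional character vector of descriptor names.
#' @return Object of class `redundancy_report`: list with `pairs`
#'   (data.frame `name_a`, `name_b`, `rho`, sorted by decreasing rho),
#'   `anchor_flagged` (names correlated above threshold with any anchor),
#'   `threshold`.
#' @export
redundant_pairs <- function(cm, threshold = 0.7, anchors = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0,1)", call. = FALSE)
  nm <- colnames(cm)
  idx <- which(upper.tri(cm) & cm > threshold, arr.ind = TRUE)
  pairs <- data.frame(name_a = nm[idx[, 1]], name_b = nm[idx[, 2]],
                      rho = cm[idx], stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$rho), , drop = FALSE]
  rownames(pairs) <- NULL
  anchor_flagged <- NULL
  if (!is.null(anchors)) {
    unknown <- setdiff(anchors, nm)
    if (length(unknown)) {
      stop("unknown anchor descriptor(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    sub <- cm[setdiff(nm, anchors), anchors, drop = FALSE]
    anchor_flagged <- rownames(sub)[apply(sub, 1, max) > threshold]
  }
  structure(list(pairs = pairs, anchor_flagged = anchor_flagged,
                 threshold = threshold),
            class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf("Redundancy screen (|rho| > %.2f): %d pair(s)\n",
              x$threshold, nrow(x$pairs)))
  if (nrow(x$pairs)) print.data.frame(utils::head(x$pairs, 20))
  if (!is.null(x$anchor_flagged)) {
    cat(sprintf("%d descriptor(s) redundant with the anchors\n",
                length(x$anchor_flagged)))
  }
  invisible(x)
}

#' Risk of at least one chance correlation among K comparisons
#'
#' At significance level `alpha`, `K` independent pairwise comparisons carry
#' a probability `1 - (1 - alpha)^K` of at least one spurious "significant"
#' correlation — the reason descriptor sets are pruned before modelling.
#'
#' @param k Number of pairwise comparisons (>= 1).
#' @param alpha Per-comparison significance level in (0, 1).
#' @return Probability in (0, 1).
#' @examples
#' chance_correlation_risk(91) # all pairs of 14 descriptors
#' @export
chance_correlation_risk <- function(k, alpha = 0.05) {
  if (!is.numeric(k) || any(k < 1) || any(k != round(k))) {
    stop("'k' must be a positive integer count", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0,1)", call. = FALSE)
  1 - (1 - alpha)^k
}
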