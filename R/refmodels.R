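#' Constant reference model (training mean or median)
#'
#' Predicts the same value — the mean or median of the training pIC50s —
#' for every test compound.  The simplest baseline a published QSAR must
#' beat; its RMSEP on a test set is the typical deviation of that set from
#' the training centre.  For an even-sized training set the median is the
#' midpoint of the two central values.
#'
#' @param train_y Numeric vector of training responses.
#' @param mode `"mean"` or `"median"`.
#' @return Object of class `ref_model`.
#' @export
ref_constant <- function(train_y, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  train_y <- as.numeric(train_y)
  if (length(train_y) == 0 || anyNA(train_y)) stop("invalid training responses", call. = FALSE)
  value <- if (mode == "mean") mean(train_y) else stats::median(train_y)
  structure(list(kind = mode, value = value, n_train = length(train_y)),
            class = "ref_model")
}

#' Univariate least-squares reference model
#'
#' Ordinary linear regression of the response on a single physicochemical
#' descriptor (logP, TPSA or van der Waals area in the canonical panel).
#' The training R-squared of the straight line is reported alongside.
#'
#' @param x Numeric vector, one descriptor for the training compounds
#'   (non-constant, N >= 3).
#' @param y Training responses.
#' @param name Descriptor name used in reports.
#' @return Object of class `ref_model` with `slope`, `intercept`, `r2`.
#' @export
ref_univariate <- function(x, y, name = deparse(substitute(x))) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) stop("need matched x/y with N >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant descriptor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(kind = "univariate_ols", descriptor = name,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2),
            class = "ref_model")
}

#' Nearest-neighbour reference model
#'
#' Each test compound is predicted to have the measured activity of the
#' training compound it is most similar to.  Two sources of the
#' neighbour assignment are supported: an explicit map (reproducing an
#' expert-elicited consensus, the workflow of a chemists' panel) or a
#' computed proxy, the nearest training compound by Euclidean distance in
#' autoscaled descriptor space (ties resolved to the earlier training row).
#' The computed policy is a stand-in for expert judgement and is labelled
#' as such in the provenance.
#'
#' @param train An `activity_table` (or data.frame with `id` and `pic50`)
#'   of training compounds.
#' @param map Optional data.frame `test_id`, `train_id`.
#' @param train_descriptors Optional descriptor matrix for the training
#'   compounds (rows named by id) enabling the computed policy.
#' @return Object of class `ref_model`; predictions require either the map
#'   to cover the test ids, or test-descriptor rows (see
#'   [predict_reference()]).
#' @export
ref_nearest_neighbor <- function(train, map = NULL, train_descriptors = NULL) {
  stopifnot(is.data.frame(train), all(c("id", "pic50") %in% names(train)))
  if (is.null(map) && is.null(train_descriptors)) {
    stop("need a neighbour map or training descriptors", call. = FALSE)
  }
  if (!is.null(map)) {
    stopifnot(all(c("test_id", "train_id") %in% names(map)))
    missing <- setdiff(map$train_id, train$id)
    if (length(missing)) {
      stop("neighbour map refers to unknown training id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  scaling <- NULL
  if (!is.null(train_descriptors)) {
    train_descriptors <- as.matrix(train_descriptors)
    if (is.null(rownames(train_descriptors)) ||
        !all(train$id %in% rownames(train_descriptors))) {
      stop("training descriptors must carry the training ids as rownames", call. = FALSE)
    }
    train_descriptors <- train_descriptors[train$id, , drop = FALSE]
    scaling <- autoscale(train_descriptors)
  }
  structure(list(kind = "nearest_neighbor",
                 train_y = stats::setNames(train$pic50, train$id),
                 map = map,
                 source = if (!is.null(map)) "file" else "computed",
                 scaled_train = if (!is.null(scaling)) scaling$scaled else NULL,
                 scaling = if (!is.null(scaling)) scaling$params else NULL),
            class = "ref_model")
}

#' Three-descriptor PLS reference model
#'
#' A small PLS model on the classic global property triplet (logP, TPSA,
#' vdW area), fit with the same engine and component-entry rule as the main
#' QSAR model unless `ncomp` is forced.
#'
#' @param x Training matrix with the three descriptor columns.
#' @param y Training responses.
#' @param ncomp Optional fixed component count; default: chosen by
#'   [select_components()].
#' @return Object of class `ref_model` wrapping the `pls_model`.
#' @export
ref_small_pls <- function(x, y, ncomp = NULL) {
  x <- as.matrix(x)
  if (is.null(ncomp)) ncomp <- select_components(x, y, a_max = min(3, ncol(x)))$ncomp
  structure(list(kind = "small_pls", model = pls_fit(x, y, ncomp)),
            class = "ref_model")
}

#' Predict test compounds with a reference model
#'
#' @param model A `ref_model`.
#' @param test An `activity_table` or data.frame with `id` (used for the
#'   constant and mapped nearest-neighbour models).
#' @param descriptors Optional test descriptor matrix (rows named by id),
#'   required for univariate, small-PLS and computed nearest-neighbour
#'   models.
#' @return Numeric vector of predictions named by test id; per-compound
#'   `NA` with a `failures` attribute when a compound cannot be covered
#'   (e.g. missing from the neighbour map).
#' @export
predict_reference <- function(model, test, descriptors = NULL) {
  stopifnot(inherits(model, "ref_model"))
  ids <- as.character(test$id)
  failures <- character(0)
  preds <- switch(model$kind,
    mean = ,
    median = stats::setNames(rep(model$value, length(ids)), ids),
    univariate_ols = {
      if (is.null(descriptors) || !model$descriptor %in% colnames(descriptors)) {
        stop("univariate model needs test descriptor '", model$descriptor, "'",
             call. = FALSE)
      }
      x <- descriptors[ids, model$descriptor]
      stats::setNames(model$intercept + model$slope * x, ids)
    },
    small_pls = {
      if (is.null(descriptors)) stop("small PLS model needs test descriptors", call. = FALSE)
      p <- predict(model$model, descriptors[ids, names(model$model$coefficients), drop = FALSE])
      stats::setNames(p$estimate, ids)
    },
    nearest_neighbor = {
      out <- stats::setNames(rep(NA_real_, length(ids)), ids)
      if (model$source == "file") {
        m <- match(ids, model$map$test_id)
        covered <- !is.na(m)
        out[covered] <- model$train_y[model$map$train_id[m[covered]]]
        failures <- ids[!covered]
      } else {
        if (is.null(descriptors)) stop("computed nearest neighbour needs test descriptors", call. = FALSE)
        ts <- apply_scaling(model$scaling, descriptors[ids, , drop = FALSE])
        for (i in seq_along(ids)) {
          d2 <- rowSums(sweep(model$scaled_train, 2, ts[i, ])^2)
          out[i] <- model$train_y[which.min(d2)] # which.min ties to earlier row
        }
      }
      out
    },
    stop("unknown reference model kind: ", model$kind, call. = FALSE)
  )
  if (length(failures)) attr(preds, "failures") <- failures
  preds
}

#' Evaluate reference (and QSAR) models over test sets
#'
#' Computes RMSEP per model and per test set, plus a combined set pooling
#' all test compounds (the union, evaluated with the pooled divisor — for
#' disjoint sets this equals `sqrt(sum(n_s * RMSEP_s^2) / sum(n_s))`).
#'
#' @param predictions Named list (one element per model) of named lists
#'   (one element per set) of prediction vectors aligned with the sets'
#'   measured values.
#' @param measured Named list (one element per set) of measured response
#'   vectors.
#' @param combined_label Name for the pooled column (default `"combined"`).
#' @return data.frame, rows = models, columns = per-set RMSEP + combined.
#' @export
evaluate_references <- function(predictions, measured, combined_label = "combined") {
  stopifnot(is.list(predictions), is.list(measured), length(measured) >= 1)
  sets <- names(measured)
  rows <- lapply(names(predictions), function(mod) {
    per_set <- vapply(sets, function(s) {
      p <- predictions[[mod]][[s]]
      if (is.null(p)) return(NA_real_)
      rmsep(measured[[s]], p)
    }, numeric(1))
    pooled_pred <- unlist(predictions[[mod]][sets], use.names = FALSE)
    pooled_meas <- unlist(measured[sets], use.names = FALSE)
    comb <- if (length(pooled_pred) == length(pooled_meas) && !anyNA(per_set)) {
      rmsep(pooled_meas, pooled_pred)
    } else NA_real_
    stats::setNames(c(per_set, comb), c(sets, combined_label))
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- names(predictions)
  out
}
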