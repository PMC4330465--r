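#' Convert an IC50 in micromolar to pIC50
#'
#' pIC50 is the negative decadic logarithm of the half-maximal inhibitory
#' concentration expressed in molar units.  Because activities are stored in
#' micromolar throughout the package, the conversion is
#' `pIC50 = 6 - log10(IC50_uM)`; the constant 6 is the µM-to-M offset and is
#' deliberately not configurable.
#'
#' @param ic50 Numeric vector of IC50 values in µM; must be positive and
#'   finite.
#' @return Numeric vector of pIC50 values (dimensionless).
#' @examples
#' ic50_to_pic50(4250) # 2.37 at 2 d.p.
#' ic50_to_pic50(100)  # 4
#' @seealso [pic50_to_ic50()]
#' @export
ic50_to_pic50 <- function(ic50) {
  if (!is.numeric(ic50) || length(ic50) == 0) {
    stop("'ic50' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("IC50 values must be positive and finite (in µM)", call. = FALSE)
  }
  6 - log10(ic50)
}

#' Convert a pIC50 back to an IC50 in micromolar
#'
#' Exact inverse of [ic50_to_pic50()] up to floating-point error.
#'
#' @param pic50 Numeric vector of pIC50 values.
#' @return IC50 values in µM.
#' @export
pic50_to_ic50 <- function(pic50) {
  if (!is.numeric(pic50) || any(!is.finite(pic50))) {
    stop("'pic50' must be finite numeric", call. = FALSE)
  }
  10^(6 - pic50)
}

#' Read an activity table from CSV
#'
#' Expected columns: `id` (required) plus at least one of `ic50_uM` and
#' `pic50`.  Optional columns: `name`, `smiles`, `ic50_lo_uM`, `ic50_hi_uM`,
#' `protonation`.  A leading `>` in `ic50_uM` marks a censored measurement
#' (e.g. poor solubility); such rows keep their printed pIC50, carry
#' `censored = TRUE`, and are excluded from the IC50/pIC50 consistency check.
#'
#' Where `pic50` is absent it is back-filled from `ic50_uM`.  Where both are
#' present they are cross-checked: a discrepancy beyond 0.005 plus the
#' rounding slack of a 2-decimal source is collected into the table's
#' `warnings` attribute (flagged, not fatal).
#'
#' @param path Path to a CSV file (UTF-8, comma separated, `.` decimal).
#' @param role `"train"` or `"test"`.
#' @param set_label Free-text label for the set (e.g. `"Set1"`).
#' @return An object of class `activity_table`: a `data.frame` with columns
#'   `id`, `name`, `smiles`, `ic50_uM`, `ic50_lo_uM`, `ic50_hi_uM`, `pic50`,
#'   `protonation`, `censored`, and attributes `role`, `set_label`,
#'   `warnings`.
#' @export
read_activity_csv <- function(path, role = c("train", "test"), set_label = "") {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) stop("activity CSV has no data rows: ", path, call. = FALSE)
  if (!"id" %in% names(raw)) stop("activity CSV must have an 'id' column", call. = FALSE)
  if (!any(c("ic50_uM", "pic50") %in% names(raw))) {
    stop("activity CSV needs at least one of 'ic50_uM'/'pic50'", call. = FALSE)
  }
  id <- trimws(raw$id)
  if (anyDuplicated(id)) {
    stop("duplicate compound ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }

  get_chr <- function(col) if (col %in% names(raw)) trimws(raw[[col]]) else rep(NA_character_, nrow(raw))
  num_or_fail <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad)) {
      stop(sprintf("unparsable number '%s' in column '%s', row %d",
                   x[bad[1]], col, bad[1]), call. = FALSE)
    }
    out[x == "" | is.na(x)] <- NA_real_
    out
  }

  ic50_raw <- get_chr("ic50_uM")
  censored <- !is.na(ic50_raw) & grepl("^>", ic50_raw)
  ic50_chr <- sub("^>", "", ic50_raw)
  ic50_chr <- gsub(",", "", ic50_chr) # tolerate thousands separators
  ic50 <- num_or_fail(ic50_chr, "ic50_uM")
  pic50 <- num_or_fail(get_chr("pic50"), "pic50")
  lo <- num_or_fail(gsub(",", "", get_chr("ic50_lo_uM")), "ic50_lo_uM")
  hi <- num_or_fail(gsub(",", "", get_chr("ic50_hi_uM")), "ic50_hi_uM")

  if (any(!is.na(ic50) & ic50 <= 0)) stop("non-positive IC50 in activity CSV", call. = FALSE)
  # a censored IC50 without a printed pIC50 carries no usable activity
  no_activity <- is.na(pic50) & (is.na(ic50) | censored)
  if (any(no_activity)) {
    stop("row(s) without usable activity (need ic50_uM or pic50): ",
         paste(id[no_activity], collapse = ", "), call. = FALSE)
  }

  warnings <- character(0)
  ci_bad <- !is.na(lo) & !is.na(hi) & !is.na(ic50) & !censored & !(lo <= ic50 & ic50 <= hi)
  if (any(ci_bad)) {
    warnings <- c(warnings, sprintf("compound %s: IC50 outside its confidence interval", id[ci_bad]))
  }

  # back-fill pIC50, then cross-check rows that printed both values
  from_ic50 <- ic50_to_pic50(ifelse(is.na(ic50) | censored, 1, ic50))
  fill <- is.na(pic50) & !is.na(ic50) & !censored
  pic50[fill] <- from_ic50[fill]
  both <- !is.na(pic50) & !is.na(ic50) & !censored & !fill
  # 0.005 direct slack + 0.005 for a source rounded to 2 d.p.
  incons <- both & abs(pic50 - from_ic50) > 0.005 + 0.005
  if (any(incons)) {
    warnings <- c(warnings,
      sprintf("compound %s: pIC50 %.3f inconsistent with IC50 %.4g µM (expected %.3f)",
              id[incons], pic50[incons], ic50[incons], from_ic50[incons]))
  }
  if (any(censored)) {
    warnings <- c(warnings,
      sprintf("compound %s: censored IC50 ('>'), pIC50 taken as printed", id[censored]))
  }

  out <- data.frame(
    id = id,
    name = get_chr("name"),
    smiles = get_chr("smiles"),
    ic50_uM = ic50,
    ic50_lo_uM = lo,
    ic50_hi_uM = hi,
    pic50 = pic50,
    protonation = get_chr("protonation"),
    censored = censored,
    stringsAsFactors = FALSE
  )
  structure(out,
            role = role, set_label = set_label, warnings = warnings,
            class = c("activity_table", "data.frame"))
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("Activity table (%s%s): %d compounds, pIC50 range %.2f-%.2f\n",
              attr(x, "role"),
              if (nzchar(attr(x, "set_label"))) paste0(", ", attr(x, "set_label")) else "",
              nrow(x), min(x$pic50), max(x$pic50)))
  w <- attr(x, "warnings")
  if (length(w)) cat("Flags:\n", paste0("  - ", w, collapse = "\n"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)[c("id", "ic50_uM", "pic50")], 10))
  invisible(x)
}

#' Construct a descriptor matrix
#'
#' @param values Numeric matrix, rows = compounds, columns = descriptors.
#'   Row and column names are required.
#' @param kind `"quantitative"` for physicochemical descriptors,
#'   `"conditional"` for binary fragment indicators (values must be 0/1).
#' @return A numeric matrix of class `descriptor_matrix` with a `kind`
#'   attribute.  Scope prefixes (`GLOBAL_`, `CAS_`, `PAS_`) in column names
#'   are preserved verbatim.
#' @export
descriptor_matrix <- function(values, kind = c("quantitative", "conditional")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("descriptor matrix needs row (compound id) and column (descriptor) names",
         call. = FALSE)
  }
  if (anyNA(values)) stop("descriptor matrix contains missing cells", call. = FALSE)
  if (kind == "conditional" && !all(values %in% c(0, 1))) {
    stop("conditional descriptor matrix must be binary (0/1)", call. = FALSE)
  }
  structure(values, kind = kind, class = c("descriptor_matrix", class(values)))
}

#' Read a descriptor matrix from CSV
#'
#' First column must be `id`; remaining columns are descriptors.  Rows must
#' be rectangular and fully numeric; a conditional matrix is additionally
#' validated as binary.
#'
#' @inheritParams descriptor_matrix
#' @param path Path to the CSV file.
#' @return A [descriptor_matrix()].
#' @export
read_matrix_csv <- function(path, kind = c("quantitative", "conditional")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("matrix CSV must have id + >=1 descriptor column", call. = FALSE)
  if (names(raw)[1] != "id") stop("first column of a matrix CSV must be 'id'", call. = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate ids in matrix CSV", call. = FALSE)
  vals <- raw[-1]
  notnum <- !vapply(vals, is.numeric, logical(1))
  if (any(notnum)) {
    stop("non-numeric descriptor column(s): ",
         paste(names(vals)[notnum], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  descriptor_matrix(m, kind = kind)
}

#' Write a descriptor matrix to CSV (inverse of [read_matrix_csv()])
#' @param m A matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Center and scale a matrix to unit variance
#'
#' Column-wise autoscaling as used before both D-optimality calculations and
#' PLS model building.  The default population divisor (`/N`) makes the
#' correlation formula in [correlation_matrix()] coincide exactly with the
#' Pearson coefficient of scaled columns; the sample divisor (`/(N-1)`) is
#' available for cross-checks.
#'
#' @param m Numeric matrix.
#' @param divisor `"population"` (default) or `"sample"`.
#' @param drop_constant If `TRUE`, constant columns are dropped (and recorded
#'   in the returned params) instead of raising an error.
#' @return A list with `scaled` (the transformed matrix) and `params`, an
#'   object of class `scaling_params` that can be re-applied to new rows with
#'   [apply_scaling()] (train scaling is applied to test rows, never refit).
#' @export
autoscale <- function(m, divisor = c("population", "sample"), drop_constant = FALSE) {
  divisor <- match.arg(divisor)
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows to autoscale", call. = FALSE)
  mu <- colMeans(m)
  ctr <- sweep(m, 2, mu)
  n <- nrow(m)
  denom <- if (divisor == "population") n else n - 1
  s <- sqrt(colSums(ctr^2) / denom)
  const <- s <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  dropped <- character(0)
  if (any(const)) {
    if (!drop_constant) {
      stop("constant column(s): ",
           paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    }
    dropped <- colnames(m)[const]
    ctr <- ctr[, !const, drop = FALSE]
    mu <- mu[!const]
    s <- s[!const]
  }
  scaled <- sweep(ctr, 2, s, "/")
  params <- structure(
    list(column_means = mu, column_scales = s, divisor_mode = divisor,
         dropped = dropped),
    class = "scaling_params")
  list(scaled = scaled, params = params)
}

#' Apply stored scaling parameters to new rows
#' @param params A `scaling_params` object from [autoscale()].
#' @param m New matrix with (at least) the scaled columns.
#' @return The scaled matrix, columns ordered as in `params`.
#' @export
apply_scaling <- function(params, m) {
  stopifnot(inherits(params, "scaling_params"))
  m <- as.matrix(m)
  cols <- names(params$column_means)
  if (!is.null(colnames(m))) {
    missing <- setdiff(cols, colnames(m))
    if (length(missing)) {
      stop("new data lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    m <- m[, cols, drop = FALSE]
  } else if (ncol(m) != length(cols)) {
    stop("column count mismatch when applying scaling", call. = FALSE)
  }
  sweep(sweep(m, 2, params$column_means), 2, params$column_scales, "/")
}

#' Invert [apply_scaling()]
#' @inheritParams apply_scaling
#' @export
unscale <- function(params, m) {
  stopifnot(inherits(params, "scaling_params"))
  sweep(sweep(as.matrix(m), 2, params$column_scales, "*"), 2,
        params$column_means, "+")
}
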