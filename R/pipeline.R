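#' Descriptor names of the curated 14-descriptor QSAR panel
#'
#' The panel combines global whole-molecule properties with properties of
#' the substructures binding the catalytic (CAS) and peripheral (PAS)
#' anionic sites of acetylcholinesterase: flexibility (fraction of
#' rotatable bonds), lipophilicity (logP), polar and total van der Waals
#' surface areas, shape (normalised principal moment of inertia, radius of
#' gyration), frontier-orbital energies and dipole moment.  It ships as a
#' packaged configuration for [descriptor_subset()]; the selection itself
#' is a modelling choice, made from covariance evidence plus domain
#' knowledge, not an automatic screen.
#'
#' @return Character vector of 14 descriptor names with `CAS_`/`PAS_`
#'   scope prefixes.
#' @export
qsar_descriptor_panel <- function() {
  c("b_1rotR", "logP(o/w)", "TPSA", "vdw_area", "rgyr",
    "CAS_Q_VSA_FPNEG", "CAS_Q_VSA_FPPOS", "CAS_AM1_HOMO", "CAS_AM1_LUMO",
    "CAS_dipole",
    "PAS_Q_VSA_FPOS", "PAS_Q_VSA_FPPOS", "PAS_AM1_LUMO", "PAS_npr1")
}

#' Slice a descriptor matrix to a named subset
#'
#' @param m A [descriptor_matrix()] (or plain named matrix).
#' @param names Character vector of column names to keep, e.g.
#'   [qsar_descriptor_panel()].
#' @return The column-sliced matrix (scope prefixes preserved).
#' @export
descriptor_subset <- function(m, names) {
  missing <- setdiff(names, colnames(m))
  if (length(missing)) {
    stop("unknown descriptor name(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- m[, names, drop = FALSE]
  if (inherits(m, "descriptor_matrix")) {
    out <- descriptor_matrix(out, attr(m, "kind"))
  }
  out
}

#' Default workflow configuration
#'
#' Defaults follow the study conventions: 200 permutations, redundancy
#' threshold 0.7, 90% coefficient confidence level, alpha 0.05, minimum
#' fragment occurrence 2, component cap 3 with Q2 entry limit 0.05.
#'
#' @param out_dir Output directory.
#' @param ... Overrides merged over the defaults.
#' @return Named list.
#' @export
workflow_config <- function(out_dir, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = 1L,
    synthetic = list(shape = c(pIa = 6, pIb = 2, pII = 2, pIII = 6),
                     sigma = 0.45, n_select = 18),
    activity = NULL,          # path to activity CSV (overrides synthetic)
    conditional = NULL,       # path to conditional descriptor CSV
    quantitative = NULL,      # path to quantitative descriptor CSV
    subset = NULL,            # descriptor names for the QSAR stage
    threshold = 0.7,
    anchors = NULL,
    ncomp = "auto",
    a_max = 3,
    q2_limit = 0.05,
    n_perm = 200,
    ci_level = 0.90,
    alpha = 0.05,
    min_occurrence = 2
  )
  utils::modifyList(cfg, list(...))
}

.write_num_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the end-to-end design/model/validate workflow
#'
#' Executes the stages in order — data (load or generate), covariance
#' screen, PLS fit with component selection, validation (leave-one-out
#' cross-validation, jack-knife coefficient intervals, response
#' permutation), training applicability domain, reference models — and
#' writes per-stage reports plus a provenance manifest into
#' `config$out_dir`.  All numeric outputs are written at full precision so
#' a rerun with the same configuration and seed is byte-identical.
#'
#' @param config A [workflow_config()] list (or path to a YAML file with
#'   the same fields).
#' @return Invisibly, a list with the in-memory stage results and the
#'   output directory.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- utils::modifyList(workflow_config(""), yaml::read_yaml(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "smdqsar",
                   version = as.character(utils::packageVersion("smdqsar")),
                   parameters = config[setdiff(names(config), "out_dir")],
                   inputs = list())
  res <- list()

  ## -- data stage
  if (!is.null(config$activity)) {
    act <- read_activity_csv(config$activity, role = "train")
    manifest$inputs$activity <- unname(tools::md5sum(config$activity))
    x <- NULL
    if (!is.null(config$conditional)) {
      x <- read_matrix_csv(config$conditional, "conditional")
      manifest$inputs$conditional <- unname(tools::md5sum(config$conditional))
    }
    if (!is.null(config$quantitative)) {
      x <- read_matrix_csv(config$quantitative, "quantitative")
      manifest$inputs$quantitative <- unname(tools::md5sum(config$quantitative))
    }
    if (is.null(x)) stop("file-based run needs a descriptor matrix", call. = FALSE)
    x <- x[act$id, , drop = FALSE]
    study <- NULL
  } else {
    study <- generate_study(library_shape = config$synthetic$shape,
                            sigma = config$synthetic$sigma,
                            n_select = config$synthetic$n_select,
                            seed = config$seed)
    act <- study$activity
    x <- study$x_reduced
    write_study(study, file.path(config$out_dir, "synthetic_input"))
  }
  if (!is.null(config$subset)) x <- descriptor_subset(x, config$subset)
  y <- act$pic50
  res$activity <- act
  res$x <- x

  ## -- design diagnostics (synthetic runs carry their own selection)
  if (!is.null(study) && !is.null(study$selection)) {
    bal <- balance_report(study$selection, study$candidates,
                          threshold = config$min_occurrence)
    .write_num_csv(as.data.frame(bal), file.path(config$out_dir, "design_balance.csv"))
    res$design <- list(selection = study$selection, balance = bal)
    manifest$design <- list(log_det = study$selection$log_det,
                            condition_number = study$selection$condition_number,
                            balance_pass = attr(bal, "verdict"))
  }

  ## -- covariance stage
  cm <- correlation_matrix(x)
  red <- redundant_pairs(cm, threshold = config$threshold, anchors = config$anchors)
  write_matrix_csv(round(unclass(cm), 10), file.path(config$out_dir, "correlation_matrix.csv"))
  jsonlite::write_json(
    list(threshold = red$threshold, n_pairs = nrow(red$pairs),
         pairs = red$pairs, anchor_flagged = red$anchor_flagged,
         chance_correlation_risk = chance_correlation_risk(choose(ncol(x), 2))),
    file.path(config$out_dir, "redundancy.json"), auto_unbox = TRUE, digits = NA)
  res$covariance <- list(correlation = cm, redundancy = red)

  ## -- model stage
  ncomp <- config$ncomp
  if (identical(ncomp, "auto")) {
    selc <- select_components(x, y, a_max = config$a_max, limit = config$q2_limit)
    ncomp <- selc$ncomp
    res$component_selection <- selc
  }
  cv <- loo_cv(x, y, ncomp)
  model <- cv$model
  ci <- jackknife_ci(cv, level = config$ci_level)
  perm <- permutation_test(x, y, ncomp, n_perm = config$n_perm, seed = config$seed)
  res$model <- model; res$cv <- cv; res$ci <- ci; res$permutation <- perm

  write_pls_model(model, file.path(config$out_dir, "model.json"))
  .write_num_csv(data.frame(id = act$id, measured = y, fitted = model$fitted,
                            loo_predicted = cv$loo_predictions),
                 file.path(config$out_dir, "fitted.csv"))
  .write_num_csv(as.data.frame(ci), file.path(config$out_dir, "coefficients.csv"))
  .write_num_csv(data.frame(id = act$id, dmodx = dmodx(model),
                            dcrit = dmodx_crit(model, config$alpha)),
                 file.path(config$out_dir, "dmodx.csv"))
  .write_num_csv(perm$perms, file.path(config$out_dir, "permutations.csv"))

  ## -- reference models (constant baselines always computable)
  refs <- list(mean = ref_constant(y, "mean"), median = ref_constant(y, "median"))
  preds <- lapply(refs, function(m) list(train = predict_reference(m, act)))
  ref_tab <- evaluate_references(preds, list(train = y))
  # training-set comparison of the fitted model against measurements
  comp <- compare_predictions(model$fitted, y, alpha = config$alpha)
  .write_num_csv(cbind(model = rownames(ref_tab), ref_tab),
                 file.path(config$out_dir, "reference_models.csv"))
  .write_num_csv(as.data.frame(comp), file.path(config$out_dir, "comparison_tests.csv"))
  res$references <- ref_tab; res$comparison <- comp

  manifest$model <- list(ncomp = ncomp, r2y = model$r2y, adj_r2y = model$adj_r2y,
                         q2 = cv$q2, rmsee = model$rmsee,
                         permutation_pass = perm$verdict)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- config$out_dir
  invisible(res)
}
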