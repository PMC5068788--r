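#' Build a pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis. Defaults equal the
#' reference workflow: pretreatment log + mean-center + Pareto, folds 6/7/8
#' with the permutation test at 7 folds and 500 permutations, 200 Monte-Carlo
#' subsets at inclusion probability 0.70 with top-50 ranking and a strict
#' >90% panel rule, q-value threshold 20%, annotation tolerance 10 ppm. All
#' stage seeds are derived deterministically from `seed`.
#'
#' @param class_col metadata column holding the class label.
#' @param case class level treated as the case group.
#' @param constraint_covariates metadata columns used as oCPLS2-DA
#'   constraints (and in the confounding screen).
#' @param ncomp number of latent components.
#' @param folds fold counts for cross-validation.
#' @param perm_folds fold count carrying the permutation test.
#' @param n_perm number of permutations.
#' @param stability a [stability_config()].
#' @param q_threshold univariate q-value threshold.
#' @param tolerance_ppm annotation mass tolerance.
#' @param ionization_mode `"negative"` or `"positive"` (selects the adduct).
#' @param pretreat a [pretreat_spec()].
#' @param seed master seed.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(class_col = "class", case = NULL,
                       constraint_covariates = NULL, ncomp = 2,
                       folds = c(6, 7, 8), perm_folds = 7, n_perm = 500,
                       stability = stability_config(), q_threshold = 0.20,
                       tolerance_ppm = 10, ionization_mode = "negative",
                       pretreat = pretreat_spec(), seed = 1L) {
  structure(list(class_col = class_col, case = case,
                 constraint_covariates = constraint_covariates,
                 ncomp = ncomp, folds = folds, perm_folds = perm_folds,
                 n_perm = n_perm, stability = stability,
                 q_threshold = q_threshold, tolerance_ppm = tolerance_ppm,
                 ionization_mode = match.arg(ionization_mode,
                                             c("negative", "positive")),
                 pretreat = pretreat, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()], with `pretreat:`
#' (`log`, `centering`, `scaling`) and `stability:` (`n_subsets`,
#' `inclusion_prob`, `top_k`, `freq_threshold`) as nested maps.
#'
#' @param path YAML file.
#' @return a [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), setdiff(names(formals(run_config)),
                                        c("stability", "pretreat")))]
  if (!is.null(y$pretreat)) args$pretreat <- do.call(pretreat_spec, y$pretreat)
  if (!is.null(y$stability))
    args$stability <- do.call(stability_config, y$stability)
  do.call(run_config, args)
}

#' Run the full discrimination pipeline on one feature table
#'
#' Executes, in order: the metadata confounding screen, pretreatment and
#' constraint encoding, the oCPLS2-DA fit with post-transformation,
#' cross-validation at the configured fold counts, the permutation test,
#' cross-validated ROC analysis, Monte-Carlo stability selection, the
#' univariate scan, and adduct-based annotation of the panel features. All
#' randomness derives from the master seed, so reruns with the same inputs
#' and configuration reproduce every number exactly.
#'
#' @param features numeric matrix (samples x RT_mz features) or a path read
#'   with [read_feature_table()].
#' @param metadata data.frame or path read with [read_metadata()]; must
#'   contain the class column and any constraint covariates.
#' @param config a [run_config()].
#' @param compounds compound table for annotation (default: bundled).
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `frequencies.csv`, `univariate.csv`, `annotations.csv` and
#'   `roc_curve.csv`.
#' @return list of class `"run_report"`.
#' @export
run_pipeline <- function(features, metadata, config = run_config(),
                         compounds = compound_table(), out_dir = NULL) {
  if (is.character(features)) features <- read_feature_table(features)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  features <- as.matrix(features)
  if (!is.null(metadata$sample_id) && !is.null(rownames(features))) {
    if (!setequal(rownames(features), metadata$sample_id))
      stop("sample ids of the feature table and metadata do not match")
    metadata <- metadata[match(rownames(features), metadata$sample_id), ]
  } else if (nrow(features) != nrow(metadata)) {
    stop("feature table and metadata disagree on the number of samples")
  }
  if (!config$class_col %in% names(metadata))
    stop("class column '", config$class_col, "' not found in metadata")
  missing_cov <- setdiff(config$constraint_covariates, names(metadata))
  if (length(missing_cov))
    stop("constraint covariate(s) not in metadata: ",
         paste(missing_cov, collapse = ", "))
  labels <- as.factor(metadata[[config$class_col]])
  if (min(table(labels)) < 3) stop("each class needs at least 3 samples")
  seed <- config$seed

  screen <- if (length(config$constraint_covariates) >= 1)
    confounding_screen(metadata, config$class_col,
                       config$constraint_covariates,
                       n_folds = config$perm_folds, seed = seed)
  else NULL

  zb <- if (length(config$constraint_covariates))
    encode_constraints(metadata, config$constraint_covariates) else NULL

  fit <- ocpls2da(features, labels, constraints = zb, ncomp = config$ncomp,
                  pretreat = config$pretreat, case = config$case)
  validation <- validate_model(features, labels, constraints = zb,
                               ncomp = config$ncomp, folds = config$folds,
                               perm_folds = config$perm_folds,
                               n_perm = config$n_perm, seed = seed,
                               pretreat = config$pretreat, case = config$case)

  stab_cfg <- config$stability
  stab_cfg$seed <- seed + 1L
  stability <- stability_select(features, labels, constraints = zb,
                                ncomp = max(1L, fit$A_pred),
                                config = stab_cfg,
                                pretreat = config$pretreat,
                                case = config$case)

  L <- if (config$pretreat$log) log(features) else features
  univar <- univariate_scan(L, labels, q_threshold = config$q_threshold,
                            case = config$case)

  ann <- NULL
  if (length(stability$panel)) {
    fid <- parse_feature_ids(stability$panel)
    fid$mode <- config$ionization_mode
    ann <- match_features(fid, compounds, config$tolerance_ppm)
  }

  report <- structure(list(screen = screen, fit = fit,
                           validation = validation, stability = stability,
                           univariate = univar, annotations = ann,
                           config = config,
                           provenance = list(package = "ocplsda",
                                             version = as.character(
                                               utils::packageVersion("ocplsda")),
                                             seed = seed)),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Pipeline report ==\n")
  if (!is.null(x$screen)) print(x$screen)
  print(x$validation)
  print(x$stability)
  cat(sprintf("Univariate: %d/%d features significant at q < %.2f\n",
              sum(x$univariate$significant), nrow(x$univariate),
              x$config$q_threshold))
  if (!is.null(x$annotations) && nrow(x$annotations))
    cat(sprintf("Annotation: %d putative match(es) for %d panel feature(s)\n",
                nrow(x$annotations), length(unique(x$annotations$feature_id))))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- report$validation
  payload <- list(
    R2 = v$R2, A_pred = v$A_pred, A_orth = v$A_orth,
    Q2_by_folds = as.list(v$Q2_by_folds),
    perm_pvalue = v$perm_pvalue, n_permutations = v$n_permutations,
    roc = list(auc = v$roc$auc, auc_ci95 = v$roc$auc_ci95,
               sensitivity = v$roc$sensitivity,
               specificity = v$roc$specificity),
    screen = if (is.null(report$screen)) NULL else
      list(q2 = report$screen$q2, confounded = report$screen$confounded),
    stability = list(panel = report$stability$panel,
                     mean_auc = report$stability$mean_auc,
                     mean_sensitivity = report$stability$mean_sensitivity,
                     mean_specificity = report$stability$mean_specificity,
                     n_models_fitted = report$stability$n_models_fitted),
    n_significant_univariate = sum(report$univariate$significant),
    provenance = report$provenance
  )
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  freq <- report$stability$selection_freq
  utils::write.csv(data.frame(feature = names(freq), frequency = freq,
                              in_panel = names(freq) %in%
                                report$stability$panel,
                              row.names = NULL),
                   file.path(out_dir, "frequencies.csv"), row.names = FALSE)
  utils::write.csv(report$univariate, file.path(out_dir, "univariate.csv"),
                   row.names = FALSE)
  if (!is.null(report$annotations))
    utils::write.csv(report$annotations,
                     file.path(out_dir, "annotations.csv"), row.names = FALSE)
  utils::write.csv(report$validation$roc$curve,
                   file.path(out_dir, "roc_curve.csv"), row.names = FALSE)
  invisible(out_dir)
}
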