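# ---- internal lean cross-validation engine ----------------------------------

# Stratified fold assignment; re-randomizes until every fold's training part
# contains both classes (up to 100 attempts).
.stratified_folds <- function(y01, n_folds, max_tries = 100L) {
  n <- length(y01)
  for (try in seq_len(max_tries)) {
    fold_id <- integer(n)
    for (g in unique(y01)) {
      idx <- sample(which(y01 == g))
      fold_id[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    ok <- all(vapply(seq_len(n_folds), function(f) {
      tr <- y01[fold_id != f]
      length(unique(tr)) == 2L
    }, logical(1)))
    if (ok) return(fold_id)
  }
  stop("could not build folds whose training parts contain both classes")
}

# Column stats for centering/scaling on training rows only.
.pre_stats <- function(L, spec) {
  mu <- if (spec$centering == "mean") colMeans(L) else numeric(ncol(L))
  scl <- rep(1, ncol(L))
  if (spec$scaling != "none") {
    s <- .col_sds(L)
    s[s <= .Machine$double.eps^0.5 * pmax(1, abs(mu))] <- 1
    scl <- if (spec$scaling == "pareto") sqrt(s) else s
  }
  list(mu = mu, scl = scl)
}

.apply_stats <- function(L, st) {
  sweep(sweep(L, 2, st$mu), 2, st$scl, "/")
}

# Center training constraint columns and drop degenerate/dependent ones.
.fold_constraints <- function(Zraw, rows) {
  if (is.null(Zraw)) return(NULL)
  Z <- Zraw[rows, , drop = FALSE]
  Z <- sweep(Z, 2, colMeans(Z))
  keep <- .col_sds(Z) > 1e-12
  Z <- Z[, keep, drop = FALSE]
  if (ncol(Z) == 0L) return(NULL)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) Z <- Z[, qz$pivot[seq_len(qz$rank)], drop = FALSE]
  Z
}

# Full cross-validation of the entire pipeline: per fold, pretreatment,
# constraint centering and the (o)CPLS2 fit are recomputed on training rows
# only; held-out responses are predicted and accumulated into
# Q2 = 1 - PRESS/TSS, with TSS referenced to the training-fold class means.
# L is the feature table with any log transform already applied; `spec` must
# therefore have log = FALSE semantics here (only centering/scaling used).
.cv_engine <- function(L, y01, Zraw, A, n_folds, fold_id, spec) {
  n <- nrow(L)
  Yraw <- cbind(y01, 1 - y01)
  press <- 0; tss <- 0
  viol <- 0
  cv_scores <- rep(NA_real_, n)
  for (f in seq_len(n_folds)) {
    te <- which(fold_id == f)
    if (!length(te)) next
    tr <- which(fold_id != f)
    st <- .pre_stats(L[tr, , drop = FALSE], spec)
    Xtr <- .apply_stats(L[tr, , drop = FALSE], st)
    ybar <- colMeans(Yraw[tr, , drop = FALSE])
    Yc <- sweep(Yraw[tr, , drop = FALSE], 2, ybar)
    Zc <- .fold_constraints(Zraw, tr)
    fit <- suppressWarnings(.ocpls_core(Xtr, Yc, Zc, A))
    viol <- max(viol, fit$constraint_viol)
    Xte <- .apply_stats(L[te, , drop = FALSE], st)
    pred <- sweep(Xte %*% fit$B, 2, ybar, "+")
    press <- press + sum((Yraw[te, , drop = FALSE] - pred)^2)
    tss <- tss + sum(sweep(Yraw[te, , drop = FALSE], 2, ybar)^2)
    cv_scores[te] <- pred[, 1]
  }
  list(Q2 = 1 - press / tss, cv_scores = cv_scores,
       max_constraint_violation = viol)
}

# Shared front-end: log once, build y01/Zraw.
.cv_setup <- function(x, y, constraints, pretreat, case) {
  x <- as.matrix(x)
  rb <- response_block(y, case)
  L <- if (isTRUE(pretreat$log)) {
    if (any(x <= 0)) stop("log transform requires positive intensities")
    log(x)
  } else x
  list(L = L, y01 = as.numeric(rb$labels == levels(rb$labels)[1]),
       Zraw = .constraint_matrix(constraints), rb = rb)
}

# ---- user-facing validation operations --------------------------------------

#' N-fold full cross-validation of an oCPLS2-DA model
#'
#' Splits samples into class-stratified folds and, for every fold, refits the
#' entire pipeline — pretreatment statistics, constraint centering and the
#' constrained PLS2 model — on the training part only, then predicts the
#' held-out class responses. Returns `Q2 = 1 - PRESS/TSS` (TSS referenced to
#' the training-fold response means) together with the per-sample
#' cross-validated predicted score of the case response column, the input to
#' cross-validated ROC analysis.
#'
#' @inheritParams ocpls2da
#' @param n_folds number of folds `N`.
#' @param seed integer seed for the stratified fold shuffle.
#' @return list with `Q2`, `cv_scores` (named per sample), `fold_id`.
#' @export
cross_validate <- function(x, y, constraints = NULL, ncomp = 2, n_folds = 7,
                           seed = 1L, pretreat = pretreat_spec(),
                           case = NULL) {
  if (n_folds < 2) stop("n_folds must be at least 2")
  su <- .cv_setup(x, y, constraints, pretreat, case)
  set.seed(as.integer(seed))
  fold_id <- .stratified_folds(su$y01, n_folds)
  out <- .cv_engine(su$L, su$y01, su$Zraw, ncomp, n_folds, fold_id, pretreat)
  names(out$cv_scores) <- rownames(as.matrix(x))
  c(out, list(fold_id = fold_id, n_folds = n_folds,
              case = levels(su$rb$labels)[1]))
}

#' Permutation test on the class responses
#'
#' Builds an empirical null for the cross-validated Q2 by permuting the class
#' labels uniformly while keeping the feature table and the constraints
#' fixed, recomputing the full N-fold cross-validation for each permutation.
#' The p-value uses the add-one estimator
#' `(#\{Q2_perm >= Q2_obs\} + 1) / (n_perm + 1)`.
#'
#' @inheritParams cross_validate
#' @param n_perm number of random permutations.
#' @return list with `p_value`, `q2_obs`, `q2_perm` (vector), `n_perm`.
#' @export
permutation_test <- function(x, y, constraints = NULL, ncomp = 2,
                             n_folds = 7, n_perm = 500, seed = 1L,
                             pretreat = pretreat_spec(), case = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  su <- .cv_setup(x, y, constraints, pretreat, case)
  set.seed(as.integer(seed))
  fold_id <- .stratified_folds(su$y01, n_folds)
  obs <- .cv_engine(su$L, su$y01, su$Zraw, ncomp, n_folds, fold_id, pretreat)
  q2_obs <- obs$Q2
  viol <- obs$max_constraint_violation
  q2_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    yp <- sample(su$y01)
    fid <- .stratified_folds(yp, n_folds)
    cvp <- .cv_engine(su$L, yp, su$Zraw, ncomp, n_folds, fid, pretreat)
    q2_perm[i] <- cvp$Q2
    viol <- max(viol, cvp$max_constraint_violation)
  }
  list(p_value = (sum(q2_perm >= q2_obs) + 1) / (n_perm + 1),
       q2_obs = q2_obs, q2_perm = q2_perm, n_perm = n_perm,
       max_constraint_violation = viol)
}

# Exact midrank Mann-Whitney AUC: P(score_case > score_control) + ties/2.
.auc_mw <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis with DeLong confidence interval
#'
#' Computes the AUC by the exact midrank Mann-Whitney identity (ties counted
#' one half), its 95% DeLong confidence interval (truncated to `[0, 1]`), the
#' full ROC curve, and sensitivity/specificity at the optimal threshold — the
#' score cutoff whose ROC point is closest to the top-left corner, i.e.
#' minimizing `(1 - Se)^2 + (1 - Sp)^2`, with ties broken in favour of higher
#' sensitivity.
#'
#' @param scores per-sample predicted score (higher = more case-like).
#' @param labels two-level class labels.
#' @param case level counted as positive; defaults to the first level.
#' @param ci compute the DeLong interval (skip for speed in resampling loops).
#' @param conf_level confidence level for the interval.
#' @return object of class `"roc_result"`: `auc`, `auc_ci95`, `sensitivity`,
#'   `specificity`, `threshold`, `curve` (data.frame with `fpr`, `tpr`).
#' @export
roc_analysis <- function(scores, labels, case = NULL, ci = TRUE,
                         conf_level = 0.95) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  if (is.null(case)) case <- levels(labels)[1]
  pos <- labels == case
  if (!any(pos) || all(pos)) stop("both classes must be present")
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  auc <- .auc_mw(scores, pos)

  s_pos <- scores[pos]; s_neg <- scores[!pos]
  u <- sort(unique(scores))
  cuts <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  se <- vapply(cuts, function(ct) mean(s_pos > ct), numeric(1))
  sp <- vapply(cuts, function(ct) mean(s_neg <= ct), numeric(1))
  d2 <- (1 - se)^2 + (1 - sp)^2
  cand <- which(d2 <= min(d2) + 1e-12)
  best <- cand[which.max(se[cand])]

  ord <- order(se + (1 - sp))  # from (0,0) to (1,1)
  curve <- data.frame(fpr = c(0, (1 - sp)[ord], 1),
                      tpr = c(0, se[ord], 1),
                      threshold = c(Inf, cuts[ord], -Inf))
  curve <- curve[!duplicated(curve[, c("fpr", "tpr")]), ]

  ci95 <- c(auc, auc)
  if (ci) {
    # a degenerate interval (all ties or perfect separation) collapses to the
    # point AUC; pROC warns about the AUC == 1 case, which is handled here
    ci95 <- tryCatch(suppressWarnings({
      rr <- pROC::roc(response = labels, predictor = as.numeric(scores),
                      levels = c(setdiff(levels(labels), case), case),
                      direction = "<", quiet = TRUE)
      as.numeric(pROC::ci.auc(rr, conf.level = conf_level,
                              method = "delong"))[c(1, 3)]
    }), error = function(e) c(auc, auc))
    if (anyNA(ci95)) ci95 <- c(auc, auc)
    ci95 <- pmin(pmax(ci95, 0), 1)
  }
  structure(list(auc = auc, auc_ci95 = ci95, sensitivity = se[best],
                 specificity = sp[best], threshold = cuts[best],
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.2f-%.2f), Sp = %.2f, Se = %.2f at threshold %.4g\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2], x$specificity,
              x$sensitivity, x$threshold))
  invisible(x)
}

#' Metadata confounding screen
#'
#' Checks whether the clinical metadata alone can discriminate the classes.
#' Fits a PCA on the unit-variance-scaled encoded covariates (with per-PC
#' class t-tests) and a PLS-DA using the metadata as the X-block; "no
#' confounding" is declared when the metadata PLS-DA cross-validated Q2 is
#' at most zero.
#'
#' @param meta metadata data.frame including the class column.
#' @param class_col name of the class column.
#' @param covariates covariate columns to screen; default: all columns except
#'   the class and any `sample_id` column.
#' @param ncomp PLS-DA components for the screen.
#' @param n_folds folds for the metadata Q2.
#' @param seed fold seed.
#' @return object of class `"confounding_screen"`: `q2`, `confounded` flag,
#'   `pca` (scores/explained), `pc_class_p` (per-PC t-test p-values).
#' @export
confounding_screen <- function(meta, class_col = "class", covariates = NULL,
                               ncomp = 1, n_folds = 7, seed = 1L) {
  if (!class_col %in% names(meta)) stop("class column '", class_col, "' not found")
  if (is.null(covariates))
    covariates <- setdiff(names(meta), c(class_col, "sample_id"))
  zb <- encode_constraints(meta, covariates)
  Zmat <- zb$Z_raw
  if (ncol(Zmat) < 1) stop("no usable covariates to screen")
  single <- ncol(Zmat) < 2
  if (single) warning("single covariate: PCA screen skipped, PLS-DA screen only")
  labels <- as.factor(meta[[class_col]])
  spec <- pretreat_spec(log = FALSE, centering = "mean", scaling = "uv")
  cv <- cross_validate(Zmat, labels, constraints = NULL,
                       ncomp = min(ncomp, ncol(Zmat), nrow(Zmat) - 2L),
                       n_folds = n_folds, seed = seed, pretreat = spec)
  pca <- NULL; pc_p <- NULL
  if (!single) {
    pca <- fit_pca(Zmat, ncomp = min(2, ncol(Zmat)), scale. = TRUE)
    pc_p <- apply(pca$scores, 2, function(s)
      stats::t.test(s ~ labels)$p.value)
  }
  structure(list(q2 = cv$Q2, confounded = cv$Q2 > 0, pca = pca,
                 pc_class_p = pc_p, n_folds = n_folds),
            class = "confounding_screen")
}

#' @export
print.confounding_screen <- function(x, ...) {
  cat(sprintf("Metadata screen: %d-fold PLS-DA Q2 = %.3f -> %s\n",
              x$n_folds, x$q2,
              if (x$confounded) "possible confounding" else "no confounding"))
  if (!is.null(x$pc_class_p))
    cat("  per-PC class t-test p:",
        paste(sprintf("%.3f", x$pc_class_p), collapse = ", "), "\n")
  invisible(x)
}

#' Correlation of the predictive score with an external binary factor
#'
#' Point-biserial correlation between the model's first predictive latent
#' score and a binary per-sample factor (e.g. presence of chorioamnionitis),
#' with its two-sided t-test p-value. A non-significant result supports the
#' claim that the discriminating latent variable is not driven by the factor.
#'
#' @param model a fitted [ocpls2da()] model with at least one predictive
#'   component.
#' @param factor binary (0/1 or two-level) per-sample vector.
#' @return list with `correlation` and `p_value`.
#' @export
external_factor_check <- function(model, factor) {
  f <- if (is.factor(factor) || is.character(factor))
    as.numeric(as.factor(factor)) - 1 else as.numeric(factor)
  if (length(unique(f)) < 2) stop("factor is constant: both levels required")
  if (length(unique(f)) > 2) stop("factor must be binary")
  if (model$A_pred < 1) stop("model has no predictive component")
  t_pred <- model$T[, 1]
  r <- stats::cor(t_pred, f)
  n <- length(f)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(correlation = r, p_value = 2 * stats::pt(-abs(tval), n - 2))
}

#' Full validation report for one model configuration
#'
#' Convenience wrapper producing the fit R2, cross-validated Q2 for several
#' fold counts, the permutation p-value for the Q2 at `perm_folds` folds, and
#' cross-validated ROC analysis of the case-response predictions.
#'
#' @inheritParams cross_validate
#' @param folds fold counts to evaluate (default 6, 7, 8).
#' @param perm_folds fold count carrying the permutation test.
#' @param n_perm number of permutations.
#' @return object of class `"validation_report"`.
#' @export
validate_model <- function(x, y, constraints = NULL, ncomp = 2,
                           folds = c(6, 7, 8), perm_folds = 7, n_perm = 500,
                           seed = 1L, pretreat = pretreat_spec(),
                           case = NULL) {
  fit <- ocpls2da(x, y, constraints = constraints, ncomp = ncomp,
                  pretreat = pretreat, case = case)
  q2 <- vapply(folds, function(nf)
    cross_validate(x, y, constraints, ncomp, nf, seed, pretreat, case)$Q2,
    numeric(1))
  names(q2) <- paste0("Q2_", folds, "folds")
  pt <- permutation_test(x, y, constraints, ncomp, perm_folds, n_perm, seed,
                         pretreat, case)
  cv <- cross_validate(x, y, constraints, ncomp, perm_folds, seed, pretreat,
                       case)
  labels <- as.factor(y)
  roc <- roc_analysis(cv$cv_scores, labels,
                      case = if (is.null(case)) levels(labels)[1] else case)
  structure(list(R2 = fit$R2, A_pred = fit$A_pred, A_orth = fit$A_orth,
                 Q2_by_folds = q2, perm_pvalue = pt$p_value,
                 n_permutations = n_perm, roc = roc, folds_seed = seed,
                 model = fit),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Model validation: A = %d+%d, R2 = %.2f\n",
              x$A_pred, x$A_orth, x$R2))
  for (nm in names(x$Q2_by_folds))
    cat(sprintf("  %s = %.2f\n", nm, x$Q2_by_folds[[nm]]))
  cat(sprintf("  permutation p-value = %.3f (%d permutations)\n",
              x$perm_pvalue, x$n_permutations))
  print(x$roc)
  invisible(x)
}
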