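#' Univariate feature scan: Welch t-tests, BH q-values and per-feature ROC
#'
#' The univariate complement to the multivariate model: every feature is
#' tested for a between-class mean difference with a (by default Welch,
#' unequal-variance) two-sample t-test, raw p-values are converted to
#' Benjamini-Hochberg q-values, and each feature is scored by ROC analysis
#' (AUC with DeLong 95% CI, sensitivity and specificity at the
#' closest-to-top-left threshold). Features are flagged significant at
#' `q < q_threshold`.
#'
#' @param x numeric matrix of (pretreated, typically log) intensities,
#'   samples in rows.
#' @param labels two-level class labels.
#' @param q_threshold q-value threshold for the `significant` flag
#'   (default 0.20).
#' @param case positive class for the ROC; defaults to the first level.
#' @param var_equal use the pooled-variance Student t-test instead of Welch.
#' @param roc compute per-feature ROC columns (skip for speed).
#' @return data.frame of class `"univariate_table"`, one row per feature:
#'   `feature`, `t`, `df`, `p`, `q`, `auc`, `auc_lo`, `auc_hi`,
#'   `sensitivity`, `specificity`, `significant`.
#' @export
univariate_scan <- function(x, labels, q_threshold = 0.20, case = NULL,
                            var_equal = FALSE, roc = TRUE) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  if (is.null(case)) case <- levels(labels)[1]
  g1 <- labels == case
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("each class needs at least 2 samples")
  p_feat <- ncol(x)
  feat <- colnames(x) %||% paste0("V", seq_len(p_feat))

  m1 <- colMeans(x[g1, , drop = FALSE]); m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- .col_sds(x[g1, , drop = FALSE])^2
  v2 <- .col_sds(x[!g1, , drop = FALSE])^2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    sem <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, p_feat)
  } else {
    sem <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / sem
  pval <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- !is.finite(sem) | sem <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance feature(s): p set to 1")
    tstat[degenerate] <- NA_real_
    df[degenerate] <- NA_real_
    pval[degenerate] <- 1
  }
  qval <- stats::p.adjust(pval, method = "BH")

  out <- data.frame(feature = feat, t = tstat, df = df, p = pval, q = qval,
                    stringsAsFactors = FALSE)
  if (roc) {
    rc <- lapply(seq_len(p_feat), function(j)
      roc_analysis(x[, j], labels, case = case, ci = TRUE))
    out$auc <- vapply(rc, `[[`, numeric(1), "auc")
    out$auc_lo <- vapply(rc, function(r) r$auc_ci95[1], numeric(1))
    out$auc_hi <- vapply(rc, function(r) r$auc_ci95[2], numeric(1))
    out$sensitivity <- vapply(rc, `[[`, numeric(1), "sensitivity")
    out$specificity <- vapply(rc, `[[`, numeric(1), "specificity")
  }
  out$significant <- out$q < q_threshold
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("univariate_table", "data.frame")
  out
}

#' @export
print.univariate_table <- function(x, n = 10, ...) {
  cat(sprintf("Univariate scan: %d features, %d significant at q < %.2f\n",
              nrow(x), sum(x$significant), attr(x, "q_threshold")))
  print.data.frame(utils::head(x[order(x$q, x$p), ], n), digits = 3,
                   row.names = FALSE)
  invisible(x)
}
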