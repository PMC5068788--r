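#' Pretreatment specification
#'
#' The column-wise pretreatment applied to a feature table before latent-
#' variable modelling. The default — natural-log transform, mean centering and
#' Pareto scaling (division of each centered column by the square root of its
#' standard deviation) — is the field-standard recipe for UPLC-MS peak
#' intensities; every element is configurable.
#'
#' @param log apply `log()` to intensities first (requires strictly positive
#'   values).
#' @param centering `"mean"` or `"none"`.
#' @param scaling `"pareto"`, `"uv"` (unit variance) or `"none"`.
#' @return a list of class `"pretreat_spec"`.
#' @export
pretreat_spec <- function(log = TRUE, centering = c("mean", "none"),
                          scaling = c("pareto", "uv", "none")) {
  structure(list(log = isTRUE(log),
                 centering = match.arg(centering),
                 scaling = match.arg(scaling)),
            class = "pretreat_spec")
}

#' Fit a pretreatment on a training feature table
#'
#' Computes per-feature means and scale divisors on the given table. Columns
#' with zero variance are flagged and given a divisor of 1 so they pass
#' through scaling untouched.
#'
#' @param x numeric matrix or data.frame, samples in rows.
#' @param spec a [pretreat_spec()].
#' @return an object of class `"pretreatment"` holding the spec, fitted means
#'   and fitted scale divisors.
#' @export
fit_pretreatment <- function(x, spec = pretreat_spec()) {
  x <- as.matrix(x)
  if (spec$log) {
    bad <- which(!(x > 0), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("log transform requires positive intensities; cell [%s, %s] = %g",
                   rownames(x)[bad[1, 1]] %||% bad[1, 1],
                   colnames(x)[bad[1, 2]] %||% bad[1, 2],
                   x[bad[1, 1], bad[1, 2]]))
    x <- log(x)
  }
  mu <- if (spec$centering == "mean") colMeans(x) else rep(0, ncol(x))
  sdv <- .col_sds(x)
  zero_var <- sdv <= .Machine$double.eps^0.5 * pmax(1, abs(mu))
  scl <- rep(1, ncol(x))
  if (spec$scaling != "none") {
    if (any(zero_var))
      warning(sum(zero_var), " zero-variance feature(s) excluded from scaling")
    s <- ifelse(zero_var, 1, sdv)
    scl <- if (spec$scaling == "pareto") sqrt(s) else s
  }
  structure(list(spec = spec, means = mu, scales = scl,
                 zero_variance = zero_var,
                 feature_names = colnames(x)),
            class = "pretreatment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  sqrt(colSums((x - rep(mu, each = n))^2) / (n - 1))
}

#' Apply a fitted pretreatment
#'
#' Transforms a table using the statistics fitted on the training table; used
#' unchanged on held-out samples so that cross-validation never leaks held-out
#' information into the pretreatment.
#'
#' @param pre a fitted `"pretreatment"`.
#' @param x table to transform (same features, any samples).
#' @return pretreated numeric matrix.
#' @export
apply_pretreatment <- function(pre, x) {
  x <- as.matrix(x)
  if (!is.null(pre$feature_names) && !is.null(colnames(x))) {
    if (!identical(colnames(x), pre$feature_names)) {
      missing_f <- setdiff(pre$feature_names, colnames(x))
      if (length(missing_f))
        stop("feature mismatch: missing ", paste(utils::head(missing_f, 3), collapse = ", "))
      x <- x[, pre$feature_names, drop = FALSE]
    }
  }
  if (pre$spec$log) x <- log(x)
  x <- sweep(x, 2, pre$means, "-")
  sweep(x, 2, pre$scales, "/")
}

#' Invert a fitted pretreatment
#'
#' Maps a pretreated matrix back to the original intensity scale; the
#' round trip `invert(apply(x))` recovers `x` to numerical precision.
#'
#' @inheritParams apply_pretreatment
#' @export
invert_pretreatment <- function(pre, x) {
  x <- sweep(as.matrix(x), 2, pre$scales, "*")
  x <- sweep(x, 2, pre$means, "+")
  if (pre$spec$log) x <- exp(x)
  x
}

#' Build the centered two-column class-response block
#'
#' Encodes a two-level class factor as a samples-by-2 indicator matrix (each
#' row sums to one before centering) and mean-centers each column. The first
#' response column corresponds to the case level.
#'
#' @param labels factor/character vector with exactly two levels.
#' @param case optional level to treat as the case (first column); defaults to
#'   the first factor level.
#' @return list of class `"response_block"` with `Y` (centered indicators),
#'   `Y_raw`, `means`, `labels`, `case`.
#' @export
response_block <- function(labels, case = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("exactly two classes are required, got ", nlevels(labels))
  if (is.null(case)) case <- levels(labels)[1]
  if (!case %in% levels(labels)) stop("unknown case level '", case, "'")
  lev <- c(case, setdiff(levels(labels), case))
  Yr <- cbind(as.numeric(labels == lev[1]), as.numeric(labels == lev[2]))
  colnames(Yr) <- lev
  mu <- colMeans(Yr)
  structure(list(Y = sweep(Yr, 2, mu), Y_raw = Yr, means = mu,
                 labels = factor(labels, levels = lev), case = case),
            class = "response_block")
}

#' Encode metadata covariates as a centered constraint matrix
#'
#' Continuous covariates map to one centered column each; binary covariates
#' are encoded 0/1 then centered; counts are treated as continuous. Constant
#' covariates carry no constraint information and are dropped with a warning.
#'
#' @param meta metadata data.frame.
#' @param covariates character vector of column names to encode, in order.
#' @return list of class `"constraint_block"` with `Z` (centered, samples x
#'   c), `Z_raw` (uncentered numeric encoding), `means`, and `encoding_map`.
#' @export
encode_constraints <- function(meta, covariates) {
  missing_c <- setdiff(covariates, names(meta))
  if (length(missing_c))
    stop("covariate(s) not found in metadata: ", paste(missing_c, collapse = ", "))
  cols <- lapply(covariates, function(nm) {
    v <- meta[[nm]]
    if (anyNA(v)) stop("covariate '", nm, "' has missing entries")
    if (is.factor(v) || is.character(v)) {
      v <- as.factor(v)
      if (nlevels(v) > 2)
        stop("covariate '", nm, "' has more than two levels; encode it numerically first")
      as.numeric(v == levels(v)[nlevels(v)])
    } else as.numeric(v)
  })
  Zr <- do.call(cbind, cols)
  colnames(Zr) <- covariates
  const <- apply(Zr, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[const], collapse = ", "))
    Zr <- Zr[, !const, drop = FALSE]
  }
  mu <- colMeans(Zr)
  structure(list(Z = sweep(Zr, 2, mu), Z_raw = Zr, means = mu,
                 encoding_map = stats::setNames(as.list(colnames(Zr)),
                                                colnames(Zr))),
            class = "constraint_block")
}

# Accept a constraint_block, a numeric matrix of raw covariate columns, or
# NULL; return the uncentered numeric matrix (centering happens at fit time
# on the training rows).
.constraint_matrix <- function(constraints) {
  if (is.null(constraints)) return(NULL)
  if (inherits(constraints, "constraint_block")) return(constraints$Z_raw)
  Z <- as.matrix(constraints)
  storage.mode(Z) <- "double"
  Z
}
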