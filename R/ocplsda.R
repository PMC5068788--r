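# Core NIPALS engine for (constrained) PLS2.
#
# E: pretreated X (n x p), F: centered Y (n x 2), Z: centered constraints
# (n x c) or NULL. Components are extracted sequentially: the weight w_a is
# the dominant left singular vector of E'F, restricted — when constraints are
# present — to the null space of K = Z'E so that the scores t_a = E w_a are
# exactly orthogonal to Z. E and F are both deflated by each component.
.ocpls_core <- function(E, F, Z = NULL, A, tol = 1e-12) {
  n <- nrow(E); p <- ncol(E)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  C <- matrix(0, ncol(F), A); Tm <- matrix(0, n, A)
  ssY <- sum(F^2)
  scale0 <- sqrt(sum(E^2) * ssY) + tol
  a_used <- 0L
  for (a in seq_len(A)) {
    M <- crossprod(E, F)                     # p x 2 covariance block
    if (!is.null(Z) && ncol(Z) > 0) {
      K <- crossprod(Z, E)                   # c x p
      sv_k <- svd(K, nu = 0)
      r <- sum(sv_k$d > max(sv_k$d[1], tol) * 1e-10)
      if (r > 0) {
        V <- sv_k$v[, seq_len(r), drop = FALSE]
        M <- M - V %*% crossprod(V, M)       # project w-space onto null(K)
      }
    }
    sv <- svd(M, nu = 1, nv = 0)
    if (sv$d[1] <= 1e-10 * scale0) break     # no Y-covariance left
    w <- sv$u[, 1]
    j <- which.max(abs(w))                   # sign convention
    if (w[j] < 0) w <- -w
    t_a <- as.vector(E %*% w)
    tt <- sum(t_a^2)
    if (tt <= tol * sum(E^2) / max(1, n)) break
    p_a <- as.vector(crossprod(E, t_a)) / tt
    c_a <- as.vector(crossprod(F, t_a)) / tt
    E <- E - tcrossprod(t_a, p_a)
    F <- F - tcrossprod(t_a, c_a)
    a_used <- a + 0L
    W[, a] <- w; P[, a] <- p_a; C[, a] <- c_a; Tm[, a] <- t_a
  }
  if (a_used < A) {
    warning("component extraction stopped early: ", a_used, " of ", A,
            " components (degenerate residual covariance)")
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    C <- C[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
  }
  if (a_used == 0L)
    return(list(W = W, P = P, C = C, T = Tm, B = matrix(0, p, ncol(F)),
                A = 0L, R2 = 0, constraint_viol = 0))
  PW <- crossprod(P, W)
  B <- W %*% solve(PW, t(C))
  R2 <- 1 - sum(F^2) / ssY
  viol <- 0
  if (!is.null(Z) && ncol(Z) > 0) {
    zt <- abs(crossprod(Z, Tm))                       # c x A
    viol <- max(zt / (norm(Z, "F") *
                        rep(sqrt(colSums(Tm^2)), each = ncol(Z))))
  }
  list(W = W, P = P, C = C, T = Tm, B = B, A = a_used, R2 = R2,
       constraint_viol = viol)
}

# Orthonormal in-model rotation separating Y-predictive from Y-orthogonal
# components. G = full left singular basis of T'Yc; the trailing A - rank
# rotated scores are exactly uncorrelated with the centered response, while
# fitted values, X-reconstruction T P' and coefficients B are unchanged.
.post_transform_core <- function(fit, Yc, tol = 1e-10) {
  A <- fit$A
  if (A == 0L) return(c(fit, list(A_pred = 0L, A_orth = 0L, G = NULL)))
  M <- crossprod(fit$T, Yc)                  # A x 2
  sv <- svd(M, nu = A)
  r <- sum(sv$d > max(sv$d[1], tol) * 1e-8)
  if (r == 0L)
    warning("no Y-correlated variation: all components are Y-orthogonal")
  G <- sv$u                                  # A x A orthonormal
  for (k in seq_len(A)) {                    # reproducible signs
    j <- which.max(abs(G[, k]))
    if (G[j, k] < 0) G[, k] <- -G[, k]
  }
  fit$T <- fit$T %*% G
  fit$P <- fit$P %*% G
  fit$W <- fit$W %*% G
  fit$C <- fit$C %*% G
  fit$G <- G
  fit$A_pred <- as.integer(r)
  fit$A_orth <- as.integer(A - r)
  fit
}

#' Fit an orthogonally constrained PLS2 discriminant model
#'
#' Fits a two-class PLS2-DA model in which every latent score is constrained
#' to be orthogonal to a block of encoded metadata covariates, so that class
#' discrimination cannot be carried by those covariates. With no constraints
#' the model reduces exactly to ordinary PLS2-DA. After fitting, the
#' components are (optionally) post-transformed into `A_pred` predictive plus
#' `A_orth` Y-orthogonal components — the "A = 1+2"-style decomposition — by
#' an orthonormal rotation that leaves fitted values, coefficients and the
#' X-reconstruction unchanged.
#'
#' @param x feature table: numeric matrix or data.frame, samples in rows,
#'   strictly positive intensities when the pretreatment takes logs.
#' @param y class labels, a factor/character vector with exactly two levels.
#' @param constraints a [encode_constraints()] result, a raw numeric matrix of
#'   covariate columns (centered internally), or `NULL` for plain PLS2-DA.
#' @param ncomp number of latent components `A`.
#' @param pretreat a [pretreat_spec()]; fitted on `x` and stored in the model
#'   so that [predict.ocpls2da()] pretreats new samples with training
#'   statistics only.
#' @param case class level treated as the "case" (first response column and
#'   positive class in downstream ROC); defaults to the first factor level.
#' @param post_transform rotate components into predictive + orthogonal form.
#' @return an object of class `"ocpls2da"`: list with weights `W`, X-loadings
#'   `P`, Y-loadings `C`, scores `T` (all feature/sample-named, rotated when
#'   post-transformed), coefficients `B`, `A_pred`/`A_orth`, `R2`, the fitted
#'   `pretreatment`, the centered constraint matrix `Z`, and the response
#'   block.
#' @examples
#' sim <- simulate_dataset(simulation_design(n_per_group = 8, n_features = 60,
#'                                           n_markers = 8, marker_effect = 2,
#'                                           seed = 3))
#' zb <- encode_constraints(sim$metadata, c("maternal_age", "bmi"))
#' fit <- ocpls2da(sim$features, sim$metadata$class, constraints = zb, ncomp = 2)
#' fit
#' max(abs(crossprod(fit$Z, fit$T)))  # scores orthogonal to constraints
#' @export
ocpls2da <- function(x, y, constraints = NULL, ncomp = 2,
                     pretreat = pretreat_spec(), case = NULL,
                     post_transform = TRUE) {
  x <- as.matrix(x)
  rb <- response_block(y, case)
  if (nrow(x) != nrow(rb$Y))
    stop("x and y disagree on the number of samples")
  Zraw <- .constraint_matrix(constraints)
  Zc <- NULL
  rz <- 0L
  if (!is.null(Zraw)) {
    if (nrow(Zraw) != nrow(x))
      stop("constraints and x disagree on the number of samples")
    Zc <- sweep(Zraw, 2, colMeans(Zraw))
    qz <- qr(Zc)
    if (qz$rank < ncol(Zc)) {
      dep <- colnames(Zc)[qz$pivot[-seq_len(qz$rank)]] %||%
        qz$pivot[-seq_len(qz$rank)]
      stop("constraint columns are linearly dependent after centering: ",
           paste(dep, collapse = ", "))
    }
    rz <- qz$rank
  }
  a_max <- min(nrow(x) - 1L - rz, ncol(x))
  if (ncomp > a_max)
    stop("ncomp = ", ncomp, " exceeds the available rank (max ", a_max, ")")
  pre <- fit_pretreatment(x, pretreat)
  Xc <- apply_pretreatment(pre, x)
  fit <- .ocpls_core(Xc, rb$Y, Zc, ncomp)
  if (post_transform) {
    fit <- .post_transform_core(fit, rb$Y)
  } else {
    fit$A_pred <- fit$A
    fit$A_orth <- 0L
    fit$G <- NULL
  }
  dimnames(fit$B) <- list(colnames(x), colnames(rb$Y_raw))
  rownames(fit$W) <- rownames(fit$P) <- colnames(x)
  rownames(fit$T) <- rownames(x)
  structure(c(fit, list(pretreatment = pre, Z = Zc, response = rb,
                        post_transformed = isTRUE(post_transform),
                        call = match.call())),
            class = "ocpls2da")
}

#' Fit an unconstrained PLS2 discriminant model
#'
#' Convenience wrapper: [ocpls2da()] with an empty constraint block.
#' @inheritParams ocpls2da
#' @export
pls2da <- function(x, y, ncomp = 2, pretreat = pretreat_spec(), case = NULL,
                   post_transform = TRUE) {
  ocpls2da(x, y, constraints = NULL, ncomp = ncomp, pretreat = pretreat,
           case = case, post_transform = post_transform)
}

#' @export
print.ocpls2da <- function(x, ...) {
  kind <- if (is.null(x$Z)) "PLS2-DA" else "oCPLS2-DA"
  cat(sprintf("%s model: A = %d+%d components, R2 = %.3f\n",
              kind, x$A_pred, x$A_orth, x$R2))
  cat(sprintf("  %d samples (%s), %d features",
              nrow(x$T), paste(levels(x$response$labels), collapse = " vs "),
              nrow(x$B)))
  if (!is.null(x$Z))
    cat(sprintf(", %d constraint column(s)", ncol(x$Z)))
  cat("\n")
  invisible(x)
}

#' @export
summary.ocpls2da <- function(object, ...) {
  out <- list(model = object,
              constraint_violation = if (is.null(object$Z)) NA_real_ else
                max(abs(crossprod(object$Z, object$T))) /
                (norm(object$Z, "F") * norm(object$T, "F")),
              score_class_t = apply(object$T, 2, function(s)
                unname(stats::t.test(s ~ object$response$labels)$statistic)))
  class(out) <- "summary.ocpls2da"
  out
}

#' @export
print.summary.ocpls2da <- function(x, ...) {
  print(x$model)
  if (!is.na(x$constraint_violation))
    cat(sprintf("  relative constraint violation max|Z't|: %.2e\n",
                x$constraint_violation))
  cat("  per-component class t-statistics of scores:\n")
  print(round(x$score_class_t, 2))
  invisible(x)
}

#' @export
coef.ocpls2da <- function(object, ...) object$B

#' @export
fitted.ocpls2da <- function(object, ...) {
  Yc <- object$T %*% t(object$C)
  sweep(Yc, 2, object$response$means, "+")
}

#' @export
residuals.ocpls2da <- function(object, ...) {
  object$response$Y_raw - fitted(object)
}

#' Predict class responses, classes or latent scores for new samples
#'
#' New samples are pretreated with the training statistics, then projected
#' through the model. `type = "response"` returns the two predicted class
#' indicators (training class means added back), `"class"` the argmax class
#' call, `"score"` the latent scores (predictive components first when the
#' model is post-transformed).
#'
#' @param object a fitted [ocpls2da()] model.
#' @param newdata feature table with the training features (any samples).
#' @param type see above.
#' @param ... unused.
#' @export
predict.ocpls2da <- function(object, newdata,
                             type = c("response", "class", "score"), ...) {
  type <- match.arg(type)
  Xc <- apply_pretreatment(object$pretreatment, as.matrix(newdata))
  if (type == "score") {
    Wstar <- object$W %*% solve(crossprod(object$P, object$W))
    return(Xc %*% Wstar)
  }
  Yhat <- sweep(Xc %*% object$B, 2, object$response$means, "+")
  if (type == "response") return(Yhat)
  factor(colnames(Yhat)[max.col(Yhat, ties.method = "first")],
         levels = levels(object$response$labels))
}

#' Score scatter plot of a fitted model
#'
#' Plots the first predictive score against the first orthogonal score (or
#' the second component when none is orthogonal), marking the two classes.
#' @param x a fitted [ocpls2da()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ocpls2da <- function(x, ...) {
  Tm <- x$T
  if (ncol(Tm) == 1L) Tm <- cbind(Tm, seq_len(nrow(Tm)))
  lab <- x$response$labels
  xlab <- if (x$A_pred >= 1) "t[pred 1]" else "t[1]"
  ylab <- if (x$A_pred >= 1 && x$A_orth >= 1) "t[orth 1]" else "t[2]"
  graphics::plot(Tm[, 1], Tm[, 2], pch = c(17, 2)[as.integer(lab)],
                 col = c("grey30", "grey60")[as.integer(lab)],
                 xlab = xlab, ylab = ylab, ...)
  graphics::legend("topright", legend = levels(lab), pch = c(17, 2),
                   col = c("grey30", "grey60"), bty = "n")
  invisible(x)
}

#' Principal component analysis of a (pretreated) matrix
#'
#' Thin wrapper over the singular value decomposition of the column-centered
#' matrix, returning scores, loadings and explained-variance fractions.
#'
#' @param x numeric matrix or data.frame, samples in rows.
#' @param ncomp number of components to retain.
#' @param scale. divide centered columns by their SD before decomposition.
#' @return list of class `"pca_model"`: `scores`, `loadings`, `explained`
#'   (variance fractions, all components), `sdev`.
#' @export
fit_pca <- function(x, ncomp = 2, scale. = FALSE) {
  x <- as.matrix(x)
  a_max <- min(nrow(x) - 1L, ncol(x))
  if (ncomp > a_max)
    stop("ncomp = ", ncomp, " exceeds the available rank (max ", a_max, ")")
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  structure(list(scores = pc$x[, seq_len(ncomp), drop = FALSE],
                 loadings = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 explained = ev / sum(ev),
                 sdev = pc$sdev),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", ncol(x$scores), "component(s) of", length(x$explained),
      "\n  explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained[seq_len(ncol(x$scores))]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes every matrix of the model, the fitted pretreatment and the response
#' encoding as nested JSON arrays, allowing exact reload with
#' [read_model_json()].
#' @param model a fitted [ocpls2da()] model.
#' @param path output file.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    matrices = lapply(model[c("W", "P", "C", "T", "B")], unclass),
    feature_names = rownames(model$B),
    A = model$A, A_pred = model$A_pred, A_orth = model$A_orth, R2 = model$R2,
    G = model$G,
    Z = model$Z,
    response = list(levels = levels(model$response$labels),
                    labels = as.character(model$response$labels),
                    means = model$response$means, case = model$response$case),
    pretreatment = list(spec = unclass(model$pretreatment$spec),
                        means = model$pretreatment$means,
                        scales = model$pretreatment$scales)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Reload a model serialized by [write_model_json()]
#' @param path JSON file written by [write_model_json()].
#' @return an object of class `"ocpls2da"` usable with [predict.ocpls2da()].
#' @export
read_model_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- lapply(js$matrices, function(el) {
    el <- as.matrix(el)
    storage.mode(el) <- "double"
    el
  })
  rb <- response_block(factor(js$response$labels, levels = js$response$levels),
                       case = js$response$case)
  pre <- structure(list(spec = structure(js$pretreatment$spec,
                                         class = "pretreat_spec"),
                        means = js$pretreatment$means,
                        scales = js$pretreatment$scales,
                        zero_variance = rep(FALSE, length(js$pretreatment$means)),
                        feature_names = js$feature_names),
                   class = "pretreatment")
  rownames(m$B) <- rownames(m$W) <- rownames(m$P) <- js$feature_names
  colnames(m$B) <- js$response$levels
  structure(c(m, list(A = js$A, A_pred = js$A_pred, A_orth = js$A_orth,
                      R2 = js$R2,
                      G = if (is.null(js$G)) NULL else as.matrix(js$G),
                      Z = if (is.null(js$Z)) NULL else as.matrix(js$Z),
                      response = rb, pretreatment = pre,
                      post_transformed = TRUE)),
            class = "ocpls2da")
}
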