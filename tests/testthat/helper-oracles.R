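# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# Random small positive-intensity instance with balanced two-class labels.
make_instance <- function(n = 12, p = 20, seed = 1, effect = 0) {
  set.seed(seed)
  labels <- factor(rep(c("case", "control"), length.out = n),
                   levels = c("case", "control"))
  logx <- matrix(rnorm(n * p, 6, 1), n, p)
  if (effect > 0)
    logx[labels == "case", seq_len(min(5, p))] <-
      logx[labels == "case", seq_len(min(5, p))] + effect
  x <- exp(logx)
  dimnames(x) <- list(paste0("s", seq_len(n)), paste0("f", seq_len(p)))
  list(x = x, labels = labels)
}

# Dominant left singular direction of M via a full eigendecomposition of MM'.
oracle_dominant_left <- function(M) {
  ev <- eigen(tcrossprod(M), symmetric = TRUE)
  ev$vectors[, 1]
}

# AUC by exhaustive pair counting (ties count one half).
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# Benjamini-Hochberg step-up q-values, q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    q[ord[i]] <- min(running, 1)
  }
  q
}

# Explicit-loop full cross-validation Q2: its own pretreatment, its own
# NIPALS with eigen-based weights, its own PRESS/TSS accumulation.
oracle_q2 <- function(x, labels, fold_id, ncomp, log = TRUE,
                      scaling = "pareto") {
  L <- if (log) log(x) else x
  y1 <- as.numeric(labels == levels(as.factor(labels))[1])
  Yraw <- cbind(y1, 1 - y1)
  press <- 0; tss <- 0
  for (f in sort(unique(fold_id))) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    mu <- apply(L[tr, , drop = FALSE], 2, mean)
    sdv <- apply(L[tr, , drop = FALSE], 2, sd)
    scl <- switch(scaling, pareto = sqrt(sdv), uv = sdv,
                  none = rep(1, length(sdv)))
    scl[scl == 0] <- 1
    E <- sweep(sweep(L[tr, , drop = FALSE], 2, mu), 2, scl, "/")
    Ete <- sweep(sweep(L[te, , drop = FALSE], 2, mu), 2, scl, "/")
    ybar <- apply(Yraw[tr, , drop = FALSE], 2, mean)
    Fm <- sweep(Yraw[tr, , drop = FALSE], 2, ybar)
    W <- NULL; P <- NULL; Cm <- NULL
    for (a in seq_len(ncomp)) {
      M <- t(E) %*% Fm
      w <- oracle_dominant_left(M)
      t_a <- as.vector(E %*% w)
      p_a <- as.vector(t(E) %*% t_a) / sum(t_a^2)
      c_a <- as.vector(t(Fm) %*% t_a) / sum(t_a^2)
      E <- E - outer(t_a, p_a)
      Fm <- Fm - outer(t_a, c_a)
      W <- cbind(W, w); P <- cbind(P, p_a); Cm <- cbind(Cm, c_a)
    }
    B <- W %*% solve(t(P) %*% W) %*% t(Cm)
    pred <- sweep(Ete %*% B, 2, ybar, "+")
    press <- press + sum((Yraw[te, , drop = FALSE] - pred)^2)
    tss <- tss + sum(sweep(Yraw[te, , drop = FALSE], 2, ybar)^2)
  }
  1 - press / tss
}
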