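# Independent brute-force reference implementations used to cross-check the
# package's SPA-LDA path. They share no code with the package internals:
# projections are recomputed from the original columns via QR at every step,
# and the cost function is evaluated with explicit base-R loops.

# Residual norm of column j of X after projecting out the span of the
# original columns in `chain`, recomputed from scratch.
oracle_residual_norm2 <- function(X, chain, j) {
  basis <- X[, chain, drop = FALSE]
  qrd <- qr(basis)
  Q <- qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
  r <- X[, j] - Q %*% crossprod(Q, X[, j])
  sum(r^2)
}

# Brute-force SPA chain from one initialiser.
oracle_chain <- function(X, init, l_max) {
  tol <- 1e-12 * max(colSums(X^2))
  chain <- init
  while (length(chain) < l_max) {
    cand <- setdiff(seq_len(ncol(X)), chain)
    norms <- vapply(cand, function(j) oracle_residual_norm2(X, chain, j),
                    numeric(1))
    if (max(norms) <= tol) break
    chain <- c(chain, cand[which.max(norms)])
  }
  chain
}

# Direct evaluation of the average-risk cost: class means and pooled
# covariance from the training matrix restricted to `subset`, then the
# risk ratio sample by sample with explicit loops.
oracle_cost <- function(train_m, train_lab, val_m, val_lab, subset) {
  tm <- train_m[, subset, drop = FALSE]
  vm <- val_m[, subset, drop = FALSE]
  cls <- sort(unique(train_lab))
  means <- lapply(cls, function(cl) colMeans(tm[train_lab == cl, , drop = FALSE]))
  S <- matrix(0, length(subset), length(subset))
  for (ci in seq_along(cls)) {
    rows <- which(train_lab == cls[ci])
    for (i in rows) {
      d <- tm[i, ] - means[[ci]]
      S <- S + outer(d, d)
    }
  }
  S <- S / (nrow(tm) - length(cls))
  S_inv <- solve(S)
  md2 <- function(x, mu) { d <- x - mu; sum(d * (S_inv %*% d)) }
  g <- numeric(nrow(vm))
  for (n in seq_len(nrow(vm))) {
    ti <- which(cls == val_lab[n])
    num <- md2(vm[n, ], means[[ti]])
    den <- min(vapply(seq_along(cls)[-ti], function(ci) md2(vm[n, ], means[[ci]]),
                      numeric(1)))
    g[n] <- num / den
  }
  mean(g)
}

# Brute-force Phase 1 + Phase 2: enumerate every chain prefix, evaluate the
# cost of each, and pick the minimiser with the documented tie-breaking
# (fewer variables, then lexicographically smallest sequence).
oracle_select <- function(train_m, train_lab, val_m, val_lab, l_max) {
  cls <- sort(unique(train_lab))
  centered <- train_m
  for (cl in cls) {
    rows <- train_lab == cl
    centered[rows, ] <- sweep(centered[rows, , drop = FALSE], 2,
                              colMeans(centered[rows, , drop = FALSE]))
  }
  best <- NULL
  for (init in seq_len(ncol(train_m))) {
    chain <- oracle_chain(centered, init, l_max)
    for (m in seq_along(chain)) {
      sub <- sort(chain[seq_len(m)])  # candidates are variable sets
      cost <- tryCatch(
        oracle_cost(train_m, train_lab, val_m, val_lab, sub),
        error = function(e) Inf)
      if (!is.finite(cost)) next
      cand <- list(subset = sub, cost = cost)
      if (is.null(best)) { best <- cand; next }
      better <- if (cost != best$cost) cost < best$cost
        else if (length(sub) != length(best$subset)) length(sub) < length(best$subset)
        else {
          key <- function(s) paste(sprintf("%08d", s), collapse = "")
          key(sub) < key(best$subset)
        }
      if (isTRUE(better)) best <- cand
    }
  }
  best
}
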