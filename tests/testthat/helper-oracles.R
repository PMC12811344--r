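# Independent oracles used by the unit and acceptance tests. These are
# deliberately brute-force implementations, kept separate from the package
# code paths they check.

# Exhaustive pairwise AUC: P(score_pos > score_neg) + P(tie)/2.
auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Maximal intersections by endpoint-pair enumeration: all (L_i, R_j] with
# L_i < R_j whose open interior contains no observed endpoint.
turnbull_classes_enum <- function(L, R) {
  cand <- expand.grid(q = unique(L), p = unique(R))
  cand <- cand[cand$q < cand$p, , drop = FALSE]
  ok <- vapply(seq_len(nrow(cand)), function(k) {
    !any(c(L, R) > cand$q[k] & c(L, R) < cand$p[k])
  }, logical(1))
  out <- cand[ok, , drop = FALSE]
  out[order(out$q), , drop = FALSE]
}

# Direct maximization of the Turnbull likelihood over the probability
# simplex (softmax parametrization, multi-start BFGS).
turnbull_simplex_oracle <- function(L, R) {
  iv <- turnbull_classes_enum(L, R)
  m <- nrow(iv)
  A <- outer(L, iv$q, `<=`) & outer(R, iv$p, `>=`)
  storage.mode(A) <- "double"
  nll <- function(th) {
    s <- exp(th - max(th))
    s <- s / sum(s)
    -sum(log(pmax(as.vector(A %*% s), 1e-300)))
  }
  best <- NULL
  for (st in 1:4) {
    th0 <- if (st == 1) rep(0, m) else rnorm(m)
    o <- optim(th0, nll, method = "BFGS", control = list(maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  s <- exp(best$par - max(best$par))
  s <- s / sum(s)
  list(intervals = iv, s = s, loglik = -best$value)
}

# Dense QP oracle for the SVM dual: maximize -c'Hc/2 + 1'c subject to
# c'V = 0, 0 <= c <= Q, by enumerating active-set patterns (each
# coefficient free, at 0, or at Q) and solving the stationarity system on
# the free set. Exact for the small point sets used in tests.
svm_dual_oracle <- function(K, V, Q) {
  n <- length(V)
  H <- K * tcrossprod(V)
  obj <- function(c) -0.5 * sum(c * (H %*% c)) + sum(c)
  best <- list(value = -Inf, c = NULL)
  pat <- rep(0L, n)
  for (code in 0:(3^n - 1)) {
    x <- code
    for (i in 1:n) {
      pat[i] <- x %% 3L
      x <- x %/% 3L
    }
    cb <- ifelse(pat == 2L, Q, 0)
    fr <- pat == 1L
    cc <- cb
    if (any(fr)) {
      nf <- sum(fr)
      M <- rbind(cbind(H[fr, fr, drop = FALSE], V[fr]), c(V[fr], 0))
      rhs <- c(1 - H[fr, !fr, drop = FALSE] %*% cb[!fr],
               -sum(V[!fr] * cb[!fr]))
      sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      cf <- sol[seq_len(nf)]
      if (any(cf < -1e-9 | cf > Q + 1e-9)) next
      cc[fr] <- pmin(pmax(cf, 0), Q)
    }
    if (abs(sum(cc * V)) > 1e-8) next
    v <- obj(cc)
    if (v > best$value) best <- list(value = v, c = cc)
  }
  best
}

# Dual objective achieved by a fitted svm_rule on its training set.
rule_dual_objective <- function(rule, z, v) {
  cc <- numeric(length(v))
  # map support vectors back to training rows
  used <- rep(FALSE, length(v))
  for (k in seq_along(rule$c)) {
    i <- which(!used & v == rule$v[k] &
                 apply(z, 1, function(r) isTRUE(all.equal(r, rule$sv[k, ],
                                                          tolerance = 1e-12,
                                                          check.attributes = FALSE))))[1]
    cc[i] <- rule$c[k]
    used[i] <- TRUE
  }
  K <- rbf_kernel(z, z, rule$gamma)
  H <- K * tcrossprod(v)
  -0.5 * sum(cc * (H %*% cc)) + sum(cc)
}

# Small hand-built mixed-case dataset used across unit tests.
toy_mcic <- function() {
  df <- data.frame(
    u_left = c(0, 0, 0.4, 0.8, 1.2, 0.6, 1.5, 2.0),
    u_right = c(0.3, 0.5, 0.9, 1.4, 1.9, Inf, Inf, Inf),
    x_a = c(-1.2, 0.4, 0.8, -0.5, 1.1, 0.3, -0.9, 1.7),
    z_a = c(-1.2, 0.4, 0.8, -0.5, 1.1, 0.3, -0.9, 1.7),
    z_b = c(0.2, -1.0, 0.5, 1.3, -0.7, 0.9, -0.2, 0.4))
  mcic_data(df, xvars = "x_a", zvars = c("z_a", "z_b"))
}
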