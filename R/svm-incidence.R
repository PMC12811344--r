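#' Radial-basis kernel
#'
#' `K(z_i, z_j) = exp(-gamma * ||z_i - z_j||^2)` with `gamma = 1/(2 sigma^2)`.
#' Given two matrices (rows = points) the full cross-kernel matrix is
#' returned; vectors are treated as single points.
#'
#' @param z1,z2 numeric vectors (single points) or matrices with matching
#'   numbers of columns.
#' @param gamma positive kernel width parameter.
#' @return a numeric matrix `nrow(z1) x nrow(z2)` (a 1x1 matrix collapses
#'   to a scalar).
#' @export
rbf_kernel <- function(z1, z2, gamma) {
  stopifnot(gamma > 0)
  if (is.vector(z1)) z1 <- matrix(z1, nrow = 1)
  if (is.vector(z2)) z2 <- matrix(z2, nrow = 1)
  if (ncol(z1) != ncol(z2)) stop("covariate dimension mismatch")
  d2 <- outer(rowSums(z1^2), rowSums(z2^2), `+`) - 2 * tcrossprod(z1, z2)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  k <- exp(-gamma * d2)
  if (length(k) == 1) as.numeric(k) else k
}

#' Train a soft-margin RBF support vector machine
#'
#' Solves the dual problem
#' `max -1/2 sum_ij c_i c_j V_i V_j K(z_i, z_j) + sum_i c_i` subject to
#' `sum_i c_i V_i = 0`, `0 <= c_i <= Q` (sequential minimal optimization,
#' via libsvm through \pkg{e1071}), and returns the decision rule
#' `g(z) = sum_i c_i V_i K(z_i, z) - b` oriented so that `g(z) > 0`
#' classifies `z` as uncured (`V = +1`).
#'
#' @param z numeric matrix of covariates (one row per subject).
#' @param v labels in `{-1, +1}` (`+1` = uncured).
#' @param Q positive cost bound on the dual coefficients.
#' @param gamma positive RBF width parameter.
#' @return an object of class `svm_rule`: list with support points `sv`,
#'   coefficients `c` (in `[0, Q]`), support labels `v`, intercept `b`,
#'   `gamma` and `Q`.
#' @export
svm_train <- function(z, v, Q, gamma) {
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  v <- as.integer(v)
  stopifnot(nrow(z) == length(v), all(v %in% c(-1L, 1L)), Q > 0, gamma > 0)
  if (length(unique(v)) < 2) stop("degenerate labels: single class")
  fit <- e1071::svm(x = z, y = factor(v, levels = c(-1, 1)),
                    type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = Q, scale = FALSE)
  a <- as.numeric(fit$coefs)       # = V_i c_i up to libsvm's orientation
  rho <- fit$rho
  # libsvm's positive class is the first label seen in the data; normalise
  # the rule so that positive decision values mean V = +1.
  pred <- stats::predict(fit, z[1, , drop = FALSE], decision.values = TRUE)
  dvname <- colnames(attr(pred, "decision.values"))[1]
  flip <- !identical(strsplit(dvname, "/", fixed = TRUE)[[1]][1], "1")
  if (flip) {
    a <- -a
    rho <- -rho
  }
  idx <- fit$index
  structure(list(sv = z[idx, , drop = FALSE], c = abs(a), v = v[idx],
                 b = rho, gamma = gamma, Q = Q, n_train = length(v)),
            class = "svm_rule")
}

#' Evaluate an SVM decision function
#'
#' Returns `g(z) = sum_i c_i V_i K(z_i, z) - b` for each row of `z`.
#' Subjects with `g(z) > 0` are classified as uncured, `g(z) < 0` as cured.
#'
#' @param rule an `svm_rule` from [svm_train].
#' @param z numeric vector (one point) or matrix of covariates.
#' @return numeric vector of decision values.
#' @export
decision_value <- function(rule, z) {
  stopifnot(inherits(rule, "svm_rule"))
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  if (ncol(z) != ncol(rule$sv)) stop("covariate dimension mismatch")
  as.vector(rbf_kernel(z, rule$sv, rule$gamma) %*% (rule$c * rule$v)) - rule$b
}

#' Platt regularised class targets
#'
#' The sigmoid calibration is fitted not to the raw `{0,1}` labels but to
#' shrunken targets: `(n1 + 1)/(n1 + 2)` for uncured subjects (`V = +1`)
#' and `1/(n0 + 2)` for cured subjects (`V = -1`), where `n1` and `n0` are
#' the class counts. The shrinkage guards the in-sample fit against
#' overconfident probabilities.
#'
#' @param v labels in `{-1, +1}`.
#' @return numeric vector of targets in `(0, 1)`.
#' @export
platt_targets <- function(v) {
  stopifnot(length(v) > 0, all(v %in% c(-1, 1)))
  n1 <- sum(v == 1)
  n0 <- sum(v == -1)
  ifelse(v == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
}

#' Fit a Platt calibration sigmoid to decision values
#'
#' Finds `(A, B)` maximizing
#' `sum_i (1 - t_i)(A g_i + B) - sum_i log(1 + exp(A g_i + B))`,
#' where `t_i` are the [platt_targets]; the fitted uncured probability is
#' `pi(z) = 1/(1 + exp(A g(z) + B))`. The objective is concave in `(A, B)`
#' and is maximized by damped Newton steps from `A = -1`,
#' `B = log((n0 + 1)/(n1 + 1))`; with separated decision values the fitted
#' `A` is negative, so larger `g` gives larger `pi`.
#'
#' @param g numeric vector of decision values.
#' @param v labels in `{-1, +1}` aligned with `g`.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `platt_calibration`: list with `A`, `B`,
#'   the achieved `objective` and the final gradient norm.
#' @export
platt_fit <- function(g, v, tol = 1e-8, max_iter = 100) {
  stopifnot(length(g) == length(v))
  if (length(unique(v)) < 2) stop("both classes required for calibration")
  tgt <- platt_targets(v)
  n1 <- sum(v == 1)
  n0 <- sum(v == -1)
  obj <- function(ab) {
    eta <- ab[1] * g + ab[2]
    sum((1 - tgt) * eta) - sum(log1p(exp(pmin(eta, 700))))
  }
  ab <- c(-1, log((n0 + 1) / (n1 + 1)))
  f <- obj(ab)
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    eta <- ab[1] * g + ab[2]
    pi_i <- stats::plogis(-eta)          # 1/(1+exp(eta))
    grad <- c(sum((pi_i - tgt) * g), sum(pi_i - tgt))
    gnorm <- sqrt(sum(grad^2))
    if (gnorm <= tol) break
    wgt <- pmax(pi_i * (1 - pi_i), 1e-12)
    H <- -rbind(c(sum(wgt * g^2), sum(wgt * g)),
                c(sum(wgt * g), sum(wgt)))
    step <- tryCatch(solve(H, grad),
                     error = function(e) solve(H - diag(1e-8, 2), grad))
    lam <- 1
    repeat {  # damping: objective is concave, so a short enough step ascends
      ab_new <- ab - lam * step
      f_new <- obj(ab_new)
      if (f_new >= f - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    ab <- ab_new
    f <- f_new
  }
  if (gnorm > max(tol, 1e-6)) {
    stop(sprintf("Platt calibration did not converge: |grad| = %.3e at A = %.4f, B = %.4f",
                 gnorm, ab[1], ab[2]))
  }
  structure(list(A = ab[1], B = ab[2], objective = f, grad_norm = gnorm),
            class = "platt_calibration")
}

#' Platt-scaled uncured probability
#'
#' @param calib a `platt_calibration` from [platt_fit].
#' @param g decision value(s).
#' @return `1/(1 + exp(A g + B))`, in `(0, 1)`.
#' @export
platt_probability <- function(calib, g) {
  stats::plogis(-(calib$A * g + calib$B))
}

# pi(z) for new points under one (rule, calibration) pair
platt_predict <- function(model, z) {
  platt_probability(model$calib, decision_value(model$rule, z))
}

#' Data-driven RBF gamma grid
#'
#' Baseline width `gamma0 = 1 / median(||z_i - z_j||^2, i < j)` — the
#' reciprocal median squared pairwise distance — expanded to the
#' multiplicative grid `gamma0 * 2^k`, `k = -3, ..., 3`.
#'
#' @param z numeric matrix of covariates.
#' @return numeric vector of 7 candidate gamma values.
#' @export
data_driven_gamma_grid <- function(z) {
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  stopifnot(nrow(z) >= 2)
  med <- stats::median(stats::dist(z)^2)
  if (med <= 0) stop("zero median distance: all points identical")
  (1 / med) * 2^(-3:3)
}

#' Tune SVM hyperparameters by stratified cross-validation
#'
#' Grid search over `(gamma, Q)` pairs minimizing the mean misclassification
#' rate under stratified k-fold cross-validation. Ties are broken in favour
#' of the smaller `Q`, then the smaller `gamma`.
#'
#' @param z covariate matrix; `v` labels in `{-1, +1}`.
#' @param v labels in `{-1, +1}`.
#' @param gamma_grid,Q_grid positive candidate values.
#' @param folds number of folds (default 10; capped at the minority class
#'   size so every training fold contains both classes).
#' @return list with `gamma`, `Q` and the matrix of CV error rates.
#' @export
tune_hyperparameters <- function(z, v, gamma_grid = 2^(-6:-4),
                                 Q_grid = 2^(4:6), folds = 10) {
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  v <- as.integer(v)
  cls <- sort(unique(v))
  if (length(cls) < 2) stop("both classes required for tuning")
  n_min <- min(table(v))
  if (n_min < 2) stop("stratified folding impossible: a class has < 2 members")
  folds <- max(2, min(folds, n_min))
  fold_id <- integer(length(v))
  for (cl in cls) {
    idx <- which(v == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  grid <- expand.grid(gamma = sort(gamma_grid), Q = sort(Q_grid))
  err <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    miss <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      rule <- svm_train(z[tr, , drop = FALSE], v[tr],
                        Q = grid$Q[gidx], gamma = grid$gamma[gidx])
      pred <- sign(decision_value(rule, z[!tr, , drop = FALSE]))
      pred[pred == 0] <- 1
      miss <- miss + sum(pred != v[!tr])
    }
    err[gidx] <- miss / length(v)
  }
  best <- which(err <= min(err) + 1e-12)
  best <- best[order(grid$Q[best], grid$gamma[best])][1]
  list(gamma = grid$gamma[best], Q = grid$Q[best],
       cv_error = cbind(grid, error = err))
}

#' Multiple-imputation SVM/Platt estimate of the uncured probability
#'
#' One M-step of the EM algorithm for the SVM incidence: for each of `M`
#' imputations, the unknown cured statuses of right-censored subjects are
#' drawn as `J ~ Bernoulli(w)` from the current E-step weights (labels
#' `V = 2J - 1`; left- and interval-censored subjects are fixed at
#' `V = +1`), an SVM is trained at the supplied hyperparameters, a Platt
#' sigmoid is fitted to the in-sample decision values, and `pi(z)` is
#' evaluated for every subject. The returned estimate is the arithmetic
#' mean over imputations.
#'
#' An imputation drawing a single class is redrawn (up to 25 attempts);
#' if still degenerate, the right-censored subject whose weight is closest
#' to 1/2 has its label flipped so the SVM stays defined.
#'
#' @param z covariate matrix for all subjects.
#' @param right_censored logical vector; `TRUE` where the cured status is
#'   unknown.
#' @param w E-step weights in `[0, 1]`; must equal 1 where
#'   `right_censored` is `FALSE`.
#' @param M number of imputations.
#' @param gamma,Q SVM hyperparameters.
#' @return list with `pi` (averaged probabilities, one per subject) and
#'   `models` (per-imputation `rule`/`calib` pairs).
#' @export
impute_and_estimate_pi <- function(z, right_censored, w, M, gamma, Q) {
  stopifnot(all(w >= 0 & w <= 1), all(w[!right_censored] == 1), M >= 1)
  n <- length(w)
  rc_idx <- which(right_censored)
  pi_mat <- matrix(NA_real_, n, M)
  models <- vector("list", M)
  for (s in seq_len(M)) {
    v <- rep(1L, n)
    for (try in seq_len(25)) {
      v[rc_idx] <- ifelse(stats::runif(length(rc_idx)) < w[rc_idx], 1L, -1L)
      if (length(unique(v)) == 2) break
    }
    if (length(unique(v)) < 2) {
      if (!length(rc_idx)) stop("degenerate labels: no right-censored subject to flip")
      flip <- rc_idx[which.min(abs(w[rc_idx] - 0.5))]
      v[flip] <- -v[flip]
    }
    rule <- svm_train(z, v, Q = Q, gamma = gamma)
    gval <- decision_value(rule, z)
    calib <- platt_fit(gval, v)
    pi_mat[, s] <- platt_probability(calib, gval)
    models[[s]] <- list(rule = rule, calib = calib)
  }
  list(pi = rowMeans(pi_mat), pi_components = pi_mat, models = models)
}
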