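#' Control parameters for micure fitting
#'
#' @param M number of imputations of the missing cured statuses per EM
#'   iteration (SVM incidence only).
#' @param eps EM convergence tolerance on the squared L2 distance between
#'   successive parameter vectors (the per-subject uncured probabilities
#'   concatenated with the latency coefficients; the Turnbull baseline is
#'   frozen and not part of the criterion).
#' @param max_iter maximum EM iterations.
#' @param gamma_grid,Q_grid hyperparameter grids for the SVM (RBF width
#'   `gamma = 1/(2 sigma^2)` and cost `Q`).
#' @param cv_folds folds for the tuning cross-validation.
#' @param data_driven_gamma if `TRUE`, replace `gamma_grid` by the
#'   median-distance grid of [data_driven_gamma_grid].
#' @param retune_every_iter if `TRUE`, re-run hyperparameter tuning at every
#'   EM iteration instead of once at initialization.
#' @param normalize_criterion if `TRUE`, divide the convergence criterion by
#'   the parameter count (the raw criterion scales with the sample size).
#' @param bootstrap_B default bootstrap replicate count for [bootstrap_se].
#' @param turnbull_tol,turnbull_max_iter passed to [turnbull_fit].
#' @return a list of class `micure_control`.
#' @export
micure_control <- function(M = 5, eps = 1e-3, max_iter = 100,
                           gamma_grid = 2^(-6:-4), Q_grid = 2^(4:6),
                           cv_folds = 10, data_driven_gamma = FALSE,
                           retune_every_iter = FALSE,
                           normalize_criterion = FALSE,
                           bootstrap_B = 100,
                           turnbull_tol = 1e-6, turnbull_max_iter = 10000) {
  stopifnot(M >= 1, eps > 0, max_iter >= 1, length(gamma_grid) > 0,
            length(Q_grid) > 0, all(gamma_grid > 0), all(Q_grid > 0),
            cv_folds >= 2, bootstrap_B >= 2)
  structure(list(M = M, eps = eps, max_iter = max_iter,
                 gamma_grid = gamma_grid, Q_grid = Q_grid,
                 cv_folds = cv_folds, data_driven_gamma = data_driven_gamma,
                 retune_every_iter = retune_every_iter,
                 normalize_criterion = normalize_criterion,
                 bootstrap_B = bootstrap_B, turnbull_tol = turnbull_tol,
                 turnbull_max_iter = turnbull_max_iter),
            class = "micure_control")
}

#' E-step weights: posterior probability of being uncured
#'
#' For left- and interval-censored subjects the uncured status is observed
#' and `w = 1`. For right-censored subjects,
#' `w = pi(z) S0(U_L)^e / (1 - pi(z) + pi(z) S0(U_L)^e)` with
#' `e = exp(x'beta)`.
#'
#' @param data an [mcic_data] object.
#' @param pi current per-subject uncured probabilities in `(0, 1)`.
#' @param beta current latency coefficients.
#' @param baseline a `turnbull` object.
#' @param parts optional precomputed [latency_parts].
#' @return weight vector in `[0, 1]`, equal to 1 off the right-censored set.
#' @export
e_step <- function(data, pi, beta, baseline, parts = NULL) {
  if (is.null(parts)) parts <- latency_parts(data, baseline)
  se <- exp(exp(as.vector(parts$x %*% beta)) * parts$logs0L)
  w <- data$delta1 + data$delta2 +
    (parts$rc) * (pi * se) / (1 - pi + pi * se)
  pmin(pmax(w, 0), 1)
}

#' Observed-data log-likelihood of the mixture cure model
#'
#' Sum over subjects of: `log pi + log(1 - S0(U_R)^e)` if left-censored,
#' `log pi + log(S0(U_L)^e - S0(U_R)^e)` if interval-censored, and
#' `log(1 - pi + pi S0(U_L)^e)` if right-censored, with `e = exp(x'beta)`.
#' A large negative sentinel is returned when an interval term is
#' non-positive.
#'
#' @inheritParams e_step
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(data, pi, beta, baseline, parts = NULL) {
  if (is.null(parts)) parts <- latency_parts(data, baseline)
  pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
  ebx <- exp(as.vector(parts$x %*% beta))
  val <- 0
  if (any(parts$d1)) {
    u <- 1 - exp(ebx[parts$d1] * parts$logs0R[parts$d1])
    if (any(u <= 0)) return(.NEG_SENTINEL)
    val <- val + sum(log(pi[parts$d1])) + sum(log(u))
  }
  if (any(parts$d2)) {
    u <- exp(ebx[parts$d2] * parts$logs0L[parts$d2]) -
      exp(ebx[parts$d2] * parts$logs0R[parts$d2])
    if (any(u <= 0)) return(.NEG_SENTINEL)
    val <- val + sum(log(pi[parts$d2])) + sum(log(u))
  }
  if (any(parts$rc)) {
    se <- exp(ebx[parts$rc] * parts$logs0L[parts$rc])
    val <- val + sum(log(1 - pi[parts$rc] + pi[parts$rc] * se))
  }
  if (!is.finite(val)) return(.NEG_SENTINEL)
  val
}

#' Fit a mixture cure model to mixed-case interval-censored data
#'
#' Fits the two-component mixture
#' `S_p(t|x,z) = 1 - pi(z) + pi(z) S0(t)^exp(x'beta)` by an EM-type
#' algorithm. The baseline survival `S0` is the Turnbull NPMLE computed
#' once from all censoring intervals and held fixed. The incidence
#' `pi(z)` is estimated either by an RBF-kernel SVM with Platt-scaled
#' posterior probabilities, refitted at every EM iteration on multiply
#' imputed cured statuses (`model = "svm"`), or by logistic regression
#' maximizing the weighted incidence likelihood (`model = "logit"`).
#' The latency coefficients maximize the weighted latency log-likelihood
#' by Nelder-Mead. Iteration stops when the squared L2 distance between
#' successive parameter vectors (uncured probabilities and latency
#' coefficients) falls below `control$eps`.
#'
#' Initialization uses the observed censoring types: subjects with a finite
#' right endpoint are labelled uncured and right-censored subjects cured,
#' a single SVM/Platt (or logistic) fit on those labels gives the starting
#' `pi`, and the starting `beta` maximizes the observed log-likelihood with
#' `pi` fixed at 1 (a no-cure proportional-hazards fit). SVM
#' hyperparameters are tuned here by stratified cross-validation and reused
#' across iterations and imputations unless `control$retune_every_iter`.
#'
#' @param formula either an [mcic_data] object, or a model formula whose
#'   left-hand side is `cbind(u_left, u_right)` (infinite `u_right` =
#'   right-censored, zero `u_left` = left-censored) or a
#'   `survival::Surv(, type = "interval2")` object, and whose right-hand
#'   side gives the latency covariates.
#' @param data a data frame (when `formula` is a formula).
#' @param cureform one-sided formula for the incidence covariates `z`;
#'   defaults to the latency covariates.
#' @param model `"svm"` or `"logit"` incidence.
#' @param control a [micure_control] list.
#' @param seed optional integer seed; fixing it makes the fit (imputations
#'   included) exactly reproducible.
#' @return an object of class `micure` with components `pi_hat`,
#'   `beta_hat`, `baseline`, `trace` (per-iteration log-likelihood and
#'   convergence criterion), `converged`, `incidence` (fitted incidence
#'   models), `tuning`, `data`, `control`, and optionally `se` after
#'   [bootstrap_se]. Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`.
#' @examples
#' sim <- generate_mcic(1, n = 120, seed = 7)
#' fit <- micure(sim$data, model = "logit", seed = 7)
#' fit
#' @export
micure <- function(formula, data = NULL, cureform = NULL,
                   model = c("svm", "logit"),
                   control = micure_control(), seed = NULL) {
  model <- match.arg(model)
  md <- if (inherits(formula, "mcic_data")) formula
        else mcic_from_formula(formula, data, cureform)
  cl <- match.call()
  fit <- fit_micure_core(md, model, control, seed)
  fit$call <- cl
  fit
}

# Build an mcic_data from formula + data frame.
mcic_from_formula <- function(formula, data, cureform) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (inherits(y, "Surv")) {
    if (attr(y, "type") != "interval") {
      stop("Surv response must use type = 'interval2'")
    }
    tt <- unclass(y)
    status <- tt[, 3]
    uL <- ifelse(status == 2, 0, tt[, 1])
    uR <- ifelse(status == 0, Inf, ifelse(status == 2, tt[, 1],
                                          ifelse(status == 3, tt[, 2], tt[, 1])))
  } else {
    if (is.null(dim(y)) || ncol(y) != 2) {
      stop("response must be cbind(u_left, u_right) or an interval2 Surv")
    }
    uL <- y[, 1]
    uR <- y[, 2]
  }
  x <- stats::model.matrix(stats::delete.response(stats::terms(mf)), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  if (is.null(cureform)) {
    z <- x
  } else {
    z <- stats::model.matrix(cureform, data)
    z <- z[, colnames(z) != "(Intercept)", drop = FALSE]
  }
  df <- data.frame(u_left = uL, u_right = uR)
  xn <- paste0("x.", colnames(x))
  zn <- paste0("z.", colnames(z))
  df[xn] <- as.data.frame(x)
  df[zn] <- as.data.frame(z)
  md <- mcic_data(df, xvars = xn, zvars = zn)
  md$x_names <- colnames(x)
  md$z_names <- colnames(z)
  colnames(md$x) <- colnames(x)
  colnames(md$z) <- colnames(z)
  md
}

fit_micure_core <- function(md, model, control, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(md$u_left)
  rc <- md$delta1 + md$delta2 == 0
  baseline <- turnbull_fit(md, control$turnbull_tol, control$turnbull_max_iter)
  parts <- latency_parts(md, baseline)
  p <- ncol(md$x)

  # --- initialization -----------------------------------------------------
  v0 <- ifelse(rc, -1L, 1L)
  tuning <- NULL
  logit_par <- NULL
  inc_models <- NULL
  if (model == "svm") {
    if (any(rc)) {
      ggrid <- if (control$data_driven_gamma) data_driven_gamma_grid(md$z)
               else control$gamma_grid
      tuning <- tune_hyperparameters(md$z, v0, ggrid, control$Q_grid,
                                     control$cv_folds)
      rule0 <- svm_train(md$z, v0, Q = tuning$Q, gamma = tuning$gamma)
      g0 <- decision_value(rule0, md$z)
      calib0 <- platt_fit(g0, v0)
      pi_cur <- platt_probability(calib0, g0)
      inc_models <- list(list(rule = rule0, calib = calib0))
    } else {
      # no right-censored subjects: every label is uncured, the SVM is
      # degenerate and the incidence collapses to the shrunken constant
      pi_cur <- rep((n + 1) / (n + 2), n)
    }
  } else {
    logit_par <- fit_logit_incidence(md$z, w = as.numeric(!rc))
    pi_cur <- stats::plogis(logit_par[1] + as.vector(md$z %*% logit_par[-1]))
  }
  # no-cure semiparametric PH fit (joint over beta and its own baseline);
  # a no-cure fit over the frozen marginal baseline attenuates badly in the
  # presence of a cured subgroup and can seed a spurious EM fixed point
  beta_cur <- noncure_ph_fit(md)$beta
  if (q_c2(beta_cur, md, rep(1, n), baseline, parts) <= .NEG_SENTINEL) {
    beta_cur <- numeric(p)  # degenerate init; restart from the null model
  }

  # --- EM loop ------------------------------------------------------------
  trace <- data.frame(iter = integer(), loglik = numeric(),
                      criterion = numeric())
  converged <- FALSE
  scale_crit <- if (control$normalize_criterion) n + p else 1
  if (!any(rc)) {
    # no missing cured statuses: a single pass is the whole fit
    beta_cur <- maximize_q_c2(md, w = rep(1, n), baseline,
                              beta_init = beta_cur)$beta
    trace <- data.frame(iter = 1L,
                        loglik = observed_loglik(md, pi_cur, beta_cur,
                                                 baseline, parts),
                        criterion = 0)
    converged <- TRUE
  } else {
    for (r in seq_len(control$max_iter)) {
      w <- e_step(md, pi_cur, beta_cur, baseline, parts)
      if (model == "svm") {
        if (control$retune_every_iter) {
          vr <- ifelse(rc, ifelse(w > 0.5, 1L, -1L), 1L)
          if (length(unique(vr)) == 2) {
            ggrid <- if (control$data_driven_gamma)
              data_driven_gamma_grid(md$z) else control$gamma_grid
            tuning <- tune_hyperparameters(md$z, vr, ggrid, control$Q_grid,
                                           control$cv_folds)
          }
        }
        inc <- impute_and_estimate_pi(md$z, rc, w, control$M,
                                      gamma = tuning$gamma, Q = tuning$Q)
        pi_new <- inc$pi
        inc_models <- inc$models
      } else {
        # fresh maximization each M-step: under separation the weighted MLE
        # is at infinity and a warm start would compound across iterations
        logit_par <- fit_logit_incidence(md$z, w)
        pi_new <- stats::plogis(logit_par[1] +
                                  as.vector(md$z %*% logit_par[-1]))
      }
      beta_new <- maximize_q_c2(md, w, baseline, beta_init = beta_cur)$beta
      crit <- sum((c(pi_new, beta_new) - c(pi_cur, beta_cur))^2) / scale_crit
      pi_cur <- pi_new
      beta_cur <- beta_new
      trace <- rbind(trace,
                     data.frame(iter = r,
                                loglik = observed_loglik(md, pi_cur, beta_cur,
                                                         baseline, parts),
                                criterion = crit))
      if (crit < control$eps) {
        converged <- TRUE
        break
      }
    }
  }

  names(beta_cur) <- md$x_names
  structure(list(pi_hat = pi_cur, beta_hat = beta_cur, baseline = baseline,
                 trace = trace, converged = converged, model = model,
                 incidence = if (model == "svm") inc_models else logit_par,
                 tuning = tuning, data = md, control = control, seed = seed,
                 se = NULL, call = NULL),
            class = "micure")
}

# pi(z) prediction shared by predict.micure and the study driver
micure_pi <- function(fit, z) {
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  if (fit$model == "svm") {
    if (is.null(fit$incidence)) {
      return(rep((length(fit$pi_hat) + 1) / (length(fit$pi_hat) + 2), nrow(z)))
    }
    pm <- vapply(fit$incidence, function(m) platt_predict(m, z),
                 numeric(nrow(z)))
    rowMeans(matrix(pm, nrow = nrow(z)))
  } else {
    par <- fit$incidence
    stats::plogis(par[1] + as.vector(z %*% par[-1]))
  }
}

#' Bootstrap standard errors for the latency coefficients
#'
#' Nonparametric bootstrap: subjects are resampled with replacement `B`
#' times, the model is refitted on each resample, and the standard error
#' of each latency coefficient is the sample standard deviation across
#' successful refits. Failed refits are dropped and counted; more than 20%
#' failures is an error.
#'
#' @param fit a fitted `micure` object.
#' @param B number of bootstrap replicates (default from the fit's control).
#' @param seed integer seed; replicate `b` uses `seed + b`.
#' @param control optional control list for the refits (e.g. a smaller
#'   `max_iter`); defaults to the original fit's control.
#' @return the `micure` object with `se` (named vector), `boot_estimates`
#'   (B x p matrix of successful refits) and `boot_failures` filled in.
#' @export
bootstrap_se <- function(fit, B = NULL, seed = NULL, control = NULL) {
  stopifnot(inherits(fit, "micure"))
  if (is.null(B)) B <- fit$control$bootstrap_B
  if (is.null(control)) control <- fit$control
  if (is.null(seed)) seed <- if (is.null(fit$seed)) 0L else fit$seed
  n <- length(fit$data$u_left)
  est <- matrix(NA_real_, B, length(fit$beta_hat))
  fails <- 0L
  for (b in seq_len(B)) {
    bseed <- (seed + b) %% .Machine$integer.max
    set.seed(bseed)
    idx <- sample.int(n, n, replace = TRUE)
    rb <- tryCatch(
      fit_micure_core(fit$data[idx], fit$model, control, seed = bseed),
      error = function(e) NULL)
    if (is.null(rb)) fails <- fails + 1L else est[b, ] <- rb$beta_hat
  }
  if (fails > 0.2 * B) {
    stop(fails, " of ", B, " bootstrap refits failed")
  }
  ok <- stats::complete.cases(est)
  se <- apply(est[ok, , drop = FALSE], 2, stats::sd)
  names(se) <- names(fit$beta_hat)
  fit$se <- se
  fit$boot_estimates <- est[ok, , drop = FALSE]
  fit$boot_failures <- fails
  fit
}
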