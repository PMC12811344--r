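# Latency component: Cox proportional-hazards structure over the frozen
# Turnbull baseline, S(t|x) = S0(t)^exp(x'beta).

# Clip baseline survival probabilities before logs/powers; Turnbull steps
# can hit exact zero.
.clip_s0 <- function(s) pmin(pmax(s, 1e-12), 1)

.NEG_SENTINEL <- -1e10

#' Conditional survival of uncured subjects
#'
#' `S(t|x) = S0(t)^exp(x'beta)`, evaluated over a fitted Turnbull baseline.
#'
#' @param beta latency coefficients (no intercept).
#' @param x covariate vector or matrix (rows = subjects).
#' @param baseline a `turnbull` object.
#' @param t time(s), recycled against the rows of `x`.
#' @return survival probabilities in `[0, 1]`.
#' @export
conditional_survival <- function(beta, x, baseline, t) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  s0 <- baseline_survival_at(baseline, t)
  ebx <- exp(as.vector(x %*% beta))
  out <- exp(ebx * log(.clip_s0(s0)))
  out[s0 == 0] <- 0
  out
}

# Precompute the pieces of the weighted latency log-likelihood that do not
# change with beta. data: mcic_data; baseline: turnbull fit.
latency_parts <- function(data, baseline) {
  uL <- data$u_left
  uR <- data$u_right
  s0L <- baseline_survival_at(baseline, uL)
  s0R <- ifelse(is.finite(uR), baseline_survival_at(baseline, uR),
                baseline$residual_mass)
  list(x = data$x,
       d1 = data$delta1 == 1, d2 = data$delta2 == 1,
       rc = data$delta1 + data$delta2 == 0,
       logs0L = log(.clip_s0(s0L)), logs0R = log(.clip_s0(s0R)))
}

#' Weighted complete-data latency log-likelihood
#'
#' The latency part of the complete-data log-likelihood with the missing
#' cured statuses replaced by E-step weights `w`:
#' left-censored subjects contribute `log(1 - S0(U_R)^e)`, interval-censored
#' subjects `log(S0(U_L)^e - S0(U_R)^e)` and right-censored subjects
#' `w * e * log S0(U_L)`, with `e = exp(x'beta)`. Returns a large negative
#' sentinel (never throws) when an interval term is non-positive, so a
#' derivative-free optimizer can recover.
#'
#' @param beta latency coefficient vector.
#' @param data an [mcic_data] object.
#' @param w weights in `[0, 1]`, equal to 1 for left/interval-censored
#'   subjects.
#' @param baseline a `turnbull` object.
#' @param parts optional precomputed [latency_parts] (internal speed-up).
#' @return the log-likelihood value (scalar).
#' @export
q_c2 <- function(beta, data, w, baseline, parts = NULL) {
  if (is.null(parts)) parts <- latency_parts(data, baseline)
  ebx <- exp(as.vector(parts$x %*% beta))
  val <- 0
  if (any(parts$d1)) {
    u <- 1 - exp(ebx[parts$d1] * parts$logs0R[parts$d1])
    if (any(u <= 0)) return(.NEG_SENTINEL)
    val <- val + sum(log(u))
  }
  if (any(parts$d2)) {
    u <- exp(ebx[parts$d2] * parts$logs0L[parts$d2]) -
      exp(ebx[parts$d2] * parts$logs0R[parts$d2])
    if (any(u <= 0)) return(.NEG_SENTINEL)
    val <- val + sum(log(u))
  }
  if (any(parts$rc)) {
    val <- val + sum(w[parts$rc] * ebx[parts$rc] * parts$logs0L[parts$rc])
  }
  if (!is.finite(val)) return(.NEG_SENTINEL)
  val
}

#' Maximize the weighted latency log-likelihood
#'
#' Nelder-Mead maximization of [q_c2] in `beta`, restarted once from the
#' first solution. If the objective is flat over the simplex (all subjects
#' in a single Turnbull class, say) the starting value is returned with a
#' warning.
#'
#' @param data an [mcic_data] object.
#' @param w E-step weights.
#' @param baseline a `turnbull` object.
#' @param beta_init starting coefficient vector.
#' @param reltol simplex convergence tolerance on the objective.
#' @return list with `beta`, the achieved `value`, and `flat` flag.
#' @export
maximize_q_c2 <- function(data, w, baseline, beta_init,
                          reltol = 1e-8) {
  parts <- latency_parts(data, baseline)
  f <- function(b) -q_c2(b, data, w, baseline, parts)
  f0 <- f(beta_init)
  if (f0 >= -.NEG_SENTINEL) stop("infeasible latency likelihood at beta_init")
  run <- function(b0) {
    suppressWarnings(stats::optim(b0, f, method = "Nelder-Mead",
                                  control = list(reltol = reltol,
                                                 maxit = 2000)))
  }
  # flatness check: a perturbation probe around the start (unidentified
  # beta, e.g. all subjects in one Turnbull class, leaves q_c2 constant)
  probe <- vapply(seq_along(beta_init), function(j) {
    b <- beta_init
    b[j] <- b[j] + 0.5
    f(b)
  }, numeric(1))
  if (all(abs(probe - f0) < 1e-8)) {
    warning("latency objective is flat; returning the starting value")
    return(list(beta = beta_init, value = -f0, flat = TRUE))
  }
  o1 <- run(beta_init)
  o2 <- run(o1$par)  # single restart from the returned point
  best <- if (o2$value <= o1$value) o2 else o1
  if (best$value > f0) {  # never accept a descent step
    return(list(beta = beta_init, value = -f0, flat = FALSE))
  }
  list(beta = best$par, value = -best$value, flat = FALSE)
}

#' No-cure semiparametric PH fit for initialization
#'
#' Maximizes the observed-data log-likelihood of an interval-censored
#' proportional-hazards model *without* a cure fraction, jointly over the
#' regression coefficients and the baseline mass vector on the Turnbull
#' equivalence classes (softmax-parametrized). This is the classical
#' semiparametric no-cure fit used to initialize the latency coefficients
#' of the mixture model; unlike a fit over a frozen marginal baseline it
#' does not attenuate the coefficients when a cured subgroup is present.
#'
#' @param data an [mcic_data] object.
#' @param beta_init starting coefficients (default zeros).
#' @param maxit BFGS iteration cap.
#' @return list with `beta` and the maximized `loglik`.
#' @export
noncure_ph_fit <- function(data, beta_init = NULL, maxit = 200) {
  iv <- turnbull_intervals(data)
  m <- nrow(iv)
  p <- ncol(data$x)
  if (is.null(beta_init)) beta_init <- numeric(p)
  fin <- is.finite(iv$p)
  # S0(t) = sum of masses of classes with right endpoint > t
  BL <- outer(data$u_left, iv$p, `<`) | matrix(!fin, length(data$u_left),
                                               m, byrow = TRUE)
  BR <- outer(data$u_right, iv$p, `<`) | matrix(!fin, length(data$u_left),
                                                m, byrow = TRUE)
  storage.mode(BL) <- "double"
  storage.mode(BR) <- "double"
  d1 <- data$delta1 == 1
  d2 <- data$delta2 == 1
  rc <- !d1 & !d2
  x <- data$x
  nll <- function(par) {
    beta <- par[seq_len(p)]
    th <- par[-seq_len(p)]
    s <- exp(th - max(th))
    s <- s / sum(s)
    SL <- pmin(pmax(as.vector(BL %*% s), 1e-10), 1)
    SR <- pmin(pmax(as.vector(BR %*% s), 1e-10), 1)
    e <- exp(as.vector(x %*% beta))
    ll <- numeric(length(e))
    ll[d1] <- log(pmax(1 - SR[d1]^e[d1], 1e-12))
    ll[d2] <- log(pmax(SL[d2]^e[d2] - SR[d2]^e[d2], 1e-12))
    ll[rc] <- e[rc] * log(SL[rc])
    -sum(ll)
  }
  # box bounds keep the fit finite on degenerate (e.g. bootstrap) resamples
  # where the no-cure likelihood has directions of unbounded ascent
  o <- stats::optim(c(beta_init, rep(0, m)), nll, method = "L-BFGS-B",
                    lower = c(rep(-15, p), rep(-30, m)),
                    upper = c(rep(15, p), rep(30, m)),
                    control = list(maxit = maxit))
  th <- o$par[-seq_len(p)]
  s <- exp(th - max(th))
  s <- s / sum(s)
  iv$s <- s
  baseline <- structure(
    list(intervals = iv[fin, , drop = FALSE],
         residual_mass = 1 - sum(s[fin]),
         loglik = -o$value, iterations = o$counts[1],
         converged = o$convergence == 0, n = length(data$u_left),
         tol = NA),
    class = "turnbull")
  list(beta = o$par[seq_len(p)], loglik = -o$value, baseline = baseline)
}
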