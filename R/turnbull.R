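#' Turnbull maximal intersections of censoring intervals
#'
#' Computes the equivalence-class ("Turnbull") intervals of a set of
#' half-open censoring intervals `(u_left, u_right]` (right-censored
#' subjects contribute `(u_left, Inf)`). These are the intervals
#' `(q, p]` with `q` an observed left endpoint, `p` an observed right
#' endpoint, `q < p`, containing no other observed endpoint in their
#' interior; the nonparametric MLE of the survival function can only place
#' probability mass on them.
#'
#' @param data an [mcic_data] object, or a list with numeric `u_left` and
#'   `u_right`.
#' @return a data frame with columns `q` and `p` (possibly `Inf`), sorted
#'   and disjoint.
#' @export
turnbull_intervals <- function(data) {
  L <- data$u_left
  R <- data$u_right
  # Sort the pooled endpoints; at ties a right endpoint precedes a left
  # endpoint so that touching intervals like (0,1], (1,2] stay distinct
  # classes. A class opens at each left endpoint immediately followed by a
  # right endpoint.
  v <- c(L, R)
  typ <- rep(c(0L, 1L), c(length(L), length(R)))  # 0 = left, 1 = right
  o <- order(v, -typ)
  v <- v[o]; typ <- typ[o]
  opens <- which(typ[-length(typ)] == 0L & typ[-1] == 1L)
  data.frame(q = v[opens], p = v[opens + 1L])
}

#' Nonparametric Turnbull estimate of the baseline survival function
#'
#' Self-consistency (EM) estimation of the survival function from
#' mixed-case interval-censored data, placing probability masses `s_j` on
#' the maximal intersections returned by [turnbull_intervals]. The masses
#' satisfy, at convergence, the self-consistency fixed point
#' `s_j = (1/n) sum_i a_ij s_j / sum_k a_ik s_k`, where `a_ij` indicates
#' that class `j` is contained in subject `i`'s interval, and the observed
#' log-likelihood is non-decreasing across iterations.
#'
#' The estimate is undefined inside a class interval; this implementation
#' evaluates the survival function as a right-continuous step with all of
#' each class's mass at its right endpoint (see [baseline_survival_at]).
#'
#' @param data an [mcic_data] object.
#' @param tol convergence tolerance on the self-consistency residual
#'   (maximum absolute change in any mass).
#' @param max_iter maximum number of self-consistency iterations.
#' @return an object of class `turnbull`: a list with the class
#'   `intervals` (data frame `q`, `p`, `s`), `residual_mass` (probability
#'   beyond the last finite class), `loglik`, `iterations` and `converged`.
#' @export
turnbull_fit <- function(data, tol = 1e-6, max_iter = 10000) {
  stopifnot(inherits(data, "mcic_data") || is.list(data))
  iv <- turnbull_intervals(data)
  m <- nrow(iv)
  n <- length(data$u_left)
  # a_ij: class j = (q_j, p_j] contained in subject i's interval (L_i, R_i]
  A <- outer(data$u_left, iv$q, `<=`) & outer(data$u_right, iv$p, `>=`)
  storage.mode(A) <- "double"
  if (any(rowSums(A) == 0)) stop("subject interval contains no Turnbull class")
  s <- rep(1 / m, m)
  conv <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    denom <- as.vector(A %*% s)
    s_new <- s * as.vector(crossprod(A, 1 / denom)) / n
    s_new <- s_new / sum(s_new)
    if (max(abs(s_new - s)) < tol) {
      s <- s_new
      conv <- TRUE
      break
    }
    s <- s_new
  }
  if (!conv) {
    warning("Turnbull self-consistency did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  ll <- sum(log(as.vector(A %*% s)))
  iv$s <- s
  fin <- is.finite(iv$p)
  structure(list(intervals = iv[fin, , drop = FALSE],
                 residual_mass = 1 - sum(s[fin]),
                 loglik = ll, iterations = it, converged = conv,
                 n = n, tol = tol),
            class = "turnbull")
}

#' Evaluate a Turnbull baseline survival function
#'
#' Right-continuous step-function convention: the mass of class `(q_j, p_j]`
#' drops at the right endpoint `p_j`, so
#' `S0(t) = 1 - sum over classes with p_j <= t of s_j`, `S0(0) = 1`, and
#' `S0(Inf)` equals the residual mass beyond the last finite class.
#'
#' @param fit a `turnbull` object from [turnbull_fit].
#' @param t vector of times, each `>= 0` (may include `Inf`).
#' @return survival probabilities, same length as `t`.
#' @export
baseline_survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "turnbull"))
  if (any(t < 0, na.rm = TRUE) || anyNA(t)) stop("times must be >= 0")
  p <- fit$intervals$p
  s <- fit$intervals$s
  fin <- is.finite(p)
  surv <- 1 - vapply(t, function(ti) sum(s[fin & p <= ti]), numeric(1))
  surv[is.infinite(t)] <- fit$residual_mass
  pmin(pmax(surv, 0), 1)
}

#' @export
print.turnbull <- function(x, ...) {
  cat("Turnbull NPMLE of the baseline survival function\n")
  cat(sprintf("  %d subjects, %d equivalence classes, residual mass %.4f\n",
              x$n, nrow(x$intervals), x$residual_mass))
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s)\n", x$loglik,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
plot.turnbull <- function(x, xlab = "time", ylab = "baseline survival", ...) {
  p <- x$intervals$p
  fin <- is.finite(p)
  tt <- c(0, p[fin])
  ss <- baseline_survival_at(x, tt)
  graphics::plot(stats::stepfun(p[fin], c(1, ss[-1])), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

#' Export a Turnbull baseline as a CSV table
#'
#' Writes one row per equivalence class (`q,p,mass`) followed by a
#' `residual` row holding the mass beyond the last finite class.
#'
#' @param fit a `turnbull` object.
#' @param path output file path.
#' @export
write_baseline <- function(fit, path) {
  stopifnot(inherits(fit, "turnbull"))
  df <- data.frame(q = as.character(fit$intervals$q),
                   p = ifelse(is.finite(fit$intervals$p),
                              as.character(fit$intervals$p), "inf"),
                   mass = fit$intervals$s)
  df <- rbind(df, data.frame(q = "residual", p = "",
                             mass = fit$residual_mass))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
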