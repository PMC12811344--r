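#' @export
print.micure <- function(x, digits = 4, ...) {
  cat("Mixture cure model for mixed-case interval-censored data\n")
  cat("  incidence:", if (x$model == "svm")
    "SVM (RBF kernel, Platt-scaled)" else "logistic regression",
    "| latency: PH over Turnbull baseline\n")
  d <- x$data
  cat(sprintf("  n = %d (left %d / interval %d / right-censored %d)\n",
              length(d$u_left), sum(d$delta1), sum(d$delta2),
              sum(d$delta1 + d$delta2 == 0)))
  if (!is.null(x$tuning)) {
    cat(sprintf("  tuned hyperparameters: gamma = %.4g, Q = %.4g\n",
                x$tuning$gamma, x$tuning$Q))
  }
  cat("  latency coefficients:\n")
  print(round(x$beta_hat, digits))
  cat(sprintf("  mean fitted uncured probability: %.3f\n", mean(x$pi_hat)))
  cat(sprintf("  EM: %d iteration(s), %sconverged (criterion %.2e)\n",
              nrow(x$trace), if (x$converged) "" else "NOT ",
              utils::tail(x$trace$criterion, 1)))
  invisible(x)
}

#' @export
coef.micure <- function(object, ...) object$beta_hat

#' Summarize a fitted micure model
#'
#' @param object a `micure` fit.
#' @param ... unused.
#' @return a `summary.micure` object: the coefficient table (with bootstrap
#'   standard errors, z statistics and p-values when [bootstrap_se] has been
#'   run), fit information and the final log-likelihood.
#' @export
summary.micure <- function(object, ...) {
  tab <- cbind(Estimate = object$beta_hat)
  if (!is.null(object$se)) {
    zstat <- object$beta_hat / object$se
    tab <- cbind(Estimate = object$beta_hat, `Boot. SE` = object$se,
                 `z value` = zstat,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(zstat)))
  }
  structure(list(coefficients = tab, model = object$model,
                 converged = object$converged,
                 iterations = nrow(object$trace),
                 loglik = utils::tail(object$trace$loglik, 1),
                 cure_rate = mean(1 - object$pi_hat),
                 tuning = object$tuning),
            class = "summary.micure")
}

#' @export
print.summary.micure <- function(x, digits = 4, ...) {
  cat("Mixture cure model (", if (x$model == "svm") "SVM" else "logit",
      " incidence)\n\nLatency coefficients:\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits,
                      has.Pvalue = "Pr(>|z|)" %in% colnames(x$coefficients))
  cat(sprintf("\nMean fitted cure rate: %.3f\n", x$cure_rate))
  cat(sprintf("Observed log-likelihood: %.3f after %d EM iteration(s)%s\n",
              x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Predictions from a fitted micure model
#'
#' @param object a `micure` fit.
#' @param newdata an [mcic_data] object, a data frame containing the model's
#'   covariate columns, or `NULL` for the training subjects.
#' @param type `"uncured"` for the incidence probability `pi(z)`,
#'   `"survival"` for the conditional (susceptible) survival `S(t|x)`, or
#'   `"population"` for `S_p(t|x,z) = 1 - pi(z) + pi(z) S(t|x)`.
#' @param times evaluation times (required for `"survival"` and
#'   `"population"`); either length 1 or one per subject.
#' @param ... unused.
#' @return a numeric vector (or, for several `times` and one subject, a
#'   vector over times).
#' @export
predict.micure <- function(object, newdata = NULL,
                           type = c("uncured", "survival", "population"),
                           times = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    x <- object$data$x
    z <- object$data$z
  } else if (inherits(newdata, "mcic_data")) {
    x <- newdata$x
    z <- newdata$z
  } else {
    stopifnot(is.data.frame(newdata))
    need_x <- object$data$x_names
    need_z <- object$data$z_names
    if (!all(need_x %in% names(newdata)) && type != "uncured") {
      stop("newdata lacks latency covariates: ",
           paste(setdiff(need_x, names(newdata)), collapse = ", "))
    }
    x <- if (all(need_x %in% names(newdata)))
      as.matrix(newdata[, need_x, drop = FALSE]) else NULL
    if (!all(need_z %in% names(newdata)) && type != "survival") {
      stop("newdata lacks incidence covariates: ",
           paste(setdiff(need_z, names(newdata)), collapse = ", "))
    }
    z <- if (all(need_z %in% names(newdata)))
      as.matrix(newdata[, need_z, drop = FALSE]) else NULL
  }
  if (type == "uncured") return(micure_pi(object, z))
  if (is.null(times)) stop("'times' is required for survival predictions")
  if (length(times) != 1 && length(times) != nrow(x) && nrow(x) != 1) {
    stop("'times' must have length 1 or one entry per subject")
  }
  if (nrow(x) == 1 && length(times) > 1) {
    x <- x[rep(1, length(times)), , drop = FALSE]
    if (!is.null(z)) z <- z[rep(1, length(times)), , drop = FALSE]
  }
  s <- conditional_survival(object$beta_hat, x, object$baseline, times)
  if (type == "survival") return(s)
  population_survival(micure_pi(object, z), s)
}

#' Diagnostic plots for a micure fit
#'
#' `which = 1` draws the Turnbull baseline survival step function;
#' `which = 2` the EM trace (observed log-likelihood and, on a log scale,
#' the convergence criterion).
#'
#' @param x a `micure` fit.
#' @param which subset of `1:2`.
#' @param ... passed to the underlying plot calls.
#' @export
plot.micure <- function(x, which = 1:2, ...) {
  if (1 %in% which) plot(x$baseline, main = "Turnbull baseline survival", ...)
  if (2 %in% which && nrow(x$trace) > 0) {
    op <- graphics::par(mar = c(5, 4, 4, 4) + 0.1)
    on.exit(graphics::par(op))
    graphics::plot(x$trace$iter, x$trace$loglik, type = "b", pch = 16,
                   xlab = "EM iteration", ylab = "observed log-likelihood",
                   main = "EM trace", ...)
    graphics::par(new = TRUE)
    graphics::plot(x$trace$iter, pmax(x$trace$criterion, 1e-16), type = "b",
                   pch = 1, lty = 2, log = "y", axes = FALSE,
                   xlab = "", ylab = "")
    graphics::axis(4)
    graphics::mtext("criterion (log scale)", side = 4, line = 2.5)
  }
  invisible(x)
}

#' Serialize a fitted micure model to JSON
#'
#' Writes the latency coefficients, fitted probabilities, baseline masses,
#' tuned hyperparameters, per-imputation SVM rules (support points,
#' coefficients, intercept) or logistic parameters, the EM trace, seed and
#' control settings.
#'
#' @param fit a `micure` object.
#' @param path output file path.
#' @export
write_micure_json <- function(fit, path) {
  stopifnot(inherits(fit, "micure"))
  ser_rule <- function(m) list(
    c = m$rule$c, v = m$rule$v, b = m$rule$b, gamma = m$rule$gamma,
    Q = m$rule$Q, support_points = unname(m$rule$sv),
    A = m$calib$A, B = m$calib$B)
  obj <- list(
    model = fit$model,
    beta_hat = as.list(fit$beta_hat),
    se = if (is.null(fit$se)) NULL else as.list(fit$se),
    pi_hat = fit$pi_hat,
    baseline = list(q = fit$baseline$intervals$q,
                    p = fit$baseline$intervals$p,
                    mass = fit$baseline$intervals$s,
                    residual_mass = fit$baseline$residual_mass),
    tuning = if (is.null(fit$tuning)) NULL else
      list(gamma = fit$tuning$gamma, Q = fit$tuning$Q),
    incidence = if (fit$model == "svm") {
      if (is.null(fit$incidence)) NULL else lapply(fit$incidence, ser_rule)
    } else as.list(fit$incidence),
    trace = fit$trace,
    converged = fit$converged,
    seed = fit$seed,
    control = unclass(fit$control))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
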