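# Evaluation metrics: bias/MSE of probability estimates, ROC/AUC against
# known cure labels, the simulation-based ROC when labels are unknown, and
# minority-class oversampling for imbalanced training sets.

#' Population (overall) survival of the mixture cure model
#'
#' `S_p = 1 - pi + pi * s`, the improper survival function with cure
#' plateau `1 - pi`.
#'
#' @param pi uncured probability in `[0, 1]`.
#' @param s conditional (susceptible) survival in `[0, 1]`.
#' @return values in `[1 - pi, 1]`.
#' @export
population_survival <- function(pi, s) {
  stopifnot(all(pi >= 0 & pi <= 1), all(s >= 0 & s <= 1))
  1 - pi + pi * s
}

#' Bias and mean squared error of per-subject estimates
#'
#' Each replication contributes its subject-mean error and squared error;
#' the report averages those per-replication summaries.
#'
#' @param estimates,truths either numeric vectors (one replication) or
#'   lists of aligned numeric vectors (one element per replication).
#' @return a list with `bias`, `mse` and `n_reps`.
#' @export
bias_mse <- function(estimates, truths) {
  if (!is.list(estimates)) estimates <- list(estimates)
  if (!is.list(truths)) truths <- list(truths)
  stopifnot(length(estimates) == length(truths), length(estimates) > 0)
  per <- mapply(function(e, t) {
    stopifnot(length(e) == length(t), length(e) > 0)
    c(bias = mean(e - t), mse = mean((e - t)^2))
  }, estimates, truths)
  list(bias = mean(per["bias", ]), mse = mean(per["mse", ]),
       n_reps = length(estimates))
}

#' ROC curve and AUC by the rank statistic
#'
#' `AUC = P(score_pos > score_neg) + P(tie)/2`, computed from midranks
#' (equivalent to the Mann-Whitney statistic); the ROC curve enumerates
#' every threshold.
#'
#' @param scores numeric predictions (larger = more likely positive).
#' @param labels 0/1 vector; 1 is the positive (uncured) class.
#' @return list with `auc` and `curve` (data frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for ROC")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == 1)
  fp <- cumsum(labels[o] == 0)
  last <- which(!duplicated(scores[o], fromLast = TRUE))  # collapse ties
  list(auc = auc,
       curve = data.frame(fpr = c(0, fp[last] / n0),
                          tpr = c(0, tp[last] / n1)))
}

# interpolate a ROC curve's TPR onto an FPR grid (vertical averaging)
roc_at_fpr <- function(curve, grid) {
  stats::approx(curve$fpr, curve$tpr, xout = grid, method = "linear",
                ties = max, rule = 2)$y
}

#' Simulation-based ROC for data with unknown cure labels
#'
#' When true cured statuses are unavailable (as with real censored data),
#' labels are simulated: for every subject the conditional probability of
#' being uncured given the data and the fitted parameters (the E-step
#' weight) is computed, cure labels are drawn from Bernoulli(w), and the
#' fitted uncured probability is scored against the drawn labels. The ROC
#' curves are averaged vertically over an FPR grid and the AUC values
#' averaged across draws.
#'
#' @param fit a fitted `micure` object.
#' @param data an [mcic_data] to evaluate on (default: the training data).
#' @param n_draws number of label draws (default 500).
#' @param fpr_grid grid for vertical curve averaging.
#' @param seed optional integer seed.
#' @return list with `auc` (mean), `auc_draws`, `curve` (averaged), and
#'   `skipped` (single-class draws).
#' @export
simulated_label_roc <- function(fit, data = NULL, n_draws = 500,
                                fpr_grid = seq(0, 1, by = 0.01),
                                seed = NULL) {
  stopifnot(inherits(fit, "micure"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(data)) data <- fit$data
  pi_hat <- micure_pi(fit, data$z)
  w <- e_step(data, pi_hat, fit$beta_hat, fit$baseline)
  aucs <- numeric(0)
  tprs <- matrix(NA_real_, n_draws, length(fpr_grid))
  skipped <- 0L
  for (d in seq_len(n_draws)) {
    lab <- as.integer(stats::runif(length(w)) < w)
    if (length(unique(lab)) < 2) {
      skipped <- skipped + 1L
      next
    }
    r <- roc_auc(pi_hat, lab)
    aucs <- c(aucs, r$auc)
    tprs[d, ] <- roc_at_fpr(r$curve, fpr_grid)
  }
  if (skipped > n_draws / 2) stop("more than half of the label draws were single-class")
  list(auc = mean(aucs), auc_draws = aucs,
       curve = data.frame(fpr = fpr_grid,
                          tpr = colMeans(tprs, na.rm = TRUE)),
       skipped = skipped)
}

#' Oversample the minority class of a training set
#'
#' Duplicates randomly chosen minority-class subjects (sampling with
#' replacement) until the class counts are equal. All original subjects
#' are retained. Class membership uses the observed uncured indicator
#' `delta1 + delta2` (right-censored subjects form the other class).
#'
#' @param data an [mcic_data] training set.
#' @return an [mcic_data] with a 1:1 class ratio.
#' @export
oversample_minority <- function(data) {
  stopifnot(inherits(data, "mcic_data"))
  grp <- data$delta1 + data$delta2
  n1 <- sum(grp == 1)
  n0 <- sum(grp == 0)
  if (n1 == 0 || n0 == 0) stop("both censoring classes required")
  if (n1 == n0) return(data)
  minority <- which(grp == (if (n1 < n0) 1 else 0))
  extra <- sample(minority, abs(n1 - n0), replace = TRUE)
  data[c(seq_along(grp), extra)]
}

#' Bias and MSE of fitted survival probabilities
#'
#' Compares the fitted overall survival `S_p` and susceptible survival `S`
#' with their true-model counterparts (true Weibull latency and true
#' incidence surface), evaluated by default at each subject's last finite
#' examination endpoint (`u_left` for right-censored subjects, `u_right`
#' otherwise) — the only times the observation scheme identifies.
#'
#' @param fit a fitted `micure` object.
#' @param data an [mcic_data] with the subjects to evaluate.
#' @param truth the matching `truth` data frame from [generate_mcic].
#' @param scenario the scenario id (for the true latency parameters), or a
#'   list like [scenario_spec]'s return value.
#' @param x_full the full true-latency covariate matrix for `data` (the
#'   generator's `x`); defaults to `data$x`, which is correct whenever the
#'   model's latency covariates are the generator's.
#' @param times optional fixed evaluation time(s) overriding the
#'   subject-anchored default.
#' @return list of two [bias_mse] reports: `overall` and `susceptible`.
#' @export
survival_bias_mse <- function(fit, data, truth, scenario, x_full = NULL,
                              times = NULL) {
  spec <- if (is.list(scenario)) scenario else scenario_spec(scenario)
  if (is.null(x_full)) x_full <- data$x
  if (is.null(times)) {
    times <- ifelse(is.finite(data$u_right), data$u_right, data$u_left)
  } else if (length(times) == 1) {
    times <- rep(times, length(data$u_left))
  }
  s_true <- exp(-exp(as.vector(x_full %*% spec$beta_true)) *
                  times^spec$alpha)
  sp_true <- population_survival(truth$pi_true, s_true)
  s_fit <- conditional_survival(fit$beta_hat, data$x, fit$baseline, times)
  sp_fit <- population_survival(micure_pi(fit, data$z), s_fit)
  list(overall = bias_mse(sp_fit, sp_true),
       susceptible = bias_mse(s_fit, s_true))
}
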