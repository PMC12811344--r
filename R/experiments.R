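# Scripted Monte-Carlo studies: data generation, train/test split, model
# fitting and metric aggregation, mirroring the benchmark table layouts
# (bias/MSE of uncured probability, training/testing AUC, bias/MSE of
# overall and susceptible survival probabilities).

# Stratified train/test split on censoring type; returns training indices.
stratified_split <- function(data, train_fraction) {
  grp <- paste(data$delta1, data$delta2)
  idx <- unlist(lapply(split(seq_along(grp), grp), function(i) {
    sample(i, max(1, round(train_fraction * length(i))))
  }), use.names = FALSE)
  sort(idx)
}

#' Run a Monte-Carlo simulation study
#'
#' For each replication: generate a scenario dataset, split it into
#' training and testing sets (stratified on censoring type), fit the
#' requested models on the training set, and score them — bias and MSE of
#' the estimated uncured probability against the true incidence surface,
#' AUC of the estimated uncured probability against the true cure labels
#' (training and testing), and bias/MSE of the fitted overall and
#' susceptible survival probabilities at each subject's last finite
#' examination endpoint. Per-replication summaries are averaged. Headline
#' metrics (π bias/MSE, survival bias/MSE) are computed on the testing
#' subjects; training-set counterparts are also reported.
#'
#' A replication whose fit fails is regenerated with a fresh derived seed
#' (at most 3 retries) and the failure count reported.
#'
#' @param scenario scenario id, 1-4.
#' @param n sample size per replication.
#' @param reps number of Monte-Carlo replications.
#' @param models character subset of `c("svm", "logit")`.
#' @param seed integer seed; replication `r` derives `seed + 1000 r`.
#' @param train_fraction fraction of subjects in the training set.
#' @param control a [micure_control] for the fits.
#' @return object of class `micure_study`: `summary` (one row per model:
#'   aggregated metrics), `per_rep` (one row per model and replication)
#'   and the configuration.
#' @export
run_simulation_study <- function(scenario, n, reps, models = c("svm", "logit"),
                                 seed = 1, train_fraction = 2 / 3,
                                 control = micure_control()) {
  stopifnot(reps >= 1, train_fraction > 0, train_fraction < 1,
            all(models %in% c("svm", "logit")))
  rows <- list()
  failures <- 0L
  for (r in seq_len(reps)) {
    for (attempt in 0:3) {
      rseed <- (seed + 1000 * r + 97 * attempt) %% .Machine$integer.max
      sim <- generate_mcic(scenario, n, seed = rseed)
      set.seed(rseed + 1)
      tr_idx <- stratified_split(sim$data, train_fraction)
      te_idx <- setdiff(seq_len(n), tr_idx)
      res <- tryCatch({
        lapply(models, function(m) {
          fit <- micure(sim$data[tr_idx], model = m, control = control,
                        seed = rseed + 2)
          score_fit(fit, sim, tr_idx, te_idx, m, r)
        })
      }, error = function(e) NULL)
      if (!is.null(res)) break
      failures <- failures + 1L
    }
    if (is.null(res)) stop("replication ", r, " failed after 3 retries")
    rows <- c(rows, res)
  }
  per_rep <- do.call(rbind, rows)
  agg <- stats::aggregate(per_rep[, setdiff(names(per_rep),
                                            c("model", "rep"))],
                          by = list(model = per_rep$model), FUN = mean)
  structure(list(summary = agg, per_rep = per_rep, scenario = scenario,
                 n = n, reps = reps, models = models, seed = seed,
                 failures = failures, control = control),
            class = "micure_study")
}

# one row of per-replication metrics for a fitted model
score_fit <- function(fit, sim, tr_idx, te_idx, model, r) {
  truth <- sim$truth
  d_tr <- sim$data[tr_idx]
  d_te <- sim$data[te_idx]
  pi_tr <- fit$pi_hat
  pi_te <- micure_pi(fit, d_te$z)
  bm_tr <- bias_mse(pi_tr, truth$pi_true[tr_idx])
  bm_te <- bias_mse(pi_te, truth$pi_true[te_idx])
  auc_tr <- roc_auc(pi_tr, truth$J_true[tr_idx])$auc
  auc_te <- roc_auc(pi_te, truth$J_true[te_idx])$auc
  sv_te <- survival_bias_mse(fit, d_te, truth[te_idx, ], sim$scenario)
  sv_tr <- survival_bias_mse(fit, d_tr, truth[tr_idx, ], sim$scenario)
  data.frame(model = model, rep = r,
             pi_bias = bm_te$bias, pi_mse = bm_te$mse,
             pi_bias_train = bm_tr$bias, pi_mse_train = bm_tr$mse,
             auc_train = auc_tr, auc_test = auc_te,
             overall_bias = sv_te$overall$bias,
             overall_mse = sv_te$overall$mse,
             susceptible_bias = sv_te$susceptible$bias,
             susceptible_mse = sv_te$susceptible$mse,
             overall_bias_train = sv_tr$overall$bias,
             susceptible_bias_train = sv_tr$susceptible$bias,
             beta1 = fit$beta_hat[1],
             beta2 = if (length(fit$beta_hat) > 1) fit$beta_hat[2] else NA)
}

#' @export
print.micure_study <- function(x, digits = 4, ...) {
  cat(sprintf("Monte-Carlo study: scenario %s, n = %d, %d replication(s)\n",
              x$scenario, x$n, x$reps))
  if (x$failures) cat("  replication retries after fit failure:",
                      x$failures, "\n")
  cols <- c("model", "pi_bias", "pi_mse", "auc_train", "auc_test",
            "overall_bias", "overall_mse", "susceptible_bias",
            "susceptible_mse")
  print(format(x$summary[, cols], digits = digits), row.names = FALSE)
  invisible(x)
}

#' End-to-end workflow on a decompression-sickness-like dataset
#'
#' Mirrors the real-data analysis pipeline on a (synthetic) fixture with
#' covariates Age, Sex, TR360 and NOADYN: split into training and testing
#' sets (stratified on censoring type), oversample the minority censoring
#' class within the training set, fit the SVM mixture cure model with
#' incidence covariates (Age, Sex) and all four latency covariates,
#' compute bootstrap standard errors, evaluate the fitted uncured
#' probability surface over (Age, Sex), and estimate predictive accuracy
#' for cure on the testing set via the simulation-based averaged ROC.
#'
#' @param data an [mcic_data] from [generate_hdsd_like] (or with the same
#'   covariate layout).
#' @param seed integer seed.
#' @param train_fraction training share (default 0.7).
#' @param control a [micure_control].
#' @param bootstrap_B bootstrap replicates for the standard errors.
#' @param roc_draws label draws for the simulation-based ROC.
#' @return list with `fit` (including bootstrap SEs), `pi_surface`
#'   (data frame Age x Sex with fitted uncured probability), `roc`
#'   (averaged ROC/AUC on the testing set) and the split indices.
#' @export
run_hdsd_workflow <- function(data, seed = 1, train_fraction = 0.7,
                              control = micure_control(),
                              bootstrap_B = 100, roc_draws = 500) {
  stopifnot(inherits(data, "mcic_data"))
  set.seed(seed)
  n <- length(data$u_left)
  tr_idx <- stratified_split(data, train_fraction)
  te_idx <- setdiff(seq_len(n), tr_idx)
  train <- oversample_minority(data[tr_idx])
  fit <- micure(train, model = "svm", control = control, seed = seed + 1)
  fit <- bootstrap_se(fit, B = bootstrap_B, seed = seed + 2)
  ages <- seq(min(data$z[, 1]), max(data$z[, 1]), length.out = 41)
  grid <- expand.grid(Age = ages, Sex = c(0, 1))
  grid$pi_hat <- micure_pi(fit, as.matrix(grid))
  roc <- simulated_label_roc(fit, data[te_idx], n_draws = roc_draws,
                             seed = seed + 3)
  list(fit = fit, pi_surface = grid, roc = roc,
       train_idx = tr_idx, test_idx = te_idx)
}
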