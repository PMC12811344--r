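# Shared Monte-Carlo studies for the acceptance tests. Computed lazily and
# cached so several test blocks can read the same study without refitting.
#
# Study sizes: scenarios 1-2 use 50 replications, scenarios 3-4 use 30
# (directional checks only). The SVM EM is capped at 15 iterations — its
# convergence criterion reaches the multiple-imputation Monte-Carlo noise
# floor well before that, so the printed stopping rule cannot trigger —
# while the logistic EM runs the printed rule (eps = 1e-3) to convergence
# with a cap of 50.

.study_cache <- new.env(parent = emptyenv())

study_control <- function(model) {
  if (model == "svm") micure_control(max_iter = 15)
  else micure_control(max_iter = 50)
}

get_study <- function(scenario) {
  key <- paste0("s", scenario)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  reps <- if (scenario <= 2) 50 else 30
  per <- list()
  for (model in c("svm", "logit")) {
    st <- run_simulation_study(scenario, n = 300, reps = reps,
                               models = model, seed = 1,
                               control = study_control(model))
    per[[model]] <- st$per_rep
  }
  out <- do.call(rbind, per)
  .study_cache[[key]] <- out
  out
}

study_mean <- function(scenario, model, col) {
  pr <- get_study(scenario)
  mean(pr[pr$model == model, col])
}
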