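test_that("E-step weights follow the posterior uncured probability", {
  tb <- structure(list(intervals = data.frame(q = 0, p = 1, s = 0.5),
                       residual_mass = 0.5, loglik = NA, iterations = 0,
                       converged = TRUE, n = 0, tol = 0),
                  class = "turnbull")
  md <- list(u_left = c(0, 0.4, 2, 2), u_right = c(0.5, 1, Inf, Inf),
             delta1 = c(1L, 0L, 0L, 0L), delta2 = c(0L, 1L, 0L, 0L),
             x = matrix(0, 4, 1), z = matrix(0, 4, 1))
  # S0(2) = 0.5, x'beta = 0: right-censored weight = .25/.75 = 1/3
  w <- e_step(md, pi = rep(0.5, 4), beta = 0, baseline = tb)
  expect_equal(w, c(1, 1, 1 / 3, 1 / 3), tolerance = 1e-12)
  # S0(U_L) = 1 makes the right-censored weight collapse to pi
  md2 <- md
  md2$u_left <- c(0, 0.4, 0.2, 0.2)
  md2$delta2 <- c(0L, 1L, 0L, 0L)
  w2 <- e_step(md2, pi = rep(0.37, 4), beta = 0, baseline = tb)
  expect_equal(w2[3:4], c(0.37, 0.37), tolerance = 1e-12)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("E-step weights are bounded on simulated data", {
  sim <- generate_mcic(2, 150, seed = 12)
  tb <- turnbull_fit(sim$data)
  set.seed(1)
  for (rep in 1:5) {
    pi <- runif(150, 0.05, 0.95)
    beta <- rnorm(2)
    w <- e_step(sim$data, pi, beta, tb)
    nonrc <- sim$data$delta1 + sim$data$delta2 == 1
    expect_true(all(w[nonrc] == 1))
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("the observed log-likelihood matches per-subject closed forms", {
  tb <- structure(list(intervals = data.frame(q = 0, p = 1, s = 0.5),
                       residual_mass = 0.5, loglik = NA, iterations = 0,
                       converged = TRUE, n = 0, tol = 0),
                  class = "turnbull")
  # single right-censored subject: log(1 - pi + pi S0(U_L)^e)
  md_r <- list(u_left = 2, u_right = Inf, delta1 = 0L, delta2 = 0L,
               x = matrix(0), z = matrix(0))
  expect_equal(observed_loglik(md_r, 0.5, 0, tb), log(0.75),
               tolerance = 1e-12)
  # single left-censored subject with pi = 1 and S0(U_R) = 0
  tb0 <- structure(list(intervals = data.frame(q = 0, p = 1, s = 1),
                        residual_mass = 0, loglik = NA, iterations = 0,
                        converged = TRUE, n = 0, tol = 0),
                   class = "turnbull")
  md_l <- list(u_left = 0, u_right = 1.5, delta1 = 1L, delta2 = 0L,
               x = matrix(0), z = matrix(0))
  expect_equal(observed_loglik(md_l, 1 - 1e-12, 0, tb0), 0,
               tolerance = 1e-9)
  # additivity over subjects
  sim <- generate_mcic(1, 60, seed = 9)
  tbs <- turnbull_fit(sim$data)
  pi <- runif(60, 0.2, 0.8)
  total <- observed_loglik(sim$data, pi, c(0.3, -0.2), tbs)
  parts <- vapply(1:60, function(i) {
    observed_loglik(sim$data[i], pi[i], c(0.3, -0.2), tbs)
  }, numeric(1))
  expect_equal(total, sum(parts), tolerance = 1e-8)
})

test_that("fits are reproducible bit-for-bit under a fixed seed", {
  sim <- generate_mcic(1, 90, seed = 31)
  ctrl <- micure_control(max_iter = 3)
  f1 <- micure(sim$data, model = "svm", control = ctrl, seed = 7)
  f2 <- micure(sim$data, model = "svm", control = ctrl, seed = 7)
  expect_identical(f1$pi_hat, f2$pi_hat)
  expect_identical(f1$beta_hat, f2$beta_hat)
  expect_identical(f1$trace, f2$trace)
  f3 <- micure(sim$data, model = "svm", control = ctrl, seed = 8)
  expect_false(identical(f3$pi_hat, f1$pi_hat))
})

test_that("a dataset without right-censored subjects fits in one pass", {
  sim <- generate_mcic(1, 250, seed = 13)
  keep <- sim$data$delta1 + sim$data$delta2 == 1
  md <- sim$data[keep]
  fit <- micure(md, model = "svm", seed = 2)
  expect_true(fit$converged)
  expect_equal(nrow(fit$trace), 1L)
  n <- sum(keep)
  expect_equal(fit$pi_hat, rep((n + 1) / (n + 2), n))
})

test_that("the EM trace records the criterion and the log-likelihood", {
  sim <- generate_mcic(1, 90, seed = 17)
  fit <- micure(sim$data, model = "logit",
                control = micure_control(max_iter = 40), seed = 3)
  expect_true(all(c("iter", "loglik", "criterion") %in% names(fit$trace)))
  expect_lte(nrow(fit$trace), 40)
  if (fit$converged) {
    expect_lt(fit$trace$criterion[nrow(fit$trace)], 1e-3)
  }
})

test_that("bootstrap standard errors are nonnegative and reproducible", {
  sim <- generate_mcic(1, 80, seed = 23)
  ctrl <- micure_control(max_iter = 2)
  fit <- micure(sim$data, model = "logit", control = ctrl, seed = 4)
  b1 <- bootstrap_se(fit, B = 6, seed = 99)
  b2 <- bootstrap_se(fit, B = 6, seed = 99)
  expect_identical(b1$se, b2$se)
  expect_true(all(is.finite(b1$se)) && all(b1$se >= 0))
  expect_equal(dim(b1$boot_estimates), c(6L, 2L))
})

test_that("predict.micure returns coherent probabilities and survivals", {
  sim <- generate_mcic(1, 120, seed = 41)
  fit <- micure(sim$data, model = "logit",
                control = micure_control(max_iter = 10), seed = 5)
  p <- predict(fit, type = "uncured")
  expect_equal(p, fit$pi_hat, tolerance = 1e-12)
  s <- predict(fit, type = "survival", times = 1)
  sp <- predict(fit, type = "population", times = 1)
  expect_true(all(sp >= s - 1e-12))
  expect_equal(sp, 1 - p + p * s, tolerance = 1e-12)
  nd <- as.data.frame(sim$data)[1:5, ]
  expect_length(predict(fit, nd, type = "uncured"), 5)
  expect_error(predict(fit, type = "survival"), "times")
})
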