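fake_baseline <- function(surv, tmax = 4, k = 800) {
  # step approximation of a smooth survival function, as a turnbull object
  p <- seq(tmax / k, tmax, length.out = k)
  s <- -diff(c(1, surv(p)))
  structure(list(intervals = data.frame(q = c(0, p[-k]), p = p, s = s),
                 residual_mass = surv(tmax), loglik = NA, iterations = 0,
                 converged = TRUE, n = 0, tol = 0),
            class = "turnbull")
}

test_that("conditional survival follows the proportional-hazards power law", {
  tb <- turnbull_fit(list(u_left = c(1, 3), u_right = c(2, 4)))
  tt <- c(0, 1.5, 2, 3.5, 5)
  # beta = 0 reduces to the baseline
  expect_equal(conditional_survival(0, matrix(1), tb, tt),
               baseline_survival_at(tb, tt))
  # baseline 1 stays 1 whatever the linear predictor
  expect_equal(conditional_survival(c(5, -3), c(2, 1), tb, 0.5), 1)
  # S0 = exp(-t) and x'beta = log 2 gives exp(-2t)
  eb <- fake_baseline(function(t) exp(-t))
  expect_equal(conditional_survival(log(2), matrix(1), eb, c(0.5, 1, 2)),
               exp(-2 * c(0.5, 1, 2)), tolerance = 1e-2)
  # non-increasing in t and decreasing in x'beta below S0 = 1
  s <- conditional_survival(0.4, matrix(1, 5, 1), eb, seq(0.5, 2.5, 0.5))
  expect_true(all(diff(s) < 0))
  expect_lt(conditional_survival(1, matrix(1), eb, 1),
            conditional_survival(0.5, matrix(1), eb, 1))
})

test_that("q_c2 reproduces closed-form contributions", {
  # one interval-censored subject with S0(L) = 0.8, S0(R) = 0.4
  tb <- structure(list(intervals = data.frame(q = c(0, 1), p = c(1, 2),
                                              s = c(0.2, 0.4)),
                       residual_mass = 0.4, loglik = NA, iterations = 0,
                       converged = TRUE, n = 0, tol = 0),
                  class = "turnbull")
  md_i <- list(u_left = 1, u_right = 2, delta1 = 0L, delta2 = 1L,
               x = matrix(0), z = matrix(0))
  expect_equal(q_c2(0, md_i, w = 1, tb), log(0.4), tolerance = 1e-12)
  # one left-censored subject with S0(R) = 0.4
  md_l <- list(u_left = 0, u_right = 2, delta1 = 1L, delta2 = 0L,
               x = matrix(0), z = matrix(0))
  expect_equal(q_c2(0, md_l, w = 1, tb), log(0.6), tolerance = 1e-12)
  # a right-censored subject with w = 0 contributes nothing
  md_r <- list(u_left = 1, u_right = Inf, delta1 = 0L, delta2 = 0L,
               x = matrix(1), z = matrix(1))
  expect_equal(q_c2(2, md_r, w = 0, tb), 0)
  # and with w = 1 contributes e^{x'b} log S0(U_L)
  expect_equal(q_c2(0.5, md_r, w = 1, tb), exp(0.5) * log(0.8),
               tolerance = 1e-12)
  # infeasible interval (no mass between the endpoints) returns the
  # sentinel, not an error
  md_bad <- list(u_left = 2.2, u_right = 2.8, delta1 = 0L, delta2 = 1L,
                 x = matrix(0), z = matrix(0))
  expect_lt(q_c2(0, md_bad, w = 1, tb), -1e9)
})

test_that("maximize_q_c2 ascends and matches a dense grid search", {
  md <- toy_mcic()
  tb <- turnbull_fit(md)
  w <- rep(1, 8)
  out <- maximize_q_c2(md, w, tb, beta_init = 0)
  expect_gte(out$value, q_c2(0, md, w, tb))
  # coarse-to-fine grid oracle over beta in [-8, 8]
  grid <- seq(-8, 8, by = 0.1)
  vals <- vapply(grid, function(b) q_c2(b, md, w, tb), numeric(1))
  expect_gte(out$value, max(vals) - 1e-8)
  expect_lte(out$value - max(vals), 1e-2)
})

test_that("an unidentified latency returns the start with a warning", {
  # right-censored subjects observed before any baseline mass: S0(U_L) = 1
  # and the weighted likelihood is constant in beta
  md <- list(u_left = c(0.5, 0.5, 0.5), u_right = c(Inf, Inf, Inf),
             delta1 = c(0L, 0L, 0L), delta2 = c(0L, 0L, 0L),
             x = matrix(c(-1, 0, 1)), z = matrix(c(-1, 0, 1)))
  tb <- structure(list(intervals = data.frame(q = 1, p = 2, s = 1),
                       residual_mass = 0, loglik = NA, iterations = 0,
                       converged = TRUE, n = 3, tol = 0),
                  class = "turnbull")
  expect_warning(out <- maximize_q_c2(md, rep(1, 3), tb, beta_init = 0.3),
                 "flat")
  expect_equal(out$beta, 0.3)
  expect_true(out$flat)
})

test_that("the no-cure semiparametric fit recovers signs and magnitude", {
  set.seed(19)
  n <- 400
  x <- matrix(rnorm(2 * n), n, 2)
  beta <- c(-1.5, 1)
  t <- as.vector(-log(runif(n)) / exp(x %*% beta))
  kmax <- 30
  ex <- t(apply(matrix(runif(n * kmax, 0.1, 0.25), n, kmax), 1, cumsum))
  j <- max.col(ex > pmin(t, 2.5), ties.method = "first")
  Uj <- ex[cbind(1:n, j)]
  Ujm1 <- ifelse(j > 1, ex[cbind(1:n, pmax(j - 1, 1))], 0)
  right <- t > 2.5
  left <- !right & Ujm1 == 0
  df <- data.frame(u_left = ifelse(right, Uj, ifelse(left, 0, Ujm1)),
                   u_right = ifelse(right, Inf, Uj),
                   x_1 = x[, 1], x_2 = x[, 2], z_1 = x[, 1], z_2 = x[, 2])
  md <- mcic_data(df, c("x_1", "x_2"), c("z_1", "z_2"))
  fit <- noncure_ph_fit(md)
  expect_equal(fit$beta, beta, tolerance = 0.35)
  # the fitted baseline is a proper turnbull object
  expect_s3_class(fit$baseline, "turnbull")
  expect_equal(sum(fit$baseline$intervals$s) + fit$baseline$residual_mass, 1,
               tolerance = 1e-8)
})
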