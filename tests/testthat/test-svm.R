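test_that("RBF kernel evaluates, is symmetric and positive semi-definite", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), gamma = 0.7), 1)
  # squared distance 1/gamma gives exp(-1)
  g <- 0.25
  z1 <- c(0, 0)
  z2 <- c(sqrt(1 / g), 0)
  expect_equal(rbf_kernel(z1, z2, g), exp(-1), tolerance = 1e-12)
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1), "dimension")
  set.seed(1)
  z <- matrix(rnorm(40), 10, 4)
  K <- rbf_kernel(z, z, gamma = 0.3)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("svm_train solves separable two-point problems and is feasible", {
  z <- matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE)
  v <- c(1, -1)
  rule <- svm_train(z, v, Q = 100, gamma = 0.05)
  expect_equal(length(rule$c), 2)
  expect_equal(rule$c[1], rule$c[2], tolerance = 1e-6)
  g <- decision_value(rule, z)
  expect_gt(g[1], 0)
  expect_lt(g[2], 0)
  # midpoint of a symmetric rule sits on the boundary
  expect_equal(decision_value(rule, c(5, 5)), 0, tolerance = 1e-8)
  expect_error(svm_train(z, c(1, 1), Q = 1, gamma = 1), "degenerate")
})

test_that("trained rules satisfy the dual constraints", {
  set.seed(11)
  for (rep in 1:6) {
    n <- 30
    z <- matrix(rnorm(2 * n), n, 2)
    v <- ifelse(z[, 1] + 0.5 * rnorm(n) > 0, 1, -1)
    if (length(unique(v)) < 2) next
    Q <- sample(c(1, 16, 64), 1)
    rule <- svm_train(z, v, Q = Q, gamma = 0.5)
    expect_true(all(rule$c >= -1e-9 & rule$c <= Q + 1e-9))
    expect_lt(abs(sum(rule$c * rule$v)), 1e-6)
  }
})

test_that("the dual objective matches a dense QP oracle on small sets", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    z <- matrix(rnorm(n), n, 1)
    v <- rep_len(c(1, -1), n)[sample(n)]
    Q <- sample(c(2, 16), 1)
    gamma <- 0.8
    rule <- svm_train(z, v, Q = Q, gamma = gamma)
    oracle <- svm_dual_oracle(rbf_kernel(z, z, gamma), v, Q)
    expect_equal(rule_dual_objective(rule, z, v), oracle$value,
                 tolerance = 1e-4)
  }
})

test_that("decision values equal the kernel expansion", {
  # hand-set rule evaluated by direct summation
  rule <- structure(list(sv = matrix(c(0, 1, -1, 0.5), 2, 2),
                         c = c(0.4, 0.7), v = c(1L, -1L), b = 0.2,
                         gamma = 0.9, Q = 1, n_train = 2),
                    class = "svm_rule")
  z <- c(0.3, -0.2)
  manual <- 0.4 * exp(-0.9 * sum((z - c(0, -1))^2)) -
    0.7 * exp(-0.9 * sum((z - c(1, 0.5))^2)) - 0.2
  expect_equal(decision_value(rule, z), manual, tolerance = 1e-12)
})

test_that("Platt targets implement the shrunken class frequencies", {
  v <- c(1, 1, 1, -1, -1)
  expect_equal(platt_targets(v), c(0.8, 0.8, 0.8, 0.25, 0.25))
  # single-class labels give the single-branch constant
  expect_equal(platt_targets(rep(1, 9)), rep(10 / 11, 9))
})

test_that("Platt calibration maximizes the sigmoid likelihood", {
  set.seed(21)
  g <- c(rnorm(40, 1.5), rnorm(40, -1.5))
  v <- rep(c(1, -1), each = 40)
  cal <- platt_fit(g, v)
  expect_lt(cal$A, 0)  # larger g must mean larger uncured probability
  tgt <- platt_targets(v)
  obj <- function(A, B) {
    eta <- A * g + B
    sum((1 - tgt) * eta) - sum(log1p(exp(eta)))
  }
  expect_gte(cal$objective, obj(0, 0))
  # a coarse lattice around the optimum cannot beat it (concavity)
  for (dA in c(-0.05, 0, 0.05)) {
    for (dB in c(-0.05, 0, 0.05)) {
      expect_lte(obj(cal$A + dA, cal$B + dB), cal$objective + 1e-3)
    }
  }
  # antisymmetric decision values with balanced labels: no intercept
  g2 <- c(2, 1.2, 0.6, -0.6, -1.2, -2)
  v2 <- c(1, 1, 1, -1, -1, -1)
  cal2 <- platt_fit(g2, v2)
  expect_equal(cal2$B, 0, tolerance = 1e-6)
})

test_that("degenerate decision values reduce to the intercept-only fit", {
  v <- c(1, 1, 1, -1, -1)
  cal <- platt_fit(rep(0, 5), v)
  # with g identically 0, pi is constant and matches the mean target
  expect_equal(platt_probability(cal, 0), mean(platt_targets(v)),
               tolerance = 1e-7)
})

test_that("platt_probability is the two-parameter sigmoid", {
  expect_equal(platt_probability(list(A = 0, B = 0), 1.7), 0.5)
  expect_equal(platt_probability(list(A = -1, B = 0), log(3)), 0.75,
               tolerance = 1e-12)
  expect_gt(platt_probability(list(A = -1, B = 0), 30), 1 - 1e-12)
  # monotone in g for A < 0
  p <- platt_probability(list(A = -2, B = 0.3), seq(-3, 3, by = 0.5))
  expect_true(all(diff(p) > 0))
})

test_that("Platt parameters are recovered on logistic synthetic data", {
  set.seed(33)
  n <- 4000
  g <- rnorm(n, 0, 2)
  A0 <- -1.3
  B0 <- 0.4
  v <- ifelse(runif(n) < plogis(-(A0 * g + B0)), 1, -1)
  cal <- platt_fit(g, v)
  expect_equal(cal$A, A0, tolerance = 0.1)
  expect_equal(cal$B, B0, tolerance = 0.1)
})

test_that("hyperparameter tuning returns grid members with tie-breaking", {
  set.seed(2)
  # far-apart blobs: zero CV error everywhere, tie-break picks both minima
  z <- rbind(matrix(rnorm(30, -20), 15), matrix(rnorm(30, 20), 15))
  v <- rep(c(-1, 1), each = 15)
  tu <- tune_hyperparameters(z, v, gamma_grid = 2^(-6:-4), Q_grid = 2^(4:6),
                             folds = 5)
  expect_equal(tu$gamma, 2^-6)
  expect_equal(tu$Q, 2^4)
  expect_true(all(tu$cv_error$error == 0))
  # uninformative labels: error near the minority share
  set.seed(3)
  z2 <- matrix(rnorm(120), 60, 2)
  v2 <- rep(c(1, -1), times = c(40, 20))[sample(60)]
  tu2 <- tune_hyperparameters(z2, v2, folds = 5)
  expect_true(tu2$gamma %in% 2^(-6:-4) && tu2$Q %in% 2^(4:6))
  expect_lt(min(tu2$cv_error$error), 0.55)
  expect_error(tune_hyperparameters(z2[1:3, ], c(1, 1, -1), folds = 5),
               "stratified")
})

test_that("the data-driven gamma grid follows the median heuristic", {
  z <- matrix(c(0, 1, 2), 3, 1)
  # pairwise squared distances 1, 1, 4 -> median 1 -> gamma0 = 1
  expect_equal(data_driven_gamma_grid(z), 2^(-3:3))
  expect_length(data_driven_gamma_grid(matrix(rnorm(20), 10, 2)), 7)
  # rescaling points by s scales gamma0 by 1/s^2
  set.seed(4)
  z2 <- matrix(rnorm(14), 7, 2)
  expect_equal(data_driven_gamma_grid(3 * z2),
               data_driven_gamma_grid(z2) / 9, tolerance = 1e-12)
  expect_error(data_driven_gamma_grid(matrix(1, 4, 2)), "zero median")
})

test_that("multiple imputation averages per-imputation probabilities", {
  set.seed(6)
  n <- 40
  z <- matrix(rnorm(2 * n), n, 2)
  rc <- rep(c(FALSE, TRUE), each = n / 2)
  w <- rep(1, n)
  w[rc] <- runif(sum(rc))
  out <- impute_and_estimate_pi(z, rc, w, M = 4, gamma = 0.25, Q = 16)
  expect_true(all(out$pi > 0 & out$pi < 1))
  expect_equal(out$pi, rowMeans(out$pi_components))
  expect_true(all(out$pi >= apply(out$pi_components, 1, min) - 1e-12))
  expect_true(all(out$pi <= apply(out$pi_components, 1, max) + 1e-12))
  # deterministic labels: w = 0 labels every right-censored subject cured
  set.seed(7)
  out0 <- impute_and_estimate_pi(z, rc, ifelse(rc, 0, 1), M = 3,
                                 gamma = 0.25, Q = 16)
  expect_equal(out0$pi_components[, 1], out0$pi_components[, 2])
  # M = 1 with 0/1 weights equals a single deterministic SVM + Platt fit
  v <- ifelse(rc, -1, 1)
  rule <- svm_train(z, v, Q = 16, gamma = 0.25)
  cal <- platt_fit(decision_value(rule, z), v)
  expect_equal(out0$pi_components[, 1],
               platt_probability(cal, decision_value(rule, z)),
               tolerance = 1e-9)
})
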