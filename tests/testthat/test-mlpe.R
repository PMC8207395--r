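test_that("AICc follows its formula and limits", {
  expect_equal(aicc(-10, 3, 10), 30)
  expect_equal(aicc(-10, 3, 1e9), -2 * -10 + 6, tolerance = 1e-6)
  expect_gt(aicc(-10, 4, 20), aicc(-10, 3, 20))
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("profiled likelihood matches the dense multivariate-normal oracle", {
  # 4 individuals, 6 pairs
  pairs <- t(combn(c("a", "b", "c", "d"), 2))
  set.seed(21)
  u <- rnorm(4, 0, 1)
  x <- rnorm(6)
  i <- match(pairs[, 1], c("a", "b", "c", "d"))
  j <- match(pairs[, 2], c("a", "b", "c", "d"))
  y <- 1 + 2 * x + u[i] + u[j] + rnorm(6, 0, 0.5)
  d <- data.frame(y = y, x = x)
  fit <- mlpe(y ~ x, d, pairs, standardize = FALSE)
  X <- cbind(1, x)
  ll_dense <- dense_mlpe_loglik(y, X, fit$coefficients, fit$sigma_u2,
                                fit$sigma_e2, pairs)
  expect_equal(fit$logLik, ll_dense, tolerance = 1e-6)

  # optimizer maximum matches a grid search over theta
  grid <- c(0, exp(seq(log(1e-4), log(1e3), length.out = 600)))
  ll_grid <- vapply(grid, function(th)
    dense_profile_loglik(y, X, th, pairs), numeric(1))
  expect_equal(fit$logLik, max(ll_grid), tolerance = 1e-3)
  expect_gte(fit$logLik, max(ll_grid) - 1e-3)
})

test_that("theta = 0 reduces to ordinary least squares", {
  d <- tiny_design(seed = 12, n_locations = 8)
  sim <- simulated_pairs(d, beta = 1.5, sigma_u = 0, sigma_e = 0.4,
                         seed = 31)
  fit <- mlpe(y ~ x, sim$data, sim$pairs, standardize = FALSE)
  ols <- lm(y ~ x, sim$data)
  expect_lt(abs(fit$theta), 0.05)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 5e-3)
  # likelihood at theta = 0 equals the OLS Gaussian log-likelihood
  X <- cbind(1, sim$data$x)
  ll0 <- dense_profile_loglik(sim$data$y, X, 0, sim$pairs)
  expect_equal(ll0, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("noiseless simulation recovers beta to many digits", {
  d <- tiny_design(seed = 14, n_locations = 8)
  pa <- enumerate_pairs(d, exclude_within_location = FALSE)
  set.seed(8)
  x <- rnorm(nrow(pa))
  y_mat <- simulate_pairwise_distances(
    d, x, list(beta = 3.25, sigma_u = 0, sigma_e = 1e-8), seed = 2)
  pm <- enumerate_pairs(d)
  sel <- match(paste(pm$i, pm$j), paste(pa$i, pa$j))
  dd <- data.frame(y = y_mat[cbind(pm$i, pm$j)], x = x[sel])
  ols <- lm(y ~ x, dd)
  expect_equal(unname(coef(ols)["x"]), 3.25, tolerance = 1e-6)
})

test_that("simulated distance matrices are deterministic, symmetric and calibrated", {
  d <- tiny_design(seed = 3, n_locations = 6, n_per_location = 2)
  pa <- enumerate_pairs(d, exclude_within_location = FALSE)
  x <- rep(0, nrow(pa))
  a <- simulate_pairwise_distances(d, x, list(beta = 0, sigma_u = 0.4,
                                              sigma_e = 0.7), seed = 5)
  b <- simulate_pairwise_distances(d, x, list(beta = 0, sigma_u = 0.4,
                                              sigma_e = 0.7), seed = 5)
  expect_identical(a, b)
  expect_equal(a, t(a))
  expect_true(all(diag(a) == 0))
  expect_true(all(is.finite(a)))
  expect_error(
    simulate_pairwise_distances(d, x[-1], list(beta = 0, sigma_u = 1,
                                               sigma_e = 1)),
    "does not match pair count")

  # Monte-Carlo: marginal var(y) = 2 sigma_u^2 + sigma_e^2 under beta = 0;
  # estimated by mean(y^2) since the mean is 0 and pairs sharing an
  # individual are correlated (which biases the within-matrix sample
  # variance)
  su <- 0.4; se <- 0.7
  vs <- vapply(1:200, function(r) {
    m <- simulate_pairwise_distances(d, x, list(beta = 0, sigma_u = su,
                                                sigma_e = se), seed = r)
    mean(m[lower.tri(m)]^2)
  }, numeric(1))
  expect_lt(abs(mean(vs) - (2 * su^2 + se^2)) / (2 * su^2 + se^2), 0.05)
})

test_that("MLPE recovers beta and rho over replicates", {
  d <- place_sampling_design(c(xmin = 0, xmax = 2e4, ymin = 0, ymax = 2e4),
                             11, 1500, 3, seed = 17)
  pa <- enumerate_pairs(d, exclude_within_location = FALSE)
  pm <- enumerate_pairs(d)
  sel <- match(paste(pm$i, pm$j), paste(pa$i, pa$j))
  # sigma_u chosen so rho = sigma_u^2/(2 sigma_u^2 + sigma_e^2) = 0.3
  se <- 0.6; su <- sqrt(0.3 * se^2 / (1 - 2 * 0.3))
  betas <- numeric(40); rhos <- numeric(40)
  for (r in 1:40) {
    set.seed(100 + r)
    x <- rnorm(nrow(pa))
    y_mat <- simulate_pairwise_distances(
      d, x, list(beta = 1, sigma_u = su, sigma_e = se), seed = 200 + r)
    dd <- data.frame(y = y_mat[cbind(pm$i, pm$j)], x = x[sel])
    fit <- mlpe(y ~ x, dd, cbind(pm$id_i, pm$id_j), standardize = FALSE)
    betas[r] <- fit$coefficients["x"]; rhos[r] <- fit$rho
  }
  expect_lt(abs(mean(betas) - 1), 0.05)
  expect_lt(abs(mean(rhos) - 0.3), 0.05)
})

test_that("fits are invariant to pair-row permutation and y-shift in AICc differences", {
  d <- tiny_design(seed = 19, n_locations = 8)
  sim <- simulated_pairs(d, seed = 44)
  fit <- mlpe(y ~ x, sim$data, sim$pairs)
  p <- sample(nrow(sim$data))
  fit_p <- mlpe(y ~ x, sim$data[p, ], sim$pairs[p, ])
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-6)
  expect_equal(fit_p$logLik, fit$logLik, tolerance = 1e-6)

  # adding a constant to y leaves AICc differences between models intact
  d1 <- sim$data; d1$z <- rnorm(nrow(d1))
  m_small <- mlpe(y ~ x, d1, sim$pairs)
  m_big <- mlpe(y ~ x + z, d1, sim$pairs)
  d2 <- d1; d2$y <- d2$y + 100
  m_small2 <- mlpe(y ~ x, d2, sim$pairs)
  m_big2 <- mlpe(y ~ x + z, d2, sim$pairs)
  expect_equal(m_big$aicc - m_small$aicc, m_big2$aicc - m_small2$aicc,
               tolerance = 1e-6)
})

test_that("mlpe validates its inputs and exposes standard methods", {
  d <- tiny_design(seed = 23, n_locations = 6)
  sim <- simulated_pairs(d, seed = 3)
  dd <- sim$data
  dd$x2 <- dd$x                                    # rank-deficient
  expect_error(mlpe(y ~ x + x2, dd, sim$pairs), "rank-deficient")
  expect_error(mlpe(y ~ x, dd, sim$pairs[-1, ]), "one row per")
  dd$cst <- 1.5
  expect_error(mlpe(y ~ x + cst, dd, sim$pairs), "constant predictor")

  fit <- mlpe(y ~ x, sim$data, sim$pairs)
  expect_s3_class(fit, "mlpe")
  expect_equal(nobs(fit), nrow(sim$data))
  expect_equal(AIC(fit), -2 * fit$logLik + 2 * fit$k)
  expect_equal(AICc(fit), aicc(fit$logLik, fit$k, fit$n))
  expect_true(fit$rho >= 0 && fit$rho <= 0.5)
  expect_length(predict(fit), fit$n)
  expect_equal(predict(fit, sim$data), unname(fitted(fit)))
  expect_equal(fitted(fit) + residuals(fit), sim$data$y,
               ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3))
  expect_output(print(fit), "MLPE")
  expect_output(print(summary(fit)), "Random effects")
  expect_equal(dim(vcov(fit)), c(2, 2))
})
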