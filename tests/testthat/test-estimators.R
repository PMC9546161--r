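test_that("trait standardization modes apply the documented transforms", {
  d <- data.frame(z = c(1, 2, 3), fitness = c(1, 1, 2))
  none <- standardize_traits(d, mode = "none")
  expect_equal(none$z, d$z)
  expect_equal(trait_standardization(none)$scale, 1)
  uv <- standardize_traits(d, mode = "unit_variance")
  expect_equal(uv$z, c(-1, 0, 1))            # sample SD of (1,2,3) is 1
  expect_equal(trait_standardization(uv)$center, 2)
  expect_equal(trait_standardization(uv)$scale, sd(c(1, 2, 3)))
  ms <- standardize_traits(data.frame(z = c(2, 4), fitness = c(1, 1)),
                           mode = "mean_standardize")
  expect_equal(ms$z, c(2 / 3, 4 / 3))
  expect_equal(trait_standardization(ms)$scale, 3)
  expect_error(
    standardize_traits(data.frame(z = c(1, 1), fitness = c(1, 1)),
                       mode = "unit_variance"),
    class = "selgrad_error_degenerate_trait"
  )
  expect_error(
    standardize_traits(data.frame(z = c(-1, 1), fitness = c(1, 1)),
                       mode = "mean_standardize"),
    class = "selgrad_error_degenerate_trait"
  )
})

test_that("design matrix uses halved squares and unhalved cross products", {
  X1 <- build_design_matrix(matrix(c(1, 2), ncol = 1))
  expect_equal(unname(X1), matrix(c(1, 1, 1, 2, 0.5, 2), 2))
  X2 <- build_design_matrix(matrix(c(2, 3), nrow = 1,
                                   dimnames = list(NULL, c("u", "v"))))
  expect_equal(unname(drop(X2)), c(1, 2, 3, 2, 4.5, 6))
  expect_equal(colnames(X2),
               c("(Intercept)", "u", "v", "I(u^2/2)", "I(v^2/2)", "u:v"))
  Xl <- build_design_matrix(matrix(c(1, 2), ncol = 1),
                            include_quadratic = FALSE)
  expect_equal(ncol(Xl), 2L)
})

test_that("log-link GLM recovers generating coefficients at large n", {
  d <- toy_poisson_table(n = 20000, b = 0.3, g = -0.2, seed = 42)
  fit <- fit_log_quadratic_glm(d)
  td <- tidy(fit)
  expect_true(fit$converged)
  expect_lt(abs(td$estimate[td$term == "b_z1"] - 0.3),
            3 * td$std_error[td$term == "b_z1"])
  expect_lt(abs(td$estimate[td$term == "g_z1"] - (-0.2)),
            3 * td$std_error[td$term == "g_z1"])
})

test_that("halved and unhalved quadratic covariates give the same model", {
  d <- toy_poisson_table(n = 500, seed = 5)
  fit <- fit_log_quadratic_glm(d)
  # refit with an unhalved squared covariate by hand
  raw <- stats::glm(d$fitness ~ d$z1 + I(d$z1^2), family = stats::poisson())
  expect_equal(unname(coef(raw)[3]) * 2, fit$coef$g[1, 1], tolerance = 1e-8)
  # covariance conversion reconciles the two conventions
  vc_raw <- vcov(raw)[-1, -1]
  cc_conv <- convert_unhalved_covariance(
    coefficient_covariance(vc_raw, k = 1))
  expect_equal(unname(cc_conv$cov), unname(fit$sampling_cov$cov),
               tolerance = 1e-8)
})

test_that("GLM front end validates its inputs", {
  expect_error(
    fit_log_quadratic_glm(data.frame(z = 1:5, fitness = c(1, 2, -1, 0, 1))),
    class = "selgrad_error_negative_fitness"
  )
  expect_error(
    fit_log_quadratic_glm(data.frame(z = 1:5, fitness = c(1, 2.5, 1, 0, 1))),
    class = "selgrad_error_non_count_fitness"
  )
  expect_error(
    fit_log_quadratic_glm(data.frame(z = c(1, 2), fitness = c(1, 2))),
    class = "selgrad_error_too_few_rows"
  )
  expect_error(
    fit_log_quadratic_glm(data.frame(z = rep(1, 20),
                                     fitness = rpois(20, 1))),
    class = "selgrad_error_rank_deficient"
  )
})

test_that("negative-binomial family fits overdispersed counts", {
  sc <- selection_scenario(b = 0.3, g = -0.2, n = 4000, seed = 17,
                           family = "negative_binomial", size = 2)
  d <- simulate_dataset(sc, 1)
  fit <- fit_log_quadratic_glm(d, family = "negative_binomial")
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "b_z1"] - 0.3),
            4 * td$std_error[td$term == "b_z1"])
  gr <- gradients_from_fit(fit, standardized_phenotype(1))
  expect_true(is.finite(tidy(gr)$se[1]))
})

test_that("gradients_from_fit closes the loop with the univariate formulas", {
  d <- toy_poisson_table(n = 2000, seed = 23)
  dstd <- standardize_traits(d, mode = "unit_variance")
  fit <- fit_log_quadratic_glm(dstd)
  gr <- gradients_from_fit(fit, standardized_phenotype(1))
  b <- fit$coef$b[1]; g <- fit$coef$g[1, 1]
  td <- tidy(gr)
  expect_equal(td$estimate[td$gradient == "beta"], b / (1 - g),
               tolerance = 1e-10, ignore_attr = TRUE)
  cc <- fit$sampling_cov
  expect_equal(td$se[td$gradient == "beta"]^2,
               var_beta_univariate(b, g, cc), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(td$se[td$gradient == "gamma"]^2,
               var_gamma_univariate(b, g, cc), tolerance = 1e-6,
               ignore_attr = TRUE)
  # standardization record survives into the result
  expect_equal(gr$standardization$scale, sd(d$z1))
})

test_that("linear-only fit returns beta = b with the GLM standard error", {
  d <- toy_poisson_table(n = 1000, g = 0, seed = 31)
  fit <- fit_log_quadratic_glm(d, include_quadratic = FALSE)
  gr <- gradients_from_fit(fit)
  td <- tidy(gr)
  tf <- tidy(fit)
  expect_equal(td$estimate[td$gradient == "beta"],
               tf$estimate[tf$term == "b_z1"], ignore_attr = TRUE)
  expect_equal(td$se[td$gradient == "beta"],
               tf$std_error[tf$term == "b_z1"],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Lande-Arnold OLS solves the worked three-point example exactly", {
  # 3 points, 3 parameters: an exact fit, so lm warns about its SEs
  o <- suppressWarnings(
    ols_lande_arnold(data.frame(z = c(-1, 0, 1), fitness = c(1, 2, 3))))
  expect_equal(unname(o$beta_hat), 0.5, tolerance = 1e-12)
  expect_equal(o$gamma_hat[1, 1], 0, tolerance = 1e-12)
  expect_equal(o$relative_fitness_mean, 1)
  # constant fitness: flat relative-fitness surface (another exact fit)
  oc <- suppressWarnings(
    ols_lande_arnold(data.frame(z = rnorm(30, sd = 1),
                                fitness = rep(3, 30))))
  expect_equal(unname(oc$beta_hat), 0, tolerance = 1e-12)
  expect_equal(oc$gamma_hat[1, 1], 0, tolerance = 1e-12)
  expect_error(
    ols_lande_arnold(data.frame(z = rnorm(10), fitness = rep(0, 10))),
    class = "selgrad_error_zero_mean_fitness"
  )
})

test_that("OLS and GLM beta agree under log-linear truth", {
  d <- toy_poisson_table(n = 20000, b = 0.2, g = 0, seed = 77)
  o <- ols_lande_arnold(d)
  fit <- fit_log_quadratic_glm(d)
  gr <- gradients_from_fit(fit)
  glm_beta <- tidy(gr)$estimate[1]
  glm_se <- tidy(gr)$se[1]
  expect_lt(abs(o$beta_hat[1] - 0.2), 3 * o$se_beta[1])
  expect_lt(abs(o$beta_hat[1] - glm_beta),
            3 * sqrt(o$se_beta[1]^2 + glm_se^2))
})

test_that("two-step OLS takes beta from the linear-only regression", {
  d <- toy_poisson_table(n = 300, seed = 41)
  o2 <- ols_lande_arnold(d, two_step = TRUE)
  w <- d$fitness / mean(d$fitness)
  ref <- lm(w ~ d$z1)
  expect_equal(unname(o2$beta_hat), unname(coef(ref)[2]), tolerance = 1e-12)
})

test_that("case bootstrap is deterministic and degenerates sensibly", {
  d <- toy_poisson_table(n = 120, seed = 3)
  b1 <- bootstrap_se(d, estimator = "ols", b_reps = 60, seed = 9)
  b2 <- bootstrap_se(d, estimator = "ols", b_reps = 60, seed = 9)
  expect_identical(b1$se, b2$se)
  expect_identical(attr(b1, "n_failed"), 0L)
  # constant fitness: every resample gives the zero-gradient fit
  dc <- data.frame(z = rnorm(50), fitness = rep(2, 50))
  bc <- suppressWarnings(
    bootstrap_se(dc, traits = "z", estimator = "ols", b_reps = 30, seed = 1))
  expect_equal(max(bc$se), 0, tolerance = 1e-12)
  expect_error(bootstrap_se(d, estimator = "ols", b_reps = 1, seed = 1),
               class = "selgrad_error_config")
})

test_that("bootstrap SE approximates the sampling SD of the OLS estimator", {
  # 60 independent datasets vs a 100-resample bootstrap on one of them;
  # the full-scale version of this check lives in the simulation study
  sc <- selection_scenario(b = 0.2, g = 0, n = 200, seed = 14)
  beta_hats <- vapply(1:60, function(r) {
    unname(ols_lande_arnold(simulate_dataset(sc, r))$beta_hat)
  }, numeric(1))
  bs <- bootstrap_se(simulate_dataset(sc, 1), estimator = "ols",
                     b_reps = 100, seed = 2)
  expect_lt(abs(bs$se[1] - sd(beta_hats)) / sd(beta_hats), 0.4)
})

test_that("GLM-route bootstrap refits gradients within each resample", {
  d <- toy_poisson_table(n = 150, seed = 19)
  bg <- bootstrap_se(d, estimator = "glm", b_reps = 40, seed = 4)
  expect_equal(bg$gradient, c("beta", "gamma"))
  expect_true(all(bg$se > 0))
  fit <- gradients_from_fit(fit_log_quadratic_glm(d))
  delta_se <- tidy(fit)$se
  # bootstrap and delta SEs agree in order of magnitude
  expect_lt(max(abs(log(bg$se / delta_se))), log(2.5))
})

test_that("numerical averaging reduces to b under log-linear fitness", {
  set.seed(6)
  d <- data.frame(z1 = rnorm(500, 1, 2))
  co <- log_quadratic_coef(a = 0.4, b = 0.37, g = 0)
  na <- numerical_average_gradients(d, coef = co)
  expect_equal(unname(na$beta), 0.37, tolerance = 1e-14)
  # gamma is exactly symmetric for any finite sample
  co2 <- log_quadratic_coef(b = c(0.2, -0.1),
                            g = matrix(c(-0.3, 0.1, 0.1, -0.2), 2))
  set.seed(7)
  d2 <- data.frame(z1 = rnorm(200), z2 = rnorm(200))
  na2 <- numerical_average_gradients(d2, coef = co2)
  expect_identical(na2$gamma, t(na2$gamma))
})

test_that("numerical averaging converges to the closed forms at large n", {
  sc <- selection_scenario(b = 0.2, g = 0.4, n = 1e5, seed = 8)
  d <- simulate_dataset(sc, 1)
  na <- numerical_average_gradients(d, coef = sc$coef)
  fit <- fit_log_quadratic_glm(d)
  gr <- gradients_from_fit(fit, standardized_phenotype(1))
  td <- tidy(gr)
  # GLM estimate and the model-free average of the true function agree
  expect_lt(abs(td$estimate[1] - na$beta[1]), 3 * td$se[1] + 0.02)
  expect_lt(abs(td$estimate[2] - na$gamma[1, 1]), 3 * td$se[2] + 0.04)
  expect_lt(abs(na$beta[1] - compute_beta(sc$coef)[1]), 0.03)
})
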