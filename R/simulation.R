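#' Define a simulation scenario
#'
#' A scenario bundles everything needed to simulate individual-level
#' trait-fitness data under the generating model: multivariate normal
#' phenotypes \eqn{z \sim N(\mu, \Sigma)} and fitness drawn from `family`
#' with log-scale expectation \eqn{a + b'z + \frac{1}{2} z' g z}. Defaults
#' mirror the estimator-performance study design: a modest sample of 200
#' individuals, Poisson fitness, a standard-normal phenotype and a zero log
#' intercept.
#'
#' @param b Log-scale linear coefficient(s).
#' @param g Log-scale quadratic coefficient(s) (scalar or symmetric matrix).
#' @param n Sample size per simulated dataset.
#' @param a Log-scale intercept.
#' @param family Fitness distribution: `"poisson"` or
#'   `"negative_binomial"`.
#' @param pheno A [phenotype_distribution()]; default standardized.
#' @param reps Replicate datasets per scenario when run through
#'   [run_study()].
#' @param boot_reps Bootstrap resamples per replicate (0 disables the
#'   bootstrap column of the study).
#' @param seed Master integer seed; replicate streams are derived
#'   deterministically from `(seed, scenario_index, replicate_index)`, so
#'   scenarios are independent and reordering them does not change any
#'   dataset.
#' @param size Negative-binomial size (dispersion) parameter when
#'   `family = "negative_binomial"`.
#' @param scenario_index Integer tag used in stream derivation; assigned
#'   automatically by [scenario_grid()].
#' @return An object of class `sel_scenario`. Construction fails
#'   (`selgrad_error_omega_not_pd`) if the post-selection covariance is not
#'   positive definite, i.e. if the fitness function curves upward too
#'   sharply for mean fitness to exist.
#' @examples
#' selection_scenario(b = 0.3, g = 0.4)
#' @export
selection_scenario <- function(b, g = 0, n = 200, a = 0,
                               family = c("poisson", "negative_binomial"),
                               pheno = standardized_phenotype(length(b)),
                               reps = 300, boot_reps = 200, seed = 1,
                               size = 1, scenario_index = 1L) {
  family <- match.arg(family)
  coef <- log_quadratic_coef(a, b, g, trait_names = pheno$trait_names)
  check_omega_condition(coef, pheno)
  stopifnot(n >= 1, reps >= 1, boot_reps >= 0)
  structure(
    list(coef = coef, pheno = pheno, n = as.integer(n), family = family,
         reps = as.integer(reps), boot_reps = as.integer(boot_reps),
         seed = as.integer(seed), size = size,
         scenario_index = as.integer(scenario_index)),
    class = "sel_scenario"
  )
}

#' @export
print.sel_scenario <- function(x, ...) {
  cat("<simulation scenario> n =", x$n, "| family:", x$family,
      "| reps:", x$reps, "\n")
  print(x$coef)
  invisible(x)
}

#' Simulate one trait-fitness dataset from a scenario
#'
#' Draws phenotypes from the scenario's multivariate normal distribution and
#' fitness from the scenario's family with log-scale expectation
#' \eqn{a + b'z + \frac{1}{2} z' g z}. The random stream is fully determined
#' by `(seed, scenario_index, replicate_index)`, so the same pair of indices
#' always yields the identical table, independently of the caller's RNG
#' state.
#'
#' @param scenario A [selection_scenario()].
#' @param replicate_index Positive integer selecting the replicate stream.
#' @return A tibble with the trait columns and a `fitness` column.
#' @examples
#' simulate_dataset(selection_scenario(b = 0.3, g = 0.4, n = 5), 1)
#' @export
simulate_dataset <- function(scenario, replicate_index = 1L) {
  stopifnot(inherits(scenario, "sel_scenario"))
  s <- derive_seed(scenario$seed, scenario$scenario_index, replicate_index)
  with_seed(s, {
    k <- scenario$coef$k
    n <- scenario$n
    if (k == 1L) {
      z <- matrix(rnorm(n, scenario$pheno$mu, sqrt(scenario$pheno$sigma[1, 1])),
                  ncol = 1)
    } else {
      z <- MASS::mvrnorm(n, scenario$pheno$mu, scenario$pheno$sigma)
    }
    colnames(z) <- scenario$pheno$trait_names
    lambda <- exp(log_fitness(scenario$coef, z))
    w <- switch(scenario$family,
                poisson = rpois(n, lambda),
                negative_binomial = rnbinom(n, size = scenario$size,
                                            mu = lambda))
    out <- as_tibble(as.data.frame(z))
    out$fitness <- as.numeric(w)
    out
  })
}

#' Default univariate scenario grid
#'
#' The crossed grid used by the estimator-performance study: directional
#' coefficients `b` from -0.5 to 0.5 (step 0.1, a configurable choice) by
#' curvature `g` in {-1, 0, 0.4}, each with n = 200 individuals, Poisson
#' fitness, zero log intercept and a standard-normal phenotype.
#'
#' @param b,g Numeric vectors of coefficient values to cross.
#' @param n Sample size per dataset.
#' @param reps Replicates per scenario.
#' @param boot_reps Bootstrap resamples per replicate (0 disables).
#' @param seed Master seed.
#' @return A list of [selection_scenario()] objects (length
#'   `length(b) * length(g)`), with `scenario_index` assigned in grid
#'   order.
#' @examples
#' length(scenario_grid())  # 33
#' @export
scenario_grid <- function(b = seq(-0.5, 0.5, by = 0.1),
                          g = c(-1, 0, 0.4),
                          n = 200, reps = 300, boot_reps = 200, seed = 1) {
  grid <- expand.grid(b = b, g = g, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    selection_scenario(b = grid$b[i], g = grid$g[i], n = n, reps = reps,
                       boot_reps = boot_reps, seed = seed,
                       scenario_index = i)
  })
}

# Fit one replicate with both estimators; returns a named numeric vector of
# the per-replicate quantities, or the failure reason.
study_one_replicate <- function(scenario, r) {
  d <- simulate_dataset(scenario, r)
  tn <- scenario$pheno$trait_names
  ols <- ols_lande_arnold(d, traits = tn, fitness = "fitness")
  out <- c(
    ols_beta = unname(ols$beta_hat[1]),
    ols_gamma = unname(pack_sym(ols$gamma_hat)[1]),
    ols_se_beta = unname(ols$se_beta[1]),
    ols_se_gamma = unname(ols$se_gamma[1])
  )
  if (scenario$boot_reps > 0) {
    bs <- bootstrap_se(d, traits = tn, fitness = "fitness",
                       estimator = "ols", b_reps = scenario$boot_reps,
                       seed = derive_seed(scenario$seed,
                                          scenario$scenario_index, r))
    out <- c(out,
             ols_boot_se_beta = unname(bs$se[bs$gradient == "beta"][1]),
             ols_boot_se_gamma = unname(bs$se[bs$gradient == "gamma"][1]))
  }
  fit <- fit_log_quadratic_glm(d, traits = tn, fitness = "fitness",
                               family = scenario$family)
  if (!fit$converged) {
    abort("GLM did not converge", class = "selgrad_error_nonconvergence")
  }
  # the generating phenotype distribution is known in a simulation study, so
  # gradients are evaluated at the true mu, Sigma (conditional estimates)
  gr <- gradients_from_fit(fit, pheno = scenario$pheno)
  td <- tidy(gr)
  c(out,
    glm_beta = unname(td$estimate[td$gradient == "beta"][1]),
    glm_gamma = unname(td$estimate[td$gradient == "gamma"][1]),
    glm_se_beta = unname(td$se[td$gradient == "beta"][1]),
    glm_se_gamma = unname(td$se[td$gradient == "gamma"][1]))
}

#' Run the estimator-performance study
#'
#' For every scenario, simulates `reps` datasets and fits both the
#' Lande-Arnold OLS estimator (analytic standard errors, plus case-bootstrap
#' standard errors when `boot_reps > 0`) and the log-link Poisson GLM
#' estimator with delta-method standard errors. Summarizes, per scenario,
#' estimator and gradient: mean estimate, bias, empirical SD across
#' replicates, mean of each standard-error type, mean squared error, and
#' Monte Carlo standard errors of the bias. Replicates where the GLM fails
#' to converge or the estimated curvature violates the validity condition
#' are dropped from the summaries and counted.
#'
#' Currently summarizes univariate scenarios (the study design); the fitting
#' machinery itself is fully multivariate.
#'
#' @param scenarios A list of [selection_scenario()]s, e.g. from
#'   [scenario_grid()], or a single scenario.
#' @param progress Print per-scenario progress to stderr?
#' @return A tibble of class `sel_study`, one row per scenario x estimator x
#'   gradient, with columns `scenario`, `b`, `g`, `n`, `truth`, `estimator`,
#'   `gradient`, `mean_estimate`, `bias`, `mc_se_bias`, `empirical_sd`,
#'   `mean_analytic_se`, `mean_boot_se`, `mean_delta_se`, `mse`,
#'   `mse_diff_vs_ols` and `mse_diff_mc_se` (paired GLM-minus-OLS MSE
#'   difference and its Monte Carlo standard error, on the GLM rows),
#'   `n_ok`, `n_failed`. Plot with [ggplot2::autoplot()].
#' @export
run_study <- function(scenarios, progress = FALSE) {
  if (inherits(scenarios, "sel_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1)
  rows <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    if (progress) {
      message(sprintf("scenario %d/%d (b = %.2f, g = %.2f)",
                      i, length(scenarios), sc$coef$b[1], sc$coef$g[1, 1]))
    }
    res <- lapply(seq_len(sc$reps), function(r) {
      tryCatch(study_one_replicate(sc, r), error = function(e) NULL)
    })
    ok <- !vapply(res, is.null, logical(1))
    mat <- do.call(rbind, res[ok])
    truth_beta <- unname(compute_beta(sc$coef, sc$pheno)[1])
    truth_gamma <- compute_gamma(sc$coef, sc$pheno)[1, 1]
    summarize_grad <- function(est_col, se_col, boot_col, delta_col, truth,
                               estimator, gradient) {
      est <- mat[, est_col]
      n_ok <- sum(ok)
      # paired MSE difference (GLM - OLS) and its MC standard error
      other <- sub("^glm", "ols", est_col)
      mse_diff <- mse_diff_se <- NA_real_
      if (estimator == "glm" && other %in% colnames(mat)) {
        dvec <- (mat[, est_col] - truth)^2 - (mat[, other] - truth)^2
        mse_diff <- mean(dvec)
        if (n_ok > 1) mse_diff_se <- sd(dvec) / sqrt(n_ok)
      }
      tibble(
        scenario = sc$scenario_index,
        b = sc$coef$b[1], g = sc$coef$g[1, 1], n = sc$n,
        estimator = estimator, gradient = gradient, truth = truth,
        mean_estimate = mean(est),
        bias = mean(est) - truth,
        mc_se_bias = if (n_ok > 1) sd(est) / sqrt(n_ok) else NA_real_,
        empirical_sd = if (n_ok > 1) sd(est) else NA_real_,
        mean_analytic_se = if (!is.na(se_col)) mean(mat[, se_col]) else NA_real_,
        mean_boot_se = if (!is.na(boot_col) && boot_col %in% colnames(mat))
          mean(mat[, boot_col]) else NA_real_,
        mean_delta_se = if (!is.na(delta_col)) mean(mat[, delta_col]) else NA_real_,
        mse = mean((est - truth)^2),
        mse_diff_vs_ols = mse_diff,
        mse_diff_mc_se = mse_diff_se,
        n_ok = n_ok, n_failed = sum(!ok)
      )
    }
    rows[[i]] <- dplyr::bind_rows(
      summarize_grad("ols_beta", "ols_se_beta", "ols_boot_se_beta", NA,
                     truth_beta, "ols", "beta"),
      summarize_grad("ols_gamma", "ols_se_gamma", "ols_boot_se_gamma", NA,
                     truth_gamma, "ols", "gamma"),
      summarize_grad("glm_beta", NA, NA, "glm_se_beta",
                     truth_beta, "glm", "beta"),
      summarize_grad("glm_gamma", NA, NA, "glm_se_gamma",
                     truth_gamma, "glm", "gamma")
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sel_study", class(out))
  out
}

#' @rdname run_study
#' @param x A `sel_study` result.
#' @param ... Unused.
#' @method glance sel_study
#' @export
glance.sel_study <- function(x, ...) {
  tibble(
    n_scenarios = dplyr::n_distinct(x$scenario),
    reps_min = min(x$n_ok + x$n_failed),
    total_failures = sum(x$n_failed[!duplicated(x$scenario)]),
    max_abs_bias = max(abs(x$bias))
  )
}

#' Plot an estimator-performance study
#'
#' Bias, standard-error calibration and mean-squared-error panels against
#' the generating `b`, faceted by metric and curvature `g`, with estimators
#' (OLS, GLM) distinguished by colour. In the SE panel, solid lines are the
#' empirical SD of the estimates and dashed lines the mean reported SE; the
#' two coincide when standard errors are well calibrated.
#'
#' @param object A `sel_study` from [run_study()].
#' @param gradient Which gradient to display (`"beta"` or `"gamma"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sel_study
#' @export
autoplot.sel_study <- function(object, gradient = c("beta", "gamma"), ...) {
  gradient <- match.arg(gradient)
  d <- dplyr::filter(object, .data$gradient == !!gradient)
  base <- dplyr::transmute(
    d, b = .data$b, g = paste0("g = ", .data$g),
    estimator = .data$estimator, bias = .data$bias, mse = .data$mse,
    empirical_sd = .data$empirical_sd,
    reported_se = dplyr::coalesce(.data$mean_delta_se, .data$mean_analytic_se)
  )
  long <- tidyr::pivot_longer(
    base, c("bias", "empirical_sd", "reported_se", "mse"),
    names_to = "metric", values_to = "value"
  )
  long$panel <- dplyr::recode(long$metric,
                              bias = "bias",
                              empirical_sd = "standard errors",
                              reported_se = "standard errors",
                              mse = "MSE")
  long$panel <- factor(long$panel, levels = c("bias", "standard errors", "MSE"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$b, y = .data$value,
                                     colour = .data$estimator,
                                     linetype = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(panel ~ g, scales = "free_y") +
    ggplot2::scale_linetype_manual(
      values = c(bias = "solid", empirical_sd = "solid",
                 reported_se = "dashed", mse = "solid"),
      guide = "none"
    ) +
    ggplot2::labs(y = NULL, x = "b (log-scale directional coefficient)",
                  colour = "estimator",
                  title = paste("Estimator performance:", gradient)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a univariate fitness function
#'
#' The fitted (or theoretical) fitness function
#' \eqn{W(z) = \exp(a + bz + \frac{1}{2} g z^2)} over a range of phenotype,
#' with the phenotype density overlaid for context.
#'
#' @param coef A [log_quadratic_coef()] with k = 1.
#' @param pheno A [phenotype_distribution()] with k = 1.
#' @param from,to Plot range; defaults to 3 SDs around the mean.
#' @return A ggplot object.
#' @export
plot_fitness_function <- function(coef, pheno = standardized_phenotype(1),
                                  from = NULL, to = NULL) {
  stopifnot(coef$k == 1L, pheno$k == 1L)
  s <- sqrt(pheno$sigma[1, 1])
  from <- from %||% (pheno$mu[1] - 3 * s)
  to <- to %||% (pheno$mu[1] + 3 * s)
  z <- seq(from, to, length.out = 200)
  d <- tibble(
    z = z,
    fitness = exp(log_fitness(coef, matrix(z, ncol = 1))),
    density = stats::dnorm(z, pheno$mu[1], s)
  )
  d$density <- d$density / max(d$density) * max(d$fitness)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$density), alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitness)) +
    ggplot2::labs(x = "phenotype z", y = "expected fitness W(z)",
                  caption = "shaded: phenotype density (rescaled)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
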