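# Independent Monte-Carlo oracle for the gradient conversions: average the
# analytic slope (b + gz) and curvature (g + (b+gz)(b+gz)') of
# W(z) = exp(a + b'z + z'gz/2) over draws z ~ N(mu, Sigma), weighting by
# W(z). Returns the ratio estimates plus Monte-Carlo standard errors of each
# component (delta-method SE for a ratio of means).
mc_gradients_oracle <- function(coef, pheno, n_draws = 1e6, seed = 1) {
  set.seed(seed)
  k <- coef$k
  if (k == 1L) {
    z <- matrix(rnorm(n_draws, pheno$mu, sqrt(pheno$sigma[1, 1])), ncol = 1)
  } else {
    z <- MASS::mvrnorm(n_draws, pheno$mu, pheno$sigma)
  }
  fz <- coef$a + z %*% coef$b + 0.5 * rowSums((z %*% coef$g) * z)
  w <- exp(drop(fz) - max(fz))                    # scale cancels in ratios
  wbar <- mean(w)
  slope <- matrix(coef$b, n_draws, k, byrow = TRUE) + z %*% coef$g
  ratio_est <- function(t) {
    est <- mean(t * w) / wbar
    se <- sd(t * w - est * w) / (wbar * sqrt(n_draws))
    c(est = est, se = se)
  }
  beta <- vapply(seq_len(k), function(i) ratio_est(slope[, i]), numeric(2))
  gamma_est <- matrix(0, k, k)
  gamma_se <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      r <- ratio_est(coef$g[i, j] + slope[, i] * slope[, j])
      gamma_est[i, j] <- gamma_est[j, i] <- r["est"]
      gamma_se[i, j] <- gamma_se[j, i] <- r["se"]
    }
  }
  list(beta = beta["est", ], beta_se = beta["se", ],
       gamma = gamma_est, gamma_se = gamma_se)
}

# Random valid univariate coefficients/phenotype. |g| sigma^2 <= 0.8 keeps
# the post-selection covariance comfortably positive definite; on the
# positive-curvature side g sigma^2 is capped at 0.45 so that the
# Monte-Carlo oracle's importance weights e^f have finite variance
# (requires Sigma^-1 - 2g positive definite), making its standard errors
# trustworthy.
random_univariate_instance <- function(seed) {
  set.seed(seed)
  sigma2 <- runif(1, 0.5, 2)
  g <- runif(1, -0.8, 0.45) / sigma2
  list(
    coef = log_quadratic_coef(a = runif(1, -1, 1), b = runif(1, -0.5, 0.5),
                              g = g),
    pheno = phenotype_distribution(runif(1, -1, 1), sigma2)
  )
}

# Random k-trait instance with Omega valid: g scaled so that the spectral
# radius of g Sigma stays below `radius`.
random_multivariate_instance <- function(seed, k = 2, radius = 0.8) {
  set.seed(seed)
  A <- matrix(rnorm(k * k), k)
  sigma <- crossprod(A) / k + diag(0.5, k)
  G <- matrix(rnorm(k * k, sd = 0.5), k)
  g <- (G + t(G)) / 2
  ev <- Re(eigen(g %*% sigma, only.values = TRUE)$values)
  # overall spectral radius <= radius (Omega valid with margin); positive
  # eigenvalues <= 0.45 so the MC oracle's weight variance is finite
  scl <- min(1, radius / max(abs(ev)),
             if (any(ev > 0)) 0.45 / max(ev) else 1)
  g <- g * scl
  list(
    coef = log_quadratic_coef(a = rnorm(1), b = rnorm(k, sd = 0.3), g = g),
    pheno = phenotype_distribution(rnorm(k, sd = 0.5), sigma)
  )
}

# Random negative-definite g (for Gaussian-equivalence checks).
random_negdef_g <- function(seed, k) {
  set.seed(seed)
  A <- matrix(rnorm(k * k), k)
  -(crossprod(A) / k + diag(0.2, k))
}

# Monte-Carlo propagation of coefficient (co)variances: sample (b, g)
# jointly normal around the point estimate, convert each draw, and take the
# empirical covariance of the gradients. Independent check of the
# delta-method propagation.
mc_propagation_oracle <- function(coef, pheno, cc, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  k <- coef$k
  x0 <- c(coef$b, selgrad:::pack_sym(coef$g))
  draws <- MASS::mvrnorm(n_draws, x0, cc$cov)
  vals <- apply(draws, 1, function(x) {
    b <- x[seq_len(k)]
    g <- selgrad:::unpack_sym(x[-seq_len(k)], k)
    co <- log_quadratic_coef(0, b, g)
    tryCatch(
      c(compute_beta(co, pheno), selgrad:::pack_sym(compute_gamma(co, pheno))),
      error = function(e) rep(NA_real_, k + k * (k + 1) / 2)
    )
  })
  vals <- t(vals)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  stats::var(vals)
}

# Small deterministic Poisson trait-fitness table for smoke tests.
toy_poisson_table <- function(n = 200, b = 0.3, g = -0.2, seed = 7) {
  simulate_dataset(selection_scenario(b = b, g = g, n = n, seed = seed), 1)
}
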