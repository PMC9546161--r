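#' @importFrom stats glm poisson binomial lm as.formula model.matrix
#' @importFrom dplyr %>%
NULL

# Resolve trait / fitness column specifications against a data frame and
# return clean numeric matrices; rows with any missing value are dropped
# with a message (count reported).
resolve_table <- function(data, traits = NULL, fitness = "fitness",
                          call = rlang::caller_env()) {
  data <- as.data.frame(data)
  if (!fitness %in% names(data)) {
    abort(sprintf("Fitness column `%s` not found.", fitness),
          class = "selgrad_error_missing_column", call = call)
  }
  if (is.null(traits)) {
    traits <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      fitness)
  }
  missing_cols <- setdiff(traits, names(data))
  if (length(missing_cols)) {
    abort(paste0("Trait column(s) not found: ",
                 paste(missing_cols, collapse = ", ")),
          class = "selgrad_error_missing_column", call = call)
  }
  w <- data[[fitness]]
  if (!is.numeric(w)) {
    w <- suppressWarnings(as.numeric(as.character(w)))
    if (anyNA(w) && !anyNA(data[[fitness]])) {
      abort("Fitness column is not numeric.",
            class = "selgrad_error_non_numeric_fitness", call = call)
    }
  }
  z <- as.matrix(data[traits])
  storage.mode(z) <- "double"
  keep <- stats::complete.cases(z, w)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("Dropped %d row(s) with missing trait or fitness values.",
                    n_drop))
    z <- z[keep, , drop = FALSE]
    w <- w[keep]
  }
  if (nrow(z) == 0L) {
    abort("No complete rows in the input.",
          class = "selgrad_error_empty_table", call = call)
  }
  if (any(w < 0)) {
    abort("Fitness must be non-negative.",
          class = "selgrad_error_negative_fitness", call = call)
  }
  list(z = z, w = w, traits = traits, fitness = fitness, n_dropped = n_drop)
}

#' Standardize trait columns
#'
#' Applies one of the conventional standardizations to the trait columns of
#' an individual-level trait-fitness table, recording the centering and
#' scaling constants so downstream gradients can be interpreted (and
#' back-transformed) on the fitted scale.
#'
#' * `"none"`: identity (center 0, scale 1).
#' * `"center"`: subtract the sample mean.
#' * `"unit_variance"`: subtract the sample mean and divide by the sample
#'   standard deviation (n - 1 denominator); gradients are then
#'   variance-standardized.
#' * `"mean_standardize"`: divide by the sample mean (no centering);
#'   gradients are then mean-standardized. Requires nonzero trait means.
#'
#' @param data A data frame, one row per individual.
#' @param traits Character vector of trait column names; default: all numeric
#'   columns except `fitness`.
#' @param fitness Name of the fitness column (left untouched).
#' @param mode One of `"none"`, `"center"`, `"unit_variance"`,
#'   `"mean_standardize"`.
#' @return A tibble with the trait columns transformed, carrying attributes
#'   `center` and `scale` (named vectors); retrieve them with
#'   [trait_standardization()].
#' @examples
#' d <- data.frame(z = c(1, 2, 3), fitness = c(1, 2, 3))
#' standardize_traits(d, mode = "unit_variance")
#' @export
standardize_traits <- function(data, traits = NULL, fitness = "fitness",
                               mode = c("none", "center", "unit_variance",
                                        "mean_standardize")) {
  mode <- match.arg(mode)
  tb <- resolve_table(data, traits, fitness)
  k <- ncol(tb$z)
  center <- setNames(rep(0, k), tb$traits)
  scale <- setNames(rep(1, k), tb$traits)
  if (mode %in% c("center", "unit_variance")) {
    center[] <- colMeans(tb$z)
  }
  if (mode == "unit_variance") {
    scale[] <- apply(tb$z, 2, sd)
    if (any(scale <= 0)) {
      abort("Cannot variance-standardize a trait with zero variance.",
            class = "selgrad_error_degenerate_trait")
    }
  }
  if (mode == "mean_standardize") {
    scale[] <- colMeans(tb$z)
    if (any(scale == 0)) {
      abort("Cannot mean-standardize a trait with zero mean.",
            class = "selgrad_error_degenerate_trait")
    }
  }
  z_std <- sweep(sweep(tb$z, 2, center, "-"), 2, scale, "/")
  out <- as_tibble(as.data.frame(z_std))
  out[[tb$fitness]] <- tb$w
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  attr(out, "standardize_mode") <- mode
  out
}

#' @rdname standardize_traits
#' @return `trait_standardization()` returns a tibble with columns `trait`,
#'   `center`, `scale` (identity if `data` was never standardized).
#' @export
trait_standardization <- function(data) {
  center <- attr(data, "center")
  scale <- attr(data, "scale")
  if (is.null(center)) {
    return(tibble(trait = character(), center = numeric(),
                  scale = numeric()))
  }
  tibble(trait = names(center), center = unname(center),
         scale = unname(scale))
}

#' Design matrix for log-quadratic (or Lande-Arnold) regression
#'
#' Builds the regression design in the canonical column order: intercept,
#' the k linear trait columns, the k *halved* squares \eqn{z_i^2/2}, then
#' the cross products \eqn{z_i z_j} (i < j, not halved). With halved
#' squares, the fitted coefficient of each quadratic column is the
#' coefficient \eqn{g_i} (log-link GLM) or \eqn{\gamma_i} (OLS on relative
#' fitness) directly, with no post-hoc doubling, and sampling covariances
#' need no convention conversion.
#'
#' @param traits Numeric matrix (n x k) of trait values, or a data frame of
#'   numeric columns.
#' @param include_quadratic Include the quadratic and cross-product columns?
#' @return An n x p numeric matrix with descriptive column labels.
#' @examples
#' build_design_matrix(matrix(c(1, 2), ncol = 1))
#' @export
build_design_matrix <- function(traits, include_quadratic = TRUE) {
  z <- as.matrix(traits)
  storage.mode(z) <- "double"
  if (!all(is.finite(z))) {
    abort("Trait values must be finite.", class = "selgrad_error_not_finite")
  }
  k <- ncol(z)
  nm <- colnames(z) %||% paste0("z", seq_len(k))
  out <- cbind(`(Intercept)` = 1, z)
  colnames(out) <- c("(Intercept)", nm)
  if (include_quadratic) {
    sq <- z^2 / 2
    colnames(sq) <- paste0("I(", nm, "^2/2)")
    out <- cbind(out, sq)
    if (k > 1L) {
      idx <- which(upper.tri(diag(k)), arr.ind = TRUE)
      idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
      cp <- z[, idx[, 1L], drop = FALSE] * z[, idx[, 2L], drop = FALSE]
      colnames(cp) <- paste0(nm[idx[, 1L]], ":", nm[idx[, 2L]])
      out <- cbind(out, cp)
    }
  }
  out
}

#' Fit a log-link GLM fitness function
#'
#' Estimates the log-quadratic fitness function
#' \eqn{W(z) = \exp(a + b'z + \frac{1}{2}z'gz)} by maximum likelihood with a
#' log link. Because the quadratic covariates are squared and halved in the
#' design (see [build_design_matrix()]), the fitted coefficients are `a`,
#' `b` and `g` directly. The sampling covariance of the `(b, g)` estimates
#' (inverse observed information, intercept dropped) is returned in the
#' canonical order expected by [propagate_multivariate()].
#'
#' @inheritParams standardize_traits
#' @param family `"poisson"` (counts), `"negative_binomial"` (overdispersed
#'   counts; dispersion estimated by maximum likelihood via
#'   [MASS::glm.nb()]; the gradient conversions use only `b` and `g`), or
#'   `"binomial_log"` (0/1 fitness components with a log link --
#'   experimental: convergence failures are common and are reported).
#' @param include_quadratic Fit the quadratic terms? `FALSE` gives the
#'   log-linear model, for which beta = b.
#' @return An object of class `selgrad_glm`: a list with `coef`
#'   ([log_quadratic_coef()]; for a linear-only fit `g = 0`),
#'   `sampling_cov` ([coefficient_covariance()]), `family`, `converged`,
#'   `standardization` (tibble), `sample_mu`, `sample_sigma` (unbiased,
#'   n - 1 denominator), `n`, `include_quadratic` and the underlying `fit`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' set.seed(1)
#' z <- rnorm(500)
#' w <- rpois(500, exp(0.3 * z - 0.1 * z^2))
#' fit <- fit_log_quadratic_glm(data.frame(z = z, fitness = w))
#' tidy(fit)
#' @export
fit_log_quadratic_glm <- function(data, traits = NULL, fitness = "fitness",
                                  family = c("poisson", "negative_binomial",
                                             "binomial_log"),
                                  include_quadratic = TRUE) {
  family <- match.arg(family)
  tb <- resolve_table(data, traits, fitness)
  z <- tb$z
  w <- tb$w
  k <- ncol(z)
  colnames(z) <- tb$traits
  p_model <- if (include_quadratic) 1L + k + k * (k + 1L) / 2L else 1L + k
  if (nrow(z) < p_model + 1L) {
    abort(sprintf("Need at least %d rows to fit %d parameters.",
                  p_model + 1L, p_model),
          class = "selgrad_error_too_few_rows")
  }
  if (family %in% c("poisson", "negative_binomial") &&
      any(abs(w - round(w)) > 1e-8)) {
    abort("Count families require integer-valued fitness.",
          class = "selgrad_error_non_count_fitness")
  }
  if (family == "binomial_log" && !all(w %in% c(0, 1))) {
    abort("binomial_log requires 0/1 fitness values.",
          class = "selgrad_error_non_binary_fitness")
  }
  X <- build_design_matrix(z, include_quadratic = include_quadratic)
  if (qr(X)$rank < ncol(X)) {
    abort("Design matrix is rank deficient.",
          class = "selgrad_error_rank_deficient")
  }
  fit <- switch(
    family,
    poisson = glm(w ~ 0 + X, family = poisson()),
    negative_binomial = MASS::glm.nb(w ~ 0 + X),
    binomial_log = {
      warn("binomial_log fits are experimental; log-link binomial models often fail to converge.")
      # a small negative intercept start keeps mu < 1 at iteration 0
      glm(w ~ 0 + X, family = binomial(link = "log"),
          start = c(-0.1, rep(0, ncol(X) - 1L)))
    }
  )
  est <- coef(fit)
  names(est) <- colnames(X)
  vc <- vcov(fit)
  dimnames(vc) <- list(colnames(X), colnames(X))
  a_hat <- est[1L]
  b_hat <- est[1L + seq_len(k)]
  if (include_quadratic) {
    g_hat <- unpack_sym(est[-(1:(1L + k))], k)
  } else {
    g_hat <- matrix(0, k, k)
  }
  cc <- coefficient_covariance_from_vcov(vc[-1L, -1L, drop = FALSE], k,
                                         include_quadratic)
  std <- trait_standardization(data)
  if (nrow(std) == 0L) {
    std <- tibble(trait = tb$traits, center = 0, scale = 1)
  }
  structure(
    list(
      coef = log_quadratic_coef(a_hat, setNames(b_hat, tb$traits), g_hat,
                                trait_names = tb$traits),
      sampling_cov = cc,
      family = family,
      converged = isTRUE(fit$converged),
      standardization = std,
      sample_mu = setNames(colMeans(z), tb$traits),
      sample_sigma = var(z),
      n = nrow(z),
      include_quadratic = include_quadratic,
      n_dropped = tb$n_dropped,
      fit = fit
    ),
    class = "selgrad_glm"
  )
}

# Embed a GLM vcov (intercept already dropped) into the canonical
# (b, diag g, upper g) order; linear-only fits get zero g rows.
coefficient_covariance_from_vcov <- function(vc, k, include_quadratic) {
  p_full <- k + k * (k + 1L) / 2L
  if (include_quadratic) {
    return(coefficient_covariance(vc, k = k))
  }
  full <- matrix(0, p_full, p_full)
  full[seq_len(k), seq_len(k)] <- vc
  coefficient_covariance(full, k = k)
}

#' @export
print.selgrad_glm <- function(x, ...) {
  cat("<log-link GLM fitness fit> family:", x$family,
      "| n =", x$n,
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  print(x$coef)
  invisible(x)
}

#' @rdname fit_log_quadratic_glm
#' @param x A `selgrad_glm` object.
#' @param ... Unused.
#' @method tidy selgrad_glm
#' @export
tidy.selgrad_glm <- function(x, ...) {
  k <- x$coef$k
  tn <- x$coef$trait_names
  terms <- c("a", paste0("b_", tn),
             if (x$include_quadratic) pack_sym_names("g", tn))
  est <- c(x$coef$a, unname(x$coef$b),
           if (x$include_quadratic) pack_sym(x$coef$g))
  se_a <- sqrt(diag(vcov(x$fit)))[1L]
  se_bg <- sqrt(diag(x$sampling_cov$cov))
  if (!x$include_quadratic) se_bg <- se_bg[seq_len(k)]
  tibble(term = terms, estimate = est, std_error = c(se_a, se_bg))
}

#' @rdname fit_log_quadratic_glm
#' @method glance selgrad_glm
#' @export
glance.selgrad_glm <- function(x, ...) {
  tibble(
    n = x$n, family = x$family, converged = x$converged,
    deviance = x$fit$deviance, aic = x$fit$aic %||% NA_real_,
    n_dropped = x$n_dropped
  )
}

#' Selection gradients and uncertainty from a fitted GLM
#'
#' Composes the closed-form coefficient-to-gradient conversion
#' ([compute_beta()], [compute_gamma()]) with delta-method propagation of
#' the sampling covariance ([propagate_multivariate()]). The phenotype
#' distribution defaults to the sample mean and (unbiased) covariance of
#' the traits actually fitted, so gradients are on the fitted
#' (possibly standardized) scale.
#'
#' @param fit A `selgrad_glm` from [fit_log_quadratic_glm()].
#' @param pheno Optional [phenotype_distribution()] overriding the sample
#'   moments.
#' @return An object of class `selgrad_gradients` with elements `gradients`
#'   (a `selection_gradients`), `uncertainty` (a `gradient_uncertainty`),
#'   `pheno`, `standardization` and `fit`. [tidy()] gives a tibble with
#'   `gradient`, `term`, `estimate`, `se`.
#' @section Errors: `selgrad_error_omega_not_pd` when the estimated
#'   curvature violates the validity condition; the message advises
#'   reporting the raw coefficient estimates.
#' @export
gradients_from_fit <- function(fit, pheno = NULL) {
  stopifnot(inherits(fit, "selgrad_glm"))
  pheno <- pheno %||% phenotype_distribution(fit$sample_mu, fit$sample_sigma,
                                             trait_names = fit$coef$trait_names)
  sg <- selection_gradients(fit$coef, pheno)
  gu <- propagate_multivariate(fit$coef, pheno, fit$sampling_cov)
  structure(
    list(gradients = sg, uncertainty = gu, pheno = pheno,
         standardization = fit$standardization, fit = fit),
    class = "selgrad_gradients"
  )
}

#' @export
print.selgrad_gradients <- function(x, ...) {
  cat("<selection gradient estimates>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname gradients_from_fit
#' @param x A `selgrad_gradients` object.
#' @param ... Unused.
#' @method tidy selgrad_gradients
#' @export
tidy.selgrad_gradients <- function(x, ...) {
  est <- tidy(x$gradients)
  se <- tidy(x$uncertainty)
  dplyr::left_join(est, se[, c("term", "se")], by = "term")
}

#' @rdname gradients_from_fit
#' @method glance selgrad_gradients
#' @export
glance.selgrad_gradients <- function(x, ...) {
  dplyr::mutate(glance(x$fit), omega_valid = x$gradients$valid)
}

#' Lande-Arnold OLS selection gradient estimator
#'
#' The classical least-squares estimator: regress relative fitness
#' \eqn{w_i = W_i / \bar W} on the quadratic design with halved squares, so
#' the linear coefficients are \eqn{\hat\beta} and the quadratic
#' coefficients are \eqn{\hat\gamma} directly. By default both gradients
#' come from the single quadratic model; `two_step = TRUE` instead takes
#' \eqn{\hat\beta} (and its SE) from a linear-only regression.
#'
#' @inheritParams standardize_traits
#' @param two_step Take beta from a separate linear-only regression?
#' @return An object of class `selgrad_ols` with `beta_hat`, `gamma_hat`,
#'   `se_beta`, `se_gamma` (packed canonical order), `n` and the underlying
#'   `fit`. Supports [tidy()] and [glance()].
#' @examples
#' ols_lande_arnold(data.frame(z = c(-1, 0, 1), fitness = c(1, 2, 3)))
#' @export
ols_lande_arnold <- function(data, traits = NULL, fitness = "fitness",
                             two_step = FALSE) {
  tb <- resolve_table(data, traits, fitness)
  z <- tb$z
  colnames(z) <- tb$traits
  k <- ncol(z)
  wbar <- mean(tb$w)
  if (wbar <= 0) {
    abort("Sample mean fitness must be positive to form relative fitness.",
          class = "selgrad_error_zero_mean_fitness")
  }
  w_rel <- tb$w / wbar
  X <- build_design_matrix(z, include_quadratic = TRUE)
  if (nrow(X) < ncol(X)) {
    abort(sprintf("Need at least %d rows for the quadratic OLS fit.",
                  ncol(X)),
          class = "selgrad_error_too_few_rows")
  }
  if (qr(X)$rank < ncol(X)) {
    abort("Design matrix is rank deficient.",
          class = "selgrad_error_rank_deficient")
  }
  fit <- lm(w_rel ~ 0 + X)
  est <- setNames(coef(fit), colnames(X))
  se <- sqrt(diag(vcov(fit)))
  beta_hat <- est[1L + seq_len(k)]
  se_beta <- se[1L + seq_len(k)]
  gamma_packed <- est[-(1:(1L + k))]
  se_gamma <- se[-(1:(1L + k))]
  fit_lin <- NULL
  if (two_step) {
    Xl <- build_design_matrix(z, include_quadratic = FALSE)
    fit_lin <- lm(w_rel ~ 0 + Xl)
    beta_hat <- setNames(coef(fit_lin)[1L + seq_len(k)], tb$traits)
    se_beta <- sqrt(diag(vcov(fit_lin)))[1L + seq_len(k)]
  }
  structure(
    list(
      beta_hat = setNames(unname(beta_hat), tb$traits),
      gamma_hat = unpack_sym(unname(gamma_packed), k),
      se_beta = setNames(unname(se_beta), tb$traits),
      se_gamma = setNames(unname(se_gamma), pack_sym_names("gamma", tb$traits)),
      trait_names = tb$traits,
      two_step = two_step,
      n = nrow(z),
      relative_fitness_mean = mean(w_rel),
      fit = fit,
      fit_linear = fit_lin
    ),
    class = "selgrad_ols"
  )
}

#' @export
print.selgrad_ols <- function(x, ...) {
  cat("<Lande-Arnold OLS selection gradients> n =", x$n,
      if (x$two_step) "(two-step beta)" else "(single quadratic model)", "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname ols_lande_arnold
#' @param x A `selgrad_ols` object.
#' @param ... Unused.
#' @method tidy selgrad_ols
#' @export
tidy.selgrad_ols <- function(x, ...) {
  tn <- x$trait_names
  k <- length(tn)
  tibble(
    gradient = c(rep("beta", k), rep("gamma", k * (k + 1L) / 2L)),
    term = c(beta_names(tn), pack_sym_names("gamma", tn)),
    estimate = c(unname(x$beta_hat), pack_sym(x$gamma_hat)),
    se = c(unname(x$se_beta), unname(x$se_gamma))
  )
}

#' @rdname ols_lande_arnold
#' @method glance selgrad_ols
#' @export
glance.selgrad_ols <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = x$n, r_squared = s$r.squared, sigma = s$sigma,
         two_step = x$two_step)
}

#' Case-bootstrap standard errors for selection gradients
#'
#' Resamples individuals (rows) with replacement, refits the chosen
#' estimator on each resample -- recomputing relative fitness and, for the
#' GLM route, the sample phenotype moments within the resample -- and
#' reports the standard deviation of the resampled gradient estimates.
#' Resamples where the fit fails (non-convergence, rank deficiency, or a
#' curvature estimate violating the validity condition) are dropped and
#' counted.
#'
#' @inheritParams standardize_traits
#' @param estimator `"ols"` or `"glm"`.
#' @param b_reps Number of bootstrap resamples (>= 2).
#' @param seed Integer seed; the same seed gives bit-identical output. The
#'   caller's RNG state is left untouched.
#' @param family GLM family, when `estimator = "glm"`.
#' @return A tibble with columns `gradient`, `term`, `se`, plus attributes
#'   `n_failed` and `n_ok`.
#' @section Errors: `selgrad_error_too_many_failures` when more than 20% of
#'   resamples fail.
#' @export
bootstrap_se <- function(data, traits = NULL, fitness = "fitness",
                         estimator = c("ols", "glm"), b_reps = 1000,
                         seed = 1, family = "poisson") {
  estimator <- match.arg(estimator)
  if (b_reps < 2) {
    abort("`b_reps` must be at least 2.", class = "selgrad_error_config")
  }
  tb <- resolve_table(data, traits, fitness)
  d <- as.data.frame(cbind(tb$z, fitness = tb$w))
  names(d) <- c(tb$traits, "fitness")
  n <- nrow(d)
  one_fit <- function(dd) {
    if (estimator == "ols") {
      fit <- ols_lande_arnold(dd, traits = tb$traits, fitness = "fitness")
      tidy(fit)$estimate
    } else {
      fit <- fit_log_quadratic_glm(dd, traits = tb$traits,
                                   fitness = "fitness", family = family)
      if (!fit$converged) {
        abort("not converged", class = "selgrad_error_nonconvergence")
      }
      tidy(gradients_from_fit(fit))$estimate
    }
  }
  template <- if (estimator == "ols") {
    tidy(ols_lande_arnold(d, traits = tb$traits, fitness = "fitness"))
  } else {
    tidy(gradients_from_fit(
      fit_log_quadratic_glm(d, traits = tb$traits, fitness = "fitness",
                            family = family)))
  }
  ests <- with_seed(seed, {
    lapply(seq_len(b_reps), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(one_fit(d[idx, , drop = FALSE]),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(ests, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * b_reps) {
    abort(sprintf("%d of %d bootstrap resamples failed (> 20%%).",
                  n_failed, b_reps),
          class = "selgrad_error_too_many_failures")
  }
  mat <- do.call(rbind, ests[ok])
  out <- template[, c("gradient", "term")]
  out$se <- apply(mat, 2, sd)
  attr(out, "n_failed") <- n_failed
  attr(out, "n_ok") <- sum(ok)
  out
}

#' Numerical-averaging selection gradient estimator
#'
#' The model-free averaging route: given fitness-function coefficients
#' (true or fitted), average the analytic slope and curvature of
#' \eqn{W(z) = e^{f(z)}} over the *observed* phenotypes, weighting by
#' predicted fitness:
#' \deqn{\hat\beta = \frac{\sum_i (b + g z_i) e^{f(z_i)}}{\sum_i e^{f(z_i)}},
#' \qquad
#' \hat\gamma = \frac{\sum_i (g + (b + g z_i)(b + g z_i)') e^{f(z_i)}}
#'   {\sum_i e^{f(z_i)}}.}
#' As the sample grows (with multivariate normal phenotypes) this converges
#' to the closed forms in [compute_beta()] and [compute_gamma()]; it serves
#' as an independent cross-check of those conversions.
#'
#' @inheritParams standardize_traits
#' @param coef A [log_quadratic_coef()].
#' @return A `selection_gradients` object (no `q` diagnostic; `valid = NA`
#'   since no positive-definiteness condition is involved).
#' @export
numerical_average_gradients <- function(data, traits = NULL, coef,
                                        fitness = NULL) {
  stopifnot(inherits(coef, "lq_coef"))
  data <- as.data.frame(data)
  traits <- traits %||% intersect(coef$trait_names, names(data))
  if (length(traits) != coef$k) {
    abort("Trait columns do not match the coefficient dimension.",
          class = "selgrad_error_dim")
  }
  z <- as.matrix(data[traits])
  storage.mode(z) <- "double"
  z <- z[stats::complete.cases(z), , drop = FALSE]
  fz <- log_fitness(coef, z)
  wt <- exp(fz - max(fz))          # common factor cancels in the ratio
  sw <- sum(wt)
  slope <- matrix(coef$b, nrow(z), coef$k, byrow = TRUE) + z %*% coef$g
  beta <- drop(crossprod(slope, wt)) / sw
  gamma <- coef$g + crossprod(slope * wt, slope) / sw
  gamma <- symmetrize(gamma)
  dimnames(gamma) <- list(coef$trait_names, coef$trait_names)
  new_selection_gradients(setNames(beta, coef$trait_names), gamma,
                          trait_names = coef$trait_names)
}
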