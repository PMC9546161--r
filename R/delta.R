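check_univariate_curvature <- function(g, call = rlang::caller_env()) {
  if (g >= 1) {
    abort("Requires g < 1 on the standardized scale (g < 1/sigma^2).",
          class = "selgrad_error_invalid_curvature", call = call)
  }
}

cc_univariate_parts <- function(cc) {
  stopifnot(inherits(cc, "coef_cov"))
  if (cc$k != 1L) {
    abort("Univariate delta formulas need a k = 1 coefficient covariance.",
          class = "selgrad_error_dim")
  }
  list(var_b = cc$cov[1, 1], var_g = cc$cov[2, 2], cov_bg = cc$cov[1, 2])
}

#' Delta-method variance of the directional gradient (univariate, standardized)
#'
#' First-order propagation of (co)variances of the log-scale coefficients
#' `b` and `g` into the variance of \eqn{\beta = b/(1-g)}, for a phenotype
#' standardized to mean 0 and variance 1:
#' \deqn{Var[\beta] \approx \frac{Var[b]}{(1-g)^2} + \frac{b^2 Var[g]}{(1-g)^4}
#'   + \frac{2 b Cov[b,g]}{(1-g)^3}.}
#' The coefficient (co)variances may be biological (variation among cohorts
#' or populations) or statistical (sampling variances of the estimates).
#'
#' @param b,g Log-scale linear and quadratic coefficients (scalars, on the
#'   standardized scale); requires `g < 1`.
#' @param cc A [coefficient_covariance()] with k = 1 (see
#'   [coef_cov_univariate()]).
#' @return The approximate variance of beta. The first-order approximation
#'   does not guarantee a non-negative result for extreme curvature; a
#'   negative value triggers a warning (floor at 0 before taking square
#'   roots).
#' @examples
#' var_beta_univariate(1.07, -0.72, coef_cov_univariate(0.25, 0.47, -0.26))
#' @export
var_beta_univariate <- function(b, g, cc) {
  check_univariate_curvature(g)
  p <- cc_univariate_parts(cc)
  d <- 1 - g
  out <- p$var_b / d^2 + b^2 * p$var_g / d^4 + 2 * b * p$cov_bg / d^3
  if (out < 0) {
    warn("First-order Var[beta] is negative; floor at 0 when reporting an SD.")
  }
  out
}

#' Delta-method variance of the quadratic gradient (univariate, standardized)
#'
#' First-order propagation into the variance of
#' \eqn{\gamma = (b^2 + g(1-g))/(1-g)^2}:
#' \deqn{Var[\gamma] \approx \frac{4 b^2 Var[b]}{(1-g)^4}
#'   + \frac{(1 + 2b^2 - g)^2 Var[g]}{(1-g)^6}
#'   + \frac{4 b (1 + 2b^2 - g) Cov[b,g]}{(1-g)^5}.}
#'
#' @inheritParams var_beta_univariate
#' @return The approximate variance of gamma (warning and floor-at-0 policy
#'   as in [var_beta_univariate()]).
#' @examples
#' var_gamma_univariate(1.07, -0.72, coef_cov_univariate(0.25, 0.47, -0.26))
#' @export
var_gamma_univariate <- function(b, g, cc) {
  check_univariate_curvature(g)
  p <- cc_univariate_parts(cc)
  d <- 1 - g
  mid <- 1 + 2 * b^2 - g
  out <- 4 * b^2 * p$var_b / d^4 + mid^2 * p$var_g / d^6 +
    4 * b * mid * p$cov_bg / d^5
  if (out < 0) {
    warn("First-order Var[gamma] is negative; floor at 0 when reporting an SD.")
  }
  out
}

# Map the packed parameter vector (b, packed g) to the packed gradient
# vector (beta, packed gamma); errors with selgrad_error_omega_not_pd when
# the perturbed point violates the Omega condition.
gradient_map <- function(x, k, pheno) {
  b <- x[seq_len(k)]
  g <- unpack_sym(x[-seq_len(k)], k)
  coef <- log_quadratic_coef(0, b, g, trait_names = pheno$trait_names)
  c(compute_beta(coef, pheno), pack_sym(compute_gamma(coef, pheno)))
}

#' Multivariate delta-method propagation into gradient uncertainty
#'
#' Generic first-order propagation of coefficient (co)variances into the
#' joint covariance of \eqn{(\beta, vech\,\gamma)}. The Jacobian of the
#' coefficient-to-gradient map is computed by central finite differences
#' (step `max(1e-6, 1e-6 |x|)` per coordinate, halved up to 8 times if a
#' perturbed point violates the positive-definiteness of the post-selection
#' covariance); the propagated covariance is \eqn{J \, cov \, J'}. For a
#' single standardized trait the result agrees with the closed forms in
#' [var_beta_univariate()] and [var_gamma_univariate()].
#'
#' @inheritParams compute_beta
#' @param cc A [coefficient_covariance()] in the canonical order
#'   `(b, diag g, upper-triangle g)`.
#' @return An object of class `gradient_uncertainty`: a list with the full
#'   propagated covariance `cov` (rows/cols named after the packed
#'   gradients), the blocks `var_beta` (k x k), `var_gamma`
#'   (k(k+1)/2 square) and `cov_beta_gamma` (k x k(k+1)/2), the Jacobian
#'   `jacobian`, and `trait_names`. Use [tidy()] for per-gradient SEs.
#' @examples
#' propagate_multivariate(log_quadratic_coef(b = 1.07, g = -0.72),
#'                        cc = coef_cov_univariate(0.25, 0.47, -0.26))
#' @export
propagate_multivariate <- function(coef,
                                   pheno = standardized_phenotype(coef$k),
                                   cc) {
  stopifnot(inherits(coef, "lq_coef"), inherits(cc, "coef_cov"))
  if (cc$k != coef$k) {
    abort("`cc` and `coef` disagree on the number of traits.",
          class = "selgrad_error_dim")
  }
  check_omega_condition(coef, pheno)
  k <- coef$k
  x0 <- c(coef$b, pack_sym(coef$g))
  p <- length(x0)
  f0 <- gradient_map(x0, k, pheno)
  jac <- matrix(NA_real_, length(f0), p)
  for (j in seq_len(p)) {
    h <- max(1e-6, 1e-6 * abs(x0[j]))
    ok <- FALSE
    for (try in 0:8) {
      xp <- x0; xp[j] <- x0[j] + h
      xm <- x0; xm[j] <- x0[j] - h
      res <- tryCatch(
        (gradient_map(xp, k, pheno) - gradient_map(xm, k, pheno)) / (2 * h),
        selgrad_error_omega_not_pd = function(e) NULL
      )
      if (!is.null(res)) {
        jac[, j] <- res
        ok <- TRUE
        break
      }
      h <- h / 2
    }
    if (!ok) {
      abort(
        "Jacobian could not be computed: every perturbation violates the positive-definiteness of the post-selection covariance.",
        class = "selgrad_error_jacobian"
      )
    }
  }
  cov_out <- symmetrize(jac %*% cc$cov %*% t(jac))
  nm <- c(beta_names(coef$trait_names),
          pack_sym_names("gamma", coef$trait_names))
  dimnames(cov_out) <- list(nm, nm)
  bi <- seq_len(k)
  gi <- k + seq_len(k * (k + 1L) / 2L)
  structure(
    list(
      cov = cov_out,
      var_beta = cov_out[bi, bi, drop = FALSE],
      var_gamma = cov_out[gi, gi, drop = FALSE],
      cov_beta_gamma = cov_out[bi, gi, drop = FALSE],
      jacobian = jac,
      trait_names = coef$trait_names
    ),
    class = "gradient_uncertainty"
  )
}

#' @export
print.gradient_uncertainty <- function(x, ...) {
  cat("<gradient uncertainty> first-order (delta-method) covariances\n")
  print(signif(x$cov, 4))
  invisible(x)
}

#' Tidy gradient uncertainty into per-term standard errors
#'
#' @param x A `gradient_uncertainty` object.
#' @param ... Unused.
#' @return A tibble with columns `gradient`, `term`, `variance`, `se`.
#'   Negative first-order variances (possible under extreme curvature) are
#'   floored at 0 in the `se` column, with a warning.
#' @method tidy gradient_uncertainty
#' @export
tidy.gradient_uncertainty <- function(x, ...) {
  v <- diag(x$cov)
  if (any(v < 0)) {
    warn("Negative first-order variances floored at 0 in reported SEs.")
  }
  k <- length(x$trait_names)
  tibble(
    gradient = c(rep("beta", k), rep("gamma", k * (k + 1L) / 2L)),
    term = names(v),
    variance = unname(v),
    se = sqrt(pmax(unname(v), 0))
  )
}

#' Delta-method correlation between beta and gamma (univariate)
#'
#' The correlation between the directional and quadratic selection gradients
#' implied by first-order propagation of the (co)variances of `b` and `g`:
#' \eqn{Cov[\beta,\gamma]/\sqrt{Var[\beta] Var[\gamma]}} from the cross block
#' of [propagate_multivariate()].
#'
#' @inheritParams var_beta_univariate
#' @return A scalar correlation in \[-1, 1\].
#' @section Errors: `selgrad_error_degenerate_variance` when either
#'   propagated variance is zero.
#' @export
corr_beta_gamma_univariate <- function(b, g, cc) {
  check_univariate_curvature(g)
  gu <- propagate_multivariate(log_quadratic_coef(0, b, g),
                               standardized_phenotype(1), cc)
  vb <- gu$cov[1, 1]
  vg <- gu$cov[2, 2]
  if (vb <= 0 || vg <= 0) {
    abort("Both propagated variances must be positive for a correlation.",
          class = "selgrad_error_degenerate_variance")
  }
  max(-1, min(1, gu$cov[1, 2] / sqrt(vb * vg)))
}
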