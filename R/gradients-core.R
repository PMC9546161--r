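#' @importFrom tibble tibble as_tibble
NULL

# Check the post-selection covariance condition: Omega^-1 = Sigma^-1 - g must
# be positive definite (univariate: g < 1/sigma^2). Errors with a dedicated
# class so callers can report b, g and the failed condition.
check_omega_condition <- function(coef, pheno, call = rlang::caller_env()) {
  prec <- solve(pheno$sigma) - coef$g
  ev <- eigen(symmetrize(prec), symmetric = TRUE, only.values = TRUE)$values
  if (!(ev[length(ev)] > 1e-12 * max(ev, 0))) {
    abort(
      paste0(
        "Post-selection covariance is not positive definite ",
        "(Omega^-1 = Sigma^-1 - g has a non-positive eigenvalue). ",
        "The fitness function curves upward too sharply for the phenotype ",
        "distribution; report b and g directly instead of gradients."
      ),
      class = "selgrad_error_omega_not_pd", call = call
    )
  }
  invisible(TRUE)
}

#' Directional selection gradient from log-quadratic coefficients
#'
#' Converts the coefficients of the fitness function
#' \eqn{W(z) = \exp(a + b'z + \frac{1}{2} z' g z)} into the directional
#' selection gradient \eqn{\beta = (I - g\Sigma)^{-1}(b + g\mu)} for a
#' multivariate normal phenotype with mean \eqn{\mu} and covariance
#' \eqn{\Sigma}. For a single trait this is \eqn{(b + g\mu)/(1 - g\sigma^2)},
#' and with a standardized phenotype simply \eqn{b/(1-g)}. When `g = 0`
#' (log-linear fitness) the gradient equals `b` exactly.
#'
#' @param coef A [log_quadratic_coef()] (the intercept `a` does not affect
#'   the gradient).
#' @param pheno A [phenotype_distribution()]; defaults to the standardized
#'   phenotype (`mu = 0`, `sigma = I`), the scale on which
#'   variance-standardized gradients are reported. Gradients are always on
#'   the same scale as `b`, `g`, `mu`, `sigma`; standardize the data before
#'   fitting to obtain standardized gradients.
#'
#' @return Named numeric vector of length k.
#' @section Validity: requires \eqn{\Omega^{-1} = \Sigma^{-1} - g} positive
#'   definite (univariate: \eqn{g < 1/\sigma^2}); otherwise an error of class
#'   `selgrad_error_omega_not_pd` is thrown.
#' @examples
#' compute_beta(log_quadratic_coef(b = 1.07, g = -0.72))  # ~0.62
#' @seealso [compute_gamma()], [selection_gradients()]
#' @export
compute_beta <- function(coef, pheno = standardized_phenotype(coef$k)) {
  stopifnot(inherits(coef, "lq_coef"), inherits(pheno, "pheno_dist"))
  if (coef$k != pheno$k) {
    abort("`coef` and `pheno` disagree on the number of traits.",
          class = "selgrad_error_dim")
  }
  check_omega_condition(coef, pheno)
  k <- coef$k
  rhs <- coef$b + drop(coef$g %*% pheno$mu)
  beta <- drop(solve(diag(k) - coef$g %*% pheno$sigma, rhs))
  setNames(beta, coef$trait_names)
}

#' Quadratic selection gradient from log-quadratic coefficients
#'
#' Computes \eqn{\gamma = \beta\beta' + Qg} with
#' \eqn{Q = (I - g\Sigma)^{-1}}, the average curvature of the relative
#' fitness surface over the phenotype distribution. For a single trait this
#' is \eqn{((b+g\mu)^2 + g(1-g\sigma^2))/(1-g\sigma^2)^2}. The result is
#' explicitly symmetrized to absorb floating-point asymmetry.
#'
#' @inheritParams compute_beta
#' @return Symmetric k x k matrix.
#' @examples
#' compute_gamma(log_quadratic_coef(b = 0.3, g = 0.4))  # 0.91667
#' @export
compute_gamma <- function(coef, pheno = standardized_phenotype(coef$k)) {
  stopifnot(inherits(coef, "lq_coef"), inherits(pheno, "pheno_dist"))
  if (coef$k != pheno$k) {
    abort("`coef` and `pheno` disagree on the number of traits.",
          class = "selgrad_error_dim")
  }
  check_omega_condition(coef, pheno)
  k <- coef$k
  ImgS <- diag(k) - coef$g %*% pheno$sigma
  beta <- drop(solve(ImgS, coef$b + drop(coef$g %*% pheno$mu)))
  gamma <- symmetrize(tcrossprod(beta) + solve(ImgS, coef$g))
  dimnames(gamma) <- list(coef$trait_names, coef$trait_names)
  gamma
}

#' Selection gradients with diagnostics
#'
#' Computes both gradients plus the matrix \eqn{Q = (I - g\Sigma)^{-1}}
#' used in the conversion, returned for diagnostic purposes.
#'
#' @inheritParams compute_beta
#' @return An object of class `selection_gradients` with elements `beta`
#'   (named vector), `gamma` (symmetric matrix), `q` (matrix), `valid`
#'   (logical: post-selection covariance positive definite) and
#'   `trait_names`. Use [generics::tidy()] for a tibble of the estimates.
#' @examples
#' sg <- selection_gradients(log_quadratic_coef(b = 0.3, g = 0.4))
#' tidy(sg)
#' @export
selection_gradients <- function(coef, pheno = standardized_phenotype(coef$k)) {
  beta <- compute_beta(coef, pheno)
  gamma <- compute_gamma(coef, pheno)
  q <- solve(diag(coef$k) - coef$g %*% pheno$sigma)
  dimnames(q) <- list(coef$trait_names, coef$trait_names)
  new_selection_gradients(beta, gamma, q = q, valid = TRUE,
                          trait_names = coef$trait_names)
}

new_selection_gradients <- function(beta, gamma, q = NULL, valid = NA,
                                    trait_names = names(beta)) {
  structure(
    list(beta = beta, gamma = gamma, q = q, valid = valid,
         trait_names = trait_names),
    class = "selection_gradients"
  )
}

#' @export
print.selection_gradients <- function(x, ...) {
  cat("<selection gradients>\n")
  cat("beta: ", paste(signif(x$beta, 4), collapse = " "), "\n")
  cat("gamma:\n")
  print(signif(x$gamma, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy selection gradients into a tibble
#'
#' @param x A `selection_gradients` object.
#' @param ... Unused.
#' @return A tibble with columns `gradient` (`"beta"` or `"gamma"`), `term`,
#'   and `estimate`; the gamma rows cover the distinct elements in canonical
#'   order (diagonal, then upper triangle).
#' @method tidy selection_gradients
#' @export
tidy.selection_gradients <- function(x, ...) {
  tn <- x$trait_names
  tibble(
    gradient = c(rep("beta", length(x$beta)), rep("gamma", length(pack_sym(x$gamma)))),
    term = c(beta_names(tn), pack_sym_names("gamma", tn)),
    estimate = c(unname(x$beta), pack_sym(x$gamma))
  )
}

#' Post-selection phenotype distribution and mean fitness
#'
#' Under a multivariate normal phenotype and log-quadratic fitness, the
#' phenotype distribution after selection is again multivariate normal, with
#' covariance \eqn{\Omega = (\Sigma^{-1} - g)^{-1}} and mean
#' \eqn{\nu = \mu + \Omega(b + g\mu)}. Mean absolute fitness
#' \eqn{\bar W = E[W(z)]} is obtained from the pointwise identity
#' \eqn{\bar W = W(z) p_{\mu,\Sigma}(z) / p_{\nu,\Omega}(z)}, which is
#' constant in z; it is evaluated at \eqn{z = \mu}.
#'
#' The post-selection mean satisfies the selection-differential identity
#' \eqn{\nu - \mu = \Sigma\beta}.
#'
#' @inheritParams compute_beta
#' @return An object of class `post_selection` with elements `nu` (named
#'   vector), `omega` (symmetric positive-definite matrix) and
#'   `mean_fitness` (positive scalar).
#' @examples
#' post_selection_distribution(log_quadratic_coef(a = 0, b = 0.3, g = 0.4))
#' @export
post_selection_distribution <- function(coef,
                                        pheno = standardized_phenotype(coef$k)) {
  stopifnot(inherits(coef, "lq_coef"), inherits(pheno, "pheno_dist"))
  if (coef$k != pheno$k) {
    abort("`coef` and `pheno` disagree on the number of traits.",
          class = "selgrad_error_dim")
  }
  check_omega_condition(coef, pheno)
  k <- coef$k
  ImgS <- diag(k) - coef$g %*% pheno$sigma
  # Omega^-1 = Sigma^-1 - g  =>  Omega = Sigma (I - g Sigma)^-1
  omega <- symmetrize(pheno$sigma %*% solve(ImgS))
  nu <- pheno$mu + drop(omega %*% (coef$b + drop(coef$g %*% pheno$mu)))
  log_wbar <- log_fitness(coef, matrix(pheno$mu, nrow = 1)) +
    dmvnorm_log(pheno$mu, pheno$mu, pheno$sigma) -
    dmvnorm_log(pheno$mu, nu, omega)
  dimnames(omega) <- list(coef$trait_names, coef$trait_names)
  structure(
    list(nu = setNames(nu, coef$trait_names), omega = omega,
         mean_fitness = exp(log_wbar)),
    class = "post_selection"
  )
}

#' @export
print.post_selection <- function(x, ...) {
  cat("<post-selection phenotype distribution>\n")
  cat("nu:   ", paste(signif(x$nu, 4), collapse = " "), "\n")
  cat("omega:\n")
  print(signif(x$omega, 4))
  cat("mean fitness:", signif(x$mean_fitness, 6), "\n")
  invisible(x)
}

#' Selection gradients under a Gaussian fitness function
#'
#' For \eqn{W(z) \propto \exp(-\frac{1}{2}(z-\theta)'\omega^{-1}(z-\theta))}
#' the classical results \eqn{\beta = -S(\mu - \theta)} and
#' \eqn{\gamma = \beta\beta' - S} with \eqn{S = (\omega + \Sigma)^{-1}}
#' hold. These coincide with [compute_beta()]/[compute_gamma()] applied to
#' the equivalent log-quadratic coefficients (`g = -omega^{-1}`,
#' `b = omega^{-1} theta`).
#'
#' @param gauss A [gaussian_fitness()] object.
#' @param pheno A [phenotype_distribution()].
#' @return A `selection_gradients` object (its `q` slot is the
#'   \eqn{(I - g\Sigma)^{-1}} diagnostic of the equivalent log-quadratic
#'   parameterization).
#' @examples
#' gradients_from_gaussian(gaussian_fitness(theta = 0.5, omega = 1),
#'                         standardized_phenotype())
#' @export
gradients_from_gaussian <- function(gauss, pheno) {
  stopifnot(inherits(gauss, "gauss_fitness"), inherits(pheno, "pheno_dist"))
  if (gauss$k != pheno$k) {
    abort("`gauss` and `pheno` disagree on the number of traits.",
          class = "selgrad_error_dim")
  }
  k <- gauss$k
  s_mat <- solve(gauss$omega + pheno$sigma)
  beta <- drop(-s_mat %*% (pheno$mu - gauss$theta))
  gamma <- symmetrize(tcrossprod(beta) - s_mat)
  g_equiv <- -solve(gauss$omega)
  q <- solve(diag(k) - g_equiv %*% pheno$sigma)
  dimnames(gamma) <- list(gauss$trait_names, gauss$trait_names)
  new_selection_gradients(setNames(beta, gauss$trait_names), gamma, q = q,
                          valid = TRUE, trait_names = gauss$trait_names)
}

#' Gaussian parameterization of a log-quadratic fitness function
#'
#' When `g` is negative definite the log-quadratic fitness function has an
#' interior maximum and can be rewritten, up to a multiplicative constant, as
#' a Gaussian fitness function with width \eqn{\omega = (-g)^{-1}} and
#' optimum \eqn{\theta = -g^{-1} b} (univariate: \eqn{\theta = -b/g}).
#'
#' @param coef A [log_quadratic_coef()] with negative-definite `g`.
#' @return A [gaussian_fitness()] object.
#' @section Errors: `selgrad_error_not_gaussian` when `g` has any
#'   non-negative eigenvalue (the fitness function has no interior maximum).
#' @examples
#' gaussian_from_coefficients(log_quadratic_coef(b = 0.3, g = -0.5))
#' @export
gaussian_from_coefficients <- function(coef) {
  stopifnot(inherits(coef, "lq_coef"))
  ev <- eigen(coef$g, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) >= -1e-12 * max(abs(ev))) {
    abort(
      "`g` is not negative definite: the fitness function has no interior maximum and no Gaussian representation.",
      class = "selgrad_error_not_gaussian"
    )
  }
  omega <- symmetrize(solve(-coef$g))
  theta <- drop(solve(-coef$g, coef$b))
  gaussian_fitness(setNames(theta, coef$trait_names), omega,
                   trait_names = coef$trait_names)
}

#' Predicted evolutionary response to selection
#'
#' The Lande equation \eqn{\Delta\bar z = G\beta}: per-generation change in
#' the mean phenotype given the additive genetic covariance matrix G and the
#' directional selection gradient.
#'
#' @param beta Directional selection gradient vector (length k).
#' @param g_matrix Additive genetic covariance matrix G (k x k, positive
#'   semidefinite); a scalar is accepted for k = 1.
#' @return Named numeric vector \eqn{\Delta\bar z}.
#' @examples
#' predict_response(c(0.1484, -0.0710),
#'                  matrix(c(0.2, 0.05, 0.05, 0.1), 2, 2))
#' @export
predict_response <- function(beta, g_matrix) {
  nm <- names(beta)
  beta <- as.numeric(beta)
  k <- length(beta)
  g_matrix <- as_square_matrix(g_matrix, k, "g_matrix")
  setNames(drop(g_matrix %*% beta), nm %||% paste0("z", seq_len(k)))
}
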