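#' Pre-selection phenotype distribution
#'
#' Bundle the mean vector and covariance matrix of the (assumed multivariate
#' normal) phenotype distribution before selection. Scalars are accepted for
#' univariate traits; a scalar `sigma` with a longer `mu` is interpreted as a
#' common variance on the diagonal.
#'
#' @param mu Numeric vector of trait means (trait units). A scalar gives a
#'   univariate distribution.
#' @param sigma Phenotypic covariance matrix (trait units squared). A scalar
#'   variance is accepted when `mu` is scalar; a vector is taken as a
#'   diagonal.
#' @param trait_names Optional character vector of trait labels; defaults to
#'   names of `mu` or `z1, z2, ...`.
#'
#' @return An object of class `pheno_dist` with elements `mu`, `sigma`,
#'   `trait_names` and `k` (number of traits).
#'
#' @details `sigma` must be symmetric (relative tolerance 1e-10) and positive
#'   definite (smallest eigenvalue greater than 1e-12 times the largest).
#'
#' @examples
#' phenotype_distribution(0, 1)                    # standardized single trait
#' phenotype_distribution(c(0, 0), diag(2))        # two uncorrelated traits
#' @export
phenotype_distribution <- function(mu, sigma, trait_names = NULL) {
  mu <- as.numeric(mu)
  k <- length(mu)
  trait_names <- trait_names %||% names(mu) %||% paste0("z", seq_len(k))
  sigma <- as_square_matrix(sigma, k, "sigma")
  sigma <- check_symmetric(sigma, "sigma")
  if (!is_pos_def(sigma)) {
    abort("`sigma` must be positive definite.",
          class = "selgrad_error_not_pd")
  }
  dimnames(sigma) <- list(trait_names, trait_names)
  structure(
    list(mu = setNames(mu, trait_names), sigma = sigma,
         trait_names = trait_names, k = k),
    class = "pheno_dist"
  )
}

#' Standardized phenotype distribution
#'
#' Shorthand for a mean-zero, identity-covariance phenotype distribution,
#' the scale on which variance-standardized selection gradients are defined.
#'
#' @param k Number of traits.
#' @inheritParams phenotype_distribution
#' @return A [phenotype_distribution()] with `mu = 0`, `sigma = I`.
#' @export
standardized_phenotype <- function(k = 1, trait_names = NULL) {
  phenotype_distribution(rep(0, k), diag(k), trait_names = trait_names)
}

#' @export
print.pheno_dist <- function(x, ...) {
  cat("<phenotype distribution>", x$k,
      if (x$k == 1L) "trait\n" else "traits\n")
  cat("mu:   ", paste(signif(x$mu, 4), collapse = " "), "\n")
  cat("sigma:\n")
  print(signif(x$sigma, 4))
  invisible(x)
}

#' Log-quadratic fitness-function coefficients
#'
#' Parameters of the exponential fitness function
#' \eqn{W(z) = \exp(a + b'z + \frac{1}{2} z' g z)}: the log-scale intercept
#' `a`, linear coefficients `b`, and the symmetric quadratic/correlational
#' coefficient matrix `g`. These are the quantities estimated directly by a
#' log-link GLM when the squared covariates are halved (see
#' [build_design_matrix()]).
#'
#' @param a Log-scale intercept (scalar).
#' @param b Numeric vector of log-scale linear coefficients (length k).
#' @param g Symmetric k x k matrix of log-scale quadratic coefficients;
#'   a scalar is accepted for k = 1, a vector as a diagonal matrix.
#' @param trait_names Optional trait labels.
#'
#' @return An object of class `lq_coef` with elements `a`, `b`, `g`,
#'   `trait_names`, `k`.
#' @examples
#' log_quadratic_coef(a = 0, b = 0.3, g = -0.5)
#' log_quadratic_coef(0, b = c(0.2, -0.1), g = matrix(c(-0.3, 0.1, 0.1, -0.2), 2))
#' @export
log_quadratic_coef <- function(a = 0, b, g = 0, trait_names = NULL) {
  b <- as.numeric(b)
  k <- length(b)
  trait_names <- trait_names %||% names(b) %||% paste0("z", seq_len(k))
  g <- as_square_matrix(g, k, "g")
  g <- check_symmetric(g, "g")
  if (!all(is.finite(c(a, b, g)))) {
    abort("All coefficients must be finite.",
          class = "selgrad_error_not_finite")
  }
  dimnames(g) <- list(trait_names, trait_names)
  structure(
    list(a = as.numeric(a), b = setNames(b, trait_names), g = g,
         trait_names = trait_names, k = k),
    class = "lq_coef"
  )
}

#' @export
print.lq_coef <- function(x, ...) {
  cat("<log-quadratic fitness coefficients> W(z) = exp(a + b'z + z'gz/2)\n")
  cat("a:", signif(x$a, 4), "\n")
  cat("b:", paste(signif(x$b, 4), collapse = " "), "\n")
  cat("g:\n")
  print(signif(x$g, 4))
  invisible(x)
}

# log W(z) = a + b'z + z'gz/2 for rows of z (n x k matrix).
log_fitness <- function(coef, z) {
  z <- matrix(as.numeric(z), ncol = coef$k)
  drop(coef$a + z %*% coef$b + 0.5 * rowSums((z %*% coef$g) * z))
}

#' Gaussian fitness-function parameters
#'
#' The classical stabilizing-selection parameterization
#' \eqn{W(z) \propto \exp(-\frac{1}{2}(z - \theta)' \omega^{-1} (z - \theta))}
#' with optimum `theta` and positive-definite width matrix `omega`. A
#' log-quadratic fitness function with negative-definite `g` is the same
#' model (see [gaussian_from_coefficients()]).
#'
#' @param theta Numeric vector: the optimal phenotype.
#' @param omega Width matrix (positive definite); a scalar is accepted for a
#'   single trait.
#' @param trait_names Optional trait labels.
#' @return An object of class `gauss_fitness` with elements `theta`, `omega`,
#'   `trait_names`, `k`.
#' @examples
#' gaussian_fitness(theta = 0.5, omega = 1)
#' @export
gaussian_fitness <- function(theta, omega, trait_names = NULL) {
  theta <- as.numeric(theta)
  k <- length(theta)
  trait_names <- trait_names %||% names(theta) %||% paste0("z", seq_len(k))
  omega <- as_square_matrix(omega, k, "omega")
  omega <- check_symmetric(omega, "omega")
  if (!is_pos_def(omega)) {
    abort("`omega` must be positive definite.",
          class = "selgrad_error_not_pd")
  }
  dimnames(omega) <- list(trait_names, trait_names)
  structure(
    list(theta = setNames(theta, trait_names), omega = omega,
         trait_names = trait_names, k = k),
    class = "gauss_fitness"
  )
}

#' @export
print.gauss_fitness <- function(x, ...) {
  cat("<Gaussian fitness function> optimum theta, width omega\n")
  cat("theta:", paste(signif(x$theta, 4), collapse = " "), "\n")
  cat("omega:\n")
  print(signif(x$omega, 4))
  invisible(x)
}

#' Coefficient (co)variance matrix
#'
#' (Co)variances of the elements of `b` and `g` -- biological (variation among
#' replicates of a selection analysis) or statistical (sampling covariance of
#' the estimates). The canonical parameter order is
#' `(b_1, ..., b_k, g_11, ..., g_kk, g_12, g_13, ..., g_{k-1,k})`:
#' linear coefficients first, then quadratic diagonals, then the upper
#' triangle row-major. All estimation front ends in this package emit
#' covariance matrices in this order.
#'
#' @param cov Symmetric positive-semidefinite p x p matrix with
#'   `p = k + k(k+1)/2`.
#' @param k Number of traits (inferred from `p` when omitted).
#' @return An object of class `coef_cov` with elements `cov`, `k`, `p`.
#' @seealso [coef_cov_univariate()] for the common k = 1 case,
#'   [convert_unhalved_covariance()] for results fitted with unhalved
#'   squared covariates.
#' @export
coefficient_covariance <- function(cov, k = NULL) {
  cov <- as.matrix(cov)
  p <- nrow(cov)
  if (is.null(k)) {
    # p = k + k(k+1)/2  =>  k = (-3 + sqrt(9 + 8p)) / 2
    k <- (-3 + sqrt(9 + 8 * p)) / 2
    if (abs(k - round(k)) > 1e-9) {
      abort(sprintf("`cov` has %d rows, not a valid k + k(k+1)/2.", p),
            class = "selgrad_error_dim")
    }
    k <- as.integer(round(k))
  }
  if (p != k + k * (k + 1L) / 2L) {
    abort(sprintf("`cov` must be %d x %d for k = %d.",
                  k + k * (k + 1L) / 2L, k + k * (k + 1L) / 2L, k),
          class = "selgrad_error_dim")
  }
  cov <- check_symmetric(cov, "cov")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1e-300)) {
    abort("`cov` must be positive semidefinite.",
          class = "selgrad_error_not_psd")
  }
  structure(list(cov = cov, k = k, p = p), class = "coef_cov")
}

#' @rdname coefficient_covariance
#' @param var_b,var_g Variances of the univariate `b` and `g` coefficients.
#' @param cov_bg Their covariance.
#' @export
coef_cov_univariate <- function(var_b, var_g = 0, cov_bg = 0) {
  coefficient_covariance(matrix(c(var_b, cov_bg, cov_bg, var_g), 2, 2), k = 1L)
}

#' @export
print.coef_cov <- function(x, ...) {
  cat("<coefficient (co)variances>", x$k,
      if (x$k == 1L) "trait," else "traits,", "order (b, diag g, upper g)\n")
  print(signif(x$cov, 4))
  invisible(x)
}

#' Convert a covariance matrix from the unhalved-squares convention
#'
#' A model fitted with plain squared covariates (not halved) estimates `g/2`
#' for the quadratic diagonal terms; the point estimates must be doubled, and
#' correspondingly the rows and columns of their sampling covariance scaled:
#' variances of diagonal-g terms by 4, their covariances with every other
#' parameter by 2. This helper applies that scaling so the result matches the
#' canonical halved-squares convention used everywhere in this package.
#'
#' @param cc A [coefficient_covariance()] from an unhalved-squares fit
#'   (same parameter order).
#' @return A [coefficient_covariance()] on the halved-squares scale.
#' @export
convert_unhalved_covariance <- function(cc) {
  stopifnot(inherits(cc, "coef_cov"))
  scale <- rep(1, cc$p)
  scale[cc$k + seq_len(cc$k)] <- 2   # diagonal-g rows/cols
  coefficient_covariance(diag(scale, cc$p) %*% cc$cov %*% diag(scale, cc$p),
                         k = cc$k)
}
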