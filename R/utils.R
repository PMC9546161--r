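#' @importFrom rlang abort warn %||%
#' @importFrom stats coef vcov sd var rnorm rpois rnbinom rbinom setNames
NULL

# Coerce a scalar / vector / matrix to a k x k matrix.
as_square_matrix <- function(x, k, arg = "x") {
  if (is.null(dim(x))) {
    if (length(x) == 1L && k > 1L) {
      return(diag(as.numeric(x), k))
    }
    if (length(x) == k && k == 1L) {
      return(matrix(as.numeric(x), 1L, 1L))
    }
    if (length(x) == k) {
      return(diag(as.numeric(x), k))
    }
    abort(sprintf("`%s` cannot be coerced to a %d x %d matrix.", arg, k, k),
          class = "selgrad_error_dim")
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(k, k))) {
    abort(sprintf("`%s` must be %d x %d, got %d x %d.", arg, k, k,
                  nrow(x), ncol(x)),
          class = "selgrad_error_dim")
  }
  storage.mode(x) <- "double"
  x
}

check_symmetric <- function(m, arg, rtol = 1e-10) {
  scale <- max(abs(m), 1e-300)
  if (max(abs(m - t(m))) > rtol * scale) {
    abort(sprintf("`%s` must be symmetric (relative tolerance %g).", arg, rtol),
          class = "selgrad_error_not_symmetric")
  }
  (m + t(m)) / 2
}

# Smallest eigenvalue must exceed 1e-12 x largest for "positive definite".
is_pos_def <- function(m, ratio = 1e-12) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] > ratio * max(ev, 0)
}

symmetrize <- function(m) (m + t(m)) / 2

# Canonical packing of a symmetric k x k matrix: diagonal first
# (m11, ..., mkk), then the upper triangle row-major (m12, m13, ..., m[k-1,k]).
# This is the parameter order used throughout for g and for vech(gamma).
pack_sym <- function(m) {
  k <- nrow(m)
  out <- unname(diag(m))
  if (k > 1L) {
    out <- c(out, t(m)[lower.tri(m)])
  }
  out
}

unpack_sym <- function(v, k) {
  m <- diag(as.numeric(v[seq_len(k)]), k)
  if (k > 1L) {
    up <- v[-seq_len(k)]
    m[upper.tri(m)] <- 0
    idx <- which(upper.tri(m), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    m[idx] <- up
    m <- m + t(m) - diag(diag(m), k)
  }
  m
}

beta_names <- function(trait_names) paste0("beta_", trait_names)

# Names for the packed symmetric entries, e.g. g labels: g_1, ..., g_12, ...
pack_sym_names <- function(prefix, trait_names) {
  k <- length(trait_names)
  nm <- paste0(prefix, "_", trait_names)
  if (k > 1L) {
    idx <- which(upper.tri(diag(k)), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    nm <- c(nm, paste0(prefix, "_", trait_names[idx[, 1L]], ":",
                       trait_names[idx[, 2L]]))
  }
  nm
}

# Log-density of N(mu, sigma) at z, via Cholesky.
dmvnorm_log <- function(z, mu, sigma) {
  k <- length(mu)
  ch <- chol(sigma)
  dev <- backsolve(ch, z - mu, transpose = TRUE)
  -0.5 * k * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(dev^2)
}

# Deterministic substream seed below 2^31 from (master, scenario, replicate).
derive_seed <- function(seed, scenario_index, replicate_index) {
  s <- (as.double(seed) %% 2147483647) * 48271 +
    as.double(scenario_index) * 69621 +
    as.double(replicate_index) * 16807 + 1
  as.integer(s %% 2147483629)
}

# Evaluate expr with a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
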