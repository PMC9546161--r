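#' Read an individual-level trait-fitness table
#'
#' Reads a CSV or TSV file with a header row (delimiter inferred from the
#' extension, `.tsv`/`.txt` meaning tab, overridable), drops rows with
#' missing trait or fitness values (with a message), and validates that
#' fitness is numeric and non-negative.
#'
#' @param path Path to the file.
#' @param traits Trait column names; default: all numeric columns except
#'   `fitness`.
#' @param fitness Name of the fitness column.
#' @param delim Optional delimiter override (`","` or `"\t"`).
#' @return A tibble with the trait columns and the fitness column.
#' @export
read_trait_fitness <- function(path, traits = NULL, fitness = "fitness",
                               delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "selgrad_error_io")
  }
  delim <- delim %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    abort("Input table is empty.", class = "selgrad_error_empty_table")
  }
  tb <- resolve_table(raw, traits, fitness)
  out <- as_tibble(as.data.frame(tb$z))
  out[[fitness]] <- tb$w
  out
}

#' Write / read a gradient analysis report
#'
#' Serializes a full gradient analysis -- coefficients, sampling covariance
#' (canonical order), gradients, standard errors, standardization record,
#' validity diagnostics, seed and package version -- as JSON, sufficient to
#' regenerate the analysis. `read_gradient_report()` restores the numeric
#' content; gradients survive the round trip exactly (JSON numbers are
#' written at full precision).
#'
#' @param x A `selgrad_gradients` object from [gradients_from_fit()].
#' @param path Output path.
#' @param seed Seed to record (optional).
#' @return `write_gradient_report()` returns `path` invisibly;
#'   `read_gradient_report()` returns a list.
#' @export
write_gradient_report <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "selgrad_gradients"))
  fit <- x$fit
  report <- list(
    package = "selgrad",
    version = as.character(utils::packageVersion("selgrad")),
    seed = seed,
    family = fit$family,
    converged = fit$converged,
    n = fit$n,
    trait_names = fit$coef$trait_names,
    a = fit$coef$a,
    b = as.list(fit$coef$b),
    g = fit$coef$g,
    sampling_cov_order = "(b, diag g, upper-triangle g row-major)",
    sampling_cov = fit$sampling_cov$cov,
    standardization = x$standardization,
    pheno = list(mu = x$pheno$mu, sigma = x$pheno$sigma),
    beta = as.list(x$gradients$beta),
    gamma = x$gradients$gamma,
    se = tidy(x$uncertainty)[, c("term", "se")],
    omega_valid = x$gradients$valid
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_gradient_report
#' @export
read_gradient_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
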