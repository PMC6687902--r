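#' Gaussian belief over a named parameter vector
#'
#' A lightweight container for a multivariate Gaussian over named
#' parameters, used for both priors and posteriors throughout the
#' inversion and model-reduction machinery.
#'
#' @param names character vector of parameter names (ordered).
#' @param mean numeric vector of means, same length as `names`.
#' @param cov covariance matrix (symmetric positive semi-definite),
#'   dimensions matching `names`. A numeric vector is taken as a
#'   diagonal.
#'
#' @return An object of class `gaussian_belief` with elements `names`,
#'   `mean` and `cov`.
#' @export
gaussian_belief <- function(names, mean, cov) {
  names <- as.character(names)
  mean <- as.numeric(mean)
  k <- length(names)
  if (length(mean) != k) {
    stop("`mean` must have one entry per parameter name", call. = FALSE)
  }
  if (is.vector(cov) && !is.matrix(cov)) {
    if (length(cov) == 1L) cov <- rep(cov, k)
    cov <- diag(cov, nrow = k)
  }
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(k, k))) {
    stop("`cov` dimensions must match the number of parameters", call. = FALSE)
  }
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("`cov` must be symmetric", call. = FALSE)
  }
  cov <- (cov + t(cov)) / 2
  attributes(cov) <- attributes(cov)["dim"]
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
    stop("`cov` must be positive semi-definite", call. = FALSE)
  }
  structure(
    list(names = names, mean = stats::setNames(mean, names), cov = cov),
    class = "gaussian_belief"
  )
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat("<gaussian_belief> over", length(x$names), "parameters\n")
  sd <- sqrt(pmax(diag(x$cov), 0))
  df <- tibble::tibble(term = x$names, mean = unname(x$mean), sd = sd)
  print(df, n = 10)
  invisible(x)
}

#' @export
as_tibble.gaussian_belief <- function(x, ...) {
  tibble::tibble(
    term = x$names,
    mean = unname(x$mean),
    sd = sqrt(pmax(diag(x$cov), 0))
  )
}

# KL(q || p) between two Gaussian beliefs with aligned names
kl_gaussian <- function(q, p) {
  stopifnot(identical(q$names, p$names))
  k <- length(q$names)
  Pp <- chol2inv(chol(p$cov))
  dm <- unname(q$mean - p$mean)
  ld_p <- as.numeric(determinant(p$cov, logarithm = TRUE)$modulus)
  ld_q <- as.numeric(determinant(q$cov, logarithm = TRUE)$modulus)
  0.5 * (sum(Pp * q$cov) + sum(dm * (Pp %*% dm)) - k + ld_p - ld_q)
}

# Symmetrize and floor the eigenvalues of a covariance-like matrix.
# Returns the repaired matrix; attribute "floored" counts lifted eigenvalues.
repair_psd <- function(S, floor_rel = 1e-12) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  floor_val <- floor_rel * max(abs(e$values), .Machine$double.eps)
  n_floored <- sum(e$values < floor_val)
  vals <- pmax(e$values, floor_val)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  attr(out, "floored") <- n_floored
  out
}
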