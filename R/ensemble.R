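# Gaussian ensemble (conjugate posterior) for the linear model with known
# error variance sigma^2 and prior beta ~ N(0, (1/b) I).
#
# The posterior is N(mu, Gamma) with
#   Gamma = (X'X / sigma^2 + b I)^{-1},   mu = Gamma X'y / sigma^2.
# The object keeps the precision matrix and its eigendecomposition as the
# working representation: one symmetric eigendecomposition per update serves
# the coefficient summaries, the MINE criterion and all four design
# generators, and stays accurate in the rank-deficient n << p regime where
# X'X alone is singular.

new_ensemble_posterior <- function(prec, Xty, n_obs, sigma, b) {
  eig <- eigen((prec + t(prec)) / 2, symmetric = TRUE)
  if (any(eig$values <= 0)) {
    # Extreme dynamic range (long runs past n ~ p) can push the smallest
    # eigenvalues below zero numerically although the precision is PD by
    # construction. Regularize with a relative jitter; only failure after
    # the jitter is a genuine degeneracy.
    jitter <- 1e-12 * sum(diag(prec)) / nrow(prec)
    eig$values <- eig$values + jitter
  }
  if (any(eig$values <= 0))
    stop_input("posterior precision is not positive definite even after ",
               "jitter regularization; check sigma and b")
  w <- crossprod(eig$vectors, Xty)[, 1L] / eig$values
  mu <- as.vector(eig$vectors %*% w)
  structure(
    list(mu = mu, prec = prec, Xty = Xty, eig = eig,
         n_obs = as.integer(n_obs), sigma = sigma, b = b),
    class = "ensemble_posterior")
}

#' Fit the Gaussian ensemble posterior for the linear model
#'
#' Computes the exact conjugate posterior over the regression coefficients
#' of \eqn{y = X\beta + \epsilon}, \eqn{\epsilon \sim N(0,\sigma^2 I)}, under
#' the prior \eqn{\beta \sim N(0, b^{-1} I)}:
#' \deqn{\Gamma = (X'X/\sigma^2 + bI)^{-1}, \qquad \mu = \Gamma X'y/\sigma^2.}
#' The posterior is well defined for any number of observations, including
#' \eqn{n = 0} (pure prior, \eqn{\mu = 0}, \eqn{\Gamma = b^{-1} I}) and the
#' rank-deficient \eqn{n < p} regime where ordinary least squares fails.
#'
#' @param data observations so far: a data frame with predictor columns
#'   followed by a response column named `y`, a list with elements `X`
#'   (n-by-p matrix) and `y` (length-n vector), or `NULL` for no data
#'   (then `p` is required).
#' @param sigma known error standard deviation (> 0).
#' @param b prior precision scale (> 0); the prior standard deviation of
#'   every coefficient is `1/sqrt(b)`. See [choose_b()].
#' @param p number of coefficients; required when `data` is `NULL` or empty,
#'   otherwise inferred (and checked) from the data.
#' @return An object of class `ensemble_posterior` with elements `mu`
#'   (posterior mean), `n_obs`, `sigma`, `b`, the precision matrix and its
#'   eigendecomposition. Use [posterior_covariance()] for the dense
#'   \eqn{\Gamma}, [tidy()] for a per-coefficient tibble.
#' @examples
#' post <- fit_posterior(list(X = matrix(c(1, 0), 1), y = 1),
#'                       sigma = 1, b = 1)
#' post$mu                        # (0.5, 0)
#' posterior_covariance(post)     # diag(1/2, 1)
#' @seealso [update_posterior()], [significance_test()], [next_design()]
#' @export
fit_posterior <- function(data, sigma, b, p = NULL) {
  sigma <- check_scalar_pos(sigma, "sigma")
  b <- check_scalar_pos(b, "b")
  ds <- as_dataset(data, p = p)
  X <- ds$X
  y <- ds$y
  p <- ncol(X)
  prec <- diag(b, p)
  Xty <- numeric(p)
  if (nrow(X) > 0) {
    prec <- prec + crossprod(X) / sigma^2
    Xty <- as.vector(crossprod(X, y)) / sigma^2
  }
  new_ensemble_posterior(prec, Xty, nrow(X), sigma, b)
}

#' Add a batch of observations to an ensemble posterior
#'
#' Sequential (batch) update of the conjugate posterior; the result is
#' identical to refitting on all data at once.
#'
#' @param post an `ensemble_posterior`.
#' @param new_X matrix of new design rows (d-by-p); a vector is taken as a
#'   single row.
#' @param new_y length-d response vector.
#' @return The updated `ensemble_posterior` with `n_obs` incremented by `d`.
#' @export
update_posterior <- function(post, new_X, new_y) {
  stopifnot(inherits(post, "ensemble_posterior"))
  if (is.null(dim(new_X))) new_X <- matrix(new_X, nrow = 1L)
  new_X <- check_matrix_finite(new_X, "new_X")
  new_y <- as.numeric(new_y)
  if (!all(is.finite(new_y))) stop_input("`new_y` contains non-finite entries")
  if (nrow(new_X) != length(new_y))
    stop_input("`new_X` has ", nrow(new_X), " rows but `new_y` has length ",
               length(new_y))
  if (nrow(new_X) == 0L) return(post)
  p <- length(post$mu)
  if (ncol(new_X) != p)
    stop_input("`new_X` has ", ncol(new_X), " columns; posterior has p = ", p)
  prec <- post$prec + crossprod(new_X) / post$sigma^2
  Xty <- post$Xty + as.vector(crossprod(new_X, new_y)) / post$sigma^2
  new_ensemble_posterior(prec, Xty, post$n_obs + nrow(new_X),
                         post$sigma, post$b)
}

#' Posterior covariance matrix of the coefficients
#'
#' @param post an `ensemble_posterior`.
#' @return The dense p-by-p symmetric positive-definite matrix \eqn{\Gamma}.
#' @export
posterior_covariance <- function(post) {
  stopifnot(inherits(post, "ensemble_posterior"))
  V <- post$eig$vectors
  G <- V %*% (t(V) / post$eig$values)
  (G + t(G)) / 2
}

#' Posterior variances (diagonal of Gamma)
#'
#' @param post an `ensemble_posterior`.
#' @return Length-p vector of per-coefficient posterior variances.
#' @export
posterior_variances <- function(post) {
  stopifnot(inherits(post, "ensemble_posterior"))
  as.vector(post$eig$vectors^2 %*% (1 / post$eig$values))
}

#' @export
print.ensemble_posterior <- function(x, ...) {
  cat("<ensemble_posterior>  p =", length(x$mu), " n_obs =", x$n_obs,
      " sigma =", format(x$sigma), " b =", format(x$b), "\n")
  cat("  prior sd 1/sqrt(b) =", format(1 / sqrt(x$b)),
      "; max |mu| =", format(max(abs(x$mu))), "\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up decisions
#'
#' Classic step-up false-discovery-rate control: sort the p-values
#' ascending, find the largest k with \eqn{p_{(k)} \le k\alpha/m}, and
#' reject those k hypotheses. Implemented through BH-adjusted p-values
#' ([stats::p.adjust()]), which is algebraically the same rule.
#'
#' @param pvals vector of p-values in \[0, 1\].
#' @param alpha FDR level in (0, 1).
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @examples
#' bh_stepup(c(0.01, 0.011, 0.9, 0.9), 0.05)  # TRUE TRUE FALSE FALSE
#' @export
bh_stepup <- function(pvals, alpha) {
  if (length(pvals) == 0L) return(logical(0))
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_input("`pvals` must lie in [0, 1]")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_input("`alpha` must be in (0, 1)")
  p.adjust(pvals, method = "BH") <= alpha
}

#' Coefficient significance under the ensemble posterior
#'
#' For each coefficient, the z-value is the posterior mean divided by the
#' posterior standard deviation (the square root of the diagonal of
#' \eqn{\Gamma}); two-sided p-values use the standard normal (the error
#' variance is known, so no t correction), and discoveries are declared by
#' the Benjamini-Hochberg step-up rule at level `alpha`.
#'
#' @param post an `ensemble_posterior`.
#' @param alpha FDR level in (0, 1); the study default is 0.01.
#' @return A tibble of class `mine_significance` with columns `index`,
#'   `mu`, `sd`, `z`, `pval`, `significant`, and attribute `alpha`.
#' @export
significance_test <- function(post, alpha = 0.01) {
  stopifnot(inherits(post, "ensemble_posterior"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_input("`alpha` must be in (0, 1)")
  v <- posterior_variances(post)
  if (any(v <= 0))
    stop_input("non-positive posterior variance encountered (numerical ",
               "degeneracy at coefficient ", which(v <= 0)[1L], ")")
  sd <- sqrt(v)
  z <- post$mu / sd
  pval <- 2 * pnorm(-abs(z))
  out <- tibble::tibble(
    index = seq_along(z), mu = post$mu, sd = sd, z = z, pval = pval,
    significant = bh_stepup(pval, alpha))
  attr(out, "alpha") <- alpha
  class(out) <- c("mine_significance", class(out))
  out
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy per-coefficient summary of an ensemble posterior
#'
#' @param x an `ensemble_posterior`.
#' @param alpha optional FDR level; when supplied the significance columns
#'   of [significance_test()] are included.
#' @param ... unused.
#' @return A tibble with one row per coefficient.
#' @export
tidy.ensemble_posterior <- function(x, alpha = NULL, ...) {
  if (!is.null(alpha)) {
    out <- significance_test(x, alpha)
    class(out) <- setdiff(class(out), "mine_significance")
    return(out)
  }
  tibble::tibble(index = seq_along(x$mu), mu = x$mu,
                 sd = sqrt(posterior_variances(x)))
}

#' One-row summary of an ensemble posterior
#'
#' @param x an `ensemble_posterior`.
#' @param ... unused.
#' @return A one-row tibble with `p`, `n_obs`, `sigma`, `b`, the largest and
#'   smallest eigenvalues of \eqn{\Gamma} and the count of unexplored
#'   (prior-level) eigendirections.
#' @export
glance.ensemble_posterior <- function(x, ...) {
  lam_gamma <- rev(1 / x$eig$values)   # descending for Gamma
  tibble::tibble(
    p = length(x$mu), n_obs = x$n_obs, sigma = x$sigma, b = x$b,
    gamma_eigen_max = lam_gamma[1L],
    gamma_eigen_min = lam_gamma[length(lam_gamma)],
    n_unexplored = sum(lam_gamma[1L] - lam_gamma <= 1e-8 * lam_gamma[1L]))
}
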