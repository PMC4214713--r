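# The MINE design criterion.
#
# For a candidate next-experiment batch X_new (d rows), the predicted
# responses X_new beta have covariance D = X_new Gamma X_new' across the
# ensemble. Normalizing D to a correlation matrix R, the criterion is
#   Psi = det R  in [0, 1],
# the squared volume of the prism spanned by the normalized predictions:
# Psi = 1 exactly when the predictions are uncorrelated, 0 when they are
# linearly dependent. By the Hadamard inequality det D <= prod(diag D), Psi
# equals the ratio det(D)/prod(diag D), a scale-free dependence measure.

#' Construct a design batch
#'
#' A design batch is the d-by-p matrix of planned observation rows for the
#' next experiment, with provenance attributes.
#'
#' @param rows d-by-p numeric matrix (a vector is one row); rows must be
#'   finite and no row may be identically zero (a zero row has zero
#'   prediction variance and the criterion is undefined).
#' @param method label of the generating method (see [next_design()]).
#' @param experiment_index integer position of this batch in the study.
#' @param seed seed used to generate the batch, if any.
#' @return The matrix with class `design_batch` and provenance attributes.
#' @export
design_batch <- function(rows, method = "manual", experiment_index = NA_integer_,
                         seed = NA_integer_) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  rows <- check_matrix_finite(rows, "rows")
  if (nrow(rows) < 1L) stop_input("a design batch needs at least one row")
  norms <- sqrt(rowSums(rows^2))
  if (any(norms == 0))
    stop_input("design row ", which(norms == 0)[1L], " is identically zero")
  structure(rows, class = c("design_batch", "matrix", "array"),
            method = method,
            experiment_index = as.integer(experiment_index),
            seed = seed)
}

#' @export
print.design_batch <- function(x, ...) {
  cat("<design_batch> ", nrow(x), "x", ncol(x),
      " method =", attr(x, "method"), "\n")
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE], 4L))
  if (nrow(x) > 4L || ncol(x) > 8L) cat("  ...\n")
  invisible(x)
}

batch_rows <- function(batch) {
  if (inherits(batch, "design_batch")) unclass(batch)
  else check_matrix_finite(batch, "batch")
}

#' Ensemble covariance of the predicted responses
#'
#' Computes \eqn{D = X_{new} \Gamma X_{new}'}, the d-by-d covariance matrix
#' of the predicted responses of the candidate batch across the current
#' posterior ensemble.
#'
#' @param post an `ensemble_posterior`.
#' @param batch a [design_batch()] or plain d-by-p matrix.
#' @return Symmetric positive-semidefinite d-by-d matrix.
#' @export
prediction_covariance <- function(post, batch) {
  stopifnot(inherits(post, "ensemble_posterior"))
  rows <- batch_rows(batch)
  if (ncol(rows) != length(post$mu))
    stop_input("batch has ", ncol(rows), " columns; posterior has p = ",
               length(post$mu))
  # D = (X V) diag(1/lambda) (X V)': PSD by construction.
  B <- rows %*% post$eig$vectors
  B <- B * rep(1 / sqrt(post$eig$values), each = nrow(B))
  D <- tcrossprod(B)
  (D + t(D)) / 2
}

#' Correlation matrix from a covariance matrix
#'
#' @param D symmetric positive-semidefinite matrix with strictly positive
#'   diagonal.
#' @return The correlation matrix \eqn{R_{ij} = D_{ij}/\sqrt{D_{ii}D_{jj}}}.
#' @export
correlation_from_covariance <- function(D) {
  D <- check_matrix_finite(D, "D")
  dg <- diag(D)
  if (any(dg <= 0))
    stop_input("degenerate prediction: non-positive variance at row ",
               which(dg <= 0)[1L],
               " (a design row with zero prediction variance?)")
  s <- 1 / sqrt(dg)
  R <- D * tcrossprod(s)
  diag(R) <- 1
  R
}

# Determinant of a symmetric PSD matrix via Cholesky; falls back to an
# eigenvalue product with negative eigenvalues clipped to zero when the
# matrix is numerically semidefinite (the near-linear-dependence regime the
# criterion is designed to flag).
det_psd <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) return(prod(diag(ch))^2)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < 1e-12 * max(ev, 0))) return(0)
  prod(pmax(ev, 0))
}

#' The MINE design criterion
#'
#' \eqn{\Psi = \det R}, the determinant of the correlation matrix of the
#' predicted responses of the candidate batch under the current ensemble.
#' \eqn{\Psi \in [0,1]}; it equals 1 exactly when the predictions are
#' mutually uncorrelated (the maximally informative case) and 0 when they
#' are linearly dependent. The criterion is scale-free: rescaling any design
#' row by a positive constant leaves it unchanged.
#'
#' @inheritParams prediction_covariance
#' @return The criterion value, a number in \[0, 1\].
#' @examples
#' post <- fit_posterior(NULL, sigma = 1, b = 1, p = 3)
#' psi_mine(post, design_batch(diag(3)))      # orthonormal rows: 1
#' psi_mine(post, design_batch(rbind(c(1,0,0), c(1,0,0))))  # duplicated: 0
#' @export
psi_mine <- function(post, batch) {
  D <- prediction_covariance(post, batch)
  R <- correlation_from_covariance(D)
  min(max(det_psd(R), 0), 1)
}

#' Hadamard dependence ratio of a prediction covariance
#'
#' \eqn{\det D / \prod_i D_{ii}}, the ratio bounded by 1 through the
#' Hadamard inequality; algebraically identical to the MINE criterion of the
#' same covariance.
#'
#' @param D symmetric PSD matrix with positive diagonal.
#' @return A number in \[0, 1\].
#' @export
hadamard_gap <- function(D) {
  D <- check_matrix_finite(D, "D")
  dg <- diag(D)
  if (any(dg <= 0))
    stop_input("degenerate prediction: non-positive variance at row ",
               which(dg <= 0)[1L])
  min(max(det_psd(D) / prod(dg), 0), 1)
}
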