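# Next-experiment construction.
#
# Theorem underpinning all standardized methods: if the rows of X_new are
# S u_1, ..., S u_d with {u_i} any orthonormal set and S the inverse
# symmetric square root of Gamma, then X_new Gamma X_new' = I_d, every
# prediction has unit ensemble variance and zero correlation, and the MINE
# criterion attains its maximum Psi = 1. The four methods differ in which
# orthonormal set they pick and whether they standardize:
#   mine_like       top-d eigenvectors of Gamma, unstandardized;
#   mine            the same eigenvectors, standardized by S;
#   random_basis    a fresh Haar-random orthonormal set, standardized;
#   random_rotation a random rotation of the degenerate (unexplored,
#                   prior-level) eigenspace of Gamma, standardized.
# Randomness is drawn from R's global RNG; callers seed it (the simulation
# harness manages named substreams).

#' Random pilot design
#'
#' The initial experiment, generated before any model-guided design is
#' possible: an n0-by-p matrix of i.i.d. Uniform(0, 10)/p entries (neither
#' normalized nor orthogonalized). When `n0` is missing, the sizing rule is
#' 10 observations for p > 50, otherwise a uniformly drawn size in 5..9.
#'
#' @param p number of coefficients.
#' @param n0 number of pilot observations; default per the sizing rule.
#' @return A [design_batch()] with method `"pilot"`.
#' @export
pilot_design <- function(p, n0 = NULL) {
  p <- check_count(p, "p")
  if (is.null(n0)) n0 <- if (p > 50L) 10L else sample(5:9, 1L)
  n0 <- check_count(n0, "n0")
  rows <- matrix(runif(n0 * p, 0, 10) / p, nrow = n0, ncol = p)
  design_batch(rows, method = "pilot", experiment_index = 0L)
}

#' Modified Gram-Schmidt orthonormalization
#'
#' Orthonormalizes the rows of a matrix by the modified Gram-Schmidt
#' algorithm (each vector is projected against the already-orthonormalized
#' ones sequentially, for numerical stability). The row span is preserved
#' and the first output row is the normalized first input row.
#'
#' @param vectors k-by-p matrix with numerically independent rows.
#' @return k-by-p matrix with orthonormal rows.
#' @export
modified_gram_schmidt <- function(vectors) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L)
  M <- check_matrix_finite(vectors, "vectors")
  k <- nrow(M)
  Q <- M
  for (i in seq_len(k)) {
    v <- Q[i, ]
    orig <- sqrt(sum(v^2))
    if (i > 1L) for (j in seq_len(i - 1L)) v <- v - sum(Q[j, ] * v) * Q[j, ]
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || orig == 0 || nv < 1e-12 * orig)
      stop_input("row ", i, " is numerically linearly dependent on the ",
                 "preceding rows")
    Q[i, ] <- v / nv
  }
  Q
}

#' Haar-random orthonormal set
#'
#' Draws d orthonormal p-vectors uniformly (Haar) by generating i.i.d.
#' standard Gaussian vectors — the first is simply normalized — and
#' orthonormalizing with modified Gram-Schmidt.
#'
#' @param p ambient dimension.
#' @param d number of vectors (d <= p).
#' @return d-by-p matrix with orthonormal rows.
#' @export
random_orthonormal_set <- function(p, d) {
  p <- check_count(p, "p"); d <- check_count(d, "d")
  if (d > p) stop_input("cannot draw ", d, " orthonormal vectors in ",
                        "dimension ", p)
  modified_gram_schmidt(matrix(rnorm(d * p), nrow = d, ncol = p))
}

# Deterministic sign convention: first component that is non-negligible
# relative to the vector's largest entry is made positive. Keeps
# eigenvector output stable across linear-algebra backends.
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    i <- which(abs(v) > 1e-8 * max(abs(v)))[1L]
    if (v[i] < 0) V[, j] <- -v
  }
  V
}

new_eigen_structure <- function(values, vectors, tie_tol) {
  ord <- order(values, decreasing = TRUE)
  values <- values[ord]
  vectors <- fix_signs(vectors[, ord, drop = FALSE])
  structure(
    list(eigenvalues = values, eigenvectors = vectors,
         degenerate_count = sum(values[1L] - values <= tie_tol * values[1L]),
         tie_tol = tie_tol),
    class = "eigen_structure")
}

#' Eigenstructure of a posterior covariance
#'
#' Descending eigendecomposition with detection of the degenerate
#' (unexplored) leading eigenspace: the set of eigenvalues tied with the
#' maximum within a relative tolerance. For the prior-only covariance
#' \eqn{b^{-1} I} every direction is degenerate; each informative
#' observation removes (up to) one direction from the degenerate set.
#'
#' @param Gamma symmetric positive-definite matrix.
#' @param tie_tol relative tolerance for an eigenvalue to count as tied with
#'   the maximum (default 1e-8, i.e. machine-precision ties).
#' @return An object of class `eigen_structure`: `eigenvalues`
#'   (non-increasing), `eigenvectors` (orthonormal columns, deterministic
#'   sign convention), `degenerate_count`.
#' @export
eigen_structure <- function(Gamma, tie_tol = 1e-8) {
  Gamma <- check_matrix_finite(Gamma, "Gamma")
  if (nrow(Gamma) != ncol(Gamma)) stop_input("`Gamma` must be square")
  asym <- max(abs(Gamma - t(Gamma)))
  if (asym > 1e-8 * max(abs(Gamma)))
    stop_input("`Gamma` is not symmetric (max asymmetry ", format(asym), ")")
  e <- eigen((Gamma + t(Gamma)) / 2, symmetric = TRUE)
  new_eigen_structure(e$values, e$vectors, tie_tol)
}

# Gamma-eigenstructure straight from a posterior's precision
# eigendecomposition: Gamma and the precision share eigenvectors, with
# reciprocal eigenvalues in reverse order. Avoids a second O(p^3) pass.
posterior_eigen_structure <- function(post, tie_tol = 1e-8) {
  idx <- rev(seq_along(post$eig$values))
  new_eigen_structure(1 / post$eig$values[idx],
                      post$eig$vectors[, idx, drop = FALSE], tie_tol)
}

#' @export
print.eigen_structure <- function(x, ...) {
  cat("<eigen_structure> p =", length(x$eigenvalues),
      " lambda_max =", format(x$eigenvalues[1L]),
      " degenerate =", x$degenerate_count, "\n")
  invisible(x)
}

#' Inverse symmetric square root of an SPD matrix
#'
#' Returns the symmetric \eqn{S = \Gamma^{-1/2}} with
#' \eqn{S \Gamma S = I}, computed from the eigendecomposition. This is the
#' standardization map of the criterion-maximizing construction: applied to
#' any orthonormal set it produces design rows whose predicted responses are
#' uncorrelated with unit ensemble variance.
#'
#' @param Gamma symmetric positive-definite matrix.
#' @return Symmetric p-by-p matrix \eqn{\Gamma^{-1/2}}.
#' @export
inv_sqrt <- function(Gamma) {
  es <- if (inherits(Gamma, "eigen_structure")) Gamma
        else eigen_structure(Gamma)
  lam <- es$eigenvalues
  if (lam[length(lam)] < 1e-14 * lam[1L])
    stop_input("matrix is numerically singular (condition number > 1e14); ",
               "cannot form the inverse square root")
  V <- es$eigenvectors
  S <- V %*% (t(V) / sqrt(lam))
  (S + t(S)) / 2
}

# Apply S = Gamma^{-1/2} to the rows of U using the posterior's cached
# eigenstructure: U S = (U V) diag(lambda^{-1/2}) V'.
standardize_rows <- function(U, es) {
  B <- U %*% es$eigenvectors
  B <- B * rep(1 / sqrt(es$eigenvalues), each = nrow(B))
  B %*% t(es$eigenvectors)
}

#' Generate the next experiment under a MINE design method
#'
#' Constructs the d-row design batch for the next experiment from the
#' current posterior, under one of the four strategies:
#' \describe{
#'   \item{`mine_like`}{the d eigenvectors of \eqn{\Gamma} with the largest
#'     eigenvalues, used as unit-norm rows without standardization.}
#'   \item{`mine`}{the same eigenvectors standardized by
#'     \eqn{S = \Gamma^{-1/2}} (for an eigenvector \eqn{v_i} this is
#'     \eqn{v_i/\sqrt{\lambda_i}}).}
#'   \item{`random_basis`}{a fresh Haar-random orthonormal set, standardized
#'     by \eqn{S}.}
#'   \item{`random_rotation`}{a Haar-random rotation applied to the
#'     degenerate (unexplored) leading eigenspace of \eqn{\Gamma}; the first
#'     d rotated vectors are standardized by \eqn{S}. If fewer than d
#'     directions are degenerate, the remainder is filled with the
#'     next-largest standardized eigenvectors in eigenvalue order.}
#' }
#' The three standardized methods achieve the criterion maximum
#' \eqn{\Psi = 1} exactly (prediction covariance \eqn{I_d}).
#'
#' @param post an `ensemble_posterior`.
#' @param d number of observations in the next experiment (d <= p).
#' @param method one of `"mine_like"`, `"mine"`, `"random_basis"`,
#'   `"random_rotation"`.
#' @param tie_tol relative eigenvalue tie tolerance defining the degenerate
#'   set for `random_rotation`.
#' @param experiment_index optional provenance index stored on the batch.
#' @return A [design_batch()].
#' @export
next_design <- function(post, d,
                        method = c("mine_like", "mine", "random_basis",
                                   "random_rotation"),
                        tie_tol = 1e-8, experiment_index = NA_integer_) {
  stopifnot(inherits(post, "ensemble_posterior"))
  method <- match.arg(method)
  p <- length(post$mu)
  d <- check_count(d, "d")
  if (d > p) stop_input("d = ", d, " exceeds p = ", p)
  es <- posterior_eigen_structure(post, tie_tol)

  rows <- switch(method,
    mine_like = ,
    mine = {
      # Within numerically tied eigenvalues the eigensolver's basis (and
      # order) is arbitrary but deterministic for a fixed input; it is kept
      # as returned. The paper's account of these methods treats exactly
      # this machine-precision arbitrariness as their implicit randomizer.
      top <- seq_len(d)
      U <- t(es$eigenvectors[, top, drop = FALSE])
      if (method == "mine")
        U / sqrt(es$eigenvalues[top])   # S v_i = v_i / sqrt(lambda_i)
      else U
    },
    random_basis = standardize_rows(random_orthonormal_set(p, d), es),
    random_rotation = {
      g <- es$degenerate_count
      k <- min(d, g)
      # First k rows of a Haar-random g x g rotation, applied to the
      # degenerate eigenvector set.
      Q <- random_orthonormal_set(g, k)
      W <- Q %*% t(es$eigenvectors[, seq_len(g), drop = FALSE])
      rot <- standardize_rows(W, es)
      if (g < d) {
        extra <- (g + 1L):d
        pad <- t(es$eigenvectors[, extra, drop = FALSE]) /
          sqrt(es$eigenvalues[extra])
        rot <- rbind(rot, pad)
      }
      rot
    })
  design_batch(rows, method = method, experiment_index = experiment_index)
}
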