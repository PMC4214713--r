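# Design construction: pilots, Gram-Schmidt, eigenstructure, inverse square
# root, and the four next-experiment methods.

test_that("pilot design follows the sizing rule and entry distribution", {
  set.seed(31)
  big <- pilot_design(1000)
  expect_equal(dim(big), c(10L, 1000L))
  expect_true(all(big >= 0 & big <= 10 / 1000))
  expect_equal(attr(big, "method"), "pilot")

  sizes <- replicate(20, nrow(pilot_design(20)))
  expect_true(all(sizes >= 5 & sizes <= 9))

  set.seed(99); a <- pilot_design(30)
  set.seed(99); b <- pilot_design(30)
  expect_identical(a, b)

  expect_equal(nrow(pilot_design(100, n0 = 4)), 4L)
})

test_that("modified Gram-Schmidt orthonormalizes and preserves the span", {
  U <- diag(3)[1:2, ]
  expect_equal(modified_gram_schmidt(U), U, tolerance = 1e-12)
  expect_equal(modified_gram_schmidt(rbind(c(1, 0, 0), c(1, 1, 0))),
               rbind(c(1, 0, 0), c(0, 1, 0)))

  set.seed(32)
  M <- matrix(rnorm(8 * 50), 8, 50)
  Q <- modified_gram_schmidt(M)
  expect_lt(max(abs(tcrossprod(Q) - diag(8))), 1e-10)
  # first output row is the normalized first input row
  expect_equal(Q[1, ], M[1, ] / sqrt(sum(M[1, ]^2)))
  # span check via projector difference, projector oracle from QR
  P_qr <- function(A) { q <- qr.Q(qr(t(A))); tcrossprod(q) }
  expect_lt(max(abs(P_qr(M) - P_qr(Q))), 1e-8)

  expect_error(modified_gram_schmidt(rbind(c(1, 0), c(2, 0))), "row 2")
})

test_that("random orthonormal sets are orthonormal and sphere-uniform", {
  set.seed(33)
  v <- random_orthonormal_set(7, 1)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)

  Q <- random_orthonormal_set(3, 3)
  expect_equal(abs(det(Q)), 1, tolerance = 1e-10)
  expect_lt(max(abs(tcrossprod(Q) - diag(3))), 1e-10)

  # E <v, e1>^2 = 1/p for Haar vectors
  m <- mean(replicate(2000, random_orthonormal_set(10, 1)[1]^2))
  expect_equal(m, 0.1, tolerance = 0.1)  # 0.1 +/- 0.01 absolute
  expect_lt(abs(m - 0.1), 0.01)

  expect_error(random_orthonormal_set(3, 4), "dimension")
})

test_that("eigenstructure sorts, reconstructs, and counts degeneracy", {
  # prior-only covariance: every direction degenerate
  p0 <- fit_posterior(NULL, 1, 0.5, p = 6)
  es0 <- eigen_structure(posterior_covariance(p0))
  expect_equal(es0$degenerate_count, 6L)

  es1 <- eigen_structure(diag(c(2, 1, 1, 1)), tie_tol = 1e-8)
  expect_equal(es1$degenerate_count, 1L)
  expect_equal(es1$eigenvalues, c(2, 1, 1, 1))

  # one observation along e1 leaves p-1 directions at the prior level
  p1 <- update_posterior(fit_posterior(NULL, 1, 0.5, p = 6),
                         diag(6)[1, , drop = FALSE], 0.3)
  es2 <- eigen_structure(posterior_covariance(p1))
  expect_equal(es2$degenerate_count, 5L)

  set.seed(34)
  G <- random_spd(9)
  es <- eigen_structure(G)
  expect_true(all(diff(es$eigenvalues) <= 0))
  rec <- es$eigenvectors %*% (t(es$eigenvectors) * es$eigenvalues)
  expect_lt(norm(G - rec, "F") / norm(G, "F"), 1e-8)
  expect_error(eigen_structure(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("inv_sqrt satisfies S Gamma S = I and is symmetric", {
  expect_equal(inv_sqrt(diag(3)), diag(3))
  expect_equal(inv_sqrt(diag(c(4, 1))), diag(c(1 / 2, 1)))
  set.seed(35)
  G <- random_spd(12)
  S <- inv_sqrt(G)
  expect_equal(S, t(S))
  expect_lt(norm(S %*% G %*% S - diag(12), "F"), 1e-8)
  expect_error(inv_sqrt(diag(c(1, 1e-15))), "singular")
})

test_that("the four methods produce their defining batches", {
  # prior-only posterior: MINE rows have norm sqrt(b)
  b <- 0.04
  post <- fit_posterior(NULL, sigma = 1, b = b, p = 8)
  set.seed(36)
  bt <- next_design(post, 3, "mine")
  expect_equal(sqrt(rowSums(bt^2)), rep(sqrt(b), 3), tolerance = 1e-10)

  # mine_like on diagonal Gamma: top eigenvectors are unit coordinate rows
  post_d <- posterior_with_gamma(diag(c(3, 2, 1)))
  ml <- next_design(post_d, 2, "mine_like")
  expect_equal(abs(unclass(ml)), diag(3)[1:2, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sqrt(rowSums(ml^2)), c(1, 1))

  # standardized methods hit prediction covariance I_d and psi = 1
  set.seed(37)
  post_r <- posterior_with_gamma(random_spd(15))
  for (m in c("mine", "random_basis", "random_rotation")) {
    bt <- next_design(post_r, 5, m)
    D <- prediction_covariance(post_r, bt)
    expect_lt(max(abs(D - diag(5))), 1e-6)
    expect_equal(psi_mine(post_r, bt), 1, tolerance = 1e-6)
    expect_equal(attr(bt, "method"), m)
  }
  expect_error(next_design(post_r, 20, "mine"), "exceeds")
  expect_error(next_design(post_r, 2, "nonsense"))
})

test_that("random rotation pads with standardized eigenvectors when the
           degenerate space is smaller than d", {
  # strong data on 3 of 4 coordinates: only e4 remains at the prior level
  post <- fit_posterior(list(X = 10 * diag(4)[1:3, ], y = rep(0, 3)),
                        sigma = 0.1, b = 1)
  es <- eigen_structure(posterior_covariance(post))
  expect_equal(es$degenerate_count, 1L)
  set.seed(38)
  bt <- next_design(post, 3, "random_rotation")
  expect_equal(nrow(bt), 3L)
  # first row spans the degenerate direction e4 (standardized)
  expect_equal(abs(unclass(bt)[1, 4]) / sqrt(sum(bt[1, ]^2)), 1,
               tolerance = 1e-8)
  # batch still maximizes the criterion
  expect_lt(max(abs(prediction_covariance(post, bt) - diag(3))), 1e-6)
})

test_that("mine reduces to standardized mine_like in the seeded degenerate
           case and no NaN propagates over long runs", {
  # prior-only: degenerate count = p >= d; rows of mine equal rows of
  # mine_like scaled by sqrt(b)
  post <- fit_posterior(NULL, sigma = 1, b = 0.25, p = 6)
  ml <- next_design(post, 4, "mine_like")
  mn <- next_design(post, 4, "mine")
  expect_equal(unclass(mn), unclass(ml) * sqrt(0.25), tolerance = 1e-10,
               ignore_attr = TRUE)

  # 100 sequential experiments at p=100 stay finite. Note the eigenvector
  # batch keeps psi = 1 whether standardized or not (eigenvectors
  # diagonalize the prediction covariance); mine_like differs from mine in
  # the information scale of its rows, not in the criterion of the batch.
  truth <- make_fixture(p = 100, n_nonzero = 5, scale = 20, seed = 4,
                        sigma = 0.05, d = 5, n_experiments = 100,
                        pilot_size = 10)
  tr <- run_replicate(truth, "mine_like", replicate = 1)
  expect_true(all(is.finite(tr$psi)))
  expect_true(all(is.finite(unlist(tr$mu_tracked))))
  expect_equal(tr$psi, rep(1, 100), tolerance = 1e-6)
})
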