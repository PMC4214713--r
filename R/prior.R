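# Prior precision scale selection.
#
# The prior beta ~ N(0, (1/b) I) acts like a fishing-net: its standard
# deviation 1/sqrt(b) must be wide enough that the true coefficients are not
# far out in the tails, or the posterior will never reach them. The binding
# constraint is 1/sqrt(b) >= max |beta|; the looser requirement that
# uncertainty with data never exceed prior uncertainty
# (1/sqrt(lambda_i + b) <= 1/sqrt(b) per eigendirection of X'X) holds
# automatically since eigenvalues of X'X are non-negative.

#' Choose the prior precision scale from the anticipated coefficient size
#'
#' Sets \eqn{b = 1/\beta_{max}^2} so that the prior standard deviation
#' \eqn{1/\sqrt{b}} equals the largest anticipated coefficient magnitude
#' (e.g. \eqn{\beta_{max} = 50} gives \eqn{b = 4\times 10^{-4}}).
#'
#' @param beta_max_magnitude largest anticipated absolute value of any
#'   regression coefficient (> 0).
#' @return The prior precision scale `b`.
#' @export
choose_b <- function(beta_max_magnitude) {
  beta_max_magnitude <- check_scalar_pos(beta_max_magnitude,
                                         "beta_max_magnitude")
  1 / beta_max_magnitude^2
}

#' Diagnostics for a prior precision scale against data and truth scale
#'
#' Checks the two constraints on `b`: data dominance (per eigendirection of
#' \eqn{X'X}, posterior uncertainty \eqn{1/\sqrt{\lambda_i + b}} does not
#' exceed prior uncertainty \eqn{1/\sqrt{b}} — always true since
#' \eqn{\lambda_i \ge 0}, asserted as a sanity invariant) and the tail bound
#' \eqn{1/\sqrt{b} \ge \beta_{max}} (the fishing-net condition; equality
#' passes, matching [choose_b()]).
#'
#' @param data observations accepted by [as_dataset()].
#' @param b prior precision scale.
#' @param beta_max_magnitude largest anticipated coefficient magnitude.
#' @param p number of coefficients if `data` is empty.
#' @return A one-row tibble of class `prior_diagnostics`: `b`, `lambda_max`
#'   (largest eigenvalue of \eqn{X'X}), `tail_bound_ok`,
#'   `data_dominance_ok`.
#' @export
check_prior <- function(data, b, beta_max_magnitude, p = NULL) {
  b <- check_scalar_pos(b, "b")
  beta_max_magnitude <- check_scalar_pos(beta_max_magnitude,
                                         "beta_max_magnitude")
  ds <- as_dataset(data, p = p)
  lam <- if (nrow(ds$X) == 0L) 0 else {
    eigen(crossprod(ds$X), symmetric = TRUE, only.values = TRUE)$values
  }
  out <- tibble::tibble(
    b = b,
    lambda_max = max(lam, 0),
    tail_bound_ok = 1 / sqrt(b) >= beta_max_magnitude,
    data_dominance_ok = all(1 / sqrt(pmax(lam, 0) + b) <= 1 / sqrt(b) + 1e-12))
  class(out) <- c("prior_diagnostics", class(out))
  out
}
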