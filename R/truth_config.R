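# Study configuration: the generative ground truth for simulation.

#' Define the ground truth for a simulated sequential-design study
#'
#' @param p number of regression coefficients.
#' @param beta_true length-p true coefficient vector.
#' @param sigma error standard deviation (> 0).
#' @param b prior precision scale (> 0); see [choose_b()].
#' @param d observations per designed experiment (1 <= d <= p).
#' @param n_experiments number of designed experiments after the pilot.
#' @param pilot_size number of pilot observations; `NULL` applies the
#'   sizing rule of [pilot_design()] (10 when p > 50, else a random 5..9).
#' @param alpha Benjamini-Hochberg FDR level in (0, 1).
#' @param seed study seed; every substream (pilot, noise, method draws)
#'   derives from it.
#' @return A validated list of class `truth_config`.
#' @export
truth_config <- function(p, beta_true, sigma, b, d = 10L,
                         n_experiments = 30L, pilot_size = NULL,
                         alpha = 0.01, seed = 1L) {
  p <- check_count(p, "p")
  beta_true <- as.numeric(beta_true)
  if (length(beta_true) != p)
    stop_input("`beta_true` has length ", length(beta_true), ", expected p = ",
               p)
  if (any(!is.finite(beta_true)))
    stop_input("`beta_true` contains non-finite entries")
  sigma <- check_scalar_pos(sigma, "sigma")
  b <- check_scalar_pos(b, "b")
  d <- check_count(d, "d")
  n_experiments <- check_count(n_experiments, "n_experiments")
  if (!is.null(pilot_size)) pilot_size <- check_count(pilot_size, "pilot_size")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_input("`alpha` must be in (0, 1)")
  seed <- check_count(seed, "seed", min = 0L)
  if (d > p) stop_input("d = ", d, " exceeds p = ", p)
  structure(
    list(p = p, beta_true = beta_true, sigma = sigma, b = b, d = d,
         n_experiments = n_experiments, pilot_size = pilot_size,
         alpha = alpha, seed = seed),
    class = "truth_config")
}

#' @export
print.truth_config <- function(x, ...) {
  nz <- sum(x$beta_true != 0)
  cat("<truth_config> p =", x$p, " nonzero =", nz, " sigma =", x$sigma,
      " b =", format(x$b), "\n  d =", x$d, " experiments =", x$n_experiments,
      " pilot =", x$pilot_size %||% "(rule)", " alpha =", x$alpha,
      " seed =", x$seed, "\n")
  invisible(x)
}

#' The reference high-dimensional study configuration
#'
#' The benchmark truth used throughout: p = 1000 coefficients of which the
#' first ten are nonzero (11, -36, -26, 9, 33, -50, -45, 15, 3, 17), error
#' sd `sigma` (default 0.01), batches of d = 10, a 10-observation pilot,
#' BH level 1%, and prior scale b = 1/2500 chosen by [choose_b()] from the
#' largest coefficient magnitude 50.
#'
#' @param sigma error standard deviation; 0.01, 0.05 and 0.10 are the
#'   studied noise levels.
#' @param n_experiments designed experiments after the pilot (default 99,
#'   bringing the total observation count to 10 + 99 x 10 = 1000).
#' @param seed study seed.
#' @return A [truth_config()].
#' @export
mine_preset <- function(sigma = 0.01, n_experiments = 99L, seed = 1L) {
  beta <- numeric(1000)
  beta[1:10] <- c(11, -36, -26, 9, 33, -50, -45, 15, 3, 17)
  truth_config(p = 1000L, beta_true = beta, sigma = sigma,
               b = choose_b(50), d = 10L, n_experiments = n_experiments,
               pilot_size = 10L, alpha = 0.01, seed = seed)
}

#' Deterministic sparse-truth fixture for small studies
#'
#' Builds a small study configuration mirroring the sparse structure of the
#' reference truth: `n_nonzero` leading nonzero coefficients with magnitudes
#' drawn in `[scale/10, scale]` and alternating-by-draw signs, the rest
#' exactly zero, with `b` set by [choose_b]`(scale)`.
#'
#' @param p number of coefficients.
#' @param n_nonzero number of truly nonzero coefficients (<= p).
#' @param scale largest anticipated coefficient magnitude.
#' @param seed seed controlling the magnitudes and signs (and stored as the
#'   study seed).
#' @param ... further arguments passed to [truth_config()] (`sigma`, `d`,
#'   `n_experiments`, `pilot_size`, `alpha`).
#' @return A [truth_config()].
#' @export
make_fixture <- function(p, n_nonzero, scale = 50, seed = 1L, ...) {
  p <- check_count(p, "p")
  n_nonzero <- check_count(n_nonzero, "n_nonzero", min = 0L)
  if (n_nonzero > p) stop_input("`n_nonzero` exceeds p")
  scale <- check_scalar_pos(scale, "scale")
  beta <- numeric(p)
  if (n_nonzero > 0L) {
    vals <- with_substream(derive_seed(seed, "fixture"), {
      mag <- runif(n_nonzero, scale / 10, scale)
      sgn <- rep_len(c(1, -1), n_nonzero) * sample(c(-1, 1), 1L)
      mag * sgn
    })
    beta[seq_len(n_nonzero)] <- vals
  }
  args <- modifyList(
    list(p = p, beta_true = beta, sigma = 0.01, b = choose_b(scale),
         d = min(10L, p), seed = seed),
    list(...))
  do.call(truth_config, args)
}

#' Read a study configuration from YAML or JSON
#'
#' Fields are those of [truth_config()]; `d` defaults to 10, `alpha` to
#' 0.01, and `pilot_size` to the sizing rule when omitted. Schema problems
#' are reported field by field.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated [truth_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  required <- c("p", "beta_true", "sigma", "b")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop_input("config is missing required field(s): ",
               paste(missing, collapse = ", "))
  allowed <- c(required, "d", "n_experiments", "pilot_size", "alpha", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop_input("config has unknown field(s): ",
               paste(unknown, collapse = ", "))
  defaults <- list(d = 10L, n_experiments = 30L, pilot_size = NULL,
                   alpha = 0.01, seed = 1L)
  args <- modifyList(defaults, cfg[lengths(cfg) > 0])
  do.call(truth_config, args)
}

#' Write a study configuration to YAML or JSON
#'
#' @param cfg a [truth_config()].
#' @param path destination ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
serialize_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "truth_config"))
  lst <- unclass(cfg)
  lst <- lst[!vapply(lst, is.null, TRUE)]
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}
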