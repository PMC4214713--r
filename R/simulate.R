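# Replicated sequential-design studies under a known truth.
#
# Replicate loop: a random pilot (shared across methods within a replicate),
# then n_experiments iterations of design -> response -> posterior update ->
# BH significance. The record at experiment e therefore reflects the pilot
# plus e designed batches (n = pilot + e*d observations).
#
# Unit convention. The study's prior scale b is expressed relative to the
# unscaled Gram matrix: the working posterior is
#   mu = (X'X + bI)^{-1} X'y,   Cov = sigma^2 (X'X + bI)^{-1},
# i.e. fit_posterior() is called with prior precision b/sigma^2. Designed
# batches are likewise scaled by sigma, which makes each planned
# observation's ensemble-prediction standard deviation equal to the
# measurement noise sigma (the rows are (X'X + bI)^{1/2} u for orthonormal
# u). The criterion is scale-free, so the batches remain exact maximizers
# (Psi = 1); the scaling only sets how much information one observation
# carries relative to the prior, which is what paces discovery.
#
# RNG discipline: two named substreams per replicate, both derived from the
# study seed -- a pilot stream keyed by (seed, replicate) only, so all
# methods see identical pilot data, and a method stream keyed by
# (seed, method, replicate) for design draws and response noise.

#' Simulate responses for a design batch under the true model
#'
#' \eqn{y = X_{new}\beta_{true} + \sigma z}, with `z` i.i.d. standard normal
#' from R's global RNG.
#'
#' @param batch a [design_batch()] or d-by-p matrix.
#' @param beta_true true coefficient vector.
#' @param sigma error standard deviation (>= 0; 0 gives exact responses).
#' @return Length-d numeric response vector.
#' @export
generate_response <- function(batch, beta_true, sigma) {
  rows <- batch_rows(batch)
  beta_true <- as.numeric(beta_true)
  if (ncol(rows) != length(beta_true))
    stop_input("batch has ", ncol(rows), " columns but beta_true has length ",
               length(beta_true))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop_input("`sigma` must be a single non-negative number")
  as.vector(rows %*% beta_true) + sigma * rnorm(nrow(rows))
}

pilot_signature <- function(X, y) c(sum(X), sum(X^2), sum(y), sum(y^2))

#' Run one replicate of a sequential-design study
#'
#' Generates the pilot data, then iterates: design the next d-row batch by
#' `method`, simulate its responses from the truth, update the posterior,
#' and test coefficient significance by BH at `truth$alpha`. Deterministic
#' given `(truth$seed, replicate, method)`; the pilot depends only on
#' `(truth$seed, replicate)` so all methods share identical pilots.
#'
#' @param truth a [truth_config()].
#' @param method design method label (see [next_design()]).
#' @param replicate replicate index (>= 1), part of the seed derivation.
#' @param tracked coefficient indices whose posterior means are recorded
#'   each experiment (default: the first `min(20, p)`).
#' @return A tibble of class `replicate_trajectory` with one row per
#'   experiment: `method`, `replicate`, `experiment`, `n_obs`,
#'   `n_true_sig`, `n_false_pos`, `psi`, and list-column `mu_tracked`.
#'   Attributes: `pilot_signature`, `tracked`.
#' @export
run_replicate <- function(truth, method, replicate = 1L, tracked = NULL) {
  stopifnot(inherits(truth, "truth_config"))
  replicate <- check_count(replicate, "replicate")
  if (is.null(tracked)) tracked <- seq_len(min(20L, truth$p))
  nz <- which(truth$beta_true != 0)

  pilot <- with_substream(derive_seed(truth$seed, "pilot", replicate), {
    X0 <- pilot_design(truth$p, truth$pilot_size)
    y0 <- generate_response(X0, truth$beta_true, truth$sigma)
    list(X = batch_rows(X0), y = y0)
  })

  with_substream(derive_seed(truth$seed, "method", method, replicate), {
    post <- fit_posterior(list(X = pilot$X, y = pilot$y),
                          sigma = truth$sigma, b = truth$b / truth$sigma^2)
    ne <- truth$n_experiments
    rec <- list(
      experiment = seq_len(ne), n_obs = integer(ne),
      n_true_sig = integer(ne), n_false_pos = integer(ne),
      psi = numeric(ne), mu_tracked = vector("list", ne))
    for (e in seq_len(ne)) {
      batch <- tryCatch(
        next_design(post, truth$d, method = method, experiment_index = e),
        error = function(err) stop_input(
          "experiment ", e, " (replicate ", replicate, ", method ", method,
          "): ", conditionMessage(err)))
      rec$psi[e] <- psi_mine(post, batch)
      rows <- truth$sigma * batch_rows(batch)   # prediction sd = noise sd
      y <- generate_response(rows, truth$beta_true, truth$sigma)
      post <- update_posterior(post, rows, y)
      sig <- significance_test(post, truth$alpha)$significant
      rec$n_obs[e] <- post$n_obs
      rec$n_true_sig[e] <- sum(sig[nz])
      rec$n_false_pos[e] <- sum(sig[-nz])
      rec$mu_tracked[[e]] <- post$mu[tracked]
    }
    out <- tibble::tibble(method = method, replicate = replicate, !!!rec)
    attr(out, "pilot_signature") <- pilot_signature(pilot$X, pilot$y)
    attr(out, "tracked") <- tracked
    class(out) <- c("replicate_trajectory", class(out))
    out
  })
}

#' Run a replicated study for one or more design methods
#'
#' Repeats [run_replicate()] over methods and replicates, asserts the
#' shared-pilot contract (within a replicate, every method sees the same
#' pilot data), and aggregates power and false-positive summaries.
#' Replicates that fail with a numerical-degeneracy error are excluded from
#' aggregation with a warning; the study refuses to aggregate if more than
#' 1 percent of replicates failed.
#'
#' @param truth a [truth_config()].
#' @param methods character vector of design method labels, or `"all"`.
#' @param n_replicates replicates per method.
#' @param workers accepted for interface compatibility; execution is
#'   sequential (aggregation is ordering-independent, so the result does not
#'   depend on this argument).
#' @param tracked coefficient indices tracked per experiment.
#' @return An object of class `mine_study`: list with `trajectories` (one
#'   tibble row per method x replicate x experiment), `truth`, `methods`,
#'   `n_replicates`, `tracked`, `failures`.
#' @export
run_study <- function(truth, methods = "all", n_replicates = 10L,
                      workers = 1L, tracked = NULL) {
  stopifnot(inherits(truth, "truth_config"))
  all_methods <- c("mine_like", "mine", "random_basis", "random_rotation")
  if (identical(methods, "all")) methods <- all_methods
  if (!all(methods %in% all_methods))
    stop_input("unknown method(s): ",
               paste(setdiff(methods, all_methods), collapse = ", "))
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (is.null(tracked)) tracked <- seq_len(min(20L, truth$p))

  runs <- vector("list", length(methods) * n_replicates)
  failures <- list()
  sig_by_rep <- vector("list", n_replicates)
  i <- 0L
  for (method in methods) {
    for (r in seq_len(n_replicates)) {
      i <- i + 1L
      tr <- tryCatch(run_replicate(truth, method, r, tracked = tracked),
                     error = function(e) e)
      if (inherits(tr, "error")) {
        failures[[length(failures) + 1L]] <-
          tibble::tibble(method = method, replicate = r,
                         error = conditionMessage(tr))
        next
      }
      ps <- attr(tr, "pilot_signature")
      if (is.null(sig_by_rep[[r]])) sig_by_rep[[r]] <- ps
      else if (!isTRUE(all.equal(sig_by_rep[[r]], ps, tolerance = 0)))
        stop_input("shared-pilot contract violated at replicate ", r,
                   " for method ", method)
      runs[[i]] <- tr
    }
  }
  failures <- if (length(failures)) dplyr::bind_rows(failures)
              else tibble::tibble(method = character(), replicate = integer(),
                                  error = character())
  n_total <- length(methods) * n_replicates
  if (nrow(failures) > 0) {
    warning(nrow(failures), " of ", n_total, " replicates failed and were ",
            "excluded", call. = FALSE)
    if (nrow(failures) / n_total > 0.01)
      stop_input("more than 1% of replicates failed (", nrow(failures), "/",
                 n_total, "); refusing to aggregate")
  }
  structure(
    list(trajectories = dplyr::bind_rows(runs[!vapply(runs, is.null, TRUE)]),
         truth = truth, methods = methods, n_replicates = n_replicates,
         tracked = tracked, failures = failures),
    class = "mine_study")
}

#' @export
print.mine_study <- function(x, ...) {
  cat("<mine_study> methods:", paste(x$methods, collapse = ", "), "\n",
      " replicates =", x$n_replicates,
      " experiments =", x$truth$n_experiments,
      " p =", x$truth$p, " sigma =", x$truth$sigma, "\n")
  if (nrow(x$failures)) cat("  failed replicates:", nrow(x$failures), "\n")
  invisible(x)
}

n_nonzero_of <- function(study) sum(study$truth$beta_true != 0)

#' Power and false-positive summary of a study
#'
#' For each method and experiment index: the percentage of replicates in
#' which at least `k` of the truly nonzero coefficients were declared
#' significant (the "power to detect k of n_nonzero"), and the mean
#' false-positive percentage, 100 x mean(false positives) / (number of truly
#' zero coefficients).
#'
#' @param study a `mine_study` from [run_study()].
#' @param k detection threshold (defaults to 7 when there are >= 7 truly
#'   nonzero coefficients, else to all of them).
#' @param experiment_indices experiments to report (default: all).
#' @return A tibble with columns `method`, `experiment`, `power_pct`,
#'   `fpr_pct`.
#' @export
summarize_power_fpr <- function(study, k = NULL, experiment_indices = NULL) {
  stopifnot(inherits(study, "mine_study"))
  nnz <- n_nonzero_of(study)
  if (is.null(k)) k <- min(7L, nnz)
  k <- check_count(k, "k")
  if (k > nnz) stop_input("k = ", k, " exceeds the ", nnz,
                          " truly nonzero coefficients")
  n_zero <- study$truth$p - nnz
  out <- study$trajectories |>
    dplyr::group_by(.data$method, .data$experiment) |>
    dplyr::summarise(
      power_pct = 100 * mean(.data$n_true_sig >= k),
      fpr_pct = 100 * mean(.data$n_false_pos) / n_zero,
      .groups = "drop")
  if (!is.null(experiment_indices))
    out <- dplyr::filter(out, .data$experiment %in% experiment_indices)
  out
}

#' Power milestones: when a method first reaches a detection level
#'
#' The first experiment index at which the fraction of replicates detecting
#' at least `k` truly nonzero coefficients reaches `threshold`.
#'
#' @param study a `mine_study`.
#' @param k detection count threshold.
#' @param threshold required fraction of replicates in \[0, 1\].
#' @return A tibble with columns `method`, `k`, `threshold`, `experiment`
#'   (`NA` if never reached within the study horizon).
#' @export
milestones <- function(study, k = 7L, threshold = 0.5) {
  stopifnot(inherits(study, "mine_study"))
  k <- check_count(k, "k")
  frac <- study$trajectories |>
    dplyr::group_by(.data$method, .data$experiment) |>
    dplyr::summarise(frac = mean(.data$n_true_sig >= k), .groups = "drop")
  frac |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      k = k, threshold = threshold,
      experiment = if (any(.data$frac >= threshold))
        min(.data$experiment[.data$frac >= threshold]) else NA_integer_,
      .groups = "drop")
}

#' Mean tracked posterior means per experiment
#'
#' Averages, over replicates, the recorded posterior means of the tracked
#' coefficient window, per method and experiment — the trajectory view used
#' to examine sign stability of the truly nonzero coefficients.
#'
#' @param study a `mine_study`.
#' @return A tibble with columns `method`, `experiment`, `index` (the
#'   coefficient index), `mean_mu`, `true_beta`.
#' @export
tracked_means <- function(study) {
  stopifnot(inherits(study, "mine_study"))
  tracked <- study$tracked
  study$trajectories |>
    dplyr::select("method", "experiment", "mu_tracked") |>
    tidyr::unnest_longer("mu_tracked", values_to = "mu",
                         indices_to = "slot") |>
    dplyr::group_by(.data$method, .data$experiment, .data$slot) |>
    dplyr::summarise(mean_mu = mean(.data$mu), .groups = "drop") |>
    dplyr::mutate(index = tracked[.data$slot],
                  true_beta = study$truth$beta_true[.data$index]) |>
    dplyr::select("method", "experiment", "index", "mean_mu", "true_beta")
}

#' Tidy trajectories of a study
#'
#' @param x a `mine_study`.
#' @param ... unused.
#' @return The per-replicate trajectory tibble (without the tracked-means
#'   list column).
#' @export
tidy.mine_study <- function(x, ...) {
  dplyr::select(x$trajectories, -"mu_tracked")
}

#' One-row-per-method study summary
#'
#' @param x a `mine_study`.
#' @param ... unused.
#' @return A tibble with, per method: the number of replicates, final-
#'   experiment power (at k = 7 or all nonzero if fewer) and false-positive
#'   percentage, and the mean criterion value over all designed batches.
#' @export
glance.mine_study <- function(x, ...) {
  final <- summarize_power_fpr(x,
    experiment_indices = x$truth$n_experiments)
  psi <- x$trajectories |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_psi = mean(.data$psi), .groups = "drop")
  dplyr::left_join(final, psi, by = "method") |>
    dplyr::mutate(n_replicates = x$n_replicates,
                  n_experiments = x$truth$n_experiments) |>
    dplyr::select("method", "n_replicates", "n_experiments",
                  "power_pct", "fpr_pct", "mean_psi")
}

#' Write study trajectories as (optionally gzipped) TSV
#'
#' Columns: method, replicate, experiment, n_obs, n_true_sig, n_false_pos,
#' psi, then one `mu_<i>` column per tracked coefficient.
#'
#' @param study a `mine_study`.
#' @param path destination; a `.gz` suffix gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(study, path) {
  stopifnot(inherits(study, "mine_study"))
  tr <- study$trajectories
  mu <- do.call(rbind, tr$mu_tracked)
  colnames(mu) <- paste0("mu_", study$tracked)
  df <- cbind(as.data.frame(tr[setdiff(names(tr), "mu_tracked")]),
              as.data.frame(apply(mu, 2L, fmt10)))
  df$psi <- fmt10(tr$psi)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to re-run a study: the configuration, the
#' derived per-replicate pilot seeds, method labels and package version.
#'
#' @param study a `mine_study`.
#' @param path optional JSON destination; when supplied the manifest is
#'   written there.
#' @return The manifest as a list, invisibly when writing.
#' @export
run_manifest <- function(study, path = NULL) {
  stopifnot(inherits(study, "mine_study"))
  cfg <- unclass(study$truth)
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  man <- list(
    config = cfg,
    config_hash = sum(unlist(cfg, use.names = FALSE)^2) %% 1e9,
    methods = study$methods,
    n_replicates = study$n_replicates,
    pilot_seeds = vapply(seq_len(study$n_replicates),
                         function(r) derive_seed(study$truth$seed, "pilot", r),
                         0L),
    version = as.character(utils::packageVersion("minedesign")),
    timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}
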