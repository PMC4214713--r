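# Data containers and deterministic serialization.
#
# The on-disk convention for observation sets is headered TSV with columns
# x1..xp then y; posterior summaries are TSV with columns index, mu, sd, z,
# pval, significant. Numeric output uses fixed 10-significant-digit
# formatting so files diff reproducibly.

#' Coerce observations to the internal dataset form
#'
#' Accepts a data frame whose response column is named `y` (all other
#' columns, in order, are the predictors), a list with elements `X` and `y`,
#' or `NULL`/empty input (then `p` must be given). Rank deficiency of
#' \eqn{X'X} is expected (n < p is the design regime) and is not an error.
#'
#' @param data observations in any accepted form.
#' @param p number of predictors, required when `data` carries none.
#' @return A list of class `mine_data` with `X` (n-by-p matrix) and `y`.
#' @export
as_dataset <- function(data, p = NULL) {
  if (inherits(data, "mine_data")) return(data)
  if (is.null(data) || (is.data.frame(data) && nrow(data) == 0L &&
                        ncol(data) == 0L)) {
    if (is.null(p)) stop_input("`p` is required when no data are supplied")
    p <- check_count(p, "p")
    return(structure(list(X = matrix(numeric(0), 0L, p), y = numeric(0)),
                     class = "mine_data"))
  }
  if (is.data.frame(data)) {
    if (!"y" %in% names(data))
      stop_input("data frame input must contain a response column `y`")
    y <- data$y
    X <- as.matrix(data[setdiff(names(data), "y")])
  } else if (is.list(data) && all(c("X", "y") %in% names(data))) {
    X <- data$X
    if (is.null(dim(X))) X <- matrix(X, nrow = length(data$y))
    y <- data$y
  } else {
    stop_input("`data` must be a data frame with a `y` column, a list with ",
               "`X` and `y`, or NULL")
  }
  X <- check_matrix_finite(X, "X")
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop_input("`y` contains non-finite entries")
  if (nrow(X) != length(y))
    stop_input("X has ", nrow(X), " rows but y has length ", length(y))
  if (!is.null(p) && ncol(X) != p)
    stop_input("X has ", ncol(X), " columns but p = ", p, " was requested")
  dimnames(X) <- NULL
  structure(list(X = X, y = y), class = "mine_data")
}

fmt10 <- function(x) formatC(x, digits = 10, format = "g")

#' Write an observation set as headered TSV
#'
#' @param data observations accepted by [as_dataset()].
#' @param path output file path (columns `x1..xp`, then `y`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  ds <- as_dataset(data)
  df <- as.data.frame(apply(cbind(ds$X, ds$y), 2L, fmt10))
  if (nrow(df) == 0L) df <- as.data.frame(matrix(character(0), 0L,
                                                 ncol(ds$X) + 1L))
  names(df) <- c(paste0("x", seq_len(ncol(ds$X))), "y")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an observation set written by [write_dataset()]
#'
#' @param path TSV file with columns `x1..xp` then `y`.
#' @return A `mine_data` list.
#' @export
read_dataset <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  as_dataset(df)
}

#' Write a posterior significance summary as TSV
#'
#' @param report a `mine_significance` tibble from [significance_test()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_significance <- function(report, path) {
  stopifnot(inherits(report, "mine_significance"))
  df <- data.frame(index = report$index, mu = fmt10(report$mu),
                   sd = fmt10(report$sd), z = fmt10(report$z),
                   pval = fmt10(report$pval),
                   significant = report$significant)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
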