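# Delay embedding: first-differencing and the lagged state-space matrix.
#
# Time indexing is 1-based everywhere, matching the usual presentation of
# simplex projection. Undefined cells of the lag matrix are stored as NA;
# input series themselves may not contain NA (checked on entry), so NA is an
# unambiguous "undefined" sentinel.

#' First-difference a time series
#'
#' Computes \eqn{Y_t = N_{t+1} - N_t} for \eqn{t = 1, \dots, T-1}. Differencing
#' removes a simple linear mean trend before delay embedding; the last value
#' \eqn{Y_T} does not exist and is not represented.
#'
#' @param series Numeric vector \eqn{N_1, \dots, N_T}, \eqn{T \ge 2}, no
#'   missing values.
#' @return Numeric vector of length \eqn{T - 1}.
#' @seealso [undifference()] for the inverse step applied to predictions.
#' @export
#' @examples
#' first_difference(c(1, 3, 2, 2)) # 2 -1 0
first_difference <- function(series) {
  check_series(series)
  if (length(series) < 2L) {
    stop("series too short to first-difference (need T >= 2, got T = ",
         length(series), ")", call. = FALSE)
  }
  diff(series)
}

#' Undo first-differencing for a single prediction
#'
#' Given a predicted difference \eqn{\hat{Y}_t} and the preceding observed
#' level \eqn{N_t}, returns \eqn{\hat{N}_{t+1} = \hat{Y}_t + N_t}.
#'
#' @param y_hat Predicted first difference (finite scalar).
#' @param n_last Observed level at the step being differenced from.
#' @return \code{y_hat + n_last}.
#' @export
undifference <- function(y_hat, n_last) {
  stopifnot(is.numeric(y_hat), length(y_hat) == 1L, is.finite(y_hat),
            is.numeric(n_last), length(n_last) == 1L, is.finite(n_last))
  y_hat + n_last
}

# Shared input validation: numeric, non-empty, no gaps. Missing values are
# rejected outright -- the embedding has no treatment for gaps.
check_series <- function(series, name = "series") {
  if (!is.numeric(series) || length(series) < 1L) {
    stop(name, " must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(series) || any(!is.finite(series))) {
    stop(name, " contains missing or non-finite values; ",
         "gaps are not supported", call. = FALSE)
  }
  invisible(series)
}

#' Build the lagged state-space matrix
#'
#' Arranges a (typically first-differenced) series into the \eqn{T \times E}
#' matrix \eqn{X} whose row \eqn{t} is the delay vector
#' \eqn{x_t = (Y_t, Y_{t-1}, \dots, Y_{t-E+1})}. Cells whose index falls
#' outside \eqn{1, \dots, L} (with \eqn{L} the length of \eqn{Y}) are
#' undefined and stored as \code{NA}.
#'
#' @param y Numeric vector \eqn{Y_1, \dots, Y_L} (no missing values).
#' @param E Embedding dimension, \eqn{1 \le E \le L}.
#' @param n_rows Number of rows of the matrix. Defaults to \code{length(y) +
#'   1}, which matches the first-differenced convention where the matrix has
#'   one row per original observation \eqn{t = 1, \dots, T} and row \eqn{T}
#'   is partially undefined.
#' @return Numeric matrix with \code{n_rows} rows and \code{E} columns;
#'   undefined cells are \code{NA}.
#' @export
build_lag_matrix <- function(y, E, n_rows = length(y) + 1L) {
  check_series(y, "y")
  L <- length(y)
  E <- check_count(E, "E")
  if (E < 1L || E > L) {
    stop("E must satisfy 1 <= E <= ", L, " (length of the differenced ",
         "series); got E = ", E, call. = FALSE)
  }
  n_rows <- check_count(n_rows, "n_rows")
  X <- matrix(NA_real_, nrow = n_rows, ncol = E,
              dimnames = list(NULL, paste0("lag", seq_len(E) - 1L)))
  for (j in seq_len(E)) {
    idx <- seq_len(n_rows) - j + 1L        # cell (t, j) holds Y[t - j + 1]
    ok <- idx >= 1L & idx <= L
    X[ok, j] <- y[idx[ok]]
  }
  X
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x)) {
    stop(name, " must be a single integer", call. = FALSE)
  }
  as.integer(x)
}

#' Embed a time series for empirical dynamic modelling
#'
#' One-stop constructor used by all downstream operations: optionally
#' first-differences the series, builds the lag matrix, and records which
#' rows are fully defined. With \code{differencing = "none"} the embedded
#' values are the raw series itself (\eqn{Y_t := N_t}), so one extra row at
#' the end of the matrix becomes defined and every downstream index rule is
#' driven by the defined-row flags rather than hard-coded offsets.
#'
#' @param series Numeric vector of observations \eqn{N_1, \dots, N_T}.
#' @param E Embedding dimension.
#' @param differencing \code{"first_difference"} (default) or \code{"none"}.
#' @return An object of class \code{edm_lag_matrix}: a list with elements
#'   \itemize{
#'     \item \code{X}: the lag matrix (\code{NA} = undefined cell),
#'     \item \code{E}: embedding dimension,
#'     \item \code{Y}: the embedded series (differences, or the raw series),
#'     \item \code{N}: the raw series (\code{NULL} when the input is already
#'       a difference-scale series supplied with \code{differencing = "none"}
#'       and no level information is wanted),
#'     \item \code{L}: length of \code{Y},
#'     \item \code{T_obs}: length of the input series,
#'     \item \code{defined}: logical, row fully defined,
#'     \item \code{excl_E}: width of the candidate-exclusion window used by
#'       library construction (equals \code{E} for univariate embeddings),
#'     \item \code{differencing}: the mode used.
#'   }
#' @export
edm_embed <- function(series, E, differencing = c("first_difference", "none")) {
  differencing <- match.arg(differencing)
  check_series(series)
  T_obs <- length(series)
  if (differencing == "first_difference") {
    y <- first_difference(series)
    n_rows <- T_obs
    N <- series
  } else {
    y <- series
    n_rows <- T_obs
    N <- series
  }
  X <- build_lag_matrix(y, E, n_rows = n_rows)
  out <- list(
    X = X,
    E = as.integer(E),
    Y = y,
    N = N,
    L = length(y),
    T_obs = T_obs,
    defined = stats::complete.cases(X),
    excl_E = as.integer(E),
    differencing = differencing
  )
  class(out) <- "edm_lag_matrix"
  out
}

#' @export
print.edm_lag_matrix <- function(x, ...) {
  cat("Lagged state-space matrix: E =", x$E, ", T =", x$T_obs,
      ", differencing =", x$differencing, "\n")
  cat("Fully defined rows:", sum(x$defined), "of", nrow(x$X), "\n")
  invisible(x)
}

#' Export a lag matrix as CSV with explicit undefined markers
#'
#' Writes the matrix with the literal character \code{"x"} in undefined
#' cells, for cross-implementation diffing. Values are written at full
#' double precision.
#'
#' @param lag An \code{edm_lag_matrix}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_lag_matrix <- function(lag, path) {
  stopifnot(inherits(lag, "edm_lag_matrix"))
  M <- matrix(vapply(lag$X, format_full, character(1)),
              nrow = nrow(lag$X))
  M[is.na(lag$X)] <- "x"
  df <- data.frame(t = seq_len(nrow(M)), M, stringsAsFactors = FALSE)
  names(df) <- c("t", colnames(lag$X))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision repr that round-trips doubles
format_full <- function(x) {
  if (is.na(x)) return(NA_character_)
  format(x, digits = 17, scientific = FALSE, trim = TRUE)
}
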