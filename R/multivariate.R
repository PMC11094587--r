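# Multivariate embeddings: state-space coordinates drawn from several
# co-observed series with per-variable lags. The candidate-library rules are
# the univariate ones with the embedding dimension E replaced by m + 1,
# where m is the maximum lag used by any coordinate — so the library size
# depends only on (T, m, t*), not on how many variables are embedded.

#' Coordinate specification for a multivariate embedding
#'
#' @param variable Character vector of variable names.
#' @param lag Non-negative integer vector of lags (recycled against
#'   \code{variable}). The prediction target is always the first
#'   coordinate's variable at lag 0.
#' @return Data frame with columns \code{variable} and \code{lag}.
#' @export
coordinate_spec <- function(variable, lag = 0L) {
  if (!is.character(variable) || length(variable) == 0L) {
    stop("variable must be a non-empty character vector", call. = FALSE)
  }
  lag <- as.integer(lag)
  if (anyNA(lag) || any(lag < 0L)) {
    stop("lags must be non-negative integers", call. = FALSE)
  }
  out <- data.frame(variable = variable, lag = lag,
                    stringsAsFactors = FALSE)
  if (out$lag[1L] != 0L) {
    stop("the first coordinate (the prediction target) must have lag 0",
         call. = FALSE)
  }
  out
}

#' Build a multivariate lag matrix
#'
#' Row \eqn{t}, column \eqn{j} holds the (optionally first-differenced)
#' value of coordinate \eqn{j}'s variable at time \eqn{t - lag_j}. With
#' first differencing the fully defined rows are \eqn{\{m+1, \dots, T-1\}};
#' without, \eqn{\{m+1, \dots, T\}}.
#'
#' With a single variable at consecutive lags \eqn{0, \dots, E-1} this
#' reduces exactly (bit-identically) to the univariate [edm_embed()].
#'
#' Distances in the embedded space mix the coordinates' units. When
#' variables are on different scales, set \code{standardise = TRUE} to
#' z-score each variable (after differencing) before embedding; the default
#' is off for comparability with univariate results.
#'
#' @param series_table Named list or data frame of equal-length numeric
#'   series.
#' @param coords A [coordinate_spec()].
#' @param differencing As in [edm_embed()].
#' @param standardise Z-score each embedded variable? Default \code{FALSE}.
#' @return An \code{edm_lag_matrix} whose \code{Y} is the (differenced)
#'   target variable and whose \code{excl_E} is \eqn{m + 1}.
#' @export
build_multivariate_matrix <- function(series_table, coords,
                                      differencing = c("first_difference", "none"),
                                      standardise = FALSE) {
  differencing <- match.arg(differencing)
  if (is.data.frame(series_table)) series_table <- as.list(series_table)
  if (!is.list(series_table) || is.null(names(series_table)) ||
      any(!nzchar(names(series_table)))) {
    stop("series_table must be a named list or data frame", call. = FALSE)
  }
  missing_vars <- setdiff(coords$variable, names(series_table))
  if (length(missing_vars) > 0L) {
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  lens <- vapply(series_table, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all series must have equal length", call. = FALSE)
  }
  T_obs <- lens[[1L]]
  for (nm in names(series_table)) check_series(series_table[[nm]], nm)

  first_diff <- differencing == "first_difference"
  ytab <- lapply(series_table, function(s) if (first_diff) diff(s) else s)
  if (standardise) {
    ytab <- lapply(ytab, function(y) as.numeric(scale(y)))
  }
  L <- length(ytab[[1L]])
  m <- max(coords$lag)
  E <- nrow(coords)
  n_rows <- T_obs
  X <- matrix(NA_real_, nrow = n_rows, ncol = E,
              dimnames = list(NULL,
                              paste0(coords$variable, "_lag", coords$lag)))
  for (j in seq_len(E)) {
    idx <- seq_len(n_rows) - coords$lag[j]
    ok <- idx >= 1L & idx <= L
    X[ok, j] <- ytab[[coords$variable[j]]][idx[ok]]
  }
  target <- ytab[[coords$variable[1L]]]
  out <- list(
    X = X,
    E = as.integer(E),
    Y = target,
    N = series_table[[coords$variable[1L]]],
    L = L,
    T_obs = T_obs,
    defined = stats::complete.cases(X),
    excl_E = as.integer(m + 1L),
    differencing = differencing,
    coords = coords,
    m = as.integer(m),
    standardised = isTRUE(standardise)
  )
  class(out) <- "edm_lag_matrix"
  out
}

#' Candidate library for a multivariate embedding
#'
#' Identical construction to the univariate [construct_library()] with
#' \eqn{E} replaced by \eqn{m + 1} in every index rule: the validity window
#' is \eqn{m + 1 \le t^* \le T - 2} and the usual library size is
#' \eqn{T - 2(m + 2)}. Adding further variables leaves the library size
#' unchanged unless they are lagged more than the existing ones (increasing
#' \eqn{m}).
#'
#' @param lag An \code{edm_lag_matrix} from [build_multivariate_matrix()].
#' @param t_star Focal time.
#' @param policy Exclusion policy.
#' @param purpose \code{"evaluation"} or \code{"forecast"}.
#' @return An \code{edm_library}.
#' @export
multivariate_library <- function(lag, t_star, policy = exclusion_policy(),
                                 purpose = c("evaluation", "forecast")) {
  construct_library(lag, t_star, policy, match.arg(purpose))
}
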