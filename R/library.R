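# Construction of the library of candidate nearest neighbours.
#
# Two bookkeeping rules that brief descriptions of simplex projection tend to
# leave implicit are made explicit here:
#   (1) which focal times t* are allowed at all, and
#   (2) which delay vectors are eligible neighbours of a given focal point.
# Under the default policy, candidates are removed by four conditions:
#   (a) the focal vector itself,
#   (b) vectors with undefined components,
#   (c) vectors whose successor is undefined (we must know where a neighbour
#       goes one step later),
#   (d) vectors that contain the very value being predicted, i.e. times
#       t*+1, ..., t*+E.
# The "radius" policy replaces (d) with an exclusion radius around t*
# (conditions (a)-(c) still apply), matching the behaviour of toolkits that
# expose an exclusionRadius argument; radius 0 excludes only the focal
# vector among temporal neighbours.

#' Neighbour-exclusion policy
#'
#' @param mode \code{"default"}: apply exclusion conditions (a)-(d), dropping
#'   every candidate that contains the value being predicted.
#'   \code{"radius"}: apply (a)-(c) plus a symmetric temporal exclusion
#'   window \eqn{|t - t^*| \le k}.
#' @param radius_k Non-negative integer exclusion radius (radius mode only).
#' @return An object of class \code{edm_policy}.
#' @export
exclusion_policy <- function(mode = c("default", "radius"), radius_k = 0L) {
  mode <- match.arg(mode)
  radius_k <- check_count(radius_k, "radius_k")
  if (radius_k < 0L) stop("radius_k must be non-negative", call. = FALSE)
  structure(list(mode = mode, radius_k = radius_k), class = "edm_policy")
}

as_policy <- function(policy) {
  if (inherits(policy, "edm_policy")) return(policy)
  if (is.character(policy) && length(policy) == 1L) {
    if (policy %in% c("default", "paper", "strict")) {
      return(exclusion_policy("default"))
    }
    if (grepl("^radius(:[0-9]+)?$", policy)) {
      k <- sub("^radius:?", "", policy)
      return(exclusion_policy("radius", if (nzchar(k)) as.integer(k) else 0L))
    }
  }
  stop("unrecognised exclusion policy; use exclusion_policy() or ",
       "'default' / 'radius:k'", call. = FALSE)
}

#' Allowable focal times
#'
#' A focal time \eqn{t^*} must have a fully defined delay vector
#' (\eqn{t^* \ge E}) and, for evaluation, a known next value
#' \eqn{Y_{t^*+1}} to compare the prediction against. For forecasting beyond
#' the data, the last embeddable time is also allowed since no comparison is
#' made.
#'
#' With first differencing the sets are \eqn{\{E, \dots, T-2\}} (evaluation)
#' and \eqn{\{E, \dots, T-1\}} (forecast).
#'
#' @param T Length of the original series.
#' @param E Embedding dimension.
#' @param purpose \code{"evaluation"} or \code{"forecast"}.
#' @param differencing As in [edm_embed()].
#' @return Increasing integer vector of valid focal times.
#' @export
valid_focal_times <- function(T, E,
                              purpose = c("evaluation", "forecast"),
                              differencing = c("first_difference", "none")) {
  purpose <- match.arg(purpose)
  differencing <- match.arg(differencing)
  T <- check_count(T, "T")
  E <- check_count(E, "E")
  L <- if (differencing == "first_difference") T - 1L else T
  hi <- if (purpose == "forecast") L else L - 1L
  if (E > hi) {
    stop("series too short for E = ", E, ": no valid focal times ",
         "(need T >= ", if (differencing == "first_difference") E + 2L else E + 1L,
         " for evaluation)", call. = FALSE)
  }
  seq.int(E, hi)
}

focal_times_for <- function(lag, purpose) {
  # defined-flag-driven version used internally: works for univariate,
  # no-differencing and multivariate embeddings alike
  def <- which(lag$defined)
  hi <- if (purpose == "forecast") lag$L else lag$L - 1L
  def[def <= hi]
}

#' Construct the library of candidate nearest neighbours
#'
#' Applies the exclusion conditions (see [exclusion_policy()]) to the rows of
#' the lag matrix and returns the surviving time indices in ascending order.
#' Downstream neighbour ranking must not rely on this ordering.
#'
#' @param lag An \code{edm_lag_matrix} from [edm_embed()] or
#'   [build_multivariate_matrix()].
#' @param t_star Focal time.
#' @param policy An [exclusion_policy()] (or a string accepted by it).
#' @param purpose \code{"evaluation"} (default) or \code{"forecast"};
#'   controls which focal times are legal, not the exclusion rules.
#' @return Object of class \code{edm_library}: list with \code{E},
#'   \code{t_star}, \code{member_times} and \code{size}.
#' @export
construct_library <- function(lag, t_star, policy = exclusion_policy(),
                              purpose = c("evaluation", "forecast")) {
  stopifnot(inherits(lag, "edm_lag_matrix"))
  purpose <- match.arg(purpose)
  policy <- as_policy(policy)
  t_star <- check_count(t_star, "t_star")
  valid <- focal_times_for(lag, purpose)
  if (!(t_star %in% valid)) {
    stop("t_star = ", t_star, " is not a valid focal time for ",
         purpose, " (valid: ", valid[1L], "..", valid[length(valid)], ")",
         call. = FALSE)
  }
  cand <- which(lag$defined)                 # condition (b)
  cand <- cand[cand + 1L <= lag$L]           # condition (c): successor known
  cand <- cand[cand != t_star]               # condition (a)
  if (policy$mode == "default") {
    # condition (d): drop vectors containing the value being predicted
    drop <- seq.int(t_star + 1L, t_star + lag$excl_E)
    cand <- setdiff(cand, drop)
  } else {
    cand <- cand[abs(cand - t_star) > policy$radius_k]
  }
  if (length(cand) == 0L) {
    stop("library for t_star = ", t_star, " is empty: series too short ",
         "or E too large", call. = FALSE)
  }
  structure(list(E = lag$E, t_star = t_star,
                 member_times = as.integer(cand),
                 size = length(cand)),
            class = "edm_library")
}

#' @export
print.edm_library <- function(x, ...) {
  cat("Library for t* =", x$t_star, "(E =", x$E, "):", x$size, "members\n")
  invisible(x)
}

#' Closed-form library size
#'
#' For a first-differenced univariate series of length \eqn{T}, the library
#' under the default policy usually has \eqn{C_E = T - 2(E + 1)} members.
#' Near the end of the series the condition-(d) window overlaps the
#' end-of-series exclusions, and the size climbs by one per step of
#' \eqn{t^*}:
#' \deqn{C_{E,t^*} = T - 2(E+1) + \max(0,\, t^* - (T - E - 2)).}
#'
#' Note the usual size is \eqn{T - 2(E+1)}, i.e. \eqn{T - 2E - 2}; it is
#' sometimes typeset ambiguously as \eqn{T - 2E + 1}, but the worked values
#' (\eqn{C_2 = 44}, \eqn{C_3 = 42} at \eqn{T = 50}) pin down this reading.
#'
#' @param T Series length.
#' @param E Embedding dimension.
#' @param t_star Focal time; must be valid for the given purpose.
#' @param purpose \code{"evaluation"} allows \eqn{E \le t^* \le T-2};
#'   \code{"forecast"} additionally allows \eqn{t^* = T-1}.
#' @return Integer library size (agrees with
#'   \code{construct_library(...)$size} under the default policy whenever
#'   that library is non-empty).
#' @export
library_size <- function(T, E, t_star, purpose = c("evaluation", "forecast")) {
  purpose <- match.arg(purpose)
  T <- check_count(T, "T")
  E <- check_count(E, "E")
  t_star <- check_count(t_star, "t_star")
  hi <- if (purpose == "forecast") T - 1L else T - 2L
  if (t_star < E || t_star > hi) {
    stop("t_star = ", t_star, " invalid for T = ", T, ", E = ", E,
         " (valid: ", E, "..", hi, ")", call. = FALSE)
  }
  base <- T - 2L * (E + 1L)
  as.integer(base + max(0L, t_star - (T - E - 2L)))
}

#' Library-size grid
#'
#' Tabulates \eqn{C_{E,t^*}} over all valid focal times for each embedding
#' dimension, the table underlying the interplay between \eqn{E} and
#' \eqn{t^*}. Invalid combinations are \code{NA}.
#'
#' @param T Series length.
#' @param E_max Largest embedding dimension to tabulate.
#' @return Data frame with column \code{t_star} and one column per
#'   \code{E1..E<E_max>}.
#' @export
library_size_grid <- function(T, E_max) {
  T <- check_count(T, "T")
  E_max <- check_count(E_max, "E_max")
  tstars <- seq_len(T)
  out <- data.frame(t_star = tstars)
  for (E in seq_len(E_max)) {
    col <- rep(NA_integer_, T)
    ok <- tstars >= E & tstars <= T - 2L
    col[ok] <- vapply(tstars[ok], function(ts) library_size(T, E, ts),
                      integer(1))
    out[[paste0("E", E)]] <- col
  }
  out
}
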