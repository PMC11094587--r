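# Simplex projection: rank library vectors by distance to the focal point,
# weight the E+1 nearest exponentially, and average where they went next.

#' Euclidean distance between two delay vectors
#'
#' @param a,b Numeric vectors of equal length with no undefined components.
#' @return Non-negative scalar; zero iff \code{a == b} element-wise.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b), call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("undefined components", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Simplex weights from ranked distances
#'
#' \eqn{w_i = \exp(-d_i / d_1)} with \eqn{d_1} the distance to the nearest
#' neighbour, so the nearest neighbour always has weight \eqn{e^{-1} =
#' 0.368}. Degenerate case: when the focal point has exact duplicates in the
#' library (\eqn{d_1 = 0}), all zero-distance neighbours get weight 1 and the
#' remaining weights use the smallest positive distance as denominator; if
#' every distance is zero all weights are 1 (an equal-weight average). This
#' is the continuity-preserving limit of the formula, which is otherwise
#' 0/0 at coincident points.
#'
#' @param distances Non-negative distances sorted in ascending order.
#' @return Weights in \eqn{(0, 1]}, non-increasing.
#' @export
simplex_weights <- function(distances) {
  if (length(distances) == 0L) stop("no distances supplied", call. = FALSE)
  if (any(distances < 0) || is.unsorted(distances)) {
    stop("distances must be non-negative and ranked ascending", call. = FALSE)
  }
  d1 <- distances[1L]
  if (d1 > 0) return(exp(-distances / d1))
  w <- rep(1, length(distances))
  pos <- distances > 0
  if (any(pos)) w[pos] <- exp(-distances[pos] / min(distances[pos]))
  w
}

#' Rank library neighbours of a focal point
#'
#' Computes the Euclidean distance from the focal delay vector to every
#' library member and returns the \code{k} nearest, with distance ties broken
#' by ascending time index (deterministic; comparisons use exact equality of
#' the computed doubles).
#'
#' @param lag An \code{edm_lag_matrix}.
#' @param library An \code{edm_library} for the same focal time.
#' @param t_star Focal time (must match \code{library$t_star}).
#' @param k Number of neighbours; default \eqn{E + 1}, the simplex.
#' @return Object of class \code{edm_neighbours}: \code{focal_t},
#'   \code{times} (\eqn{\psi_1, \dots, \psi_k}), \code{distances},
#'   \code{weights}.
#' @export
rank_neighbours <- function(lag, library, t_star, k = lag$E + 1L) {
  stopifnot(inherits(lag, "edm_lag_matrix"), inherits(library, "edm_library"))
  k <- check_count(k, "k")
  if (library$t_star != t_star) {
    stop("library was built for t_star = ", library$t_star, call. = FALSE)
  }
  if (library$size < k) {
    stop("library too small: C = ", library$size, " candidates but k = ",
         k, " neighbours requested", call. = FALSE)
  }
  focal <- lag$X[t_star, ]
  members <- library$member_times
  d <- vapply(members, function(t) euclidean_distance(focal, lag$X[t, ]),
              numeric(1))
  ord <- order(d, members)          # ties by ascending time index
  sel <- ord[seq_len(k)]
  structure(list(focal_t = t_star,
                 times = members[sel],
                 distances = d[sel],
                 weights = simplex_weights(d[sel])),
            class = "edm_neighbours")
}

#' @export
print.edm_neighbours <- function(x, ...) {
  cat("Neighbours of t* =", x$focal_t, "\n")
  print(data.frame(rank = seq_along(x$times), psi = x$times,
                   distance = x$distances, weight = x$weights))
  invisible(x)
}

#' One simplex prediction
#'
#' Predicts \eqn{\hat{Y}_{t^*+1}} as the weighted average of where the
#' nearest neighbours moved one step later:
#' \deqn{\hat{Y}_{t^*+1} = \sum_i w_i Y_{\psi_i + 1} \,/\, \sum_j w_j .}
#' When the embedding carries level information the prediction is also
#' un-differenced to \eqn{\hat{N}_{t^*+2} = \hat{Y}_{t^*+1} + N_{t^*+1}}.
#'
#' @param lag An \code{edm_lag_matrix}.
#' @param t_star Focal time.
#' @param policy Exclusion policy (see [exclusion_policy()]).
#' @param k Number of neighbours, default \eqn{E + 1}.
#' @param purpose \code{"evaluation"} or \code{"forecast"}.
#' @return Object of class \code{edm_prediction}: \code{focal_t},
#'   \code{y_hat}, \code{n_hat}, \code{neighbours}.
#' @export
predict_point <- function(lag, t_star, policy = exclusion_policy(),
                          k = lag$E + 1L,
                          purpose = c("evaluation", "forecast")) {
  purpose <- match.arg(purpose)
  lib <- construct_library(lag, t_star, policy, purpose)
  nb <- rank_neighbours(lag, lib, t_star, k)
  targets <- lag$Y[nb$times + 1L]
  y_hat <- sum(nb$weights * targets) / sum(nb$weights)
  n_hat <- if (lag$differencing == "first_difference") {
    y_hat + lag$N[t_star + 1L]
  } else {
    y_hat
  }
  structure(list(focal_t = t_star, y_hat = y_hat, n_hat = n_hat,
                 neighbours = nb),
            class = "edm_prediction")
}

#' @export
print.edm_prediction <- function(x, ...) {
  cat(sprintf("t* = %d: Y_hat = %.6g, N_hat = %.6g\n",
              x$focal_t, x$y_hat, x$n_hat))
  invisible(x)
}

#' Forecast the next value of a series
#'
#' Runs simplex projection at the last embeddable focal time (the one step
#' beyond the evaluation window) to forecast \eqn{\hat{Y}_T}, then
#' un-differences to \eqn{\hat{N}_{T+1} = \hat{Y}_T + N_T}. Because the
#' forecast is a convex combination on the difference scale only, the level
#' forecast can exceed the observed range and even go negative for
#' population data; two remedies are available:
#' \describe{
#'   \item{\code{clamp_to_min}}{replace a negative level forecast with the
#'     smallest observed value;}
#'   \item{\code{log_transform}}{run the whole pipeline on \eqn{\log N_t} and
#'     back-transform (requires strictly positive data; changes relative
#'     neighbour distances, so results differ from a clamped forecast).}
#' }
#'
#' @param series Numeric vector of observations.
#' @param E Embedding dimension.
#' @param policy Exclusion policy.
#' @param remedy \code{"none"}, \code{"clamp_to_min"} or
#'   \code{"log_transform"}.
#' @param k Number of neighbours, default \eqn{E + 1}.
#' @param differencing As in [edm_embed()].
#' @return List with \code{y_hat}, \code{n_hat}, \code{remedy},
#'   \code{remedy_applied} (logical) and the underlying \code{prediction}.
#' @export
forecast_next <- function(series, E, policy = exclusion_policy(),
                          remedy = c("none", "clamp_to_min", "log_transform"),
                          k = NULL,
                          differencing = c("first_difference", "none")) {
  remedy <- match.arg(remedy)
  differencing <- match.arg(differencing)
  if (remedy == "log_transform") {
    if (any(series <= 0)) {
      stop("log_transform remedy requires strictly positive values",
           call. = FALSE)
    }
    inner <- forecast_next(log(series), E, policy, remedy = "none", k = k,
                           differencing = differencing)
    return(list(y_hat = inner$y_hat, n_hat = exp(inner$n_hat),
                remedy = remedy, remedy_applied = TRUE,
                prediction = inner$prediction))
  }
  lag <- edm_embed(series, E, differencing)
  t_star <- lag$L                    # forecast-mode focal time (T - 1 when
                                     # first-differenced)
  if (is.null(k)) k <- lag$E + 1L
  pred <- predict_point(lag, t_star, policy, k, purpose = "forecast")
  n_hat <- pred$n_hat
  applied <- FALSE
  if (remedy == "clamp_to_min" && n_hat < 0) {
    n_hat <- min(series)
    applied <- TRUE
  }
  list(y_hat = pred$y_hat, n_hat = n_hat, remedy = remedy,
       remedy_applied = applied, prediction = pred)
}
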