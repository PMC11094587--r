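# Leave-one-out evaluation of forecast skill and selection of the embedding
# dimension.

#' Pearson correlation between observed and predicted values
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 3),
#'   each with non-zero variance.
#' @return Pearson correlation in \eqn{[-1, 1]}.
#' @export
pearson_rho <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted differ in length", call. = FALSE)
  }
  if (length(observed) < 3L) {
    stop("need at least 3 paired values to compute rho", call. = FALSE)
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop("missing values in rho inputs", call. = FALSE)
  }
  if (stats::var(observed) == 0) {
    stop("observed values have zero variance; rho undefined", call. = FALSE)
  }
  if (stats::var(predicted) == 0) {
    stop("predicted values have zero variance; rho undefined", call. = FALSE)
  }
  stats::cor(observed, predicted)
}

#' Leave-one-out predictions and forecast skill for one embedding dimension
#'
#' Makes a simplex prediction at every valid focal time and correlates
#' predictions with observations. On the difference scale (\code{scale =
#' "Y"}) the pairing is \eqn{\hat{Y}_{t^*+1}} vs \eqn{Y_{t^*+1}}; on the
#' level scale (\code{"N"}) each prediction is un-differenced first, pairing
#' \eqn{\hat{N}_{t^*+2} = \hat{Y}_{t^*+1} + N_{t^*+1}} with
#' \eqn{N_{t^*+2}}. High skill on the difference scale need not imply high
#' skill on the level scale, so both are worth inspecting.
#'
#' @param series Numeric vector of observations.
#' @param E Embedding dimension.
#' @param policy Exclusion policy.
#' @param scale \code{"Y"} (difference scale, default) or \code{"N"}.
#' @param k Number of neighbours (default \eqn{E + 1}).
#' @param differencing As in [edm_embed()].
#' @return List with \code{rho}, \code{scale}, and \code{predictions}, a data
#'   frame with one row per focal time (\code{t_star}, \code{y_obs},
#'   \code{y_hat}, \code{n_obs}, \code{n_hat}). Focal times where no
#'   prediction could be made (empty library) are recorded in
#'   \code{skipped}.
#' @export
evaluate_embedding <- function(series, E, policy = exclusion_policy(),
                               scale = c("Y", "N"), k = NULL,
                               differencing = c("first_difference", "none")) {
  scale <- match.arg(scale)
  differencing <- match.arg(differencing)
  lag <- edm_embed(series, E, differencing)
  if (is.null(k)) k <- lag$E + 1L
  tstars <- focal_times_for(lag, "evaluation")
  if (length(tstars) < 3L) {
    stop("fewer than 3 valid focal times for E = ", E, call. = FALSE)
  }
  rows <- vector("list", length(tstars))
  skipped <- integer(0)
  first_diff <- differencing == "first_difference"
  for (i in seq_along(tstars)) {
    ts <- tstars[i]
    pred <- tryCatch(predict_point(lag, ts, policy, k, "evaluation"),
                     error = function(e) NULL)
    if (is.null(pred)) {
      skipped <- c(skipped, ts)
      next
    }
    # observed level one step beyond the predicted difference:
    # Y_{t*+1} = N_{t*+2} - N_{t*+1}
    n_obs <- if (first_diff) lag$N[ts + 2L] else lag$Y[ts + 1L]
    rows[[i]] <- data.frame(t_star = ts,
                            y_obs = lag$Y[ts + 1L], y_hat = pred$y_hat,
                            n_obs = n_obs, n_hat = pred$n_hat)
  }
  predictions <- do.call(rbind, rows)
  if (is.null(predictions) || nrow(predictions) < 3L) {
    stop("too few successful predictions to evaluate E = ", E, call. = FALSE)
  }
  rho <- if (scale == "Y") {
    pearson_rho(predictions$y_obs, predictions$y_hat)
  } else {
    pearson_rho(predictions$n_obs, predictions$n_hat)
  }
  list(rho = rho, scale = scale, E = E, predictions = predictions,
       skipped = skipped)
}

#' Select the embedding dimension by cross-validated correlation
#'
#' Repeats the leave-one-out evaluation for each candidate \eqn{E} and picks
#' the one with the highest difference-scale correlation (\eqn{\rho_Y});
#' ties go to the smallest \eqn{E} (parsimony). The level-scale correlation
#' \eqn{\rho_N} is reported alongside but plays no part in the selection.
#'
#' Larger \eqn{E} admits fewer valid focal times, so by default each
#' \eqn{E} is scored on its own focal-time set. With \code{common_tstar =
#' TRUE} every \eqn{E} is scored only on the intersection of all valid sets
#' (i.e. the most restrictive E's set), removing that asymmetry at the cost
#' of discarding early predictions.
#'
#' @param series Numeric vector of observations.
#' @param E_range Integer vector of embedding dimensions to try; default
#'   \code{2:floor(sqrt(T))} (the customary upper bound of about
#'   \eqn{\sqrt{T}}).
#' @param policy Exclusion policy.
#' @param common_tstar Score all E on the shared focal-time set? Default
#'   \code{FALSE}.
#' @param k Number of neighbours (default \eqn{E + 1} per E).
#' @param differencing As in [edm_embed()].
#' @return Object of class \code{edm_evaluation}: \code{per_E} (named list
#'   with \code{predictions}, \code{rho_Y}, \code{rho_N},
#'   \code{valid_tstars}), \code{E_star}, \code{rho_star}, and a
#'   \code{summary} data frame (E, rho_Y, rho_N, n_predictions).
#' @export
select_E <- function(series, E_range = NULL, policy = exclusion_policy(),
                     common_tstar = FALSE, k = NULL,
                     differencing = c("first_difference", "none")) {
  differencing <- match.arg(differencing)
  check_series(series)
  if (is.null(E_range)) {
    E_range <- seq.int(2L, max(2L, floor(sqrt(length(series)))))
  }
  E_range <- sort(unique(as.integer(E_range)))
  if (length(E_range) == 0L) stop("E_range is empty", call. = FALSE)

  per_E <- list()
  for (E in E_range) {
    res <- tryCatch(
      evaluate_embedding(series, E, policy, scale = "Y", k = k,
                         differencing = differencing),
      error = function(e) NULL)
    if (is.null(res)) next
    per_E[[as.character(E)]] <- list(
      E = E,
      predictions = res$predictions,
      valid_tstars = res$predictions$t_star,
      skipped = res$skipped
    )
  }
  if (length(per_E) == 0L) {
    stop("no embedding dimension in E_range could be evaluated", call. = FALSE)
  }

  common <- NULL
  if (common_tstar) {
    common <- Reduce(intersect, lapply(per_E, `[[`, "valid_tstars"))
    if (length(common) < 3L) {
      stop("fewer than 3 focal times shared across E_range", call. = FALSE)
    }
  }
  for (nm in names(per_E)) {
    p <- per_E[[nm]]$predictions
    if (common_tstar) p <- p[p$t_star %in% common, , drop = FALSE]
    per_E[[nm]]$rho_Y <- pearson_rho(p$y_obs, p$y_hat)
    per_E[[nm]]$rho_N <- pearson_rho(p$n_obs, p$n_hat)
    per_E[[nm]]$n_predictions <- nrow(p)
  }

  summary <- data.frame(
    E = vapply(per_E, `[[`, integer(1), "E"),
    rho_Y = vapply(per_E, `[[`, numeric(1), "rho_Y"),
    rho_N = vapply(per_E, `[[`, numeric(1), "rho_N"),
    n_predictions = vapply(per_E, `[[`, integer(1), "n_predictions"),
    row.names = NULL
  )
  best <- which.max(summary$rho_Y)   # which.max returns the first (smallest
                                     # E, rows are sorted) on ties
  out <- list(per_E = per_E,
              E_star = summary$E[best],
              rho_star = summary$rho_Y[best],
              common_tstar = common_tstar,
              summary = summary)
  class(out) <- "edm_evaluation"
  out
}

#' @export
print.edm_evaluation <- function(x, ...) {
  cat("Embedding-dimension selection (rho on the difference scale):\n")
  print(transform(x$summary, rho_Y = round(rho_Y, 3), rho_N = round(rho_N, 3)))
  cat("Selected E* =", x$E_star, "with rho =", round(x$rho_star, 3), "\n")
  invisible(x)
}

#' Evaluate skill by predicting the second half from the first
#'
#' For longer series, out-of-sample skill can be estimated by restricting
#' the library to delay vectors from the first half of the series and
#' predicting every focal time in the second half.
#'
#' @param series Numeric vector; needs \eqn{T \ge 4E + 8} so both halves
#'   support the embedding.
#' @param E Embedding dimension.
#' @param policy Exclusion policy.
#' @param k Number of neighbours (default \eqn{E + 1}).
#' @param differencing As in [edm_embed()].
#' @return Difference-scale correlation over the second-half focal times.
#' @export
split_half_evaluate <- function(series, E, policy = exclusion_policy(),
                                k = NULL,
                                differencing = c("first_difference", "none")) {
  differencing <- match.arg(differencing)
  check_series(series)
  E <- check_count(E, "E")
  T_obs <- length(series)
  if (T_obs < 4L * E + 8L) {
    stop("series too short for split-half evaluation: need T >= ",
         4L * E + 8L, ", got ", T_obs, call. = FALSE)
  }
  lag <- edm_embed(series, E, differencing)
  if (is.null(k)) k <- lag$E + 1L
  half <- T_obs %/% 2L
  tstars <- focal_times_for(lag, "evaluation")
  tstars <- tstars[tstars > half]
  obs <- hat <- numeric(0)
  for (ts in tstars) {
    lib <- construct_library(lag, ts, policy, "evaluation")
    keep <- lib$member_times[lib$member_times <= half]
    if (length(keep) < k) next
    lib$member_times <- keep
    lib$size <- length(keep)
    nb <- rank_neighbours(lag, lib, ts, k)
    y_hat <- sum(nb$weights * lag$Y[nb$times + 1L]) / sum(nb$weights)
    obs <- c(obs, lag$Y[ts + 1L])
    hat <- c(hat, y_hat)
  }
  if (length(obs) < 3L) {
    stop("second half yields fewer than 3 usable focal times", call. = FALSE)
  }
  pearson_rho(obs, hat)
}
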