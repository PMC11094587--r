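# S-map: a locally weighted linear map fitted over the whole library, with
# nonlinearity parameter theta. theta = 0 weights all library points equally
# and reduces to a global linear autoregressive fit; increasing theta
# concentrates weight on states close to the focal point, letting the fitted
# map vary across the attractor.

#' S-map configuration
#'
#' @param E Embedding dimension.
#' @param theta Nonlinearity parameter, \eqn{\theta \ge 0}.
#' @param policy Exclusion policy (shared with simplex projection: S-map uses
#'   the identical candidate library).
#' @param intercept Include an intercept column in the local design? Default
#'   \code{TRUE}; conventions vary in the literature, so it is exposed.
#' @return Object of class \code{edm_smap_config}.
#' @export
smap_config <- function(E, theta = 0, policy = exclusion_policy(),
                        intercept = TRUE) {
  E <- check_count(E, "E")
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0) {
    stop("theta must be a single non-negative number", call. = FALSE)
  }
  structure(list(E = E, theta = theta, policy = as_policy(policy),
                 intercept = isTRUE(intercept)),
            class = "edm_smap_config")
}

#' S-map weights over a library
#'
#' \eqn{w_t = \exp(-\theta \, d_t / \bar{d})} for every library member,
#' where \eqn{d_t} is the member's distance to the focal vector and
#' \eqn{\bar{d}} is the mean of those distances. If \eqn{\bar{d} = 0} (all
#' library members coincide with the focal point) all weights are 1.
#' Weights are returned in library (ascending time) order, unnormalised:
#' S-map predictions are invariant to rescaling all weights by a positive
#' constant.
#'
#' @param lag An \code{edm_lag_matrix}.
#' @param library An \code{edm_library}.
#' @param t_star Focal time (must match the library).
#' @param theta Nonlinearity parameter, \eqn{\ge 0}.
#' @return Numeric vector of weights, one per library member.
#' @export
smap_weights <- function(lag, library, t_star, theta) {
  stopifnot(inherits(lag, "edm_lag_matrix"), inherits(library, "edm_library"))
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0) {
    stop("theta must be a single non-negative number", call. = FALSE)
  }
  if (library$t_star != t_star) {
    stop("library was built for t_star = ", library$t_star, call. = FALSE)
  }
  focal <- lag$X[t_star, ]
  d <- vapply(library$member_times,
              function(t) euclidean_distance(focal, lag$X[t, ]), numeric(1))
  dbar <- mean(d)
  if (dbar == 0) return(rep(1, length(d)))
  exp(-theta * d / dbar)
}

#' One S-map prediction
#'
#' Fits the weighted linear map \eqn{Y_{\psi+1} \approx c_0 + \sum_j c_j
#' x_\psi[j]} over \emph{all} library members (no neighbour truncation: this
#' is what distinguishes S-map from simplex projection) and evaluates the
#' fitted map at the focal vector. The weighted least-squares problem is
#' solved through a singular value decomposition with a relative singular
#' value cutoff of \code{1e-10}, so small, collinear libraries yield the
#' minimum-norm solution rather than an error.
#'
#' @param lag An \code{edm_lag_matrix} built with the same \code{E} as the
#'   config.
#' @param t_star Focal time.
#' @param config An [smap_config()].
#' @param purpose \code{"evaluation"} or \code{"forecast"}.
#' @return Object of class \code{edm_smap_fit}: \code{focal_t},
#'   \code{coefficients} (intercept first, then one per embedding
#'   coordinate), \code{y_hat}, \code{n_hat}, \code{weights},
#'   \code{library}.
#' @export
smap_predict <- function(lag, t_star, config,
                         purpose = c("evaluation", "forecast")) {
  stopifnot(inherits(lag, "edm_lag_matrix"), inherits(config, "edm_smap_config"))
  purpose <- match.arg(purpose)
  if (lag$E != config$E) {
    stop("lag matrix has E = ", lag$E, " but config has E = ", config$E,
         call. = FALSE)
  }
  lib <- construct_library(lag, t_star, config$policy, purpose)
  p <- lag$E + as.integer(config$intercept)
  if (lib$size < p + 1L) {
    stop("library too small for S-map: ", lib$size, " members for ", p,
         " coefficients", call. = FALSE)
  }
  w <- smap_weights(lag, lib, t_star, config$theta)
  Xlib <- lag$X[lib$member_times, , drop = FALSE]
  if (config$intercept) Xlib <- cbind(1, Xlib)
  y <- lag$Y[lib$member_times + 1L]
  coef <- weighted_svd_solve(Xlib, y, w)
  focal <- lag$X[t_star, ]
  if (config$intercept) focal <- c(1, focal)
  y_hat <- drop(focal %*% coef)
  n_hat <- if (lag$differencing == "first_difference") {
    y_hat + lag$N[t_star + 1L]
  } else {
    y_hat
  }
  if (!config$intercept) coef <- c(0, coef)  # uniform length-(E+1) layout
  structure(list(focal_t = t_star, coefficients = unname(coef),
                 y_hat = y_hat, n_hat = n_hat,
                 weights = w, library = lib),
            class = "edm_smap_fit")
}

# Minimum-norm weighted least squares via SVD with relative cutoff.
weighted_svd_solve <- function(X, y, w, rcond = 1e-10) {
  sw <- sqrt(w)
  A <- X * sw
  b <- y * sw
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1L]
  if (!any(keep)) stop("design matrix numerically zero", call. = FALSE)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  drop(sv$v %*% (dinv * (t(sv$u) %*% b)))
}

#' @export
print.edm_smap_fit <- function(x, ...) {
  cat(sprintf("S-map fit at t* = %d: Y_hat = %.6g\n", x$focal_t, x$y_hat))
  cat("coefficients (intercept first):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-out S-map skill over a grid of theta values
#'
#' For each theta, makes an S-map prediction at every valid focal time and
#' returns the difference-scale Pearson correlation with the observations.
#' Comparing the curve against theta = 0 (the global linear fit) is the
#' usual test for state-dependent (nonlinear) dynamics.
#'
#' @param series Numeric vector of observations.
#' @param E Embedding dimension.
#' @param thetas Numeric vector of candidate theta values (>= 0).
#' @param policy Exclusion policy.
#' @param differencing As in [edm_embed()].
#' @param intercept Passed to [smap_config()].
#' @return Data frame with columns \code{theta}, \code{rho},
#'   \code{n_predictions}.
#' @export
theta_scan <- function(series, E, thetas, policy = exclusion_policy(),
                       differencing = c("first_difference", "none"),
                       intercept = TRUE) {
  differencing <- match.arg(differencing)
  if (length(thetas) == 0L) stop("thetas is empty", call. = FALSE)
  lag <- edm_embed(series, E, differencing)
  tstars <- focal_times_for(lag, "evaluation")
  out <- data.frame(theta = as.numeric(thetas), rho = NA_real_,
                    n_predictions = NA_integer_)
  for (i in seq_along(thetas)) {
    cfg <- smap_config(E, thetas[i], policy, intercept)
    obs <- hat <- numeric(0)
    for (ts in tstars) {
      fit <- tryCatch(smap_predict(lag, ts, cfg, "evaluation"),
                      error = function(e) NULL)
      if (is.null(fit)) next
      obs <- c(obs, lag$Y[ts + 1L])
      hat <- c(hat, fit$y_hat)
    }
    if (length(obs) >= 3L) {
      out$rho[i] <- pearson_rho(obs, hat)
      out$n_predictions[i] <- length(obs)
    }
  }
  out
}
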