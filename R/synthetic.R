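# Seed-deterministic synthetic series for tests and examples, plus a
# fingerprint-checked loader for the published 100-step simulated salmon
# example series used in cross-implementation golden tests (that file is not
# bundled; see load_reference_series).

#' Configuration for the spiky boom-bust generator
#'
#' The generator emulates the phenomenology of semelparous fish population
#' data: values mostly near a low base level, with occasional large spikes
#' followed by an immediate crash back down. It is a Ricker map with
#' multiplicative log-normal noise and occasional large positive shocks:
#' \deqn{N_{t+1} = N_t \exp\{r (1 - N_t / b) + \epsilon_t\},}
#' where \eqn{b} is the base level, \eqn{\epsilon_t \sim
#' \mathcal{N}(0, \sigma^2)} plus, with probability \code{spike_rate}, an
#' extra shock of size \code{spike_scale}. Overcompensation in the Ricker
#' term produces the immediate post-spike crash.
#'
#' @param T Series length (>= 10), default 100.
#' @param base_level Equilibrium low level \eqn{b > 0}; default 0.3
#'   (abstract population units, matching the order of magnitude of the
#'   quiet phase in typical boom-bust examples).
#' @param spike_rate Per-step probability of a large shock, in \eqn{[0,1]};
#'   default 0.1, i.e. roughly one spike per ten steps.
#' @param spike_scale Log-scale size of a shock; default 2.5 (a spike
#'   multiplies the population by about \eqn{e^{2.5} \approx 12}).
#' @param noise_sd Standard deviation of the background log-scale noise;
#'   default 0.3.
#' @param seed Integer seed; fully determines the output.
#' @return Object of class \code{edm_spiky_config} (a validated list).
#' @export
spiky_series_config <- function(T = 100L, base_level = 0.3, spike_rate = 0.1,
                                spike_scale = 2.5, noise_sd = 0.3,
                                seed = 42L) {
  T <- check_count(T, "T")
  if (T < 10L) stop("T must be at least 10", call. = FALSE)
  stopifnot(is.numeric(base_level), base_level > 0,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(spike_scale), spike_scale >= 0)
  if (!is.numeric(spike_rate) || spike_rate < 0 || spike_rate > 1) {
    stop("spike_rate must be a probability in [0, 1]", call. = FALSE)
  }
  structure(list(T = T, base_level = base_level, spike_rate = spike_rate,
                 spike_scale = spike_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "edm_spiky_config")
}

#' Generate a spiky boom-bust series
#'
#' @param config An [spiky_series_config()].
#' @return Numeric vector of length \code{config$T}, strictly positive, with
#'   the generating configuration attached as attribute \code{"config"}.
#' @export
generate_spiky_series <- function(config = spiky_series_config()) {
  stopifnot(inherits(config, "edm_spiky_config"))
  r <- 1.0   # Ricker growth rate; fixed so that post-spike overcompensation
             # crashes the population within one step
  N <- numeric(config$T)
  N[1L] <- config$base_level
  with_seed(config$seed, {
    eps <- stats::rnorm(config$T - 1L, 0, config$noise_sd)
    spikes <- stats::runif(config$T - 1L) < config$spike_rate
    for (t in seq_len(config$T - 1L)) {
      shock <- eps[t] + if (spikes[t]) config$spike_scale else 0
      N[t + 1L] <- N[t] * exp(r * (1 - N[t] / config$base_level) + shock)
    }
  })
  stopifnot(all(is.finite(N)), all(N > 0))
  attr(N, "config") <- unclass(config)
  N
}

#' Generate a linear autoregressive series
#'
#' \eqn{Y_t = \sum_j c_j Y_{t-j} + \epsilon_t} for \eqn{t > p}, seeded with
#' the initial values. With \code{noise_sd = 0} this is an exact linear
#' recurrence, the canonical fixture for S-map coefficient-recovery tests
#' (fit the series with \code{differencing = "none"}).
#'
#' @param coeffs Numeric vector \eqn{c_1, \dots, c_p} (coefficient on lag 1
#'   first).
#' @param init Initial values \eqn{Y_1, \dots, Y_p}; same length as
#'   \code{coeffs}.
#' @param T Output length (> length of \code{init}).
#' @param noise_sd Standard deviation of additive Gaussian noise; default 0.
#' @param seed Integer seed (used only when \code{noise_sd > 0}).
#' @return Numeric vector of length \code{T} with the generating
#'   configuration attached as attribute \code{"config"}.
#' @export
generate_linear_recurrence <- function(coeffs, init, T, noise_sd = 0,
                                       seed = 1L) {
  if (length(coeffs) != length(init)) {
    stop("coeffs and init must have the same length", call. = FALSE)
  }
  p <- length(coeffs)
  if (p == 0L) stop("coeffs must be non-empty", call. = FALSE)
  T <- check_count(T, "T")
  if (T <= p) stop("T must exceed the recurrence order", call. = FALSE)
  y <- numeric(T)
  y[seq_len(p)] <- init
  eps <- if (noise_sd > 0) {
    with_seed(as.integer(seed), stats::rnorm(T - p, 0, noise_sd))
  } else {
    numeric(T - p)
  }
  for (t in seq.int(p + 1L, T)) {
    y[t] <- sum(coeffs * y[t - seq_len(p)]) + eps[t - p]
  }
  attr(y, "config") <- list(coeffs = coeffs, init = init, T = T,
                            noise_sd = noise_sd, seed = as.integer(seed))
  y
}

# Evaluate expr under a seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Load the reference example series, with fingerprint validation
#'
#' Loads the well-known 100-step simulated salmon series used for
#' cross-implementation golden-value tests, from a CSV with a header and a
#' column \code{N} (levels) and/or \code{Y} (first differences), optionally
#' with a time column \code{t}. The file is \emph{not} bundled with this
#' package (redistribution rights for the supplementary data are uncertain);
#' obtain it separately and pass its path, e.g. place it at
#' \code{inst/extdata/reference_series.csv} before building.
#'
#' To prevent silently testing against the wrong data, the loader validates
#' fingerprints: \eqn{(Y_1, \dots, Y_4) = (-0.057, 0.059, 5.241, -4.854)}
#' (to 3 decimals) and, when levels are available, \eqn{N_{100} = 0.060}.
#' If only \code{Y} is supplied the level fingerprint cannot be checked and
#' level-scale results are unavailable.
#'
#' @param path Path to the CSV file.
#' @return Numeric vector of levels \eqn{N_t} (or differences if only
#'   \code{Y} was supplied; see attribute \code{"scale"}).
#' @export
load_reference_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  has_N <- "N" %in% names(df)
  has_Y <- "Y" %in% names(df)
  if (!has_N && !has_Y) {
    stop("expected a column 'N' or 'Y' in ", path, call. = FALSE)
  }
  if (has_N) {
    N <- as.numeric(df$N)
    if (length(N) != 100L) {
      stop("expected 100 values, got ", length(N), call. = FALSE)
    }
    check_series(N, "N")
    Y <- first_difference(N)
    if (has_Y) {
      Ygiven <- as.numeric(df$Y)
      if (max(abs(Ygiven[seq_len(99L)] - Y), na.rm = TRUE) > 1e-6) {
        stop("columns N and Y are inconsistent", call. = FALSE)
      }
    }
  } else {
    Y <- as.numeric(df$Y)
    Y <- Y[!is.na(Y)]
    N <- NULL
  }
  fp <- c(-0.057, 0.059, 5.241, -4.854)
  if (length(Y) < 4L || any(abs(Y[1:4] - fp) > 5e-4)) {
    stop("fingerprint mismatch on (Y_1..Y_4): expected (",
         paste(fp, collapse = ", "), "), got (",
         paste(round(Y[seq_len(min(4, length(Y)))], 3), collapse = ", "),
         ")", call. = FALSE)
  }
  if (has_N) {
    if (abs(N[100L] - 0.060) > 5e-4) {
      stop("fingerprint mismatch on N_100: expected 0.060, got ",
           round(N[100L], 3), call. = FALSE)
    }
    attr(N, "scale") <- "N"
    return(N)
  }
  attr(Y, "scale") <- "Y"
  Y
}
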