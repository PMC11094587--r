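# Independent oracles used to cross-check the implementation. These are
# deliberately naive and share no code with the package internals.

# Crossing-out oracle for the candidate library: scans every row of the
# (conceptual) T x E lag matrix and applies the four exclusion conditions
# literally, cell by cell. L is the length of the embedded series
# (T - 1 when first-differenced).
oracle_library <- function(T, E, t_star, mode = "default", radius_k = 0L,
                           L = T - 1L) {
  row_defined <- function(t) {
    if (t < 1L || t > T) return(FALSE)
    idx <- t - seq_len(E) + 1L
    all(idx >= 1L & idx <= L)
  }
  members <- integer(0)
  for (t in seq_len(T)) {
    if (t == t_star) next                                   # (a)
    if (!row_defined(t)) next                               # (b)
    if (!row_defined(t + 1L)) next                          # (c)
    if (mode == "default") {
      if (t >= t_star + 1L && t <= t_star + E) next         # (d)
    } else {
      if (abs(t - t_star) <= radius_k) next
    }
    members <- c(members, t)
  }
  members
}

# Brute-force simplex prediction straight from the defining formulas:
# explicit lag matrix, explicit distances, full sort, exponential weights.
oracle_simplex <- function(y, E, t_star, members, k = E + 1L) {
  L <- length(y)
  lagvec <- function(t) {
    idx <- t - seq_len(E) + 1L
    ifelse(idx >= 1L & idx <= L, y[idx], NA_real_)
  }
  focal <- lagvec(t_star)
  d <- vapply(members, function(t) sqrt(sum((focal - lagvec(t))^2)),
              numeric(1))
  ord <- order(d, members)
  sel <- ord[seq_len(k)]
  dd <- d[sel]
  w <- if (dd[1L] > 0) exp(-dd / dd[1L]) else {
    ww <- rep(1, k)
    pos <- dd > 0
    if (any(pos)) ww[pos] <- exp(-dd[pos] / min(dd[pos]))
    ww
  }
  targets <- y[members[sel] + 1L]
  list(y_hat = sum(w * targets) / sum(w),
       psi = members[sel], d = dd, w = w)
}

# Textbook Pearson correlation from the covariance/SD definition.
oracle_rho <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# A strictly periodic positive series: `reps` repetitions of a fixed block.
periodic_series <- function(block, reps) rep(block, reps)

# Path to the (unbundled) reference example series; golden-value tests skip
# when it is absent.
reference_series_path <- function() {
  system.file("extdata", "reference_series.csv", package = "edmforecast")
}

# Synthetic stand-in file that passes the loader's fingerprints: the first
# five values reproduce the published differences and the final level; the
# middle is filler. Only used to exercise the loader's validation logic,
# never as a substitute for the real data.
write_synthetic_fingerprint_csv <- function(path, perturb_Y3 = FALSE,
                                            truncate = FALSE,
                                            column = "N") {
  y_head <- c(-0.057, 0.059, 5.241, -4.854)
  if (perturb_Y3) y_head[3L] <- 99
  N <- numeric(100)
  N[1L] <- 0.10
  for (i in 1:4) N[i + 1L] <- N[i] + y_head[i]
  N[100L] <- 0.060
  N[5:100] <- seq(N[5L], N[100L], length.out = 96L)
  if (truncate) N <- N[1:50]
  if (column == "N") {
    df <- data.frame(t = seq_along(N), N = N)
  } else {
    Y <- diff(N)
    df <- data.frame(t = seq_along(Y), Y = Y)
  }
  utils::write.csv(df, path, row.names = FALSE)
  path
}
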