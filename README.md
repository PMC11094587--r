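# edmforecast

Empirical dynamic modelling (EDM) for ecological and other time series:
simplex projection and S-map forecasting on delay embeddings, with every
intermediate quantity — candidate libraries, neighbour times, distances,
weights, local coefficients — exposed for inspection and
cross-implementation comparison.

## The problem

Population forecasts are usually made by fitting a prescribed mechanistic
model. EDM instead reconstructs the system's dynamics directly from the
data: a series \(N_1, \dots, N_T\) is first-differenced,
\(Y_t = N_{t+1} - N_t\), and embedded as delay vectors
\(x_t = (Y_t, Y_{t-1}, \dots, Y_{t-E+1})\) in an E-dimensional state space.
To predict from a focal time \(t^*\), the simplex algorithm finds the
\(E+1\) nearest neighbours of \(x_{t^*}\) among the eligible library
vectors, weights them by
\(w_i = \exp(-\lVert x_{t^*} - x_{\psi_i}\rVert / \lVert x_{t^*} -
x_{\psi_1}\rVert)\) (so the nearest always has weight \(e^{-1} = 0.368\)),
and averages where they went one step later:

\[\hat{Y}_{t^*+1} = \frac{\sum_{i=1}^{E+1} w_i Y_{\psi_i + 1}}
                        {\sum_{j=1}^{E+1} w_j}.\]

Forecast skill is the Pearson correlation \(\rho\) between predictions and
observations over all valid focal times; the embedding dimension \(E\) is
chosen to maximise it. The S-map variant fits a locally weighted linear map
over the whole library with weights \(\exp(-\theta d / \bar{d})\); at
\(\theta = 0\) it reduces to a global linear autoregression.

What this package makes explicit — and what most EDM descriptions leave
implicit — is the bookkeeping:

- **valid focal times**: \(t^* \in \{E, \dots, T-2\}\) for evaluation,
  with \(t^* = T-1\) allowed only for the true forecast;
- **the candidate library** \(\mathcal{L}_{E,t^*}\): vectors excluded
  because they (a) are the focal vector, (b) contain undefined lags,
  (c) have an undefined successor, or (d) contain the very value
  \(Y_{t^*+1}\) being predicted;
- **its size in closed form**:
  \(C_{E,t^*} = T - 2(E+1) + \max(0,\, t^* - (T-E-2))\) — constant over
  most focal times, climbing by one per step over the last \(E\);
- an **exclusion-radius option** reproducing the behaviour of toolkits that
  keep temporally adjacent vectors (condition (d) off), which is exactly
  where implementations disagree.

Multivariate embeddings (several variables with per-variable lags) use the
same library rules with \(E\) replaced by \(m+1\), \(m\) the maximum lag.

## Worked example

```r
library(edmforecast)

# a spiky boom-bust series: mostly low values, occasional spikes followed
# by immediate crashes (seed-deterministic)
s <- generate_spiky_series(spiky_series_config(T = 100, seed = 42))

# library bookkeeping: size at T = 50 is 44 for E = 2 in the usual region,
# climbing to 46 at the last valid focal time
library_size(50, 2, 10)   # 44
library_size(50, 2, 48)   # 46

# choose E by leave-one-out correlation, then forecast one step ahead
ev <- select_E(s, 2:6)
ev
#> Embedding-dimension selection (rho on the difference scale):
#>   E rho_Y rho_N n_predictions
#> 1 2 0.744 0.396            97
#> 2 3 0.745 0.307            96
#> 3 4 0.723 0.240            95
#> 4 5 0.731 0.254            94
#> 5 6 0.730 0.255            93
#> Selected E* = 3 with rho = 0.745

fc <- forecast_next(s, ev$E_star, remedy = "clamp_to_min")
fc$y_hat   # 0.5379103  predicted next first-difference
fc$n_hat   # 0.8426199  forecast population one step past the data
```

`rho_Y` is skill on the difference scale (used for selection); `rho_N` on
the level scale — the two can disagree, which is why both are reported. The
forecast is a convex combination on the difference scale, so the level
forecast can go negative for population data; `remedy = "clamp_to_min"`
replaces a negative forecast with the smallest observed value.

Single predictions with full neighbour bookkeeping:

```r
lag <- edm_embed(s, 2)
predict_point(lag, 39)$neighbours   # psi_i, distances, weights
smap_predict(lag, 30, smap_config(2, theta = 2))  # local linear coefficients
theta_scan(s, 2, c(0, 0.5, 1, 2, 4))              # nonlinearity test
```

## Command line

```sh
Rscript inst/cli/edm generate --kind spiky --T 100 --seed 42 -o series.csv
Rscript inst/cli/edm library --T 50 --E 2 --tstar 10      # size: 44 + members
Rscript inst/cli/edm library-grid --T 50 --Emax 8 -o grid.csv
Rscript inst/cli/edm evaluate --input series.csv --Emax 6 -o rho.csv
Rscript inst/cli/edm simplex --input series.csv --E 3 -o pred.csv
Rscript inst/cli/edm forecast --input series.csv --E 3 --remedy clamp
Rscript inst/cli/edm run --input series.csv --Emax 6 --output-dir out/
```

`run` writes predictions, per-E skill, neighbour bookkeeping, a forecast
JSON and a log; data files carry full double precision for diffing against
other implementations.

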