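---
title: "Simplex projection and S-map forecasting: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplex projection and S-map forecasting: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmforecast)
```

## The model

Empirical dynamic modelling makes forecasts without prescribing a
mechanistic model. The assumptions are minimal but real: the observed series
is taken to be generated by an underlying deterministic system (possibly
noisy) whose state can be reconstructed from lagged observations. If the
system were purely stochastic, nothing here would work — and the diagnostic
for that failure mode is visible in the output (no embedding dimension shows
a pronounced skill maximum; skill keeps changing with `E` without peaking).

Given observations $N_1, \dots, N_T$, the pipeline is:

1. **Difference**: $Y_t = N_{t+1} - N_t$, $t = 1, \dots, T-1$. This removes
   a simple linear mean trend. It is optional (`differencing = "none"` embeds
   the raw values, with every index rule shifted accordingly); the package
   never auto-selects between the two, because no principled tie-break
   exists — sensitivity to differencing is data-dependent and should be
   tested by the analyst.
2. **Embed**: delay vectors $x_t = (Y_t, \dots, Y_{t-E+1})$ form the rows of
   a $T \times E$ matrix. Rows $1..E-1$ and $T$ contain undefined cells
   (lags before the series start; $Y_T$ does not exist). Undefined cells are
   `NA` — unambiguous because gappy input is rejected at the door rather
   than imputed.
3. **Choose a focal time** $t^*$ with $x_{t^*}$ fully defined. For
   evaluation, $Y_{t^*+1}$ must also be known, so
   $t^* \in \{E, \dots, T-2\}$; only the true forecast may use $t^* = T-1$.
4. **Build the candidate library** by exclusion:
   (a) the focal vector itself; (b) vectors with undefined cells;
   (c) vectors whose successor is undefined (we must know where a neighbour
   went); (d) vectors containing $Y_{t^*+1}$, the value being predicted —
   i.e. times $t^*+1, \dots, t^*+E$.
5. **Predict** (simplex): the $E+1$ nearest library vectors by Euclidean
   distance, weighted $w_i = \exp(-d_i/d_1)$, vote on where the system goes:
   $\hat{Y}_{t^*+1} = \sum w_i Y_{\psi_i+1} / \sum w_j$.
6. **Score**: Pearson $\rho$ between predictions and observations over all
   valid $t^*$; pick the $E$ maximising it; forecast with that $E$.

### The library size in closed form

Conditions (a)–(d) interact with the series ends. Away from them the
library has $C_E = T - 2(E+1)$ members; for the last $E$ focal times the
condition-(d) window overlaps the end-of-series exclusions and the size
climbs by one per step:

$$C_{E,t^*} = T - 2(E+1) + \max\{0,\ t^* - (T - E - 2)\}.$$

This expression sometimes appears typeset as $T - 2E + 1$, which is
inconsistent with its own worked values ($C_2 = 44$ and $C_3 = 42$ at
$T = 50$ require $T - 2E - 2$); the package implements, tests and documents
the $T - 2(E+1)$ reading, verified exhaustively against a crossing-out
oracle that literally deletes rows from the lag matrix.

```{r}
library_size(50, 2, 10)                                   # usual region: 44
sapply(41:48, function(ts) library_size(50, 8, ts))       # climb 33..40
```

### Exclusion policies

Condition (d) is where mature EDM implementations genuinely differ: some
keep temporally adjacent vectors in the library even though they contain the
value being predicted, offering instead an exclusion *radius* around $t^*$.
Both behaviours are first-class here and never silently mixed:

* `exclusion_policy("default")` — conditions (a)–(d). Chosen as the default
  because using a vector that contains the target value leaks information
  when measuring predictive skill.
* `exclusion_policy("radius", k)` — conditions (a)–(c) plus
  $|t - t^*| \le k$; `k = 0` excludes only the focal vector among temporal
  neighbours, matching the permissive default of radius-based toolkits.

The default library is always a subset of the radius-0 library. On real
boom-bust data at $E = 2$ the two typically disagree at only a couple of
focal times — but those disagreements grow with $E$, since condition (d)
removes $E$ vectors. In forecast mode ($t^* = T-1$) the condition-(d)
window lies wholly beyond the data, so the policies agree on the forecast
itself; they still affect $\rho$ and hence which $E$ gets used. Whether a
radius should also apply symmetrically in forecast mode is unspecified in
the literature we follow; we apply the same rule symmetrically for
consistency.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `E` | embedding dimension; also sets neighbour count $E+1$ | selected over `2:floor(sqrt(T))` | above $\approx\sqrt{T}$ the library (size $\approx T - 2(E+1)$) becomes too thin to populate an $E$-dimensional space |
| `k` | neighbours used by simplex | $E+1$ | the geometric simplex; exposed because altering it is a legitimate experiment |
| `theta` | S-map localisation (dimensionless) | 0 in `smap_config` | $\theta = 0$ is the global linear benchmark; skill rising with $\theta$ is evidence of state-dependent dynamics |
| `differencing` | first-difference or embed raw values | `"first_difference"` | removes linear trend; both exposed, never auto-selected |
| `remedy` | handling of negative level forecasts | `"none"` | difference-scale predictions are convex combinations, level forecasts are not; clamping to the observed minimum and log-transforming are offered, log-transform changes neighbour geometry and therefore results |

## Numerical choices

* **Tie-breaking.** Equal distances are ranked by ascending time index —
  deterministic and reproducible. Comparisons use exact equality of computed
  doubles, no epsilon: an epsilon would merely relocate the arbitrariness
  while making it platform-dependent.
* **Coincident points.** $w_i = \exp(-d_i/d_1)$ is $0/0$ when the focal
  vector has an exact duplicate in the library ($d_1 = 0$). The implemented
  limit: all zero-distance neighbours get weight 1; remaining weights use
  the smallest positive distance as denominator; all-zero distances give
  equal weights. This preserves convexity and continuity.
* **S-map solve.** Weighted least squares through an SVD with a relative
  singular-value cutoff of $10^{-10}$: libraries are small and can be
  collinear (e.g. a series that has collapsed onto a low-dimensional
  subspace), and the minimum-norm solution keeps predictions well-defined
  there. A consequence worth knowing: on a strongly damped linear recurrence
  the states collapse onto one eigendirection, predictions remain exact but
  the individual coefficients are no longer identifiable — coefficient
  recovery tests therefore use an oscillatory (complex-root) recurrence,
  whose orbit spans the plane.
* **S-map weights** are $\exp(-\theta d_t/\bar{d})$ with $\bar{d}$ the mean
  library distance, intercept included by default (conventions differ; it is
  a flag). Predictions are invariant to rescaling all weights, which is
  tested.
* **Degenerate inputs.** Missing values are rejected, never imputed. Focal
  times whose library is empty are dropped from $\rho$ pairing (and logged),
  not imputed. $\rho$ is refused (error, naming the offending side) when
  either vector has zero variance.
* **Exact arithmetic caveat.** `undifference(Y_t, N_t)` equals $N_{t+1}$
  only to one ulp: $(a-b)+b$ need not equal $a$ in floating point. Tests
  use tolerance-based equality for this identity and bit-identity everywhere
  determinism is claimed.

## Evaluation design

Skill is computed on two scales. Selection uses $\rho$ on the difference
scale ($\hat{Y}$ vs $Y$); the level scale ($\hat{N}_{t^*+2} =
\hat{Y}_{t^*+1} + N_{t^*+1}$ vs $N_{t^*+2}$) is reported alongside because
high difference-scale correlation does not imply high level-scale
correlation, and the level is usually what a manager cares about. The level
pairing is forced by the differencing identity — there is no other index
alignment consistent with $Y_t = N_{t+1} - N_t$.

Larger $E$ admits fewer valid focal times, so small-$E$ evaluations include
early (often poorly predicted) focal times that large-$E$ evaluations never
see. `common_tstar = TRUE` restricts every $E$ to the shared focal-time set
before computing $\rho$; the default is `FALSE` (the customary procedure),
and the option exists precisely because the customary procedure compares
$E$ values on unequal footing.

Ties in the $E$ selection go to the smallest $E$ (parsimony). For longer
series, `split_half_evaluate()` builds the library from first-half vectors
only and predicts second-half focal times.

## Multivariate embeddings

Coordinates are (variable, lag) pairs; the target is always the first
coordinate's variable one step ahead. The library rules are the univariate
ones with $E$ replaced by $m+1$ ($m$ = maximum lag), so the library size
depends only on $(T, m, t^*)$ — adding variables at lags $\le m$ changes
nothing. A single variable at consecutive lags is bit-identical to the
univariate path (tested, including downstream predictions). Euclidean
distance mixes units, so an optional per-variable z-scoring
(`standardise = TRUE`) is provided; it is off by default to keep univariate
comparability, and turning it on changes neighbour geometry and results.

## What the synthetic generator does and does not establish

`generate_spiky_series()` is a Ricker map with log-normal noise and
occasional large positive shocks:
$N_{t+1} = N_t \exp\{r(1 - N_t/b) + \epsilon_t\}$, $r = 1$, with a shock of
size 2.5 added to $\epsilon_t$ with probability 0.1 per step (defaults:
$T = 100$, base level $b = 0.3$, background noise sd 0.3). These values were
chosen once to reproduce the stated phenomenology — mostly low values,
roughly one spike per ten steps, each spike crushed within one step by
Ricker overcompensation — and are not tuned against any test statistic. The
generated phase plane shows the characteristic three-arm structure (spike
onset, crash, recovery) with an empty "two large rises in a row" corner,
and the tests assert exactly that.

What a green test on this generator establishes: the bookkeeping, the
algorithms and the determinism of the pipeline on data with the right
qualitative geometry. What it does not establish: agreement with any
published numeric result (that is the golden suite's job, active only when
the unbundled reference series file is supplied — see
`?load_reference_series`), nor performance on data with observation error,
trends, or regime shifts, none of which the generator emulates.

`generate_linear_recurrence()` provides exact linear fixtures for the S-map
oracle tests ($\theta = 0$ must match an unweighted least-squares fit to
$10^{-8}$; noise-free recurrences must be predicted with ~zero residuals).

## Known limitations

* No treatment of missing observations (rejected, not imputed) and no
  detrending other than first differencing.
* Exact, exhaustive neighbour search only — appropriate because libraries
  are small by construction; no KD-trees.
* No bootstrap confidence intervals for predictions, and no convergent
  cross-mapping; `k` and the policy switches provide the hooks a user would
  need to build the former.
* The S-map coefficients are returned for inspection but no
  Jacobian/interaction-strength analysis is built on them.
* Forecasts are one-step-ahead only; iterating forecasts feeds estimated
  values back into the embedding and is deliberately not provided.
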