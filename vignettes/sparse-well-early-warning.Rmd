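---
title: "Sparse-coding early warning for bacterial contamination in water wells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-coding early warning for bacterial contamination in water wells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsewell)
```

## The surveillance problem

Fecal coliform counts from supply wells arrive a handful of times per
quarter, at dates chosen by the utility, and are overwhelmingly zero.
Contamination arrives as exponential growth episodes: a run of small
non-zero counts over days to weeks, then counts above the regulatory
threshold of 10 CFU/100 ml. The monitoring question is not "is this sample
high?" (the standard answers that) but "does the recent pattern look like
the run-up to an exceedance?" — a prediction problem on a sparse,
irregular count series.

`sparsewell` treats the count record as a signal. Its chain is:

grid → label → window → DCT → reduce → classify → alarm → evaluate.

This vignette explains each stage, the tunable parameters, the numerical
choices, and what the synthetic test bed does and does not establish.

## Gridding and the fictitious-zero argument

`to_daily_grid()` assigns every calendar day between the first and last
sample one slot; unsampled days get value 0 with `observed = FALSE`. The
time axis must be calendar-true — two counts two years apart carry a
different causal relationship than two counts two days apart — and a daily
grid is the natural resolution for 90-day windows.

Inserting zeroes is not a claim that the well was clean on those days. It
is justified *after* the transform: the DCT coefficient
$X_k = \sum_n x_n \cos[\tfrac{\pi}{N}(n+\tfrac12)k]$ is a sum of per-sample
terms, and a zero sample contributes nothing to any coefficient. The
package exposes this as a testable identity
(`zero_contribution_check()`): the transform of a window equals the sum of
count-times-basis-column over its non-zero entries alone. The flip side,
worth stating honestly: the analysis cannot distinguish "measured zero"
from "not measured", so a well that was contaminated while unmonitored
contributes a clean-looking window.

## Events, labels and windows

An *event* is an observed count strictly above `threshold`
(default 10 CFU/100 ml). Strictness matters at the boundary: a count of
exactly 10 — or the borderline 9 — is not an exceedance, and the package
keeps both the threshold and the strict comparison configurable.

`contaminated_spans()` labels the `span_days = 90` days up to and including
each event as contaminated. Ninety days is the regulatory sampling-interval
unit, and labeling the *pre-event* period is what turns classification into
prediction: the classifiers learn the phenomena that led to the exceedance,
not the exceedance itself.

`extract_windows()` labels a window contaminated when any of its days lies
in a contaminated span (`rule = "span"`, the default). The alternative
`rule = "exceedance"` — contaminated only when the window itself contains
an above-threshold observed count — is strictly narrower and is provided
because both readings are defensible; span labeling subsumes exceedance
labeling and gives the classifiers more positive examples of the run-up
phase, which is the phase we want alarms in.

Day indexing is 0-based from the grid start throughout; windows are
inclusive runs of exactly `window_days` entries.

## Spectral representation and dimension reduction

The forward transform is the *unnormalized* type-II DCT written above,
applied verbatim; the inverse applies the standard orthogonality weights
($1/N$ for $k=0$, $2/N$ otherwise). Using the unnormalized form everywhere
keeps classifier features on one consistent scale across windows. Features
are raw coefficients by default; `standardize = TRUE` switches on
training-set centering/scaling, recorded in the stored model.

`select_coefficients()` draws `n_coeffs = 30` of the 90 indices uniformly
without replacement, once per run, from a recorded seed; every window of
the run is reduced with the same indices. Thirty of ninety is the package
default operating point: enough coefficients that run-up structure
survives reduction, few enough that the ellipsoid stays well conditioned
on realistic training sizes (`coefficient_sweep()` reproduces the
trade-off curve on any well). An option to force the DC coefficient into
the selection exists but is off by default — the selection is arbitrary by
design, and determinism comes from the recorded seed, not from a
privileged index.

Two implementation notes. `sliding_spectra(mode = "incremental")` keeps the
running set of non-zero samples inside the window as it slides (one sample
enters, one leaves) and evaluates each coefficient over that active set
only — on sparse grids this does a small fraction of the direct work and
agrees with direct recomputation to floating-point accuracy (tested at
1e-6). And the energy-compaction folklore deserves precision: a window
that is sparse *in time* has its spectral energy spread over many
coefficients (the top 30 of 90 carry far more than their third of the
energy, but not 90 % of it). What makes the reduction work is not
concentration of energy in the top coefficients but the incoherence of
spikes with the cosine basis — which is exactly why basis pursuit can
reconstruct the series from few random coefficients.

## Basis pursuit

`basis_pursuit()` solves $\min \|x\|_1$ s.t. $Ax = b$, where the rows of
$A$ are the measured rows of the DCT matrix. Two solvers are provided:

* `method = "lp"`: the textbook linear program ($x = u - v$, $u, v \ge 0$,
  minimize $\sum(u+v)$), solved with `pracma::linprog`. Rows are scaled to
  unit norm first — pure row scaling, which leaves the solution unchanged
  but keeps the simplex from hitting singular bases. Used by default for
  $n \le 128$.
* `method = "admm"`: a first-order splitting method that alternates
  projection onto $\{x : Ax = b\}$ with soft thresholding. Because DCT rows
  are mutually orthogonal, $AA^\top$ is diagonal and the projection costs
  two matrix-vector products, so the solver scales to thousands of
  variables where a dense simplex does not. Every 100 iterations the
  active support is polished by least squares; a polished point is accepted
  when it is feasible to 1e-8 and its $\ell_1$ norm does not exceed the
  iterate's. Used by default for large $n$.

The two routes are cross-checked against each other and against support
enumeration on small systems. With few measurements the $\ell_1$ optimum
need not be unique (ties occur already at $n = 8$, $m = 4$), so
correctness is asserted on the optimal norm and feasibility, not on a
particular minimizer. "Exact recovery" in the package's tests means a
maximum absolute error below 1e-6.

## Classifiers

**Soft-margin SVM.** `svm_train()` assembles the dual of
$\min \tfrac12\|w\|^2 + C\sum_i S_i$ s.t.
$y_i(w^\top x_i + b) \ge 1 - S_i$, $S_i \ge 0$, and solves it with
`quadprog` (an exact active-set QP solver). Count windows repeat — many
training windows are identical zero vectors — so the kernel matrix is only
positive semi-definite and a ridge of $10^{-7}(\overline{K_{ii}}+1)$ is
added for the solver's benefit (with two larger fallbacks if the active-set
method still fails). The ridge bias is then removed by a KKT polish: the
active set is read off the solution, the free multipliers and $b$ are
recovered exactly from the linear KKT system, and the polished point is
accepted only if it satisfies every KKT condition; several active-set
thresholds are tried and the best valid polish kept. Tests certify the
result two ways: the duality gap of the returned solution is below
$10^{-7}$, and the objective matches an independent reference QP (libsvm
via e1071, run to tolerance 1e-12 without shrinking) to 1e-6. Default
kernel linear with $C = 1$; RBF and polynomial kernels are available.
Decision ties ($w^\top x + b = 0$) resolve to the normal class: an alarm
requires strictly positive evidence.

**Minimum-volume ellipsoid.** `mve_fit()` implements Khachiyan's algorithm
on the lifted points: starting from uniform weights (the largest feasible
trial ellipsoid), each iteration shifts weight toward the point most
outside the current trial ellipsoid, shrinking it until the weight update
falls below `tolerance` (default 1e-7, capped at $10^5$ iterations, with
rank-1 updates of the inverse and a full recompute every 500 iterations
for numerical hygiene). The fitted shape is rescaled so the most extreme
training point lies exactly on the boundary — containment of the training
set is then exact rather than approximate, at the cost of a volume factor
bounded by the convergence tolerance. A rank-deficient normal cloud (fewer
independent window shapes than feature dimensions — the common case on
very sparse wells) triggers a ridge of $10^{-8}\,\mathrm{tr}(S)/m$ on the
scatter and a warning. The consequence is operationally conservative: in
directions the training data never explored, the ellipsoid is extremely
thin, so any count at a previously unseen window position is flagged. That
raises the false-positive day fraction on sparse wells and is the main
price of one-class training; it is reported, never hidden.

**Delay-embedded network.** `ann_fit_grid()` embeds a scalar series as
$y(t) = f(y(t-1), \ldots, y(t-d))$ and fits one hidden layer of $f$ units
(`nnet`, quasi-Newton optimization, fixed-seed initialization, inputs
scaled by the series maximum) for every $(f, d)$ on the grid, keeping the
pair with minimal normalized MSE (MSE over target variance; for a
zero-variance target the raw MSE is used, so a constant series scores ~0).
In the pipeline the network embeds the raw daily counts: the recursion is
scalar, whereas the reduced representation is a 30-vector per window, so
"reduced-coefficient" input would require an arbitrary scalarization;
`ann_fit_grid()` itself accepts any scalar series if the user prefers one.
`ann_alarm()` iterates the network forward and alarms when any forecast
within the horizon (default 14 days) exceeds the event threshold — the
forecasted window would be labeled contaminated under the training rule.

## The energy alarm

The signal energy of a count vector is $\sum x^2$; `energy_jump()` reports,
for each day, the energy of the trailing `window_days` — equivalently the
increment of cumulative energy over that window. The phrase "change in
energy between successive counts" and the phrase "window size by which the
energy change is computed" pull in different directions; the trailing
window reading is the one under which optimized window sizes of hundreds
of days are meaningful, and it reduces to the successive-count difference
when the window just covers the last inter-sample gap.

`pareto_search()` scores every (threshold, window) pair by average time
saved and false-positive day fraction and returns the non-dominated set.
Candidate defaults: 50 log-spaced thresholds spanning the observed positive
jump range, windows 10–400 days in steps of 10. Since no selection rule is
canonical, the package picks the knee — the frontier point at maximal
perpendicular distance from the chord joining the frontier extremes, after
rescaling both objectives to [0, 1] — and offers "max time saved subject to
an FP cap" as the alternative. Each well gets its own optimum; nothing
suggests thresholds or windows transfer between wells. The energy alarm is
a crude activity indicator, not the production detector: it sees total
activity, not its pattern.

## Pipeline, training regime and evaluation

`run_well()` composes the chain. The training span is a prefix of the
record (`history_days`, default half the grid — enough multi-year history
to contain several episodes); the SVM requires both labels in that span,
the MVE at least $m+1$ normal windows. Training windows are cut at
`train_stride = 7` days: daily training windows are highly redundant
(adjacent windows share 89 of 90 days) and a weekly stride keeps the QP
and the ellipsoid well fed at a fraction of the cost. Prediction windows
slide at `stride = 1` day, and a contaminated classification throws an
alarm on the window's last day.

`evaluate_alarms()` credits an event as detected when an alarm falls in
$[e - 90, e)$; time saved is the gap from the first such alarm, hence in
$[1, 90]$ by construction. The false-positive denominator — never defined
unambiguously for percentages printed without a base — is the number of
evaluated days outside every contaminated span; alarm days inside a span
are never false positives, even after the event day (the event has
occurred; the alarm is late, not wrong). This definition is stated
prominently because comparability of any published FP percentage depends
on it. With zero events the FN fraction and time saved are undefined and
flagged rather than coerced to a number.

Rolling retraining (refitting as the series grows) is a natural extension
and deliberately out of the default path: a fixed training prefix keeps
every downstream number attributable to one model.

## The synthetic test bed

`generate_well()` emulates the documented statistical shape of real well
records: routine samples at geometric gaps (`mean_interval_days = 15`,
within the 12–44 day range of documented wells), ~10.7-year spans,
baseline counts zero with probability 0.95 (else 1–3 CFU/100 ml),
outburst episodes at `outburst_rate = 0.9`/year with at least 180 days
separation, exponential growth at `growth_rate = 0.15`/day to a random
peak capped at `max_count = 120` CFU/100 ml, sampling densified roughly
threefold during episodes (the regulatory response), a guaranteed strictly
rising sub-threshold run-up of `runup_samples = 3` non-zero counts before
the first exceedance, and a short decay tail. With `runup_samples = 0`
episodes degenerate to isolated single-sample spikes — the unpredictable
case. Every episode is logged with its start, peak and first exceedance
for ground-truth evaluation.

What the generator does *not* emulate: seasonality and inter-episode
dependence (episodes are a stationary renewal process), measurement error
and lab censoring, well shutdown gaps, slow baseline drift, and
correlated multi-well contamination. Consequently, passing the synthetic
suite shows the pipeline recovers the episode structure it was told to
expect — run-ups that resemble training run-ups — not that real wells are
this predictable. The honest reading of the synthetic detection rates is
as a correctness check of the machinery under favorable, controlled
conditions; transfer to a particular well still depends on that well's
history, as it does for any trained detector.

## Numerical choices, in one place

* DCT round-trip tolerance 1e-9; incremental-vs-direct tolerance 1e-6.
* Basis pursuit: feasibility 1e-8; "exact recovery" at 1e-6; LP default
  below n = 128, splitting solver above; splitting step parameter set from
  the scale of the minimum-norm feasible point.
* SVM: quadprog on the ridged dual (ridge $10^{-7}(\overline{K_{ii}}+1)$,
  escalated ×100 / ×10⁴ on failure), KKT polish over active-set thresholds
  {1e-6, 1e-4, 1e-3, 1e-2, 5e-2}, ties to the normal class.
* MVE: tolerance 1e-7 on the weight update, max 1e5 iterations, boundary
  rescaling to exact containment, ridge $10^{-8}\mathrm{tr}(S)/m$ on
  degeneracy (with warning).
* ANN: nnet decay 1e-6, maxit 300 (150 in the pipeline), weight-init seed
  derived from the run seed; nMSE tie-breaks favor the earlier (smaller)
  grid point.
* Generator and pipeline randomness derives from recorded integer seeds;
  identical configuration and seed reproduce `alarms.csv` and
  `report.json` byte for byte.
* Problem sizes in the shipped tests: 90-day windows, 30 coefficients,
  ~10.7-year wells, 20-well cohorts, 3000-day basis-pursuit instances at a
  10 % measurement fraction over 20 seeds — sizes at which the full suite
  runs in a couple of minutes on one CPU.

## Known limitations

* The fictitious-zero device conflates "not sampled" with "clean"; windows
  covering unmonitored contamination look normal.
* One-class training on very sparse wells yields a rank-deficient normal
  cloud; the regularized ellipsoid then flags any count at an unseen
  window position, inflating false-positive days. More history, more
  coefficients-to-data balance, or standardization all soften this.
* The SVM sees the union of run-up spectra across window positions, which
  a single linear hyperplane represents only roughly; kernels help but
  need not match the sample geometry.
* Wells are idiosyncratic: energy thresholds, window sizes and trained
  models do not transfer between wells, and a model trained on too little
  or too messy history degrades — the cure is more history and periodic
  retraining, not parameter tweaking.
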