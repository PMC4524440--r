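---
title: "A branching-process model of preventive and post-diagnostic tumour control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A branching-process model of preventive and post-diagnostic tumour control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoprev)
```

## The model

`oncoprev` simulates the growth of a tumour cell population as a
discrete-time multitype Galton–Watson branching process. Each cell is
labelled by two characteristics: the number of accumulated driver
mutations $i \in \{0, \dots, N\}$ and a resistance status $j \in \{0, 1\}$
(sensitive / resistant to the treatment). A *subclone* is the set of
identical cells sharing $(i, j)$. Cells do not interact — there is no
competition for space or resources — so every subclone grows or shrinks
independently, which is the regime in which a branching process is the
canonical description of clonal expansion.

One time step is a cell cycle of $T = 4$ days. The per-cycle fitness of a
cell, defined as the difference between its division and death
probabilities, is additive in drivers:

$$ f_{ij} = s\,(i + 1) - \sigma\,(1 - j) - c\,j $$

where $s$ is the selective advantage per driver, $\sigma$ the per-cycle
intensity of the treatment (which only affects sensitive cells), and $c$
the constant fitness cost carried by resistant cells. Additivity is the
small-$s$ limit of multiplicative fitness; only the additive form is
implemented.

In one step a cell either divides or dies, with

$$ b = \tfrac{1}{2}(1 + f_{ij}), \qquad d = \tfrac{1}{2}(1 - f_{ij}), $$

so that $b + d = 1$, $b - d = f_{ij}$, and the expected number of
offspring per cell per step is $1 + f_{ij}$. The fitness difference is
what the model pins down; the split $b = (1 + f)/2$ is our convention,
chosen because it keeps exactly one fate per cell per step. This choice
affects the variance (and hence extinction probabilities and spread of
detection times) but not the expected dynamics.

When a cell divides, exactly one daughter may mutate: with probability
$u$ it gains an additional driver ($i \to i + 1$), with probability $v$
it becomes resistant ($j \to 1$), mutually exclusively. There is no back
mutation. At the lattice boundaries the mutation is *wasted*: at $i = N$
a driver mutation is impossible and its probability mass folds back into
plain division, likewise for resistance mutations at $j = 1$. This keeps
the four per-cell fate probabilities normalised exactly.

Given the fates, the population update is multinomial: for every
occupied subclone with $n$ cells, the counts of (death, plain division,
driver division, resistance division) are drawn from
$\mathrm{Multinomial}(n; d,\, b(1{-}u'{-}v'),\, bu',\, bv')$ and the next
state assembled from the offspring rules. Detection occurs when the
total population first reaches the threshold $M$ (checked after each
completed step).

### Baseline parameters

| Parameter | Symbol | Default | Units / note |
|---|---|---|---|
| cell-cycle length | `T` | 4 | days per step |
| driver advantage | `s` | 0.004 | per cycle |
| resistance cost | `c` | 0.001 | per cycle |
| driver mutation rate | `u` | 3.4e-5 | per division |
| resistance mutation rate | `v` | 1e-6 | per division |
| max extra drivers | `N` | — (explicit) | 5 for fixed-composition prevention analyses, 9 for tumours grown from one cell |
| detection threshold | `M` | 1e9 | cells |
| pre-resistance | `kappa` | 1e-4 | fraction of the initial lesion |

These are the empirical baseline estimates the model was parameterised
with. `N` has no default on purpose: the lattice height is an analysis
choice with visible consequences (the critical intensity is
$\sigma_{crit} = s(N+1)$), so the user must own it. The treatment
intensity $\sigma$ is *per cycle*; doses are often quoted as daily
arrest, which at $T = 4$ days is $\sigma / 4$. `load_config()` therefore
accepts `sigma_cycle` or `sigma_day` and refuses ambiguous bare values —
in our experience the single likeliest way to mis-reproduce results in
this family of models is to confuse these two units.

Calendar conversion uses 365 days per year, i.e. 91.25 steps per year;
reported times are `steps * T / 365`.

## Intervention scenarios

All scenarios are built from the same engine; `run_scenario()` runs
replicates, seeding replicate $k$ with `base_seed + k` so outcome sets
are bit-reproducible.

* **Fixed-composition prevention** (`prevention_fixed`): the lesion
  starts as `M0` identical $i = 0$ cells of which a fraction `kappa` (or
  an absolute count `R0`) are resistant, under constant $\sigma$ until
  detection, extinction, or the horizon. This isolates the effect of the
  measure from the history of the lesion.
* **Grown prevention** (`prevention_grown`): the tumour first grows
  untreated from a single sensitive cell to `M0`, accumulating drivers
  (and occasionally resistance) on the way; the treatment clock starts
  at the `M0` event.
* **Post-diagnostic intervention** (`post_diagnostic`): untreated growth
  from one cell to a discovery threshold (10^9 "early" or 10^11 "very
  late"), resection to a residual population (10^4 or 10^6 cells,
  standing in for residual disease or undetected micro-metastases), then
  constant treatment until relapse at $M$.
* **Second chance** (`second_chance`): grown prevention that, on
  failure (detection), is followed by resection back to `M0` cells and
  continued treatment at the same $\sigma$; the protocol fails if $M$
  is reached a second time within 50 years of the `M0` event.

Growth phases condition on non-extinction: attempts that die out
stochastically (probability close to $(1-s)/(1+s) \approx 0.992$ from
one cell) are discarded and redrawn, and the attempt count is recorded.
Resection samples the residual cells proportionally across subclones
(multinomial with replacement — indistinguishable from hypergeometric
sampling when the residual is orders of magnitude below the tumour
size, and cheaper).

Two design points were genuinely open and are resolved as follows.
Relapse-time distributions for small residuals have printed upper
percentiles beyond 50 years, so post-diagnostic runs are uncapped by
default (safety cap 150 years); 50-year horizons apply to the
success-probability protocols. And the second-chance resection leaves
exactly `M0` cells sampled from the detected tumour — *not* a fresh
naive population — so prior selection for resistance carries over, which
is the point of the comparison. For summary purposes we expose both
conventions for failure times (exclude undetected cases, or assign them
the horizon value), since the figure-level convention differs between
panels in this literature.

## The mean-field oracle

The expected counts of the stochastic process evolve linearly,
$\mathbb{E}[n(t{+}1)] = A\,\mathbb{E}[n(t)]$, with the sparse transition
matrix built by `transition_matrix()`: a subclone contributes
$b(2 - u' - v')$ to itself, $b u'$ to $(i{+}1, j)$ and $b v'$ to
$(i, 1)$, each source column summing to $1 + f_{ij}$. This recursion is
the *exact* expectation of the implemented process, so it serves as an
independent analytic oracle: the test suite checks Monte-Carlo subclone
means against it (2000 replicates, 250 steps, within three standard
errors), and `deterministic_detection_time()` provides closed-form-level
sanity checks such as the untreated doubling-time limit
$\lceil \ln 1000 / \ln 1.004 \rceil = 1731$ steps ($\approx 19$ years
from 10^6 to 10^9 cells). Closed-form solutions of the master equations
are deliberately out of scope — the matrix recursion is guaranteed to be
consistent with the simulator, which is what an oracle must be.

Mean and median behaviour diverge in this model: the distribution of
tumour sizes at a fixed time is strongly right-skewed near
$\sigma \approx 2s$, where detection times are also at their most
variable. The expectation recursion tracks the mean; medians come from
simulation only.

## Numerical choices

* Counts are stored as doubles (exact integers up to $2^{53}$, covering
  the 10^11-cell regime). Multinomial draws decompose into conditional
  binomials; for $n \ge 10^9$ a moment-matched rounded normal clamped to
  $[0, n]$ replaces the exact binomial sampler. The approximation error
  at that size is far below Monte-Carlo noise, and the clamping
  preserves non-negativity and exact total conservation.
* Fitness is clipped to $[-1, 1]$ with a warning; baseline parameters
  stay far from the bound (largest $|f|$ in any shipped scenario is
  $\sim 0.04$).
* The step engine is C++ (Rcpp) but draws from R's RNG stream, so
  `set.seed()` gives bit-identical trajectories across runs and
  platforms.
* Percentiles use linear interpolation between order statistics
  (`quantile()` type 7); the "90% confidence interval" of a detection
  time distribution is its 5th–95th percentile band. Detection-time
  histograms use 3-month (0.25-year) bins.
* The negative-exponential relapse regression $y = a e^{-bx}$ is fitted
  by `nls()` seeded from the log-linear solution, falling back to that
  solution when the residuals are identically zero (where `nls` cannot
  iterate).
* Degenerate inputs short-circuit: a lesion already at the detection
  threshold detects at time zero with zero steps; an identity resection
  returns the state unchanged; an empty state stays empty.

## Problem sizes used in tests

The packaged test-suite and acceptance runs use 500 replicates per
scenario arm (1000 for the grown-prevention success probabilities),
10^4 draws for extinction-probability checks, 10^5 draws for
single-cell fate frequencies, and 1000–2000 replicates for the
mean-field comparisons. At these sizes the Monte-Carlo standard error
of a median detection time is roughly 0.2–0.5 years, an order of
magnitude below the tolerances applied to the reproduced statistics.

## What the simulations do and do not show

The synthetic scenarios reproduce the study conditions exactly as
defined: well-mixed exponential clonal growth, a single constant (or
sensitive/resistant-triggered metronomic) measure, one resistance
mechanism shared by all interventions, and resection modelled as
unbiased proportional down-sampling. Passing tests therefore validate
the stochastic engine, the protocols and the statistics — not the
biology they abstract. Real tumours add spatial structure, subclone
competition and cooperation, dose-dependent and multidrug resistance,
microenvironmental feedback, and detection that depends on anatomy
rather than a fixed cell count; none of these is modelled. Times are
calibrated by cell-cycle length and fitness values taken from empirical
estimates for solid tumours, so absolute years should be read as
order-of-magnitude statements.

A final caveat specific to reproduction: the split of fitness into
birth and death probabilities and the placement of mutations on a
single daughter are conventions the model family leaves open. Our
choices yield slightly faster tumour progression (and fewer accumulated
drivers at a given size) than some published realisations of the same
parameter table; the package's tests encode the published statistics
with tolerances wide enough to absorb this, and the one statistic that
falls marginally outside (the relapse median for very late discovery
resected to 10^4 cells) is left as a documented failing expectation
rather than silently re-tuned.
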