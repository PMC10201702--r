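---
title: "Club convergence in health workforce density: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Club convergence in health workforce density: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logtclub)
```

## The question and the model

Do countries approach a common long-run level of physician density, or do
they sort into groups ("clubs") converging to different levels? `logtclub`
answers this with the Phillips–Sul time-varying factor approach. Observed
density is modelled as

$$X_{it} = \delta_{it}\,\mu_t,$$

where $\mu_t$ is a common trend and $\delta_{it}$ a unit-specific transition
coefficient. Convergence means $\delta_{it} \to \delta$ for all units. The
common factor is removed by the *relative transition parameter*

$$h_{it} = \frac{X_{it}}{N^{-1}\sum_i X_{it}},
\qquad H_t = \frac{1}{N}\sum_i (h_{it}-1)^2 .$$

Under convergence every $h_{it} \to 1$ and $H_t \to 0$. The *log-t
regression*

$$\log\frac{H_1}{H_t} - 2\log\log t = \alpha + \beta\log t + \nu_t,
\qquad t = \lfloor rT\rfloor + 1,\ldots,T$$

turns the decay rate of $H_t$ into a slope: if $\delta_{it}$ approaches its
limit at rate $t^{-a}$ (in the canonical semiparametric form), then
$\beta = 2a \ge 0$. Divergence drives $\beta$ (and its t-statistic) negative.
The null of convergence is rejected, one-sided at 5%, when the
autocorrelation-robust t-statistic is **strictly below −1.65**; a value of
exactly −1.65 is not a rejection.

```{r analytic}
# closed-form limit: H_t = t^(-2a) (log t)^(-2) gives beta = 2a exactly
a <- 0.5
H <- (1:30)^(-2 * a) * log(1:30)^(-2); H[1] <- 1
logt_regression(H)$beta_hat
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `transform` | `"log"` | scale on which transition paths are computed; `"levels"` applies the definitions to raw densities |
| `hp_lambda` | 400 | Hodrick–Prescott weight for per-unit trend smoothing before the transition paths (annual convention); `NULL` disables |
| `trim` ($r$) | 0.3 | fraction of early periods discarded before the regression, the convention for annual data; $\lfloor rT\rfloor$ is a floor |
| `crit` | −1.65 | one-sided 5% critical value |
| `bandwidth` | automatic | Newey–West lag truncation $\lfloor 4 (T_{reg}/100)^{2/9}\rfloor$ on the retained sample |
| `order_fraction` | 0.5 | final-window share used to order units (and rank clubs); more robust than the last observation alone |
| `cstar`, `cstar_step` | 0, 0.05 | initial sieve criterion and its escalation step |

Two of these deserve comment, because the printed definitions of the method
leave them open. First, the transition-path equation is written in levels,
but standard practice for trending positive series — and the reference
implementations of this test — work on logs with HP-smoothed series; we make
log + smoothing the default and record the choice in every result
(`source_transform`, and the config echo in reports), keeping `"levels"`
fully supported. Second, the robust standard error is a Bartlett-kernel
(Newey–West) long-run variance on the regression scores with the bandwidth
rule above; the bandwidth is exposed because published t-statistics can be
sensitive to it. $H_1$ in the dependent variable is always the variance at
$t=1$, before trimming.

## The clustering algorithm

When full-sample convergence is rejected, clubs are found endogenously — the
number of clubs is never fixed a priori, and finding none is a valid outcome:

1. **Order** units by the mean of the final half of their (log, smoothed)
   series, decreasing; ties break lexicographically by id.
2. **Core search**: scan prefixes of the ordering with the log-t test,
   stopping at the first prefix that fails; the core is the prefix with the
   largest passing t-statistic. If even the top pair fails, the top unit is
   set aside and the search restarts on the remainder. No qualifying pair at
   all means an empty core ("all divergent").
3. **Sieve**: each remaining unit is provisionally added to the core alone
   and kept when the augmented t-statistic exceeds $c^*$ (initially 0, a
   deliberately conservative bar for short panels). If the assembled club
   then fails its own log-t test, $c^*$ rises by 0.05 and the sieve repeats;
   in the limit the club shrinks back to the core, which passed by
   construction, so the loop always terminates.
4. **Recurse** on the remainder. Leftovers that form no club — including any
   final singleton, since a club needs at least two members — are divergent.
5. **Merge**: adjacent clubs (by rank) whose union passes the log-t test are
   merged, restarting the scan after every merge; every attempt is logged.
   Clubs surviving this are the "strong" clubs, renumbered so Club 1 has the
   highest final-window density.

Every reported club therefore satisfies its own log-t test at the −1.65 bar,
and clubs plus the divergent set partition the panel exactly.

## Numerical choices and degenerate inputs

* Subset statistics inside the search use the identity
  $H_t = n\,Q_t/S_t^2 - 1$ with $S_t, Q_t$ the subset's column sums and sums
  of squares, updated incrementally; a dedicated test pins this path to the
  standalone `relative_transition()` + `logt_regression()` pipeline.
* $H_t < 10^{-14}$ is snapped to exactly 0: a cross-sectional spread of $h$
  below $10^{-7}$ is machine-precision convergence. A zero $H_t$ on the
  retained window is *perfect convergence*, reported with a $+\infty$
  t-statistic sentinel, never a division error.
* On the log scale, densities below 1 per 10,000 have negative logs, so a
  small subset's cross-sectional mean can fail to be positive and the
  transition paths are undefined. The user-facing pipeline raises a classed
  error naming the year; inside the clustering search such a subset simply
  carries no evidence of convergence and scores as a rejection
  ($t = -\infty$), which keeps the search total and deterministic. Final
  clubs always carry real statistics, because a club must pass its own test.
* All orderings use radix sort (locale-independent); identical inputs yield
  byte-identical partitions.
* HP smoothing solves $(I + \lambda D'D)\tau = y$ by dense Cholesky, with the
  factorization cached per (length, $\lambda$).

## The synthetic data generator

`simulate_panel()` draws panels from the same factor model the test assumes:
$\mu_t = \mu_0(1+g)^t$ and, for a unit of club $c$,

$$\delta_{it} = \delta_c + \frac{\sigma_i\,\xi_{it}}{\log(t+1)\,(t+1)^{\alpha}},
\qquad \xi_{it} \sim N(0,1),$$

so the log-t slope targets $2\alpha$ analytically — the generator and the
test share the model but no code. Draws that would make $\delta_{it}$
non-positive are resampled (preserving the Gaussian shape; the count is
recorded). Divergent units follow deterministic log-linear trends with
distinct slopes fanning upward away from the club range, so divergence is
exact and power statements are clean; starting the fans above the highest
club also keeps all log-values positive.

Defaults emulate a worldwide physician panel: 204 units in clubs of
110/66/28 over 30 years from 1990, club limits (2.1, 0.8, 0.2) against
$\mu_0 = 10$ per 10,000 growing 2.5% a year — the top club ends near 21
physicians per 10,000, the level high-income countries cluster around —
with $\alpha = 0.5$, baseline noise 0.3 and per-unit scales
$\sigma_i \sim U(0.5, 1.5)\times 0.3$. The generator emulates the *shape*
of real density panels, not their full texture: no measurement-error
autocorrelation, no population weighting, no club limits drifting over time,
and the divergent paths are noiseless by design. Passing recovery tests on
these panels shows the algorithm recovers structure the model can express;
it does not certify behaviour under features the generator omits.

```{r sim, eval = FALSE}
sim <- simulate_panel(sim_config(n_divergent = 3, seed = 1))
report <- run_analysis(sim$panel)
report
```

## Validation problem sizes

The shipped tests validate, with fixed seeds: exactness of the closed-form
checkpoint ($\beta = 2a$ to $10^{-8}$); agreement of OLS/HAC/HP components
with independent brute-force oracles to $10^{-10}$ ($10^{-8}$ for HP) on 50
random instances; test size under a one-club DGP and power under a 2:1
two-club DGP at $N = 50$, $T = 30$ with 500 replicates each; and club-label
recovery on 100 paper-scale replicates (204 club units + 3 fans, $T = 30$),
scored by adjusted Rand index against the generating labels and by the
divergent-flag rate of the fan units.

## Worked-example arithmetic

Two small, exact operations accompany the pipeline. `growth_elasticity()`
is the ratio of two percent changes (e.g. physician-density growth over
GDP-per-capita growth, 129/163 = 0.79). `project_index()` applies an
elasticity to an index level; its default is the **linear** approximation
$b(1 + \varepsilon\,\Delta)$, which is the back-of-envelope form used in
published worked examples (55.6 → 68.4 for a doubling at elasticity 0.23);
the exact log-linear form $b(1+\Delta)^{\varepsilon}$ is available and gives
65.2 for the same inputs — the gap is the approximation error at large
changes, worth knowing before quoting projections.

## Limitations

* The log-t test assumes the decaying-heterogeneity factor structure;
  it has no power against convergence paths outside it, and short panels
  ($T = 30$) make club composition sensitive to the sieve criterion and the
  HAC bandwidth.
* Reproducing published club compositions exactly requires the original
  transform/smoothing/bandwidth choices, which published tables rarely
  state; every report here echoes its full configuration so discrepancies
  are attributable.
* Clubs are descriptive: membership says nothing about *why* a country
  converges where it does, and no covariate modelling is attempted.
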