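---
title: "Multistage cancer risk under size and longevity scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage cancer risk under size and longevity scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoscale)
```

## The model

`oncoscale` implements the multistage (Armitage–Doll-type) model of cancer
initiation. A tissue contains $C$ at-risk stem cells; each divides $k$ times
per year; at each division, each of $M$ required driver mutations arises
with probability $u$; a cell that has accumulated all $M$ drivers initiates
a cancer. Under independent exponential waiting times per driver, the
probability that a given driver is present in a lineage by age $t$ is
$x = 1 - e^{-ukt}$, and the lifetime risk is

$$p = 1 - \left\{1 - (1-e_c)\,\big[(1-e_d)\,x\big]^M\right\}^C ,$$

where the two optional immune-policing terms act multiplicatively: $e_c$ is
the efficiency with which fully transformed cancer cells are detected and
eliminated, and $e_d$ the per-driver efficiency against any cell carrying a
driver mutation. With $e_c = e_d = 0$ this is the classical form; with only
one of them nonzero it is the single-policing extension. The two are allowed
simultaneously (their effects multiply on the per-cell probability) although
typical analyses use one at a time.

Assumptions inherited from this form, and therefore by everything in the
package: all drivers share one rate $u$; driver acquisition is independent
across drivers and across cells; there is no clonal expansion, selection or
niche structure between driver acquisitions; $u$ and $k$ enter only through
their product $uk$ (the package tests assert this exchangeability). $M$ is
biologically an integer, but the risk functions accept real $M$ so that the
added-driver solver can report fractional requirements.

The familiar small-risk approximation $p \approx C(ukt)^M$ is provided
(`lifetime_risk_approx()`) but is not used by any solver. Its leading
relative error is $M\,ukt/2 + Cq/2$ (from linearizing $x$ and the outer
power, $q$ the per-cell probability), so it is reliable only when *both*
terms are small; a bound on $ukt$ alone does not control the error for
large $M$. The test suite verifies sub-1% agreement on the domain
$M\,ukt < 0.012,\ p < 0.005$.

## Parameters and defaults

| symbol | meaning | units | default source |
|---|---|---|---|
| $C$ | at-risk stem cells | count | human tissue measurements, scaled by mass |
| $k$ | stem-cell division rate | divisions/yr | human tissue measurements, MR-scaled |
| $u$ | driver mutation probability | per division | calibrated (see below) |
| $M$ | required driver mutations | count | calibrated integer $\ge 2$ |
| $t$ | age / exposure | years | species lifespan |
| $e_c, e_d$ | policing efficiencies | probability | 0 unless solved for |
| $\beta$ | MR scaling exponent on $k$ | — | 0, −0.15, −0.3 |

The shipped configuration (`default_config()`, YAML under `inst/extdata/`)
defines mouse (0.02 kg, 2 yr), human (60 kg, 80 yr) and blue whale
(150,000 kg, 90 yr), and three human stem-cell compartments: colorectal
(2×10⁸ cells, 73 divisions/yr), hepatocellular (3.01×10⁸, 0.9125/yr) and
esophageal (6.6528×10⁶, 33.2/yr). These tissues were chosen because they
span the parameter corners: large/fast, large/slow, and small/intermediate.

## Allometric scaling

Cell number is taken proportional to body mass, so
$C = C_{\mathrm{ref}} \cdot W/W_{\mathrm{ref}}$. Under the metabolic-rate
(MR) hypothesis, cellular metabolic rate falls as $W^{-0.3}$ (Kleiber's
whole-body 0.7 exponent divided by mass), and the mutation accumulation rate
$uk$ falls proportionally. The package carries this through $k$:
$k = k_{\mathrm{ref}}(W/W_{\mathrm{ref}})^\beta$. Because risk depends only
on $uk$, attributing the change to $k$ rather than $u$ is a labelling
convention with no numerical effect. Writing the scaling against mass
ratios rather than cell-count ratios is equivalent up to a constant absorbed
in the reference rate, since $C \propto W$.

**All scaling anchors on the human reference.** The human $C$ and $k$ are
the empirically measured values; mouse and whale values are both derived
from them. The alternative (chaining mouse → whale through the mouse) gives
identical results because the scalings form a multiplicative group action —
a property the tests assert — provided one anchor is used consistently.

Two consequences of the MR hypothesis frame the analysis:

* *Intraspecific*: with lifespan fixed, $p \propto C^{1+\beta M}$
  (`intraspecific_risk_exponent()`). At $\beta = -0.3$ this gives exponents
  0.4 / 0.1 / −0.2 for $M$ = 2/3/4 — risk should be flat or falling with
  body size within a species for $M \ge 3$, which is the opposite of what is
  observed in humans and dogs; hence the intermediate $\beta = -0.15$ is the
  strongest MR effect treated as viable.
* *Interspecific*: with the lifespan allometry $T = T'C^{0.3}$
  (`lifespan_from_size()`), the product $ukT$ is size-independent at
  $\beta = -0.3$ and the small-p risk grows linearly in $C$ — the MR effect
  cannot neutralize the joint size + longevity increase. The tests verify
  the log–log slope of exactly 1.
* `implied_exponent()` converts an observed mutation-rate ratio between two
  species into the equivalent exponent; a 3-fold mouse/human ratio over
  0.02 vs 60 kg gives −0.137, i.e. about −0.14, motivating −0.15 as the
  intermediate scenario.

## Baseline calibration

The mouse baseline fixes the free parameters $(M, u)$ per tissue and per
$\beta$: the lifetime risk of the hypothetical mouse is pinned at
`p_target` = 1%. Inverting the exact form gives the closed chain

$$q = 1-(1-p)^{1/C}, \qquad x = q^{1/M}, \qquad u = -\log(1-x)/(kt),$$

implemented with `expm1`/`log1p` throughout (`per_cell_target()`,
`solve_u_for_risk()`). For each integer $M \in \{2,\dots,M_{\max}\}$
(default $M_{\max} = 10$, covering the plausible biological range) the
solved $u$ is compared to the anchor $10^{-5}$ per division on a **log10
scale** — candidate rates span orders of magnitude, so linear distance would
always favor the smallest candidate — and the closest is selected, ties
going to the smaller $M$ (a convention; no shipped scenario triggers it).
Note that the solved $u$ *increases* with $M$: requiring more drivers at a
fixed total risk means each driver must be more probable, since
$x = q^{1/M}$ grows with $M$ for $q < 1$.

The mouse cell count is carried at full precision (e.g. 2×10⁸/3000 =
66,666.67), never rounded to an integer: the outer exponent $C$ is a
continuous parameter of the model, and rounding it would shift calibrated
rates by more than the reproduction tolerances used in the tests.

## Hypothesis solvers

For a calibrated baseline and a larger target species, each solver inverts
the **exact** equation — not the small-p approximation, whose error at the
calibration point is already ~1% — for one parameter, holding the others at
baseline:

* fold-reduction in $u$: solve for $u^\ast$ at target scale, report
  $u_{\mathrm{baseline}}/u^\ast$;
* added drivers: $M' = \log q / \log x$ with $x$ at the baseline $u$ and
  target-species $kt$; report $M' - M_{\mathrm{baseline}}$ (real-valued);
* policing of cancer cells: escape $1-e_c = q/x^M$;
* policing of driver-bearing cells: escape $1-e_d = q^{1/M}/x$.

Every solution is verified by substituting it back into the exact risk; the
`achieved_risk` field is asserted (to 10⁻⁶ absolute in the tests), never
assumed. When the target risk is already met (the baseline species itself,
or anything smaller), the solvers return sentinel "no change" solutions
(fold 1, 0 added drivers, escape 1) flagged `no_change_needed`, rather than
erroring. Escapes are clamped at 1. `build_table2()` assembles the full
grid and always reports these internally verified values; the verification
columns ride along in the output so any inconsistency is visible rather
than silent. Display formatting follows comparative-oncology convention
(3 significant figures, capital-E scientific notation, one decimal for
added drivers); full-precision values are what the data frame holds.

## The stochastic simulator

`simulate_cohort()` is the package's brute-force oracle: it realizes the
generative reading of the model rather than its closed form, so agreement
between the two validates the algebra (in particular the unified policing
parameterization) independently of the analytic code path.

Design choices:

* **Per-division Bernoulli(u)** acquisition over `n_divisions = floor(kt)`
  divisions, matching the definition of $u$ as a per-division probability.
  The analytic form uses the exponential $1-e^{-ukt}$; the two differ at
  relative order $u$ (from $\log(1-u) = -u - u^2/2\cdots$), negligible in
  the enforced regime $u \le 10^{-2}$ and bounded explicitly by a test.
* Per cell and per driver, acquisition over $n$ divisions is drawn as
  `rbinom(., n, u) >= 1` — the exact distribution of $n$ per-division
  Bernoulli trials, vectorized. Cells are exchangeable, so only the count
  of cells that have passed each successive driver (and each policing
  check: per-driver escape $1-e_d$, final-cell escape $1-e_c$) is carried.
  The simulator never touches the $x^M$ / outer-power structure it is meant
  to check.
* Desk-scale guards: $C \le 10^6$, $u \le 10^{-2}$, $M \le 6$. Standard
  errors are binomial across replicate cohorts, not within one cohort.
* `generate_scenarios()` draws $u$ and $C$ log-uniformly (defaults
  $u \in [5\times10^{-5}, 2\times10^{-3}]$, $C \in [50, 2\times10^4]$,
  $M \in \{1,2,3\}$, 50–400 divisions, 600 replicates) under a single seed,
  each scenario carrying its own derived seed, so property tests are
  deterministic. The acceptance-style check runs 20 scenarios and requires
  the empirical incidence within 3 standard errors of the exact risk in at
  least 95% of them, with the SE taken at the analytic risk so that
  near-degenerate scenarios ($\hat p \in \{0, 1\}$) are judged fairly.

What passing these tests shows: the closed forms and the generative process
agree under the model's own assumptions. What it does **not** show:
anything about clonal expansion, stem-cell niche architecture, selection
among mutant clones, or the dynamics of immune escape over a tumor's life —
none of which the model contains. The simulator emulates the model, not
real tissue.

## Numerical choices

* All risk evaluation is in log space: the per-cell probability is built as
  $\exp(\log(1-e_c) + M[\log(1-e_d) + \log x])$ and the outer power as
  $-\mathrm{expm1}(C \log(1-q))$. At whale scale ($C \approx 7.5\times
  10^{11}$, $q \approx 10^{-14}$) naive powers underflow to 0 or round to 1;
  the log-space path keeps full precision and is pinned in the tests against
  50-digit arbitrary-precision reference values.
* Inversions are closed-form (no iteration, no tolerance knobs); the tests
  cross-check them against bracketed root-finding (`uniroot` at machine
  tolerance) on every shipped scenario.
* Literal textbook restatements of the risk (used as independent checks in
  the tests) lose roughly $10^{-16}/q$ relative precision to the rounding
  of $1-q$, so equivalence is asserted at $10^{-11}$ relative on the
  well-conditioned region $q \ge 10^{-4}$ and the stable log-space forms are
  used for root-finding elsewhere.
* Degenerate inputs are defined, not special-cased errors: $u = 0$, $t = 0$
  or $e_c = 1$ give risk 0 exactly; saturated per-driver probability with
  $C \ge 1$ gives 1.

## Problem sizes

The test suite and the acceptance script run the full 18-scenario grid
analytically (milliseconds), 20 simulation scenarios of ≤ 2×10⁴ cells × 600
replicates, plus a handful of targeted simulations up to 3,000 replicates —
a few tens of seconds in total on one core. These sizes were chosen so the
Monte Carlo standard errors (~1–2 percentage points) are tight enough to
expose any structural disagreement with the analytic forms while keeping
the suite fast.

## Known limitations

* Identical $u$ across drivers, no dominant/recessive distinction, no
  time-varying rates: the closed form requires them, and relaxing them is
  out of scope here.
* The evolutionary *dynamics* by which any solved parameter change would
  spread (selection coefficients, effective population size thresholds) are
  not modeled; the solvers answer "what change would suffice", not "would
  it evolve".
* Calibration to a hypothetical 1% mouse baseline is a device for comparing
  hypotheses on equal footing, not an estimate of real murine incidence.
* The real-valued added-driver solution is a mathematical requirement;
  biological increments come in units of one (dominant) or two (recessive)
  drivers per recruited gene.
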