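# oncoscale

Multistage carcinogenesis risk scaling across body size and lifespan.

## The problem

The multistage model of carcinogenesis holds that a cancer initiates once a
single cell accumulates *M* driver mutations. If a tissue holds *C* at-risk
stem cells, each dividing *k* times per year with a driver mutation
probability *u* per division, the accumulated lifetime risk by age *t* is

```
p = 1 − {1 − [1 − exp(−u·k·t)]^M}^C                       (exact)
p ≈ C · (u·k·t)^M                                          (small risk)
```

Taken at face value this predicts that large, long-lived species (more cells,
more years) should be overwhelmed by cancer relative to a mouse — yet cancer
incidence is roughly flat across mammals spanning seven orders of magnitude
in mass. That contradiction is Peto's paradox. `oncoscale` implements the
model machinery needed to quantify the paradox and to compare candidate
resolutions:

- **Metabolic-rate (MR) scaling** — cellular metabolic rate declines as
  `W^−0.3`; if somatic mutation accumulation (`u·k`) declines with it, risk
  is partly offset. Exponents 0, −0.15 and −0.3 are tabulated.
- **Lower somatic mutation rate** — the fold-reduction in `u` needed to hold
  lifetime risk at a target.
- **Added genetic suppression** — the number of extra driver mutations
  (added layers of tumor-suppressor control) needed.
- **Immune policing** — the detection efficiency needed against completed
  cancer cells (`e_c`, via `p = 1 − {1 − (1−e_c)·x^M}^C`) or against every
  driver-bearing cell (`e_d`, via `p = 1 − {1 − [(1−e_d)·x]^M}^C`), reported
  as the maximum tolerable escape probability `1 − e`.

The default configuration ships the standard comparison: mouse (0.02 kg,
2 yr), human (60 kg, 80 yr), blue whale (150,000 kg, 90 yr) and three human
tissue stem-cell compartments — colorectal (2×10⁸ cells, 73 divisions/yr),
hepatocellular (3.01×10⁸, 0.9125/yr), esophageal (6.6528×10⁶, 33.2/yr).
Tissue cell number scales with body mass; division rate optionally scales
with the MR exponent; a hypothetical mouse baseline is calibrated to 1%
lifetime risk with integer `M ≥ 2` chosen to keep `u` near 10⁻⁵ per
division; the solvers then invert the exact risk equation for each
hypothesis at human and whale scale.

A seeded stochastic lineage simulator (per-division Bernoulli driver
acquisition, optional policing) provides a brute-force cross-check on the
analytic formulas.

## Worked example

```r
library(oncoscale)
cfg <- default_config()

# 1. calibrate the hypothetical mouse colorectal baseline (no MR effect)
base <- calibrate_baseline(cfg$tissues$colorectal, cfg$species$mouse,
                           cfg$species$human, beta = 0)
base
#> Baseline calibration: colorectal in mouse (beta = 0)
#>   C = 66666.7 cells, k = 73 /yr, t = 2 yr
#>   selected M = 3, u = 3.655e-05  (anchor 1e-05)
#>   achieved lifetime risk = 0.01 (target 0.01)

# 2. what happens at human scale with no adaptation?
m <- multistage_model(C = 2e8, k = 73, u = base$u, M = 3, t = 80)
lifetime_risk(m)
#> [1] 1        # a 1% mouse risk becomes certainty at human scale

# 3. what change would restore a 1% lifetime risk in humans?
sol <- solve_hypotheses(base, cfg$tissues$colorectal, cfg$species$human,
                        cfg$species$human)
sol$mutation_rate
#> Hypothesis solution: mutation_rate, colorectal -> human (beta = 0)
#>   unmitigated risk : 1
#>   fold-reduction in u : 578.3
#>   achieved risk    : 0.01
sol$added_drivers
#> Hypothesis solution: added_drivers, colorectal -> human (beta = 0)
#>   unmitigated risk : 1
#>   added driver mutations : 11.38
#>   achieved risk    : 0.01
```

So holding human colorectal risk at the mouse's 1% would take a 578-fold
drop in the somatic mutation rate, or 11.4 extra driver mutations (about six
additional recessive tumor-suppressor layers); the policing solutions
(`sol$policing_cancer`, `sol$policing_driver`) show the immune system would
have to let through only ~7 in 10⁹ cancer cells, or ~2 in 10³ driver-bearing
cells. `build_table2()` assembles the full grid (3 MR exponents × 3 tissues
× human/whale) with the 9 calibrated baselines attached, and
`write_table2()` emits CSV/TSV/Markdown.

A command-line wrapper is installed under `exec/`:

```sh
oncoscale table2 --scaling 0 --format csv --out table2a.csv
oncoscale risk --C 2e8 --k 73 --u 3.66e-5 --M 3 --t 80
```

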