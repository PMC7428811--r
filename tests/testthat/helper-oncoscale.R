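# Shared fixtures: study species/tissues, independent literal risk forms,
# and expected values frozen from a 50-digit arbitrary-precision evaluation
# of the closed forms (independent of the package's log-space code paths).

mouse <- species_spec("mouse", weight = 0.02, lifespan = 2)
human <- species_spec("human", weight = 60, lifespan = 80)
whale <- species_spec("whale", weight = 150000, lifespan = 90)

colorectal <- tissue_spec("colorectal", cells = 2e8, divisions_per_year = 73)
hepatocellular <- tissue_spec("hepatocellular", cells = 3.01e8,
                              divisions_per_year = 0.9125)
esophageal <- tissue_spec("esophageal", cells = 6.6528e6,
                          divisions_per_year = 33.2)
tissues3 <- list(colorectal = colorectal, hepatocellular = hepatocellular,
                 esophageal = esophageal)

# literal textbook forms, written naively (no log-space tricks) so they are
# an independent check on the package's evaluation
naive_risk_base <- function(C, k, u, M, t) {
  1 - (1 - (1 - exp(-u * k * t))^M)^C
}
naive_risk_policing_cancer <- function(C, k, u, M, t, e_c) {
  1 - (1 - (1 - e_c) * (1 - exp(-u * k * t))^M)^C
}
naive_risk_policing_driver <- function(C, k, u, M, t, e_d) {
  1 - (1 - ((1 - e_d) * (1 - exp(-u * k * t)))^M)^C
}

# numerically stable restatement of the same closed forms, written here so
# root-finding cross-checks have a forward evaluation that stays accurate at
# whale-scale cell counts (the naive forms above lose the root to the
# rounding of 1-q once q ~ 1e-14)
stable_risk <- function(C, k, u, M, t, e_c = 0, e_d = 0) {
  x <- -expm1(-u * k * t)
  if (x == 0 || e_c >= 1 || e_d >= 1) return(0)
  -expm1(C * log1p(-exp(log1p(-e_c) + M * (log1p(-e_d) + log(x)))))
}

# same risks parameterized by the escape probability itself, so that escapes
# around 1e-12 are not destroyed by forming 1 - escape first
stable_risk_escape_c <- function(C, k, u, M, t, escape) {
  x <- -expm1(-u * k * t)
  -expm1(C * log1p(-exp(log(escape) + M * log(x))))
}
stable_risk_escape_d <- function(C, k, u, M, t, escape) {
  x <- -expm1(-u * k * t)
  -expm1(C * log1p(-exp(M * (log(escape) + log(x)))))
}

# mouse baselines per (beta, tissue): M selected by the u-anchor rule and the
# solved u, frozen from the arbitrary-precision oracle
oracle_baselines <- data.frame(
  beta = rep(c(0, -0.15, -0.3), each = 3),
  tissue = rep(c("colorectal", "hepatocellular", "esophageal"), 3),
  M = c(3, 2, 2, 3, 2, 2, 4, 2, 3),
  u = c(3.6550727e-05, 1.7344969e-04, 3.2095400e-05,
        1.0998357e-05, 5.2192168e-05, 9.6577200e-06,
        1.2342214e-05, 1.5704971e-05, 2.2755142e-05)
)

# full-precision oracle values for selected human/whale scenarios
oracle_solutions <- data.frame(
  beta = c(0, 0, 0, 0, 0, -0.15, -0.15),
  tissue = c("colorectal", "colorectal", "hepatocellular", "hepatocellular",
             "esophageal", "colorectal", "colorectal"),
  species = c("human", "whale", "human", "whale", "human", "human", "whale"),
  fold = c(578.33373, 8831.8555, 2191.2306, 123257.07, 2193.1805,
           174.02448, 821.85039),
  esc_c = c(7.07629e-09, 2.06602e-12, 2.10918e-07, 6.6766e-11, 2.26252e-07,
            2.08712e-07, 1.86266e-09),
  esc_d = c(1.91986e-03, 1.27363e-04, 4.59259e-04, 8.17105e-06, 4.75660e-04,
            5.93174e-03, 1.23040e-03),
  dM = c(11.3795, 17.4234, 3.51316, 5.5019, 6.10955, 5.53874, 5.27280)
)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
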