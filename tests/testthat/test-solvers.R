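# solver behaviour across the full default study (3 betas x 3 tissues x
# human/whale); closed forms are cross-checked against an independent
# bracketed root-finder on the exact literal equations

test_that("every hypothesis solution restores the target risk on re-evaluation", {
  tab <- build_table2()
  expect_identical(nrow(tab), 18L)
  ach <- as.matrix(tab[, grep("^achieved_risk_", names(tab))])
  expect_true(all(abs(ach - 0.01) < 1e-6))
})

test_that("closed-form solvers agree with independent root-finding", {
  for (i in seq_len(nrow(oracle_solutions))) {
    s <- oracle_solutions[i, ]
    tis <- tissues3[[s$tissue]]
    sp <- get(s$species)
    base <- calibrate_baseline(tis, mouse, human, beta = s$beta)
    C <- scale_cell_count(tis, sp, human)
    k <- scale_division_rate(tis, sp, human, beta = s$beta)
    t <- sp$lifespan

    fold <- solve_mutation_fold(base, tis, sp, human)$value
    r_fold <- uniroot(
      function(lu) stable_risk(C, k, 10^lu, base$M, t) - 0.01,
      c(-15, -2), tol = .Machine$double.eps)$root
    expect_rel_equal(fold, base$u / 10^r_fold, 1e-8)

    esc_c <- solve_policing_cancer(base, tis, sp, human)$value
    r_c <- uniroot(
      function(le) stable_risk_escape_c(C, k, base$u, base$M, t, 10^le) - 0.01,
      c(-15, 0), tol = .Machine$double.eps)$root
    expect_rel_equal(esc_c, 10^r_c, 1e-8)

    esc_d <- solve_policing_driver(base, tis, sp, human)$value
    r_d <- uniroot(
      function(le) stable_risk_escape_d(C, k, base$u, base$M, t, 10^le) - 0.01,
      c(-10, 0), tol = .Machine$double.eps)$root
    expect_rel_equal(esc_d, 10^r_d, 1e-8)

    dM <- solve_added_drivers(base, tis, sp, human)$value
    r_M <- uniroot(
      function(M) stable_risk(C, k, base$u, M, t) - 0.01,
      c(1, 60), tol = .Machine$double.eps)$root
    expect_rel_equal(dM, r_M - base$M, 1e-8)
  }
})

test_that("solved values match the frozen oracle", {
  for (i in seq_len(nrow(oracle_solutions))) {
    s <- oracle_solutions[i, ]
    tis <- tissues3[[s$tissue]]
    sp <- get(s$species)
    base <- calibrate_baseline(tis, mouse, human, beta = s$beta)
    sol <- solve_hypotheses(base, tis, sp, human)
    expect_rel_equal(sol$mutation_rate$value, s$fold, 1e-5)
    expect_rel_equal(sol$policing_cancer$value, s$esc_c, 1e-5)
    expect_rel_equal(sol$policing_driver$value, s$esc_d, 1e-5)
    expect_rel_equal(sol$added_drivers$value, s$dM, 1e-5)
  }
})

test_that("mutation-rate fold and per-driver escape are reciprocal at small x", {
  # fold * (1 - e_d) ~ 1 to first order when the per-driver probability is
  # small (hepatocellular human, x ~ 0.013)
  base <- calibrate_baseline(hepatocellular, mouse, human, beta = 0)
  fold <- solve_mutation_fold(base, hepatocellular, human, human)$value
  esc_d <- solve_policing_driver(base, hepatocellular, human, human)$value
  x <- per_driver_prob(base$u, 0.9125, 80)
  expect_lt(abs(fold * esc_d - 1), x)
})

test_that("added-driver requirement ranks by division rapidity", {
  dM <- vapply(tissues3, function(tis) {
    base <- calibrate_baseline(tis, mouse, human, beta = -0.15)
    solve_added_drivers(base, tis, human, human)$value
  }, numeric(1))
  expect_true(dM[["colorectal"]] > dM[["esophageal"]])
  expect_true(dM[["esophageal"]] > dM[["hepatocellular"]])
})

test_that("the baseline species itself needs no change", {
  base <- calibrate_baseline(colorectal, mouse, human, beta = 0)
  expect_rel_equal(unmitigated_risk(base, colorectal, mouse, human), 0.01,
                   1e-9)
  # risk is already at target: sentinel solutions, not errors
  sol <- solve_hypotheses(base, colorectal, mouse, human)
  expect_equal(sol$mutation_rate$value, 1)
  expect_equal(sol$added_drivers$value, 0)
  expect_equal(sol$policing_cancer$value, 1)
  expect_equal(sol$policing_driver$value, 1)
})

test_that("a species smaller than the baseline returns no-change sentinels", {
  shrew <- species_spec("shrew", weight = 0.005, lifespan = 1)
  base <- calibrate_baseline(colorectal, mouse, human, beta = 0)
  sol <- solve_mutation_fold(base, colorectal, shrew, human)
  expect_true(sol$no_change_needed)
  expect_equal(sol$value, 1)
  expect_lt(sol$unmitigated_risk, 0.01)
})

test_that("unmitigated risk never decreases from mouse to larger species", {
  tab <- build_table2()
  expect_true(all(tab$unmitigated_risk >= 0.01))
})
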