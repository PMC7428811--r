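test_that("constructor validates parameter domains", {
  expect_error(multistage_model(C = 0.5, k = 73, u = 1e-5, M = 3, t = 2), "'C'")
  expect_error(multistage_model(C = 10, k = -1, u = 1e-5, M = 3, t = 2), "'k'")
  expect_error(multistage_model(C = 10, k = 73, u = 2, M = 3, t = 2), "'u'")
  expect_error(multistage_model(C = 10, k = 73, u = 1e-5, M = 0.5, t = 2), "'M'")
  expect_error(multistage_model(C = 10, k = 73, u = 1e-5, M = 3, t = -1), "'t'")
  expect_error(multistage_model(C = 10, k = 73, u = 1e-5, M = 3, t = 2,
                                e_c = 1.5), "'e_c'")
  m <- multistage_model(C = 10, k = 73, u = 1e-5, M = 3, t = 2)
  expect_s3_class(m, "multistage_model")
  expect_named(coef(m), c("C", "k", "u", "M", "t", "e_c", "e_d"))
})

test_that("per-driver probability matches its closed form and limits", {
  expect_identical(per_driver_prob(0, 73, 80), 0)
  expect_equal(per_driver_prob(1, 1e6, 1), 1)
  # frozen from the high-precision oracle
  expect_equal(per_driver_prob(3.66e-5, 73, 2), 5.3293483658307e-3,
               tolerance = 1e-12)
  expect_error(per_driver_prob(-1e-5, 73, 2), "nonnegative")
  expect_error(per_driver_prob(1e-5, -73, 2), "nonnegative")
  # monotone nondecreasing in each argument
  expect_true(per_driver_prob(2e-5, 73, 2) > per_driver_prob(1e-5, 73, 2))
  expect_true(per_driver_prob(1e-5, 80, 2) > per_driver_prob(1e-5, 73, 2))
  expect_true(per_driver_prob(1e-5, 73, 3) > per_driver_prob(1e-5, 73, 2))
})

test_that("exact risk reduces to the literal base and policing forms", {
  # the literal forms lose precision to cancellation once p is tiny, so the
  # 1e-12 relative comparison applies where they are well-conditioned and an
  # absolute comparison (at the naive form's own error level) elsewhere
  set.seed(42)
  checked <- 0
  for (i in 1:300) {
    C <- 10^runif(1, 0, 6)
    k <- runif(1, 0.5, 100)
    u <- 10^runif(1, -5, -3)
    M <- sample(1:4, 1)
    t <- runif(1, 1, 90)
    e <- runif(1, 0, 0.9)
    # the naive forms lose ~1e-16/q relative precision to the rounding of
    # (1 - q), so the comparison is confined to per-cell probabilities where
    # they still carry 11+ digits
    x <- per_driver_prob(u, k, t)
    if (min(x^M * (1 - e), ((1 - e) * x)^M) < 1e-4) next
    checked <- checked + 1
    m0 <- multistage_model(C, k, u, M, t)
    mc <- multistage_model(C, k, u, M, t, e_c = e)
    md <- multistage_model(C, k, u, M, t, e_d = e)
    expect_equal(lifetime_risk(m0), naive_risk_base(C, k, u, M, t),
                 tolerance = 1e-11)
    expect_equal(lifetime_risk(mc),
                 naive_risk_policing_cancer(C, k, u, M, t, e),
                 tolerance = 1e-11)
    expect_equal(lifetime_risk(md),
                 naive_risk_policing_driver(C, k, u, M, t, e),
                 tolerance = 1e-11)
  }
  expect_gt(checked, 15)
})

test_that("risk depends on u and k only through their product", {
  m1 <- multistage_model(C = 1e5, k = 73, u = 3e-5, M = 3, t = 10)
  for (cc in c(0.1, 2, 50)) {
    m2 <- multistage_model(C = 1e5, k = 73 / cc, u = 3e-5 * cc, M = 3, t = 10)
    expect_equal(lifetime_risk(m1), lifetime_risk(m2), tolerance = 1e-12)
  }
})

test_that("degenerate parameters give the expected trivial risks", {
  expect_identical(
    lifetime_risk(multistage_model(1e8, 73, 0, 3, 80)), 0)
  expect_identical(
    lifetime_risk(multistage_model(1e8, 73, 1e-4, 3, 80, e_c = 1)), 0)
  expect_identical(
    lifetime_risk(multistage_model(1e8, 73, 1e-4, 3, 0)), 0)
  # saturated per-driver probability with no policing: certain cancer
  expect_equal(
    lifetime_risk(multistage_model(10, 1e6, 1, 2, 80)), 1)
})

test_that("log-space evaluation survives whale-scale cell counts", {
  # C ~ 7.5e11 with q_cell ~ 1e-14: naive powers underflow, log1p form works
  m <- multistage_model(C = 7.525e11, k = 0.9125, u = 1.407e-9, M = 2, t = 90)
  p <- lifetime_risk(m)
  expect_gt(p, 0)
  expect_lt(p, 1)
  x <- per_driver_prob(1.407e-9, 0.9125, 90)
  expect_equal(p, -expm1(7.525e11 * log1p(-x^2)), tolerance = 1e-12)
})

test_that("risk is monotone in each parameter over a random grid", {
  set.seed(7)
  for (i in 1:20) {
    C <- 10^runif(1, 1, 7)
    k <- runif(1, 1, 80)
    u <- 10^runif(1, -6, -3.5)
    M <- sample(2:5, 1)
    t <- runif(1, 2, 80)
    e <- runif(1, 0.05, 0.9)
    p0 <- lifetime_risk(multistage_model(C, k, u, M, t, e_c = e, e_d = e))
    up <- function(...) lifetime_risk(multistage_model(...))
    expect_gte(up(C * 1.1, k, u, M, t, e_c = e, e_d = e), p0)
    expect_gte(up(C, k * 1.1, u, M, t, e_c = e, e_d = e), p0)
    expect_gte(up(C, k, u * 1.1, M, t, e_c = e, e_d = e), p0)
    expect_gte(up(C, k, u, M, t * 1.1, e_c = e, e_d = e), p0)
    # decreasing in M (per-driver probability < 1) and in both policing terms
    expect_lte(up(C, k, u, M + 1, t, e_c = e, e_d = e), p0)
    expect_gte(up(C, k, u, M, t, e_c = e * 0.9, e_d = e), p0)
    expect_gte(up(C, k, u, M, t, e_c = e, e_d = e * 0.9), p0)
  }
})

test_that("small-risk approximation agrees with the exact form when risk is small", {
  # mouse colorectal baseline: approximation error is M*ukt/2 + C*q/2 ~ 1.3%
  m <- multistage_model(C = 2e8 * 0.02 / 60, k = 73, u = 3.6550727e-5,
                        M = 3, t = 2)
  expect_rel_equal(lifetime_risk_approx(m), lifetime_risk(m), 0.02)
  expect_equal(lifetime_risk_approx(m), 0.0102, tolerance = 1e-2)
  expect_identical(
    lifetime_risk_approx(multistage_model(1e8, 73, 0, 3, 80)), 0)
  # sweep: the leading error terms are M*ukt/2 (per-driver linearization)
  # and C*q/2 (outer power), so within M*ukt < 0.012 and exact < 0.005 the
  # relative error stays below 1%
  set.seed(11)
  checked <- 0
  for (i in 1:200) {
    C <- 10^runif(1, 0, 8)
    k <- runif(1, 0.5, 100)
    u <- 10^runif(1, -8, -4)
    M <- sample(1:6, 1)
    t <- runif(1, 1, 90)
    if (M * u * k * t >= 0.012) next
    m <- multistage_model(C, k, u, M, t)
    p <- lifetime_risk(m)
    if (p >= 0.005 || p == 0) next
    checked <- checked + 1
    expect_rel_equal(lifetime_risk_approx(m), p, 0.01)
  }
  expect_gt(checked, 20)
})

test_that("per-cell target inverts the outer power accurately", {
  expect_equal(per_cell_target(0.01, 1), 0.01, tolerance = 1e-15)
  # frozen from the high-precision oracle
  expect_equal(per_cell_target(0.01, 2e8), 5.0251679266245e-11,
               tolerance = 1e-10)
  # round trip to 1e-12 relative across magnitudes of C
  for (C in 10^c(0, 4, 8, 12)) {
    q <- per_cell_target(0.01, C)
    expect_rel_equal(-expm1(C * log1p(-q)), 0.01, 1e-12)
  }
  # first-order limit: q -> p/C as p -> 0
  expect_equal(per_cell_target(1e-10, 50) * 50, 1e-10, tolerance = 1e-6)
  expect_error(per_cell_target(0, 10), "p_target")
  expect_error(per_cell_target(1, 10), "p_target")
  expect_error(per_cell_target(0.01, 0.5), "'C'")
})

test_that("predict and summary expose exact and approximate risk", {
  m <- multistage_model(C = 2e8, k = 73, u = 3.66e-5, M = 3, t = 80)
  expect_equal(predict(m, t = c(2, 80)),
               lifetime_risk(m, t = c(2, 80)))
  expect_equal(predict(m, type = "approx"), lifetime_risk_approx(m))
  s <- summary(m)
  expect_equal(s$risk_exact, lifetime_risk(m))
  expect_output(print(m), "lifetime risk")
})
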