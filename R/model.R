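#' Multistage carcinogenesis model
#'
#' Constructs a multistage model of cancer initiation: a tissue of `C` at-risk
#' stem cells, each dividing `k` times per year, develops cancer once a single
#' cell accumulates `M` driver mutations, each arising with probability `u`
#' per division. Two immune-policing extensions are supported: detection of
#' fully transformed cancer cells with efficiency `e_c`, and detection of any
#' cell carrying a driver mutation with per-driver efficiency `e_d`.
#'
#' The lifetime risk by age `t` is
#' \deqn{p = 1 - \{1 - (1-e_c)\,[(1-e_d)\,x]^M\}^C, \quad x = 1 - e^{-ukt}.}
#' With `e_c = e_d = 0` this is the classical multistage form; `e_c > 0`
#' policing removes completed cancer cells, `e_d > 0` policing removes each
#' driver independently. Both extensions may be combined (multiplicative
#' semantics), although typical analyses use one at a time.
#'
#' `u` and `k` enter the risk only through their product `u*k`, so the model
#' is invariant to rescaling one against the other.
#'
#' @param C at-risk stem-cell count (>= 1; need not be an integer after
#'   mass scaling).
#' @param k stem-cell division rate, divisions per year (>= 0).
#' @param u driver mutation probability per cell division, in \[0, 1\].
#' @param M required number of driver mutations (>= 1). Real values are
#'   accepted so that fractional "added driver" solutions can be evaluated.
#' @param t age / exposure time in years (>= 0).
#' @param e_c immune detection efficiency against completed cancer cells,
#'   probability in \[0, 1\] (default 0).
#' @param e_d immune detection efficiency against each driver mutation,
#'   probability in \[0, 1\] (default 0).
#' @return An object of class `"multistage_model"`: a list with the validated
#'   parameters.
#' @seealso [lifetime_risk()], [lifetime_risk_approx()], [per_driver_prob()],
#'   [simulate.multistage_model()]
#' @examples
#' m <- multistage_model(C = 2e8, k = 73, u = 3.66e-5, M = 3, t = 80)
#' lifetime_risk(m)          # ~1: human-scale tissue with mouse-like u
#' predict(m, t = c(2, 40, 80))
#' @export
multistage_model <- function(C, k, u, M, t, e_c = 0, e_d = 0) {
  stopifnot(
    length(C) == 1L, length(k) == 1L, length(u) == 1L,
    length(M) == 1L, length(t) == 1L, length(e_c) == 1L, length(e_d) == 1L
  )
  if (!is.finite(C) || C < 1) stop("'C' must be a finite cell count >= 1")
  if (!is.finite(k) || k < 0) stop("'k' must be a nonnegative division rate")
  if (!is.finite(u) || u < 0 || u > 1) stop("'u' must be a probability in [0, 1]")
  if (!is.finite(M) || M < 1) stop("'M' must be >= 1")
  if (!is.finite(t) || t < 0) stop("'t' must be a nonnegative age in years")
  if (e_c < 0 || e_c > 1) stop("'e_c' must be a probability in [0, 1]")
  if (e_d < 0 || e_d > 1) stop("'e_d' must be a probability in [0, 1]")
  structure(
    list(C = C, k = k, u = u, M = M, t = t, e_c = e_c, e_d = e_d),
    class = "multistage_model"
  )
}

#' Per-driver mutation probability by age t
#'
#' Probability that a given driver mutation has occurred in a cell lineage by
#' age `t`: `x = 1 - exp(-u*k*t)`. Monotone nondecreasing in each argument.
#'
#' @param u driver mutation probability per division (>= 0).
#' @param k division rate per year (>= 0).
#' @param t age in years (>= 0).
#' @return Probability in \[0, 1\]; vectorized over its arguments.
#' @examples
#' per_driver_prob(3.66e-5, 73, 2)
#' @export
per_driver_prob <- function(u, k, t) {
  if (any(!is.finite(u)) || any(u < 0)) stop("'u' must be nonnegative")
  if (any(!is.finite(k)) || any(k < 0)) stop("'k' must be nonnegative")
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be nonnegative")
  -expm1(-u * k * t)
}

# log of the per-cell transformation probability
#   q = (1 - e_c) * ((1 - e_d) * x)^M
# computed in log space so that q down to ~1e-300 is representable.
.log_q_cell <- function(x, M, e_c, e_d) {
  out <- rep(-Inf, length(x))
  pos <- x > 0 & e_c < 1 & e_d < 1
  out[pos] <- log1p(-e_c) + M * (log1p(-e_d) + log(x[pos]))
  out
}

.risk_exact <- function(C, k, u, M, t, e_c = 0, e_d = 0) {
  x <- -expm1(-u * k * t)
  log_q <- .log_q_cell(x, M, e_c, e_d)
  q <- exp(log_q)
  # p = 1 - (1 - q)^C via C * log1p(-q); exact at q = 1 (log1p(-1) = -Inf)
  -expm1(C * log1p(-q))
}

#' Exact lifetime cancer risk
#'
#' Evaluates the exact multistage risk
#' `p = 1 - {1 - (1-e_c) * ((1-e_d) * x)^M}^C` with `x = 1 - exp(-u*k*t)`,
#' in log space (`log1p`/`expm1`) so that cell counts up to ~1e12 with
#' per-cell probabilities down to ~1e-14 neither underflow nor lose
#' precision.
#'
#' @param object a [multistage_model()] object.
#' @param t optional age(s) in years at which to evaluate the risk; defaults
#'   to the model's own `t`.
#' @return Lifetime risk, a probability in \[0, 1\] (vectorized over `t`).
#' @examples
#' mouse <- multistage_model(C = 2e8 * 0.02 / 60, k = 73, u = 3.66e-5,
#'                           M = 3, t = 2)
#' lifetime_risk(mouse)  # ~0.01
#' @export
lifetime_risk <- function(object, t = NULL) {
  stopifnot(inherits(object, "multistage_model"))
  if (is.null(t)) t <- object$t
  if (any(t < 0)) stop("'t' must be nonnegative")
  .risk_exact(object$C, object$k, object$u, object$M, t,
              object$e_c, object$e_d)
}

#' Small-risk approximation of the lifetime risk
#'
#' The familiar power-law approximation `p = C * (1-e_c) * ((1-e_d)*u*k*t)^M`.
#' It is accurate only when the risk is small (relative error < 1% whenever
#' the exact risk is below ~0.005) and may exceed 1 outside that regime; it
#' is provided for the scaling arguments in which risk is proportional to
#' `C` and to `t^M`, not for general evaluation.
#'
#' @inheritParams lifetime_risk
#' @return Approximate risk (may exceed 1; see Details).
#' @examples
#' mouse <- multistage_model(C = 2e8 * 0.02 / 60, k = 73, u = 3.66e-5,
#'                           M = 3, t = 2)
#' lifetime_risk_approx(mouse)
#' @export
lifetime_risk_approx <- function(object, t = NULL) {
  stopifnot(inherits(object, "multistage_model"))
  if (is.null(t)) t <- object$t
  if (any(t < 0)) stop("'t' must be nonnegative")
  with(object, C * (1 - e_c) * ((1 - e_d) * u * k * t)^M)
}

#' Per-cell transformation probability implied by a tissue-level risk
#'
#' Inverts the outer power of the exact risk: the per-cell probability `q`
#' such that `1 - (1 - q)^C` equals `p_target`. Computed as
#' `q = -expm1(log1p(-p_target) / C)`, which is accurate for `C` up to 1e12
#' and `q` down to the underflow limit.
#'
#' @param p_target tissue-level lifetime risk, strictly in (0, 1).
#' @param C at-risk cell count (>= 1).
#' @return Per-cell probability `q` in (0, 1).
#' @examples
#' per_cell_target(0.01, 2e8)   # ~5.025e-11
#' @export
per_cell_target <- function(p_target, C) {
  if (any(!is.finite(p_target)) || any(p_target <= 0) || any(p_target >= 1))
    stop("'p_target' must be strictly inside (0, 1)")
  if (any(!is.finite(C)) || any(C < 1)) stop("'C' must be >= 1")
  -expm1(log1p(-p_target) / C)
}

#' @export
print.multistage_model <- function(x, ...) {
  cat("Multistage carcinogenesis model\n")
  cat(sprintf("  C = %.6g cells, k = %.6g divisions/yr, u = %.4g /division\n",
              x$C, x$k, x$u))
  cat(sprintf("  M = %g driver mutations, t = %g yr\n", x$M, x$t))
  if (x$e_c > 0 || x$e_d > 0)
    cat(sprintf("  immune policing: e_c = %.4g, e_d = %.4g\n", x$e_c, x$e_d))
  cat(sprintf("  lifetime risk (exact): %.4g\n", lifetime_risk(x)))
  invisible(x)
}

#' @export
coef.multistage_model <- function(object, ...) {
  unlist(object[c("C", "k", "u", "M", "t", "e_c", "e_d")])
}

#' @export
summary.multistage_model <- function(object, ...) {
  p <- lifetime_risk(object)
  out <- list(
    params = coef(object),
    per_driver = per_driver_prob(object$u, object$k, object$t),
    risk_exact = p,
    risk_approx = lifetime_risk_approx(object)
  )
  class(out) <- "summary.multistage_model"
  out
}

#' @export
print.summary.multistage_model <- function(x, ...) {
  cat("Multistage model summary\n")
  print(x$params)
  cat(sprintf("per-driver probability by t : %.6g\n", x$per_driver))
  cat(sprintf("lifetime risk (exact)       : %.6g\n", x$risk_exact))
  cat(sprintf("lifetime risk (small-p)     : %.6g\n", x$risk_approx))
  invisible(x)
}

#' Predict lifetime risk at given ages
#'
#' @param object a [multistage_model()] object.
#' @param t ages (years) at which to evaluate the accumulated risk; defaults
#'   to the model's `t`.
#' @param type `"exact"` for the closed form, `"approx"` for the small-risk
#'   power law.
#' @param ... unused.
#' @return Numeric vector of risks, one per element of `t`.
#' @export
predict.multistage_model <- function(object, t = NULL,
                                     type = c("exact", "approx"), ...) {
  type <- match.arg(type)
  switch(type,
    exact = lifetime_risk(object, t),
    approx = lifetime_risk_approx(object, t)
  )
}
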