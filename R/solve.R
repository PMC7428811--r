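#' Hypothesis solvers: parameter changes that stabilize cancer risk
#'
#' Given a calibrated small-species baseline and a larger/longer-lived target
#' species, each solver computes the change in one model parameter required
#' to hold the target species' lifetime risk at the baseline target (1% by
#' default), inverting the exact risk form:
#'
#' * `solve_mutation_fold()` — the fold-reduction in the somatic mutation
#'   rate `u` (reported as the divisor of the baseline value);
#' * `solve_added_drivers()` — the number of extra driver mutations
#'   (real-valued `M' - M_baseline`) recruited as added genetic suppression;
#' * `solve_policing_cancer()` — the maximum escape probability `1 - e_c` of
#'   a completed cancer cell from immune policing;
#' * `solve_policing_driver()` — the maximum per-driver escape probability
#'   `1 - e_d` from policing of driver-bearing cells.
#'
#' Every solution is verified by plugging it back into the exact risk; the
#' achieved risk is returned alongside the value. When the unmitigated risk
#' is already at or below target (e.g. the target species is the baseline
#' itself), the sentinel "no change" solution is returned (fold 1, 0 added
#' drivers, escape probability 1) with `no_change_needed = TRUE`.
#'
#' @param baseline an [calibrate_baseline()] result (`ms_calibration`).
#' @param tissue the [tissue_spec()] used for the baseline.
#' @param species target [species_spec()].
#' @param reference reference [species_spec()] anchoring the scaling (human).
#' @param beta MR scaling exponent (should match the baseline's).
#' @param p_target target lifetime risk; defaults to the baseline's.
#' @return A `"hypothesis_solution"` list with elements `hypothesis`,
#'   `value`, `achieved_risk`, `unmitigated_risk`, `no_change_needed`, and
#'   the scenario labels.
#' @name hypothesis_solvers
#' @examples
#' cfg <- default_config()
#' base <- calibrate_baseline(cfg$tissues$colorectal, cfg$species$mouse,
#'                            cfg$species$human, beta = 0)
#' solve_mutation_fold(base, cfg$tissues$colorectal, cfg$species$human,
#'                     cfg$species$human)   # ~578
NULL

# scaled target-species parameters plus the per-cell and per-driver
# requirements shared by all four solvers
.scenario <- function(baseline, tissue, species, reference, beta, p_target) {
  C <- scale_cell_count(tissue, species, reference)
  k <- scale_division_rate(tissue, species, reference, beta)
  t <- species$lifespan
  list(
    C = C, k = k, t = t,
    q = per_cell_target(p_target, C),
    x = per_driver_prob(baseline$u, k, t),
    unmitigated = .risk_exact(C, k, baseline$u, baseline$M, t)
  )
}

.solution <- function(hypothesis, value, achieved, sc, baseline, species,
                      no_change = FALSE) {
  structure(
    list(
      hypothesis = hypothesis, value = value,
      achieved_risk = achieved, unmitigated_risk = sc$unmitigated,
      no_change_needed = no_change,
      tissue = baseline$tissue, species = species$name,
      beta = baseline$beta, baseline_M = baseline$M, baseline_u = baseline$u
    ),
    class = "hypothesis_solution"
  )
}

#' Unmitigated lifetime risk at target-species scale
#'
#' The lifetime risk in the target species using the baseline (mouse) `u` and
#' `M` unchanged — the "no change versus mouse" column.
#'
#' @inheritParams hypothesis_solvers
#' @return Lifetime risk (probability).
#' @export
unmitigated_risk <- function(baseline, tissue, species, reference,
                             beta = baseline$beta) {
  stopifnot(inherits(baseline, "ms_calibration"))
  .scenario(baseline, tissue, species, reference, beta,
            baseline$p_target)$unmitigated
}

#' @rdname hypothesis_solvers
#' @export
solve_mutation_fold <- function(baseline, tissue, species, reference,
                                beta = baseline$beta,
                                p_target = baseline$p_target) {
  stopifnot(inherits(baseline, "ms_calibration"))
  sc <- .scenario(baseline, tissue, species, reference, beta, p_target)
  if (sc$unmitigated < p_target) {
    return(.solution("mutation_rate", 1, sc$unmitigated, sc, baseline,
                     species, no_change = TRUE))
  }
  u_req <- solve_u_for_risk(sc$C, sc$k, sc$t, baseline$M, p_target)
  achieved <- .risk_exact(sc$C, sc$k, u_req, baseline$M, sc$t)
  .solution("mutation_rate", baseline$u / u_req, achieved, sc, baseline,
            species)
}

#' @rdname hypothesis_solvers
#' @export
solve_added_drivers <- function(baseline, tissue, species, reference,
                                beta = baseline$beta,
                                p_target = baseline$p_target) {
  stopifnot(inherits(baseline, "ms_calibration"))
  sc <- .scenario(baseline, tissue, species, reference, beta, p_target)
  if (sc$unmitigated < p_target) {
    return(.solution("added_drivers", 0, sc$unmitigated, sc, baseline,
                     species, no_change = TRUE))
  }
  if (sc$x >= 1) stop("per-driver probability is 1: added drivers cannot reduce risk")
  M_req <- log(sc$q) / log(sc$x)
  achieved <- .risk_exact(sc$C, sc$k, baseline$u, M_req, sc$t)
  .solution("added_drivers", M_req - baseline$M, achieved, sc, baseline,
            species)
}

#' @rdname hypothesis_solvers
#' @export
solve_policing_cancer <- function(baseline, tissue, species, reference,
                                  beta = baseline$beta,
                                  p_target = baseline$p_target) {
  stopifnot(inherits(baseline, "ms_calibration"))
  sc <- .scenario(baseline, tissue, species, reference, beta, p_target)
  if (sc$unmitigated < p_target) {
    return(.solution("policing_cancer", 1, sc$unmitigated, sc, baseline,
                     species, no_change = TRUE))
  }
  escape <- exp(log(sc$q) - baseline$M * log(sc$x))
  escape <- min(escape, 1)
  achieved <- .risk_exact(sc$C, sc$k, baseline$u, baseline$M, sc$t,
                          e_c = 1 - escape)
  .solution("policing_cancer", escape, achieved, sc, baseline, species)
}

#' @rdname hypothesis_solvers
#' @export
solve_policing_driver <- function(baseline, tissue, species, reference,
                                  beta = baseline$beta,
                                  p_target = baseline$p_target) {
  stopifnot(inherits(baseline, "ms_calibration"))
  sc <- .scenario(baseline, tissue, species, reference, beta, p_target)
  if (sc$unmitigated < p_target) {
    return(.solution("policing_driver", 1, sc$unmitigated, sc, baseline,
                     species, no_change = TRUE))
  }
  escape <- exp(log(sc$q) / baseline$M - log(sc$x))
  escape <- min(escape, 1)
  achieved <- .risk_exact(sc$C, sc$k, baseline$u, baseline$M, sc$t,
                          e_d = 1 - escape)
  .solution("policing_driver", escape, achieved, sc, baseline, species)
}

#' All four hypothesis solutions for one scenario
#'
#' @inheritParams hypothesis_solvers
#' @return Named list of four `"hypothesis_solution"` objects:
#'   `mutation_rate`, `policing_cancer`, `policing_driver`, `added_drivers`.
#' @export
solve_hypotheses <- function(baseline, tissue, species, reference,
                             beta = baseline$beta,
                             p_target = baseline$p_target) {
  list(
    mutation_rate = solve_mutation_fold(baseline, tissue, species,
                                        reference, beta, p_target),
    policing_cancer = solve_policing_cancer(baseline, tissue, species,
                                            reference, beta, p_target),
    policing_driver = solve_policing_driver(baseline, tissue, species,
                                            reference, beta, p_target),
    added_drivers = solve_added_drivers(baseline, tissue, species,
                                        reference, beta, p_target)
  )
}

#' @export
print.hypothesis_solution <- function(x, ...) {
  label <- switch(x$hypothesis,
    mutation_rate = "fold-reduction in u",
    added_drivers = "added driver mutations",
    policing_cancer = "cancer-cell escape probability (1 - e_c)",
    policing_driver = "per-driver escape probability (1 - e_d)"
  )
  cat(sprintf("Hypothesis solution: %s, %s -> %s (beta = %g)\n",
              x$hypothesis, x$tissue, x$species, x$beta))
  cat(sprintf("  unmitigated risk : %.4g\n", x$unmitigated_risk))
  if (x$no_change_needed) {
    cat("  no change needed (risk already at or below target)\n")
  } else {
    cat(sprintf("  %s : %.4g\n", label, x$value))
    cat(sprintf("  achieved risk    : %.6g\n", x$achieved_risk))
  }
  invisible(x)
}
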