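#' Solve for the mutation rate giving a target lifetime risk
#'
#' Inverts the exact multistage risk for `u` at fixed `C`, `k`, `t`, `M`:
#' with `q = per_cell_target(p_target, C)` and per-driver requirement
#' `x = q^(1/M)`, the closed form is `u = -log1p(-x) / (k*t)`. The inversion
#' uses the exact form, not the small-risk approximation.
#'
#' @param C at-risk cell count (>= 1).
#' @param k division rate per year (> 0).
#' @param t lifespan in years (> 0).
#' @param M required driver mutations (>= 1; real values allowed).
#' @param p_target target lifetime risk, strictly in (0, 1).
#' @return Mutation rate `u` per division such that the exact lifetime risk
#'   equals `p_target`.
#' @examples
#' u <- solve_u_for_risk(C = 2e8 * 0.02 / 60, k = 73, t = 2, M = 3,
#'                       p_target = 0.01)
#' u  # ~3.66e-5
#' @export
solve_u_for_risk <- function(C, k, t, M, p_target = 0.01) {
  if (!is.finite(k) || k <= 0 || !is.finite(t) || t <= 0)
    stop("'k' and 't' must be > 0")
  if (!is.finite(M) || M < 1) stop("'M' must be >= 1")
  q <- per_cell_target(p_target, C)
  x <- exp(log(q) / M)
  if (x >= 1) stop("target risk unreachable: per-driver requirement >= 1")
  -log1p(-x) / (k * t)
}

#' Calibrate the small-species baseline for a tissue
#'
#' Constructs the hypothetical small-species (mouse) baseline against which
#' size/longevity scaling is measured: the tissue's reference (human)
#' stem-cell count is scaled down by mass, the division rate is scaled by the
#' MR exponent `beta`, and then an integer driver count `M >= 2` is combined
#' with a solved mutation rate `u` so the baseline lifetime risk is exactly
#' `p_target`. Among `M = 2, ..., M_max`, the value keeping `u` closest to
#' `u_anchor` on a log10 scale is selected (ties go to the smaller `M`;
#' log-scale distance is used because candidate rates span orders of
#' magnitude).
#'
#' @param tissue a [tissue_spec()] measured in `reference`.
#' @param species baseline [species_spec()] (the hypothetical mouse).
#' @param reference reference [species_spec()] (human).
#' @param beta MR scaling exponent (<= 0).
#' @param p_target baseline lifetime risk (default 0.01).
#' @param u_anchor mutation-rate anchor (default 1e-5 per division).
#' @param M_max largest driver count searched (default 10).
#' @return An `"ms_calibration"` object: tissue/species labels, `beta`, the
#'   selected `M` and `u`, the scaled `C`, `k`, `t`, `achieved_risk`, and a
#'   `candidates` data frame with the full search trace.
#' @examples
#' cfg <- default_config()
#' calibrate_baseline(cfg$tissues$colorectal, cfg$species$mouse,
#'                    cfg$species$human, beta = 0)
#' @export
calibrate_baseline <- function(tissue, species, reference, beta = 0,
                               p_target = 0.01, u_anchor = 1e-5,
                               M_max = 10) {
  stopifnot(M_max >= 2)
  C <- scale_cell_count(tissue, species, reference)
  k <- scale_division_rate(tissue, species, reference, beta)
  t <- species$lifespan
  M_grid <- as.integer(seq.int(2L, M_max))
  u_grid <- vapply(M_grid, function(M)
    solve_u_for_risk(C, k, t, M, p_target), numeric(1))
  dist <- abs(log10(u_grid) - log10(u_anchor))
  sel <- which.min(dist)  # which.min takes the first (smallest M) on ties
  M <- M_grid[sel]
  u <- u_grid[sel]
  achieved <- .risk_exact(C, k, u, M, t)
  structure(
    list(
      tissue = tissue$name, species = species$name,
      reference = reference$name, beta = beta,
      M = M, u = u, C = C, k = k, t = t,
      p_target = p_target, u_anchor = u_anchor,
      achieved_risk = achieved,
      candidates = data.frame(M = M_grid, u = u_grid, log10_dist = dist)
    ),
    class = "ms_calibration"
  )
}

#' @export
print.ms_calibration <- function(x, ...) {
  cat(sprintf("Baseline calibration: %s in %s (beta = %g)\n",
              x$tissue, x$species, x$beta))
  cat(sprintf("  C = %.6g cells, k = %.6g /yr, t = %g yr\n", x$C, x$k, x$t))
  cat(sprintf("  selected M = %d, u = %.4g  (anchor %.1g)\n",
              x$M, x$u, x$u_anchor))
  cat(sprintf("  achieved lifetime risk = %.6g (target %g)\n",
              x$achieved_risk, x$p_target))
  invisible(x)
}

# multistage_model holding a calibration's baseline parameters, optionally
# re-scaled to another species
.model_from_calibration <- function(baseline, C = baseline$C,
                                    k = baseline$k, t = baseline$t,
                                    u = baseline$u, M = baseline$M,
                                    e_c = 0, e_d = 0) {
  multistage_model(C = C, k = k, u = u, M = M, t = t, e_c = e_c, e_d = e_d)
}
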