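#' Build the full size-scaling comparison table
#'
#' For each MR scaling exponent, tissue, and target species, calibrates the
#' baseline-species (mouse) parameters to the target lifetime risk and solves
#' all four evolutionary hypotheses for the parameter change needed to hold
#' the target species at that risk. This reproduces the mouse-to-human /
#' mouse-to-blue-whale comparison across the three cancer types at MR
#' exponents 0, -0.15 and -0.3 (18 scenario rows, 9 baseline records under
#' the default configuration).
#'
#' @param config a `"scaling_config"` (default [default_config()]).
#' @param betas MR exponents to tabulate; defaults to `config$betas`.
#' @return A data frame of class `"table2"` with one row per
#'   beta x tissue x target species: `beta`, `tissue`, `species`,
#'   `baseline_M`, `baseline_u`, `unmitigated_risk`, `mutation_fold`,
#'   `policing_cancer_escape`, `policing_driver_escape`, `added_drivers`,
#'   and the verification columns `achieved_risk_*`. The 9 baseline records
#'   (one per beta x tissue) are attached as `attr(, "baselines")`.
#' @examples
#' \donttest{
#' tab <- build_table2()
#' subset(tab, beta == 0 & tissue == "colorectal")
#' }
#' @export
build_table2 <- function(config = default_config(), betas = config$betas) {
  ref <- config$species[[config$reference_species]]
  base_sp <- config$species[[config$baseline_species]]
  rows <- list()
  bases <- list()
  for (beta in betas) {
    for (tn in names(config$tissues)) {
      tissue <- config$tissues[[tn]]
      base <- calibrate_baseline(tissue, base_sp, ref, beta = beta,
                                 p_target = config$p_target,
                                 u_anchor = config$u_anchor,
                                 M_max = config$M_max)
      bases[[length(bases) + 1L]] <- data.frame(
        beta = beta, tissue = tn, M = base$M, u = base$u,
        C = base$C, k = base$k, t = base$t,
        achieved_risk = base$achieved_risk
      )
      for (sn in config$target_species) {
        sp <- config$species[[sn]]
        sol <- solve_hypotheses(base, tissue, sp, ref, beta,
                                config$p_target)
        rows[[length(rows) + 1L]] <- data.frame(
          beta = beta, tissue = tn, species = sn,
          baseline_M = base$M, baseline_u = base$u,
          unmitigated_risk = sol$mutation_rate$unmitigated_risk,
          mutation_fold = sol$mutation_rate$value,
          policing_cancer_escape = sol$policing_cancer$value,
          policing_driver_escape = sol$policing_driver$value,
          added_drivers = sol$added_drivers$value,
          achieved_risk_mutation = sol$mutation_rate$achieved_risk,
          achieved_risk_policing_cancer = sol$policing_cancer$achieved_risk,
          achieved_risk_policing_driver = sol$policing_driver$achieved_risk,
          achieved_risk_added_drivers = sol$added_drivers$achieved_risk
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  baselines <- do.call(rbind, bases)
  rownames(baselines) <- NULL
  attr(out, "baselines") <- baselines
  attr(out, "p_target") <- config$p_target
  class(out) <- c("table2", "data.frame")
  out
}

#' Format a number in the table's scientific style
#'
#' Three significant figures with a capital exponent marker, e.g.
#' `"7.10E-09"`, matching the printed style of comparative-risk tables.
#'
#' @param x numeric vector.
#' @param digits significant digits (default 3).
#' @return Character vector.
#' @examples
#' format_sci(7.0954e-09)
#' @export
format_sci <- function(x, digits = 3) {
  toupper(formatC(x, format = "e", digits = digits - 1))
}

#' @export
`[.table2` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.table2 <- function(x, digits = 3, ...) {
  p_target <- attr(x, "p_target")
  cat(sprintf(
    "Parameter changes needed for a lifetime risk of %g%% at target scale\n",
    100 * p_target))
  for (b in unique(x$beta)) {
    cat(sprintf("\nMR scaling beta = %g\n", b))
    sub <- x[x$beta == b, ]
    for (tn in unique(sub$tissue)) {
      rows <- sub[sub$tissue == tn, ]
      cat(sprintf("  %s (baseline M = %d, u = %s)\n", tn,
                  rows$baseline_M[1], format_sci(rows$baseline_u[1])))
      for (i in seq_len(nrow(rows))) {
        r <- rows[i, ]
        cat(sprintf(
          "    %-6s risk %3.0f%%  u-fold %s  escape(e_c) %s  escape(e_d) %s  added M %.1f\n",
          r$species, 100 * r$unmitigated_risk,
          formatC(signif(r$mutation_fold, digits), format = "fg", big.mark = ","),
          format_sci(r$policing_cancer_escape),
          format_sci(r$policing_driver_escape),
          r$added_drivers))
      }
    }
  }
  invisible(x)
}

#' Write a comparison table to disk
#'
#' CSV (canonical, full precision), TSV, or Markdown (paper-style formatted
#' values for human diffing). Output is deterministic: identical tables give
#' byte-identical files.
#'
#' @param table a `"table2"` data frame from [build_table2()].
#' @param path output file path.
#' @param format `"csv"`, `"tsv"` or `"md"`.
#' @param baselines also write the baseline records to
#'   `<path>` with suffix `_baselines` before the extension (CSV/TSV only).
#' @return `path`, invisibly.
#' @export
write_table2 <- function(table, path, format = c("csv", "tsv", "md"),
                         baselines = TRUE) {
  format <- match.arg(format)
  df <- as.data.frame(table)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       qmethod = "double")
    if (baselines && !is.null(attr(table, "baselines"))) {
      bpath <- sub("(\\.[^.]+)$", "_baselines\\1", path)
      utils::write.table(attr(table, "baselines"), bpath, sep = sep,
                         row.names = FALSE, qmethod = "double")
    }
  } else {
    fmt <- data.frame(
      beta = df$beta, tissue = df$tissue, species = df$species,
      M = df$baseline_M, u = format_sci(df$baseline_u),
      risk = sprintf("%.0f%%", 100 * df$unmitigated_risk),
      u_fold = formatC(signif(df$mutation_fold, 3), format = "fg",
                       big.mark = ","),
      escape_ec = format_sci(df$policing_cancer_escape),
      escape_ed = format_sci(df$policing_driver_escape),
      added_M = sprintf("%.1f", df$added_drivers)
    )
    header <- paste0("| ", paste(names(fmt), collapse = " | "), " |")
    rule <- paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|")
    body <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, rule, body), path)
  }
  invisible(path)
}
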