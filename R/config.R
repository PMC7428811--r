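#' Read a study configuration
#'
#' A configuration lists the species (mass, lifespan), the tissue stem-cell
#' compartments measured in the reference species, the calibration target
#' risk and mutation-rate anchor, and the MR scaling exponents. YAML and JSON
#' files are accepted (by extension).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A `"scaling_config"` list with elements `species` (named list of
#'   [species_spec()]), `tissues` (named list of [tissue_spec()]),
#'   `reference_species`, `baseline_species`, `target_species`, `p_target`,
#'   `u_anchor`, `M_max` and `betas`.
#' @seealso [default_config()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  )
  as_scaling_config(raw)
}

#' Default study configuration
#'
#' The configuration shipped with the package: mouse (0.02 kg, 2 yr), human
#' (60 kg, 80 yr) and blue whale (150,000 kg, 90 yr); human-measured
#' colorectal (2e8 cells, 73 divisions/yr), hepatocellular (3.01e8, 0.9125/yr)
#' and esophageal (6.6528e6, 33.2/yr) stem-cell compartments; 1% target
#' lifetime risk; mutation-rate anchor 1e-5 per division; MR exponents
#' 0, -0.15 and -0.3.
#'
#' @return A `"scaling_config"` list (see [read_config()]).
#' @examples
#' cfg <- default_config()
#' names(cfg$tissues)
#' @export
default_config <- function() {
  read_config(system.file("extdata", "default_config.yaml",
                          package = "oncoscale", mustWork = TRUE))
}

as_scaling_config <- function(raw) {
  need <- c("species", "tissues", "reference_species", "p_target", "u_anchor")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("config is missing fields: ", paste(miss, collapse = ", "))
  species <- lapply(names(raw$species), function(nm) {
    s <- raw$species[[nm]]
    species_spec(nm, s$weight, s$lifespan)
  })
  names(species) <- names(raw$species)
  tissues <- lapply(names(raw$tissues), function(nm) {
    s <- raw$tissues[[nm]]
    tissue_spec(nm, s$cells, s$divisions_per_year)
  })
  names(tissues) <- names(raw$tissues)
  if (!raw$reference_species %in% names(species))
    stop("reference_species '", raw$reference_species, "' not among species")
  cfg <- list(
    species = species,
    tissues = tissues,
    reference_species = raw$reference_species,
    baseline_species = raw$baseline_species %||% "mouse",
    target_species = raw$target_species %||%
      setdiff(names(species), raw$baseline_species %||% "mouse"),
    p_target = raw$p_target,
    u_anchor = raw$u_anchor,
    M_max = raw$M_max %||% 10L,
    betas = raw$betas %||% c(0, -0.15, -0.3)
  )
  if (!cfg$baseline_species %in% names(species))
    stop("baseline_species '", cfg$baseline_species, "' not among species")
  if (!all(cfg$target_species %in% names(species)))
    stop("target_species must all be defined under species")
  if (cfg$p_target <= 0 || cfg$p_target >= 1)
    stop("p_target must be in (0, 1)")
  if (any(cfg$betas > 0)) stop("betas must be <= 0")
  class(cfg) <- "scaling_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scaling_config <- function(x, ...) {
  cat("Scaling configuration\n")
  cat("  species :", paste(names(x$species), collapse = ", "), "\n")
  cat("  tissues :", paste(names(x$tissues), collapse = ", "), "\n")
  cat(sprintf("  reference %s; baseline %s; targets %s\n",
              x$reference_species, x$baseline_species,
              paste(x$target_species, collapse = ", ")))
  cat(sprintf("  p_target = %g, u_anchor = %g, betas = %s\n",
              x$p_target, x$u_anchor, paste(x$betas, collapse = ", ")))
  invisible(x)
}
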